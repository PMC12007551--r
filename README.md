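# tmsresponse

Average response models of cortical neurons under transcranial magnetic
stimulation (TMS).

TMS induces an electric field in the cortex; whether a neuron fires
depends on the field magnitude at its soma, the polar angle θ between
the field and the neuron's somato-dendritic axis, and the relative
change of field magnitude with depth Δ|Ẽ| (%/mm). Simulating every
neuron at every cortical location is prohibitively expensive, so this
package characterises a neuron population once over the parameterized
field family

    E(z) = E_soma · (sinθ cosφ, sinθ sinφ, cosθ) · max(Δ|Ẽ|/100 · (z − z_soma) + 1, 0)

and reduces the result to fast surfaces: an averaged threshold map over
(θ, Δ|Ẽ|), recruitment-rate sigmoids f(E) = (1 + e^{−r(E−E₀)})^{−1},
generalized polynomial chaos (gPC) surrogates with Sobol sensitivity
indices, and verification machinery that closes the reduced model
against direct per-neuron simulation.

It is aimed at computational neuroscientists and brain-stimulation
modellers who want a self-contained, scriptable pipeline: SWC
morphologies (with myelination: 1 µm nodes of Ranvier, internode
L/D = 100, terminal L/D = 70), quasipotential field coupling,
a compiled backward-Euler Hodgkin–Huxley cable solver, binary-search
firing thresholds (0.05 V/m precision, ≥3 compartments crossing 0 mV),
and seeded synthetic populations and cortical patches for end-to-end
experiments.

## Worked example

The myelinated ball-and-stick cell is the simplest benchmark: a 20 µm
soma with a straight 760 µm × 15 µm axon along −z. Its firing threshold
under a monophasic pulse follows the cosine law exactly, because only
the field component along the axon drives it:

```r
library(tmsresponse)

cell <- generate_ball_and_stick(760, 15, soma_diameter = 20)
cm   <- discretize(cell, max_len = 20)       # ≤ 20 µm compartments
w    <- make_waveform("monophasic", dt = 5, duration = 1000)

find_threshold(cm, membrane_model(), field_params(theta = 0), w, sim_config())
#> <tms_threshold_result> E_thres = 32.349 V/m (bracket [32.324, 32.373],
#>   12 evaluations, 40 compartment(s) fired)

for (th in c(0, 30, 60)) {
  r <- find_threshold(cm, membrane_model(), field_params(th), w, sim_config())
  cat(sprintf("theta = %2d deg: E_thres = %7.2f V/m, x |cos| = %6.2f\n",
              th, r$threshold, r$threshold * abs(cos(th * pi / 180))))
}
#> theta =  0 deg: E_thres =   32.35 V/m, x |cos| =  32.35
#> theta = 30 deg: E_thres =   37.38 V/m, x |cos| =  32.37
#> theta = 60 deg: E_thres =   64.72 V/m, x |cos| =  32.36
```

The threshold at θ = 0 is 32.35 V/m; multiplying each threshold by
|cos θ| recovers that constant to within the 0.05 V/m search precision —
the straight-axon limit of the cortical-column cosine model
`cosine_model()`, which diverges at θ = 90° while branched cells
(`generate_synthetic_population()`) stay finite there.

A full pipeline builds a threshold grid over (θ, φ, Δ|Ẽ|), averages it
over cells and azimuths, fits recruitment sigmoids, and attaches a gPC
surrogate:

```r
cells <- generate_synthetic_population(5, "basket_like", seed = 42)
g     <- build_threshold_grid(cells, theta_axis = seq(0, 180, 15),
                              phi_axis = seq(0, 330, 30),
                              delta_axis = seq(-100, 100, 20), waveform = w)
map   <- average_map(g)                 # mean ± CI over cells × azimuths
surf  <- recruitment_surface(g)         # r(θ, Δ), E0(θ, Δ)
gpc   <- build_gpc(map, list(param_dist("beta", c(0, 180), c(1.51, 1.56)),
                             param_dist("beta", c(-30, 30), c(13.86, 13.78))),
                   order = 15)
sobol_indices(gpc)                      # basis_size(15, 2) == 136 coefficients
```

`verify_map()` then closes the loop: on a seeded synthetic cortical
patch it compares the bilinear map lookup against the mean of direct
per-neuron threshold simulations with each element's actual field, and
reports NRMSE, MAPE, R² and the 1st/99th percentiles of per-element
relative differences.

A thin command-line dispatcher is installed as `exec/tmsneuro`
(`generate-cells`, `make-waveform`, `compute-threshold`, `build-map`,
`recruitment`, `verify`).

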