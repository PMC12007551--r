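---
title: "Average response models of cortical neurons under TMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average response models of cortical neurons under TMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsresponse)
```

## The modelling problem

Transcranial magnetic stimulation (TMS) induces an electric field in the
cortex that couples into the cable equations of cortical neurons and, at
sufficient intensity, elicits action potentials. Whether a given neuron
fires depends on the local field magnitude, its direction relative to the
neuron's somato-dendritic axis, and how the field magnitude changes with
cortical depth. Simulating every neuron at every cortical location is
enormously expensive, so this package implements the *average response
model* idea: characterise a population of model neurons once, over a
parameterized family of fields, and reduce the result to fast look-up
surfaces — an averaged threshold map and recruitment-rate sigmoids — that
can stand in for direct simulation.

## Field parameterization and coupling

Each neuron sits in a local frame with the somato-dendritic axis along
$z$; the soma is near the origin and the axon descends toward negative
$z$. The field at a point with coordinate $z$ (in mm) is

$$\mathbf{E}(z) = E_{\mathrm{soma}}
\begin{pmatrix} \sin\theta\cos\varphi \\ \sin\theta\sin\varphi \\
\cos\theta \end{pmatrix}
\max\!\Big(\tfrac{\Delta|\tilde E|}{100}\,(z - z_{\mathrm{soma}}) + 1,\; 0\Big),$$

with the polar angle $\theta \in [0, 180]^\circ$ between field and axis,
the azimuth $\varphi \in [0, 360)^\circ$, and the relative change of
magnitude per millimetre $\Delta|\tilde E|$ in %/mm, clamped so the
magnitude never goes negative. The field enters the cable equation as an
extracellular quasipotential obtained by line-integrating
$\mathbf{E}\cdot d\mathbf{l}$ along the neuron tree
(`quasipotentials()`). Two numerical choices matter here:

* the reference potential is fixed to zero at the root (soma)
  compartment — the quasipotential is defined up to a constant, and the
  cable dynamics only see differences;
* each tree edge is integrated with the trapezoid rule on the
  compartment-center coordinates, which is *exact* for this field family
  (the integrand is linear in position along straight edges). Uniform
  fields therefore reproduce $-\mathbf{E}\cdot\mathbf{r}$ to rounding
  error, a property the test suite checks on random branched trees.

## Morphologies

Morphologies are trees of polyline sections in micrometres, read and
written as SWC. SWC has no myelin vocabulary, so three custom type codes
extend it (11 internode, 12 node of Ranvier, 13 myelinated terminal).
Axons are myelinated by registering 1 µm nodes of Ranvier between
internodes of length/diameter ratio 100, with terminal myelinated
sections of L/D = 70; remainders shorter than a node are merged into the
neighbouring internode rather than creating stub sections. Everything is
discretized into compartments of at most 20 µm. Nodes, terminals and
unmyelinated axon are electrically active; internodes are passive with
strongly reduced capacitance and conductance; soma and dendrites are
passive with leak. The actual ion-channel tables of the reference
morphologies live in an external database, so the package uses classic
squid-type Hodgkin–Huxley kinetics with Q10 = 2.3 rate scaling to 37 °C
on active compartments (2.3 is the classic measured gating Q10, and the
resulting kinetics stay well resolved by the 5 µs step) — absolute thresholds are therefore *not* comparable
to published values for reconstructed cells; all structural behaviour
(cosine limits, monotonicity, map and recruitment shapes) is.

### The synthetic population

The reconstructed cortical cells the method was designed for are
external assets, so the package generates stand-in populations
(`generate_synthetic_population()`): a spherical soma, one (pyramidal)
or two (basket) axonal trunks with randomized collaterals that fork into
daughter branches, all myelinated, plus passive dendrites. Collateral
directions are drawn area-uniformly over polar angles 20–160° so that
excitable terminals exist for every field orientation — the property of
real arbors that makes averaged threshold maps smooth and keeps
tangential-field thresholds finite. Pyramidal-like cells are taller than
wide and their main descending axon is treated as a severed projection
axon (its distal end stays passive myelin — the usual treatment of
corticospinal main axons that leave the modelled volume, which would
otherwise dominate as artificial sealed endings); basket-like cells are
near-isotropic and keep
their terminals. The generator emulates the *geometry statistics* that
drive field-coupling — direction coverage, branch lengths, myelination —
and not electrophysiological diversity, synaptic input, or the layer
placement of real cortex; closure results on synthetic patches
demonstrate the reduction machinery, not fidelity to any real cell type.

The unmyelinated axon initial segment length has no single canonical
value; it is exposed as a parameter with a 30 µm default, a typical
initial-segment scale.

## Simulation and thresholds

The branched cable equation with the extracellular drive is integrated
by backward Euler (Hines-ordered elimination, unconditionally stable at
the default 5 µs step over a 1 ms window) with a staggered gating
update: rates are evaluated at the previous voltage, each gate relaxes
exponentially (exactly, for frozen rates), and the voltage step is then
linear. Gates are initialised at their steady state for the −70 mV
initial voltage and each compartment's leak reversal is solved so that
−70 mV is an exact rest point; this replaces a settling pre-run at zero
cost and makes the zero-drive trace constant to rounding error. Gating
rates come from lookup tables (0.02 mV grid) rebuilt only when the time
step or temperature changes, the usual simulator optimisation.

A cell "fires" when at least three compartments cross 0 mV upward; 0 mV
is the conventional spike-detection level and "anywhere on the cell"
resolves the ambiguity of where those compartments may lie. The
threshold `find_threshold()` is the minimum soma-referenced field
magnitude that fires the cell, found by doubling/halving from 50 V/m
(capped at $10^5$ V/m, past which a configuration is reported
not-excitable rather than failing) and bisecting to 0.05 V/m. Because
the drive is linear in the field magnitude, the static quasipotential
profile is computed once per configuration and only rescaled.

## Reduction: maps and recruitment

`build_threshold_grid()` sweeps thresholds over the
$(\theta, \varphi, \Delta|\tilde E|)$ grid (defaults 3°, 6°, 10 %/mm;
the azimuth axis is half-open so 0° and 360° are not double-counted). `average_map()` averages over cells and
azimuths — the assumption being that tangential neuron orientations in
cortex are random — excluding not-excitable sentinels and reporting the
exclusion count per bin. The 95% confidence halfwidth uses the normal
approximation (1.96 standard errors of the mean); the reduced map is
queried by bilinear interpolation with no extrapolation.

The recruitment rate at a bin is the empirical CDF of the pooled
thresholds — the fraction of the population firing at intensity $E$ —
smoothed by least-squares logistic fits
$f(E) = (1 + e^{-r(E - E_0)})^{-1}$ with $r > 0$ enforced,
initialised at $E_0 = \mathrm{median}$, $r = 1.1/\mathrm{IQR}$ (a
logistic distribution matched to the sample spread). The CDF is the
natural formalisation of "integrating the thresholds along the field
magnitude": each threshold marks the intensity at which one more member
of the population joins. `polar_sensitivity_curve()` reads the fitted
surfaces at fixed multiples of a reference intensity and normalizes each
curve to its maximum, mirroring how orientation-selectivity experiments
report motor-evoked-potential amplitudes at fixed fractions of the
resting motor threshold; directional modulation flattens as intensity
grows because the sigmoids saturate.

## Surrogates and sensitivity

`build_gpc()` fits a generalized polynomial chaos expansion of any map
or function over $(\theta, \Delta|\tilde E|)$: orthonormal Legendre
polynomials for uniform inputs and Jacobi polynomials for beta inputs.
Beta$(p, q)$ on $[a, b]$ standardizes to $x \in [-1, 1]$ with weight
$(1-x)^{q-1}(1+x)^{p-1}$, i.e. Jacobi parameters $\alpha = q - 1$,
$\beta = p - 1$ — the convention is stated explicitly because both
orderings circulate, and the test suite verifies orthonormality under
Monte-Carlo sampling of the actual input measure. The default input
distributions are the layer-5 field-parameter fits: beta(1.51, 1.56) on
$[0, 180]^\circ$ for $\theta$ and beta(13.86, 13.78) on $[-30, 30]$ %/mm
for $\Delta|\tilde E|$. Coefficients come from seeded, 2.5×-oversampled
least-squares point collocation (dimension-agnostic, and the natural
companion to arbitrary evaluable targets); the regression condition
number is checked and reported. With an orthonormal basis the Sobol
indices are ratios of summed squared coefficients grouped by
multi-index support; for two inputs the three indices sum to one
identically, which is asserted rather than assumed. A 15th-order,
two-parameter expansion has $\binom{17}{2} = 136$ coefficients.

## Verification

`generate_synthetic_patch()` emulates a cortical region of interest:
elements with random unit normals, field vectors whose polar angles and
decays follow the layer-5 beta distributions, and log-normal magnitude
spread. It replaces the finite-element head model that the full method
uses; it has no spatial correlation structure, no tissue boundaries and
no coil geometry, so it exercises the *reduction* error (parameter
extraction + interpolation + azimuth averaging), not field-modelling
error. `verify_map()` compares, per element, the reduced-model lookup
against the mean of direct per-neuron threshold simulations with the
element's actual field, using the same azimuth set as the map build so
the comparison isolates extraction and interpolation. Reported metrics
are NRMSE, MAPE, the printed-form $R^2$ (which normalizes by the
*reduced* model's variance about its own mean — preserved verbatim
because that is how the reference formula is written) alongside a
conventionally normalized $R^2$, and the 1st/99th percentiles of
per-element relative differences.

Two baselines bound the behaviour: the cortical-column cosine model
$y(\theta) = \hat y / |\cos\theta|$ (default $\hat y = 233.66$ V/m),
which diverges at 90° — returned as an `Inf` sentinel, optionally capped
for plotting — and the myelinated ball-and-stick cell (default axon
760 µm × 15 µm), whose straight axon makes the drive scale exactly with
$\cos\theta$, so its threshold curve follows the cosine law up to solver
tolerance. Branched cells stay finite at 90°, reproducing the
qualitative contrast between full arbors and the cosine baseline.

## Problem sizes and numerical defaults

The package's own test and verification runs use a 3-4-cell basket-like
population, a reduced sweep grid (15° in $\theta$, 45° in $\varphi$,
20 %/mm in $\Delta|\tilde E|$) and patches of 100–150 elements. These
sizes were chosen so a full closure run takes minutes on one core, and
they are sufficient for stable closure statistics (MAPE well under 1%,
relative differences within ±2%) because the closure error is dominated
by the $(\theta, \Delta|\tilde E|)$ interpolation resolution, which is
kept at full scale: the azimuth rotation set is shared between the map
build and the per-element reference simulations, so its size cancels
from the comparison rather than adding sampling noise. Degenerate inputs are handled explicitly: empty bins signal
`tms_empty_bin`, all-sentinel map bins stay sentinels, sub-three-point
sigmoid fits are refused, zero-variance surrogates refuse Sobol indices,
and out-of-range map or surrogate queries raise range errors instead of
extrapolating.

## Known limitations

* Channel kinetics are classic squid-type HH, not the layered cortical
  channel tables of reconstructed models; absolute thresholds are
  internally consistent but not comparable to published cortical values.
* The synthetic cells are geometric stand-ins; population-level claims
  (recruitment order of cell types, absolute Sobol values) require the
  real reconstructions.
* The patch generator draws independent elements; spatially correlated
  field structure over a ROI is out of scope.
* Repetitive protocols, synaptic activity and network effects are not
  modelled; each pulse acts on a quiescent cell.
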