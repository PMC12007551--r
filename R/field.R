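## Parameterized TMS electric fields and their coupling into neurons as
## extracellular quasipotentials.
##
## The field at a point with coordinate z (mm, along the somato-dendritic
## axis) is
##   E(z) = E_soma * (sin th cos ph, sin th sin ph, cos th) *
##          max(delta/100 * (z - z_soma) + 1, 0)
## i.e. direction fixed by the polar angle theta (from +z) and azimuth phi,
## magnitude E_soma at the soma, changing linearly by `delta` percent per mm
## along z and clamped at zero.

#' Field parameterization
#'
#' @param theta polar angle between field and somato-dendritic axis, degrees
#'   in \[0, 180\].
#' @param phi azimuthal angle, degrees in \[0, 360).
#' @param delta relative change of field magnitude per mm along z, %/mm in
#'   \[-100, 100\].
#' @param E_soma field magnitude at the soma, V/m (>= 0); at firing threshold
#'   this is the threshold intensity.
#' @param z_soma soma position on the z-axis, mm.
#' @return an object of class `tms_field_params`.
#' @export
field_params <- function(theta, phi = 0, delta = 0, E_soma = 1, z_soma = 0) {
  if (!is.finite(theta) || theta < 0 || theta > 180)
    tms_stop("tms_config_error", "theta must be in [0, 180] degrees")
  if (!is.finite(phi) || phi < 0 || phi >= 360)
    tms_stop("tms_config_error", "phi must be in [0, 360) degrees")
  if (!is.finite(delta) || abs(delta) > 100)
    tms_stop("tms_config_error", "delta must be in [-100, 100] %%/mm")
  if (!is.finite(E_soma) || E_soma < 0)
    tms_stop("tms_config_error", "E_soma must be >= 0")
  structure(list(theta = theta, phi = phi, delta = delta,
                 E_soma = E_soma, z_soma = z_soma),
            class = "tms_field_params")
}

field_direction <- function(fp) {
  th <- deg2rad(fp$theta); ph <- deg2rad(fp$phi)
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Per-compartment electric field vectors
#'
#' Evaluates the parameterized field at each compartment center.
#'
#' @param cm a `tms_compartment_model`.
#' @param fp a [field_params()] object.
#' @return numeric matrix (compartments x 3), V/m.
#' @export
field_vectors <- function(cm, fp) {
  if (n_compartments(cm) == 0L)
    tms_stop("tms_config_error", "empty compartment model")
  z_mm <- cm$center[, 3] / 1000
  fac <- pmax(fp$delta / 100 * (z_mm - fp$z_soma) + 1, 0)
  outer(fp$E_soma * fac, field_direction(fp))
}

#' Extracellular quasipotentials along the neuron tree
#'
#' Line-integrates the field along tree edges (compartment center to parent
#' center) with the trapezoid rule, which is exact for fields linear in
#' position, and accumulates from the root.  The root (soma) potential is
#' fixed at 0 mV; cable dynamics depend only on potential differences.
#'
#' @param cm a `tms_compartment_model`.
#' @param vectors field vectors from [field_vectors()] (compartments x 3,
#'   V/m).
#' @return numeric vector of static potentials, mV, with attribute
#'   `reference_compartment` (the root index).
#' @export
quasipotentials <- function(cm, vectors) {
  n <- n_compartments(cm)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != n)
    tms_stop("tms_config_error", "field vectors not aligned with compartments")
  if (n > 1L && any(is.na(cm$parent[-1L])))
    tms_stop("tms_topology_error", "compartment model is disconnected")
  phi <- numeric(n)
  for (i in seq_len(n)[-1L]) {
    p <- cm$parent[i]
    dr <- cm$center[i, ] - cm$center[p, ]           # micrometres
    emid <- 0.5 * (vectors[i, ] + vectors[p, ])     # V/m
    ## V/m * um = uV; convert to mV
    phi[i] <- phi[p] - sum(emid * dr) * 1e-3
  }
  attr(phi, "reference_compartment") <- 1L
  phi
}

## ---- pulse waveforms ----------------------------------------------------

#' Generate a normalized TMS pulse waveform
#'
#' Analytic stand-ins for recorded stimulator pulses, normalized to unit
#' peak: `monophasic` is a damped half-sine, `biphasic` a damped cosine over
#' one full cycle, `trapezoidal_monophasic` rises linearly (60 us), holds
#' (30 us) and falls linearly (43.2 us) by default, and `custom` takes
#' samples directly.  All are zero-padded to `duration`.
#'
#' @param kind waveform kind.
#' @param dt sample spacing, microseconds.
#' @param duration total duration, microseconds (coerced to a multiple of
#'   `dt`).
#' @param period,damping_time damped-oscillation parameters, microseconds.
#' @param rise,hold,fall trapezoid timings, microseconds.
#' @param samples numeric vector for `kind = "custom"`.
#' @return an object of class `tms_pulse_waveform` with fields `kind`,
#'   `samples` (max |amplitude| = 1), `dt` and `duration`.
#' @export
make_waveform <- function(kind = c("monophasic", "biphasic",
                                   "trapezoidal_monophasic", "custom"),
                          dt = 5, duration = 1000,
                          period = 280, damping_time = NULL,
                          rise = 60, hold = 30, fall = 43.2,
                          samples = NULL) {
  if (is.character(kind) &&
      !kind[1L] %in% c("monophasic", "biphasic", "trapezoidal_monophasic",
                       "custom"))
    tms_stop("tms_config_error", "unknown waveform kind '%s'", kind[1L])
  kind <- match.arg(kind)
  stopifnot_scalar_pos(dt, "dt")
  nt <- floor(duration / dt + 1e-9) + 1L
  t <- (seq_len(nt) - 1L) * dt
  s <- switch(kind,
    monophasic = {
      tau <- damping_time %||% (period / 4)
      ifelse(t <= period / 2, exp(-t / tau) * sin(2 * pi * t / period), 0)
    },
    biphasic = {
      tau <- damping_time %||% (1.6 * period)
      ifelse(t <= period, exp(-t / tau) * cos(2 * pi * t / period), 0)
    },
    trapezoidal_monophasic = {
      ifelse(t <= rise, t / rise,
             ifelse(t <= rise + hold, 1,
                    ifelse(t <= rise + hold + fall,
                           1 - (t - rise - hold) / fall, 0)))
    },
    custom = {
      if (is.null(samples))
        tms_stop("tms_config_error", "custom waveform requires 'samples'")
      s <- as.numeric(samples)
      length(s) <- nt
      s[is.na(s)] <- 0
      s
    })
  peak <- max(abs(s))
  if (peak == 0) tms_stop("tms_config_error", "waveform is identically zero")
  structure(list(kind = kind, samples = s / peak, dt = dt,
                 duration = (nt - 1L) * dt),
            class = "tms_pulse_waveform")
}

#' @export
print.tms_pulse_waveform <- function(x, ...) {
  cat(sprintf("<tms_pulse_waveform> %s: %d samples, dt = %g us, duration = %g us\n",
              x$kind, length(x$samples), x$dt, x$duration))
  invisible(x)
}

#' Read / write a waveform as CSV
#'
#' Two columns, `time_us` and `amplitude_normalized`; the reader validates
#' strictly increasing uniform time steps and unit peak amplitude.
#'
#' @param path CSV path.
#' @return a `tms_pulse_waveform` (reader) or `path` invisibly (writer).
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_us", "amplitude_normalized") %in% names(d)))
    tms_stop("tms_parse_error",
             "waveform CSV needs columns time_us, amplitude_normalized")
  dt <- diff(d$time_us)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    tms_stop("tms_parse_error", "waveform time axis must be uniform and increasing")
  if (abs(max(abs(d$amplitude_normalized)) - 1) > 1e-6)
    tms_stop("tms_parse_error", "waveform must be normalized to unit peak")
  structure(list(kind = "custom", samples = d$amplitude_normalized,
                 dt = mean(dt), duration = (nrow(d) - 1L) * mean(dt)),
            class = "tms_pulse_waveform")
}

#' @rdname read_waveform_csv
#' @param w a `tms_pulse_waveform`.
#' @export
write_waveform_csv <- function(w, path) {
  t <- (seq_along(w$samples) - 1L) * w$dt
  utils::write.csv(data.frame(time_us = t,
                              amplitude_normalized = w$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Assemble the time-varying extracellular drive
#'
#' Scales the static quasipotential profile by the pulse waveform and
#' amplitude: `phi_e[i, t] = amplitude * samples[t] * static_phi[i]`.
#'
#' @param static_phi static quasipotentials, mV (from [quasipotentials()]
#'   at unit field magnitude).
#' @param w a `tms_pulse_waveform`.
#' @param amplitude scalar field amplitude multiplier.
#' @param cfg optional [sim_config()]; its `dt` must match the waveform's.
#' @return an object of class `tms_drive_potentials`: matrix
#'   (compartments x time steps), mV.
#' @export
assemble_drive <- function(static_phi, w, amplitude, cfg = NULL) {
  if (!is.null(cfg) && abs(cfg$dt - w$dt) > 1e-9)
    tms_stop("tms_config_error",
             "waveform dt (%g us) does not match simulation dt (%g us)",
             w$dt, cfg$dt)
  phi <- outer(as.numeric(static_phi), amplitude * w$samples)
  structure(phi,
            reference_compartment = attr(static_phi, "reference_compartment") %||% 1L,
            dt = w$dt,
            class = "tms_drive_potentials")
}
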