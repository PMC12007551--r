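## Multicompartment cable equation with Hodgkin-Huxley membrane dynamics
## under an extracellular quasipotential drive.  Voltages are integrated by
## backward Euler with a staggered gating update and a Hines-ordered
## elimination on the branched tree (unconditionally stable at the 5 us
## default step).  Gating variables start at their steady state for the
## initial voltage and the leak reversal of every compartment is solved so
## that `v_init` is an exact rest point.

#' Simulation configuration
#'
#' @param dt time step, microseconds.
#' @param duration simulated time, microseconds.
#' @param temperature bath temperature, degrees Celsius (Q10 = 2.3 scaling
#'   of channel kinetics relative to 6.3 C).
#' @param v_init initial/rest voltage, mV.
#' @param ap_voltage action-potential detection voltage, mV (upward
#'   crossing).
#' @param ap_min_compartments minimum number of compartments that must fire.
#' @return an object of class `tms_sim_config`.
#' @export
sim_config <- function(dt = 5, duration = 1000, temperature = 37,
                       v_init = -70, ap_voltage = 0,
                       ap_min_compartments = 3L) {
  stopifnot_scalar_pos(dt, "dt")
  stopifnot_scalar_pos(duration, "duration")
  if (ap_min_compartments < 1)
    tms_stop("tms_config_error", "ap_min_compartments must be >= 1")
  structure(list(dt = dt, duration = duration, temperature = temperature,
                 v_init = v_init, ap_voltage = ap_voltage,
                 ap_min_compartments = as.integer(ap_min_compartments)),
            class = "tms_sim_config")
}

#' Membrane model parameters per compartment role
#'
#' Classic squid-type Hodgkin-Huxley sodium/potassium kinetics (with Q10
#' temperature scaling) on active compartments (nodes of Ranvier, axon
#' terminals, unmyelinated axon); soma and dendrites are passive with leak;
#' myelinated internodes are passive with strongly reduced membrane
#' conductance and capacitance.  Densities are in mS/cm2, capacitances in
#' uF/cm2, axial resistivity in Ohm cm.
#'
#' @param Ra axial resistivity, Ohm cm.
#' @param active list with `cm`, `gna`, `gk`, `gl`, `e_na`, `e_k` for
#'   active compartments.
#' @param soma_dendrite list with `cm`, `g_pas`.
#' @param myelin list with `cm`, `g_pas`.
#' @return an object of class `tms_membrane_model`.
#' @export
membrane_model <- function(Ra = 100,
                           active = list(cm = 1, gna = 120, gk = 36,
                                         gl = 0.3, e_na = 50, e_k = -77),
                           soma_dendrite = list(cm = 1, g_pas = 0.1),
                           myelin = list(cm = 0.02, g_pas = 0.002)) {
  stopifnot_scalar_pos(Ra, "Ra")
  for (nm in c("cm", "gna", "gk", "gl"))
    if (active[[nm]] < 0 || (nm == "cm" && active[[nm]] <= 0))
      tms_stop("tms_config_error", "invalid active membrane parameter '%s'", nm)
  for (l in list(soma_dendrite, myelin))
    if (l$cm <= 0 || l$g_pas < 0)
      tms_stop("tms_config_error", "capacitance must be > 0, conductances >= 0")
  structure(list(Ra = Ra, active = active, soma_dendrite = soma_dendrite,
                 myelin = myelin),
            class = "tms_membrane_model")
}

## HH steady-state gating at voltage v (temperature-independent)
hh_steady <- function(v) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6,
                                 y * (1 - x / y / 2), x / (exp(x / y) - 1))
  am <- 0.1 * vtrap(-(v + 40), 10); bm <- 4 * exp(-(v + 65) / 18)
  ah <- 0.07 * exp(-(v + 65) / 20); bh <- 1 / (1 + exp(-(v + 35) / 10))
  an <- 0.01 * vtrap(-(v + 55), 10); bn <- 0.125 * exp(-(v + 65) / 80)
  list(m = am / (am + bm), h = ah / (ah + bh), n = an / (an + bn))
}

#' Disable active conductances in selected sections
#'
#' Marks compartments of the given section indices as passive (used, e.g.,
#' to silence a main axon while keeping collaterals excitable).
#'
#' @param cm a `tms_compartment_model`.
#' @param section_ids integer indices into the morphology's section list.
#' @return the modified compartment model.
#' @export
disable_sections <- function(cm, section_ids) {
  cm$role[cm$section %in% section_ids & cm$role == "active_node"] <-
    "passive_soma_dendrite"
  cm
}

## Precompute per-compartment solver arrays (areas in cm2, conductances in
## uS, capacitance in uF); leak reversals are solved so that v_init is an
## exact rest point of every compartment.
build_sim_arrays <- function(cm, mm, cfg) {
  n <- n_compartments(cm)
  d_cm <- cm$diam * 1e-4
  L_cm <- cm$length * 1e-4
  area <- ifelse(cm$is_sphere, pi * d_cm^2, pi * d_cm * L_cm)
  active <- cm$role == "active_node"
  role_cm <- ifelse(active, mm$active$cm,
                    ifelse(cm$role == "passive_myelin", mm$myelin$cm,
                           mm$soma_dendrite$cm))
  role_gp <- ifelse(active, mm$active$gl,
                    ifelse(cm$role == "passive_myelin", mm$myelin$g_pas,
                           mm$soma_dendrite$g_pas))
  cap <- role_cm * area                      # uF
  g_pas <- role_gp * area * 1000             # uS
  gna <- ifelse(active, mm$active$gna, 0) * area * 1000
  gk <- ifelse(active, mm$active$gk, 0) * area * 1000
  ## leak reversal balancing the steady-state active currents at v_init
  ss <- hh_steady(cfg$v_init)
  e_pas <- rep(cfg$v_init, n)
  bal <- active & role_gp > 0
  if (any(bal)) {
    i_act <- mm$active$gna * ss$m^3 * ss$h * (cfg$v_init - mm$active$e_na) +
      mm$active$gk * ss$n^4 * (cfg$v_init - mm$active$e_k)
    e_pas[bal] <- cfg$v_init + i_act / role_gp[bal]
  }
  ## axial conductances (uS) between each compartment and its parent
  rhalf <- mm$Ra * (L_cm / 2) / (pi * (d_cm / 2)^2) / 1e6   # MOhm
  g_ax <- numeric(n)
  for (i in seq_len(n)[-1L]) {
    p <- cm$parent[i]
    g_ax[i] <- 1 / (rhalf[i] + rhalf[p])
  }
  qt <- 2.3^((cfg$temperature - 6.3) / 10)
  list(parent = ifelse(is.na(cm$parent), -1L, cm$parent - 1L),
       g_ax = g_ax, cap = cap, g_pas = g_pas, e_pas = e_pas,
       gna = gna, gk = gk,
       e_na = mm$active$e_na, e_k = mm$active$e_k,
       active = active, qt = qt)
}

#' Integrate the cable equation under an extracellular drive
#'
#' @param cm a `tms_compartment_model`.
#' @param mm a [membrane_model()].
#' @param drive a `tms_drive_potentials` matrix (compartments x time steps,
#'   mV) from [assemble_drive()].
#' @param cfg a [sim_config()].
#' @return an object of class `tms_voltage_traces`: matrix `v`
#'   (compartments x time steps, mV) plus `dt` (microseconds).
#' @export
simulate_cable <- function(cm, mm, drive, cfg = sim_config()) {
  a <- build_sim_arrays(cm, mm, cfg)
  phi <- unclass(drive)
  if (nrow(phi) != n_compartments(cm))
    tms_stop("tms_config_error", "drive rows must match compartment count")
  res <- cable_solve_cpp(a$parent, a$g_ax, a$cap, a$g_pas, a$e_pas,
                         a$gna, a$gk, a$e_na, a$e_k, a$active,
                         phi, numeric(0), numeric(0), 0,
                         cfg$dt / 1000, cfg$v_init, cfg$ap_voltage, a$qt,
                         TRUE)
  if (res$diverged >= 0)
    tms_stop("tms_divergence_error",
             "non-finite voltages at time step %d", res$diverged)
  structure(list(v = res$v, dt = cfg$dt,
                 fired = as.logical(res$fired)),
            class = "tms_voltage_traces")
}

#' @export
print.tms_voltage_traces <- function(x, ...) {
  cat(sprintf("<tms_voltage_traces> %d compartments x %d steps (dt = %g us)\n",
              nrow(x$v), ncol(x$v), x$dt))
  cat(sprintf("  voltage range: [%.1f, %.1f] mV; %d compartment(s) crossed AP level\n",
              min(x$v), max(x$v), sum(x$fired)))
  invisible(x)
}

#' @export
plot.tms_voltage_traces <- function(x, compartments = NULL, ...) {
  idx <- compartments %||% unique(round(seq(1, nrow(x$v), length.out = 6)))
  t <- (seq_len(ncol(x$v)) - 1) * x$dt
  graphics::matplot(t, t(x$v[idx, , drop = FALSE]), type = "l", lty = 1,
                    xlab = "time (us)", ylab = "membrane potential (mV)", ...)
  invisible(x)
}

#' Detect action potentials in voltage traces
#'
#' A compartment counts as firing if its voltage crosses `ap_voltage`
#' upward at least once; the cell fires if at least `ap_min_compartments`
#' compartments do.
#'
#' @param tr a `tms_voltage_traces`.
#' @param cfg a [sim_config()].
#' @return list with `fired` (logical) and `compartments` (indices).
#' @export
detect_action_potentials <- function(tr, cfg = sim_config()) {
  v <- tr$v
  nt <- ncol(v)
  crossed <- rowSums(v[, -1L, drop = FALSE] >= cfg$ap_voltage &
                       v[, -nt, drop = FALSE] < cfg$ap_voltage) > 0
  idx <- which(crossed)
  list(fired = length(idx) >= cfg$ap_min_compartments, compartments = idx)
}

## fast fire test used by the threshold search (no trace allocation)
fires_at <- function(arrays, static_phi, w, amplitude, cfg) {
  res <- cable_solve_cpp(arrays$parent, arrays$g_ax, arrays$cap,
                         arrays$g_pas, arrays$e_pas, arrays$gna, arrays$gk,
                         arrays$e_na, arrays$e_k, arrays$active,
                         matrix(0, 0, 0), as.numeric(static_phi), w$samples,
                         amplitude, cfg$dt / 1000, cfg$v_init,
                         cfg$ap_voltage, arrays$qt, FALSE,
                         cfg$ap_min_compartments)
  if (res$diverged >= 0)
    tms_stop("tms_divergence_error",
             "non-finite voltages at time step %d (amplitude %g)",
             res$diverged, amplitude)
  fired <- which(res$fired)
  list(fired = length(fired) >= cfg$ap_min_compartments,
       compartments = fired)
}

#' Find the firing threshold by binary search
#'
#' Determines the minimum soma-referenced field magnitude (V/m) for which
#' the cell elicits action potentials in at least `ap_min_compartments`
#' compartments.  A bracket is established by amplitude doubling (or
#' halving) from `bracket_start`, then bisected to `precision`.
#'
#' @param cm a `tms_compartment_model`.
#' @param mm a [membrane_model()].
#' @param fp a [field_params()] giving direction and decay; its `E_soma` is
#'   ignored (the magnitude is what is searched).
#' @param w a `tms_pulse_waveform`.
#' @param cfg a [sim_config()].
#' @param precision bracket width at termination, V/m.
#' @param bracket_start initial amplitude guess, V/m.
#' @param cap amplitude at which the cell is declared not excitable, V/m.
#' @return an object of class `tms_threshold_result` with fields
#'   `threshold` (V/m; `NA` with `not_excitable = TRUE` when the cap is
#'   hit), `bracket`, `fired_compartments`, `n_evaluations`.
#' @export
find_threshold <- function(cm, mm, fp, w, cfg = sim_config(),
                           precision = 0.05, bracket_start = 50,
                           cap = 1e5) {
  stopifnot_scalar_pos(precision, "precision")
  arrays <- build_sim_arrays(cm, mm, cfg)
  ## without active membrane no action potential can occur at any amplitude
  if (!any(arrays$active))
    return(structure(list(threshold = NA_real_, not_excitable = TRUE,
                          bracket = c(NA_real_, NA_real_),
                          fired_compartments = integer(0),
                          n_evaluations = 0L),
                     class = "tms_threshold_result"))
  fp1 <- field_params(fp$theta, fp$phi, fp$delta, E_soma = 1,
                      z_soma = fp$z_soma)
  static_phi <- quasipotentials(cm, field_vectors(cm, fp1))
  neval <- 0L
  test <- function(a) {
    neval <<- neval + 1L
    fires_at(arrays, static_phi, w, a, cfg)
  }
  lo <- NA_real_; hi <- NA_real_
  r0 <- test(bracket_start)
  if (r0$fired) {
    hi <- bracket_start; lo <- bracket_start / 2
    while (lo > precision && test(lo)$fired) {
      hi <- lo; lo <- lo / 2
    }
    if (lo <= precision) lo <- 0
  } else {
    lo <- bracket_start; hi <- 2 * bracket_start
    repeat {
      if (hi > cap)
        return(structure(list(threshold = NA_real_, not_excitable = TRUE,
                              bracket = c(lo, NA), fired_compartments = integer(0),
                              n_evaluations = neval),
                         class = "tms_threshold_result"))
      if (test(hi)$fired) break
      lo <- hi; hi <- 2 * hi
    }
  }
  while (hi - lo > precision) {
    mid <- (hi + lo) / 2
    if (test(mid)$fired) hi <- mid else lo <- mid
  }
  ## full-window evaluation at hi for the complete fired-compartment set
  neval <- neval + 1L
  res_hi <- cable_solve_cpp(arrays$parent, arrays$g_ax, arrays$cap,
                            arrays$g_pas, arrays$e_pas, arrays$gna,
                            arrays$gk, arrays$e_na, arrays$e_k,
                            arrays$active, matrix(0, 0, 0),
                            as.numeric(static_phi), w$samples, hi,
                            cfg$dt / 1000, cfg$v_init, cfg$ap_voltage,
                            arrays$qt, FALSE, 0L)
  fired <- which(res_hi$fired)
  structure(list(threshold = (lo + hi) / 2, not_excitable = FALSE,
                 bracket = c(lo, hi), fired_compartments = fired,
                 n_evaluations = neval),
            class = "tms_threshold_result")
}

#' @export
print.tms_threshold_result <- function(x, ...) {
  if (isTRUE(x$not_excitable)) {
    cat("<tms_threshold_result> not excitable (cap reached after",
        x$n_evaluations, "evaluations)\n")
  } else {
    cat(sprintf("<tms_threshold_result> E_thres = %.3f V/m (bracket [%.3f, %.3f], %d evaluations, %d compartment(s) fired)\n",
                x$threshold, x$bracket[1], x$bracket[2], x$n_evaluations,
                length(x$fired_compartments)))
  }
  invisible(x)
}

#' Export a single compartment's voltage trace as CSV
#'
#' @param tr a `tms_voltage_traces`.
#' @param compartment compartment index.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(tr, compartment, path) {
  t <- (seq_len(ncol(tr$v)) - 1) * tr$dt
  utils::write.csv(data.frame(time_us = t, v_mV = tr$v[compartment, ]),
                   path, row.names = FALSE)
  invisible(path)
}
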