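## Threshold grids over (theta, phi, delta) and their reduction to the
## averaged threshold map over (theta, delta).  Azimuthal rotation is
## implemented by rotating the field about z (equivalent to rotating the
## cell); the reduced map averages over cells and azimuths under the
## assumption that tangential neuron orientations in the cortex are random.

#' Sweep firing thresholds over a (theta, phi, delta) grid
#'
#' Runs [find_threshold()] for every cell and every field configuration.
#' Not-excitable configurations are stored as `NA` and propagated without
#' aborting the sweep.
#'
#' @param cells list of `tms_morphology` or `tms_compartment_model`
#'   objects.
#' @param theta_axis polar angles, degrees (default 0:3:180).
#' @param phi_axis azimuths, degrees, half-open \[0, 360) (default 0:6:354).
#' @param delta_axis field decays, %/mm (default -100:10:100).
#' @param waveform a `tms_pulse_waveform`.
#' @param cfg a [sim_config()].
#' @param mm a [membrane_model()].
#' @param precision binary-search precision, V/m.
#' @param z_soma soma z position, mm.
#' @param max_len discretization limit for morphologies, micrometres.
#' @param progress print a line per cell.
#' @return an object of class `tms_threshold_grid`: `thresholds` array
#'   \[cells x theta x phi x delta\] (V/m, `NA` = not excitable) plus axes
#'   and provenance metadata.
#' @export
build_threshold_grid <- function(cells,
                                 theta_axis = seq(0, 180, by = 3),
                                 phi_axis = seq(0, 354, by = 6),
                                 delta_axis = seq(-100, 100, by = 10),
                                 waveform = make_waveform("monophasic"),
                                 cfg = sim_config(),
                                 mm = membrane_model(),
                                 precision = 0.05,
                                 z_soma = 0,
                                 max_len = 20,
                                 progress = FALSE) {
  if (length(cells) < 1L)
    tms_stop("tms_config_error", "at least one cell is required")
  if (any(theta_axis < 0 | theta_axis > 180))
    tms_stop("tms_config_error", "theta_axis must lie in [0, 180]")
  if (any(phi_axis < 0 | phi_axis >= 360))
    tms_stop("tms_config_error", "phi_axis must lie in [0, 360)")
  if (any(abs(delta_axis) > 100))
    tms_stop("tms_config_error", "delta_axis must lie in [-100, 100]")
  cms <- lapply(cells, function(c)
    if (inherits(c, "tms_compartment_model")) c else discretize(c, max_len))
  th <- array(NA_real_,
              dim = c(length(cms), length(theta_axis), length(phi_axis),
                      length(delta_axis)))
  for (ci in seq_along(cms)) {
    cm <- cms[[ci]]
    for (ti in seq_along(theta_axis))
      for (pi_ in seq_along(phi_axis)) {
        warm <- NA_real_   # warm-start bracket from the neighbouring bin
        for (di in seq_along(delta_axis)) {
          fp <- field_params(theta_axis[ti], phi_axis[pi_],
                             delta_axis[di], 1, z_soma)
          res <- find_threshold(cm, mm, fp, waveform, cfg,
                                precision = precision,
                                bracket_start = if (is.finite(warm)) warm else 50)
          if (!isTRUE(res$not_excitable)) {
            th[ci, ti, pi_, di] <- res$threshold
            warm <- res$threshold
          } else warm <- NA_real_
        }
      }
    if (progress)
      message(sprintf("cell %d/%d (%s) done", ci, length(cms), cm$cell_id))
  }
  structure(list(thresholds = th,
                 theta_axis = theta_axis, phi_axis = phi_axis,
                 delta_axis = delta_axis,
                 cell_ids = vapply(cms, function(c) c$cell_id, character(1)),
                 waveform_kind = waveform$kind,
                 precision = precision),
            class = "tms_threshold_grid")
}

#' @export
print.tms_threshold_grid <- function(x, ...) {
  d <- dim(x$thresholds)
  cat(sprintf("<tms_threshold_grid> %d cell(s) x %d theta x %d phi x %d delta (%s waveform)\n",
              d[1], d[2], d[3], d[4], x$waveform_kind))
  cat(sprintf("  thresholds: %.2f-%.2f V/m, %d not excitable\n",
              min(x$thresholds, na.rm = TRUE), max(x$thresholds, na.rm = TRUE),
              sum(is.na(x$thresholds))))
  invisible(x)
}

#' Reduce a threshold grid to the averaged threshold map
#'
#' Means over cells and azimuths per (theta, delta) bin, excluding
#' not-excitable sentinels (the excluded fraction is reported), with a
#' normal-approximation 95% confidence halfwidth of the mean
#' (1.96 standard errors).
#'
#' @param g a `tms_threshold_grid`.
#' @return an object of class `tms_average_threshold_map` with matrices
#'   `mean`, `ci95_halfwidth`, `n_samples`, `n_excluded` over
#'   \[theta x delta\].
#' @export
average_map <- function(g) {
  th <- g$thresholds
  mean_m <- apply(th, c(2, 4), function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else mean(x)
  })
  ci_m <- apply(th, c(2, 4), function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) NA_real_ else 1.96 * stats::sd(x) / sqrt(length(x))
  })
  n_m <- apply(th, c(2, 4), function(x) sum(is.finite(x)))
  excl <- apply(th, c(2, 4), function(x) sum(!is.finite(x)))
  structure(list(theta_axis = g$theta_axis, delta_axis = g$delta_axis,
                 mean = mean_m, ci95_halfwidth = ci_m,
                 n_samples = n_m, n_excluded = excl,
                 waveform_kind = g$waveform_kind,
                 ci_rule = "normal approximation, 1.96 * SE of the mean"),
            class = "tms_average_threshold_map")
}

#' @export
print.tms_average_threshold_map <- function(x, ...) {
  cat(sprintf("<tms_average_threshold_map> %d theta x %d delta (%s waveform)\n",
              length(x$theta_axis), length(x$delta_axis), x$waveform_kind))
  cat(sprintf("  mean threshold: %.2f-%.2f V/m; %d bin(s) with exclusions\n",
              min(x$mean, na.rm = TRUE), max(x$mean, na.rm = TRUE),
              sum(x$n_excluded > 0)))
  invisible(x)
}

#' @export
plot.tms_average_threshold_map <- function(x, ...) {
  graphics::image(x$theta_axis, x$delta_axis, x$mean,
                  xlab = "polar angle theta (deg)",
                  ylab = "field change delta (%/mm)",
                  main = "average threshold (V/m)", ...)
  invisible(x)
}

#' Bilinear interpolation of the averaged threshold map
#'
#' Exact at grid nodes and linear along axes; queries outside the axis
#' ranges raise a range error (no extrapolation).
#'
#' @param m a `tms_average_threshold_map`.
#' @param theta,delta query coordinates (vectors of equal length or length
#'   1, recycled).
#' @return interpolated thresholds, V/m.
#' @export
interpolate_threshold <- function(m, theta, delta) {
  k <- max(length(theta), length(delta))
  theta <- rep_len(theta, k); delta <- rep_len(delta, k)
  tx <- m$theta_axis; dx <- m$delta_axis
  if (any(theta < min(tx) | theta > max(tx)))
    tms_stop("tms_range_error", "theta outside map range [%g, %g]",
             min(tx), max(tx))
  if (any(delta < min(dx) | delta > max(dx)))
    tms_stop("tms_range_error", "delta outside map range [%g, %g]",
             min(dx), max(dx))
  ti <- pmin(pmax(findInterval(theta, tx), 1L), length(tx) - 1L)
  di <- pmin(pmax(findInterval(delta, dx), 1L), length(dx) - 1L)
  ft <- (theta - tx[ti]) / (tx[ti + 1L] - tx[ti])
  fd <- (delta - dx[di]) / (dx[di + 1L] - dx[di])
  v00 <- m$mean[cbind(ti, di)]
  v10 <- m$mean[cbind(ti + 1L, di)]
  v01 <- m$mean[cbind(ti, di + 1L)]
  v11 <- m$mean[cbind(ti + 1L, di + 1L)]
  (1 - ft) * (1 - fd) * v00 + ft * (1 - fd) * v10 +
    (1 - ft) * fd * v01 + ft * fd * v11
}

#' Export an averaged threshold map as CSV plus JSON sidecar metadata
#'
#' @param m a `tms_average_threshold_map`.
#' @param path CSV path; metadata is written next to it as `<path>.json`.
#' @export
write_map_csv <- function(m, path) {
  d <- expand.grid(theta_deg = m$theta_axis, delta_pct_per_mm = m$delta_axis)
  d$mean_threshold_vpm <- as.vector(m$mean)
  d$ci95_halfwidth_vpm <- as.vector(m$ci95_halfwidth)
  d$n_samples <- as.vector(m$n_samples)
  d$n_excluded <- as.vector(m$n_excluded)
  utils::write.csv(d, path, row.names = FALSE)
  meta <- list(units = list(threshold = "V/m", theta = "degrees",
                            delta = "%/mm"),
               waveform_kind = m$waveform_kind, ci_rule = m$ci_rule,
               package_version = as.character(utils::packageVersion("tmsresponse")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
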