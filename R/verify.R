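## Verification of the reduced average-response model against direct
## per-neuron reference simulation on synthetic cortical patches, plus the
## cortical-column cosine and ball-and-stick baselines.

#' Generate a synthetic cortical patch
#'
#' Stand-in for a cortical region of interest: each surface element carries
#' a random unit normal, an electric field vector at the layer (with the
#' requested polar-angle distribution relative to the normal and a
#' log-normal magnitude spread around `intensity_scale`), and a relative
#' field decay along the normal.
#'
#' @param n_elements number of elements (>= 1).
#' @param theta_dist [param_dist()] for the polar angle, degrees (default:
#'   beta(1.51, 1.56) on \[0, 180\]).
#' @param delta_dist [param_dist()] for the field decay, %/mm (default:
#'   beta(13.86, 13.78) on \[-30, 30\]).
#' @param intensity_scale median field magnitude per unit stimulator
#'   intensity, V/m.
#' @param magnitude_sdlog log-normal spread of the field magnitudes.
#' @param seed integer seed.
#' @return an object of class `tms_synthetic_patch` with a data frame of
#'   elements (`normal`, `field_at_layer`, `decay_along_normal`,
#'   `position`).
#' @export
generate_synthetic_patch <- function(n_elements,
                                     theta_dist = param_dist("beta", c(0, 180),
                                                             c(1.51, 1.56)),
                                     delta_dist = param_dist("beta", c(-30, 30),
                                                             c(13.86, 13.78)),
                                     intensity_scale = 100,
                                     magnitude_sdlog = 0.2,
                                     seed = 1L) {
  if (n_elements < 1) tms_stop("tms_config_error", "n_elements must be >= 1")
  for (d in list(theta_dist, delta_dist))
    if (!inherits(d, "tms_parameter_distribution"))
      tms_stop("tms_config_error", "distributions must be param_dist objects")
  with_seed(seed, {
    theta <- sample_parameters(list(theta_dist), n_elements,
                               seed = sample.int(2^30, 1))[, 1]
    delta <- sample_parameters(list(delta_dist), n_elements,
                               seed = sample.int(2^30, 1))[, 1]
    ## isotropic unit normals
    z <- stats::runif(n_elements, -1, 1)
    az <- stats::runif(n_elements, 0, 2 * pi)
    normals <- cbind(sqrt(1 - z^2) * cos(az), sqrt(1 - z^2) * sin(az), z)
    mags <- intensity_scale * stats::rlnorm(n_elements, 0, magnitude_sdlog)
    psi <- stats::runif(n_elements, 0, 2 * pi)
    fields <- matrix(NA_real_, n_elements, 3)
    for (i in seq_len(n_elements)) {
      nrm <- normals[i, ]
      ## orthonormal frame (u, w) perpendicular to the normal
      ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * nrm) * nrm; u <- u / sqrt(sum(u^2))
      w <- c(nrm[2] * u[3] - nrm[3] * u[2],
             nrm[3] * u[1] - nrm[1] * u[3],
             nrm[1] * u[2] - nrm[2] * u[1])
      th <- deg2rad(theta[i])
      dirv <- cos(th) * nrm + sin(th) * (cos(psi[i]) * u + sin(psi[i]) * w)
      fields[i, ] <- mags[i] * dirv
    }
    pos <- matrix(stats::runif(3 * n_elements, -10, 10), ncol = 3)
    structure(list(normal = normals, field_at_layer = fields,
                   decay_along_normal = delta, position = pos,
                   theta_true = theta, seed = seed),
              class = "tms_synthetic_patch")
  })
}

#' @export
print.tms_synthetic_patch <- function(x, ...) {
  cat(sprintf("<tms_synthetic_patch> %d elements (seed %d)\n",
              nrow(x$normal), x$seed))
  cat(sprintf("  |field|: %.1f-%.1f V/m; decay: %.1f-%.1f %%/mm\n",
              min(sqrt(rowSums(x$field_at_layer^2))),
              max(sqrt(rowSums(x$field_at_layer^2))),
              min(x$decay_along_normal), max(x$decay_along_normal)))
  invisible(x)
}

#' Extract (theta, delta) field parameters of a patch element
#'
#' The polar angle is the angle between the field and the element normal;
#' the decay is the percentage change of field magnitude per mm along the
#' normal, estimated from two probe magnitudes straddling the layer (the
#' element's linear decay evaluated at the probe offsets).
#'
#' @param patch a `tms_synthetic_patch`.
#' @param i element index.
#' @param probe_offsets two offsets along the normal, mm, straddling 0.
#' @return list with `theta` (degrees) and `delta` (%/mm).
#' @export
extract_field_params <- function(patch, i, probe_offsets = c(-0.1, 0.1)) {
  if (length(probe_offsets) != 2L || probe_offsets[1] >= 0 ||
      probe_offsets[2] <= 0)
    tms_stop("tms_config_error", "probe offsets must straddle the layer")
  f <- patch$field_at_layer[i, ]
  nrm <- patch$normal[i, ]
  m0 <- sqrt(sum(f^2))
  if (m0 == 0)
    tms_stop("tms_undefined_angle", "zero-magnitude field at element %d", i)
  cth <- sum(f * nrm) / m0
  theta <- acos(min(max(cth, -1), 1)) * 180 / pi
  dec <- patch$decay_along_normal[i]
  mag_at <- function(s) m0 * (1 + dec / 100 * s)
  delta <- (mag_at(probe_offsets[2]) - mag_at(probe_offsets[1])) /
    (diff(probe_offsets) * m0) * 100
  list(theta = theta, delta = delta)
}

#' Agreement metrics between reference and reduced-model thresholds
#'
#' NRMSE = sqrt(sum((y_ref - y)^2)) / sqrt(sum(y_ref^2)); MAPE = mean
#' |(y_ref - y)/y_ref|; the primary R^2 normalizes the residual sum of
#' squares by the variance of the reduced model about its own mean; a
#' conventional R^2 (normalizing by the reference variance) is reported
#' alongside.
#'
#' @param y_ref reference values.
#' @param y reduced-model values (same length).
#' @return list with `nrmse`, `mape`, `r2`, `r2_conventional`.
#' @export
agreement_metrics <- function(y_ref, y) {
  if (length(y_ref) != length(y) || length(y) < 1L)
    tms_stop("tms_config_error", "inputs must have equal length >= 1")
  if (any(y_ref == 0))
    tms_warn("tms_undefined_metric", "zero reference values; MAPE undefined terms dropped")
  nrmse <- sqrt(sum((y_ref - y)^2)) / sqrt(sum(y_ref^2))
  ok <- y_ref != 0
  mape <- mean(abs((y_ref[ok] - y[ok]) / y_ref[ok]))
  sse <- sum((y - y_ref)^2)
  den_model <- sum((y - mean(y))^2)
  den_ref <- sum((y_ref - mean(y_ref))^2)
  r2 <- if (length(y) < 2L || den_model == 0) {
    tms_warn("tms_undefined_metric", "R2 undefined (degenerate variance)")
    NA_real_
  } else 1 - sse / den_model
  r2c <- if (length(y) < 2L || den_ref == 0) NA_real_ else 1 - sse / den_ref
  list(nrmse = nrmse, mape = mape, r2 = r2, r2_conventional = r2c)
}

#' Verify an averaged threshold map against direct reference simulation
#'
#' For every patch element the reference threshold is the mean over cells
#' and azimuth rotations of direct [find_threshold()] runs with the
#' element's actual field parameters; the reduced-model threshold is the
#' bilinear map lookup at the element's extracted (theta, delta).  The same
#' azimuth set as the map build isolates field-parameter extraction and
#' interpolation as the only error sources.
#'
#' @param patch a `tms_synthetic_patch`.
#' @param map a `tms_average_threshold_map`.
#' @param cells list of morphologies or compartment models (the population
#'   the map was built from).
#' @param waveform a `tms_pulse_waveform`.
#' @param cfg a [sim_config()].
#' @param mm a [membrane_model()].
#' @param phi_set azimuth rotation set, degrees.
#' @param precision threshold search precision, V/m.
#' @param progress print progress every 50 elements.
#' @return an object of class `tms_verification_report`: metrics, the
#'   {p1, p99} percentiles of per-element relative differences (%), the
#'   per-element table, and the count of out-of-range elements.
#' @export
verify_map <- function(patch, map, cells, waveform = make_waveform("monophasic"),
                       cfg = sim_config(), mm = membrane_model(),
                       phi_set = seq(0, 330, by = 30), precision = 0.05,
                       progress = FALSE) {
  cms <- lapply(cells, function(c)
    if (inherits(c, "tms_compartment_model")) c else discretize(c))
  n <- nrow(patch$normal)
  pars <- lapply(seq_len(n), function(i) extract_field_params(patch, i))
  theta_e <- vapply(pars, `[[`, numeric(1), "theta")
  delta_e <- vapply(pars, `[[`, numeric(1), "delta")
  in_range <- theta_e >= min(map$theta_axis) & theta_e <= max(map$theta_axis) &
    delta_e >= min(map$delta_axis) & delta_e <= max(map$delta_axis)
  if (!any(in_range))
    tms_stop("tms_config_error", "all patch elements outside the map range")
  reduced <- rep(NA_real_, n)
  reduced[in_range] <- interpolate_threshold(map, theta_e[in_range],
                                             delta_e[in_range])
  reference <- rep(NA_real_, n)
  for (i in which(in_range)) {
    vals <- numeric(0)
    for (cm in cms) {
      warm <- NA_real_
      for (ph in phi_set) {
        res <- find_threshold(cm, mm,
                              field_params(theta_e[i], ph, delta_e[i]),
                              waveform, cfg, precision = precision,
                              bracket_start = if (is.finite(warm)) warm else 50)
        if (!isTRUE(res$not_excitable)) {
          vals <- c(vals, res$threshold)
          warm <- res$threshold
        } else warm <- NA_real_
      }
    }
    reference[i] <- if (length(vals)) mean(vals) else NA_real_
    if (progress && i %% 50 == 0)
      message(sprintf("element %d/%d done", i, n))
  }
  ok <- in_range & is.finite(reference) & is.finite(reduced)
  rel_diff <- 100 * (reduced[ok] - reference[ok]) / reference[ok]
  metrics <- agreement_metrics(reference[ok], reduced[ok])
  mag <- sqrt(rowSums(patch$field_at_layer^2))
  structure(list(nrmse = metrics$nrmse, mape = metrics$mape,
                 r2 = metrics$r2, r2_conventional = metrics$r2_conventional,
                 rel_diff_percentiles = stats::quantile(rel_diff,
                                                        c(0.01, 0.99),
                                                        names = FALSE),
                 rel_diff = rel_diff,
                 elements = data.frame(theta = theta_e, delta = delta_e,
                                       reference = reference,
                                       reduced = reduced,
                                       intensity_reference = reference / mag,
                                       intensity_reduced = reduced / mag),
                 n_out_of_range = sum(!in_range)),
            class = "tms_verification_report")
}

#' @export
print.tms_verification_report <- function(x, ...) {
  cat("<tms_verification_report>\n")
  cat(sprintf("  NRMSE = %.4f, MAPE = %.4f, R2 = %.4f (conventional %.4f)\n",
              x$nrmse, x$mape, x$r2, x$r2_conventional))
  cat(sprintf("  relative differences: p1 = %.2f%%, p99 = %.2f%% (n = %d, %d out of range)\n",
              x$rel_diff_percentiles[1], x$rel_diff_percentiles[2],
              length(x$rel_diff), x$n_out_of_range))
  invisible(x)
}

#' Write a verification report as JSON plus per-element CSV
#'
#' @param report a `tms_verification_report`.
#' @param path JSON path; per-element differences go to `<path>.csv`.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(nrmse = report$nrmse, mape = report$mape,
                            r2 = report$r2,
                            r2_conventional = report$r2_conventional,
                            rel_diff_p1 = report$rel_diff_percentiles[1],
                            rel_diff_p99 = report$rel_diff_percentiles[2],
                            n_out_of_range = report$n_out_of_range),
                       path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$elements, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' Cortical-column cosine baseline
#'
#' The baseline assuming only the field component along the cortical
#' normal stimulates: y(theta) = y_hat / |cos(theta)|, diverging at 90
#' degrees (returned as `Inf`, or capped when `cap` is finite).
#'
#' @param theta polar angles, degrees in \[0, 180\].
#' @param y_hat threshold at theta = 0, V/m.
#' @param cap optional finite cap for plotting.
#' @return thresholds, V/m (possibly `Inf`).
#' @export
cosine_model <- function(theta, y_hat = 233.66, cap = Inf) {
  if (any(theta < 0 | theta > 180))
    tms_stop("tms_range_error", "theta must be in [0, 180] degrees")
  stopifnot_scalar_pos(y_hat, "y_hat")
  c_ <- abs(cos(deg2rad(theta)))
  y <- ifelse(c_ < 1e-12, Inf, y_hat / c_)
  pmin(y, cap)
}

#' Ball-and-stick threshold curve over theta
#'
#' Builds the myelinated ball-and-stick cell and runs the threshold search
#' per polar angle at delta = 0.  For a straight axon the drive scales with
#' cos(theta), so the curve follows the cosine model up to solver
#' tolerance; near 90 degrees the cap may be hit (not-excitable `NA`).
#'
#' @param axon_length,axon_diameter axon geometry, micrometres (defaults
#'   760 and 15).
#' @param theta_axis polar angles, degrees.
#' @param waveform a `tms_pulse_waveform`.
#' @param cfg a [sim_config()].
#' @param mm a [membrane_model()].
#' @param soma_diameter soma diameter, micrometres.
#' @param precision threshold search precision, V/m.
#' @return data frame with `theta` and `threshold` (V/m, `NA` when not
#'   excitable).
#' @export
ball_and_stick_curve <- function(axon_length = 760, axon_diameter = 15,
                                 theta_axis = seq(0, 180, by = 15),
                                 waveform = make_waveform("monophasic"),
                                 cfg = sim_config(), mm = membrane_model(),
                                 soma_diameter = 20, precision = 0.05) {
  cm <- discretize(generate_ball_and_stick(axon_length, axon_diameter,
                                           soma_diameter = soma_diameter))
  th <- vapply(theta_axis, function(t) {
    res <- find_threshold(cm, mm, field_params(t, 0, 0), waveform, cfg,
                          precision = precision)
    if (isTRUE(res$not_excitable)) NA_real_ else res$threshold
  }, numeric(1))
  data.frame(theta = theta_axis, threshold = th)
}
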