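## Recruitment-rate surfaces: the fraction of the neuron population firing
## at field intensity E, per (theta, delta) bin.  The discrete behavior is
## the empirical CDF of the pooled per-cell, per-azimuth thresholds; it is
## smoothed by least-squares fits of the logistic
##   f(E) = 1 / (1 + exp(-r (E - E0)))
## with slope r (1/(V/m)) and shift E0 (V/m, the 50% recruitment level).

grid_bin_index <- function(axis, value, name) {
  i <- which(abs(axis - value) < 1e-6)
  if (length(i) != 1L)
    tms_stop("tms_range_error", "%s = %g is not a grid node", name, value)
  i
}

#' Empirical recruitment rate at one (theta, delta) bin
#'
#' Pools the thresholds of all cells and azimuths at the bin and returns
#' their empirical CDF: the fraction of the population with threshold <= E.
#'
#' @param g a `tms_threshold_grid`.
#' @param theta,delta grid-node coordinates.
#' @return a step function of E (class `ecdf`) with attribute
#'   `thresholds` (the pooled finite samples).
#' @export
empirical_recruitment <- function(g, theta, delta) {
  ti <- grid_bin_index(g$theta_axis, theta, "theta")
  di <- grid_bin_index(g$delta_axis, delta, "delta")
  pooled <- as.vector(g$thresholds[, ti, , di])
  pooled <- pooled[is.finite(pooled)]
  if (!length(pooled))
    tms_stop("tms_empty_bin", "no finite thresholds at (theta = %g, delta = %g)",
             theta, delta)
  f <- stats::ecdf(pooled)
  attr(f, "thresholds") <- pooled
  f
}

#' Fit the recruitment sigmoid to CDF points
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the logistic with the
#' constraint r > 0; initialised at E0 = median(E), r = 1.1/IQR(E).
#'
#' @param E field intensities, V/m (>= 3 distinct values).
#' @param f recruitment fractions in \[0, 1\] at `E`.
#' @return an object of class `tms_recruitment_sigmoid` with elements `r`,
#'   `E0`, `residuals`, `rms_residual`, `converged`.
#' @export
fit_sigmoid <- function(E, f) {
  if (length(unique(E)) < 3L)
    tms_stop("tms_config_error", "need >= 3 distinct intensity points")
  if (length(E) != length(f))
    tms_stop("tms_config_error", "E and f must have equal length")
  iqr <- stats::IQR(E)
  start <- list(r = if (iqr > 0) 1.1 / iqr else 1, E0 = stats::median(E))
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ 1 / (1 + exp(-r * (E - E0))),
                      data = data.frame(E = E, f = f),
                      start = start, lower = c(r = 1e-9, E0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(r = NA_real_, E0 = NA_real_,
                          residuals = rep(NA_real_, length(E)),
                          rms_residual = NA_real_, converged = FALSE),
                     class = "tms_recruitment_sigmoid"))
  }
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  structure(list(r = unname(co["r"]), E0 = unname(co["E0"]),
                 residuals = as.numeric(res),
                 rms_residual = sqrt(mean(res^2)), converged = TRUE),
            class = "tms_recruitment_sigmoid")
}

#' @export
print.tms_recruitment_sigmoid <- function(x, ...) {
  if (!x$converged) cat("<tms_recruitment_sigmoid> fit did not converge\n")
  else cat(sprintf("<tms_recruitment_sigmoid> r = %.4g 1/(V/m), E0 = %.4g V/m (RMS residual %.3g)\n",
                   x$r, x$E0, x$rms_residual))
  invisible(x)
}

#' @export
coef.tms_recruitment_sigmoid <- function(object, ...)
  c(r = object$r, E0 = object$E0)

#' @export
predict.tms_recruitment_sigmoid <- function(object, newdata, ...) {
  E <- if (is.data.frame(newdata)) newdata$E else newdata
  1 / (1 + exp(-object$r * (E - object$E0)))
}

#' Recruitment-rate surface over the whole (theta, delta) grid
#'
#' Applies [empirical_recruitment()] and [fit_sigmoid()] per bin; bins with
#' too few samples or failed fits are flagged in the convergence mask.
#'
#' @param g a `tms_threshold_grid`.
#' @return an object of class `tms_recruitment_surface` with matrices `r`,
#'   `E0`, `rms_residual`, `converged` over \[theta x delta\].
#' @export
recruitment_surface <- function(g) {
  nt <- length(g$theta_axis); nd <- length(g$delta_axis)
  r <- E0 <- rms <- matrix(NA_real_, nt, nd)
  conv <- matrix(FALSE, nt, nd)
  for (ti in seq_len(nt)) for (di in seq_len(nd)) {
    pooled <- as.vector(g$thresholds[, ti, , di])
    pooled <- sort(pooled[is.finite(pooled)])
    if (!length(pooled)) next
    if (length(unique(pooled)) < 3L) {
      ## (near-)identical thresholds: the recruitment rate is a step; use
      ## a logistic rising from 1% to 99% over one search precision
      r[ti, di] <- 2 * log(99) / g$precision
      E0[ti, di] <- stats::median(pooled)
      rms[ti, di] <- 0
      conv[ti, di] <- TRUE
      next
    }
    fcdf <- seq_along(pooled) / length(pooled)
    fit <- fit_sigmoid(pooled, fcdf)
    if (fit$converged) {
      r[ti, di] <- fit$r; E0[ti, di] <- fit$E0
      rms[ti, di] <- fit$rms_residual; conv[ti, di] <- TRUE
    }
  }
  structure(list(theta_axis = g$theta_axis, delta_axis = g$delta_axis,
                 r = r, E0 = E0, rms_residual = rms, converged = conv,
                 waveform_kind = g$waveform_kind),
            class = "tms_recruitment_surface")
}

#' @export
print.tms_recruitment_surface <- function(x, ...) {
  cat(sprintf("<tms_recruitment_surface> %d theta x %d delta, %d/%d bins converged\n",
              length(x$theta_axis), length(x$delta_axis),
              sum(x$converged), length(x$converged)))
  if (any(x$converged))
    cat(sprintf("  E0: %.2f-%.2f V/m, median r = %.4g 1/(V/m)\n",
                min(x$E0, na.rm = TRUE), max(x$E0, na.rm = TRUE),
                stats::median(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Directional sensitivity of recruitment at fixed relative intensities
#'
#' Reads the recruitment rate along the theta axis at multiples of a
#' reference intensity (the 50% recruitment level E0 at `theta_ref`), and
#' normalizes each curve to its maximum -- the modelling counterpart of
#' comparing motor-evoked-potential amplitudes across pulse orientations at
#' fixed percentages of the resting motor threshold.
#'
#' @param s a `tms_recruitment_surface`.
#' @param intensities_rel positive multiples of the reference intensity
#'   (e.g. `c(1.1, 1.2, 1.4, 1.6)`).
#' @param delta field-decay grid node, %/mm.
#' @param theta_ref reference polar angle, degrees (grid node).
#' @return matrix \[theta x intensity\] of normalized recruitment values;
#'   attributes `raw` (unnormalized) and `E_ref` (V/m).
#' @export
polar_sensitivity_curve <- function(s, intensities_rel = c(1.1, 1.2, 1.4, 1.6),
                                    delta = 0, theta_ref = 0) {
  if (any(!is.finite(intensities_rel) | intensities_rel <= 0))
    tms_stop("tms_config_error", "relative intensities must be positive")
  di <- grid_bin_index(s$delta_axis, delta, "delta")
  ti0 <- grid_bin_index(s$theta_axis, theta_ref, "theta_ref")
  E_ref <- s$E0[ti0, di]
  if (!is.finite(E_ref))
    tms_stop("tms_empty_bin", "no converged fit at the reference bin")
  raw <- sapply(intensities_rel, function(mlt)
    1 / (1 + exp(-s$r[, di] * (mlt * E_ref - s$E0[, di]))))
  norm <- sweep(raw, 2, apply(raw, 2, max, na.rm = TRUE), "/")
  dimnames(norm) <- list(theta = s$theta_axis,
                         intensity = intensities_rel)
  structure(norm, raw = raw, E_ref = E_ref)
}
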