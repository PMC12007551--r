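## Generalized polynomial chaos surrogates of threshold maps over
## (theta, delta), with Sobol sensitivity indices.  The basis is
## orthonormal with respect to the input probability measure: Legendre
## polynomials for uniform inputs, Jacobi polynomials for beta inputs.
##
## Beta(p, q) on [min, max] standardizes to x in [-1, 1] with density
## proportional to (1-x)^(q-1) (1+x)^(p-1); that is the Jacobi weight with
## alpha = q - 1, beta = p - 1.  The three-term recurrence is run in its
## orthonormal form, so basis norms are exact and Sobol indices reduce to
## ratios of squared coefficients.

#' Input parameter distribution
#'
#' @param kind `"uniform"` or `"beta"`.
#' @param support numeric `c(min, max)` in the parameter's physical units.
#' @param shape numeric `c(p, q)` for the beta kind (both > 0).
#' @return an object of class `tms_parameter_distribution`.
#' @export
param_dist <- function(kind = c("uniform", "beta"), support, shape = NULL) {
  if (is.character(kind) && !kind[1L] %in% c("uniform", "beta"))
    tms_stop("tms_config_error", "unknown distribution kind '%s'", kind[1L])
  kind <- match.arg(kind)
  if (length(support) != 2L || !all(is.finite(support)) ||
      support[1] >= support[2])
    tms_stop("tms_config_error", "support must be c(min, max) with min < max")
  if (kind == "beta") {
    if (is.null(shape) || length(shape) != 2L || any(shape <= 0))
      tms_stop("tms_config_error", "beta distribution needs shape c(p, q) > 0")
  }
  structure(list(kind = kind, support = as.numeric(support),
                 shape = if (kind == "beta") as.numeric(shape) else NULL),
            class = "tms_parameter_distribution")
}

#' Number of basis functions of a total-order expansion
#'
#' Counts the multi-indices of `dims` variables with total degree at most
#' `order`, i.e. choose(order + dims, dims).
#'
#' @param order total polynomial order (>= 0).
#' @param dims number of input parameters (>= 1).
#' @return integer count.
#' @export
basis_size <- function(order, dims) {
  if (!is.numeric(order) || !is.numeric(dims) || order < 0 || dims < 1)
    tms_stop("tms_config_error", "order must be >= 0 and dims >= 1")
  choose(order + dims, dims)
}

#' Multi-indices with total degree at most `order`
#'
#' @inheritParams basis_size
#' @return integer matrix (Nc x dims), one multi-index per row, ordered by
#'   total degree then lexicographically.
#' @export
multi_indices <- function(order, dims) {
  if (order < 0 || dims < 1)
    tms_stop("tms_config_error", "order must be >= 0 and dims >= 1")
  grid <- as.matrix(expand.grid(rep(list(0:order), dims)))
  grid <- grid[rowSums(grid) <= order, , drop = FALSE]
  grid <- grid[order(rowSums(grid), apply(grid, 1, paste, collapse = ",")), ,
               drop = FALSE]
  dimnames(grid) <- NULL
  grid
}

#' Draw samples from input distributions
#'
#' @param dists list of [param_dist()] objects.
#' @param n number of samples.
#' @param seed integer seed; the draw is reproducible.
#' @return numeric matrix (n x dims) in physical units.
#' @export
sample_parameters <- function(dists, n, seed = 1L) {
  if (n < 1) tms_stop("tms_config_error", "n must be >= 1")
  for (d in dists)
    if (!inherits(d, "tms_parameter_distribution"))
      tms_stop("tms_config_error", "dists must be param_dist objects")
  with_seed(seed, {
    cols <- lapply(dists, function(d) {
      u <- if (d$kind == "uniform") stats::runif(n)
      else stats::rbeta(n, d$shape[1], d$shape[2])
      d$support[1] + u * diff(d$support)
    })
    do.call(cbind, cols)
  })
}

## Orthonormal polynomial recurrence coefficients under the normalized
## input measure on [-1, 1].  Monic recurrence p_{k+1} = (x - a_k) p_k -
## b_k p_{k-1}; with the probability normalization b_0 = 1.
recurrence_coeffs <- function(dist, order) {
  if (dist$kind == "uniform") {
    k <- seq_len(order)
    list(a = rep(0, order + 1L), b = c(1, k^2 / (4 * k^2 - 1)))
  } else {
    al <- dist$shape[2] - 1   # alpha = q - 1
    be <- dist$shape[1] - 1   # beta  = p - 1
    a <- numeric(order + 1L); b <- numeric(order + 1L)
    b[1] <- 1
    a[1] <- (be - al) / (al + be + 2)
    for (k in seq_len(order)) {
      ab <- al + be
      a[k + 1L] <- (be^2 - al^2) / ((2 * k + ab) * (2 * k + ab + 2))
      b[k + 1L] <- if (k == 1L)
        4 * (1 + al) * (1 + be) / ((2 + ab)^2 * (3 + ab))
      else
        4 * k * (k + al) * (k + be) * (k + ab) /
          ((2 * k + ab)^2 * (2 * k + ab + 1) * (2 * k + ab - 1))
    }
    list(a = a, b = b)
  }
}

## Evaluate orthonormal polynomials 0..order at standardized x in [-1, 1];
## returns length(x) x (order + 1) matrix.
eval_orthonormal <- function(x, dist, order) {
  rc <- recurrence_coeffs(dist, order)
  out <- matrix(0, length(x), order + 1L)
  out[, 1L] <- 1
  if (order >= 1L)
    out[, 2L] <- (x - rc$a[1L]) * out[, 1L] / sqrt(rc$b[2L])
  if (order >= 2L)
    for (k in 2:order)
      out[, k + 1L] <- ((x - rc$a[k]) * out[, k] -
                          sqrt(rc$b[k]) * out[, k - 1L]) / sqrt(rc$b[k + 1L])
  out
}

standardize <- function(v, dist)
  2 * (v - dist$support[1]) / diff(dist$support) - 1

gpc_design_matrix <- function(m_idx, pts, dists, order) {
  n <- nrow(pts)
  per_dim <- lapply(seq_along(dists), function(j)
    eval_orthonormal(standardize(pts[, j], dists[[j]]), dists[[j]], order))
  Psi <- matrix(1, n, nrow(m_idx))
  for (j in seq_along(dists))
    Psi <- Psi * per_dim[[j]][, m_idx[, j] + 1L, drop = FALSE]
  Psi
}

#' Fit a generalized polynomial chaos surrogate
#'
#' Oversampled least-squares regression (point collocation) of the target
#' on the orthonormal basis at points sampled from the input
#' distributions.  A target that is itself a polynomial of total degree
#' <= `order` is reproduced to machine precision.
#'
#' @param target function taking a numeric matrix (n x dims) of physical
#'   parameter values and returning n target values, or a
#'   `tms_average_threshold_map` (evaluated by [interpolate_threshold()]).
#' @param dists list of [param_dist()] objects, one per input dimension.
#' @param order total polynomial order (default 15).
#' @param n_train number of regression points (default `2.5 * Nc`,
#'   minimum `2 * Nc`).
#' @param seed integer seed for the sampling.
#' @param max_condition regression condition-number threshold above which a
#'   diagnostic error advises more samples.
#' @return an object of class `tms_gpc_model` with `multi_indices`,
#'   `coefficients`, `dists`, `order` and regression `diagnostics`.
#' @export
build_gpc <- function(target, dists, order = 15, n_train = NULL, seed = 1L,
                      max_condition = 1e8) {
  m_idx <- multi_indices(order, length(dists))
  nc <- nrow(m_idx)
  n_train <- n_train %||% ceiling(2.5 * nc)
  if (n_train < 2 * nc)
    tms_stop("tms_config_error",
             "n_train must be >= 2 * Nc = %d (oversampled regression)", 2 * nc)
  pts <- sample_parameters(dists, n_train, seed)
  fn <- if (inherits(target, "tms_average_threshold_map"))
    function(p) interpolate_threshold(target, p[, 1], p[, 2])
  else target
  y <- fn(pts)
  if (length(y) != n_train || any(!is.finite(y)))
    tms_stop("tms_config_error", "target must return %d finite values", n_train)
  Psi <- gpc_design_matrix(m_idx, pts, dists, order)
  qrd <- qr(Psi)
  cond <- kappa(qr.R(qrd), exact = FALSE)
  if (cond > max_condition)
    tms_stop("tms_diagnostic_error",
             "ill-conditioned gPC regression (condition %.3g); increase n_train",
             cond)
  coefs <- qr.coef(qrd, y)
  resid <- y - Psi %*% coefs
  structure(list(multi_indices = m_idx, coefficients = as.numeric(coefs),
                 dists = dists, order = order,
                 diagnostics = list(n_train = n_train, condition = cond,
                                    rms_residual = sqrt(mean(resid^2)),
                                    seed = seed)),
            class = "tms_gpc_model")
}

#' @export
print.tms_gpc_model <- function(x, ...) {
  cat(sprintf("<tms_gpc_model> order %d, %d dims, Nc = %d coefficients\n",
              x$order, ncol(x$multi_indices), length(x$coefficients)))
  cat(sprintf("  regression: n = %d, condition = %.3g, RMS residual = %.3g\n",
              x$diagnostics$n_train, x$diagnostics$condition,
              x$diagnostics$rms_residual))
  invisible(x)
}

#' Evaluate a gPC surrogate in matrix form
#'
#' Builds the (n x Nc) basis matrix row-wise and returns its product with
#' the coefficient vector.
#'
#' @param m a `tms_gpc_model`.
#' @param Theta,Delta query vectors in physical units (equal length), or
#'   more generally one vector per input dimension via `...`.
#' @return numeric vector of surrogate values.
#' @export
evaluate_gpc <- function(m, Theta, Delta = NULL) {
  pts <- if (is.null(Delta)) as.matrix(Theta) else cbind(Theta, Delta)
  if (nrow(pts) == 0L) return(numeric(0))
  if (ncol(pts) != ncol(m$multi_indices))
    tms_stop("tms_config_error", "query must have %d columns",
             ncol(m$multi_indices))
  for (j in seq_along(m$dists)) {
    s <- m$dists[[j]]$support
    if (any(pts[, j] < s[1] - 1e-9 | pts[, j] > s[2] + 1e-9))
      tms_stop("tms_range_error",
               "query outside support [%g, %g] in dimension %d", s[1], s[2], j)
  }
  Psi <- gpc_design_matrix(m$multi_indices, pts, m$dists, m$order)
  as.numeric(Psi %*% m$coefficients)
}

#' @export
predict.tms_gpc_model <- function(object, newdata, ...) {
  evaluate_gpc(object, as.matrix(newdata))
}

#' First- and second-order Sobol indices of a 2-parameter gPC model
#'
#' With an orthonormal basis the output variance is the sum of squared
#' non-constant coefficients; each index is the fraction contributed by the
#' multi-indices supported on the corresponding variable subset.  For two
#' dimensions the three indices sum to one.
#'
#' @param m a `tms_gpc_model`.
#' @return named list `S_theta`, `S_delta`, `S_theta_delta` (for dims = 2);
#'   for general dims, per-subset indices.
#' @export
sobol_indices <- function(m) {
  c2 <- m$coefficients^2
  deg <- m$multi_indices
  total <- sum(c2[-1L])
  if (total <= 1e-20 * max(1, c2[1L]))
    tms_stop("tms_undefined_indices", "model variance is zero")
  if (ncol(deg) == 2L) {
    list(S_theta = sum(c2[deg[, 1] > 0 & deg[, 2] == 0]) / total,
         S_delta = sum(c2[deg[, 1] == 0 & deg[, 2] > 0]) / total,
         S_theta_delta = sum(c2[deg[, 1] > 0 & deg[, 2] > 0]) / total)
  } else {
    support <- apply(deg > 0, 1, function(r) paste(which(r), collapse = "&"))
    v <- tapply(c2, support, sum)
    v <- v[names(v) != ""]
    as.list(v / total)
  }
}

#' Serialize / restore a gPC model as JSON
#'
#' @param m a `tms_gpc_model`.
#' @param path JSON path.
#' @export
write_gpc_json <- function(m, path) {
  jsonlite::write_json(
    list(order = m$order,
         multi_indices = m$multi_indices,
         coefficients = m$coefficients,
         dists = lapply(m$dists, unclass),
         diagnostics = m$diagnostics),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gpc_json
#' @export
read_gpc_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dists <- lapply(seq_len(nrow(j$dists) %||% length(j$dists)), function(i) {
    d <- if (is.data.frame(j$dists)) j$dists[i, ] else j$dists[[i]]
    param_dist(d$kind[[1]] %||% d$kind, unlist(d$support),
               if ((d$kind[[1]] %||% d$kind) == "beta") unlist(d$shape))
  })
  structure(list(multi_indices = as.matrix(j$multi_indices),
                 coefficients = as.numeric(j$coefficients),
                 dists = dists, order = j$order,
                 diagnostics = as.list(j$diagnostics)),
            class = "tms_gpc_model")
}
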