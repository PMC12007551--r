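#' @useDynLib tmsresponse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbeta runif rlnorm rnorm median quantile sd coef predict
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180

## Classed conditions so callers can distinguish failure modes.
tms_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tms_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

tms_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "tms_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

## Run code with a fixed RNG stream without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    tms_stop("tms_config_error", "'%s' must be a positive finite scalar", name)
  invisible(x)
}
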