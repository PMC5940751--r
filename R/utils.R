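# internal numerics shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed`, so simulators are
#' reproducible without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, on log scale
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  stopifnot(a >= b)
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

# -log10 of the two-sided normal p-value, stable for very large |z|
neglog10_p_from_z <- function(z) {
  -(stats::pnorm(-abs(z), log.p = TRUE) + log(2)) / log(10)
}

# weighted least squares of y on (1, x); returns c(intercept, slope)
fit_wls <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  det <- sw * sxx - sx * sx
  if (!is.finite(det) || abs(det) < .Machine$double.eps * sw * sxx) {
    stop("degenerate design: regressor has no usable variation", call. = FALSE)
  }
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sy - slope * sx) / sw
  c(intercept = intercept, slope = slope)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
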