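#' Per-variant Wald ratio causal estimates
#'
#' The causal effect of the exposure on the outcome identified by one
#' instrument is the ratio of the outcome association to the exposure
#' association, theta = b_out / b_exp. Its standard error is either
#' first-order, se_out / |b_exp| (the default, treating the exposure
#' effect as fixed), or second-order delta-method,
#' sqrt(se_out^2/b_exp^2 + b_out^2 se_exp^2 / b_exp^4).
#'
#' @param b_out,se_out outcome log-odds effect and standard error.
#' @param b_exp,se_exp exposure log-odds effect and standard error.
#' @param rsid optional variant labels, recycled.
#' @param order `"first"` or `"second"`.
#' @return data frame of class `wald_estimates`: `rsid`, `theta`, `se`.
#'   Vector inputs give one row per instrument.
#' @export
wald_ratio <- function(b_out, se_out, b_exp, se_exp,
                       order = c("first", "second"), rsid = NULL) {
  order <- match.arg(order)
  n <- length(b_out)
  stopifnot(length(se_out) == n, length(b_exp) == n, length(se_exp) == n)
  if (any(!is.finite(b_exp)) || any(b_exp == 0)) {
    stop("undefined Wald ratio: exposure beta is zero or non-finite; ",
         "exclude such variants upstream", call. = FALSE)
  }
  if (any(se_out <= 0) || any(se_exp < 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  theta <- b_out / b_exp
  se <- if (order == "first") {
    se_out / abs(b_exp)
  } else {
    sqrt(se_out^2 / b_exp^2 + b_out^2 * se_exp^2 / b_exp^4)
  }
  structure(data.frame(rsid = rsid %||% paste0("iv", seq_len(n)),
                       theta = theta, se = se, stringsAsFactors = FALSE),
            order = order, class = c("wald_estimates", "data.frame"))
}

#' Wald ratios from a harmonized exposure/outcome table
#'
#' @param pairs result of [harmonize()]; only retained rows are used.
#' @inheritParams wald_ratio
#' @return A [wald_ratio()] table.
#' @export
wald_ratios_from_pairs <- function(pairs, order = c("first", "second")) {
  stopifnot(inherits(pairs, "harmonized_pairs"))
  p <- pairs[pairs$kept, , drop = FALSE]
  wald_ratio(p$beta_out, p$se_out, p$beta_exp, p$se_exp,
             order = order, rsid = p$rsid)
}

#' Cochran Q heterogeneity of per-instrument causal estimates
#'
#' Q = sum w_i (theta_i - theta_hat)^2 with inverse-variance weights
#' w_i = 1/se_i^2; chi-square with k-1 degrees of freedom under
#' homogeneity.
#'
#' @param estimates a [wald_ratio()] table (>= 2 rows).
#' @param theta_hat the pooled estimate the deviations are taken from.
#' @return list `q`, `df`, `p_het`.
#' @export
cochran_q <- function(estimates, theta_hat) {
  k <- nrow(estimates)
  if (k < 2L) stop("heterogeneity undefined for fewer than 2 instruments",
                   call. = FALSE)
  w <- 1 / estimates$se^2
  q <- sum(w * (estimates$theta - theta_hat)^2)
  df <- k - 1L
  list(q = q, df = df, p_het = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Fixed-effect inverse-variance-weighted pooling of Wald ratios
#'
#' theta_hat = sum(w_i theta_i)/sum(w_i) with w_i = 1/se_i^2 and pooled
#' standard error (sum w_i)^(-1/2); two-sided normal p-value. Cochran Q
#' is attached whenever k >= 2. Exponentiated, theta_hat is the odds
#' ratio for the outcome per log-odds unit of the exposure.
#'
#' @param estimates a [wald_ratio()] table (k >= 1 rows).
#' @return object of class `mr_fit`: `theta_hat`, `se`, `or_`, `ci95`
#'   (odds-ratio scale), `p`, `q`, `df`, `p_het`, `k`.
#' @export
ivw_fixed <- function(estimates) {
  k <- nrow(estimates)
  if (is.null(k) || k < 1L) stop("no instruments to pool", call. = FALSE)
  if (any(estimates$se <= 0)) stop("standard errors must be positive",
                                   call. = FALSE)
  w <- 1 / estimates$se^2
  theta_hat <- sum(w * estimates$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- if (k >= 2L) cochran_q(estimates, theta_hat)
         else list(q = NA_real_, df = NA_integer_, p_het = NA_real_)
  structure(list(theta_hat = theta_hat, se = se,
                 or_ = exp(theta_hat),
                 ci95 = exp(theta_hat + c(-1, 1) * stats::qnorm(0.975) * se),
                 p = 2 * stats::pnorm(-abs(theta_hat / se)),
                 q = het$q, df = het$df, p_het = het$p_het, k = k),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("IVW fixed-effect MR: k = %d instruments\n", x$k))
  cat(sprintf("  OR %.3f [%.3f-%.3f], p = %s\n",
              x$or_, x$ci95[1], x$ci95[2], format_p(x$p)))
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran Q = %.2f, df = %d, p_het = %s\n",
                x$q, x$df, format_p(x$p_het)))
  }
  invisible(x)
}

# mirrors journal-style reporting of doubles that underflow
format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 2.2e-308) return("<2.2e-308")
  format(p, digits = 3)
}

#' Leave-one-out outlier diagnosis for IVW MR
#'
#' Refits the fixed-effect pool with each instrument removed in turn.
#' The dominant outlier is the variant whose removal reduces Cochran Q
#' by the largest margin; it is flagged when the full-set heterogeneity
#' is significant (`p_het <= p_het_threshold`). Whether removing it
#' leaves no residual heterogeneity (residual p_het above the
#' threshold) is reported separately as `resolved`.
#'
#' @param estimates a [wald_ratio()] table (k >= 3 rows).
#' @param p_het_threshold heterogeneity significance level (default 0.05).
#' @return list of class `loo_mr`: `table` (per-variant leave-one-out
#'   fits with `q_drop`), `outlier` (rsid or `NA`), `resolved`
#'   (logical), `full` (the all-instrument `mr_fit`).
#' @export
leave_one_out <- function(estimates, p_het_threshold = 0.05) {
  k <- nrow(estimates)
  if (k < 3L) stop("leave-one-out needs at least 3 instruments", call. = FALSE)
  full <- ivw_fixed(estimates)
  rows <- lapply(seq_len(k), function(i) {
    f <- ivw_fixed(estimates[-i, , drop = FALSE])
    data.frame(rsid = estimates$rsid[i], theta_hat = f$theta_hat,
               se = f$se, or_ = f$or_, p = f$p, q = f$q, df = f$df,
               p_het = f$p_het, q_drop = full$q - f$q,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  flagged <- !is.na(full$p_het) && full$p_het <= p_het_threshold
  i_star <- which.max(tab$q_drop)
  structure(list(table = tab,
                 outlier = if (flagged) tab$rsid[i_star] else NA_character_,
                 resolved = flagged && tab$p_het[i_star] > p_het_threshold,
                 full = full),
            class = "loo_mr")
}

#' MR-Egger regression sensitivity analysis
#'
#' Weighted least-squares regression of outcome effects on exposure
#' effects with a free intercept, weights 1/se_out^2, after orienting
#' every instrument so its exposure effect is positive. The slope is a
#' causal estimate robust to directional pleiotropy under the InSIDE
#' assumption; the intercept estimates the average direct (pleiotropic)
#' effect, and should be zero for valid instruments. Inference uses the
#' t distribution with k-2 degrees of freedom.
#'
#' @param pairs result of [harmonize()] (>= 3 retained rows), or any
#'   data frame with `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @return object of class `egger_fit`: slope (+ se, p, odds-ratio CI),
#'   intercept (+ se, p), `k`.
#' @export
egger <- function(pairs) {
  p <- if (!is.null(pairs$kept)) pairs[pairs$kept, , drop = FALSE] else pairs
  k <- nrow(p)
  if (k < 3L) stop("Egger regression needs at least 3 instruments",
                   call. = FALSE)
  s <- sign(p$beta_exp)
  bx <- abs(p$beta_exp)
  by <- p$beta_out * s
  if (stats::sd(bx) == 0) {
    stop("degenerate design: all exposure effects identical after orientation",
         call. = FALSE)
  }
  fit <- stats::lm(by ~ bx, weights = 1 / p$se_out^2)
  cf <- summary(fit)$coefficients
  ci <- cf["bx", 1] + c(-1, 1) * stats::qt(0.975, k - 2) * cf["bx", 2]
  structure(list(slope = cf["bx", 1], slope_se = cf["bx", 2],
                 slope_p = cf["bx", 4],
                 or_ = exp(cf["bx", 1]), ci95 = exp(ci),
                 intercept = cf["(Intercept)", 1],
                 intercept_se = cf["(Intercept)", 2],
                 intercept_p = cf["(Intercept)", 4],
                 k = k),
            class = "egger_fit")
}

#' @export
print.egger_fit <- function(x, ...) {
  cat(sprintf("MR-Egger: k = %d instruments\n", x$k))
  cat(sprintf("  slope OR %.3f [%.3f-%.3f], p = %s\n",
              x$or_, x$ci95[1], x$ci95[2], format_p(x$slope_p)))
  cat(sprintf("  intercept %.4f (se %.4f), p = %s\n",
              x$intercept, x$intercept_se, format_p(x$intercept_p)))
  invisible(x)
}

#' Approximate power of a two-sample MR analysis with a binary outcome
#'
#' Normal-approximation power for detecting a causal odds ratio
#' `true_or` at two-sided level `alpha`, given the variance in the
#' exposure explained by the instruments and the outcome study size:
#' with x = |log OR| * sqrt(N R2 phi (1-phi)), N the total outcome
#' sample size and phi its case fraction,
#' power = Phi(-z_{1-alpha/2} + x) + Phi(-z_{1-alpha/2} - x).
#' Also reports the smallest OR detectable at 80% power, found by
#' numerical inversion.
#'
#' @param k number of instruments (recorded, not used by the formula).
#' @param variance_explained R-squared of the instruments on the
#'   exposure, in (0,1).
#' @param n_cases,n_controls outcome study counts.
#' @param true_or causal odds ratio to detect.
#' @param alpha two-sided type-I error level.
#' @return object of class `mr_power`: `power`, `alpha`, `k`,
#'   `variance_explained`, `n_cases`, `n_controls`, `detectable_or`.
#' @export
mr_power <- function(k, variance_explained, n_cases, n_controls,
                     true_or, alpha = 0.05) {
  stopifnot(is_scalar_number(variance_explained),
            variance_explained > 0, variance_explained < 1,
            is_scalar_number(n_cases), n_cases > 0,
            is_scalar_number(n_controls), n_controls > 0,
            is_scalar_number(true_or), true_or > 0,
            is_scalar_number(alpha), alpha > 0, alpha < 1)
  n_eff <- n_cases + n_controls
  phi <- n_cases / n_eff
  z <- stats::qnorm(1 - alpha / 2)
  fac <- sqrt(n_eff * variance_explained * phi * (1 - phi))
  pw <- function(or) {
    x <- abs(log(or)) * fac
    stats::pnorm(-z + x) + stats::pnorm(-z - x)
  }
  detectable <- stats::uniroot(function(lo) pw(exp(lo)) - 0.80,
                               lower = 1e-8, upper = 10, tol = 1e-12)$root
  structure(list(power = pw(true_or), alpha = alpha, k = k,
                 variance_explained = variance_explained,
                 n_cases = n_cases, n_controls = n_controls,
                 detectable_or = exp(detectable)),
            class = "mr_power")
}
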