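#' Wakefield approximate Bayes factor for a single association
#'
#' Evidence for association versus the null from one estimate and its
#' standard error under a normal prior on the true effect with variance
#' `w`: with V = se^2 and z = beta/se,
#' ABF = sqrt(V/(V+w)) * exp(z^2 * w / (2 (V+w))).
#' `log = TRUE` returns the log Bayes factor, which stays finite for
#' arbitrarily extreme z.
#'
#' @param beta effect estimate.
#' @param se its standard error (> 0).
#' @param w prior variance of the true effect (default 0.04, i.e. a
#'   prior sd of 0.2 on the log-odds scale).
#' @param log return the log-ABF.
#' @return numeric vector of (log-)Bayes factors.
#' @export
wakefield_abf <- function(beta, se, w = 0.04, log = FALSE) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  if (any(w < 0)) stop("prior variance must be >= 0", call. = FALSE)
  V <- se^2
  z <- beta / se
  labf <- 0.5 * base::log(V / (V + w)) + z^2 * w / (2 * (V + w))
  if (log) labf else exp(labf)
}

#' Prior configuration for the four-model regional scan
#'
#' @param pi1,pi2 prior probability a variant is causal for trait 1
#'   only / trait 2 only (default 1e-4 each).
#' @param pi12 prior a variant is causal for both traits (default 1e-5).
#' @param w1,w2 prior effect-size variances feeding the two traits'
#'   Bayes factors (default 0.04 on the log-odds scale).
#' @return list of class `scan_priors`.
#' @export
scan_priors <- function(pi1 = 1e-4, pi2 = 1e-4, pi12 = 1e-5,
                        w1 = 0.04, w2 = 0.04) {
  stopifnot(pi1 > 0, pi2 > 0, pi12 > 0, pi1 + pi2 + pi12 < 1,
            w1 > 0, w2 > 0)
  structure(list(pi1 = pi1, pi2 = pi2, pi12 = pi12, w1 = w1, w2 = w2),
            class = "scan_priors")
}

#' Posterior probabilities of five regional association models
#'
#' Compares, for one genomic region with per-variant effects for two
#' traits, the hypotheses: no association (model 0), a causal variant
#' for trait 1 only (1), for trait 2 only (2), one variant shared by
#' both traits (3), and two distinct variants, one per trait (4). Each
#' model's evidence combines per-variant Wakefield log-ABFs A_i, B_i
#' with the priors: E0 = 1, E1 = pi1 sum A_i, E2 = pi2 sum B_i,
#' E3 = pi12 sum A_i B_i, E4 = pi1 pi2 sum_{i != j} A_i B_j (computed
#' as (sum A)(sum B) - sum A_i B_i). Everything is evaluated on the
#' log scale with log-sum-exp, so signals as extreme as z = 60 do not
#' overflow. A single causal variant per trait is assumed; LD between
#' variants is not modelled in the evidence sums.
#'
#' @param region data frame with per-variant columns `beta1`, `se1`,
#'   `beta2`, `se2` and optionally `rsid`.
#' @param priors a [scan_priors()].
#' @return object of class `region_posteriors`: `pp0`..`pp4` (summing
#'   to 1), `log_evidence` (the five unnormalized log evidences), `k`.
#' @export
region_posteriors <- function(region, priors = scan_priors()) {
  stopifnot(is.data.frame(region),
            all(c("beta1", "se1", "beta2", "se2") %in% names(region)))
  k <- nrow(region)
  if (k < 1L) stop("empty region", call. = FALSE)
  la <- wakefield_abf(region$beta1, region$se1, priors$w1, log = TRUE)
  lb <- wakefield_abf(region$beta2, region$se2, priors$w2, log = TRUE)
  sA <- logsumexp(la)
  sB <- logsumexp(lb)
  sAB <- logsumexp(la + lb)
  le <- c(
    pp0 = 0,
    pp1 = log(priors$pi1) + sA,
    pp2 = log(priors$pi2) + sB,
    pp3 = log(priors$pi12) + sAB,
    pp4 = if (k < 2L) -Inf
          else log(priors$pi1) + log(priors$pi2) + logdiffexp(sA + sB, sAB)
  )
  pp <- exp(le - logsumexp(le))
  pp <- pp / sum(pp)
  structure(c(as.list(pp), list(log_evidence = le, k = k, priors = priors)),
            class = "region_posteriors")
}

#' @export
print.region_posteriors <- function(x, ...) {
  cat(sprintf("Regional four-model scan (%d variants)\n", x$k))
  lab <- c("null", "trait 1 only", "trait 2 only",
           "shared variant", "distinct variants")
  pp <- unlist(x[c("pp0", "pp1", "pp2", "pp3", "pp4")])
  for (i in seq_along(pp)) {
    cat(sprintf("  pp%d (%s): %.4f\n", i - 1L, lab[i], pp[i]))
  }
  invisible(x)
}

#' Per-variant signal table for regional plots
#'
#' Plot-ready summary of a paired region: -log10 p per trait (stable
#' for arbitrarily extreme z), log-ABFs, and r-squared to a chosen
#' index variant when a haplotype panel is available.
#'
#' @inheritParams region_posteriors
#' @param index rsid of the reference variant for the LD column;
#'   defaults to the strongest trait-2 signal.
#' @param panel optional [haplotype_panel()] covering the region.
#' @return data frame: `rsid`, `z1`, `z2`, `neglog10_p1`,
#'   `neglog10_p2`, `log_abf1`, `log_abf2`, `r2_index`.
#' @export
scan_signal_table <- function(region, priors = scan_priors(),
                              index = NULL, panel = NULL) {
  stopifnot(nrow(region) >= 1L)
  rsid <- region$rsid %||% paste0("v", seq_len(nrow(region)))
  z1 <- region$beta1 / region$se1
  z2 <- region$beta2 / region$se2
  if (is.null(index)) index <- rsid[which.max(abs(z2))]
  if (!index %in% rsid) stop("index variant not in region: ", index,
                             call. = FALSE)
  r2 <- rep(NA_real_, length(rsid))
  if (!is.null(panel)) {
    r2 <- vapply(rsid, function(v) {
      if (v == index) return(1)
      tryCatch(ld_d_prime_r2(panel, index, v)$r2,
               error = function(e) NA_real_)
    }, numeric(1))
  } else {
    r2[rsid == index] <- 1
  }
  data.frame(rsid = rsid, z1 = z1, z2 = z2,
             neglog10_p1 = neglog10_p_from_z(z1),
             neglog10_p2 = neglog10_p_from_z(z2),
             log_abf1 = wakefield_abf(region$beta1, region$se1, priors$w1,
                                      log = TRUE),
             log_abf2 = wakefield_abf(region$beta2, region$se2, priors$w2,
                                      log = TRUE),
             r2_index = r2, stringsAsFactors = FALSE, row.names = NULL)
}
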