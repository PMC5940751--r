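#' Read LD scores from a whitespace-delimited file
#'
#' Expected columns (header row): `rsid`, `chrom`, `pos`, `l` where `l`
#' is each variant's LD score, the sum of r-squared with surrounding
#' panel variants.
#' @param path file path.
#' @return data frame `rsid`, `chrom`, `pos`, `l`.
#' @export
read_ldscores <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("rsid", "l")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("LD-score file lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$l < 0)) stop("negative LD score", call. = FALSE)
  df
}

#' LD scores from a haplotype panel
#'
#' For each panel variant, sums r-squared with all panel variants
#' (including itself) within a physical window, the usual proxy for a
#' 1 cM window when only positions are available.
#'
#' @param panel a [haplotype_panel()] with positions.
#' @param window_bp window half-width in base pairs (default 1 Mb).
#' @return data frame `rsid`, `chrom`, `pos`, `l`.
#' @export
ld_scores_from_panel <- function(panel, window_bp = 1e6) {
  v <- panel$variants
  if (any(is.na(v$pos))) stop("panel positions required", call. = FALSE)
  m <- nrow(v)
  l <- vapply(seq_len(m), function(i) {
    near <- which(abs(v$pos - v$pos[i]) <= window_bp &
                  (is.na(v$chrom) | v$chrom == v$chrom[i]))
    sum(vapply(near, function(j) {
      if (j == i) return(1)
      tryCatch(ld_d_prime_r2(panel, v$rsid[i], v$rsid[j])$r2,
               error = function(e) 0)
    }, numeric(1)))
  }, numeric(1))
  data.frame(rsid = v$rsid, chrom = v$chrom, pos = v$pos, l = l,
             stringsAsFactors = FALSE)
}

#' Delete-one-block jackknife standard error
#'
#' Splits the rows of `values` into `n_blocks` contiguous blocks,
#' recomputes a (possibly vector-valued) statistic with each block
#' deleted, and returns the jackknife pseudovalue estimate and standard
#' error. Contiguous blocks respect the serial (genomic) ordering of
#' the rows, so locally correlated contributions stay together.
#'
#' @param values vector, matrix or data frame of per-variant
#'   contributions, ordered along the genome.
#' @param n_blocks number of blocks (>= 2).
#' @param statistic function taking a row-subset of `values` and
#'   returning a numeric vector (the estimator).
#' @return list `estimate` (pseudovalue mean), `se`, `n_blocks`.
#' @export
block_jackknife <- function(values, n_blocks, statistic) {
  n <- if (is.null(dim(values))) length(values) else nrow(values)
  if (n_blocks < 2L) stop("jackknife undefined for a single block",
                          call. = FALSE)
  if (n < n_blocks) stop("fewer observations than jackknife blocks",
                         call. = FALSE)
  take <- function(idx) {
    if (is.null(dim(values))) values[idx] else values[idx, , drop = FALSE]
  }
  block_of <- ceiling(seq_len(n) / (n / n_blocks))
  full <- statistic(values)
  d <- length(full)
  pseudo <- matrix(NA_real_, n_blocks, d)
  for (b in seq_len(n_blocks)) {
    part <- statistic(take(which(block_of != b)))
    pseudo[b, ] <- n_blocks * full - (n_blocks - 1) * part
  }
  est <- colMeans(pseudo)
  se <- sqrt(apply(pseudo, 2, stats::var) / n_blocks)
  names(est) <- names(se) <- names(full)
  list(estimate = est, se = se, n_blocks = n_blocks)
}

# shared plumbing: x = sqrt(n1*n2) * l / m regressor and two-pass weights
ldsc_xreg <- function(l, n1, n2, m) sqrt(n1 * n2) * l / m

#' Single-trait SNP heritability by LD score regression
#'
#' Regresses squared z-scores on n*l/m with a free intercept: the slope
#' estimates SNP heritability and the intercept, near 1 in the absence
#' of confounding, absorbs population stratification and cryptic
#' relatedness. A first unweighted pass (1/l weights) supplies plug-in
#' values for heteroskedasticity weights
#' 1 / (l * (intercept0 + n*h2_0*l/m)^2) in the second pass.
#' Uncertainty by delete-one-block jackknife over contiguous blocks.
#'
#' @param z2 squared z-scores, one per variant, genome-ordered.
#' @param ldscores LD scores: numeric vector or [read_ldscores()] frame
#'   matched to `z2`.
#' @param n GWAS sample size.
#' @param m number of variants the heritability is spread over
#'   (defaults to `length(z2)`).
#' @param n_blocks jackknife blocks (default 200).
#' @param chisq_max cap applied to `z2` before fitting, guarding the
#'   regression against enormous single-locus signals (default 80; set
#'   `Inf` to disable).
#' @return list `h2`, `h2_se`, `intercept`, `intercept_se`, `n_blocks`.
#' @export
h2_regression <- function(z2, ldscores, n, m = length(z2),
                          n_blocks = 200, chisq_max = 80) {
  l <- if (is.data.frame(ldscores)) ldscores$l else ldscores
  if (length(l) != length(z2)) {
    stop("z-scores and LD scores must be matched per variant", call. = FALSE)
  }
  if (length(z2) < n_blocks) {
    stop("fewer variants than jackknife blocks", call. = FALSE)
  }
  if (stats::sd(l) == 0) stop("constant LD scores: slope unidentifiable",
                              call. = FALSE)
  z2 <- pmin(z2, chisq_max)
  x <- ldsc_xreg(l, n, n, m)
  pass1 <- fit_wls(x, z2, 1 / pmax(l, 1))
  v <- pmax(pass1["intercept"] + pass1["slope"] * x, 0.05)
  w <- 1 / (pmax(l, 1) * v^2)
  dat <- data.frame(x = x, y = z2, w = w)
  jk <- block_jackknife(dat, n_blocks,
                        function(d) fit_wls(d$x, d$y, d$w))
  list(h2 = unname(jk$estimate["slope"]),
       h2_se = unname(jk$se["slope"]),
       intercept = unname(jk$estimate["intercept"]),
       intercept_se = unname(jk$se["intercept"]),
       n_blocks = n_blocks)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses the per-variant product z1*z2 on sqrt(n1*n2)*l/m with a
#' free intercept. The slope estimates the genetic covariance; the
#' intercept absorbs sample overlap (rho * N_shared / sqrt(n1*n2)), the
#' property that makes the estimator robust to shared participants.
#' The genetic correlation is rg = gcov / sqrt(h2_1 * h2_2) with the
#' heritabilities from per-trait [h2_regression()]. All standard
#' errors, including rg's, come from one joint delete-one-block
#' jackknife so the correlation between the three regressions is
#' respected; p_rg is a two-sided normal test of rg = 0.
#'
#' @param z1,z2 per-variant z-scores for the two traits on a shared,
#'   genome-ordered variant set.
#' @param ldscores matched LD scores (vector or data frame).
#' @param n1,n2 the two GWAS sample sizes.
#' @param m variant count for scaling (default `length(z1)`).
#' @param n_blocks jackknife blocks (default 200).
#' @param chisq_max per-trait cap on z^2 before fitting (default 80).
#' @return object of class `ldsc_fit`: `h2_1`, `h2_2`, `gcov`, `rg`
#'   with `*_se` fields, `intercept_1`, `intercept_2`, `intercept_x`
#'   (+ ses), `p_rg`, `rg_out_of_range` flag, `n_blocks`, `m`.
#' @export
rg_regression <- function(z1, z2, ldscores, n1, n2, m = length(z1),
                          n_blocks = 200, chisq_max = 80) {
  l <- if (is.data.frame(ldscores)) ldscores$l else ldscores
  stopifnot(length(z1) == length(z2), length(l) == length(z1))
  if (length(z1) < n_blocks) stop("fewer variants than jackknife blocks",
                                  call. = FALSE)
  if (stats::sd(l) == 0) stop("constant LD scores: slope unidentifiable",
                              call. = FALSE)
  cap <- sqrt(chisq_max)
  z1 <- pmax(pmin(z1, cap), -cap)
  z2 <- pmax(pmin(z2, cap), -cap)
  x1 <- ldsc_xreg(l, n1, n1, m)
  x2 <- ldsc_xreg(l, n2, n2, m)
  xx <- ldsc_xreg(l, n1, n2, m)
  lw <- pmax(l, 1)

  # pass 1: 1/l weights give plug-in variances/covariance for pass 2
  p1 <- fit_wls(x1, z1^2, 1 / lw)
  p2 <- fit_wls(x2, z2^2, 1 / lw)
  px <- fit_wls(xx, z1 * z2, 1 / lw)
  v1 <- pmax(p1["intercept"] + p1["slope"] * x1, 0.05)
  v2 <- pmax(p2["intercept"] + p2["slope"] * x2, 0.05)
  cx <- px["intercept"] + px["slope"] * xx
  w1 <- 1 / (lw * v1^2)
  w2 <- 1 / (lw * v2^2)
  wx <- 1 / (lw * (v1 * v2 + cx^2))

  dat <- data.frame(x1 = x1, x2 = x2, xx = xx,
                    y1 = z1^2, y2 = z2^2, yx = z1 * z2,
                    w1 = w1, w2 = w2, wx = wx)
  stat <- function(d) {
    f1 <- fit_wls(d$x1, d$y1, d$w1)
    f2 <- fit_wls(d$x2, d$y2, d$w2)
    fx <- fit_wls(d$xx, d$yx, d$wx)
    h2a <- f1[["slope"]]; h2b <- f2[["slope"]]; gcov <- fx[["slope"]]
    c(h2_1 = h2a, h2_2 = h2b, gcov = gcov,
      rg = gcov / sqrt(h2a * h2b),
      intercept_1 = f1[["intercept"]], intercept_2 = f2[["intercept"]],
      intercept_x = fx[["intercept"]])
  }
  full <- stat(dat)
  jk <- block_jackknife(dat, n_blocks, stat)
  rg <- unname(full["rg"])
  rg_se <- unname(jk$se["rg"])
  structure(list(h2_1 = unname(full["h2_1"]), h2_1_se = unname(jk$se["h2_1"]),
                 h2_2 = unname(full["h2_2"]), h2_2_se = unname(jk$se["h2_2"]),
                 gcov = unname(full["gcov"]), gcov_se = unname(jk$se["gcov"]),
                 rg = rg, rg_se = rg_se,
                 rg_ci95 = rg + c(-1, 1) * stats::qnorm(0.975) * rg_se,
                 p_rg = 2 * stats::pnorm(-abs(rg / rg_se)),
                 intercept_1 = unname(full["intercept_1"]),
                 intercept_1_se = unname(jk$se["intercept_1"]),
                 intercept_2 = unname(full["intercept_2"]),
                 intercept_2_se = unname(jk$se["intercept_2"]),
                 intercept_x = unname(full["intercept_x"]),
                 intercept_x_se = unname(jk$se["intercept_x"]),
                 rg_out_of_range = is.finite(rg) && abs(rg) > 1,
                 n_blocks = n_blocks, m = m),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("Cross-trait LD score regression\n")
  cat(sprintf("  h2 trait 1: %.4f (se %.4f), intercept %.3f\n",
              x$h2_1, x$h2_1_se, x$intercept_1))
  cat(sprintf("  h2 trait 2: %.4f (se %.4f), intercept %.3f\n",
              x$h2_2, x$h2_2_se, x$intercept_2))
  cat(sprintf("  rg = %.3f [%.3f-%.3f], p = %s; cross-intercept %.4f\n",
              x$rg, x$rg_ci95[1], x$rg_ci95[2], format_p(x$p_rg),
              x$intercept_x))
  if (x$rg_out_of_range) cat("  note: |rg| > 1 (reported unclamped)\n")
  invisible(x)
}
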