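# Independent brute-force oracles and shared fixture builders.
# Oracles are deliberately naive re-derivations, kept free of any
# package internals, so estimator tests have a second route.

# two-pass inverse-variance pooling + Q, written naively
oracle_ivw <- function(theta, se) {
  w <- 1 / se^2
  pooled <- sum(w * theta) / sum(w)
  q <- 0
  for (i in seq_along(theta)) q <- q + w[i] * (theta[i] - pooled)^2
  list(theta_hat = pooled, se = sqrt(1 / sum(w)), q = q)
}

# O(m^2) Benjamini-Hochberg: largest k with p_(k) <= k*q/m, reject all
# p <= p_(k)
oracle_bh <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  kmax <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  if (kmax == 0L) rep(FALSE, m) else p <= ps[kmax]
}

# D', r2 by direct haplotype-frequency enumeration
oracle_ld <- function(h1, h2) {
  pA <- mean(h1); pB <- mean(h2)
  D <- mean(h1 == 1 & h2 == 1) - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(d_prime = if (D == 0) 0 else abs(D) / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# five-model regional evidences by direct double loop (safe only for
# moderate z, where exp() cannot overflow)
oracle_region_pp <- function(beta1, se1, beta2, se2,
                             pi1 = 1e-4, pi2 = 1e-4, pi12 = 1e-5,
                             w = 0.04) {
  abf <- function(b, s) {
    V <- s^2
    sqrt(V / (V + w)) * exp((b / s)^2 * w / (2 * (V + w)))
  }
  A <- abf(beta1, se1); B <- abf(beta2, se2)
  k <- length(A)
  e4 <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) e4 <- e4 + A[i] * B[j]
  }
  e <- c(1, pi1 * sum(A), pi2 * sum(B), pi12 * sum(A * B), pi1 * pi2 * e4)
  e / sum(e)
}

# small sumstats table built directly from vectors
make_sumstats <- function(rsid, ea, oa, beta, se,
                          eaf = rep(0.3, length(rsid)),
                          pvalue = rep(0.5, length(rsid)), ...) {
  as_sumstats(data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
                         beta = beta, se = se, eaf = eaf, pvalue = pvalue,
                         ..., stringsAsFactors = FALSE))
}

random_panel <- function(m = 6, n_hap = 40) {
  H <- matrix(rbinom(m * n_hap, 1, runif(m, 0.2, 0.8)), m, n_hap)
  # guard against monomorphic rows
  H[rowSums(H) == 0, 1] <- 1
  H[rowSums(H) == n_hap, 1] <- 0
  haplotype_panel(H, data.frame(rsid = paste0("v", seq_len(m)),
                                chrom = 1, pos = seq_len(m) * 1e3))
}
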