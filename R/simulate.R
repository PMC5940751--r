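# Simulators of paired GWAS artefacts with serialized ground truth.
# All work at the summary-statistic level: sufficient for every
# estimator in the package and orders of magnitude faster than
# genotype-level simulation. Each simulator draws from its own seeded
# stream and restores the caller's RNG state.

NON_PALINDROMIC <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                        c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

# se of a per-allele log-odds estimate in a case-control GWAS
binary_se <- function(eaf, n_cases, n_controls) {
  n <- n_cases + n_controls
  phi <- n_cases / n
  1 / sqrt(2 * eaf * (1 - eaf) * n * phi * (1 - phi))
}

#' Simulate a two-sample MR study with known causal effect
#'
#' Draws `k` independent instruments: exposure effect sizes uniform in
#' magnitude on `[beta_range[1], beta_range[2]]` (echoing the modest
#' per-allele odds ratios typical of complex-disease instruments),
#' standard errors from the binary-trait approximation given allele
#' frequency and study size, and observed outcome effects
#' `gamma * beta_exp + alpha_i + noise`. Pleiotropy `alpha_i` is zero
#' (`none`), normal with a directional mean (`directional`), or a
#' single large direct effect on one variant (`outlier`, emulating an
#' APOE-like invalid instrument; default effect log(3.2), the epsilon4
#' heterozygote odds ratio scale). The outcome table is emitted with
#' random allele swaps and strand flips so harmonization is exercised.
#'
#' @param k number of instruments (>= 2).
#' @param gamma true causal effect, outcome log-odds per exposure
#'   log-odds.
#' @param pleiotropy_spec `list(type = "none")`,
#'   `list(type = "directional", mean = ...)`, or
#'   `list(type = "outlier", index = i, effect = ...)`.
#' @param n_exp_cases,n_exp_controls exposure study size (defaults
#'   60,801 / 123,504).
#' @param n_out_cases,n_out_controls outcome study size (defaults
#'   17,008 / 37,154).
#' @param beta_range magnitude range of true exposure effects.
#' @param seed integer seed; same seed, same output.
#' @return list: `exposure` and `outcome` [as_sumstats()] tables and
#'   `truth` (a `truth_record` with `gamma`, per-variant `pleiotropy`,
#'   true betas and the seed).
#' @export
simulate_mr_study <- function(k = 52, gamma = 0,
                              pleiotropy_spec = list(type = "none"),
                              n_exp_cases = 60801, n_exp_controls = 123504,
                              n_out_cases = 17008, n_out_controls = 37154,
                              beta_range = c(0.03, 0.3), seed = 1) {
  stopifnot(k >= 2)
  type <- pleiotropy_spec$type %||% "none"
  if (!type %in% c("none", "directional", "outlier")) {
    stop("unknown pleiotropy type: ", type, call. = FALSE)
  }
  with_seed(seed, {
    rsid <- sprintf("rs%06d", sample.int(999999, k))
    chrom <- sample(1:22, k, replace = TRUE)
    pos <- sample.int(1e8, k)
    eaf <- stats::runif(k, 0.05, 0.95)
    alleles <- NON_PALINDROMIC[sample.int(length(NON_PALINDROMIC), k,
                                          replace = TRUE)]
    ea <- vapply(alleles, `[`, character(1), 1L)
    oa <- vapply(alleles, `[`, character(1), 2L)

    beta_exp_true <- sample(c(-1, 1), k, replace = TRUE) *
      stats::runif(k, beta_range[1], beta_range[2])
    se_exp <- binary_se(eaf, n_exp_cases, n_exp_controls)
    se_out <- binary_se(eaf, n_out_cases, n_out_controls)
    alpha <- switch(type,
      none = rep(0, k),
      directional = stats::rnorm(k, mean = pleiotropy_spec$mean %||% 0.05,
                                 sd = abs(pleiotropy_spec$mean %||% 0.05) / 2),
      outlier = {
        a <- rep(0, k)
        a[pleiotropy_spec$index %||% sample.int(k, 1)] <-
          pleiotropy_spec$effect %||% log(3.2)
        a
      })
    beta_out_true <- gamma * beta_exp_true + alpha
    beta_exp_hat <- stats::rnorm(k, beta_exp_true, se_exp)
    beta_out_hat <- stats::rnorm(k, beta_out_true, se_out)

    p_from <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)), 1e-320)
    exposure <- as_sumstats(data.frame(
      rsid = rsid, chrom = chrom, pos = pos, effect_allele = ea,
      other_allele = oa, eaf = eaf, beta = beta_exp_hat, se = se_exp,
      pvalue = p_from(beta_exp_hat, se_exp),
      n_cases = n_exp_cases, n_controls = n_exp_controls,
      stringsAsFactors = FALSE), provenance = "simulated exposure GWAS")

    # re-express a third of the outcome rows with swapped labels and a
    # third on the opposite strand, so harmonize() has work to do
    relabel <- sample(c("as-is", "swap", "flip"), k, replace = TRUE)
    o_ea <- ea; o_oa <- oa; o_beta <- beta_out_hat; o_eaf <- eaf
    sw <- relabel == "swap"
    o_ea[sw] <- oa[sw]; o_oa[sw] <- ea[sw]
    o_beta[sw] <- -o_beta[sw]; o_eaf[sw] <- 1 - o_eaf[sw]
    fl <- relabel == "flip"
    o_ea[fl] <- COMPLEMENT[o_ea[fl]]
    o_oa[fl] <- COMPLEMENT[o_oa[fl]]
    outcome <- as_sumstats(data.frame(
      rsid = rsid, chrom = chrom, pos = pos, effect_allele = o_ea,
      other_allele = o_oa, eaf = o_eaf, beta = o_beta, se = se_out,
      pvalue = p_from(o_beta, se_out),
      n_cases = n_out_cases, n_controls = n_out_controls,
      stringsAsFactors = FALSE), provenance = "simulated outcome GWAS")

    truth <- truth_record(
      gamma = gamma, pleiotropy = stats::setNames(alpha, rsid),
      config = paste0("mr:", type), seed = seed,
      extra = list(beta_exp_true = stats::setNames(beta_exp_true, rsid),
                   outlier_rsid = if (type == "outlier")
                     rsid[which(alpha != 0)] else NA_character_,
                   relabel = stats::setNames(relabel, rsid)))
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate genome-wide z-score pairs under the LD-score model
#'
#' Per variant j with LD score l_j, draws (z1, z2) from a bivariate
#' normal with variances 1 + n_t h2_t l_j / m and covariance
#' sqrt(n1 n2) rg sqrt(h2_1 h2_2) l_j / m plus an overlap intercept
#' N_shared * rho_pheno / sqrt(n1 n2), where N_shared =
#' `overlap * min(n1, n2)` and `rho_pheno` is the phenotypic
#' correlation among shared samples.
#'
#' @param m number of variants.
#' @param h2_1,h2_2 SNP heritabilities in `[0,1]`.
#' @param rg genetic correlation in `[-1,1]`.
#' @param n1,n2 GWAS sample sizes.
#' @param overlap shared-sample fraction of the smaller study, in `[0,1]`.
#' @param rho_pheno phenotypic correlation among shared samples
#'   (default 0.2).
#' @param ld_scores optional LD-score vector; otherwise drawn as
#'   1 + Exponential with mean `mean_l - 1`.
#' @param mean_l mean of generated LD scores (default 10).
#' @param seed integer seed.
#' @return list: `z1`, `z2`, `ldscores` (data frame `rsid`, `chrom`,
#'   `pos`, `l`), `n1`, `n2`, `truth` (includes the implied
#'   `intercept_x_true`).
#' @export
simulate_ldsc_panel <- function(m = 5000, h2_1 = 0.3, h2_2 = 0.3, rg = 0,
                                n1 = 2000, n2 = 2000, overlap = 0,
                                rho_pheno = 0.2, ld_scores = NULL,
                                mean_l = 10, seed = 1) {
  stopifnot(abs(rg) <= 1, h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1,
            overlap >= 0, overlap <= 1)
  with_seed(seed, {
    l <- ld_scores %||% (1 + stats::rexp(m, rate = 1 / (mean_l - 1)))
    stopifnot(length(l) == m)
    v1 <- 1 + n1 * h2_1 * l / m
    v2 <- 1 + n2 * h2_2 * l / m
    intercept_x <- overlap * min(n1, n2) * rho_pheno / sqrt(n1 * n2)
    cv <- sqrt(n1 * n2) * rg * sqrt(h2_1 * h2_2) * l / m + intercept_x
    resid <- v2 - cv^2 / v1
    if (any(resid < 0)) stop("infeasible covariance structure", call. = FALSE)
    a <- stats::rnorm(m)
    b <- stats::rnorm(m)
    z1 <- sqrt(v1) * a
    z2 <- (cv / sqrt(v1)) * a + sqrt(resid) * b
    truth <- truth_record(
      rg_true = rg, h2_true = c(h2_1, h2_2), overlap = overlap,
      config = "ldsc", seed = seed,
      extra = list(intercept_x_true = intercept_x, rho_pheno = rho_pheno))
    list(z1 = z1, z2 = z2,
         ldscores = data.frame(rsid = sprintf("snp%06d", seq_len(m)),
                               chrom = 1L, pos = seq_len(m) * 1000L, l = l,
                               stringsAsFactors = FALSE),
         n1 = n1, n2 = n2, truth = truth)
  })
}

#' Simulate a paired regional signal with a known causal configuration
#'
#' Draws z-vectors for two traits over `m` variants under first-order
#' autoregressive LD, `R[i,j] = ld_rho^|i-j|`: z_t ~ MVN(R lambda_t, R)
#' where lambda_t is zero except at the configured causal indices.
#' Configurations: `null` (no signal), `trait1`/`trait2` (one causal
#' variant for one trait), `shared` (the same variant for both), and
#' `distinct` (two well-separated variants, one per trait, mirroring a
#' locus where the two traits track different alleles).
#'
#' @param m variants in the region.
#' @param ld_rho adjacent-variant correlation in `[0,1)` (default 0.5),
#'   or a full positive-semi-definite correlation matrix.
#' @param config one of `"null"`, `"trait1"`, `"trait2"`, `"shared"`,
#'   `"distinct"`.
#' @param z_causal signal size at the causal variant(s) (default 8).
#' @param se constant per-variant standard error used to convert z to
#'   betas (default 0.03, a typical GWAS log-odds se).
#' @param seed integer seed.
#' @return list: `region` (data frame `rsid`, `beta1`, `se1`, `beta2`,
#'   `se2`), `truth` (records config and causal indices).
#' @export
simulate_region <- function(m = 50, ld_rho = 0.5,
                            config = c("null", "trait1", "trait2",
                                       "shared", "distinct"),
                            z_causal = 8, se = 0.03, seed = 1) {
  config <- match.arg(config)
  if (is.matrix(ld_rho)) {
    R <- ld_rho
    stopifnot(nrow(R) == m, ncol(R) == m)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("LD matrix not positive semi-definite",
                              call. = FALSE)
  } else {
    stopifnot(is_scalar_number(ld_rho), ld_rho >= 0, ld_rho < 1)
    R <- ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
  }
  with_seed(seed, {
    i1 <- sample(seq_len(ceiling(m / 3)), 1)           # first third
    i2 <- sample(seq(floor(2 * m / 3) + 1, m), 1)      # last third
    lam1 <- lam2 <- rep(0, m)
    if (config %in% c("trait1", "shared")) lam1[i1] <- z_causal
    if (config == "trait2") lam2[i1] <- z_causal
    if (config == "shared") lam2[i1] <- z_causal
    if (config == "distinct") { lam1[i1] <- z_causal; lam2[i2] <- z_causal }
    U <- chol(R + diag(1e-10, m))
    draw <- function(lam) drop(R %*% lam + crossprod(U, stats::rnorm(m)))
    z1 <- draw(lam1)
    z2 <- draw(lam2)
    causal <- switch(config, null = integer(0),
                     trait1 = i1, trait2 = i1, shared = i1,
                     distinct = c(i1, i2))
    truth <- truth_record(config = paste0("region:", config), seed = seed,
                          extra = list(causal_index = causal,
                                       z_causal = z_causal, ld_rho =
                                         if (is.matrix(ld_rho)) NA else ld_rho))
    list(region = data.frame(rsid = sprintf("reg%04d", seq_len(m)),
                             beta1 = z1 * se, se1 = se,
                             beta2 = z2 * se, se2 = se,
                             stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate a haplotype panel with decaying LD
#'
#' Generates `n_hap` haplotypes over `m` variants by a Markovian
#' copying process: each haplotype's allele at variant j+1 copies its
#' allele at variant j with probability exp(-decay) (after matching
#' marginal frequencies), so adjacent-variant correlation decays along
#' the panel. `decay = 0` gives identical variants (r2 = 1 everywhere);
#' large `decay` gives independent variants. Optionally plants a
#' 4-variant block containing a low-frequency allele nested within a
#' common one — complete D' with small r2, the classic signature of a
#' rare functional allele riding on a common haplotype.
#'
#' @param m variants (before any planted block).
#' @param n_hap haplotypes (>= 4).
#' @param decay LD decay parameter (>= 0).
#' @param plant_block add the 4-variant nested block (rsids
#'   `blockA`..`blockD`; the `blockC`/`blockD` pair is the planted
#'   D'=1, low-r2 pair).
#' @param seed integer seed.
#' @return A [haplotype_panel()].
#' @export
simulate_haplotypes <- function(m = 20, n_hap = 100, decay = 1,
                                plant_block = FALSE, seed = 1) {
  stopifnot(n_hap >= 4, m >= 1, decay >= 0)
  with_seed(seed, {
    copy_p <- exp(-decay)
    p <- stats::runif(m, 0.1, 0.9)
    H <- matrix(0, m, n_hap)
    H[1, ] <- stats::rbinom(n_hap, 1, p[1])
    if (m > 1) for (j in 2:m) {
      fresh <- stats::rbinom(n_hap, 1, p[j])
      keep <- stats::runif(n_hap) < copy_p
      H[j, ] <- ifelse(keep, H[j - 1, ], fresh)
    }
    variants <- data.frame(rsid = sprintf("hv%04d", seq_len(m)),
                           chrom = 1L, pos = seq_len(m) * 1000L,
                           stringsAsFactors = FALSE)
    if (plant_block) {
      # blockC: frequency-0.5 allele; blockD: rare allele carried only
      # on blockC haplotypes -> D' = 1, r2 << 1
      nC <- round(n_hap / 2)
      nD <- max(1L, round(0.08 * n_hap))
      ord <- sample.int(n_hap)
      hC <- hD <- hA <- hB <- numeric(n_hap)
      hC[ord[seq_len(nC)]] <- 1
      hD[ord[seq_len(nD)]] <- 1
      # two common variants in moderate LD with blockC
      flipA <- stats::runif(n_hap) < 0.2
      flipB <- stats::runif(n_hap) < 0.3
      hA <- ifelse(flipA, 1 - hC, hC)
      hB <- ifelse(flipB, 1 - hC, hC)
      H <- rbind(H, hA, hB, hC, hD)
      variants <- rbind(variants,
                        data.frame(rsid = c("blockA", "blockB", "blockC",
                                            "blockD"),
                                   chrom = 1L,
                                   pos = (m + 1:4) * 1000L,
                                   stringsAsFactors = FALSE))
    }
    haplotype_panel(H, variants)
  })
}

#' Ground-truth record serialized alongside simulated data
#'
#' Recovery tests read simulation truth only from these records; they
#' round-trip losslessly through JSON via [write_truth()] /
#' [read_truth()].
#'
#' @param gamma true causal effect (MR simulations).
#' @param pleiotropy named per-variant direct effects.
#' @param rg_true,h2_true,overlap LD-score simulation truth.
#' @param config configuration label.
#' @param seed the seed the dataset was generated from.
#' @param extra named list of simulator-specific fields.
#' @return list of class `truth_record`.
#' @export
truth_record <- function(gamma = NA_real_, pleiotropy = NULL,
                         rg_true = NA_real_, h2_true = NA_real_,
                         overlap = NA_real_, config = NA_character_,
                         seed = NA_integer_, extra = list()) {
  structure(c(list(gamma = gamma, pleiotropy = pleiotropy,
                   rg_true = rg_true, h2_true = h2_true,
                   overlap = overlap, config = config, seed = seed),
              extra),
            class = "truth_record")
}

#' @rdname truth_record
#' @param truth a `truth_record`.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname truth_record
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "truth_record")
}
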