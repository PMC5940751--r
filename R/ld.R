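#' Haplotype reference panels
#'
#' A `haplotype_panel` holds a binary variants-by-haplotypes matrix
#' (1 = the counted allele) plus per-variant metadata, and stands in
#' for an external LD reference. Build one from a 0/1 matrix with a
#' sidecar variant table, or from a phased VCF.
#'
#' @param H numeric 0/1 matrix, variants in rows, haplotypes in columns.
#' @param variants data frame with columns `rsid` and optionally
#'   `chrom`, `pos`, `allele1` (the counted allele), `allele0`; one row
#'   per row of `H`.
#' @return A `haplotype_panel` list with elements `H` and `variants`.
#' @export
haplotype_panel <- function(H, variants) {
  H <- as.matrix(H)
  stopifnot(is.data.frame(variants), nrow(variants) == nrow(H),
            "rsid" %in% names(variants))
  if (ncol(H) < 2L) stop("a panel needs at least 2 haplotypes", call. = FALSE)
  if (!all(H %in% c(0, 1))) stop("haplotype matrix must be 0/1", call. = FALSE)
  if (anyDuplicated(variants$rsid)) stop("duplicate rsids in panel", call. = FALSE)
  for (cc in c("chrom", "pos", "allele1", "allele0"))
    if (is.null(variants[[cc]])) variants[[cc]] <- NA
  rownames(H) <- variants$rsid
  structure(list(H = H, variants = variants), class = "haplotype_panel")
}

#' Read a haplotype panel from a phased VCF or a plain matrix
#'
#' `read_panel_vcf` parses phased GT fields (`0|1`) into two haplotype
#' columns per sample (requires the vcfR package). `read_panel_matrix`
#' reads a whitespace-delimited 0/1 matrix together with a sidecar
#' variant list (columns `rsid`, optionally `chrom`, `pos`).
#'
#' @param path VCF file (may be uncompressed or gzipped).
#' @return A [haplotype_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF panels requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(!grepl("^[01]\\|[01]$", gt))) {
    stop("panel VCF must contain phased biallelic GT fields (0|0 .. 1|1)",
         call. = FALSE)
  }
  a <- matrix(as.numeric(substr(gt, 1, 1)), nrow = nrow(gt))
  b <- matrix(as.numeric(substr(gt, 3, 3)), nrow = nrow(gt))
  H <- cbind(a, b)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(rsid = fix$ID, chrom = fix$CHROM,
                         pos = as.numeric(fix$POS),
                         allele1 = fix$ALT, allele0 = fix$REF,
                         stringsAsFactors = FALSE)
  haplotype_panel(H, variants)
}

#' @rdname read_panel_vcf
#' @param matrix_path whitespace-delimited 0/1 matrix, variants in rows.
#' @param variants_path sidecar variant table with a header row.
#' @export
read_panel_matrix <- function(matrix_path, variants_path) {
  H <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  variants <- utils::read.table(variants_path, header = TRUE,
                                stringsAsFactors = FALSE)
  haplotype_panel(H, variants)
}

panel_row <- function(panel, rsid) {
  i <- match(rsid, panel$variants$rsid)
  if (is.na(i)) stop("variant not in panel: ", rsid, call. = FALSE)
  panel$H[i, ]
}

#' Pairwise linkage disequilibrium from haplotype counts
#'
#' Computes D' and r-squared for two panel variants from their joint
#' haplotype frequencies: with p_A, p_B the counted-allele frequencies
#' and p_AB the two-allele haplotype frequency, D = p_AB - p_A p_B;
#' D' = |D| / D_max where D_max = min(p_A(1-p_B), (1-p_A)p_B) when
#' D > 0 and min(p_A p_B, (1-p_A)(1-p_B)) otherwise;
#' r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B)). The two measures disagree
#' exactly when allele frequencies differ: a rare allele can be in
#' complete coupling (D' = 1) yet share almost no variance (small r^2).
#'
#' @param panel a [haplotype_panel()].
#' @param v1,v2 rsids of two panel variants.
#' @return list of class `ld_pair` with `d_prime` and `r2`.
#' @export
ld_d_prime_r2 <- function(panel, v1, v2) {
  h1 <- panel_row(panel, v1)
  h2 <- panel_row(panel, v2)
  pA <- mean(h1); pB <- mean(h2)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("LD undefined: monomorphic variant in panel", call. = FALSE)
  }
  pAB <- mean(h1 * h2)
  D <- pAB - pA * pB
  d_max <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(d_prime = d_prime, r2 = r2), class = "ld_pair")
}

#' Find the best LD proxy for an instrument absent from a study
#'
#' Among `candidates` present in the panel, returns the variant with
#' maximal r-squared to `target` provided it reaches `r2_min`
#' (instrument-substitution threshold, default 0.80). Ties are broken
#' by smaller base-position distance to the target, then by rsid.
#'
#' @param target rsid of the missing instrument (must be in the panel).
#' @param candidates a [as_sumstats()] table (or data frame with
#'   `rsid`) of variants available in the other study.
#' @param panel a [haplotype_panel()].
#' @param r2_min minimum r-squared to qualify.
#' @return the proxy rsid, or `NA_character_` if none qualifies.
#' @export
find_proxy <- function(target, candidates, panel, r2_min = 0.80) {
  stopifnot(is_scalar_number(r2_min), r2_min > 0, r2_min <= 1)
  if (!target %in% panel$variants$rsid) {
    stop("proxy target not in panel: ", target, call. = FALSE)
  }
  cand <- intersect(candidates$rsid, panel$variants$rsid)
  if (length(cand) == 0L) return(NA_character_)
  r2 <- vapply(cand, function(v) {
    if (v == target) return(1)
    tryCatch(ld_d_prime_r2(panel, target, v)$r2, error = function(e) NA_real_)
  }, numeric(1))
  ok <- !is.na(r2) & r2 >= r2_min
  if (!any(ok)) return(NA_character_)
  cand <- cand[ok]; r2 <- r2[ok]
  tpos <- panel$variants$pos[match(target, panel$variants$rsid)]
  dist <- abs(panel$variants$pos[match(cand, panel$variants$rsid)] - tpos)
  dist[is.na(dist)] <- Inf
  ord <- order(-r2, dist, cand)
  cand[ord[1L]]
}
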