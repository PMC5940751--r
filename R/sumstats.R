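#' GWAS summary-statistics tables
#'
#' A `sumstats` object is a validated data frame of per-variant,
#' per-effect-allele association summaries from one GWAS: one row per
#' variant with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n_cases`,
#' `n_controls`. `beta` is on the log-odds scale per copy of the effect
#' allele. Rows violating the invariants (positive `se`, `pvalue` in
#' (0,1], distinct single-nucleotide alleles, `eaf` in `[0,1]`) are
#' rejected at construction and reported.
#'
#' @param df data frame with at least `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`. `eaf`, `chrom`, `pos`,
#'   `n_cases`, `n_controls` are optional and filled with `NA`.
#' @param provenance label recorded on the object (study name, file).
#' @return A `sumstats` data frame; attributes `provenance`,
#'   `n_accepted`, `n_rejected` and `rejected` (a data frame of
#'   `rsid`/`reason` for every dropped row).
#' @export
as_sumstats <- function(df, provenance = "unknown") {
  stopifnot(is.data.frame(df))
  need <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  opt <- c("chrom", "pos", "eaf", "n_cases", "n_controls")
  for (cc in setdiff(opt, names(df))) df[[cc]] <- rep(NA, nrow(df))
  df <- df[c("rsid", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pvalue", "n_cases", "n_controls")]
  df$rsid <- as.character(df$rsid)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (cc in c("pos", "eaf", "beta", "se", "pvalue", "n_cases", "n_controls"))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))

  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) reason[is.na(reason) & cond] <<- why
  nuc <- c("A", "C", "G", "T")
  bad(is.na(df$rsid) | df$rsid == "", "missing rsid")
  bad(duplicated(df$rsid), "duplicate rsid")
  bad(!(df$effect_allele %in% nuc) | !(df$other_allele %in% nuc),
      "non-SNV or invalid allele")
  bad(df$effect_allele == df$other_allele, "identical alleles")
  bad(!is.finite(df$beta), "missing/non-finite beta")
  bad(!is.finite(df$se) | df$se <= 0, "se not > 0")
  bad(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
      "pvalue outside (0,1]")
  bad(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0,1]")
  bad(!is.na(df$n_cases) & df$n_cases < 0, "negative n_cases")
  bad(!is.na(df$n_controls) & df$n_controls < 0, "negative n_controls")

  rejected <- data.frame(rsid = df$rsid[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            provenance = provenance,
            n_accepted = nrow(out),
            n_rejected = nrow(rejected),
            rejected = rejected,
            class = c("sumstats", "data.frame"))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads tab- or whitespace-delimited text (gzip handled transparently)
#' with a header row, renames columns via `column_map`, and validates
#' every row; invalid rows are dropped and reported via the returned
#' object's `rejected` attribute.
#'
#' @param path file path.
#' @param column_map named character vector mapping internal field names
#'   to file column names. Defaults follow common GWAS conventions:
#'   `SNP, CHR, BP, A1, A2, FRQ, BETA, SE, P, N_CASES, N_CONTROLS`.
#' @param provenance label stored on the table; defaults to the file name.
#' @return A [as_sumstats()] table.
#' @export
read_sumstats <- function(path,
                          column_map = c(rsid = "SNP", chrom = "CHR",
                                         pos = "BP", effect_allele = "A1",
                                         other_allele = "A2", eaf = "FRQ",
                                         beta = "BETA", se = "SE",
                                         pvalue = "P", n_cases = "N_CASES",
                                         n_controls = "N_CONTROLS"),
                          provenance = basename(path)) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE,
                           comment.char = "", check.names = FALSE)
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  have <- column_map[column_map %in% names(raw)]
  miss <- setdiff(mandatory, names(have))
  if (length(miss)) {
    stop("input lacks mandatory column(s): ",
         paste(column_map[miss], collapse = ", "), call. = FALSE)
  }
  df <- raw[unname(have)]
  names(df) <- names(have)
  as_sumstats(df, provenance = provenance)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics [%s]: %d variants (%d rejected on read)\n",
              attr(x, "provenance") %||% "unknown",
              nrow(x), attr(x, "n_rejected") %||% 0L))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Select genetic instruments by significance or false discovery rate
#'
#' In `gws` mode keeps variants with `pvalue <= gws_alpha` (default
#' genome-wide significance, 5e-8). In `fdr` mode applies
#' Benjamini-Hochberg across all p-values in the table and keeps
#' variants with adjusted p `<= fdr_q`. In both modes variants whose
#' minor allele frequency falls below `maf_min` are flagged via the
#' `low_maf` column but never removed, so low-frequency instruments can
#' be retained in sensitivity sets.
#'
#' @param table a [as_sumstats()] table.
#' @param mode `"gws"` or `"fdr"`.
#' @param gws_alpha p-value threshold for `gws` mode.
#' @param fdr_q target false discovery rate for `fdr` mode.
#' @param maf_min minor-allele-frequency flag threshold.
#' @return data frame `rsid`, `pvalue`, `maf`, `low_maf`, ordered as in
#'   the input table.
#' @export
select_instruments <- function(table, mode = c("gws", "fdr"),
                               gws_alpha = 5e-8, fdr_q = 0.05,
                               maf_min = 0.05) {
  mode <- match.arg(mode)
  empty <- data.frame(rsid = character(), pvalue = numeric(),
                      maf = numeric(), low_maf = logical())
  if (nrow(table) == 0L) {
    warning("empty summary-statistics table: no instruments selected")
    return(empty)
  }
  keep <- if (mode == "gws") {
    table$pvalue <= gws_alpha
  } else {
    stats::p.adjust(table$pvalue, method = "BH") <= fdr_q
  }
  sel <- table[keep, , drop = FALSE]
  maf <- pmin(sel$eaf, 1 - sel$eaf)
  data.frame(rsid = sel$rsid, pvalue = sel$pvalue, maf = maf,
             low_maf = !is.na(maf) & maf < maf_min,
             stringsAsFactors = FALSE, row.names = NULL)
}
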