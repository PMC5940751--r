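COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) unname(COMPLEMENT[a1]) == a2

#' Harmonize outcome effects onto the exposure's effect alleles
#'
#' For every rsid shared between the two tables the outcome effect is
#' re-expressed per copy of the exposure's effect allele. Allele pairs
#' are reconciled by, in order: identity (`kept`), label swap
#' (`swapped`: outcome beta negated, eaf complemented), strand
#' complement (`strand-flipped`: A<->T, C<->G, beta unchanged), and
#' complement plus swap (`swapped+flipped`). Palindromic variants (A/T
#' or C/G) carry no strand information in their labels, so they are
#' aligned by effect-allele frequency instead and dropped
#' (`dropped-palindromic`) whenever either study's frequency lies
#' within `0.5 +/- palindrome_eaf_window` or is missing. rsids present
#' in only one table are reported as `dropped-missing`; irreconcilable
#' allele pairs as `allele-mismatch`.
#'
#' @param exposure,outcome [as_sumstats()] tables.
#' @param palindrome_eaf_window half-width of the ambiguous frequency
#'   band around 0.5 (default 0.08).
#' @return data frame of class `harmonized_pairs` with one row per
#'   rsid in the union of the tables: `rsid`, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `beta_out`, `se_out`, `eaf_out`, `action`, `kept`
#'   (logical).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  w <- palindrome_eaf_window
  stopifnot(is_scalar_number(w), w >= 0, w < 0.5)
  oidx <- match(exposure$rsid, outcome$rsid)

  one <- function(i) {
    e <- exposure[i, ]
    j <- oidx[i]
    row <- list(rsid = e$rsid, beta_exp = e$beta, se_exp = e$se,
                eaf_exp = e$eaf, beta_out = NA_real_, se_out = NA_real_,
                eaf_out = NA_real_, action = "dropped-missing")
    if (is.na(j)) return(row)
    o <- outcome[j, ]
    ea <- e$effect_allele; oa <- e$other_allele
    b <- o$beta; f <- o$eaf
    action <-
      if (o$effect_allele == ea && o$other_allele == oa) "kept"
      else if (o$effect_allele == oa && o$other_allele == ea) "swapped"
      else if (COMPLEMENT[o$effect_allele] == ea &&
               COMPLEMENT[o$other_allele] == oa) "strand-flipped"
      else if (COMPLEMENT[o$effect_allele] == oa &&
               COMPLEMENT[o$other_allele] == ea) "swapped+flipped"
      else "allele-mismatch"
    if (action == "allele-mismatch") { row$action <- action; return(row) }
    if (action %in% c("swapped", "swapped+flipped")) { b <- -b; f <- 1 - f }

    if (is_palindromic(ea, oa)) {
      ambiguous <- function(p) is.na(p) || abs(p - 0.5) <= w
      if (ambiguous(e$eaf) || ambiguous(f)) {
        row$action <- "dropped-palindromic"
        return(row)
      }
      # labels cannot distinguish "same strand" from "flipped + swapped":
      # trust frequency agreement, not the nominal label match
      if (sign(e$eaf - 0.5) != sign(f - 0.5)) {
        b <- -b; f <- 1 - f
        action <- switch(action,
                         "kept" = "swapped+flipped",
                         "swapped" = "strand-flipped",
                         "strand-flipped" = "swapped",
                         "swapped+flipped" = "kept")
      }
    }
    row$beta_out <- b; row$se_out <- o$se; row$eaf_out <- f
    row$action <- action
    row
  }

  rows <- lapply(seq_len(nrow(exposure)), one)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  extra <- setdiff(outcome$rsid, exposure$rsid)
  if (length(extra)) {
    out <- rbind(out, data.frame(rsid = extra, beta_exp = NA_real_,
                                 se_exp = NA_real_, eaf_exp = NA_real_,
                                 beta_out = NA_real_, se_out = NA_real_,
                                 eaf_out = NA_real_,
                                 action = "dropped-missing"))
  }
  out$kept <- out$action %in% c("kept", "swapped", "strand-flipped",
                                "swapped+flipped")
  rownames(out) <- NULL
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

#' Write a harmonization report as TSV
#'
#' One row per variant: rsid, the action taken, and whether the pair
#' was retained for analysis.
#' @param pairs result of [harmonize()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(pairs, path) {
  stopifnot(inherits(pairs, "harmonized_pairs"))
  utils::write.table(pairs[c("rsid", "action", "kept")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
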