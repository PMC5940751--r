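#' Analysis configuration
#'
#' Collects every input and threshold of the end-to-end workflow.
#' Inputs may be file paths (read on demand) or in-memory objects.
#' A configuration round-trips losslessly through a flat `key = value`
#' text file via [write_config()] / [read_config()].
#'
#' @param exposure,outcome [as_sumstats()] tables or file paths.
#' @param mode instrument selection: `"gws"`, `"fdr"`, or `"list"`
#'   (use `instruments` as given).
#' @param instruments optional rsid vector (required for `"list"`).
#' @param gws_alpha,fdr_q,maf_min selection thresholds.
#' @param r2_min proxy-substitution threshold.
#' @param palindrome_window ambiguous-frequency half-width for
#'   harmonization.
#' @param panel optional [haplotype_panel()] (or `NULL`: proxy search
#'   disabled).
#' @param p_het_threshold heterogeneity level for outlier flagging.
#' @param wald_order `"first"` or `"second"` Wald standard errors.
#' @param regions optional named list of region data frames for the
#'   four-model scan.
#' @param ldsc optional list `z1`, `z2`, `ldscores`, `n1`, `n2` for
#'   cross-trait LD score regression.
#' @param annotation optional local phenotype-association table for
#'   [annotate_pleiotropy()].
#' @param outdir optional output directory for TSV/JSON artefacts.
#' @param seed integer seed recorded with the run.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(exposure, outcome, mode = c("gws", "fdr", "list"),
                            instruments = NULL, gws_alpha = 5e-8,
                            fdr_q = 0.05, maf_min = 0.05, r2_min = 0.80,
                            palindrome_window = 0.08, panel = NULL,
                            p_het_threshold = 0.05,
                            wald_order = c("first", "second"),
                            regions = NULL, ldsc = NULL, annotation = NULL,
                            outdir = NULL, seed = 1) {
  mode <- match.arg(mode)
  wald_order <- match.arg(wald_order)
  if (mode == "list" && is.null(instruments)) {
    stop("mode 'list' needs an instrument rsid vector", call. = FALSE)
  }
  structure(list(exposure = exposure, outcome = outcome, mode = mode,
                 instruments = instruments, gws_alpha = gws_alpha,
                 fdr_q = fdr_q, maf_min = maf_min, r2_min = r2_min,
                 palindrome_window = palindrome_window, panel = panel,
                 p_het_threshold = p_het_threshold,
                 wald_order = wald_order, regions = regions, ldsc = ldsc,
                 annotation = annotation, outdir = outdir, seed = seed),
            class = "analysis_config")
}

# stable fingerprint of a configuration, for bundle provenance
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Write/read a flat key = value configuration file
#'
#' Serializes the scalar fields of an [analysis_config()] (table-like
#' inputs are written as the file paths they came from, when they are
#' paths). Lossless for path-based configurations.
#' @param config an [analysis_config()].
#' @param path output file.
#' @export
write_config <- function(config, path) {
  scalar <- Filter(function(x) is.null(x) || (is.atomic(x) && length(x) == 1L),
                   unclass(config))
  lines <- vapply(names(scalar), function(k) {
    v <- scalar[[k]]
    sprintf("%s = %s", k, if (is.null(v)) "" else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- stats::setNames(lapply(kv, function(x) if (length(x) > 1) x[2] else ""),
                         vapply(kv, `[`, character(1), 1L))
  for (k in c("gws_alpha", "fdr_q", "maf_min", "r2_min",
              "palindrome_window", "p_het_threshold", "seed")) {
    if (!is.null(out[[k]])) out[[k]] <- as.numeric(out[[k]])
  }
  out
}

resolve_sumstats <- function(x, provenance) {
  if (inherits(x, "sumstats")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_sumstats(x))
  if (is.data.frame(x)) return(as_sumstats(x, provenance))
  stop("cannot interpret summary-statistics input", call. = FALSE)
}

#' Run the two-sample MR workflow end-to-end
#'
#' Instrument selection, proxy substitution for instruments absent
#' from the outcome study, harmonization, per-variant Wald ratios,
#' fixed-effect pooling with Cochran Q, leave-one-out outlier
#' diagnosis, re-analysis with the flagged outlier excluded, and Egger
#' regression. Every variant that enters is accounted for: the bundle
#' ledger records each exclusion with its reason, so selected =
#' analysed + excluded.
#'
#' @param config an [analysis_config()].
#' @return list of class `mr_bundle`: `fit_all`, `fit_excl` (after
#'   outlier exclusion, or `NULL`), `egger`, `loo`, `estimates`,
#'   `pairs`, `selection`, `ledger` (data frame `rsid`, `stage`,
#'   `detail`), `table1` (analysis-by-analysis summary rows), `forest`
#'   (per-variant odds ratios for both traits, oriented to the
#'   risk-increasing exposure allele), `config_hash`.
#' @export
run_mr_workflow <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  exposure <- resolve_sumstats(config$exposure, "exposure")
  outcome <- resolve_sumstats(config$outcome, "outcome")
  ledger <- data.frame(rsid = character(), stage = character(),
                       detail = character(), stringsAsFactors = FALSE)
  note <- function(rsid, stage, detail) {
    ledger <<- rbind(ledger, data.frame(rsid = rsid, stage = stage,
                                        detail = detail,
                                        stringsAsFactors = FALSE))
  }

  sel <- if (config$mode == "list") {
    miss <- setdiff(config$instruments, exposure$rsid)
    for (v in miss) note(v, "selection", "not in exposure table")
    data.frame(rsid = intersect(config$instruments, exposure$rsid),
               stringsAsFactors = FALSE)
  } else {
    select_instruments(exposure, mode = config$mode,
                       gws_alpha = config$gws_alpha,
                       fdr_q = config$fdr_q, maf_min = config$maf_min)
  }

  # recessive-model instruments are not usable under the per-allele
  # model; they must be marked by a logical `recessive` column upstream
  if (!is.null(exposure$recessive)) {
    rec <- exposure$rsid[which(exposure$recessive)]
    drop <- intersect(sel$rsid, rec)
    for (v in drop) note(v, "selection", "recessive association")
    sel <- sel[!sel$rsid %in% drop, , drop = FALSE]
  }

  # proxy substitution for instruments the outcome study lacks
  keep <- sel$rsid
  absent <- setdiff(keep, outcome$rsid)
  if (length(absent) && !is.null(config$panel)) {
    for (v in absent) {
      pr <- tryCatch(find_proxy(v, outcome, config$panel, config$r2_min),
                     error = function(e) NA_character_)
      if (!is.na(pr) && !pr %in% keep && pr %in% exposure$rsid) {
        note(v, "proxy", paste0("replaced by ", pr))
        keep <- c(setdiff(keep, v), pr)
      } else {
        note(v, "proxy", "no proxy with sufficient r2")
        keep <- setdiff(keep, v)
      }
    }
  } else if (length(absent)) {
    if (is.null(config$panel)) {
      warning("no LD panel configured: proxy search disabled")
    }
    for (v in absent) note(v, "proxy", "absent from outcome; proxy search off")
    keep <- setdiff(keep, absent)
  }

  exp_sub <- exposure[exposure$rsid %in% keep, , drop = FALSE]
  class(exp_sub) <- class(exposure)
  pairs <- harmonize(exp_sub, outcome,
                     palindrome_eaf_window = config$palindrome_window)
  pairs <- pairs[pairs$rsid %in% keep, , drop = FALSE]
  class(pairs) <- c("harmonized_pairs", "data.frame")
  for (i in which(!pairs$kept)) {
    note(pairs$rsid[i], "harmonization", pairs$action[i])
  }
  k <- sum(pairs$kept)
  if (k < 3L) {
    stop("fewer than 3 instruments survive harmonization (", k,
         "); aborting MR workflow", call. = FALSE)
  }

  estimates <- wald_ratios_from_pairs(pairs, order = config$wald_order)
  fit_all <- ivw_fixed(estimates)
  loo <- leave_one_out(estimates, p_het_threshold = config$p_het_threshold)
  fit_excl <- NULL
  if (!is.na(loo$outlier)) {
    note(loo$outlier, "outlier",
         sprintf("dominant heterogeneity contributor (resolved=%s)",
                 loo$resolved))
    fit_excl <- ivw_fixed(estimates[estimates$rsid != loo$outlier, ,
                                    drop = FALSE])
  }
  egger_fit <- egger(pairs)

  row <- function(label, f, kk) {
    data.frame(analysis = label, k = kk, or_ = f$or_,
               ci_low = f$ci95[1], ci_high = f$ci95[2], p = f$p,
               q = f$q %||% NA_real_, df = f$df %||% NA_integer_,
               p_het = f$p_het %||% NA_real_, stringsAsFactors = FALSE)
  }
  table1 <- rbind(
    row("IVW (all instruments)", fit_all, fit_all$k),
    if (!is.null(fit_excl)) {
      row(paste0("IVW (excluding ", loo$outlier, ")"), fit_excl, fit_excl$k)
    },
    data.frame(analysis = "Egger MR", k = egger_fit$k, or_ = egger_fit$or_,
               ci_low = egger_fit$ci95[1], ci_high = egger_fit$ci95[2],
               p = egger_fit$slope_p, q = fit_all$q, df = fit_all$df,
               p_het = fit_all$p_het, stringsAsFactors = FALSE))

  kept <- pairs[pairs$kept, , drop = FALSE]
  orient <- sign(kept$beta_exp)          # report per risk-increasing allele
  z <- stats::qnorm(0.975)
  forest <- data.frame(
    rsid = kept$rsid,
    or_exp = exp(kept$beta_exp * orient),
    or_exp_low = exp(kept$beta_exp * orient - z * kept$se_exp),
    or_exp_high = exp(kept$beta_exp * orient + z * kept$se_exp),
    or_out = exp(kept$beta_out * orient),
    or_out_low = exp(kept$beta_out * orient - z * kept$se_out),
    or_out_high = exp(kept$beta_out * orient + z * kept$se_out),
    stringsAsFactors = FALSE)
  forest <- forest[order(-forest$or_exp), ]

  bundle <- structure(list(fit_all = fit_all, fit_excl = fit_excl,
                           egger = egger_fit, loo = loo,
                           estimates = estimates, pairs = pairs,
                           selection = sel, ledger = ledger,
                           table1 = table1, forest = forest,
                           config_hash = config_hash(config)),
                      class = "mr_bundle")
  if (!is.null(config$outdir)) write_mr_bundle(bundle, config$outdir)
  bundle
}

write_mr_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(bundle$table1, "mr_results.tsv")
  wt(bundle$forest, "forest.tsv")
  wt(bundle$ledger, "exclusions.tsv")
  write_harmonization_report(bundle$pairs,
                             file.path(outdir, "harmonization.tsv"))
  invisible(outdir)
}

#' @export
print.mr_bundle <- function(x, ...) {
  cat("Two-sample MR workflow\n")
  print(x$fit_all)
  if (!is.na(x$loo$outlier)) {
    cat(sprintf("  outlier: %s (heterogeneity resolved: %s)\n",
                x$loo$outlier, x$loo$resolved))
    print(x$fit_excl)
  }
  print(x$egger)
  invisible(x)
}

#' Annotate instruments with known phenotype associations
#'
#' Local-table substitute for a phenome-wide lookup: joins the
#' instruments against a user-supplied association table and keeps
#' entries below a Bonferroni-style threshold. The default threshold
#' divides 0.05 by the number of distinct phenotypes in the table.
#'
#' @param variants rsid character vector.
#' @param table data frame `rsid`, `phenotype`, `pvalue`, optional
#'   `source` (p-values in (0,1]).
#' @param alpha significance threshold; `NULL` for the Bonferroni
#'   default.
#' @return list: `hits` (data frame of significant variant-phenotype
#'   pairs), `counts` (variants per phenotype), `alpha`.
#' @export
annotate_pleiotropy <- function(variants, table, alpha = NULL) {
  empty <- list(hits = data.frame(rsid = character(),
                                  phenotype = character(),
                                  pvalue = numeric(), source = character(),
                                  stringsAsFactors = FALSE),
                counts = integer(0), alpha = alpha %||% NA_real_)
  if (is.null(table) || nrow(table) == 0L) {
    warning("empty annotation table: nothing to report")
    return(empty)
  }
  stopifnot(all(c("rsid", "phenotype", "pvalue") %in% names(table)))
  if (any(table$pvalue <= 0 | table$pvalue > 1)) {
    stop("annotation p-values must be in (0,1]", call. = FALSE)
  }
  if (is.null(table$source)) table$source <- NA_character_
  alpha <- alpha %||% (0.05 / length(unique(table$phenotype)))
  hits <- table[table$rsid %in% variants & table$pvalue < alpha, ,
                drop = FALSE]
  hits <- hits[order(hits$phenotype, hits$pvalue), , drop = FALSE]
  rownames(hits) <- NULL
  counts <- vapply(split(hits$rsid, hits$phenotype),
                   function(v) length(unique(v)), integer(1))
  list(hits = hits, counts = counts, alpha = alpha)
}

#' Run the full cross-trait study
#'
#' [run_mr_workflow()] plus, when configured, cross-trait LD score
#' regression, the four-model scan for each region, and the local
#' pleiotropy annotation join. Stage failures are captured per stage
#' so a partial bundle is still returned.
#'
#' @param config an [analysis_config()].
#' @return list of class `study_bundle`: `mr`, `ldsc`, `regions`
#'   (named list of [region_posteriors()]), `pleiotropy`, `status`
#'   (per-stage `"ok"`/error message), `config_hash`.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  status <- list()
  stage <- function(name, expr) {
    tryCatch({
      out <- force(expr)
      status[[name]] <<- "ok"
      out
    }, error = function(e) {
      status[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  mr <- stage("mr", run_mr_workflow(config))
  ldsc <- if (!is.null(config$ldsc)) {
    stage("ldsc", do.call(rg_regression, config$ldsc))
  } else {
    status$ldsc <- "skipped: no inputs"
    NULL
  }
  regions <- if (!is.null(config$regions)) {
    stage("regions", lapply(config$regions, region_posteriors))
  } else {
    status$regions <- "skipped: no regions"
    NULL
  }
  pleio <- if (!is.null(config$annotation) && !is.null(mr)) {
    stage("pleiotropy",
          annotate_pleiotropy(mr$estimates$rsid, config$annotation))
  } else {
    status$pleiotropy <- "skipped: no annotation table"
    NULL
  }
  bundle <- structure(list(mr = mr, ldsc = ldsc, regions = regions,
                           pleiotropy = pleio, status = status,
                           config_hash = config_hash(config)),
                      class = "study_bundle")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    summ <- list(status = status, config_hash = bundle$config_hash)
    if (!is.null(mr)) summ$mr <- mr$table1
    if (!is.null(ldsc)) {
      summ$ldsc <- ldsc[c("h2_1", "h2_2", "gcov", "rg", "rg_se", "p_rg",
                          "intercept_x")]
    }
    if (!is.null(regions)) {
      summ$regions <- lapply(regions, function(r)
        r[c("pp0", "pp1", "pp2", "pp3", "pp4")])
    }
    jsonlite::write_json(summ, file.path(config$outdir, "study_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  bundle
}

#' Parse a region specification string
#'
#' `"chr19:44744147-46101600"` -> list(chrom, start, end), 1-based
#' inclusive.
#' @param spec region string.
#' @export
parse_region_spec <- function(spec) {
  m <- regmatches(spec, regexec("^(chr)?([0-9XY]+):([0-9,]+)-([0-9,]+)$", spec))[[1]]
  if (length(m) == 0L) stop("malformed region spec: ", spec, call. = FALSE)
  strip <- function(x) as.numeric(gsub(",", "", x))
  out <- list(chrom = m[3], start = strip(m[4]), end = strip(m[5]))
  if (out$start > out$end) stop("region start after end: ", spec, call. = FALSE)
  out
}
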