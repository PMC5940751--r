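exp1 <- function(ea = "A", oa = "G", beta = 0.1, eaf = 0.3) {
  make_sumstats("rs1", ea, oa, beta, 0.02, eaf = eaf)
}
out1 <- function(ea, oa, beta = 0.2, eaf = 0.3) {
  make_sumstats("rs1", ea, oa, beta, 0.05, eaf = eaf)
}

test_that("allele orientations resolve to the documented actions", {
  h <- harmonize(exp1(), out1("A", "G"))
  expect_equal(h$action, "kept")
  expect_equal(h$beta_out, 0.2)

  h <- harmonize(exp1(), out1("G", "A", beta = 0.2, eaf = 0.7))
  expect_equal(h$action, "swapped")
  expect_equal(h$beta_out, -0.2)
  expect_equal(h$eaf_out, 0.3)

  h <- harmonize(exp1(), out1("T", "C"))   # opposite strand of A/G
  expect_equal(h$action, "strand-flipped")
  expect_equal(h$beta_out, 0.2)

  h <- harmonize(exp1(), out1("C", "T", eaf = 0.7))
  expect_equal(h$action, "swapped+flipped")
  expect_equal(h$beta_out, -0.2)

  h <- harmonize(exp1(), out1("A", "C"))   # irreconcilable
  expect_equal(h$action, "allele-mismatch")
  expect_false(h$kept)
})

test_that("palindromic variants are dropped in the ambiguous band, else aligned by frequency", {
  # eaf exactly 0.5: unresolvable at any window
  h <- harmonize(exp1("A", "T", eaf = 0.50), out1("A", "T", eaf = 0.3))
  expect_equal(h$action, "dropped-palindromic")

  # both frequencies clear of 0.5 and concordant: kept as labelled
  h <- harmonize(exp1("A", "T", eaf = 0.2), out1("A", "T", eaf = 0.25))
  expect_equal(h$action, "kept")
  expect_equal(h$beta_out, 0.2)

  # discordant frequencies reveal a strand flip despite matching labels
  h <- harmonize(exp1("A", "T", eaf = 0.2), out1("A", "T", eaf = 0.75))
  expect_equal(h$action, "swapped+flipped")
  expect_equal(h$beta_out, -0.2)
  expect_equal(h$eaf_out, 0.25)

  # window boundary: eaf 0.57 inside default 0.5 +/- 0.08
  h <- harmonize(exp1("A", "T", eaf = 0.57), out1("A", "T", eaf = 0.62))
  expect_equal(h$action, "dropped-palindromic")
  h <- harmonize(exp1("A", "T", eaf = 0.57), out1("A", "T", eaf = 0.62),
                 palindrome_eaf_window = 0.05)
  expect_equal(h$action, "kept")
})

test_that("rsids absent from either table are reported as dropped-missing", {
  e <- make_sumstats(c("rs1", "rs2"), "A", "G", 0.1, 0.02)
  o <- make_sumstats(c("rs2", "rs9"), "A", "G", 0.2, 0.05)
  h <- harmonize(e, o)
  expect_setequal(h$rsid, c("rs1", "rs2", "rs9"))
  expect_equal(h$action[h$rsid == "rs1"], "dropped-missing")
  expect_equal(h$action[h$rsid == "rs9"], "dropped-missing")
  expect_equal(sum(h$kept), 1L)
})

test_that("harmonization is idempotent on an already-aligned pair", {
  set.seed(42)
  for (rep in 1:25) {
    pair <- sample(list(c("A", "G"), c("C", "T"), c("G", "C"), c("A", "T")), 1)[[1]]
    eaf <- sample(c(0.2, 0.8), 1)
    e <- exp1(pair[1], pair[2], beta = rnorm(1), eaf = eaf)
    o <- out1(pair[1], pair[2], beta = rnorm(1), eaf = eaf)
    h1 <- harmonize(e, o)
    if (!h1$kept) next
    # feed the harmonized outcome back in: nothing may change
    o2 <- make_sumstats("rs1", pair[1], pair[2], h1$beta_out, h1$se_out,
                        eaf = h1$eaf_out)
    h2 <- harmonize(e, o2)
    expect_equal(h2$action, "kept")
    expect_equal(h2$beta_out, h1$beta_out)
    expect_equal(h2$eaf_out, h1$eaf_out)
  }
})

test_that("negating the outcome beta and swapping its alleles round-trips", {
  set.seed(42)
  pairs <- list(c("A", "G"), c("C", "A"), c("T", "G"), c("C", "T"),
                c("A", "T"), c("G", "C"))
  for (rep in 1:40) {
    pr <- pairs[[sample(length(pairs), 1)]]
    eaf <- runif(1, 0.1, 0.9)
    if (abs(eaf - 0.5) <= 0.1) eaf <- 0.2      # stay out of the drop band
    b <- rnorm(1)
    e <- exp1("A", "G", eaf = 0.2)
    e <- make_sumstats("rs1", pr[1], pr[2], 0.1, 0.02, eaf = eaf)
    o <- make_sumstats("rs1", pr[1], pr[2], b, 0.05, eaf = eaf)
    o_sw <- make_sumstats("rs1", pr[2], pr[1], -b, 0.05, eaf = 1 - eaf)
    h <- harmonize(e, o)
    h_sw <- harmonize(e, o_sw)
    expect_equal(h_sw$beta_out, h$beta_out)
    expect_equal(h_sw$eaf_out, h$eaf_out)
  }
})

test_that("the harmonization report round-trips through TSV", {
  e <- make_sumstats(c("rs1", "rs2"), "A", "G", 0.1, 0.02)
  o <- make_sumstats("rs2", "G", "A", 0.2, 0.05, eaf = 0.7)
  h <- harmonize(e, o)
  f <- tempfile(fileext = ".tsv")
  write_harmonization_report(h, f)
  back <- read.delim(f)
  expect_equal(back$action[back$rsid == "rs2"], "swapped")
  expect_equal(nrow(back), nrow(h))
})
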