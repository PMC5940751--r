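test_that("every simulator is byte-reproducible under a fixed seed", {
  expect_identical(simulate_mr_study(k = 12, gamma = 0.2, seed = 42),
                   simulate_mr_study(k = 12, gamma = 0.2, seed = 42))
  expect_identical(simulate_ldsc_panel(m = 500, seed = 42),
                   simulate_ldsc_panel(m = 500, seed = 42))
  expect_identical(simulate_region(m = 20, config = "shared", seed = 42),
                   simulate_region(m = 20, config = "shared", seed = 42))
  expect_identical(simulate_haplotypes(m = 10, n_hap = 30, seed = 42),
                   simulate_haplotypes(m = 10, n_hap = 30, seed = 42))
  # and different seeds diverge
  expect_false(identical(simulate_mr_study(k = 12, seed = 1),
                         simulate_mr_study(k = 12, seed = 2)))
})

test_that("simulators leave the caller's RNG stream untouched", {
  set.seed(7)
  a <- runif(1)
  set.seed(7)
  invisible(simulate_mr_study(k = 5, seed = 99))
  expect_identical(runif(1), a)
})

test_that("null causal effect is recovered: IVW within 2 SEs of 0 in >=95/100", {
  hit <- 0
  for (s in 1:100) {
    sim <- simulate_mr_study(k = 20, gamma = 0, seed = s)
    est <- wald_ratios_from_pairs(harmonize(sim$exposure, sim$outcome))
    f <- ivw_fixed(est)
    if (abs(f$theta_hat) < 2 * f$se) hit <- hit + 1
  }
  expect_gte(hit, 95)
})

test_that("the truth record describes the planted outlier and round-trips JSON", {
  sim <- simulate_mr_study(k = 52, gamma = 0,
                           pleiotropy_spec = list(type = "outlier", index = 3),
                           seed = 42)
  truth <- sim$truth
  expect_equal(unname(truth$pleiotropy[truth$outlier_rsid]), log(3.2))
  expect_equal(sum(truth$pleiotropy != 0), 1L)

  f <- tempfile(fileext = ".json")
  write_truth(truth, f)
  back <- read_truth(f)
  expect_equal(back$gamma, truth$gamma)
  expect_equal(back$outlier_rsid, truth$outlier_rsid)
  expect_equal(unname(unlist(back$pleiotropy)), unname(truth$pleiotropy))
})

test_that("simulated z-score moments follow the LD-score model", {
  sim <- simulate_ldsc_panel(m = 20000, h2_1 = 0.3, h2_2 = 0.3, rg = 0.4,
                             n1 = 2000, n2 = 2000, seed = 42)
  l <- sim$ldscores$l
  expected <- 1 + 2000 * 0.3 * l / 20000
  # bin by LD score and compare conditional means of z^2
  bins <- cut(l, quantile(l, 0:5 / 5), include.lowest = TRUE)
  obs <- tapply(sim$z1^2, bins, mean)
  exp_ <- tapply(expected, bins, mean)
  expect_lt(max(abs(obs - exp_) / exp_), 0.1)
  # cross-moment carries the genetic covariance
  expect_equal(mean(sim$z1 * sim$z2),
               mean(2000 * 0.4 * 0.3 * l / 20000), tolerance = 0.1)
  expect_error(simulate_ldsc_panel(m = 100, h2_1 = 0, h2_2 = 0, rg = 1,
                                   overlap = 1, rho_pheno = 3, seed = 1),
               "infeasible")
})

test_that("regional simulations carry their causal configuration", {
  sim <- simulate_region(m = 40, config = "distinct", seed = 42)
  expect_equal(length(sim$truth$causal_index), 2L)
  expect_equal(nrow(sim$region), 40L)
  # distinct causal variants are separated into opposite thirds
  expect_lt(sim$truth$causal_index[1], 14)
  expect_gt(sim$truth$causal_index[2], 26)
  expect_equal(simulate_region(m = 20, config = "null",
                               seed = 1)$truth$causal_index, integer(0))
  expect_error(simulate_region(m = 3, ld_rho = matrix(c(1, 2, 2, 2, 1, 2,
                                                        2, 2, 1), 3), seed = 1),
               "positive semi-definite")
})

test_that("haplotype LD decays as configured", {
  # decay = 0: perfect copying, adjacent r2 = 1
  p0 <- simulate_haplotypes(m = 5, n_hap = 50, decay = 0, seed = 42)
  expect_equal(ld_d_prime_r2(p0, "hv0001", "hv0005")$r2, 1)

  # large decay: independence; mean off-diagonal r2 ~ 1/n_hap
  set.seed(42)
  r2s <- c()
  for (s in 1:5) {
    p <- simulate_haplotypes(m = 12, n_hap = 100, decay = 50, seed = s)
    pr <- t(combn(p$variants$rsid, 2))
    r2s <- c(r2s, apply(pr, 1, function(v)
      tryCatch(ld_d_prime_r2(p, v[1], v[2])$r2, error = function(e) NA)))
  }
  expect_equal(mean(r2s, na.rm = TRUE), 1 / 100, tolerance = 0.5)

  # planted block: complete D' with low r2, the rare-on-common signature
  pb <- simulate_haplotypes(m = 6, n_hap = 200, decay = 1,
                            plant_block = TRUE, seed = 42)
  ld <- ld_d_prime_r2(pb, "blockC", "blockD")
  expect_equal(ld$d_prime, 1)
  expect_lt(ld$r2, 0.1)
})
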