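test_that("Wald ratios and their first/second-order standard errors", {
  w <- wald_ratio(0.2, 0.1, 0.1, 0.02, order = "first")
  expect_equal(w$theta, 2)
  expect_equal(w$se, 1)
  w <- wald_ratio(0, 0.1, 0.5, 0.01, order = "first")
  expect_equal(w$theta, 0)
  expect_equal(w$se, 0.2)
  w <- wald_ratio(0.2, 0.1, 0.1, 0.02, order = "second")
  expect_equal(w$se, sqrt(1.16))   # delta-method plug-in
  expect_error(wald_ratio(0.1, 0.1, 0, 0.01), "zero")
})

test_that("IVW pooling: identity, equal weights, and the brute-force oracle", {
  one <- wald_ratio(0.2, 0.1, 0.1, 0.02)
  f1 <- ivw_fixed(one)
  expect_equal(f1$theta_hat, one$theta)
  expect_equal(f1$se, one$se)
  expect_true(is.na(f1$q))

  two <- data.frame(rsid = c("a", "b"), theta = c(1, 3), se = c(1, 1))
  f2 <- ivw_fixed(two)
  expect_equal(f2$theta_hat, 2)
  expect_equal(f2$se, 1 / sqrt(2))
  expect_equal(f2$q, 2)
  expect_equal(f2$df, 1L)
  expect_equal(f2$p_het, pchisq(2, 1, lower.tail = FALSE))
  expect_true(f2$ci95[1] < f2$or_ && f2$or_ < f2$ci95[2])

  set.seed(42)
  for (rep in 1:100) {
    k <- sample(2:60, 1)
    est <- data.frame(rsid = paste0("v", 1:k), theta = rnorm(k),
                      se = runif(k, 0.05, 2))
    f <- ivw_fixed(est)
    o <- oracle_ivw(est$theta, est$se)
    expect_equal(f$theta_hat, o$theta_hat, tolerance = 1e-10)
    expect_equal(f$se, o$se, tolerance = 1e-10)
    expect_equal(f$q, o$q, tolerance = 1e-10)
    # Q invariant to instrument ordering
    f_perm <- ivw_fixed(est[sample(k), ])
    expect_equal(f_perm$q, f$q, tolerance = 1e-10)
  }
})

test_that("pooled standard error strictly decreases as instruments accrue", {
  set.seed(42)
  est <- data.frame(rsid = paste0("v", 1:10), theta = rnorm(10, 0.2, 0.01),
                    se = runif(10, 0.1, 0.5))
  ses <- vapply(2:10, function(k) ivw_fixed(est[1:k, ])$se, numeric(1))
  expect_true(all(diff(c(ivw_fixed(est[1, , drop = FALSE])$se, ses)) < 0))
})

test_that("identical estimates are perfectly homogeneous", {
  est <- data.frame(rsid = paste0("v", 1:5), theta = 0.3, se = 0.1)
  f <- ivw_fixed(est)
  expect_equal(f$q, 0)
  expect_equal(f$p_het, 1)
  expect_error(cochran_q(est[1, , drop = FALSE], 0.3), "fewer than 2")
})

test_that("leave-one-out flags a planted outlier and nothing when homogeneous", {
  set.seed(42)
  k <- 20
  se <- runif(k, 0.05, 0.15)
  theta <- rep(0.2, k)
  theta[7] <- 4                      # gross invalid instrument
  est <- data.frame(rsid = paste0("v", 1:k), theta = theta, se = se)
  loo <- leave_one_out(est)
  expect_equal(loo$outlier, "v7")
  expect_true(loo$resolved)
  expect_equal(nrow(loo$table), k)
  expect_true(loo$table$q_drop[7] == max(loo$table$q_drop))

  homog <- data.frame(rsid = paste0("v", 1:5), theta = 0.3, se = 0.1)
  expect_true(is.na(leave_one_out(homog)$outlier))
  expect_error(leave_one_out(est[1:2, ]), "at least 3")
})

test_that("Egger regression recovers exact lines and affine pleiotropy", {
  bx <- c(0.05, 0.1, 0.2, 0.3)
  mk <- function(by) data.frame(beta_exp = bx, se_exp = 0.01,
                                beta_out = by, se_out = c(0.1, 0.2, 0.1, 0.3))
  f <- suppressWarnings(egger(mk(0.5 * bx)))   # exact fit trips summary.lm
  expect_equal(f$slope, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  f <- suppressWarnings(egger(mk(0.1 + 0.5 * bx)))
  expect_equal(f$slope, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 0.1, tolerance = 1e-12)
  expect_true(f$slope_se > 0 && f$intercept_se > 0)
  expect_error(egger(data.frame(beta_exp = c(0.1, 0.1, 0.1), se_exp = 0.01,
                                beta_out = 1:3, se_out = 0.1)),
               "degenerate")
})

test_that("Egger orients instruments to positive exposure effects", {
  set.seed(42)
  bx <- runif(10, 0.05, 0.3) * sample(c(-1, 1), 10, replace = TRUE)
  by <- 0.4 * bx + rnorm(10, 0, 0.05)
  d <- data.frame(beta_exp = bx, se_exp = 0.01, beta_out = by,
                  se_out = runif(10, 0.05, 0.2))
  d_flip <- d
  d_flip$beta_exp <- -d_flip$beta_exp
  d_flip$beta_out <- -d_flip$beta_out
  expect_equal(egger(d)$slope, egger(d_flip)$slope)
  expect_equal(egger(d)$intercept, egger(d_flip)$intercept)
})

test_that("Egger with the intercept pinned to zero reproduces IVW", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(3:40, 1)
    d <- data.frame(beta_exp = runif(k, 0.05, 0.4),
                    se_exp = runif(k, 0.005, 0.02),
                    beta_out = rnorm(k, 0, 0.2),
                    se_out = runif(k, 0.02, 0.2))
    ivw <- ivw_fixed(wald_ratio(d$beta_out, d$se_out, d$beta_exp, d$se_exp,
                                order = "first"))
    slope0 <- coef(lm(beta_out ~ beta_exp - 1, data = d,
                      weights = 1 / d$se_out^2))[[1]]
    expect_equal(slope0, ivw$theta_hat, tolerance = 1e-10)
  }
})

test_that("MR power: null boundary, monotonicity, detectable OR", {
  p <- mr_power(52, 0.133, 17008, 37154, true_or = 1.0, alpha = 0.05)
  expect_equal(p$power, 0.05)                    # two-sided size at the null
  p1 <- mr_power(52, 0.133, 17008, 37154, 1.10)
  p2 <- mr_power(52, 0.133, 2 * 17008, 2 * 37154, 1.10)
  expect_gte(p2$power, p1$power)
  # closed-form oracle at the study scale
  n <- 17008 + 37154; phi <- 17008 / n
  x <- log(1.10) * sqrt(n * 0.133 * phi * (1 - phi))
  expect_equal(p1$power, pnorm(-qnorm(0.975) + x) + pnorm(-qnorm(0.975) - x))
  # detectable OR sits exactly at 80% power
  expect_equal(mr_power(52, 0.133, 17008, 37154, p1$detectable_or)$power,
               0.80, tolerance = 1e-4)
  expect_error(mr_power(52, 1.3, 100, 100, 1.1), "variance_explained")
})
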