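test_that("latent IQ draws are seeded Normal(0, 15^2)", {
  x <- gen_iq_start(6000, seed = 1)
  expect_equal(mean(x), 0, tolerance = 0.6)
  expect_equal(sd(x), 15, tolerance = 0.4)
  expect_identical(x, gen_iq_start(6000, seed = 1))
  # distributional check against the target CDF at large n
  y <- gen_iq_start(1e5, seed = 2)
  D <- suppressWarnings(ks.test(y, pnorm, 0, 15))$statistic
  expect_lt(unname(D), 0.01)
  expect_error(gen_iq_start(1), ">= 2")
})

test_that("childhood score has reliability rho and variance 225", {
  x <- gen_iq_start(5e4, seed = 3)
  expect_identical(gen_iq_child(x, rho = 1), x)
  ch <- gen_iq_child(x, rho = 0.84, seed = 4)
  expect_equal(cor(ch, x), 0.84, tolerance = 0.01)
  expect_equal(var(ch), 225, tolerance = 5)
  expect_error(gen_iq_child(x, rho = 0), "rho")
  expect_error(gen_iq_child(x, rho = 1.2), "rho")
})

test_that("continuous adult score is variance-completed around its systematic part", {
  x <- gen_iq_start(6000, seed = 5)
  he <- p_selection(x, seed = 6)
  null_params <- model_params(b_HE = 0, b_start = 0)
  a0 <- gen_iq_afterN(x, he, null_params, seed = 7)
  expect_equal(var(a0), 225, tolerance = 8)
  expect_equal(cor(a0, x), 0, tolerance = 0.05)

  p <- model_params(b_HE = 4, b_start = 0.6)
  a <- gen_iq_afterN(x, he, p, seed = 8)
  expect_equal(var(a), 225, tolerance = 8)

  # infeasible systematic variance is refused
  expect_error(gen_iq_afterN(x, he, model_params(b_start = 1.01)),
               "infeasible")
})

test_that("nonlinear effect maps are applied per education level", {
  x <- gen_iq_start(8000, seed = 9)
  he <- rep(c(0, 2, 6, 10), each = 2000)
  em <- c(`0` = 0, `2` = 2.4, `6` = 3.1, `10` = 3.8)
  p <- model_params(b_start = 0.6, effect_map = em)
  a <- gen_iq_afterN(x, he, p, seed = 10)
  gains <- tapply(a - 0.6 * x, he, mean)
  centred <- em - mean(em[as.character(he)])
  expect_equal(as.numeric(gains),
               as.numeric(centred[as.character(c(0, 2, 6, 10))]),
               tolerance = 0.35)
  # map must cover every level present
  expect_error(gen_iq_afterN(x, he, model_params(effect_map = em[-2])),
               "lacks entries")
  expect_error(model_params(effect_map = c(`0` = 1, `2` = 0)),
               "non-decreasing")
})

test_that("e_after satisfies the exact reconstruction identity", {
  x <- gen_iq_start(2000, seed = 11)
  he <- p_selection(x, seed = 12)
  p <- model_params(b_HE = 4, b_start = 0.6)
  sysv <- 4 * (he - mean(he)) + 0.6 * x
  eN <- rnorm(2000, 0, sqrt(225 - var(sysv)))
  # identity scheme: no discretization error at all
  expect_identical(compute_e_after(x, he, eN, p, scheme = NULL), eN)
  # discretized: systematic + e_after reproduces the discrete variable
  sch <- make_scheme("triangular", 4)
  ea <- compute_e_after(x, he, eN, p, scheme = sch)
  expect_equal(sysv + ea, discretize(sysv + eN, sch), tolerance = 1e-12)
  expect_error(compute_e_after(x[-1], he, eN, p, sch), "same length")
})

test_that("a ceiling-style discretization induces negative error-predictor covariance", {
  # two levels, 90% low / 10% high: the top level absorbs a wide range of
  # high predictors, compressing them downward
  sch <- discretization_scheme(c(1, 2), c(0.9, 0.1))
  x <- gen_iq_start(1e4, seed = 13)
  he <- p_selection(x, seed = 14)
  p <- model_params(b_HE = 2, b_start = 0.6)
  sysv <- 2 * (he - mean(he)) + 0.6 * x
  eN <- withr::with_seed(15, rnorm(1e4, 0, sqrt(225 - var(sysv))))
  ea <- compute_e_after(x, he, eN, p, scheme = sch)
  expect_lt(cov(ea, x), 0)
})

test_that("with perfect measurement, plain regression recovers the truth", {
  # rho = 1 and no discretization: the observed-data regression is unbiased
  est <- replicate(20, {
    coh <- emulate_toy_cohort(n = 4000, b_HE = 4, rho = 1, scheme = NULL)
    estimate_cov(coh)$b_HE
  })
  expect_equal(mean(est), 4, tolerance = 3 * sd(est) / sqrt(20))
})

test_that("selection moments validate and serialize", {
  m <- selection_moments(c(0, 2, 6, 10), c(3877, 655, 1808, 426),
                         c(-6.2, 2.8, 8.1, 18.0))
  # latent IQ is centred: counts-weighted mean near zero relative to scale
  expect_lt(abs(sum(m$count * m$mean)) / sum(m$count), 0.1)
  expect_equal(moments_from_json(moments_to_json(m)), m)
  expect_error(selection_moments(c(0, 2), c(10, 20), c(1, NA)), "finite")
  expect_error(selection_moments(c(2, 0), c(10, 20), c(1, 2)), "increasing")
})

test_that("cohort validation catches malformed tables", {
  coh <- tiny_cohort()
  expect_s3_class(as_cohort(coh), "tbl_df")
  expect_error(as_cohort(coh[, c("iq_child", "he_years")]), "iq_after")
  bad <- coh
  bad$iq_child[1] <- NA
  expect_error(as_cohort(bad), "non-finite")
  bad2 <- coh
  bad2$he_years[1] <- -1
  expect_error(as_cohort(bad2), "non-negative")
})
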