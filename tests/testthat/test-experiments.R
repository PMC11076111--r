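test_that("the cohort emulator reproduces the design counts and latent means", {
  al <- calibrate_quota(6766, cohort_moments())
  coh <- emulate_cohort(seed = 1, alphas = al)
  expect_equal(nrow(coh), 6766)
  expect_equal(unname(table(coh$he_years)), c(3877L, 655L, 1808L, 426L),
               ignore_attr = TRUE)
  # observed outcome takes only scheme values (the rarest levels can be
  # empty at this n under largest-remainder counts)
  expect_true(all(coh$iq_after %in% numeracy_scheme()$levels))
  expect_gte(length(unique(coh$iq_after)), 20)
  means <- rowMeans(vapply(2:7, function(s) {
    c2 <- emulate_cohort(seed = s, alphas = al)
    unname(tapply(c2$iq_start, c2$he_years, mean))
  }, numeric(4)))
  expect_equal(means, cohort_moments()$mean, tolerance = 0.5)
})

test_that("a null education effect leaves adult scores flat across levels", {
  al <- calibrate_quota(6766, cohort_moments())
  diffs <- vapply(1:5, function(s) {
    coh <- emulate_cohort(params = model_params(b_HE = 0, b_start = 0),
                          seed = 10 + s, alphas = al)
    max(abs(tapply(coh$iq_after, coh$he_years, mean)))
  }, numeric(1))
  expect_lt(mean(diffs), 2)
})

test_that("cohort size can be rescaled while preserving the selection shape", {
  coh <- emulate_cohort(n = 1000, seed = 2)
  expect_equal(nrow(coh), 1000)
  tab <- unname(table(coh$he_years))
  expect_equal(as.integer(tab),
               as.integer(ismreg:::largest_remainder(
                 cohort_moments()$count / 6766, 1000)))
})

test_that("experiment runners are deterministic given a seed", {
  g1 <- run_toy_grid(b_HE = 4, rho = 1, selection = "p",
                     discretization = "uniform", reps = 3, n = 1500,
                     seed = 9)
  g2 <- run_toy_grid(b_HE = 4, rho = 1, selection = "p",
                     discretization = "uniform", reps = 3, n = 1500,
                     seed = 9)
  expect_equal(g1, g2)
  g3 <- run_toy_grid(b_HE = 4, rho = 1, selection = "p",
                     discretization = "uniform", reps = 3, n = 1500,
                     seed = 10)
  expect_false(isTRUE(all.equal(g1$mean, g3$mean)))
})

test_that("matched study returns tidy estimates and per-level diagnostics", {
  st <- run_matched_study("linear", reps = 3, n = 1600, seed = 11)
  expect_s3_class(st, "he_study")
  expect_equal(sort(unique(st$estimates$method)), c("cov", "eiv", "ism"))
  expect_equal(nrow(st$estimates), 9)
  td <- tidy(st)
  expect_equal(nrow(td), 3)
  gl <- glance(st)
  expect_equal(gl$level, c(0, 2, 6, 10))
  expect_true(all(is.finite(gl$mean_difference)))
})

test_that("nonlinear truth uses the requested cumulative gain variant", {
  expect_equal(unname(nonlinear_effect("text")), c(0, 2.4, 3.1, 3.8))
  expect_equal(unname(nonlinear_effect("table")), c(0, 2.6, 3.2, 3.8))
  st <- run_matched_study("nonlinear",
                          effect_map = nonlinear_effect("table"),
                          reps = 2, n = 1600, seed = 12)
  expect_equal(st$truth, "nonlinear")
})

test_that("autoplot and diagnostic plots build without error", {
  g <- run_toy_grid(b_HE = 4, rho = 1, selection = "p",
                    discretization = c("none", "uniform"), reps = 2,
                    n = 1200, seed = 13)
  expect_s3_class(autoplot(g), "ggplot")
  st <- run_matched_study("linear", reps = 2, n = 1600, seed = 14)
  expect_s3_class(plot_diagnostics(st), "ggplot")
  coh <- tiny_cohort(n = 500, scheme = make_scheme("uniform", 4))
  b <- bootstrap_estimates(coh, method = "cov", B = 20, seed = 15)
  expect_s3_class(autoplot(b), "ggplot")
})
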