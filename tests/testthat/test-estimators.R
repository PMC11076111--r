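test_that("the covariate estimator equals brute-force normal equations and lm()", {
  d <- hand_cohort()
  fit <- estimate_cov(d)
  oracle <- ols_oracle(d)
  expect_equal(fit$b_HE, oracle[1], tolerance = 1e-10)
  expect_equal(fit$b_start, oracle[2], tolerance = 1e-10)
  lmfit <- lm(iq_after ~ I(he_years - mean(he_years)) + iq_child, data = d)
  expect_equal(fit$b_HE, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(fit$b_start, unname(coef(lmfit)[3]), tolerance = 1e-10)
})

test_that("eiv with perfect reliability reduces exactly to the covariate estimator", {
  for (s in 1:5) {
    coh <- tiny_cohort(seed = s)
    cv <- estimate_cov(coh)
    ev <- estimate_eiv(coh, rho = 1)
    expect_equal(ev$b_HE, cv$b_HE, tolerance = 1e-12)
    expect_equal(ev$b_start, cv$b_start, tolerance = 1e-12)
  }
})

test_that("with an orthogonal covariate, b_HE is the simple regression slope for any rho", {
  d <- tibble::tibble(iq_child = c(1, -1, 1, -1),
                      he_years = c(0, 0, 1, 1),
                      iq_after = c(2, -1, 5, 1))
  slope <- cov(d$iq_after, d$he_years) / var(d$he_years)
  expect_equal(estimate_cov(d)$b_HE, slope, tolerance = 1e-12)
  expect_equal(estimate_eiv(d, 0.84)$b_HE, slope, tolerance = 1e-12)
  expect_equal(estimate_eiv(d, 0.6)$b_HE, slope, tolerance = 1e-12)
})

test_that("eiv is unbiased under classical error without discretization", {
  est <- vapply(1:30, function(s) {
    coh <- emulate_toy_cohort(n = 6000, b_HE = 4, rho = 0.84,
                              selection = "p", scheme = NULL, seed = 500 + s)
    estimate_eiv(coh, 0.84)$b_HE
  }, numeric(1))
  expect_equal(mean(est), 4, tolerance = 3 * sd(est) / sqrt(30))
})

test_that("degenerate designs raise informative estimator errors", {
  d <- hand_cohort()
  d$he_years <- rep(2, 6)
  expect_error(estimate_cov(d), "zero variance")
  d2 <- hand_cohort()
  d2$iq_child <- d2$he_years * 3  # perfectly collinear
  expect_error(estimate_cov(d2), "[Cc]ollinear")
  expect_error(estimate_eiv(hand_cohort(), rho = 0.05), "implausibly low")
})

test_that("the latent spec satisfies its moment contract", {
  n <- 1e4
  coh <- emulate_toy_cohort(n = n, b_HE = 4, rho = 0.84, selection = "p",
                            seed = 23, scheme = make_scheme("uniform", 4))
  spec <- compute_latent_spec(coh, 0.84)
  sims <- vapply(1:100, function(s) {
    sim <- simulate_iq_start(coh, spec, seed = 600 + s)
    c(var(sim), cov(sim, coh$iq_child),
      mean(sim[coh$he_years == 1]))
  }, numeric(3))
  expect_equal(mean(sims[1, ]), 225, tolerance = 3)
  expect_equal(mean(sims[2, ]), 225 * 0.84, tolerance = 3)
  m1_child <- mean(coh$iq_child[coh$he_years == 1])
  expect_equal(mean(sims[3, ]), m1_child / 0.84, tolerance = 0.3)
})

test_that("perfect reliability collapses the latent simulation onto the childhood score", {
  coh <- tiny_cohort(rho = 1)
  spec <- compute_latent_spec(coh, 1)
  expect_equal(spec$beta, 0)
  expect_equal(spec$e_start_sd, 0)
  expect_equal(simulate_iq_start(coh, spec), coh$iq_child)
})

test_that("balanced two-level designs scale latent group means by 1/rho exactly", {
  # group means of the deterministic part of the generating equation;
  # data built on the IQ scale (within-group spread completes var to ~225)
  child <- withr::with_seed(77, c(rnorm(100, 0, sqrt(125)) - 10,
                                  rnorm(100, 0, sqrt(125)) + 10))
  child <- child - mean(child)
  d <- tibble::tibble(iq_child = child,
                      he_years = rep(c(0, 1), each = 100),
                      iq_after = child)
  rho <- 0.84
  spec <- compute_latent_spec(d, rho)
  sysL <- spec$beta * spec$m_child + (1 / rho - spec$beta) * d$iq_child
  g <- tapply(d$iq_child, d$he_years, mean)
  expect_equal(unname(tapply(sysL, d$he_years, mean)), unname(g) / rho,
               tolerance = 1e-10)
})

test_that("simulated latent draws are seeded and reduce to an affine map at zero noise", {
  coh <- tiny_cohort()
  spec <- compute_latent_spec(coh, 0.84)
  s1 <- simulate_iq_start(coh, spec, seed = 42)
  expect_identical(s1, simulate_iq_start(coh, spec, seed = 42))
  expect_false(identical(s1, simulate_iq_start(coh, spec, seed = 43)))
  spec0 <- spec
  spec0$sd[] <- 0
  expect_equal(simulate_iq_start(coh, spec0),
               spec$beta * spec$m_child +
                 (1 / 0.84 - spec$beta) * coh$iq_child)
})

test_that("the per-level latent construction is the exact group-wise posterior", {
  coh <- emulate_toy_cohort(n = 5000, b_HE = 4, rho = 0.84, selection = "p2",
                            scheme = make_scheme("uniform", 4), seed = 61)
  spec <- compute_latent_spec(coh, 0.84, latent = "by_level")
  # per level: shrinkage toward the level mean of child / rho, residual sd
  # shared within the level
  for (l in c(0, 1)) {
    i <- coh$he_years == l
    expect_equal(length(unique(round(spec$sd[i], 10))), 1)
    # posterior means average to the level mean scaled by 1/rho
    expect_equal(mean(spec$mean[i]), mean(coh$iq_child[i]) / 0.84,
                 tolerance = 1e-10)
  }
  # at rho = 1 both constructions collapse onto the childhood score
  s1 <- compute_latent_spec(coh, 1, latent = "by_level")
  expect_equal(s1$mean, coh$iq_child)
  expect_equal(s1$sd, rep(0, nrow(coh)))
  # the heteroscedastic construction removes the residual bias of the
  # global one in the extreme uniform-discretization cell
  est <- vapply(1:30, function(s) {
    d <- emulate_toy_cohort(n = 6000, b_HE = 8, rho = 0.84,
                            selection = "p2",
                            scheme = make_scheme("uniform", 4),
                            seed = 900 + s)
    estimate_ism(d, 0.84, scheme = make_scheme("uniform", 4),
                 seed = 950 + s, latent = "by_level")$b_HE
  }, numeric(1))
  expect_equal(mean(est), 8, tolerance = 3 * sd(est) / sqrt(30))
})

test_that("ism with an undiscretized outcome agrees with eiv", {
  coh <- emulate_toy_cohort(n = 6000, b_HE = 4, rho = 0.84, selection = "p",
                            scheme = NULL, seed = 29)
  ev <- estimate_eiv(coh, 0.84)
  im <- estimate_ism(coh, 0.84, scheme = NULL, D = 50, seed = 30)
  expect_equal(im$b_HE, ev$b_HE, tolerance = 0.25)
  expect_equal(im$b_start, ev$b_start, tolerance = 0.05)
})

test_that("the ism fixed point is stable and reproducible", {
  sch <- make_scheme("triangular", 4)
  coh <- emulate_toy_cohort(n = 6000, b_HE = 4, rho = 0.84, selection = "p",
                            scheme = sch, seed = 31)
  fit <- estimate_ism(coh, 0.84, scheme = sch, seed = 32)
  expect_true(fit$converged)
  # same seed, same answer
  fit2 <- estimate_ism(coh, 0.84, scheme = sch, seed = 32)
  expect_identical(fit$b_HE, fit2$b_HE)
  # restarting at the converged values moves less than the tolerance
  fit3 <- estimate_ism(coh, 0.84, scheme = sch, seed = 32,
                       b_init = c(fit$b_HE, fit$b_start))
  expect_lt(abs(fit3$b_HE - fit$b_HE), fit$tolerance)
  expect_lt(abs(fit3$b_start - fit$b_start), fit$tolerance)
})

test_that("hitting the iteration cap flags non-convergence", {
  sch <- make_scheme("triangular", 4)
  coh <- emulate_toy_cohort(n = 2000, b_HE = 4, rho = 0.84, selection = "p",
                            scheme = sch, seed = 33)
  expect_warning(fit <- estimate_ism(coh, 0.84, scheme = sch, seed = 34,
                                     max_iter = 1, tolerance = 1e-6),
                 "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$iterations, 1)
})

test_that("fit objects tidy, glance and serialize", {
  coh <- tiny_cohort(scheme = make_scheme("uniform", 4))
  fit <- estimate_ism(coh, 0.84, seed = 35)
  td <- tidy(fit)
  expect_equal(td$term, c("b_HE", "b_start"))
  expect_equal(td$estimate, c(fit$b_HE, fit$b_start))
  gl <- glance(fit)
  expect_equal(gl$method, "ism")
  expect_true(is.finite(gl$iterations))
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$b_HE, fit$b_HE)
  expect_equal(js$method, "ism")
})
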