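# Shared fixtures, built in code.

# A small deterministic cohort with nontrivial selection, used where the
# statistical content of the data does not matter.
tiny_cohort <- function(n = 400, seed = 7, rho = 0.84, scheme = NULL) {
  emulate_toy_cohort(n = n, b_HE = 4, rho = rho, selection = "p",
                     scheme = scheme, seed = seed)
}

# Six-row dataset for closed-form estimator checks (hand-checkable scale).
hand_cohort <- function() {
  tibble::tibble(
    iq_child = c(-12, -5, 0, 3, 8, 14),
    he_years = c(0, 0, 2, 2, 6, 6),
    iq_after = c(-10, -7, 1, 4, 9, 15))
}

# Brute-force normal-equation solve for the covariate regression:
# independent linear-algebra oracle for estimate_cov().
ols_oracle <- function(data) {
  hec <- data$he_years - mean(data$he_years)
  X <- cbind(1, hec, data$iq_child)
  solve(t(X) %*% X, t(X) %*% data$iq_after)[2:3]
}

# Synthetic raw extract mimicking a cohort-study export (twins, missing
# education, zero scores included on purpose).
synthetic_extract <- function(n = 40, seed = 31) {
  withr::with_seed(seed, {
    quals <- sample(c("None", "O-level", "A-level", "Degree",
                      "Higher degree", "PGCE"), n, replace = TRUE)
    df <- tibble::tibble(
      id = seq_len(n),
      twin = rep(c(0, 0, 0, 0, 1), length.out = n),
      qualification = quals,
      word_definitions = rpois(n, 15) + 1,
      recall_digits = rpois(n, 20) + 1,
      similarities = rpois(n, 10) + 1,
      matrices = rpois(n, 12) + 1,
      numeracy = pmin(23, rpois(n, 17) + 1))
    df$qualification[3] <- NA
    df$numeracy[8] <- 0
    df
  })
}
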