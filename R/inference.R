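#' Nonparametric bootstrap for the education-effect estimators
#'
#' Case resampling of individuals with replacement. Each resample is
#' re-estimated with the chosen method; the reported point estimate is the
#' mean over resamples (the full-sample plug-in estimate is also kept) and
#' the confidence interval is the percentile interval. A resample on which
#' the estimator fails (e.g. a singular design) is redrawn and the redraw
#' count recorded.
#'
#' @inheritParams estimate_eiv
#' @param method One of `"cov"`, `"eiv"`, `"ism"`.
#' @param scheme Discretization scheme for `method = "ism"`; default is the
#'   empirical scheme of the observed outcome.
#' @param B Number of bootstrap resamples (>= 2).
#' @param level Confidence level for the percentile interval.
#' @param seed Optional integer seed.
#' @param ... Passed on to the estimator (e.g. `D`, `tolerance`).
#' @return A `he_boot` object; `tidy()` gives one row per parameter with
#'   point estimate and interval, `glance()` the resampling metadata.
#' @examples
#' cohort <- emulate_cohort(n = 1500, seed = 1)
#' bootstrap_estimates(cohort, method = "eiv", rho = 0.84, B = 50, seed = 2)
#' @export
bootstrap_estimates <- function(data, method = c("ism", "eiv", "cov"),
                                rho = 0.84, scheme = NULL, B = 1000,
                                level = 0.95, seed = NULL, ...) {
  data <- as_cohort(data)
  method <- match.arg(method)
  if (B < 2) stop("`B` must be at least 2.", call. = FALSE)
  n <- nrow(data)
  if (method == "ism" && is.null(scheme)) {
    scheme <- make_scheme("empirical", observed = data$iq_after)
  }
  one_estimate <- function(d, s) {
    switch(method,
           cov = estimate_cov(d),
           eiv = estimate_eiv(d, rho),
           ism = estimate_ism(d, rho, scheme = scheme, seed = s, ...))
  }
  plugin <- one_estimate(data, seed)
  seeds <- child_seeds(seed, 2L * B)
  draws <- with_seed_(seed, replicate(B, sample.int(n, n, replace = TRUE),
                                      simplify = FALSE))
  failures <- 0L
  reps <- vector("list", B)
  extra <- B  # next spare seed index
  for (b in seq_len(B)) {
    idx <- draws[[b]]
    repeat {
      fit <- tryCatch(
        suppressWarnings(one_estimate(data[idx, ], seeds[[b]])),
        error = function(e) NULL)
      if (!is.null(fit)) break
      failures <- failures + 1L
      extra <- extra + 1L
      if (extra > length(seeds)) {
        stop("Too many estimator failures during bootstrap.", call. = FALSE)
      }
      idx <- with_seed_(seeds[[extra]], sample.int(n, n, replace = TRUE))
    }
    reps[[b]] <- c(fit$b_HE, fit$b_start)
  }
  mat <- do.call(rbind, reps)
  colnames(mat) <- c("b_HE", "b_start")
  alpha <- (1 - level) / 2
  structure(list(method = method, rho = rho, B = B, level = level,
                 replicates = tibble::as_tibble(mat),
                 point = colMeans(mat),
                 plugin = c(b_HE = plugin$b_HE, b_start = plugin$b_start),
                 ci_low = apply(mat, 2, stats::quantile, probs = alpha),
                 ci_high = apply(mat, 2, stats::quantile, probs = 1 - alpha),
                 failures = failures),
            class = "he_boot")
}

#' @export
print.he_boot <- function(x, ...) {
  cat("<he_boot: ", x$method, ">  B = ", x$B, " resamples, ",
      round(100 * x$level), "% percentile CIs\n", sep = "")
  for (p in names(x$point)) {
    cat(sprintf("  %-8s %.3f [%.3f, %.3f]\n", p, x$point[[p]],
                x$ci_low[[p]], x$ci_high[[p]]))
  }
  invisible(x)
}

#' @rdname tidy.he_fit
#' @export
tidy.he_boot <- function(x, ...) {
  tibble::tibble(term = names(x$point),
                 estimate = unname(x$point),
                 plugin = unname(x$plugin),
                 conf.low = unname(x$ci_low),
                 conf.high = unname(x$ci_high),
                 method = x$method)
}

#' @rdname tidy.he_fit
#' @export
glance.he_boot <- function(x, ...) {
  tibble::tibble(method = x$method, rho = x$rho, B = x$B, level = x$level,
                 failures = x$failures)
}

#' Per-level model-fit diagnostics
#'
#' Compares the mean observed adult score at each length of higher
#' education with the mean simulated adult score in the final iteration of
#' the ism fit. Systematic per-level differences flag model misspecification:
#' in particular, a true education effect that is concentrated in the first
#' years shows up as the observed 2-year group scoring above the linear-model
#' simulation.
#'
#' @param data The cohort the fit was computed on.
#' @param fit An [estimate_ism()] result (must carry simulated outcomes).
#' @return A tibble with columns `level`, `n`, `observed`, `simulated`,
#'   `difference` (observed minus simulated, IQ points).
#' @export
fit_diagnostics <- function(data, fit) {
  data <- as_cohort(data)
  stopifnot(inherits(fit, "he_fit"))
  if (is.null(fit$sim_after)) {
    stop("`fit` carries no simulated outcomes; use an estimate_ism() result.",
         call. = FALSE)
  }
  if (length(fit$sim_after) != nrow(data) ||
      !isTRUE(all.equal(fit$he_years, data$he_years))) {
    stop("`fit` was not computed on `data`.", call. = FALSE)
  }
  tibble::tibble(level = data$he_years,
                 observed = data$iq_after,
                 simulated = fit$sim_after) |>
    dplyr::group_by(level) |>
    dplyr::summarise(n = dplyr::n(),
                     observed = mean(observed),
                     simulated = mean(simulated),
                     .groups = "drop") |>
    dplyr::mutate(difference = observed - simulated)
}

#' Reliability of the childhood score for start-of-education IQ
#'
#' Combines published test-retest correlations into the reliability `rho`
#' used by the eiv and ism estimators: the 6-year retest correlations at two
#' anchor ages are linearly interpolated at `target_age`, then divided by
#' the square root of the same-day retest correlation to remove the error in
#' the hypothetical later test itself.
#'
#' @param retest_6yr_age9 Six-year test-retest correlation anchored at age 9.
#' @param retest_6yr_age12 Six-year test-retest correlation anchored at age
#'   12.
#' @param target_age Age (years) at which the childhood test was taken.
#' @param shortterm_retest Same-day retest correlation of the later test.
#' @return Estimated reliability `rho` (scalar).
#' @examples
#' estimate_reliability(0.81, 0.84, target_age = 10, shortterm_retest = 0.95)
#' @export
estimate_reliability <- function(retest_6yr_age9, retest_6yr_age12,
                                 target_age = 10, shortterm_retest = 0.95) {
  for (r in c(retest_6yr_age9, retest_6yr_age12, shortterm_retest)) {
    if (!is.numeric(r) || r <= 0 || r > 1) {
      stop("Correlations must lie in (0, 1].", call. = FALSE)
    }
  }
  if (target_age < 9 || target_age > 12) {
    warning("`target_age` outside [9, 12]; extrapolating the retest ",
            "correlations.")
  }
  w <- (target_age - 9) / 3
  retest <- (1 - w) * retest_6yr_age9 + w * retest_6yr_age12
  retest / sqrt(shortterm_retest)
}
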