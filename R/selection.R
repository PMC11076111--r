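#' Rank-probability selection into higher education
#'
#' Stochastic selection rules that create the confounding between latent
#' ability and education. With `p(i)` the proportion of individuals with
#' strictly lower latent IQ than individual `i` (ties share the average
#' rank), `p_selection()` assigns one year of higher education with
#' probability `p(i)` and `p2_selection()` with probability `p(i)^2`.
#' Expected selected fractions are 1/2 and 1/3; the analytic group means of
#' latent IQ under a Normal(0, 15^2) population are +/- 15/sqrt(pi) = 8.46
#' for p-selection and (-45/(4*sqrt(pi)) * ... ) -6.35 / +12.69 for
#' p^2-selection.
#'
#' @param iq_start Latent IQ vector (length >= 2).
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector of years of higher education.
#' @export
p_selection <- function(iq_start, seed = NULL) {
  p <- rank_proportion(iq_start)
  with_seed_(seed, stats::rbinom(length(iq_start), 1L, p))
}

#' @rdname p_selection
#' @export
p2_selection <- function(iq_start, seed = NULL) {
  p <- rank_proportion(iq_start)
  with_seed_(seed, stats::rbinom(length(iq_start), 1L, p^2))
}

# proportion with strictly lower value; ties share the average rank,
# scaled to [0, 1)
rank_proportion <- function(x) {
  n <- length(x)
  if (n < 2) stop("Need at least 2 individuals.", call. = FALSE)
  (rank(x, ties.method = "average") - 1) / n
}

#' Calibrated multi-level quota selection
#'
#' Assigns exactly `count` individuals to each education level so that the
#' realized group means of latent IQ match the `mean` targets of a
#' [selection_moments()] object on average over seeds, while keeping the
#' assignment stochastic so groups overlap in latent IQ as under real
#' selection. Levels are filled from highest to lowest by weighted sampling
#' without replacement with weights `exp(alpha_l * p(i))` (rank-proportion
#' weights, overflow-safe); each `alpha_l` is calibrated by root-finding on
#' a Monte-Carlo-averaged realized mean computed on a population-quantile
#' reference sample. The lowest level takes the remainder.
#'
#' @param iq_start Latent IQ vector whose length must equal the total of
#'   `target$count`.
#' @param target A [selection_moments()] object.
#' @param seed Optional integer seed for the assignment draw.
#' @param calibration_tol Tolerance (IQ points) for the calibrated expected
#'   group means; calibration failing to reach it raises an error with
#'   diagnostics.
#' @param alphas Optional precomputed tilt parameters from
#'   [calibrate_quota()]; supply these when generating many replicate
#'   cohorts from the same target to avoid recalibrating.
#' @return Numeric vector of years of higher education (values
#'   `target$level`).
#' @export
quota_selection <- function(iq_start, target, seed = NULL,
                            calibration_tol = 0.5, alphas = NULL) {
  stopifnot(inherits(target, "selection_moments"))
  n <- length(iq_start)
  if (sum(target$count) != n) {
    stop("Target counts sum to ", sum(target$count), " but n = ", n, ".",
         call. = FALSE)
  }
  if (nrow(target) == 1) {
    return(rep(target$level, n))
  }
  if (is.null(alphas)) {
    alphas <- calibrate_quota(n, target, tol = calibration_tol)
  }
  with_seed_(seed, quota_draw(iq_start, target, alphas))
}

# one stochastic assignment given calibrated tilts
quota_draw <- function(iq_start, target, alphas) {
  n <- length(iq_start)
  p <- rank_proportion(iq_start)
  he <- rep(target$level[1], n)
  pool <- seq_len(n)
  ord <- order(target$level, decreasing = TRUE)
  for (k in ord[-length(ord)]) {
    w <- tilt_weights(alphas[k], p[pool])
    sel <- pool[sample.int(length(pool), target$count[k], prob = w)]
    he[sel] <- target$level[k]
    pool <- setdiff(pool, sel)
  }
  he
}

tilt_weights <- function(a, p) exp(a * (p - max(p)))

#' Calibrate quota-selection tilt parameters
#'
#' Finds, level by level from the highest down, the exponential tilt
#' `alpha_l` for which the expected realized group mean of latent IQ matches
#' the target. The objective is evaluated on the population-quantile
#' reference sample `qnorm((i - 0.5)/n) * 15` with a fixed internal RNG, so
#' the result is deterministic and transfers across cohort draws (the
#' weights depend only on ranks).
#'
#' @param n Cohort size.
#' @param target A [selection_moments()] object.
#' @param nrep Internal Monte-Carlo draws per objective evaluation.
#' @param tol Acceptable absolute error (IQ points) of the calibrated
#'   expected mean per level.
#' @return Named numeric vector of tilts, one per level (lowest level 0).
#' @export
calibrate_quota <- function(n, target, nrep = 10, tol = 0.5) {
  if (sum(target$count) != n) {
    stop("Target counts sum to ", sum(target$count), " but n = ", n,
         "; rescale the design to the cohort size first.", call. = FALSE)
  }
  x <- stats::qnorm((seq_len(n) - 0.5) / n) * 15
  p <- rank_proportion(x)
  K <- nrow(target)
  alphas <- stats::setNames(numeric(K), target$level)
  ord <- order(target$level, decreasing = TRUE)
  pool <- seq_len(n)
  for (k in ord[-length(ord)]) {
    N <- target$count[k]
    tgt <- target$mean[k]
    ip <- pool
    objective <- function(a) {
      withr::with_seed(1733, {
        mean(vapply(seq_len(nrep), function(r) {
          w <- tilt_weights(a, p[ip])
          mean(x[ip[sample.int(length(ip), N, prob = w)]])
        }, numeric(1)))
      }) - tgt
    }
    root <- tryCatch(stats::uniroot(objective, c(-60, 60))$root,
                     error = function(e) NA_real_)
    if (is.na(root) || abs(objective(root)) > tol) {
      stop("Quota calibration failed for level ", target$level[k],
           ": target mean ", tgt, " not reachable within tolerance ", tol,
           " (achieved offset ",
           if (is.na(root)) "no root in [-60, 60]" else
             round(objective(root), 3),
           "). Check that the target means are feasible for the counts.",
           call. = FALSE)
    }
    alphas[k] <- root
    # representative removal so later levels are calibrated on the
    # remaining pool
    pool <- withr::with_seed(1933, {
      w <- tilt_weights(root, p[ip])
      setdiff(pool, ip[sample.int(length(ip), N, prob = w)])
    })
  }
  alphas
}

#' Observed per-level moments of a cohort
#'
#' Computes the per-level counts and mean latent IQ from data, the empirical
#' counterpart of [selection_moments()]. Levels with no individuals are
#' dropped with a warning.
#'
#' @param iq_start Latent (or proxy) IQ vector.
#' @param he_years Years of higher education, same length.
#' @return A [selection_moments()] object.
#' @export
empirical_moments <- function(iq_start, he_years) {
  if (length(iq_start) != length(he_years)) {
    stop("`iq_start` and `he_years` must have the same length.", call. = FALSE)
  }
  lev <- sort(unique(he_years))
  counts <- vapply(lev, function(l) sum(he_years == l), integer(1))
  means <- vapply(lev, function(l) mean(iq_start[he_years == l]), numeric(1))
  keep <- counts > 0
  if (any(!keep)) warning("Dropping empty education level(s).")
  selection_moments(lev[keep], counts[keep], means[keep])
}
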