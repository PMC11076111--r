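#' Generative model parameters
#'
#' Bundles the structural parameters of the education-intelligence model:
#' the reliability `rho` of the childhood IQ score as a measure of latent IQ
#' at the start of higher education, the per-year education effect `b_HE`
#' (IQ points per year), the slope `b_start` of start-of-education IQ on
#' adult IQ, and optionally a nonlinear `effect_map` giving the cumulative
#' IQ gain for each years-of-education level, which overrides the linear
#' `b_HE * HE` term in data generation.
#'
#' @param rho Reliability correlation, in (0, 1].
#' @param b_HE Education effect, IQ points per year.
#' @param b_start Contribution of start-of-education IQ (unitless slope).
#' @param effect_map Optional named numeric vector mapping years of higher
#'   education (names) to cumulative IQ gains (values); must be
#'   non-decreasing in years.
#' @return An object of class `model_params`.
#' @examples
#' model_params(rho = 0.84, b_HE = 0.45, b_start = 0.6)
#' model_params(0.84, b_start = 0.6, effect_map = c(`0` = 0, `2` = 2.4, `6` = 3.1, `10` = 3.8))
#' @export
model_params <- function(rho = 0.84, b_HE = 0.45, b_start = 0.6,
                         effect_map = NULL) {
  check_rho(rho)
  if (!is.null(effect_map)) {
    if (is.null(names(effect_map))) {
      stop("`effect_map` must be a named vector (names = years of HE).",
           call. = FALSE)
    }
    yrs <- as.numeric(names(effect_map))
    if (any(is.na(yrs))) {
      stop("`effect_map` names must be numeric years.", call. = FALSE)
    }
    o <- order(yrs)
    if (any(diff(effect_map[o]) < 0)) {
      stop("`effect_map` must be non-decreasing in years of education.",
           call. = FALSE)
    }
  }
  structure(list(rho = rho, b_HE = b_HE, b_start = b_start,
                 effect_map = effect_map),
            class = "model_params")
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) ||
      rho <= 0 || rho > 1) {
    stop("`rho` must be a single value in (0, 1].", call. = FALSE)
  }
  invisible(rho)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> rho =", x$rho, " b_HE =", x$b_HE,
      " b_start =", x$b_start)
  if (!is.null(x$effect_map)) {
    cat("  effect_map:", paste(names(x$effect_map), x$effect_map,
                               sep = "->", collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Draw latent IQ at the start of higher education
#'
#' Independent draws from Normal(0, 15^2), the assumed population
#' distribution of true IQ at the start of higher education.
#'
#' @param n Number of individuals (at least 2).
#' @param seed Optional integer seed for a locally scoped RNG state.
#' @return Numeric vector of length `n` (IQ points).
#' @export
gen_iq_start <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("`n` must be a single count >= 2.", call. = FALSE)
  }
  with_seed_(seed, stats::rnorm(n, 0, 15))
}

#' Generate the observed childhood IQ score
#'
#' The childhood score is `rho * iq_start` plus classical error with
#' variance `225 * (1 - rho^2)`, so the population variance of the result
#' stays at 225 and its correlation with the latent score is `rho`. With
#' `rho = 1` the latent vector is returned unchanged.
#'
#' @param iq_start Latent IQ vector (IQ points).
#' @param rho Reliability, in (0, 1].
#' @param seed Optional integer seed.
#' @return Numeric vector, same length as `iq_start`.
#' @export
gen_iq_child <- function(iq_start, rho, seed = NULL) {
  check_rho(rho)
  if (rho == 1) return(iq_start)
  with_seed_(seed, rho * iq_start +
               stats::rnorm(length(iq_start), 0, 15 * sqrt(1 - rho^2)))
}

#' Generate properly measured (continuous) adult IQ
#'
#' Adult IQ before discretization follows the linear model
#' `b_HE * HE_centred + b_start * iq_start + e`, or, when `params$effect_map`
#' is supplied, the mapped cumulative gain (centred on its sample mean)
#' replaces the linear education term. The error variance is 225 minus the
#' sample variance of the systematic part, so generated samples are
#' self-standardizing: the population variance of the output is 225.
#' Years of education are centred on their sample mean internally; pass raw
#' years.
#'
#' @param iq_start Latent IQ vector.
#' @param he_years Raw years of higher education (small discrete set).
#' @param params A [model_params()] object.
#' @param seed Optional integer seed.
#' @return Numeric vector of continuous adult IQ (IQ points).
#' @export
gen_iq_afterN <- function(iq_start, he_years, params, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (length(iq_start) != length(he_years)) {
    stop("`iq_start` and `he_years` must have the same length.", call. = FALSE)
  }
  sys <- systematic_part(iq_start, he_years, params)
  v <- stats::var(sys)
  if (v >= 225) {
    stop("Systematic part has variance >= 225; parameters are infeasible ",
         "for a variance-225 outcome.", call. = FALSE)
  }
  with_seed_(seed, sys + stats::rnorm(length(sys), 0, sqrt(225 - v)))
}

# b_HE * HE_centred + b_start * iq_start, or the effect_map variant
systematic_part <- function(iq_start, he_years, params) {
  if (is.null(params$effect_map)) {
    hec <- he_years - mean(he_years)
    params$b_HE * hec + params$b_start * iq_start
  } else {
    key <- as.character(he_years)
    miss <- setdiff(unique(key), names(params$effect_map))
    if (length(miss) > 0) {
      stop("`effect_map` lacks entries for HE level(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    g <- unname(params$effect_map[key])
    (g - mean(g)) + params$b_start * iq_start
  }
}

#' Discretization error of the observed adult measure
#'
#' The observed adult score equals the discretized continuous score, and can
#' be written as systematic part plus an error term `e_after` that is
#' *determined* by the latent IQ, education, and the classical error:
#' `e_after = Discretize(sys + e_afterN) - sys`. Unlike `e_afterN`, this
#' error is correlated with the predictors (non-classical), which is the
#' bias the ism estimator corrects.
#'
#' @param iq_start Latent IQ vector.
#' @param he_years Raw years of higher education.
#' @param e_afterN Classical error draws for the continuous adult score.
#' @param params A [model_params()] object.
#' @param scheme An [discretization_scheme()] or `NULL` for no
#'   discretization (then `e_after == e_afterN`).
#' @return Numeric vector of errors (IQ points).
#' @export
compute_e_after <- function(iq_start, he_years, e_afterN, params,
                            scheme = NULL) {
  nlen <- unique(c(length(iq_start), length(he_years), length(e_afterN)))
  if (length(nlen) != 1) {
    stop("All input vectors must have the same length.", call. = FALSE)
  }
  sys <- systematic_part(iq_start, he_years, params)
  if (is.null(scheme)) return(e_afterN)
  discretize(sys + e_afterN, scheme) - sys
}

#' Per-level selection moments
#'
#' Summarizes the selection effect as the ordered education levels, the
#' number of individuals at each level, and the mean latent IQ at the start
#' of education within each level.
#'
#' @param levels Ordered years-of-education values.
#' @param counts Individuals per level.
#' @param means Mean latent IQ per level (IQ points).
#' @return An object of class `selection_moments` (also a tibble with
#'   columns `level`, `count`, `mean`).
#' @examples
#' selection_moments(c(0, 2, 6, 10), c(3877, 655, 1808, 426),
#'                   c(-6.2, 2.8, 8.1, 18.0))
#' @export
selection_moments <- function(levels, counts, means) {
  if (length(levels) != length(counts) || length(levels) != length(means)) {
    stop("`levels`, `counts` and `means` must have equal length.",
         call. = FALSE)
  }
  if (any(diff(levels) <= 0)) {
    stop("`levels` must be strictly increasing.", call. = FALSE)
  }
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("`counts` must be positive integers.", call. = FALSE)
  }
  if (any(!is.finite(means))) stop("`means` must be finite.", call. = FALSE)
  out <- tibble::tibble(level = as.numeric(levels),
                        count = as.integer(counts),
                        mean = as.numeric(means))
  class(out) <- c("selection_moments", class(out))
  out
}

#' @rdname selection_moments
#' @param x A `selection_moments` object.
#' @param path Optional file path.
#' @export
moments_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "selection_moments"))
  js <- jsonlite::toJSON(list(levels = x$level, counts = x$count,
                              means = x$mean), digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname selection_moments
#' @param json JSON string (ignored when `path` is given).
#' @export
moments_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path, warn = FALSE), collapse = "")
  x <- jsonlite::fromJSON(json)
  selection_moments(x$levels, x$counts, x$means)
}

#' Validate a cohort data frame
#'
#' A cohort table holds one row per individual with the observed triple
#' `iq_child`, `he_years`, `iq_after`, and optionally the latent columns
#' `iq_start` and `iq_afterN` when the cohort was simulated. Checks lengths,
#' finiteness and that `he_years` takes a small set of non-negative values.
#'
#' @param data A data frame.
#' @param require_after If `FALSE`, `iq_after` may be absent (e.g. before
#'   outcome construction).
#' @return The data as a tibble, invisibly validated.
#' @export
as_cohort <- function(data, require_after = TRUE) {
  data <- tibble::as_tibble(data)
  need <- c("iq_child", "he_years", if (require_after) "iq_after")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("Cohort data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c(need, "iq_start", "iq_afterN"), names(data))) {
    if (any(!is.finite(data[[col]]))) {
      stop("Column `", col, "` contains non-finite values.", call. = FALSE)
    }
  }
  if (any(data$he_years < 0)) {
    stop("`he_years` must be non-negative.", call. = FALSE)
  }
  if (length(unique(data$he_years)) > 25) {
    stop("`he_years` should take a small set of discrete values.",
         call. = FALSE)
  }
  data
}

# Run `expr` under a locally scoped seed when one is given.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic child seeds (one per replicate) derived from a root seed.
child_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  withr::with_seed(as.integer(seed),
                   as.list(sample.int(.Machine$integer.max, k)))
}
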