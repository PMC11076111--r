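#' Discretization schemes for coarse intelligence measures
#'
#' A discretization scheme describes how a continuous, normally distributed
#' IQ score is mapped onto the small set of values that a coarse test can
#' actually produce. It consists of ordered representative `levels` (on the
#' standardized IQ scale, population mean 0 and s.d. 15) and the
#' `proportions` of the population falling at each level. Discretization is
#' rank-based: the lowest block of a sample maps to the lowest level, and so
#' on, so realized per-level counts are fixed by the proportions.
#'
#' @param levels Numeric vector of strictly increasing representative values
#'   (IQ points, standardized scale).
#' @param proportions Numeric vector of positive level probabilities summing
#'   to one, same length as `levels`.
#' @param standardize If `TRUE`, affinely rescale `levels` so the scheme has
#'   population mean 0 and s.d. 15 under `proportions`.
#' @return An object of class `iq_scheme`: a list with elements `levels` and
#'   `proportions`.
#' @examples
#' discretization_scheme(1:4, rep(0.25, 4))
#' @export
discretization_scheme <- function(levels, proportions, standardize = TRUE) {
  levels <- as.numeric(levels)
  proportions <- as.numeric(proportions)
  if (length(levels) != length(proportions)) {
    stop("`levels` and `proportions` must have the same length.", call. = FALSE)
  }
  if (any(!is.finite(levels)) || any(!is.finite(proportions))) {
    stop("Scheme levels and proportions must be finite.", call. = FALSE)
  }
  if (any(diff(levels) <= 0)) {
    stop("Scheme levels must be strictly increasing.", call. = FALSE)
  }
  if (any(proportions <= 0)) {
    stop("Scheme proportions must all be positive.", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    proportions <- proportions / sum(proportions)
  }
  if (standardize) {
    if (length(levels) < 2) {
      stop("Cannot standardize a scheme with a single level (zero variance).",
           call. = FALSE)
    }
    mu <- sum(proportions * levels)
    sigma <- sqrt(sum(proportions * levels^2) - mu^2)
    levels <- (levels - mu) / sigma * 15
  }
  structure(list(levels = levels, proportions = proportions),
            class = "iq_scheme")
}

#' @export
print.iq_scheme <- function(x, ...) {
  cat("<iq_scheme> ", length(x$levels), " levels, range [",
      round(min(x$levels), 1), ", ", round(max(x$levels), 1), "] IQ points\n",
      sep = "")
  invisible(x)
}

#' Construct standard discretization schemes
#'
#' Builds the scheme variants used in the simulation studies: `"uniform"`
#' (k equidistant levels, equal proportions), `"triangular"` (k equidistant
#' levels with proportions proportional to 1..k, so mass piles up at the top),
#' and `"empirical"` (levels and proportions read off an observed discrete
#' vector, preserved exactly). Uniform and triangular schemes are
#' standardized to mean 0, s.d. 15; an empirical scheme keeps the observed
#' values as-is, since those are already on the standardized scale.
#'
#' @param kind One of `"uniform"`, `"triangular"`, `"empirical"`.
#' @param k Number of levels (ignored for `"empirical"`).
#' @param observed Discrete numeric vector from which to read an empirical
#'   scheme.
#' @return An [discretization_scheme()] object.
#' @examples
#' make_scheme("triangular", k = 4)
#' @export
make_scheme <- function(kind = c("uniform", "triangular", "empirical"),
                        k = 4, observed = NULL) {
  kind <- match.arg(kind)
  if (kind == "empirical") {
    if (is.null(observed)) {
      stop("An empirical scheme requires the `observed` vector.", call. = FALSE)
    }
    tab <- table(observed)
    lev <- as.numeric(names(tab))
    ord <- order(lev)
    return(discretization_scheme(lev[ord],
                                 as.numeric(tab)[ord] / length(observed),
                                 standardize = FALSE))
  }
  if (k < 2) {
    stop("Uniform and triangular schemes need at least k = 2 levels.",
         call. = FALSE)
  }
  props <- switch(kind,
    uniform = rep(1 / k, k),
    triangular = seq_len(k) / sum(seq_len(k))
  )
  # equidistant grid; spacing and origin cancel under standardization
  discretization_scheme(seq_len(k), props, standardize = TRUE)
}

#' Synthetic left-skewed numeracy-test scheme
#'
#' Emulates the discrete distribution of an adult numeracy assessment whose
#' squared raw score is standardized to an IQ metric. Raw scores 1..`k` are
#' given beta-binomial(`k`, `shape1`, `shape2`) probabilities (truncated at
#' zero, since zero scores are treated as missing), which for the defaults
#' yields a left-skewed distribution with most mass near the top of the
#' scale, so the few highest levels absorb a wide range of latent ability.
#' Scores are squared before standardization, mirroring how such a measure
#' is constructed from test data.
#'
#' This is a synthetic stand-in: the real score distribution comes from
#' restricted-access cohort data and is not shipped. The defaults were fixed
#' once for realism (mean raw score about 78% of the maximum) and give a
#' 23-level measure with a pronounced ceiling.
#'
#' @param k Maximum raw score (number of levels).
#' @param shape1,shape2 Beta-binomial shape parameters controlling skew.
#' @return An [discretization_scheme()] object with `k` levels.
#' @export
numeracy_scheme <- function(k = 23, shape1 = 7, shape2 = 2) {
  s <- seq_len(k)
  pr <- choose(k, s) * beta(s + shape1, k - s + shape2) / beta(shape1, shape2)
  pr <- pr / sum(pr)
  discretization_scheme(s^2, pr, standardize = TRUE)
}

#' Rank-based discretization of a continuous IQ vector
#'
#' Maps a continuous vector onto the scheme's levels by rank: the lowest
#' `round(p1 * n)` observations receive the lowest level, the next block the
#' second level, and so on. Per-level counts follow the scheme proportions
#' with largest-remainder rounding (so they sum to `n` exactly); ties are
#' broken by stable sort order. The mapping is monotone non-decreasing and
#' idempotent given the same scheme.
#'
#' @param values Finite numeric vector (IQ points).
#' @param scheme An [discretization_scheme()] object.
#' @return Numeric vector of the same length taking only `scheme$levels`
#'   values.
#' @examples
#' sch <- make_scheme("uniform", 4)
#' table(discretize(rnorm(1000, 0, 15), sch))
#' @export
discretize <- function(values, scheme) {
  stopifnot(inherits(scheme, "iq_scheme"))
  if (any(!is.finite(values))) {
    stop("`values` must be finite.", call. = FALSE)
  }
  n <- length(values)
  if (n < length(scheme$levels)) {
    warning("Fewer observations than scheme levels; some levels stay empty.")
  }
  counts <- largest_remainder(scheme$proportions, n)
  out <- numeric(n)
  out[order(values)] <- rep(scheme$levels, counts)
  out
}

# Apportion n into integer counts ~ p * n, largest-remainder method.
largest_remainder <- function(p, n) {
  q <- p * n
  f <- floor(q)
  r <- n - sum(f)
  if (r > 0) {
    o <- order(q - f, decreasing = TRUE)
    f[o[seq_len(r)]] <- f[o[seq_len(r)]] + 1
  }
  as.integer(f)
}

#' Standardize a score vector to the IQ metric
#'
#' Affine transform to sample mean 0 and sample s.d. 15. The s.d. uses the
#' usual n-1 denominator; the convention matters only at very small n but is
#' fixed here for reproducibility.
#'
#' @param values Numeric vector with positive variance.
#' @return Numeric vector with mean 0 and s.d. 15.
#' @export
standardize_iq <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("Cannot standardize a vector with zero variance.", call. = FALSE)
  }
  (values - mean(values)) / s * 15
}

#' Serialize / deserialize a scheme as JSON
#'
#' @param scheme An [discretization_scheme()] object.
#' @param path File path; if `NULL`, `scheme_to_json()` returns the JSON
#'   string.
#' @return `scheme_to_json()`: JSON string (invisibly, when writing to a
#'   file); `scheme_from_json()`: an `iq_scheme`.
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "iq_scheme"))
  js <- jsonlite::toJSON(list(levels = scheme$levels,
                              proportions = scheme$proportions),
                         digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname scheme_to_json
#' @param json JSON string (ignored when `path` is given).
#' @export
scheme_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path, warn = FALSE), collapse = "")
  x <- jsonlite::fromJSON(json)
  discretization_scheme(x$levels, x$proportions, standardize = FALSE)
}
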