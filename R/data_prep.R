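#' Convert qualification labels to years of higher education
#'
#' Maps highest-qualification labels onto the four-level years scale used
#' throughout the package: none/CSE/GCSE/O-level -> 0; A-level/SSCE/AS-level
#' -> 2; degree/diploma/teaching/nursing -> 6; higher degree/PGCE -> 10.
#' Unknown labels raise an error rather than being dropped silently.
#'
#' @param qualification Character vector of qualification labels
#'   (case-insensitive).
#' @return Numeric vector of years of higher education.
#' @examples
#' code_he_years(c("A-level", "PGCE", "O-level"))
#' @export
code_he_years <- function(qualification) {
  key <- tolower(trimws(qualification))
  map <- c(
    "none" = 0, "no qualifications" = 0, "cse" = 0, "gcse" = 0,
    "o-level" = 0, "o level" = 0,
    "a-level" = 2, "a level" = 2, "ssce" = 2, "as-level" = 2, "as level" = 2,
    "degree" = 6, "diploma" = 6, "diploma of higher education" = 6,
    "teaching" = 6, "teaching qualification" = 6, "nursing" = 6,
    "nursing qualification" = 6,
    "higher degree" = 10, "pgce" = 10)
  unknown <- setdiff(unique(key), names(map))
  if (length(unknown) > 0) {
    stop("Unmapped qualification label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(map[key])
}

#' Build the childhood IQ score from subscale scores
#'
#' Each of the four ability subscales is z-scored, the per-participant
#' average is taken, and the average is restandardized to the IQ metric
#' (mean 0, s.d. 15).
#'
#' @param subscale_scores Data frame or list of exactly four complete
#'   numeric score vectors.
#' @return Numeric vector of childhood IQ scores.
#' @export
build_iq_child <- function(subscale_scores) {
  sc <- as.data.frame(subscale_scores)
  if (ncol(sc) != 4) {
    stop("Exactly four subscale score vectors are required.", call. = FALSE)
  }
  z <- vapply(sc, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("A subscale has zero variance.", call. = FALSE)
    }
    (v - mean(v)) / s
  }, numeric(nrow(sc)))
  standardize_iq(rowMeans(z))
}

#' Build the discrete adult IQ measure from numeracy scores
#'
#' Squares the raw test score (which partially un-skews a ceiling-limited
#' count of correct answers) and standardizes the squared scores to the IQ
#' metric. The result is discrete, with at most one level per distinct raw
#' score.
#'
#' @param numeracy_scores Non-negative integer scores.
#' @return Numeric vector of discrete adult IQ scores.
#' @export
build_iq_after <- function(numeracy_scores) {
  if (any(numeracy_scores < 0) ||
      any(numeracy_scores != round(numeracy_scores))) {
    stop("Numeracy scores must be non-negative integers.", call. = FALSE)
  }
  standardize_iq(numeracy_scores^2)
}

#' Prepare a raw cohort extract
#'
#' Applies the inclusion criteria and variable-construction recipes to a
#' generic raw extract: rows are excluded when the individual is a twin,
#' the qualification is missing, or any intelligence score is zero or
#' missing (zero is treated as a missing-data code); remaining rows are
#' converted to the cohort schema via [code_he_years()], [build_iq_child()]
#' and [build_iq_after()]. Exclusion counts are reported as an attribute
#' and a message.
#'
#' @param raw Data frame with raw columns.
#' @param mapping Named list giving the raw column names for `twin`,
#'   `qualification`, the four `subscales`, and `numeracy`.
#' @return A cohort tibble (`id`, `iq_child`, `he_years`, `iq_after`) with
#'   attribute `exclusions`.
#' @export
prepare_cohort <- function(raw,
                           mapping = list(twin = "twin",
                                          qualification = "qualification",
                                          subscales = c("word_definitions",
                                                        "recall_digits",
                                                        "similarities",
                                                        "matrices"),
                                          numeracy = "numeracy")) {
  raw <- tibble::as_tibble(raw)
  need <- c(mapping$twin, mapping$qualification, mapping$subscales,
            mapping$numeracy)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("Raw extract lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  iq_cols <- c(mapping$subscales, mapping$numeracy)
  is_twin <- raw[[mapping$twin]] %in% c(TRUE, 1, "yes", "twin")
  no_edu <- is.na(raw[[mapping$qualification]]) |
    trimws(as.character(raw[[mapping$qualification]])) == ""
  bad_iq <- Reduce(`|`, lapply(raw[iq_cols],
                               function(v) is.na(v) | v == 0))
  keep <- !is_twin & !no_edu & !bad_iq
  exclusions <- c(twin = sum(is_twin), no_education = sum(no_edu & !is_twin),
                  zero_or_missing_scores = sum(bad_iq & !is_twin & !no_edu))
  message("Excluded ", sum(!keep), " of ", nrow(raw), " rows (",
          paste(names(exclusions), exclusions, sep = " = ",
                collapse = ", "), ").")
  kept <- raw[keep, ]
  out <- tibble::tibble(
    id = seq_len(nrow(kept)),
    iq_child = build_iq_child(kept[mapping$subscales]),
    he_years = code_he_years(kept[[mapping$qualification]]),
    iq_after = build_iq_after(kept[[mapping$numeracy]]))
  attr(out, "exclusions") <- exclusions
  out
}

#' Read / write a cohort CSV
#'
#' The cohort interchange format: a header CSV with columns `id`,
#' `iq_child`, `he_years`, `iq_after` and optionally the latent columns
#' `iq_start`, `iq_afterN`. Missing values are disallowed.
#'
#' @param path File path.
#' @return `read_cohort_csv()`: a validated cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  as_cohort(df)
}

#' @rdname read_cohort_csv
#' @param data Cohort data frame.
#' @export
write_cohort_csv <- function(data, path) {
  data <- as_cohort(data)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
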