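# Patient-level outcome scoring: ACSS-MH continuity of care (31 items,
# 1..5 each, total 31..155, plus configurable subscales), SIX social
# integration (employment 0..2 + accommodation 0..2 + family 0..1 +
# friendship 0..1, total 0..6), HoNOS range validation, and
# patient-characteristics descriptives.

#' Default ACSS-MH subscale map
#'
#' The instrument's three dimensions are individualized care, system
#' responsiveness and carer responsiveness, and analyses additionally use a
#' "relational base" subscale. The exact item membership is not public in
#' the sources this package follows, so the shipped map is a documented
#' stand-in partition (items 1-12 / 13-22 / 23-31, relational base items
#' 1-6 and 13-16): replace it with the licensed instrument's map via
#' \code{\link{read_subscale_map}} for substantive use. No item is
#' reverse-scored by default.
#'
#' @return Named list of 1-based item index vectors.
#' @export
default_subscale_map <- function() {
  list(individualized_care = 1:12,
       system_responsiveness = 13:22,
       carer_responsiveness = 23:31,
       relational_base = c(1:6, 13:16))
}

#' Read a subscale map from YAML
#'
#' The file maps subscale names to lists of 1-based item indices matching
#' the \code{acss_01..acss_31} columns, e.g.
#' \code{individualized_care: [1, 2, 3]}.
#'
#' @param path YAML file path.
#' @return Named list of integer vectors.
#' @export
read_subscale_map <- function(path) {
  m <- yaml::read_yaml(path)
  m <- lapply(m, function(v) sort(as.integer(unlist(v))))
  bad <- vapply(m, function(v) any(v < 1L | v > 31L | duplicated(v)), TRUE)
  if (any(bad))
    stop("subscale item indices must be unique and within 1..31: ",
         paste(names(m)[bad], collapse = ", "), call. = FALSE)
  m
}

#' ACSS-MH continuity-of-care score
#'
#' Total continuity score (plain sum of the 31 item ratings, range 31..155)
#' and subscale sums under the configured item map.
#'
#' @param items Numeric vector of exactly 31 integer ratings in 1..5.
#' @param subscale_map Named list of item index vectors; see
#'   \code{\link{default_subscale_map}}.
#' @return List with \code{total} and \code{subscales} (named numeric).
#' @export
#' @examples
#' acss_total(rep(5, 31))$total  # 155
acss_total <- function(items, subscale_map = default_subscale_map()) {
  if (length(items) != 31L)
    stop("exactly 31 ACSS items required, got ", length(items), call. = FALSE)
  if (anyNA(items) || any(items < 1 | items > 5 | items != round(items)))
    stop("ACSS items must be integers in 1..5", call. = FALSE)
  list(total = sum(items),
       subscales = vapply(subscale_map, function(ix) sum(items[ix]),
                          numeric(1)))
}

#' SIX social-integration score
#'
#' Sum of the four objective social-outcome components: employment (0..2),
#' accommodation (0..2), family contact (0..1) and friendship (0..1);
#' total 0 (no social integration) to 6 (high social integration).
#'
#' @param employment,accommodation,family,friendship Integer components.
#' @return Integer total in 0..6.
#' @export
#' @examples
#' six_total(2, 2, 1, 1)  # 6
six_total <- function(employment, accommodation, family, friendship) {
  comp <- c(employment = employment, accommodation = accommodation,
            family = family, friendship = friendship)
  maxv <- c(2, 2, 1, 1)
  if (anyNA(comp) || any(comp < 0 | comp > maxv | comp != round(comp)))
    stop("SIX components out of range (max 2/2/1/1)", call. = FALSE)
  as.integer(sum(comp))
}

#' Validate a HoNOS total
#'
#' Health of the Nation Outcome Scale total: 0 (no impairment) to 48
#' (extreme impairment).
#'
#' @param value Integer.
#' @return The validated value.
#' @export
validate_honos <- function(value) {
  if (anyNA(value) || any(value < 0 | value > 48 | value != round(value)))
    stop("HoNOS must be an integer in 0..48", call. = FALSE)
  value
}

#' Score a patient table
#'
#' Adds outcome columns to a validated patient table (see
#' \code{\link{read_patients}}): \code{acss_total}, one
#' \code{acss_<subscale>} column per configured subscale, and
#' \code{six_total}. Incomplete records get NA outcomes.
#'
#' @param patients Validated patient data frame.
#' @param subscale_map See \code{\link{default_subscale_map}}.
#' @return The patient data frame with score columns appended.
#' @export
score_patients <- function(patients, subscale_map = default_subscale_map()) {
  items <- as.matrix(patients[, acss_cols()])
  patients$acss_total <- rowSums(items)
  for (s in names(subscale_map))
    patients[[paste0("acss_", s)]] <-
      rowSums(items[, subscale_map[[s]], drop = FALSE])
  patients$six_total <- patients$six_employment +
    patients$six_accommodation + patients$six_family + patients$six_friends
  patients
}

#' Descriptive outcome table
#'
#' Mean and standard deviation of each outcome, service-use count and
#' numeric covariate over the analysis set (complete records), plus the
#' diagnosis percentage breakdown — the patient-characteristics table of a
#' clustered outcome study.
#'
#' @param patients A scored patient table (\code{\link{score_patients}}).
#' @return List with \code{stats} (variable, mean, std) and
#'   \code{diagnosis_pct} (named percentages).
#' @export
outcome_table <- function(patients) {
  if (!"acss_total" %in% names(patients))
    patients <- score_patients(patients)
  x <- if ("complete" %in% names(patients))
    patients[patients$complete, ] else patients
  if (nrow(x) == 0L) stop("empty analysis set", call. = FALSE)
  vars <- c("acss_total", "six_total", "n_outpatient", "n_social",
            "n_residential", "age", "honos")
  vars <- intersect(vars, names(x))
  stats_df <- data.frame(
    variable = vars,
    mean = vapply(vars, function(v) mean(x[[v]], na.rm = TRUE), numeric(1)),
    std = vapply(vars, function(v)
      if (sum(!is.na(x[[v]])) > 1) stats::sd(x[[v]], na.rm = TRUE) else 0,
      numeric(1)))
  if ("sex" %in% names(x))
    stats_df <- rbind(stats_df, data.frame(
      variable = "male_pct",
      mean = 100 * mean(x$sex == "male", na.rm = TRUE), std = NA_real_))
  rownames(stats_df) <- NULL
  diag_pct <- if ("diagnosis" %in% names(x))
    100 * prop.table(table(factor(x$diagnosis, levels = DIAGNOSES)))
  else NULL
  list(stats = stats_df, diagnosis_pct = diag_pct, n = nrow(x))
}
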