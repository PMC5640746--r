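# Reading, validating and writing the three survey tables
# (services roster, tie survey, patient records) in a fixed CSV dialect:
# comma-separated, UTF-8, mandatory header, no row-name column.

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L)
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  x
}

check_enum <- function(values, allowed, what, allow_na = FALSE) {
  bad <- !(values %in% allowed)
  if (allow_na) bad <- bad & !is.na(values)
  if (any(bad)) {
    rows <- which(bad)
    stop("invalid ", what, " value(s) ",
         paste(unique(values[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(rows, 10L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a service roster
#'
#' Reads \code{services.csv}: one row per service with columns
#' \code{service_id}, \code{network_id}, \code{service_type} (one of the
#' nine categories in \code{\link{carenets_vocab}}) and \code{participated}
#' (logical: did the service answer the tie survey).
#'
#' @param path Path to the roster CSV.
#' @return A data frame with the four validated columns, row order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_roster(data.frame(service_id = c("a", "b"), network_id = "n1",
#'   service_type = c("primary_care", "social_services"),
#'   participated = TRUE), f)
#' read_roster(f)
read_roster <- function(path) {
  x <- read_csv_strict(path,
    c("service_id", "network_id", "service_type", "participated"))
  validate_roster(x)
}

#' @rdname read_roster
#' @param roster A data frame shaped like the roster table (used to validate
#'   in-memory rosters, e.g. from the synthetic generator).
#' @export
validate_roster <- function(roster) {
  roster$service_id <- as.character(roster$service_id)
  roster$network_id <- as.character(roster$network_id)
  roster$service_type <- as.character(roster$service_type)
  check_enum(roster$service_type, SERVICE_TYPES, "service_type")
  if (is.character(roster$participated))
    roster$participated <- toupper(roster$participated) %in% c("TRUE", "T", "1")
  roster$participated <- as.logical(roster$participated)
  if (anyNA(roster$participated))
    stop("participated must be logical with no missing values", call. = FALSE)
  dup <- duplicated(roster[, c("network_id", "service_id")])
  if (any(dup))
    stop("duplicate service_id within network: ",
         paste(unique(roster$service_id[dup]), collapse = ", "),
         call. = FALSE)
  roster[, c("service_id", "network_id", "service_type", "participated")]
}

#' Read tie-survey records
#'
#' Reads \code{ties.csv}: one row per reported tie with columns
#' \code{network_id}, \code{reporter_id}, \code{alter_id},
#' \code{relation_kind} (referral_sent, referral_received, info_exchange,
#' organizational) and \code{frequency} (never / sometimes / often).
#' Frequencies are also returned numerically coded 0/1/2 in
#' \code{freq_code}. Reporters must be participating services of the same
#' network as their alters; self-ties and missing frequencies are invalid.
#'
#' @param path Path to the tie CSV.
#' @param roster A validated roster (see \code{\link{read_roster}}) against
#'   which reporter and alter ids are resolved.
#' @param strict If \code{TRUE} (default) any invalid row is an error naming
#'   the rows; if \code{FALSE}, invalid rows are dropped with a warning and
#'   returned in the \code{"rejected"} attribute (columns \code{row},
#'   \code{reason}).
#' @return A data frame of validated tie records with a \code{freq_code}
#'   column.
#' @export
read_ties <- function(path, roster, strict = TRUE) {
  x <- read_csv_strict(path,
    c("network_id", "reporter_id", "alter_id", "relation_kind", "frequency"))
  validate_ties(x, roster, strict = strict)
}

#' @rdname read_ties
#' @param ties A data frame shaped like the tie table.
#' @export
validate_ties <- function(ties, roster, strict = TRUE) {
  for (cl in c("network_id", "reporter_id", "alter_id",
               "relation_kind", "frequency"))
    ties[[cl]] <- as.character(ties[[cl]])
  roster <- validate_roster(roster)
  key <- function(net, id) paste(net, id, sep = "\r")
  roster_key <- key(roster$network_id, roster$service_id)
  participants <- roster_key[roster$participated]

  reason <- character(nrow(ties))
  flag <- function(bad, why) {
    hit <- bad & reason == ""
    reason[hit] <<- why
  }
  flag(!(ties$relation_kind %in% RELATION_KINDS), "unknown relation_kind")
  flag(is.na(ties$frequency) | ties$frequency == "" |
         !(ties$frequency %in% c(FREQ_LEVELS, NA)), "missing or invalid frequency")
  flag(ties$reporter_id == ties$alter_id, "self-tie")
  flag(!(key(ties$network_id, ties$reporter_id) %in% roster_key),
       "unknown reporter_id")
  flag(!(key(ties$network_id, ties$alter_id) %in% roster_key),
       "unknown alter_id")
  flag(!(key(ties$network_id, ties$reporter_id) %in% participants),
       "reporter did not participate")

  bad <- reason != ""
  if (any(bad)) {
    report <- data.frame(row = which(bad), reason = reason[bad])
    if (strict)
      stop("invalid tie record(s): ",
           paste(sprintf("row %d (%s)", utils::head(report$row, 10L),
                         utils::head(report$reason, 10L)), collapse = "; "),
           call. = FALSE)
    warning(sum(bad), " invalid tie record(s) dropped", call. = FALSE)
  }
  out <- ties[!bad, c("network_id", "reporter_id", "alter_id",
                      "relation_kind", "frequency")]
  rownames(out) <- NULL
  out$freq_code <- match(out$frequency, FREQ_LEVELS) - 1L
  if (any(bad)) attr(out, "rejected") <- report
  out
}

acss_cols <- function() sprintf("acss_%02d", 1:31)

patient_cols <- function() {
  c("patient_id", "network_id", "recruitment_service_type", acss_cols(),
    "six_employment", "six_accommodation", "six_family", "six_friends",
    "age", "sex", "honos", "diagnosis",
    "n_outpatient", "n_social", "n_residential")
}

#' Read patient records
#'
#' Reads \code{patients.csv}: one row per surveyed patient with the 31
#' ACSS-MH item ratings (\code{acss_01} .. \code{acss_31}, each 1..5), the
#' four SIX components (employment 0..2, accommodation 0..2, family 0..1,
#' friends 0..1), covariates (age, sex, HoNOS 0..48, diagnosis,
#' recruitment service type) and service-use counts. Records with any
#' missing outcome item or covariate are kept but flagged
#' \code{complete = FALSE} and excluded from the analysis set (listwise
#' exclusion); out-of-range values are errors.
#'
#' @param path Path to the patient CSV.
#' @return A data frame with a logical \code{complete} column; the analysis
#'   set is \code{x[x$complete, ]}. The number of exclusions is reported in
#'   a message.
#' @export
read_patients <- function(path) {
  x <- read_csv_strict(path, patient_cols())
  validate_patients(x)
}

#' @rdname read_patients
#' @param patients A data frame shaped like the patient table.
#' @export
validate_patients <- function(patients) {
  x <- patients[, patient_cols()]
  x$patient_id <- as.character(x$patient_id)
  x$network_id <- as.character(x$network_id)
  check_enum(x$recruitment_service_type, SERVICE_TYPES,
             "recruitment_service_type")
  for (cl in acss_cols()) {
    v <- x[[cl]]
    out_of_range <- !is.na(v) & (v < 1 | v > 5 | v != round(v))
    if (any(out_of_range))
      stop("ACSS item ", cl, " outside 1..5 at row(s) ",
           paste(utils::head(which(out_of_range), 10L), collapse = ", "),
           call. = FALSE)
  }
  six_max <- c(six_employment = 2, six_accommodation = 2,
               six_family = 1, six_friends = 1)
  for (cl in names(six_max)) {
    v <- x[[cl]]
    out_of_range <- !is.na(v) & (v < 0 | v > six_max[[cl]] | v != round(v))
    if (any(out_of_range))
      stop("SIX component ", cl, " outside 0..", six_max[[cl]],
           " at row(s) ",
           paste(utils::head(which(out_of_range), 10L), collapse = ", "),
           call. = FALSE)
  }
  bad_honos <- !is.na(x$honos) & (x$honos < 0 | x$honos > 48)
  if (any(bad_honos))
    stop("honos outside 0..48 at row(s) ",
         paste(utils::head(which(bad_honos), 10L), collapse = ", "),
         call. = FALSE)
  check_enum(x$diagnosis, DIAGNOSES, "diagnosis", allow_na = TRUE)

  needed <- c(acss_cols(), names(six_max),
              "age", "sex", "honos", "recruitment_service_type")
  x$complete <- stats::complete.cases(x[, needed])
  n_excl <- sum(!x$complete)
  if (n_excl > 0L)
    message(n_excl, " of ", nrow(x),
            " patient records incomplete; analysis set n = ",
            sum(x$complete))
  x
}

write_canonical_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write survey tables in the canonical CSV dialect
#'
#' Writers matching \code{\link{read_roster}}, \code{\link{read_ties}} and
#' \code{\link{read_patients}}: comma-separated, UTF-8, header row, no
#' quoting, empty string for missing. \code{write(read(f))} reproduces a
#' canonical file byte for byte.
#'
#' @param roster,ties,patients Validated tables.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_roster <- function(roster, path) {
  write_canonical_csv(validate_roster(roster), path)
}

#' @rdname write_roster
#' @export
write_ties <- function(ties, path) {
  cols <- c("network_id", "reporter_id", "alter_id",
            "relation_kind", "frequency")
  write_canonical_csv(ties[, cols], path)
}

#' @rdname write_roster
#' @export
write_patients <- function(patients, path) {
  write_canonical_csv(patients[, patient_cols()], path)
}
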