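#' Column-name mapping for 311 report exports
#'
#' Municipal 311 exports vary in column naming across vintages; a dialect
#' maps the exporter's column names onto the canonical record fields
#' (\code{report_id}, \code{category}, \code{agency}, \code{opened_at},
#' \code{lon}, \code{lat}, \code{status_notes}).  The default dialect
#' matches the CSV written by \code{\link{materialize_reports}}; the SF
#' open-data portal export is covered by \code{dialect_sf_open_data()}.
#'
#' @param report_id,category,agency,opened_at,lon,lat,status_notes source
#'   column names.
#' @return named character vector (canonical field -> source column).
#' @export
report_dialect <- function(report_id = "report_id",
                           category = "category",
                           agency = "agency",
                           opened_at = "opened_at",
                           lon = "lon", lat = "lat",
                           status_notes = "status_notes") {
  c(report_id = report_id, category = category, agency = agency,
    opened_at = opened_at, lon = lon, lat = lat,
    status_notes = status_notes)
}

#' @rdname report_dialect
#' @export
dialect_sf_open_data <- function() {
  report_dialect(report_id = "CaseID", category = "Category",
                 agency = "Responsible Agency", opened_at = "Opened",
                 lon = "Longitude", lat = "Latitude",
                 status_notes = "Status Notes")
}

#' Read a 311-style report export
#'
#' Reads a CSV export and maps it into canonical report records.  Rows
#' whose coordinates or timestamps cannot be parsed (or whose report id
#' is empty) are dropped and returned separately as a rejects log rather
#' than failing the ingest.
#'
#' Timestamps are parsed as \code{"\%Y-\%m-\%d \%H:\%M:\%S"} (optionally
#' date-only) in UTC; the pipeline treats all times in a single zone so
#' week assignment is unambiguous.
#'
#' @param path CSV file path.
#' @param dialect a \code{\link{report_dialect}} mapping.
#' @param rejects_path optional path; when given, the reject log is also
#'   written there as CSV.
#' @return list with \code{records} (data frame: \code{report_id},
#'   \code{category}, \code{agency}, \code{opened_at} (\code{POSIXct},
#'   UTC), \code{lon}, \code{lat}, \code{status_notes}) and
#'   \code{rejects} (the offending raw rows plus a \code{reject_reason}).
#' @export
read_reports <- function(path, dialect = report_dialect(),
                         rejects_path = NULL) {
  if (!file.exists(path)) stop("report file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  miss <- setdiff(unname(dialect), names(raw))
  if (length(miss))
    stop("mapped column(s) absent from ", path, ": ",
         paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    empty <- data.frame(report_id = character(), category = character(),
                        agency = character(),
                        opened_at = as.POSIXct(character(), tz = "UTC"),
                        lon = numeric(), lat = numeric(),
                        status_notes = character(),
                        stringsAsFactors = FALSE)
    return(list(records = empty, rejects = cbind(raw, reject_reason = character())))
  }

  rec <- data.frame(
    report_id = raw[[dialect[["report_id"]]]],
    category = raw[[dialect[["category"]]]],
    agency = raw[[dialect[["agency"]]]],
    opened_at = parse_report_time(raw[[dialect[["opened_at"]]]]),
    lon = suppressWarnings(as.numeric(raw[[dialect[["lon"]]]])),
    lat = suppressWarnings(as.numeric(raw[[dialect[["lat"]]]])),
    status_notes = raw[[dialect[["status_notes"]]]],
    stringsAsFactors = FALSE
  )
  rec$status_notes[is.na(rec$status_notes)] <- ""

  reason <- rep(NA_character_, nrow(rec))
  reason[is.na(rec$lon) | is.na(rec$lat)] <- "bad_coordinates"
  ok_coord <- !is.na(rec$lon) & !is.na(rec$lat)
  reason[ok_coord & (abs(rec$lat) > 90 | abs(rec$lon) > 180)] <- "bad_coordinates"
  reason[is.na(reason) & is.na(rec$opened_at)] <- "bad_timestamp"
  reason[is.na(reason) & (is.na(rec$report_id) | rec$report_id == "")] <- "missing_id"

  keep <- is.na(reason)
  rejects <- cbind(raw[!keep, , drop = FALSE],
                   reject_reason = reason[!keep])
  rownames(rejects) <- NULL
  records <- rec[keep, , drop = FALSE]
  rownames(records) <- NULL
  if (!is.null(rejects_path))
    utils::write.csv(rejects, rejects_path, row.names = FALSE)
  list(records = records, rejects = rejects)
}

# Per-element format fallback: base as.POSIXct() selects one format from
# the first parseable element, which would reject rows in a mixed or
# partly corrupt column wholesale.
parse_report_time <- function(x) {
  fmts <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M",
            "%Y-%m-%d", "%m/%d/%Y %I:%M:%S %p", "%m/%d/%Y")
  out <- rep(NA_real_, length(x))
  todo <- which(!is.na(x) & nzchar(x))
  for (f in fmts) {
    if (!length(todo)) break
    t <- as.POSIXct(strptime(x[todo], f, tz = "UTC"), tz = "UTC")
    ok <- !is.na(t)
    out[todo[ok]] <- as.numeric(t[ok])
    todo <- todo[!ok]
  }
  as.POSIXct(out, origin = "1970-01-01", tz = "UTC")
}

#' Inclusion/exclusion rules for report records
#'
#' A record is retained iff its category is in \code{include_categories},
#' no excluded substring occurs (case-insensitively, anywhere) in its
#' status notes, its agency is whitelisted (when a whitelist is given),
#' and its timestamp falls in \code{date_range} (half-open, when given).
#' The defaults implement the exposed-feces proxy rules: only the
#' "Human/Animal Waste" category, dropping records whose notes flag them
#' as duplicates ("dup") or transfers ("transfer").
#'
#' @param include_categories non-empty character vector of categories.
#' @param exclude_note_substrings substrings that exclude a record when
#'   found in its status notes (case-insensitive).
#' @param agency_whitelist optional character vector; \code{NULL}
#'   disables agency filtering.
#' @param date_range optional length-2 vector (start, end); retained iff
#'   \code{start <= opened_at < end}.
#' @return object of class \code{"filter_config"}.
#' @export
filter_config <- function(include_categories = "Human/Animal Waste",
                          exclude_note_substrings = c("dup", "transfer"),
                          agency_whitelist = NULL,
                          date_range = NULL) {
  if (length(include_categories) == 0L)
    stop("include_categories must be non-empty")
  if (!is.null(date_range)) {
    date_range <- as.POSIXct(paste(date_range), tz = "UTC",
                             tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
    if (length(date_range) != 2L || any(is.na(date_range)))
      stop("date_range must be two parseable dates")
  }
  structure(list(include_categories = include_categories,
                 exclude_note_substrings = exclude_note_substrings,
                 agency_whitelist = agency_whitelist,
                 date_range = date_range),
            class = "filter_config")
}

#' Apply inclusion/exclusion rules to report records
#'
#' Removed records are tallied by the first matching reason in the fixed
#' order category, note, agency, date, so the tallies partition the
#' removed set: \code{nrow(retained) + sum(tally) == nrow(records)}.
#'
#' @param records record data frame from \code{\link{read_reports}}.
#' @param config a \code{\link{filter_config}}.
#' @param tally_path optional path to also write the tally as JSON.
#' @return list with \code{records} (retained rows) and \code{tally}
#'   (named integer vector: \code{category}, \code{note}, \code{agency},
#'   \code{date}).
#' @export
filter_reports <- function(records, config = filter_config(),
                           tally_path = NULL) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  bad_cat <- !(records$category %in% config$include_categories)
  reason[bad_cat] <- "category"

  notes <- tolower(records$status_notes)
  bad_note <- rep(FALSE, n)
  for (s in config$exclude_note_substrings)
    bad_note <- bad_note | grepl(tolower(s), notes, fixed = TRUE)
  reason[is.na(reason) & bad_note] <- "note"

  if (!is.null(config$agency_whitelist)) {
    bad_agency <- !(records$agency %in% config$agency_whitelist)
    reason[is.na(reason) & bad_agency] <- "agency"
  }
  if (!is.null(config$date_range)) {
    bad_date <- records$opened_at < config$date_range[1] |
      records$opened_at >= config$date_range[2]
    reason[is.na(reason) & bad_date] <- "date"
  }

  tally <- c(category = sum(reason == "category", na.rm = TRUE),
             note = sum(reason == "note", na.rm = TRUE),
             agency = sum(reason == "agency", na.rm = TRUE),
             date = sum(reason == "date", na.rm = TRUE))
  retained <- records[is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  if (!is.null(tally_path))
    jsonlite::write_json(as.list(tally), tally_path, auto_unbox = TRUE)
  list(records = retained, tally = tally)
}
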