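#' Construct a study dataset
#'
#' Bundles participant records and session measurements from a two-group
#' (CAD / control), two-condition (moderate / high intensity), four-timepoint
#' (pre, 5, 15, 30 min) crossover trial into a single validated container.
#'
#' @param participants Tibble with one row per enrolled participant. Mandatory
#'   columns: `participant_id` (unique string), `group` (`"CAD"` or `"CON"`).
#'   Optional covariates (kept verbatim): `age`, `sex`, `vo2peak`, `hr_max`,
#'   `hypertensive`, and medication flags `ace`, `beta_blocker`, `ca_blocker`,
#'   `anticoagulant`, `statin`. Missing optional values are `NA`, never
#'   sentinel numbers.
#' @param measurements Tibble with one row per (participant, condition,
#'   timepoint) session observation. Columns: `participant_id`, `condition`
#'   (`"MOD"`/`"HIGH"`), `timepoint` (`"PRE"`, `"P5"`, `"P15"`, `"P30"`),
#'   `hr` (beats/min), `bsbp`, `bdbp`, `csbp` (mmHg), and optionally `cfpwv`
#'   (m/s).
#' @param provenance Free-text source tag.
#'
#' @return An object of class `study_dataset`: a list with elements
#'   `participants`, `measurements` and `provenance`.
#' @export
#' @examples
#' d <- study_dataset(
#'   participants = tibble::tibble(participant_id = "p1", group = "CAD"),
#'   measurements = tibble::tibble(
#'     participant_id = "p1", condition = "MOD", timepoint = "PRE",
#'     hr = 60, bsbp = 112, bdbp = 70, csbp = 101, cfpwv = NA_real_
#'   )
#' )
#' d
study_dataset <- function(participants, measurements, provenance = "in-memory") {
  participants <- tibble::as_tibble(participants)
  measurements <- tibble::as_tibble(measurements)
  if (!"cfpwv" %in% names(measurements) && nrow(measurements) >= 0) {
    measurements$cfpwv <- rep(NA_real_, nrow(measurements))
  }
  out <- structure(
    list(participants = participants, measurements = measurements,
         provenance = as.character(provenance)[1]),
    class = "study_dataset"
  )
  validate_study_dataset(out)
  out
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "<study_dataset> %d participants (%s), %d measurements [%s]\n",
    nrow(x$participants),
    paste(sprintf("%s: %d", GROUPS,
                  vapply(GROUPS, function(g) sum(x$participants$group == g),
                         integer(1))),
          collapse = ", "),
    nrow(x$measurements), x$provenance
  ))
  invisible(x)
}

PARTICIPANT_OPTIONAL <- c("age", "sex", "vo2peak", "hr_max", "hypertensive",
                          "ace", "beta_blocker", "ca_blocker",
                          "anticoagulant", "statin")
MEASUREMENT_MANDATORY <- c("participant_id", "condition", "timepoint",
                           "hr", "bsbp", "bdbp", "csbp")

#' Validate a study dataset
#'
#' Checks every structural invariant of the data model: mandatory columns,
#' enum membership of group/condition/timepoint, unique participant ids, at
#' most one record per (participant, condition, timepoint), referential
#' integrity of measurements, and the pressure ordering `bsbp > bdbp > 0`,
#' `csbp > 0` on every row. Validation is total: malformed input raises a
#' classed error (`peh_error_schema`, `peh_error_parse`,
#' `peh_error_integrity`), never a partially checked dataset.
#'
#' @param data A [study_dataset()].
#' @return `data`, invisibly, if valid.
#' @export
validate_study_dataset <- function(data) {
  p <- data$participants
  m <- data$measurements

  for (col in c("participant_id", "group")) {
    if (!col %in% names(p)) {
      stop_schema(sprintf("participants is missing mandatory column '%s'", col))
    }
  }
  for (col in MEASUREMENT_MANDATORY) {
    if (!col %in% names(m)) {
      stop_schema(sprintf("measurements is missing mandatory column '%s'", col))
    }
  }

  if (anyDuplicated(p$participant_id)) {
    dup <- p$participant_id[duplicated(p$participant_id)][1]
    stop_integrity(sprintf("duplicate participant id '%s'", dup))
  }
  bad_group <- setdiff(unique(p$group), GROUPS)
  if (length(bad_group)) {
    stop_parse(sprintf("unknown group label '%s' (expected %s)",
                       bad_group[1], paste(GROUPS, collapse = "/")))
  }
  if ("age" %in% names(p)) {
    bad <- which(!is.na(p$age) & p$age <= 0)
    if (length(bad)) {
      stop_integrity(sprintf("non-positive age for participant '%s'",
                             p$participant_id[bad[1]]))
    }
  }

  if (nrow(m)) {
    for (col in c("hr", "bsbp", "bdbp", "csbp", "cfpwv")) {
      if (!is.numeric(m[[col]])) {
        stop_parse(sprintf("column '%s' is not numeric", col))
      }
    }
    bad_cond <- setdiff(unique(m$condition), CONDITIONS)
    if (length(bad_cond)) {
      stop_parse(sprintf("unknown condition label '%s' (expected %s)",
                         bad_cond[1], paste(CONDITIONS, collapse = "/")))
    }
    bad_tp <- setdiff(unique(m$timepoint), TIMEPOINTS)
    if (length(bad_tp)) {
      stop_parse(sprintf("unknown timepoint label '%s' (expected %s)",
                         bad_tp[1], paste(TIMEPOINTS, collapse = "/")))
    }
    key <- paste(m$participant_id, m$condition, m$timepoint, sep = "|")
    if (anyDuplicated(key)) {
      stop_integrity(sprintf(
        "duplicate measurement for (%s) at row %d",
        gsub("\\|", ", ", key[duplicated(key)][1]),
        which(duplicated(key))[1]
      ))
    }
    orphan <- setdiff(unique(m$participant_id), p$participant_id)
    if (length(orphan)) {
      stop_integrity(sprintf(
        "measurement references unknown participant '%s'", orphan[1]))
    }
    bad_row <- which(!is.na(m$bsbp) & !is.na(m$bdbp) &
                       (m$bdbp <= 0 | m$bsbp <= m$bdbp))
    if (length(bad_row)) {
      stop_integrity(sprintf(
        "row %d: requires bsbp > bdbp > 0 (got bsbp = %s, bdbp = %s)",
        bad_row[1], m$bsbp[bad_row[1]], m$bdbp[bad_row[1]]))
    }
    bad_c <- which(!is.na(m$csbp) & m$csbp <= 0)
    if (length(bad_c)) {
      stop_integrity(sprintf("row %d: csbp must be positive", bad_c[1]))
    }
  }
  invisible(data)
}

# Numeric minute labels used by spreadsheet layouts -> canonical timepoints.
TIMEPOINT_MINUTES <- c("0" = "PRE", "5" = "P5", "15" = "P15", "30" = "P30")

canonical_timepoint <- function(x) {
  x <- as.character(x)
  mapped <- unname(TIMEPOINT_MINUTES[x])
  ifelse(is.na(mapped), x, mapped)
}

#' Read a study dataset from a long-format table
#'
#' Ingests the canonical long layout (one row per participant x condition x
#' timepoint) from CSV or from the first sheet of an XLSX workbook (the
#' deposited-trial layout), applying an optional column-name mapping so
#' spreadsheets with other headers can be adapted without editing the file.
#' Numeric minute timepoints (0/5/15/30) are mapped to PRE/P5/P15/P30 on read.
#' Unknown columns are ignored with a warning; row order is preserved.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`. XLSX reading
#'   requires the readxl package.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(participant_id = "ID", bsbp = "SBP_brachial")`.
#' @param provenance Source tag stored on the dataset; defaults to the file
#'   name.
#' @return A validated [study_dataset()].
#' @export
read_study_dataset <- function(path,
                               format = c("auto", "csv", "xlsx"),
                               col_map = NULL,
                               provenance = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_schema(sprintf("file '%s' does not exist", path))
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }

  if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_schema("reading XLSX requires the 'readxl' package")
    }
    raw <- readxl::read_excel(path, sheet = 1)
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  }

  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop_schema(sprintf("mapped column '%s' (for '%s') not found in file",
                            src, canon))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }

  known <- c(MEASUREMENT_MANDATORY, "group", "cfpwv", PARTICIPANT_OPTIONAL)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warn(sprintf("ignoring unknown column(s): %s",
                 paste(unknown, collapse = ", ")))
    raw <- raw[known[known %in% names(raw)]]
  }
  for (col in c(MEASUREMENT_MANDATORY, "group")) {
    if (!col %in% names(raw)) {
      stop_schema(sprintf("missing mandatory column '%s'", col))
    }
  }

  numeric_cols <- intersect(
    c("hr", "bsbp", "bdbp", "csbp", "cfpwv", "age", "vo2peak", "hr_max"),
    names(raw))
  for (col in numeric_cols) {
    vals <- as.character(raw[[col]])
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "NA" & vals != "" & is.na(parsed))
    if (length(bad)) {
      stop_parse(sprintf("column '%s' row %d: cannot parse '%s' as a number",
                         col, bad[1], vals[bad[1]]))
    }
    raw[[col]] <- parsed
  }
  logical_cols <- intersect(
    c("hypertensive", "ace", "beta_blocker", "ca_blocker",
      "anticoagulant", "statin"), names(raw))
  for (col in logical_cols) raw[[col]] <- as.logical(raw[[col]])

  raw$participant_id <- as.character(raw$participant_id)
  raw$group <- as.character(raw$group)
  raw$condition <- as.character(raw$condition)
  raw$timepoint <- canonical_timepoint(raw$timepoint)
  if (!"cfpwv" %in% names(raw)) raw$cfpwv <- NA_real_
  if ("sex" %in% names(raw)) raw$sex <- as.character(raw$sex)

  part_cols <- c("participant_id", "group",
                 intersect(PARTICIPANT_OPTIONAL, names(raw)))
  participants <- dplyr::distinct(raw[part_cols])
  measurements <- raw[c("participant_id", "condition", "timepoint",
                        "hr", "bsbp", "bdbp", "csbp", "cfpwv")]
  study_dataset(participants, measurements, provenance = provenance)
}

#' Write a study dataset to the canonical long CSV
#'
#' Emits one row per measurement with the participant's group and covariates
#' joined on, so that [read_study_dataset()] recovers the dataset exactly
#' (`read(write(d)) == d` for any valid dataset in which every participant has
#' at least one measurement). An empty dataset yields a header-only file.
#'
#' @param data A validated [study_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_dataset <- function(data, path) {
  validate_study_dataset(data)
  joined <- dplyr::left_join(data$measurements, data$participants,
                             by = "participant_id")
  front <- c("participant_id", "group", "condition", "timepoint",
             "hr", "bsbp", "bdbp", "csbp", "cfpwv")
  joined <- joined[c(front, setdiff(names(joined), front))]
  readr::write_csv(joined, path, progress = FALSE)
  invisible(path)
}

#' Identify participants complete for an outcome and condition
#'
#' A participant is complete for an outcome x condition when the PRE
#' measurement and at least one of the 15- or 30-min measurements carry a
#' non-missing value of the outcome.
#'
#' @param data A [study_dataset()].
#' @param outcome `"csbp"` or `"bsbp"`.
#' @param condition `"MOD"` or `"HIGH"`.
#' @return Character vector of complete participant ids, in enrolment order.
#' @export
complete_participants <- function(data, outcome = OUTCOMES,
                                  condition = CONDITIONS) {
  outcome <- match.arg(outcome)
  condition <- match.arg(condition)
  m <- data$measurements
  m <- m[m$condition == condition & !is.na(m[[outcome]]), ]
  ok <- vapply(data$participants$participant_id, function(id) {
    tp <- m$timepoint[m$participant_id == id]
    "PRE" %in% tp && any(c("P15", "P30") %in% tp)
  }, logical(1))
  data$participants$participant_id[ok]
}
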