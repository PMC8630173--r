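#' Cohort feature tables
#'
#' A cohort is an ordinary tibble with one row per patient and a fixed column
#' schema of coded ECG features: identifiers, sex, QRS duration, frontal axis,
#' PR interval, V1 morphology, per-lead notch/slur flags, per-lead Q-wave
#' flags, and R-wave-peak-time (RWPT) threshold flags for V5/V6. Notching and
#' slurring are collapsed into one boolean per lead because every definition
#' scored here treats "notching/slurring" as a single disjunctive feature.
#' RWPT is likewise coded as a `> 60 ms` boolean per lead; an opaque optional
#' numeric for lead I is carried for descriptive parity with published tables
#' (its printed unit is inconsistent and not asserted).
#'
#' @name cohort
NULL

# canonical column order for serialization
COHORT_COLS <- c("patient_id", "sex", "qrsd_ms", "frontal_axis_deg", "pr_ms",
                 "v1_morphology",
                 "notch_I", "notch_aVL", "notch_V1", "notch_V2", "notch_V5",
                 "notch_V6", "notch_II", "notch_III", "notch_aVF",
                 "q_I", "q_aVL", "q_V5", "q_V6",
                 "rwpt_gt60_v5", "rwpt_gt60_v6", "rwpt_lead1_ms")

COHORT_LOGICAL_COLS <- c(paste0("notch_", NOTCH_LEADS), paste0("q_", Q_LEADS),
                         "rwpt_gt60_v5", "rwpt_gt60_v6")

COHORT_NUMERIC_COLS <- c("qrsd_ms", "frontal_axis_deg", "pr_ms",
                         "rwpt_lead1_ms")

#' Construct an empty cohort skeleton
#'
#' Returns a zero-row tibble with the full cohort column schema; mainly useful
#' for building cohorts programmatically.
#'
#' @return A zero-row tibble with the cohort schema.
#' @export
cohort_template <- function() {
  tibble(
    patient_id = character(), sex = character(), qrsd_ms = double(),
    frontal_axis_deg = double(), pr_ms = double(), v1_morphology = character(),
    notch_I = logical(), notch_aVL = logical(), notch_V1 = logical(),
    notch_V2 = logical(), notch_V5 = logical(), notch_V6 = logical(),
    notch_II = logical(), notch_III = logical(), notch_aVF = logical(),
    q_I = logical(), q_aVL = logical(), q_V5 = logical(), q_V6 = logical(),
    rwpt_gt60_v5 = logical(), rwpt_gt60_v6 = logical(),
    rwpt_lead1_ms = double()
  )
}

#' Validate a cohort feature table
#'
#' Checks every structural invariant of the cohort schema and returns the
#' violations as data rather than raising conditions: positive QRS duration,
#' frontal axis within `[-180, 180)` when present, sex coded M/F, V1
#' morphology one of QS/rS/other, all required per-lead flags present
#' (non-missing booleans), and unique patient identifiers.
#'
#' @param cohort A cohort tibble (see [cohort]).
#' @return A tibble with columns `patient_id`, `field`, `rule`; zero rows iff
#'   the cohort is valid.
#' @examples
#' validate_features(simulate_cohort(sim_params(n = 5, seed = 1)))
#' @export
validate_features <- function(cohort) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(COHORT_COLS, names(cohort))
  if (length(missing_cols) > 0) {
    return(tibble(patient_id = NA_character_, field = missing_cols,
                  rule = "required column missing"))
  }
  bad <- list()
  viol <- function(id, field, rule) tibble(patient_id = id, field = field,
                                           rule = rule)
  id <- as.character(cohort$patient_id)

  dup <- id[duplicated(id)]
  if (length(dup) > 0)
    bad[[length(bad) + 1]] <- viol(unique(dup), "patient_id",
                                   "patient_id must be unique within a cohort")
  bad_qrsd <- is.na(cohort$qrsd_ms) | cohort$qrsd_ms <= 0
  if (any(bad_qrsd))
    bad[[length(bad) + 1]] <- viol(id[bad_qrsd], "qrsd_ms",
                                   "qrsd_ms must be a positive duration")
  ax <- cohort$frontal_axis_deg
  bad_ax <- !is.na(ax) & (ax < -180 | ax >= 180)
  if (any(bad_ax))
    bad[[length(bad) + 1]] <- viol(id[bad_ax], "frontal_axis_deg",
                                   "frontal_axis_deg must lie in [-180, 180)")
  bad_sex <- is.na(cohort$sex) | !cohort$sex %in% c("M", "F")
  if (any(bad_sex))
    bad[[length(bad) + 1]] <- viol(id[bad_sex], "sex",
                                   "sex must be 'M' or 'F'")
  bad_v1 <- is.na(cohort$v1_morphology) |
    !cohort$v1_morphology %in% c("QS", "rS", "other")
  if (any(bad_v1))
    bad[[length(bad) + 1]] <- viol(id[bad_v1], "v1_morphology",
                                   "v1_morphology must be QS, rS or other")
  for (col in COHORT_LOGICAL_COLS) {
    v <- cohort[[col]]
    bad_flag <- !is.logical(v) | is.na(v)
    if (any(bad_flag))
      bad[[length(bad) + 1]] <- viol(id[bad_flag], col,
                                     "required lead flag must be TRUE/FALSE")
  }
  if (length(bad) == 0) {
    tibble(patient_id = character(), field = character(), rule = character())
  } else {
    bind_rows(bad)
  }
}

assert_cohort <- function(cohort, arg = "cohort") {
  v <- validate_features(cohort)
  if (nrow(v) > 0) {
    msg <- paste0(utils::head(paste0(v$patient_id, ": ", v$field, " (", v$rule,
                                     ")"), 5), collapse = "; ")
    abort(paste0("invalid cohort in `", arg, "`: ", msg))
  }
  invisible(as_tibble(cohort))
}

parse_strict_logical <- function(x, col, rows) {
  out <- rep(NA, length(x))
  x_chr <- trimws(as.character(x))
  ok_true <- x_chr %in% c("1", "true", "TRUE")
  ok_false <- x_chr %in% c("0", "false", "FALSE")
  miss <- is.na(x) | x_chr == ""
  bad <- !(ok_true | ok_false | miss)
  if (any(bad)) {
    abort(paste0("parse error in column '", col, "', row ",
                 rows[which(bad)[1]], ": '", x_chr[which(bad)[1]],
                 "' is not a boolean (accepted: 0, 1, true, false, TRUE, FALSE)"))
  }
  out[ok_true] <- TRUE
  out[ok_false] <- FALSE
  out
}

parse_num <- function(x, col, rows) {
  x_chr <- trimws(as.character(x))
  miss <- is.na(x) | x_chr == ""
  out <- suppressWarnings(as.numeric(x_chr))
  bad <- !miss & is.na(out)
  if (any(bad))
    abort(paste0("parse error in column '", col, "', row ",
                 rows[which(bad)[1]], ": '", x_chr[which(bad)[1]],
                 "' is not numeric"))
  out
}

#' Read a cohort feature table from CSV or JSON
#'
#' CSV files must carry the documented header (see [cohort_template] for the
#' column set); JSON files hold an array of objects with the same fields.
#' Booleans are accepted as `0`, `1`, `true`, `false`, `TRUE` or `FALSE`;
#' anything else is a parse error naming the row and column. Lines starting
#' with `#` (provenance headers written by [write_cohort]) are skipped.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"json"`, or `"auto"` (from the file extension).
#' @param validate Assert the schema invariants after parsing (default); set
#'   `FALSE` to obtain the parsed table for inspection with
#'   [validate_features()].
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json"),
                        validate = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0) abort(paste0("no patients in '", path, "'"))
    raw <- as_tibble(raw)
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           comment = "#", progress = FALSE,
                           show_col_types = FALSE)
    if (nrow(raw) == 0) abort(paste0("no patients in '", path, "'"))
  }
  missing_cols <- setdiff(setdiff(COHORT_COLS, c("frontal_axis_deg", "pr_ms",
                                                 "rwpt_lead1_ms")),
                          names(raw))
  if (length(missing_cols) > 0)
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  for (opt in c("frontal_axis_deg", "pr_ms", "rwpt_lead1_ms"))
    if (!opt %in% names(raw)) raw[[opt]] <- NA_real_
  rows <- seq_len(nrow(raw))
  out <- tibble(
    patient_id = as.character(raw$patient_id),
    sex = as.character(raw$sex),
    qrsd_ms = parse_num(raw$qrsd_ms, "qrsd_ms", rows),
    frontal_axis_deg = parse_num(raw$frontal_axis_deg, "frontal_axis_deg", rows),
    pr_ms = parse_num(raw$pr_ms, "pr_ms", rows),
    v1_morphology = as.character(raw$v1_morphology)
  )
  for (col in COHORT_LOGICAL_COLS)
    out[[col]] <- parse_strict_logical(raw[[col]], col, rows)
  out$rwpt_lead1_ms <- parse_num(raw$rwpt_lead1_ms, "rwpt_lead1_ms", rows)
  out <- out[, COHORT_COLS]
  if (validate) {
    dup <- unique(out$patient_id[duplicated(out$patient_id)])
    if (length(dup) > 0)
      abort(paste0("duplicate patient_id: ", paste(dup, collapse = ", ")))
    assert_cohort(out, arg = path)
  }
  out
}

#' Write a cohort feature table to CSV or JSON
#'
#' CSV output codes booleans as `0`/`1` and missing optional values as empty
#' fields, so a write/read round trip reproduces the cohort field-for-field
#' and repeated writes are byte-identical. An optional provenance header
#' (comment lines starting `#`) can be prepended.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param header Optional character vector of provenance comment lines
#'   (written as `# ...`; CSV only).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json"),
                         header = NULL) {
  format <- match.arg(format)
  cohort <- assert_cohort(cohort)
  if (format == "json") {
    jsonlite::write_json(cohort, path, auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  out <- cohort[, COHORT_COLS]
  for (col in COHORT_LOGICAL_COLS) out[[col]] <- as.integer(out[[col]])
  lines <- character()
  if (!is.null(header)) lines <- paste0("# ", header)
  csv <- readr::format_csv(out, na = "")
  writeLines(c(lines, sub("\n$", "", csv)), path)
  invisible(path)
}
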