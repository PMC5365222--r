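#' Survival outcome vector pair
#'
#' Lightweight container for right-censored survival outcomes: follow-up
#' time in days and a death indicator. All evaluation and fitting
#' functions in the package accept this projection of a cohort table.
#'
#' @param time_days positive numeric vector, days from baseline.
#' @param event 0/1 vector, 1 = death observed, 0 = right-censored.
#' @return an object of class `surv_outcome` with elements `time` and
#'   `event`.
#' @export
surv_outcome <- function(time_days, event) {
  time_days <- as.numeric(time_days)
  event <- as.numeric(event)
  if (length(time_days) != length(event))
    stop("`time_days` and `event` must have equal length", call. = FALSE)
  if (anyNA(time_days) || anyNA(event))
    stop("survival outcome may not contain missing values", call. = FALSE)
  if (any(time_days <= 0))
    stop("all `time_days` must be > 0", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("`event` must be coded 0/1", call. = FALSE)
  structure(list(time = time_days, event = event), class = "surv_outcome")
}

#' @export
length.surv_outcome <- function(x) length(x$time)

#' @rdname surv_outcome
#' @param cohort a [cohort_table()].
#' @export
as_surv_outcome <- function(cohort) {
  surv_outcome(cohort$time_days, cohort$event)
}

#' @export
print.surv_outcome <- function(x, ...) {
  cat(sprintf("<surv_outcome> n = %d, events = %d (%.1f%%)\n",
              length(x$time), sum(x$event),
              100 * mean(x$event)))
  invisible(x)
}

valid_tags <- c("categorical", "ordinal", "numeric", "binary")

#' Patient-level cohort table
#'
#' A validated data frame with one row per patient: identifier, trial
#' label, survival time in days, death indicator and tagged covariate
#' columns. Covariate tags (`categorical`, `ordinal`, `numeric`,
#' `binary`) are carried as the `schema` attribute and drive design
#' matrix construction. Missing values are stored as `NA`, never zero.
#'
#' @param data a data.frame containing `patient_id`, `trial`,
#'   `time_days`, `event` and the covariate columns named in `schema`.
#' @param schema named character vector mapping each covariate column to
#'   its tag.
#' @return a `cohort_table` (data.frame subclass).
#' @export
cohort_table <- function(data, schema) {
  schema <- validate_schema(schema)
  mandatory <- c("patient_id", "trial", "time_days", "event")
  missing_cols <- setdiff(c(mandatory, names(schema)), names(data))
  if (length(missing_cols))
    stop("cohort is missing declared column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(data), c(mandatory, names(schema)))
  if (length(extra)) {
    warning("ignoring undeclared column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    data <- data[, setdiff(names(data), extra), drop = FALSE]
  }
  data <- data[, c(mandatory, names(schema)), drop = FALSE]
  data$patient_id <- as.character(data$patient_id)
  data$trial <- as.character(data$trial)
  data$time_days <- as.numeric(data$time_days)
  data$event <- as.numeric(data$event)

  if (anyDuplicated(data$patient_id))
    stop("duplicate patient_id value(s): ",
         paste(unique(data$patient_id[duplicated(data$patient_id)]),
               collapse = ", "), call. = FALSE)
  bad_time <- which(is.na(data$time_days) | data$time_days <= 0)
  if (length(bad_time))
    stop("time_days must be > 0; offending patient_id(s): ",
         paste(data$patient_id[bad_time], collapse = ", "), call. = FALSE)
  if (!all(data$event %in% c(0, 1)))
    stop("event must be coded 0/1", call. = FALSE)
  for (cv in names(schema)) {
    if (schema[[cv]] == "binary") {
      v <- data[[cv]]
      if (!all(v[!is.na(v)] %in% c(0, 1)))
        stop("binary covariate `", cv, "` has values outside {0,1}",
             call. = FALSE)
    }
  }
  structure(data, schema = schema,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  sch <- attr(x, "schema")
  cat(sprintf(
    "<cohort_table> %d patients, %d events, %d trials, %d covariates\n",
    nrow(x), sum(x$event), length(unique(x$trial)), length(sch)))
  NextMethod()
}

#' Schema of covariate tags
#'
#' @param x named character vector, or path to a YAML/JSON file mapping
#'   column names to tags.
#' @return named character vector of validated tags.
#' @export
validate_schema <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    x <- read_schema(x)
  }
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("schema must be a named map column -> tag", call. = FALSE)
  bad <- setdiff(unique(x), valid_tags)
  if (length(bad))
    stop("unknown covariate tag(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(valid_tags, collapse = ", "),
         call. = FALSE)
  x
}

#' @rdname validate_schema
#' @param path file path; `.json` parsed with jsonlite, anything else
#'   with yaml.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  sch <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_schema(sch)
}

#' @rdname validate_schema
#' @param schema named character vector of tags.
#' @export
write_schema <- function(schema, path) {
  schema <- validate_schema(schema)
  yaml::write_yaml(as.list(schema), path)
  invisible(path)
}

#' Read and write cohort CSV files
#'
#' The cohort CSV has a header row with columns `patient_id`, `trial`,
#' `time_days`, `event`, then covariates. Empty cells are read as `NA`
#' and written back as empty, so missingness round-trips exactly.
#'
#' @param path CSV file path.
#' @param schema covariate tag map (named vector or schema file path).
#' @return `read_cohort()` a validated [cohort_table()];
#'   `write_cohort()` the path, invisibly.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  check.names = FALSE)
  cohort_table(raw, schema)
}

#' @rdname read_cohort
#' @param cohort a [cohort_table()].
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Lesion-level table
#'
#' One row per target lesion: patient identifier, lesion size
#' (nonnegative, unit-agnostic) and a bone/non-bone flag. Sizes may be
#' missing, which routes the patient to the imputation path of
#' [impute_tlv()]. Patients absent from the table have zero target
#' lesions.
#'
#' @param data data.frame with columns `patient_id`, `size`, `is_bone`.
#' @return a `lesion_table` (data.frame subclass).
#' @export
lesion_table <- function(data) {
  need <- c("patient_id", "size", "is_bone")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("lesion table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- data[, need, drop = FALSE]
  data$patient_id <- as.character(data$patient_id)
  data$size <- as.numeric(data$size)
  data$is_bone <- as.numeric(data$is_bone)
  if (any(data$size[!is.na(data$size)] < 0))
    stop("lesion sizes must be >= 0", call. = FALSE)
  if (!all(data$is_bone[!is.na(data$is_bone)] %in% c(0, 1)))
    stop("is_bone must be coded 0/1", call. = FALSE)
  structure(data, class = c("lesion_table", "data.frame"))
}

#' @rdname lesion_table
#' @param path CSV file path.
#' @export
read_lesions <- function(path) {
  if (!file.exists(path)) stop("lesion file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  check.names = FALSE)
  lesion_table(raw)
}

#' @rdname lesion_table
#' @param lesions a `lesion_table`.
#' @export
write_lesions <- function(lesions, path) {
  stopifnot(inherits(lesions, "lesion_table"))
  write.csv(as.data.frame(lesions), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert months to days
#'
#' Evaluation windows are quoted in months but times are stored in days;
#' the conversion uses the mean Gregorian month of 30.4375 days.
#'
#' @param months numeric vector.
#' @return days.
#' @export
months_to_days <- function(months) months * 30.4375
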