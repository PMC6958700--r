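#' Construct a patient diary
#'
#' Bundles one patient's validated, date-ordered diary entries together with
#' the list of calendar gaps (dates between the first and last entry with no
#' record).
#'
#' @param entries data.frame of validated entries (as produced by
#'   [validate_entry()]) for one patient.
#' @return An object of class `patient_diary`: list with `patient_id`,
#'   `entries` (date-sorted data.frame incl. `total`) and `gaps` (Date vector).
#' @export
patient_diary <- function(entries) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1)
  pid <- unique(entries$patient_id)
  if (length(pid) != 1) stop("entries must belong to a single patient")
  entries <- entries[order(entries$date), , drop = FALSE]
  if (anyDuplicated(entries$date)) {
    dup <- entries$date[duplicated(entries$date)][1]
    stop(sprintf("duplicate record for patient %s on %s", pid, dup),
         call. = FALSE)
  }
  rownames(entries) <- NULL
  span <- seq(min(entries$date), max(entries$date), by = "day")
  gaps <- span[!(span %in% entries$date)]
  structure(list(patient_id = pid, entries = entries, gaps = gaps),
            class = "patient_diary")
}

#' @export
print.patient_diary <- function(x, ...) {
  cat(sprintf("BEST diary for patient %s: %d entries, %s to %s (%d gap days)\n",
              x$patient_id, nrow(x$entries), min(x$entries$date),
              max(x$entries$date), length(x$gaps)))
  invisible(x)
}

#' Construct a set of patient diaries
#' @param diaries List of `patient_diary` objects.
#' @return Named list of class `diary_set` (names are patient ids).
#' @export
diary_set <- function(diaries) {
  stopifnot(all(vapply(diaries, inherits, logical(1), "patient_diary")))
  names(diaries) <- vapply(diaries, function(d) d$patient_id, character(1))
  structure(diaries, class = "diary_set")
}

#' @export
print.diary_set <- function(x, ...) {
  n_entries <- sum(vapply(x, function(d) nrow(d$entries), numeric(1)))
  cat(sprintf("BEST diary set: %d patients, %d patient-days\n",
              length(x), n_entries))
  invisible(x)
}

diary_csv_columns <- function() {
  c("patient_id", "date", best_item_names(), "reported_flag",
    "antibiotic_start")
}

#' Read a diary CSV file
#'
#' Expects columns `patient_id,date,breathlessness,fatigue,sputum_volume,
#' sputum_colour,cough,cold_flu,reported_flag,antibiotic_start` with ISO dates
#' and 0/1 flags. Every row is validated; all malformed rows are reported with
#' their line numbers before the reader fails. Duplicate (patient, day) pairs
#' are an error. Missing calendar days become diary gaps.
#'
#' @param path Path to a CSV file.
#' @return A [diary_set()].
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  unknown <- setdiff(names(raw), diary_csv_columns())
  if (length(unknown)) {
    stop(sprintf("%s: unknown column(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing_cols <- setdiff(setdiff(diary_csv_columns(),
                                  c("reported_flag", "antibiotic_start")),
                          names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0) return(diary_set(list()))

  errs <- character(0)
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    v <- validate_entry(as.list(raw[i, , drop = FALSE]))
    if (!v$ok) {
      # +1 for the header line
      errs <- c(errs, sprintf("%s line %d: %s", path, i + 1,
                              paste(v$errors, collapse = "; ")))
    } else {
      rows[[i]] <- v$entry
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  all_entries <- do.call(rbind, rows)
  key <- paste(all_entries$patient_id, all_entries$date)
  if (anyDuplicated(key)) {
    d <- all_entries[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("%s: duplicate record for patient %s on %s", path,
                 d$patient_id, d$date), call. = FALSE)
  }
  split_entries <- split(all_entries, all_entries$patient_id)
  diary_set(lapply(split_entries, patient_diary))
}

#' Write a diary set to CSV
#'
#' Inverse of [read_diary_csv()]: `read_diary_csv(write_diary_csv(x, p))`
#' reproduces `x` exactly. Gap days are simply absent from the file.
#'
#' @param diaries A [diary_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(diaries, path) {
  cols <- diary_csv_columns()
  if (length(diaries) == 0) {
    df <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                          cols)
  } else {
    df <- do.call(rbind, lapply(diaries, function(d) d$entries[, cols]))
  }
  df$date <- format(as.Date(df$date), "%Y-%m-%d")
  df$reported_flag <- as.integer(df$reported_flag)
  df$antibiotic_start <- as.integer(df$antibiotic_start)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an anchor questionnaire CSV
#'
#' Columns: `patient_id,visit,sgrq_total,sgrq_symptom,cat,lcq,six_mwt_m`;
#' `visit` one of baseline, exac_start, exac_end, end_of_study; blank cells
#' are missing values.
#'
#' @param path Path to a CSV file.
#' @return data.frame with typed columns.
#' @export
read_anchor_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "visit", "sgrq_total", "sgrq_symptom", "cat",
            "lcq", "six_mwt_m")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- !(df$visit %in% c("baseline", "exac_start", "exac_end",
                           "end_of_study"))
  if (any(bad)) {
    stop(sprintf("%s: invalid visit value(s): %s", path,
                 paste(unique(df$visit[bad]), collapse = ", ")), call. = FALSE)
  }
  for (nm in setdiff(need, c("patient_id", "visit"))) {
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Write an anchor questionnaire CSV
#' @param anchors data.frame as returned by [read_anchor_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchor_csv <- function(anchors, path) {
  utils::write.csv(anchors, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
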