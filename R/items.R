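#' BEST diary item definitions
#'
#' The BEST (Bronchiectasis Exacerbation and Symptom Tool) diary records six
#' symptom domains every day: breathlessness (MRC-style grading, 0-4), fatigue
#' (0-4), sputum volume (0-4, anchored to household volume equivalents),
#' sputum colour (0-5, clear through dark green plus blood-stained), cough
#' (0-4) and cold/flu-like systemic symptoms (levels 0, 1, 2 and 5 only; 3 and
#' 4 are undefined on the diary card). The daily total is the sum of the six
#' item scores and ranges 0-26.
#'
#' @return A list with one element per item; each element has `name`,
#'   `allowed_levels` (integer vector) and `level_labels` (named character
#'   vector over the allowed levels).
#' @examples
#' items <- best_items()
#' sum(vapply(items, function(it) max(it$allowed_levels), numeric(1))) # 26
#' @export
best_items <- function() {
  list(
    breathlessness = list(
      name = "breathlessness",
      allowed_levels = 0:4,
      level_labels = c(
        "0" = "None",
        "1" = "Breathlessness when hurrying or walking up a slight hill",
        "2" = "Have to walk slowly or stop for breath on level ground",
        "3" = "Can walk less than 100 m before having to stop",
        "4" = "Breathless when washing or dressing"
      )
    ),
    fatigue = list(
      name = "fatigue",
      allowed_levels = 0:4,
      level_labels = c(
        "0" = "I do not feel tired",
        "1" = "I feel a little tired",
        "2" = "I feel tired but can still do the things I would like to do",
        "3" = "Tiredness is stopping me from doing some things I want to do",
        "4" = "I am so tired I am unable to carry out my usual daily activities"
      )
    ),
    sputum_volume = list(
      name = "sputum_volume",
      allowed_levels = 0:4,
      level_labels = c(
        "0" = "No sputum",
        "1" = "Less than a teaspoon",
        "2" = "Teaspoon to an eggcup",
        "3" = "Egg-cup to a cup",
        "4" = "More than a cup"
      )
    ),
    sputum_colour = list(
      name = "sputum_colour",
      allowed_levels = 0:5,
      level_labels = c(
        "0" = "No sputum",
        "1" = "White",
        "2" = "Yellow",
        "3" = "Green",
        "4" = "Dark green",
        "5" = "Blood stained"
      )
    ),
    cough = list(
      name = "cough",
      allowed_levels = 0:4,
      level_labels = c(
        "0" = "None",
        "1" = "Mild",
        "2" = "Moderate",
        "3" = "Severe",
        "4" = "Very severe"
      )
    ),
    cold_flu = list(
      name = "cold_flu",
      allowed_levels = c(0L, 1L, 2L, 5L),
      level_labels = c(
        "0" = "None",
        "1" = "Sore throat, sore muscles, or runny nose",
        "2" = "Fever/high temperature or shivers",
        "5" = "I feel like I have an infection"
      )
    )
  )
}

#' Names of the six BEST items
#' @return Character vector of length 6, in diary-card order.
#' @export
best_item_names <- function() {
  c("breathlessness", "fatigue", "sputum_volume", "sputum_colour",
    "cough", "cold_flu")
}

#' Maximum attainable BEST total
#' @return 26.
#' @export
best_max_score <- function() {
  sum(vapply(best_items(), function(it) max(it$allowed_levels), numeric(1)))
}

#' Score one diary entry
#'
#' Sums the six item scores of a validated entry. The total lies in 0-26.
#'
#' @param entry A list or one-row data.frame with the six item fields named as
#'   in [best_item_names()].
#' @param validate Check item levels before summing (default TRUE).
#' @return Integer total score.
#' @examples
#' score_entry(list(breathlessness = 1, fatigue = 2, sputum_volume = 2,
#'                  sputum_colour = 2, cough = 1, cold_flu = 1)) # 9
#' @export
score_entry <- function(entry, validate = TRUE) {
  vals <- vapply(best_item_names(), function(nm) as.numeric(entry[[nm]]),
                 numeric(1))
  if (validate) {
    errs <- check_item_levels(vals)
    if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  }
  as.integer(sum(vals))
}

# Returns a character vector of violations for a named numeric vector of the
# six item values (NA allowed in input; reported as missing).
check_item_levels <- function(vals) {
  defs <- best_items()
  errs <- character(0)
  for (nm in best_item_names()) {
    v <- vals[[nm]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      errs <- c(errs, sprintf("%s: missing value", nm))
      next
    }
    if (!is.finite(v) || v != round(v)) {
      errs <- c(errs, sprintf("%s: score %s is not an integer", nm,
                              format(v)))
      next
    }
    allowed <- defs[[nm]]$allowed_levels
    if (!(v %in% allowed)) {
      errs <- c(errs, sprintf("%s level %d not defined (allowed: %s)", nm,
                              as.integer(v), paste(allowed, collapse = ",")))
    }
  }
  errs
}

#' Validate a raw diary record
#'
#' Checks a single raw record (one patient-day) against the diary card: all
#' six items present, integer scores within each item's defined levels
#' (`cold_flu` may only take 0, 1, 2 or 5), a parseable ISO date and a patient
#' id. All violations are collected, not just the first.
#'
#' @param record Named list or one-row data.frame with fields `patient_id`,
#'   `date`, the six items, and optional `reported_flag` / `antibiotic_start`
#'   (0/1 or logical, default 0).
#' @param lenient_coldflu If TRUE, undefined cold_flu levels 3 and 4 are
#'   remapped to 2 with a warning rather than rejected. Default FALSE.
#' @return A list with `ok` (logical), `errors` (character vector), and when
#'   valid `entry`: a one-row data.frame with typed columns plus `total`.
#' @export
validate_entry <- function(record, lenient_coldflu = FALSE) {
  errs <- character(0)
  pid <- record[["patient_id"]]
  if (is.null(pid) || is.na(pid) || !nzchar(as.character(pid))) {
    errs <- c(errs, "patient_id: missing")
  }
  day <- record[["date"]]
  day <- tryCatch(as.Date(day), error = function(e) NA)
  if (is.null(day) || length(day) != 1 || is.na(day)) {
    errs <- c(errs, "date: missing or unparseable (expected ISO-8601)")
  }

  vals <- stats::setNames(vector("list", 6), best_item_names())
  for (nm in best_item_names()) {
    v <- record[[nm]]
    vals[[nm]] <- if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  if (lenient_coldflu && !is.na(vals$cold_flu) && vals$cold_flu %in% c(3, 4)) {
    warning(sprintf("cold_flu level %d remapped to 2 (lenient mode)",
                    as.integer(vals$cold_flu)), call. = FALSE)
    vals$cold_flu <- 2
  }
  errs <- c(errs, check_item_levels(vals))

  flag <- function(nm) {
    v <- record[[nm]]
    if (is.null(v) || length(v) == 0 || is.na(v)) return(FALSE)
    if (is.logical(v)) return(v)
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v) || !(v %in% c(0, 1))) {
      errs <<- c(errs, sprintf("%s: flag must be 0 or 1", nm))
      return(FALSE)
    }
    v == 1
  }
  reported <- flag("reported_flag")
  abx <- flag("antibiotic_start")
  if (isTRUE(abx) && !isTRUE(reported)) {
    # Treatment in this study is commenced by the team after patient contact.
    errs <- c(errs, "antibiotic_start without reported_flag")
  }

  if (length(errs)) return(list(ok = FALSE, errors = errs, entry = NULL))
  entry <- data.frame(
    patient_id = as.character(pid), date = day,
    breathlessness = as.integer(vals$breathlessness),
    fatigue = as.integer(vals$fatigue),
    sputum_volume = as.integer(vals$sputum_volume),
    sputum_colour = as.integer(vals$sputum_colour),
    cough = as.integer(vals$cough),
    cold_flu = as.integer(vals$cold_flu),
    reported_flag = reported, antibiotic_start = abx,
    stringsAsFactors = FALSE
  )
  entry$total <- score_entry(entry, validate = FALSE)
  list(ok = TRUE, errors = character(0), entry = entry)
}

#' Map an expectorated sputum volume in millilitres to the diary category
#'
#' The diary anchors sputum volume to household equivalents: a teaspoon is
#' 5 ml, a tablespoon 15 ml, an egg-cup 45 ml and a cup approximately 250 ml.
#' Category boundaries are half-open with the boundary assigned to the higher
#' category (exactly 5 ml scores 2, "teaspoon to an eggcup").
#'
#' @param volume_ml Non-negative numeric vector of daily sputum volumes (ml).
#' @return Integer vector of categories 0-4.
#' @examples
#' ml_to_volume_category(c(0, 3, 5, 100, 300)) # 0 1 2 3 4
#' @export
ml_to_volume_category <- function(volume_ml) {
  if (any(!is.finite(volume_ml)) || any(volume_ml < 0)) {
    stop("volume_ml must be finite and non-negative", call. = FALSE)
  }
  out <- integer(length(volume_ml))
  out[volume_ml > 0] <- 1L
  out[volume_ml >= 5] <- 2L
  out[volume_ml >= 45] <- 3L
  out[volume_ml >= 250] <- 4L
  out
}
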