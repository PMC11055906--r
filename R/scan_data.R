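#' @name scan-data
#' @title Scan-sampling data model
#'
#' @description
#' Hourly scan-sampling location data are kept in a long-format data frame,
#' one row per animal x scheduled scan, with columns:
#'
#' * `trio_id` — identifier of the social group (trio),
#' * `gilt_id` — identifier of the animal,
#' * `side` — `"LEFT"` or `"RIGHT"` experimental pen,
#' * `season` — `"SUMMER"` or `"WINTER"` replicate block,
#' * `day` — experimental day, 1..`n_days`,
#' * `hour` — hour of day, 0..23,
#' * `location` — `"IN"` (in a crate), `"OUT"` (in the open area) or
#'   `NA` for a missing scan (lost video).
#'
#' On disk (`scans.csv`) the same columns are used and a missing location is
#' an empty field. `validate_scans()` enforces the invariants: unique
#' `(gilt_id, day, hour)` keys, in-range day/hour, known location codes, and
#' a constant trio/side/season per animal.
NULL

SIDE_LEVELS <- c("LEFT", "RIGHT")
SEASON_LEVELS <- c("SUMMER", "WINTER")
LOCATION_LEVELS <- c("IN", "OUT")
SCAN_COLUMNS <- c("trio_id", "gilt_id", "side", "season", "day", "hour", "location")
ETHOGRAM_COLUMNS <- c("gilt_id", "lines_crossed", "nose_wall_s", "nose_floor_s",
                      "lie_down_s", "latency_contact_s", "nose_object_s")
ETHOGRAM_BEHAVIOURS <- setdiff(ETHOGRAM_COLUMNS, "gilt_id")

#' Validate a scan table
#'
#' Checks the invariants of the long-format scan schema (see [scan-data]) and
#' fails with row-numbered messages on violations.
#'
#' @param scans A data frame in the scan schema.
#' @param n_days Highest permitted experimental day (default 7).
#' @return The validated data frame, invisibly classed as `scan_table`.
#' @export
validate_scans <- function(scans, n_days = 7L) {
  if (!is.data.frame(scans)) stop("`scans` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(SCAN_COLUMNS, names(scans))
  if (length(missing_cols))
    stop("scan table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  scans <- as.data.frame(scans)[SCAN_COLUMNS]
  scans$trio_id <- as.character(scans$trio_id)
  scans$gilt_id <- as.character(scans$gilt_id)
  scans$side <- toupper(as.character(scans$side))
  scans$season <- toupper(as.character(scans$season))
  loc <- toupper(as.character(scans$location))
  loc[!is.na(loc) & (loc == "" | loc == "MISSING" | loc == "NA")] <- NA_character_
  scans$location <- loc

  bad <- function(rows, what) {
    if (length(rows))
      stop(sprintf("%s (rows %s)", what,
                   paste(utils::head(rows, 5L), collapse = ", ")), call. = FALSE)
  }
  bad(which(!scans$side %in% SIDE_LEVELS), "unknown side code; expected LEFT/RIGHT")
  bad(which(!scans$season %in% SEASON_LEVELS), "unknown season code; expected SUMMER/WINTER")
  bad(which(!(is.na(scans$location) | scans$location %in% LOCATION_LEVELS)),
      "unknown location code; expected IN, OUT or empty for missing")
  bad(which(is.na(scans$day) | scans$day < 1 | scans$day > n_days |
              scans$day != floor(scans$day)),
      sprintf("`day` must be an integer in 1..%d", n_days))
  bad(which(is.na(scans$hour) | scans$hour < 0 | scans$hour > 23 |
              scans$hour != floor(scans$hour)),
      "`hour` must be an integer in 0..23")
  scans$day <- as.integer(scans$day)
  scans$hour <- as.integer(scans$hour)

  key <- paste(scans$gilt_id, scans$day, scans$hour, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicated (gilt_id, day, hour) key: %s (first duplicate at row %d)",
                 key[dup[1L]], dup[1L]), call. = FALSE)

  # each gilt belongs to exactly one trio / side / season
  for (f in c("trio_id", "side", "season")) {
    n_per_gilt <- tapply(scans[[f]], scans$gilt_id, function(v) length(unique(v)))
    off <- names(n_per_gilt)[n_per_gilt > 1L]
    if (length(off))
      stop(sprintf("gilt(s) %s mapped to more than one `%s`",
                   paste(off, collapse = ", "), f), call. = FALSE)
  }
  class(scans) <- c("scan_table", "data.frame")
  invisible(scans)
}

#' Load a scan table from CSV
#'
#' Reads `scans.csv` (schema in [scan-data]; empty `location` fields become
#' missing scans) and validates it.
#'
#' @param path Path to the CSV file.
#' @param n_days Highest permitted experimental day.
#' @return A validated `scan_table` data frame.
#' @export
load_scans <- function(path, n_days = 7L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  scans <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(location = "character"),
                           na.strings = c("", "NA"))
  validate_scans(scans, n_days = n_days)
}

#' Load an ethogram table from CSV
#'
#' Reads `ethogram.csv`: one row per animal with the six open-field /
#' novel-object behaviours (`lines_crossed`, `nose_wall_s`, `nose_floor_s`,
#' `lie_down_s` over the full 10 min; `latency_contact_s`, `nose_object_s`
#' over the 5-min novel-object phase). An empty latency field means the
#' animal never contacted the object.
#'
#' @param path Path to the CSV file.
#' @return A data frame with class `ethogram_table`.
#' @export
load_ethogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  etho <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_ethogram(etho)
}

#' @rdname load_ethogram
#' @param etho A data frame in the ethogram schema.
#' @export
validate_ethogram <- function(etho) {
  missing_cols <- setdiff(ETHOGRAM_COLUMNS, names(etho))
  if (length(missing_cols))
    stop("ethogram table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  etho <- as.data.frame(etho)[ETHOGRAM_COLUMNS]
  etho$gilt_id <- as.character(etho$gilt_id)
  if (anyDuplicated(etho$gilt_id))
    stop("duplicated gilt_id in ethogram table", call. = FALSE)
  for (b in ETHOGRAM_BEHAVIOURS) {
    v <- etho[[b]]
    if (!is.numeric(v)) stop_field(b, "must be numeric")
    if (any(v < 0, na.rm = TRUE)) stop_field(b, "must be nonnegative")
  }
  if (any(etho$latency_contact_s > 300, na.rm = TRUE))
    stop_field("latency_contact_s", "exceeds the 300 s novel-object phase")
  for (b in c("nose_wall_s", "nose_floor_s", "lie_down_s"))
    if (any(etho[[b]] > 600, na.rm = TRUE))
      stop_field(b, "exceeds the 600 s test duration")
  if (any(etho$nose_object_s > 300, na.rm = TRUE))
    stop_field("nose_object_s", "exceeds the 300 s novel-object phase")
  class(etho) <- c("ethogram_table", "data.frame")
  invisible(etho)
}

#' Day/night period of an hourly scan
#'
#' Maps an hour of day to the trial's two periods: daytime is 08h00-19h00
#' inclusive, nighttime is 20h00-07h00. Each 24-h day therefore contributes
#' exactly 12 DAY and 12 NIGHT scans.
#'
#' @param hour Integer vector, hours in 0..23.
#' @return Character vector of `"DAY"` / `"NIGHT"`.
#' @examples
#' derive_period(c(7, 8, 19, 20))  # NIGHT DAY DAY NIGHT
#' @export
derive_period <- function(hour) {
  if (any(is.na(hour)) || any(hour < 0 | hour > 23 | hour != floor(hour)))
    stop("`hour` must be integers in 0..23", call. = FALSE)
  ifelse(hour >= 8 & hour <= 19, "DAY", "NIGHT")
}

#' Time budgets over analysis windows
#'
#' Computes, per animal and window, the number of observed (non-missing)
#' scans, the number of scans out of the crate, and the proportion out.
#' Missing scans never enter the denominator. Windows with no observed scan
#' are kept with `prop_out = NA` and flagged, not dropped.
#'
#' @param scans A `scan_table` (see [validate_scans()]).
#' @param by Window specification: `"full"` (whole trial), `"per_day"`
#'   (one window per experimental day) or `"per_period"` (one window per
#'   day x day/night period).
#' @return A data frame with columns `gilt_id`, `window_id`, `n_obs`,
#'   `n_out`, `prop_out`, `empty`.
#' @export
time_budget <- function(scans, by = c("full", "per_day", "per_period")) {
  by <- match.arg(by)
  scans <- validate_scans(scans, n_days = max(scans$day))
  window_id <- switch(by,
    full = rep("FULL", nrow(scans)),
    per_day = sprintf("day%d", scans$day),
    per_period = sprintf("day%d_%s", scans$day, derive_period(scans$hour))
  )
  f <- interaction(scans$gilt_id, window_id, sep = "\r", drop = FALSE)
  observed <- !is.na(scans$location)
  n_obs <- tapply(observed, f, sum)
  n_out <- tapply(!is.na(scans$location) & scans$location == "OUT", f, sum)
  keys <- do.call(rbind, strsplit(names(n_obs), "\r", fixed = TRUE))
  keep <- !is.na(n_obs)
  out <- data.frame(
    gilt_id = keys[keep, 1L],
    window_id = keys[keep, 2L],
    n_obs = as.integer(n_obs[keep]),
    n_out = as.integer(n_out[keep]),
    stringsAsFactors = FALSE
  )
  out$prop_out <- ifelse(out$n_obs > 0L, out$n_out / out$n_obs, NA_real_)
  out$empty <- out$n_obs == 0L
  out[order(out$gilt_id, out$window_id), , drop = FALSE]
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement between two raters coding the same scans:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with expected agreement `p_e` from the
#' product of the raters' marginal label frequencies. Used as the
#' inter-observer reliability check for video coding.
#'
#' @param labels_a,labels_b Equal-length label vectors from the two raters.
#' @return Kappa in `[-1, 1]`. If both raters use a single identical
#'   category throughout (`p_e = 1`), agreement is perfect but chance
#'   correction is undefined; 1 is returned with a warning.
#' @examples
#' cohen_kappa(c("IN", "OUT", "IN"), c("IN", "OUT", "OUT"))
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label sequences differ in length", call. = FALSE)
  if (length(labels_a) < 1L) stop("need at least one pair of labels", call. = FALSE)
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    warning("both raters used a single category; kappa undefined, returning 1")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Compare location distributions across sampling rates
#'
#' Pearson chi-square test that the distribution of coded locations is the
#' same when animals are scanned at a fine rate (e.g. every 15 min) versus
#' the working rate (every 60 min). A non-significant result supports the
#' coarser sampling frequency. The test is on the 2-way location x rate
#' contingency table of non-missing scans; the degrees of freedom of that
#' table are reported as computed.
#'
#' @param scans_fine,scans_coarse Scan tables (or any data frames with a
#'   `location` column) at the two sampling rates.
#' @return A list of class `qc_result` with `chi2_stat`, `chi2_df`, `chi2_p`
#'   and the underlying contingency `table`.
#' @export
sampling_rate_check <- function(scans_fine, scans_coarse) {
  loc_f <- scans_fine$location[!is.na(scans_fine$location)]
  loc_c <- scans_coarse$location[!is.na(scans_coarse$location)]
  if (!length(loc_f) || !length(loc_c))
    stop("both tables must contain observed locations", call. = FALSE)
  lev <- sort(unique(c(loc_f, loc_c)))
  tab <- rbind(fine = table(factor(loc_f, levels = lev)),
               coarse = table(factor(loc_c, levels = lev)))
  empty <- colSums(tab) == 0
  if (any(empty)) {
    warning("dropping empty location category from tabulation; df adjusted")
    tab <- tab[, !empty, drop = FALSE]
  }
  if (ncol(tab) < 2L) {
    # single location category observed: distributions trivially identical
    res <- list(chi2_stat = 0, chi2_df = 0L, chi2_p = 1, table = tab)
    class(res) <- "qc_result"
    return(res)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- list(chi2_stat = unname(ct$statistic), chi2_df = unname(ct$parameter),
              chi2_p = unname(ct$p.value), table = tab)
  class(res) <- "qc_result"
  res
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("Sampling-rate check: X^2 = %.3f, df = %d, P = %.3g\n",
              x$chi2_stat, x$chi2_df, x$chi2_p))
  invisible(x)
}
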