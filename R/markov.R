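#' Fit a two-state location transition matrix
#'
#' Counts IN/OUT transitions between consecutively observed hourly scans of
#' one animal and returns the row-wise posterior-mean transition matrix
#' under a symmetric Dirichlet prior: each row's probabilities are
#' `(count + alpha) / (row total + 2 * alpha)`. Missing scans break the
#' chain: a transition is counted only when both the scan and its successor
#' were observed. `alpha = 0` gives the maximum-likelihood estimate; the
#' default `alpha = 1` (uniform prior per row) keeps probabilities off the
#' boundary for animals observed in a single location throughout, so that
#' their occupancy can still be simulated with sampling variability.
#'
#' @param seq Character vector of `"IN"`/`"OUT"` with `NA` for missing
#'   scans, in chronological order.
#' @param alpha Pseudo-count of the symmetric Dirichlet row prior, >= 0.
#' @return An object of class `transition_matrix`: list with `p` (2x2
#'   row-stochastic matrix, states IN/OUT), `counts` (observed transition
#'   counts) and `alpha`. A row whose state was never observed as a
#'   transition origin is `NA` under `alpha = 0` and uniform under
#'   `alpha > 0`.
#' @examples
#' fit_transition(c("OUT", "OUT", "IN", "IN", "OUT"), alpha = 0)
#' @export
fit_transition <- function(seq, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop_field("alpha", "must be a single number >= 0")
  seq <- as.character(seq)
  if (length(seq) < 2L)
    stop("sequence must have length >= 2", call. = FALSE)
  if (!all(seq[!is.na(seq)] %in% LOCATION_LEVELS))
    stop("sequence states must be IN/OUT (NA for missing)", call. = FALSE)
  from <- seq[-length(seq)]
  to <- seq[-1L]
  ok <- !is.na(from) & !is.na(to)
  if (!any(ok))
    stop("no observable transition in sequence; flag this window as NA",
         call. = FALSE)
  counts <- table(factor(from[ok], levels = LOCATION_LEVELS),
                  factor(to[ok], levels = LOCATION_LEVELS))
  counts <- matrix(as.integer(counts), 2L, 2L,
                   dimnames = list(from = LOCATION_LEVELS, to = LOCATION_LEVELS))
  totals <- rowSums(counts)
  p <- (counts + alpha) / (totals + 2 * alpha)
  p[totals == 0L & alpha == 0, ] <- NA_real_
  structure(list(p = p, counts = counts, alpha = alpha),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Two-state transition matrix (alpha = %g):\n", x$alpha))
  print(round(x$p, 4))
  invisible(x)
}

#' Stationary probability of being out of the crate
#'
#' Long-run occupancy of the OUT state of a two-state chain:
#' `pi_out = p(IN->OUT) / (p(IN->OUT) + p(OUT->IN))`. An absorbing state
#' gives 0 or 1; a chain with both off-diagonal probabilities zero (no
#' mixing) has no unique stationary distribution and returns `NA` with a
#' warning.
#'
#' @param tm A `transition_matrix` from [fit_transition()], or a 2x2
#'   row-stochastic matrix with IN/OUT rows.
#' @return Probability of OUT, or `NA`.
#' @export
stationary_distribution <- function(tm) {
  p <- if (inherits(tm, "transition_matrix")) tm$p else tm
  p_in_out <- p["IN", "OUT"]
  p_out_in <- p["OUT", "IN"]
  if (is.na(p_out_in) && !is.na(p_in_out) && p_in_out > 0) return(1)  # never seen in OUT, driven there
  if (is.na(p_in_out)) {
    if (!is.na(p_out_in) && p_out_in == 0) return(1)  # OUT absorbing, IN never visited
    warning("IN row unobserved and reachable; stationary distribution undefined")
    return(NA_real_)
  }
  if (p_in_out == 0 && p_out_in == 0) {
    warning("reducible chain (no transitions between states); stationary distribution undefined")
    return(NA_real_)
  }
  p_in_out / (p_in_out + p_out_in)
}

#' Simulate occupancy proportions from a fitted chain
#'
#' Draws `n_sims` binary location sequences of the window's scheduled
#' length from a transition matrix and returns the proportion of scans
#' spent OUT in each sequence. This Monte-Carlo sample of time-budget
#' proportions is the basis of the per-animal confidence intervals.
#'
#' @param tm A `transition_matrix`.
#' @param length Sequence length in scans (the trial uses 168, 24 or 12).
#' @param n_sims Number of simulated sequences (the trial uses 10,000).
#' @param init Initial state: `"stationary"` (draw from the chain's
#'   stationary distribution), `"IN"`, `"OUT"`, or a numeric probability of
#'   starting OUT.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Numeric vector of `n_sims` proportions in `[0, 1]`.
#' @export
simulate_occupancy <- function(tm, length, n_sims = 10000L, init = "stationary",
                               seed = NULL) {
  stopifnot(inherits(tm, "transition_matrix"))
  length <- check_count(length, "length")
  n_sims <- check_count(n_sims, "n_sims")
  if (!is.null(seed)) set.seed(seed)
  p_init_out <- if (is.numeric(init)) {
    if (init < 0 || init > 1) stop_field("init", "probability must be in [0, 1]")
    init
  } else switch(match.arg(init, c("stationary", "IN", "OUT")),
    stationary = {
      s <- stationary_distribution(tm)
      if (is.na(s))
        stop("stationary initial state undefined for this chain; ",
             "supply an explicit `init` (e.g. the first observed state)",
             call. = FALSE)
      s
    },
    IN = 0, OUT = 1)
  p_out_out <- tm$p["OUT", "OUT"]
  p_in_out <- tm$p["IN", "OUT"]
  in_reachable <- p_init_out < 1 || (!is.na(p_out_out) && p_out_out < 1)
  if (in_reachable && is.na(p_in_out))
    stop("IN row of the transition matrix is NA but reachable; refit with alpha > 0",
         call. = FALSE)
  if (is.na(p_out_out) && p_init_out > 0)
    stop("OUT row of the transition matrix is NA but reachable; refit with alpha > 0",
         call. = FALSE)

  # unreachable NA rows were ruled out above; zero them for the arithmetic
  if (is.na(p_in_out)) p_in_out <- 0
  if (is.na(p_out_out)) p_out_out <- 0
  cur <- as.integer(stats::runif(n_sims) < p_init_out)
  n_out <- cur
  slope <- p_out_out - p_in_out
  if (length > 1L) for (t in 2:length) {
    cur <- as.integer(stats::runif(n_sims) < p_in_out + slope * cur)
    n_out <- n_out + cur
  }
  n_out / length
}

#' Preference test for one animal-window
#'
#' The core inference of the package: fit the animal's two-state location
#' chain over a window, simulate `n_sims` sequences of the window's
#' scheduled length, take the central `level` percentile interval of the
#' simulated proportions of time out of the crate, and compare it with the
#' area-proportional null occupancy. The animal is classified as preferring
#' the open pen (`PEN`) when the whole interval lies above the null, the
#' crate (`CRATE`) when it lies below, and `NONE` otherwise. A t-style
#' statistic `(sim_mean - null_prop) / sim_sd` is reported for audit; the
#' percentile rule is the classification authority. Windows with no
#' observed scans, or with no observable transition, are classified `NA`.
#'
#' @param seq Character `"IN"`/`"OUT"`/`NA` sequence covering the window's
#'   scheduled scans in chronological order.
#' @param alpha Dirichlet pseudo-count for [fit_transition()].
#' @param n_sims Number of simulated sequences.
#' @param null_prop Null occupancy of the open area (see
#'   [null_space_fraction()]).
#' @param level Confidence level of the percentile interval.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param gilt_id,window_id Identifiers carried into the result row.
#' @return One-row data frame: `gilt_id`, `window_id`, `n_obs`,
#'   `prop_out_observed`, `sim_mean`, `sim_sd`, `ci_low`, `ci_high`,
#'   `null_prop`, `t_stat`, `classification`.
#' @export
preference_test <- function(seq, alpha = 1, n_sims = 10000L, null_prop,
                            level = 0.95, seed = NULL,
                            gilt_id = NA_character_, window_id = NA_character_) {
  null_prop <- check_prob_open(null_prop, "null_prop")
  if (level <= 0 || level >= 1) stop_field("level", "must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  seq <- as.character(seq)
  n_obs <- sum(!is.na(seq))
  base <- data.frame(
    gilt_id = gilt_id, window_id = window_id, n_obs = n_obs,
    prop_out_observed = NA_real_, sim_mean = NA_real_, sim_sd = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, null_prop = null_prop,
    t_stat = NA_real_, classification = NA_character_,
    stringsAsFactors = FALSE
  )
  if (n_obs == 0L) return(base)
  base$prop_out_observed <- mean(seq[!is.na(seq)] == "OUT")
  tm <- tryCatch(fit_transition(seq, alpha = alpha), error = function(e) NULL)
  if (is.null(tm)) return(base)  # no observable transition: flagged NA
  first_obs <- seq[which(!is.na(seq))[1L]]
  # under alpha = 0 a state that was entered but never left observed has an
  # undefined (NA) row; simulation from such a chain is impossible, so the
  # window is flagged NA rather than silently regularized
  sims <- tryCatch(
    simulate_occupancy(tm, length = length(seq), n_sims = n_sims,
                       init = first_obs),
    error = function(e) NULL)
  if (is.null(sims)) return(base)
  qs <- stats::quantile(sims, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  base$sim_mean <- mean(sims)
  base$sim_sd <- stats::sd(sims)
  base$ci_low <- qs[1L]
  base$ci_high <- qs[2L]
  base$t_stat <- if (base$sim_sd > 0) (base$sim_mean - null_prop) / base$sim_sd else
    sign(base$sim_mean - null_prop) * Inf
  base$classification <- if (qs[1L] > null_prop) "PEN" else
    if (qs[2L] < null_prop) "CRATE" else "NONE"
  base
}

#' Preference tests over all animals and windows
#'
#' Applies [preference_test()] to every animal over the requested window
#' types: `"full"` (the whole trial, 168 scans at the default design),
#' `"per_day"` (each experimental day, 24 scans) and `"per_period"` (each
#' day x day/night period, 12 scans). Windows are calendar-aligned; the 12
#' night scans of a day (00h-07h and 20h-23h) are coded as one 12-element
#' sequence, as are the 12 day scans.
#'
#' @param scans A `scan_table`.
#' @param windows Character subset of `c("full", "per_day", "per_period")`.
#' @param alpha,n_sims,level As in [preference_test()].
#' @param null_prop Null occupancy; defaults to the trial geometry's
#'   open-space fraction (0.71).
#' @param seed Seed for the whole batch (one stream, windows processed in a
#'   fixed order, so results are reproducible).
#' @return Data frame of class `preference_results`, one row per animal x
#'   window, with a `window_type` column in addition to the columns of
#'   [preference_test()].
#' @export
analyze_preferences <- function(scans,
                                windows = c("full", "per_day", "per_period"),
                                alpha = 1, n_sims = 10000L,
                                null_prop = NULL, level = 0.95, seed = NULL) {
  windows <- match.arg(windows, several.ok = TRUE)
  scans <- validate_scans(scans, n_days = max(scans$day))
  null_prop <- null_prop %||% null_space_fraction(pen_geometry())
  if (!is.null(seed)) set.seed(seed)
  scans <- scans[order(scans$gilt_id, scans$day, scans$hour), , drop = FALSE]
  gilts <- unique(scans$gilt_id)
  period <- derive_period(scans$hour)

  rows <- list()
  for (g in gilts) {
    gi <- scans$gilt_id == g
    for (w in windows) {
      idx_sets <- switch(w,
        full = list(FULL = which(gi)),
        per_day = {
          days <- sort(unique(scans$day[gi]))
          stats::setNames(lapply(days, function(d) which(gi & scans$day == d)),
                          sprintf("day%d", days))
        },
        per_period = {
          days <- sort(unique(scans$day[gi]))
          out <- list()
          for (d in days) for (p in c("DAY", "NIGHT"))
            out[[sprintf("day%d_%s", d, p)]] <-
              which(gi & scans$day == d & period == p)
          out
        })
      for (wid in names(idx_sets)) {
        res <- preference_test(scans$location[idx_sets[[wid]]], alpha = alpha,
                               n_sims = n_sims, null_prop = null_prop,
                               level = level, gilt_id = g, window_id = wid)
        res$window_type <- toupper(w)
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("preference_results", "data.frame")
  out
}

#' Summarise preference classifications
#'
#' Tabulates PEN / CRATE / NONE (and unclassifiable NA) calls per window
#' type, and counts the per-day windows an animal spent entirely out of, or
#' entirely in, the crate.
#'
#' @param results A `preference_results` data frame from
#'   [analyze_preferences()].
#' @return List with `counts` (window_type x classification counts),
#'   `all_out_gilt_days` and `all_in_gilt_days` (counts over observed
#'   per-day windows).
#' @export
summarize_preferences <- function(results) {
  if (!nrow(results)) stop("empty results table", call. = FALSE)
  cls <- factor(ifelse(is.na(results$classification), "NA", results$classification),
                levels = c("PEN", "NONE", "CRATE", "NA"))
  counts <- as.data.frame(table(window_type = results$window_type,
                                classification = cls),
                          stringsAsFactors = FALSE)
  names(counts)[3L] <- "n"
  per_day <- results[results$window_type == "PER_DAY" & results$n_obs > 0, ]
  list(
    counts = counts[order(counts$window_type, counts$classification), ],
    all_out_gilt_days = sum(per_day$prop_out_observed == 1, na.rm = TRUE),
    all_in_gilt_days = sum(per_day$prop_out_observed == 0, na.rm = TRUE)
  )
}
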