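#' Configuration of the synthetic trial generator
#'
#' Defines the design and the data-generating process for a synthetic
#' free-access preference trial: trios of gilts scanned hourly over several
#' days, with day/night and day-number effects on occupancy, per-animal
#' heterogeneity, an effect of a latent engagement trait, and completely
#' random scan loss.
#'
#' Occupancy follows a two-state (IN/OUT) Markov chain per animal. The
#' baseline transition probabilities `baseline_stay_out` = p(OUT->OUT) and
#' `baseline_return_out` = p(IN->OUT) describe a daytime, day-1, average
#' animal; they fix the chain's persistence
#' `m = p(IN->OUT) + p(OUT->IN)`, which is held constant, and its
#' stationary occupancy `pi0 = p(IN->OUT) / m`. Covariate effects
#' (`night_logodds_shift`, `day_trend_logodds`, the per-animal intercept
#' with SD `gilt_sd`, and `engagement_effect` per unit of the latent
#' engagement score) act additively on the log-odds of the stationary
#' occupancy, so the hourly occupancy model that the analysis fits is
#' exactly the model that generated the data; the chain at scan t moves by
#' `p(OUT_t | previous) = (1 - m) * [previous == OUT] + m * pi_t`.
#'
#' Defaults emulate the trial the package was built around: 10 trios of 3
#' gilts, 7 days x 24 hourly scans, 2.4% of scans lost, a night odds ratio
#' of 0.49, a per-day odds ratio of 0.70, an engagement odds ratio of 0.39,
#' and a baseline (daytime, day 1, average animal) open-area occupancy of
#' 0.99 — which, combined with those effects, puts the median animal's
#' whole-week occupancy near 95% and, with `gilt_sd = 1.5`, spreads
#' animals over roughly 45-100%.
#'
#' @param n_trios Number of trios (default 10).
#' @param gilts_per_trio Animals per trio (default 3).
#' @param n_days Experimental days (default 7).
#' @param scans_per_day Hourly scans per day, at hours `0..scans_per_day-1`
#'   (default 24).
#' @param missing_rate Fraction of scheduled scans lost completely at
#'   random (default 0.024).
#' @param baseline_stay_out p(OUT->OUT) for a daytime day-1 average animal
#'   (default 0.995).
#' @param baseline_return_out p(IN->OUT) for the same animal (default
#'   0.495).
#'   Must not exceed `baseline_stay_out` (persistence must be <= 1).
#' @param night_logodds_shift Additive shift of the occupancy log-odds at
#'   night (default `log(0.49)`).
#' @param day_trend_logodds Additive shift per experimental day beyond the
#'   first (default `log(0.70)`).
#' @param gilt_sd SD of the per-animal normal random intercept on the
#'   occupancy log-odds (default 1.5).
#' @param engagement_effect Shift of the occupancy log-odds per unit latent
#'   engagement (default `log(0.39)`).
#' @param ethogram_noise Multiplier on the residual SDs of the generated
#'   open-field/novel-object behaviours (default 1; 0 gives noiseless
#'   behaviours that are exact functions of the two latent traits).
#' @param seed Master seed; every stage of the generator derives its own
#'   substream from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_trios = 10L, gilts_per_trio = 3L,
                              n_days = 7L, scans_per_day = 24L,
                              missing_rate = 0.024,
                              baseline_stay_out = 0.995,
                              baseline_return_out = 0.495,
                              night_logodds_shift = log(0.49),
                              day_trend_logodds = log(0.70),
                              gilt_sd = 1.5,
                              engagement_effect = log(0.39),
                              ethogram_noise = 1,
                              seed = 1L) {
  cfg <- list(
    n_trios = check_count(n_trios, "n_trios"),
    gilts_per_trio = check_count(gilts_per_trio, "gilts_per_trio"),
    n_days = check_count(n_days, "n_days"),
    scans_per_day = check_count(scans_per_day, "scans_per_day"),
    missing_rate = missing_rate,
    baseline_stay_out = check_prob_open(baseline_stay_out, "baseline_stay_out"),
    baseline_return_out = check_prob_open(baseline_return_out, "baseline_return_out"),
    night_logodds_shift = check_number(night_logodds_shift, "night_logodds_shift"),
    day_trend_logodds = check_number(day_trend_logodds, "day_trend_logodds"),
    gilt_sd = check_number(gilt_sd, "gilt_sd"),
    engagement_effect = check_number(engagement_effect, "engagement_effect"),
    ethogram_noise = check_number(ethogram_noise, "ethogram_noise"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(missing_rate) || length(missing_rate) != 1L ||
      is.na(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop_field("missing_rate", "must be in [0, 1)")
  if (cfg$scans_per_day > 24L)
    stop_field("scans_per_day", "at most 24 hourly scans fit in a day")
  if (cfg$baseline_return_out > cfg$baseline_stay_out)
    stop_field("baseline_return_out",
               "must not exceed baseline_stay_out (chain persistence would exceed 1)")
  if (cfg$gilt_sd < 0) stop_field("gilt_sd", "must be >= 0")
  if (cfg$ethogram_noise < 0) stop_field("ethogram_noise", "must be >= 0")
  # persistence and baseline stationary occupancy of the open area
  cfg$persistence <- cfg$baseline_return_out + (1 - cfg$baseline_stay_out)
  cfg$baseline_pi <- cfg$baseline_return_out / cfg$persistence
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Synthetic trial: %d trios x %d gilts, %d days x %d scans (seed %d)\n",
              x$n_trios, x$gilts_per_trio, x$n_days, x$scans_per_day, x$seed))
  cat(sprintf("  baseline occupancy pi0 = %.3f, persistence m = %.3f, missing %.1f%%\n",
              x$baseline_pi, x$persistence, 100 * x$missing_rate))
  invisible(x)
}

# Stage-specific substream seeds derived from the master seed, kept within
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 1013L * stage) %% 2147483647)
}

gilt_ids_for <- function(cfg) {
  trios <- sprintf("T%02d", seq_len(cfg$n_trios))
  list(
    trios = trios,
    gilts = as.vector(vapply(trios, function(tr)
      paste0(tr, "_G", seq_len(cfg$gilts_per_trio)), character(cfg$gilts_per_trio)))
  )
}

#' Latent personality traits of the simulated animals
#'
#' Draws one standard-normal `passivity` and `engagement` score per animal.
#' These latent traits drive both the occupancy generator (through
#' `engagement_effect`) and the ethogram generator, standing in for the two
#' component scores the personality analysis recovers.
#'
#' @param config A [simulation_config()].
#' @return Data frame with `gilt_id`, `passivity`, `engagement`; one row per
#'   simulated animal.
#' @export
latent_traits <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- gilt_ids_for(config)
  n <- length(ids$gilts)
  set.seed(stage_seed(config$seed, 0L))
  data.frame(
    gilt_id = ids$gilts,
    passivity = stats::rnorm(n),
    engagement = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic scan table
#'
#' Simulates each animal's hourly location over the trial as a two-state
#' Markov chain whose stationary occupancy log-odds are
#' `qlogis(pi0) + night_shift * [night] + trend * (day - 1) + b_gilt +
#' engagement_effect * engagement`, with constant persistence (see
#' [simulation_config()]). Within a regime block (a run of scans sharing
#' the same period and day covariates) the chain steps with its
#' persistence; at each regime boundary — and at the first scan — the state
#' is drawn afresh from the new regime's stationary occupancy, so every
#' scan's marginal probability of OUT is exactly the logistic model above
#' and the process is exactly Markov within each regime. Exactly
#' `floor(missing_rate * N)` scans, chosen uniformly at random, are then
#' blanked to missing. Deterministic given `config` (and `traits`).
#'
#' @param config A [simulation_config()].
#' @param traits Optional data frame from [latent_traits()]; drawn from the
#'   config's seed when omitted. Must cover every simulated animal.
#' @return A validated `scan_table` with one row per animal x scheduled scan.
#' @export
generate_occupancy <- function(config, traits = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- gilt_ids_for(config)
  traits <- traits %||% latent_traits(config)
  if (!all(ids$gilts %in% traits$gilt_id))
    stop("`traits` does not cover all simulated gilts", call. = FALSE)
  traits <- traits[match(ids$gilts, traits$gilt_id), , drop = FALSE]
  n_gilts <- length(ids$gilts)
  n_scans <- config$n_days * config$scans_per_day
  day <- rep(seq_len(config$n_days), each = config$scans_per_day)
  hour <- rep(seq_len(config$scans_per_day) - 1L, times = config$n_days)
  night <- derive_period(hour) == "NIGHT"

  set.seed(stage_seed(config$seed, 1L))
  b_gilt <- stats::rnorm(n_gilts, sd = config$gilt_sd)
  base_logit <- qlogis_(config$baseline_pi)
  # gilts x scans matrix of stationary occupancy probabilities
  eta <- outer(b_gilt + config$engagement_effect * traits$engagement,
               config$night_logodds_shift * night +
                 config$day_trend_logodds * (day - 1L), `+`) + base_logit
  pi_mat <- plogis_(eta)
  m <- config$persistence

  regime <- paste(day, night)
  new_block <- c(TRUE, regime[-1L] != regime[-n_scans])
  states <- matrix(0L, nrow = n_gilts, ncol = n_scans)  # 1 = OUT
  states[, 1L] <- as.integer(stats::runif(n_gilts) < pi_mat[, 1L])
  for (t in seq_len(n_scans)[-1L]) {
    p_out <- if (new_block[t]) pi_mat[, t] else
      (1 - m) * states[, t - 1L] + m * pi_mat[, t]
    states[, t] <- as.integer(stats::runif(n_gilts) < p_out)
  }

  scans <- data.frame(
    trio_id = rep(substr(ids$gilts, 1L, 3L), each = n_scans),
    gilt_id = rep(ids$gilts, each = n_scans),
    day = rep(day, times = n_gilts),
    hour = rep(hour, times = n_gilts),
    location = ifelse(as.vector(t(states)) == 1L, "OUT", "IN"),
    stringsAsFactors = FALSE
  )
  # season blocks (~40% of trios in summer, as in the trial) and pen side
  trio_idx <- match(scans$trio_id, ids$trios)
  n_summer <- max(1L, round(0.4 * config$n_trios))
  scans$season <- ifelse(trio_idx <= n_summer, "SUMMER", "WINTER")
  scans$side <- ifelse(trio_idx %% 2L == 1L, "LEFT", "RIGHT")

  n_total <- nrow(scans)
  n_missing <- floor(config$missing_rate * n_total)
  if (n_missing > 0L)
    scans$location[sample.int(n_total, n_missing)] <- NA_character_
  validate_scans(scans[SCAN_COLUMNS], n_days = config$n_days)
}

# behaviour means and latent loadings of the ethogram generator:
# value = mean + b_passivity * P + b_engagement * E + N(0, sd * ethogram_noise),
# clamped to [0, max]. Signs follow the field's usual loading pattern:
# passive animals approach late, nose the floor long, cross few lines and
# nose walls little; engaged animals nose the object long and lie little.
ETHOGRAM_MODEL <- data.frame(
  behaviour = ETHOGRAM_BEHAVIOURS,
  mean = c(40, 100, 250, 120, 100, 120),
  b_passivity = c(-10, -30, 70, 0, 55, 0),
  b_engagement = c(0, 0, 0, -45, 0, 45),
  sd = c(6, 18, 40, 30, 25, 25),
  max = c(Inf, 600, 600, 600, 300, 300),
  stringsAsFactors = FALSE
)

#' Generate a synthetic ethogram table
#'
#' Draws the six open-field/novel-object behaviours per animal as linear
#' functions of the latent passivity and engagement traits plus Gaussian
#' noise, clamped to their natural ranges (10-min durations in `[0, 600]` s,
#' novel-object durations and latency in `[0, 300]` s, line crossings a
#' nonnegative count). Exactly one animal — the one with the largest
#' underlying latency — is recorded as never approaching the object and gets
#' a missing latency, mirroring a non-approaching animal in a real test.
#'
#' @inheritParams generate_occupancy
#' @return A validated `ethogram_table`, one row per animal.
#' @export
generate_ethogram <- function(config, traits = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  traits <- traits %||% latent_traits(config)
  n <- nrow(traits)
  set.seed(stage_seed(config$seed, 3L))
  etho <- data.frame(gilt_id = traits$gilt_id, stringsAsFactors = FALSE)
  raw_latency <- NULL
  for (i in seq_len(nrow(ETHOGRAM_MODEL))) {
    mm <- ETHOGRAM_MODEL[i, ]
    raw <- mm$mean + mm$b_passivity * traits$passivity +
      mm$b_engagement * traits$engagement +
      stats::rnorm(n, sd = mm$sd * config$ethogram_noise)
    if (mm$behaviour == "latency_contact_s") raw_latency <- raw
    val <- pmin(pmax(raw, 0), mm$max)
    etho[[mm$behaviour]] <- if (mm$behaviour == "lines_crossed")
      as.integer(round(val)) else round(val, 1)
  }
  if (n >= 1L)
    etho$latency_contact_s[which.max(raw_latency)] <- NA_real_
  validate_ethogram(etho)
}

#' Write synthetic fixtures to CSV
#'
#' Writes `scans.csv` and `ethogram.csv` in the documented schemas (missing
#' values as empty fields) so that [load_scans()] / [load_ethogram()]
#' round-trip the tables exactly.
#'
#' @param scans A `scan_table`.
#' @param etho An `ethogram_table`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(scans, etho, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir, call. = FALSE)
  paths <- c(scans = file.path(dir, "scans.csv"),
             ethogram = file.path(dir, "ethogram.csv"))
  utils::write.csv(as.data.frame(scans), paths[["scans"]], row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(etho), paths[["ethogram"]], row.names = FALSE, na = "")
  invisible(paths)
}
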