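#' Mixed-effects logistic model of hourly occupancy
#'
#' Fits the trial's occupancy model: the probability that an animal is out
#' of the crate at a scan, as a function of period of day (night vs day,
#' reference DAY), experimental day (numeric, 1..7, so the printed odds
#' ratio is "per day"), pen side (reference LEFT), season (reference
#' SUMMER) and, when trait scores are supplied, the Passivity and
#' Engagement component scores — with random intercepts for animal nested
#' within trio. Fitting uses the Laplace approximation
#' ([lme4::glmer()]); odds ratios with Wald 95% confidence intervals and
#' Wald p-values are reported per fixed effect. Missing scans are dropped.
#'
#' @param scans A `scan_table`.
#' @param traits Optional trait-score data frame (`gilt_id`, `passivity`,
#'   `engagement`), e.g. `score_traits(...)$scores`; omit for the
#'   design-only model.
#' @param conf_level Confidence level of the Wald intervals (default 0.95).
#' @return Object of class `glmm_result`: `terms` (data frame with
#'   `estimate`, `se`, `z`, `p_value`, `odds_ratio`, `ci_low`, `ci_high`
#'   per fixed effect), `varcor` (random-intercept variances), `n_obs`,
#'   `converged`, `singular` (a variance component estimated at exactly
#'   zero — a legitimate boundary fit, flagged for inspection), `messages`,
#'   and the underlying `fit`.
#' @export
fit_occupancy_glmm <- function(scans, traits = NULL, conf_level = 0.95) {
  scans <- validate_scans(scans, n_days = max(scans$day))
  dat <- as.data.frame(scans)
  dat <- dat[!is.na(dat$location), , drop = FALSE]
  dat$out <- as.integer(dat$location == "OUT")
  dat$period <- factor(derive_period(dat$hour), levels = c("DAY", "NIGHT"))
  dat$side <- factor(dat$side, levels = SIDE_LEVELS)
  dat$season <- factor(dat$season, levels = SEASON_LEVELS)
  dat$day_num <- as.numeric(dat$day)

  rhs <- "period + day_num"
  if (nlevels(droplevels(dat$side)) > 1L) rhs <- paste(rhs, "+ side")
  if (nlevels(droplevels(dat$season)) > 1L) rhs <- paste(rhs, "+ season")
  if (!is.null(traits)) {
    need <- c("gilt_id", "passivity", "engagement")
    if (!all(need %in% names(traits)))
      stop("`traits` must have columns gilt_id, passivity, engagement", call. = FALSE)
    dat <- merge(dat, traits[need], by = "gilt_id")
    rhs <- paste(rhs, "+ passivity + engagement")
  }
  form <- stats::as.formula(paste("out ~", rhs, "+ (1 | trio_id / gilt_id)"))

  messages <- character()
  fit <- withCallingHandlers(
    lme4::glmer(form, data = dat, family = stats::binomial(),
                control = lme4::glmerControl(optimizer = "bobyqa")),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  # a boundary (singular) fit — a variance component estimated at exactly
  # zero — is a legitimate optimum, not a convergence failure
  conv_msgs <- unlist(fit@optinfo$conv$lme4)
  singular <- lme4::isSingular(fit)
  conv_msgs <- conv_msgs[!grepl("singular", conv_msgs)]
  converged <- length(conv_msgs) == 0L &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0L)
  co <- summary(fit)$coefficients
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- data.frame(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    z = co[, "z value"],
    p_value = co[, "Pr(>|z|)"],
    odds_ratio = exp(co[, "Estimate"]),
    ci_low = exp(co[, "Estimate"] - zcrit * co[, "Std. Error"]),
    ci_high = exp(co[, "Estimate"] + zcrit * co[, "Std. Error"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  vc <- lme4::VarCorr(fit)
  varcor <- stats::setNames(vapply(vc, function(v) as.numeric(v[1L]), numeric(1L)),
                            names(vc))
  if (!converged)
    warning("occupancy GLMM did not converge cleanly: ",
            paste(unique(conv_msgs), collapse = "; "))
  structure(list(terms = terms, varcor = varcor, n_obs = nrow(dat),
                 converged = converged, singular = singular,
                 messages = unique(messages), fit = fit),
            class = "glmm_result")
}

#' @export
print.glmm_result <- function(x, digits = 2, ...) {
  cat(sprintf("Occupancy GLMM (%d scans, %s%s):\n", x$n_obs,
              if (x$converged) "converged" else "NOT converged",
              if (isTRUE(x$singular)) ", singular variance component" else ""))
  t <- x$terms
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-12s OR = %.2f [%.2f, %.2f], P = %.3g\n",
                t$term[i], t$odds_ratio[i], t$ci_low[i], t$ci_high[i],
                t$p_value[i]))
  cat("  random-intercept variances:",
      paste(sprintf("%s = %.3f", names(x$varcor), x$varcor), collapse = ", "), "\n")
  invisible(x)
}

#' Proportional-odds model of preference class on trait scores
#'
#' Ordinal logistic regression of the three-level preference
#' classification (ordered `CRATE < NONE < PEN`, so positive coefficients
#' mean more preference for the open pen) on the Passivity and Engagement
#' scores, for the animal-windows of a single window. Uses the
#' proportional-odds fit of [MASS::polr()]; Wald z and p-values are
#' reported per covariate.
#'
#' @param pref A `preference_results` data frame restricted to one window
#'   (e.g. one day x period), one row per animal.
#' @param traits Trait-score data frame (`gilt_id`, `passivity`,
#'   `engagement`).
#' @return Object of class `ordinal_result`: `coefficients` (data frame
#'   with `estimate`, `se`, `z`, `p_value` per covariate), `thresholds`
#'   (the two cut points), `levels`, `n`, `converged`, and the `fit`.
#' @export
fit_preference_ordinal <- function(pref, traits) {
  if (any(duplicated(pref$gilt_id)))
    stop("`pref` must contain a single window (one row per animal); ",
         "subset a preference_results table first", call. = FALSE)
  need <- c("gilt_id", "passivity", "engagement")
  if (!all(need %in% names(traits)))
    stop("`traits` must have columns gilt_id, passivity, engagement", call. = FALSE)
  dat <- merge(pref[c("gilt_id", "classification")], traits[need], by = "gilt_id")
  dat <- dat[!is.na(dat$classification), , drop = FALSE]
  lev <- c("CRATE", "NONE", "PEN")
  present <- lev %in% dat$classification
  if (!all(present))
    stop("outcome level(s) absent: ", paste(lev[!present], collapse = ", "),
         "; consider collapsing levels or choosing another window", call. = FALSE)
  dat$pref <- factor(dat$classification, levels = lev, ordered = TRUE)

  messages <- character()
  fit <- withCallingHandlers(
    MASS::polr(pref ~ passivity + engagement, data = dat, Hess = TRUE),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  cf <- co[names(fit$coefficients), , drop = FALSE]
  se <- cf[, "Std. Error"]
  converged <- fit$convergence == 0L && all(is.finite(se)) && all(se < 1e3)
  if (!converged)
    warning("proportional-odds fit unreliable (possible separation); ",
            "inspect coefficients and data")
  z <- cf[, "Value"] / se
  coefficients <- data.frame(
    term = rownames(cf), estimate = cf[, "Value"], se = se, z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefficients, thresholds = fit$zeta,
                 levels = lev, n = nrow(dat), converged = converged,
                 messages = unique(messages), fit = fit),
            class = "ordinal_result")
}

#' @export
print.ordinal_result <- function(x, ...) {
  cat(sprintf("Proportional-odds model (%d animals, %s; %s):\n", x$n,
              paste(x$levels, collapse = " < "),
              if (x$converged) "converged" else "NOT converged"))
  t <- x$coefficients
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-12s beta = %+.3f, z = %.2f, P = %.3g\n",
                t$term[i], t$estimate[i], t$z[i], t$p_value[i]))
  invisible(x)
}
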