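#' Pipeline run configuration
#'
#' Bundles everything a full analysis run needs: either paths to observed
#' `scans.csv` / `ethogram.csv` tables or a [simulation_config()] (exactly
#' one of the two), the pen geometry, and the analysis options.
#'
#' @param scans,ethogram Paths to input CSV files (observed-data mode).
#' @param simulate A [simulation_config()] (simulate mode).
#' @param geometry A [pen_geometry()]; its open-space fraction is the
#'   default preference null.
#' @param alpha Dirichlet pseudo-count for transition fitting.
#' @param n_sims Simulated sequences per animal-window.
#' @param level Confidence level of percentile intervals.
#' @param null_prop Optional override of the geometric null occupancy.
#' @param seed Master seed; each pipeline stage uses a derived substream.
#' @param output_dir Directory for all artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scans = NULL, ethogram = NULL, simulate = NULL,
                       geometry = pen_geometry(), alpha = 1,
                       n_sims = 10000L, level = 0.95, null_prop = NULL,
                       seed = 1L, output_dir = tempfile("penchoice_run_")) {
  has_paths <- !is.null(scans) || !is.null(ethogram)
  if (has_paths == !is.null(simulate))
    stop("supply either input paths (`scans`, `ethogram`) or a `simulate` ",
         "config, not both and not neither", call. = FALSE)
  if (has_paths && (is.null(scans) || is.null(ethogram)))
    stop("observed-data mode needs both `scans` and `ethogram` paths", call. = FALSE)
  if (!is.null(simulate)) stopifnot(inherits(simulate, "simulation_config"))
  stopifnot(inherits(geometry, "pen_geometry"))
  structure(list(
    scans = scans, ethogram = ethogram, simulate = simulate,
    geometry = geometry, alpha = alpha,
    n_sims = check_count(n_sims, "n_sims"), level = level,
    null_prop = null_prop %||% null_space_fraction(geometry),
    seed = check_count(seed, "seed", min = 0L), output_dir = output_dir
  ), class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Fitted transition matrices for all animal-windows
#'
#' Convenience tabulation of [fit_transition()] across animals and windows,
#' one row per animal-window with the four transition probabilities and the
#' observed transition counts. Windows without an observable transition get
#' `NA` probabilities.
#'
#' @param scans A `scan_table`.
#' @param windows Window types as in [analyze_preferences()].
#' @param alpha Dirichlet pseudo-count.
#' @return Data frame with `gilt_id`, `window_type`, `window_id`,
#'   `p_in_in`, `p_in_out`, `p_out_in`, `p_out_out` and `n_**` counts.
#' @export
transition_table <- function(scans, windows = c("full", "per_day", "per_period"),
                             alpha = 1) {
  windows <- match.arg(windows, several.ok = TRUE)
  scans <- validate_scans(scans, n_days = max(scans$day))
  scans <- scans[order(scans$gilt_id, scans$day, scans$hour), , drop = FALSE]
  period <- derive_period(scans$hour)
  rows <- list()
  for (g in unique(scans$gilt_id)) {
    gi <- scans$gilt_id == g
    sets <- list()
    if ("full" %in% windows) sets[["FULL.FULL"]] <- which(gi)
    for (d in sort(unique(scans$day[gi]))) {
      if ("per_day" %in% windows)
        sets[[sprintf("PER_DAY.day%d", d)]] <- which(gi & scans$day == d)
      if ("per_period" %in% windows)
        for (p in c("DAY", "NIGHT"))
          sets[[sprintf("PER_PERIOD.day%d_%s", d, p)]] <-
            which(gi & scans$day == d & period == p)
    }
    for (nm in names(sets)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
      tm <- tryCatch(fit_transition(scans$location[sets[[nm]]], alpha = alpha),
                     error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        gilt_id = g, window_type = parts[1L], window_id = parts[2L],
        p_in_in = if (is.null(tm)) NA_real_ else tm$p["IN", "IN"],
        p_in_out = if (is.null(tm)) NA_real_ else tm$p["IN", "OUT"],
        p_out_in = if (is.null(tm)) NA_real_ else tm$p["OUT", "IN"],
        p_out_out = if (is.null(tm)) NA_real_ else tm$p["OUT", "OUT"],
        n_in_in = if (is.null(tm)) NA_integer_ else tm$counts["IN", "IN"],
        n_in_out = if (is.null(tm)) NA_integer_ else tm$counts["IN", "OUT"],
        n_out_in = if (is.null(tm)) NA_integer_ else tm$counts["OUT", "IN"],
        n_out_out = if (is.null(tm)) NA_integer_ else tm$counts["OUT", "OUT"],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load or simulate the input tables, fit
#' per-animal preference tests over all window types, derive personality
#' traits, fit the occupancy GLMM and the proportional-odds preference
#' models — and writes every artifact (CSV tables, a markdown report and a
#' reproducibility manifest) to the configured output directory. Runs are
#' idempotent under a fixed seed: each stage draws from a substream derived
#' from the master seed, so the same configuration always produces the
#' same artifacts.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages (default `FALSE`).
#' @return Invisibly, a list of all in-memory artifacts (`scans`, `etho`,
#'   `budget_full`, `preferences`, `summary`, `transitions`, `pca`,
#'   `traits`, `glmm`, `ordinal`, `config`, paths).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf("[penchoice %5.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), sprintf(...))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  say("stage load/simulate")
  inputs <- with_stage("load/simulate", {
    if (!is.null(config$simulate)) {
      traits_true <- latent_traits(config$simulate)
      scans <- generate_occupancy(config$simulate, traits_true)
      etho <- generate_ethogram(config$simulate, traits_true)
      write_fixtures(scans, etho, config$output_dir)
      list(scans = scans, etho = etho)
    } else {
      list(scans = load_scans(config$scans), etho = load_ethogram(config$ethogram))
    }
  })

  say("stage preference (%d windows x %d sims)", 22L, config$n_sims)
  prefs <- with_stage("preference", {
    set.seed(stage_seed(config$seed, 11L))
    analyze_preferences(inputs$scans, alpha = config$alpha,
                        n_sims = config$n_sims, null_prop = config$null_prop,
                        level = config$level)
  })
  summ <- summarize_preferences(prefs)
  budget_full <- time_budget(inputs$scans, "full")
  transitions <- with_stage("transition matrices",
                            transition_table(inputs$scans, alpha = config$alpha))

  say("stage personality")
  personality <- with_stage("personality", {
    etho_complete <- impute_missing(inputs$etho)
    pca <- run_pca(etho_complete)
    traits <- score_traits(pca)
    list(pca = pca, traits = traits)
  })

  say("stage models")
  glmm <- with_stage("occupancy model",
                     fit_occupancy_glmm(inputs$scans, personality$traits$scores))
  # ordinal stage needs all three outcome levels; record absence honestly
  ordinal <- tryCatch(
    fit_preference_ordinal(prefs[prefs$window_type == "FULL", ],
                           personality$traits$scores),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "ordinal_skipped"))

  say("stage report")
  artifacts <- list(scans = inputs$scans, etho = inputs$etho,
                    budget_full = budget_full, preferences = prefs,
                    summary = summ, transitions = transitions,
                    pca = personality$pca, traits = personality$traits,
                    glmm = glmm, ordinal = ordinal, config = config)
  write_artifact_csvs(artifacts, config$output_dir)
  write_report(artifacts, file.path(config$output_dir, "report.md"))
  write_manifest(config, file.path(config$output_dir, "manifest.json"))
  say("done -> %s", config$output_dir)
  invisible(artifacts)
}

write_artifact_csvs <- function(a, dir) {
  w <- function(x, f) utils::write.csv(as.data.frame(x), file.path(dir, f),
                                       row.names = FALSE, na = "")
  w(a$budget_full, "time_budget_full.csv")
  w(a$transitions, "transition_matrices.csv")
  w(a$preferences, "preference_results.csv")
  w(a$summary$counts, "preference_summary.csv")
  pca_summary <- data.frame(
    component = colnames(a$pca$loadings),
    eigenvalue = a$pca$eigenvalues,
    var_explained = a$pca$var_explained,
    bartlett_stat = a$pca$bartlett_stat, bartlett_df = a$pca$bartlett_df,
    bartlett_p = a$pca$bartlett_p, kmo_msa = a$pca$kmo_msa)
  w(pca_summary, "pca_summary.csv")
  w(cbind(behaviour = rownames(a$pca$loadings),
          as.data.frame(a$pca$loadings)), "loadings.csv")
  w(a$traits$scores, "trait_scores.csv")
  w(a$glmm$terms, "glmm_summary.csv")
  if (inherits(a$ordinal, "ordinal_result")) w(a$ordinal$coefficients,
                                               "ordinal_summary.csv")
  invisible(NULL)
}

json_escape <- function(x) gsub('"', '\\\\"', x)

write_manifest <- function(config, path) {
  cfg_repr <- paste(deparse(config[setdiff(names(config), "output_dir")]),
                    collapse = "")
  tf <- tempfile(); writeLines(cfg_repr, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  lines <- c(
    "{",
    sprintf('  "package": "penchoice %s",',
            as.character(utils::packageVersion("penchoice"))),
    sprintf('  "r_version": "%s",', json_escape(R.version.string)),
    sprintf('  "seed": %d,', config$seed),
    sprintf('  "n_sims": %d,', config$n_sims),
    sprintf('  "alpha": %g,', config$alpha),
    sprintf('  "null_prop": %.10f,', config$null_prop),
    sprintf('  "mode": "%s",', if (is.null(config$simulate)) "observed" else "simulate"),
    sprintf('  "config_md5": "%s"', hash),
    "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write the markdown summary report
#'
#' Renders the pipeline artifacts into a human-readable markdown report:
#' the per-animal time-budget distribution, preference classification
#' counts per window type (zero classes included), the occupancy-model
#' odds-ratio table and the PCA summary. Numbers are rounded only here, at
#' the presentation layer. Regenerating the report from saved artifacts
#' reproduces it exactly.
#'
#' @param artifacts The list returned by [run_pipeline()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(artifacts, path) {
  need <- c("budget_full", "preferences", "summary", "pca", "glmm")
  absent <- need[!need %in% names(artifacts)]
  if (length(absent))
    stop("missing artifact(s): ", paste(absent, collapse = ", "), call. = FALSE)
  a <- artifacts
  b <- a$budget_full
  p <- 100 * b$prop_out[!is.na(b$prop_out)]
  lines <- c(
    "# Free-access housing preference report", "",
    sprintf("Animals: %d; scheduled scans: %d; observed: %d (%.1f%% missing).",
            length(unique(a$scans$gilt_id)), nrow(a$scans),
            sum(!is.na(a$scans$location)),
            100 * mean(is.na(a$scans$location))),
    "",
    "## Time out of the crate (whole trial)", "",
    sprintf("min %.1f%%, median %.1f%%, IQR %.1f, max %.1f%%.",
            min(p), stats::median(p), stats::IQR(p), max(p)),
    "",
    "## Preference classifications", "",
    "| window type | PEN | NONE | CRATE | NA |",
    "|---|---|---|---|---|")
  cts <- a$summary$counts
  for (wt in unique(cts$window_type)) {
    n <- function(cl) cts$n[cts$window_type == wt & cts$classification == cl]
    lines <- c(lines, sprintf("| %s | %d | %d | %d | %d |", wt,
                              n("PEN"), n("NONE"), n("CRATE"), n("NA")))
  }
  lines <- c(lines, "",
    sprintf("Gilt-days entirely out of the crate: %d; entirely in: %d.",
            a$summary$all_out_gilt_days, a$summary$all_in_gilt_days),
    "", "## Occupancy model (odds ratios, Wald 95% CI)", "",
    "| term | OR | 95% CI | P |", "|---|---|---|---|")
  t <- a$glmm$terms
  for (i in seq_len(nrow(t)))
    lines <- c(lines, sprintf("| %s | %.2f | [%.2f, %.2f] | %.3g |",
                              t$term[i], t$odds_ratio[i], t$ci_low[i],
                              t$ci_high[i], t$p_value[i]))
  lines <- c(lines, "", "## Personality components", "",
    sprintf("Eigenvalues: %s; first two explain %.1f%% of variance.",
            paste(sprintf("%.2f", a$pca$eigenvalues), collapse = ", "),
            100 * sum(a$pca$var_explained[1:2])),
    sprintf("Bartlett K^2 = %.1f (df %d, P = %.3g); KMO MSA = %.2f.",
            a$pca$bartlett_stat, a$pca$bartlett_df, a$pca$bartlett_p,
            a$pca$kmo_msa))
  if (inherits(a$ordinal, "ordinal_result")) {
    oc <- a$ordinal$coefficients
    lines <- c(lines, "", "## Preference vs traits (proportional odds)", "")
    for (i in seq_len(nrow(oc)))
      lines <- c(lines, sprintf("- %s: beta = %+.3f, z = %.2f, P = %.3g",
                                oc$term[i], oc$estimate[i], oc$z[i],
                                oc$p_value[i]))
  } else if (!is.null(a$ordinal$error)) {
    lines <- c(lines, "", sprintf("Ordinal stage not fitted: %s", a$ordinal$error))
  }
  writeLines(lines, path)
  invisible(path)
}
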