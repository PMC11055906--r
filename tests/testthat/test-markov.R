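test_that("transition fitting reproduces hand-counted examples", {
  s <- c("OUT", "OUT", "IN", "IN", "OUT")
  tm0 <- fit_transition(s, alpha = 0)
  expect_equal(tm0$p["OUT", "IN"], 0.5)
  expect_equal(tm0$p["IN", "OUT"], 0.5)
  expect_equal(sum(tm0$counts), 4L)

  # conjugate posterior mean: (1 + 1) / (2 + 2)
  tm1 <- fit_transition(s, alpha = 1)
  expect_equal(tm1$p["OUT", "IN"], 0.5)

  # 168 consecutive OUT scans: (0 + 1) / (167 + 2)
  tma <- fit_transition(rep("OUT", 168), alpha = 1)
  expect_equal(tma$p["OUT", "IN"], 1 / 169)
  expect_equal(tma$p["IN", "OUT"], 0.5)  # unobserved row, uniform prior

  # same sequence at alpha = 0: OUT absorbing, IN row undefined
  tmb <- fit_transition(rep("OUT", 168), alpha = 0)
  expect_equal(tmb$p["OUT", "OUT"], 1)
  expect_true(all(is.na(tmb$p["IN", ])))
})

test_that("missing scans break the transition chain instead of bridging it", {
  tm <- fit_transition(c("OUT", "OUT", NA, "IN", "IN"), alpha = 0)
  expect_equal(sum(tm$counts), 2L)  # only OUT->OUT and IN->IN
  expect_equal(tm$counts["OUT", "OUT"], 1L)
  expect_equal(tm$counts["IN", "IN"], 1L)
  expect_error(fit_transition(c("OUT", NA, "IN"), alpha = 0),
               "no observable transition")
  expect_error(fit_transition("OUT"), "length >= 2")
  expect_error(fit_transition(c("OUT", "IN"), alpha = -1), "alpha")
})

test_that("fitted rows are row-stochastic and match brute-force counting", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(4:60, 1L)
    s <- sample(c("IN", "OUT"), n, replace = TRUE)
    s[stats::runif(n) < 0.15] <- NA
    oracle <- tryCatch(brute_force_ratios(s), error = function(e) NULL)
    fit <- tryCatch(fit_transition(s, alpha = 0), error = function(e) NULL)
    if (is.null(fit)) {
      expect_true(is.null(oracle) || all(is.na(oracle)))
      next
    }
    expect_equal(unname(fit$p), unname(oracle))
    sums <- rowSums(fit$p)
    expect_true(all(is.na(sums) | abs(sums - 1) < 1e-12))
    # posterior mean interpolates counts and prior
    fit2 <- fit_transition(s, alpha = 2)
    expect_equal(unname(fit2$p),
                 unname((fit$counts + 2) / (rowSums(fit$counts) + 4)))
  }
})

test_that("stationary distribution solves pi T = pi", {
  expect_equal(stationary_distribution(mk_tm(0.5, 0.5)), 0.5)
  expect_equal(stationary_distribution(mk_tm(0.3, 0.9)), 0.75)
  expect_equal(stationary_distribution(mk_tm(0.3, 1)), 1.0)   # OUT absorbing
  expect_equal(stationary_distribution(mk_tm(0, 0.7)), 0.0)   # IN absorbing
  expect_warning(s <- stationary_distribution(mk_tm(0, 1)), "reducible")
  expect_true(is.na(s))
})

test_that("occupancy simulation matches independent oracles", {
  # absorbing OUT: every simulated proportion is 1
  expect_equal(simulate_occupancy(mk_tm(0.3, 1), 24, 200, init = "OUT", seed = 1),
               rep(1, 200))

  # symmetric 0.5 chain: scans are i.i.d. fair coins; mean of 10,000
  # proportions of 12 scans within 3 SE of 0.5 (SE from the Bernoulli oracle)
  sims <- simulate_occupancy(mk_tm(0.5, 0.5), 12, 10000, init = "stationary",
                             seed = 2)
  se <- sqrt(0.25 / 12) / sqrt(10000)
  expect_lt(abs(mean(sims) - 0.5), 3 * se)

  # ergodic theorem: long sequences concentrate on the stationary occupancy
  tm <- mk_tm(0.6, 0.8)  # pi = 0.75, fast mixing
  long <- simulate_occupancy(tm, 10000, 50, init = "stationary", seed = 3)
  expect_true(all(abs(long - 0.75) < 0.02))

  # deterministic under a fixed seed
  expect_identical(simulate_occupancy(tm, 24, 100, seed = 9),
                   simulate_occupancy(tm, 24, 100, seed = 9))
})

test_that("preference classification follows the percentile rule", {
  # absorbing chains give degenerate intervals and decisive calls
  out <- preference_test(rep("OUT", 24), alpha = 0, n_sims = 100,
                         null_prop = 0.71, seed = 4)
  expect_equal(out$classification, "PEN")
  expect_equal(c(out$ci_low, out$ci_high), c(1, 1))

  inn <- preference_test(rep("IN", 24), alpha = 0, n_sims = 100,
                         null_prop = 0.71, seed = 4)
  expect_equal(inn$classification, "CRATE")
  expect_equal(inn$prop_out_observed, 0)

  # all-missing window: NA classification, not an error
  empty <- preference_test(rep(NA_character_, 12), n_sims = 10, null_prop = 0.71)
  expect_true(is.na(empty$classification))
  expect_equal(empty$n_obs, 0L)

  # single observed scan: no transition, flagged NA
  one <- preference_test(c("OUT", rep(NA_character_, 11)), n_sims = 10,
                         null_prop = 0.71)
  expect_true(is.na(one$classification))
  expect_equal(one$prop_out_observed, 1)
})

test_that("classification is monotone in the null occupancy", {
  set.seed(6)
  s <- rchain(0.4, 0.9, 72, 0.8)
  rank <- c(PEN = 1L, NONE = 2L, CRATE = 3L)
  cls <- vapply(seq(0.05, 0.95, by = 0.05), function(null)
    preference_test(s, alpha = 1, n_sims = 2000, null_prop = null,
                    seed = 7)$classification, character(1L))
  expect_true(all(diff(rank[cls]) >= 0L))
})

test_that("window bookkeeping conserves totals across animals and days", {
  cfg <- simulation_config(n_trios = 2L, n_days = 3L, seed = 13L)
  sc <- generate_occupancy(cfg)
  pr <- analyze_preferences(sc, n_sims = 100L, seed = 8L)
  n_gilts <- length(unique(sc$gilt_id))
  expect_equal(sum(pr$window_type == "FULL"), n_gilts)
  expect_equal(sum(pr$window_type == "PER_DAY"), n_gilts * 3L)
  expect_equal(sum(pr$window_type == "PER_PERIOD"), n_gilts * 3L * 2L)
  expect_true(all(pr$ci_low <= pr$sim_mean + 1e-12, na.rm = TRUE))
  expect_true(all(pr$sim_mean <= pr$ci_high + 1e-12, na.rm = TRUE))

  summ <- summarize_preferences(pr)
  expect_equal(sum(summ$counts$n[summ$counts$window_type == "PER_DAY"]),
               n_gilts * 3L)

  # batch runs are reproducible under a fixed seed
  pr2 <- analyze_preferences(sc, n_sims = 100L, seed = 8L)
  expect_identical(pr, pr2)
})

test_that("transition_table tabulates every animal-window", {
  cfg <- simulation_config(n_trios = 2L, n_days = 2L, seed = 21L)
  sc <- generate_occupancy(cfg)
  tt <- transition_table(sc)
  expect_equal(nrow(tt), 6L * (1L + 2L + 4L))
  ok <- !is.na(tt$p_in_in)
  expect_true(all(abs(tt$p_in_in[ok] + tt$p_in_out[ok] - 1) < 1e-12))
})
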