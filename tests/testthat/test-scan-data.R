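test_that("derive_period splits the day into 12 day and 12 night scans", {
  expect_equal(derive_period(c(8, 19)), c("DAY", "DAY"))
  expect_equal(derive_period(c(20, 7)), c("NIGHT", "NIGHT"))
  per <- derive_period(0:23)
  expect_equal(sum(per == "DAY"), 12L)
  expect_equal(sum(per == "NIGHT"), 12L)
  expect_error(derive_period(24), "0\\.\\.23")
  expect_error(derive_period(-1), "0\\.\\.23")
})

test_that("scan validation rejects schema violations with informative messages", {
  sc <- tiny_scans()
  expect_s3_class(validate_scans(sc), "scan_table")

  dup <- rbind(sc, sc[5L, ])
  expect_error(validate_scans(dup), "duplicated \\(gilt_id, day, hour\\)")
  expect_error(validate_scans(dup), "T01_G1\\|1\\|4")  # names the duplicate key

  bad_loc <- sc; bad_loc$location[3L] <- "OUTSIDE"
  expect_error(validate_scans(bad_loc), "unknown location")

  two_trios <- sc; two_trios$trio_id[1L] <- "T02"
  expect_error(validate_scans(two_trios), "more than one `trio_id`")

  bad_day <- sc; bad_day$day[1L] <- 9
  expect_error(validate_scans(bad_day), "`day` must be an integer in 1\\.\\.7")
})

test_that("scan tables round-trip through CSV with missing-scan sentinels", {
  cfg <- simulation_config(n_trios = 2L, seed = 5L)
  scans <- generate_occupancy(cfg)
  etho <- generate_ethogram(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(scans, etho, dir)
  scans2 <- load_scans(paths[["scans"]])
  etho2 <- load_ethogram(paths[["ethogram"]])
  expect_equal(as.data.frame(scans2), as.data.frame(scans))
  expect_equal(as.data.frame(etho2), as.data.frame(etho))
  # missing scans survived as empty fields, reloaded as NA
  expect_gt(sum(is.na(scans2$location)), 0L)

  # empty table writes a header-only CSV
  write_fixtures(scans[0L, ], etho[0L, ], dir)
  expect_equal(length(readLines(paths[["scans"]])), 1L)
  expect_equal(nrow(load_scans(paths[["scans"]])), 0L)
})

test_that("time budgets count only observed scans and respect windows", {
  sc <- tiny_scans(n_gilts = 1L, n_days = 1L)
  expect_equal(time_budget(sc, "full")$prop_out, 1.0)

  sc$location[1:7] <- "IN"  # 17 OUT of 24
  expect_equal(time_budget(sc, "full")$prop_out, 17 / 24)

  # missing scans leave the denominator
  sc$location[8:9] <- NA
  tb <- time_budget(sc, "full")
  expect_equal(tb$n_obs, 22L)
  expect_equal(tb$prop_out, 15 / 22)

  # a fully missing window is flagged, not dropped
  sc2 <- tiny_scans(n_gilts = 1L, n_days = 2L)
  sc2$location[sc2$day == 2L] <- NA
  tbd <- time_budget(sc2, "per_day")
  expect_equal(nrow(tbd), 2L)
  expect_true(tbd$empty[tbd$window_id == "day2"])
  expect_true(is.na(tbd$prop_out[tbd$window_id == "day2"]))
})

test_that("full-window proportion is the n-weighted mean of per-day proportions", {
  cfg <- simulation_config(n_trios = 3L, seed = 11L)
  sc <- generate_occupancy(cfg)
  full <- time_budget(sc, "full")
  per_day <- time_budget(sc, "per_day")
  for (g in full$gilt_id) {
    pd <- per_day[per_day$gilt_id == g & per_day$n_obs > 0L, ]
    expect_equal(full$prop_out[full$gilt_id == g],
                 sum(pd$prop_out * pd$n_obs) / sum(pd$n_obs))
  }
  expect_true(all(full$prop_out >= 0 & full$prop_out <= 1))
})

test_that("Cohen's kappa matches the chance-corrected agreement formula", {
  expect_equal(cohen_kappa(c("IN", "OUT", "IN"), c("IN", "OUT", "IN")), 1.0)

  ind <- labels_from_confusion(matrix(c(25, 25, 25, 25), 2, 2))
  expect_equal(cohen_kappa(ind$a, ind$b), 0.0)

  # hand computation: p_o = 0.85, p_e = 0.5 -> kappa = 0.7
  conf <- labels_from_confusion(matrix(c(40, 10, 5, 45), 2, 2, byrow = TRUE))
  expect_equal(cohen_kappa(conf$a, conf$b), 0.7)

  expect_error(cohen_kappa(c("A", "B"), c("A")), "length")
  expect_warning(k1 <- cohen_kappa(rep("IN", 5), rep("IN", 5)), "single category")
  expect_equal(k1, 1)
})

test_that("kappa stays in [-1, 1] and is 1 on self-agreement", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:60, 1L)
    a <- sample(c("IN", "OUT"), n, replace = TRUE)
    b <- sample(c("IN", "OUT"), n, replace = TRUE)
    k <- suppressWarnings(cohen_kappa(a, b))
    expect_gte(k, -1); expect_lte(k, 1)
    if (length(unique(a)) > 1L) expect_equal(cohen_kappa(a, a), 1)
  }
})

test_that("sampling-rate check is null for identical or replicated distributions", {
  sc <- tiny_scans(n_gilts = 1L, n_days = 1L)
  sc$location[1:6] <- "IN"
  res <- sampling_rate_check(sc, sc)
  expect_equal(res$chi2_stat, 0)
  expect_equal(res$chi2_p, 1)

  # exact 4x replication of the coarse table (15-min vs 60-min scans)
  fine <- sc[rep(seq_len(nrow(sc)), each = 4L), ]
  res4 <- sampling_rate_check(fine, sc)
  expect_equal(res4$chi2_stat, 0)

  expect_error(sampling_rate_check(sc[0L, ], sc), "observed locations")
})

test_that("sampling-rate check holds its nominal size on exchangeable scans", {
  # scans drawn i.i.d. (a memoryless location process): comparing 600
  # fine-rate with 150 coarse-rate scans should reject at ~ the 5% level
  set.seed(47)
  reps <- 600L
  pvals <- replicate(reps, {
    fine <- data.frame(location = sample(c("IN", "OUT"), 600, TRUE, prob = c(0.3, 0.7)))
    coarse <- data.frame(location = sample(c("IN", "OUT"), 150, TRUE, prob = c(0.3, 0.7)))
    sampling_rate_check(fine, coarse)$chi2_p
  })
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})
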