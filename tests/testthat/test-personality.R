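test_that("Bartlett statistic matches the closed form and flags singularity", {
  set.seed(41)
  n <- 40L
  x <- matrix(rnorm(n * 6L), n, 6L)
  x[, 2L] <- x[, 1L] * 0.6 + x[, 2L] * 0.8  # known dependence
  colnames(x) <- paste0("b", 1:6)
  df <- as.data.frame(x)
  res <- adequacy_checks(df)
  R <- cor(x)
  expect_equal(res$bartlett_stat,
               -(n - 1 - (2 * 6 + 5) / 6) * log(det(R)))
  expect_equal(res$bartlett_df, 15)
  expect_true(res$kmo_msa >= 0 && res$kmo_msa <= 1)
  expect_equal(length(res$kmo_per_variable), 6L)

  # bivariate closed form: det R = 1 - r^2
  df2 <- df[, 1:2]
  r <- cor(df2)[1L, 2L]
  res2 <- adequacy_checks(df2)
  expect_equal(res2$bartlett_stat, -(n - 1 - (2 * 2 + 5) / 6) * log(1 - r^2))
  expect_equal(res2$bartlett_df, 1)

  dup <- df; dup$b2 <- dup$b1
  expect_error(adequacy_checks(dup), "singular")
})

test_that("iterative-PCA imputation completes low-rank tables exactly", {
  # rank-1 noiseless table: one blanked entry must be recovered
  set.seed(43)
  u <- runif(20L, 1, 3)
  v <- c(10, 20, 5, 40, 8, 15)
  x <- outer(u, v)
  colnames(x) <- ETHOGRAM_COLS <- c("lines_crossed", "nose_wall_s", "nose_floor_s",
                                    "lie_down_s", "latency_contact_s", "nose_object_s")
  etho <- cbind(data.frame(gilt_id = sprintf("G%02d", 1:20)), as.data.frame(x))
  etho <- suppressWarnings(validate_ethogram(etho))
  truth <- etho$latency_contact_s[7L]
  etho$latency_contact_s[7L] <- NA
  done <- impute_missing(etho, ncp = 1L)
  expect_lt(abs(done$latency_contact_s[7L] - truth), 1e-6)
  # complete rows untouched
  expect_identical(done$nose_floor_s, etho$nose_floor_s)
  expect_identical(done$latency_contact_s[-7L], etho$latency_contact_s[-7L])
})

test_that("tables without missing values pass through imputation unchanged", {
  cfg <- simulation_config(n_trios = 4L, seed = 3L)
  etho <- generate_ethogram(cfg)
  etho$latency_contact_s[is.na(etho$latency_contact_s)] <- 150
  expect_identical(as.data.frame(impute_missing(etho)), as.data.frame(etho))
})

test_that("the non-approaching animal is retained through imputation and PCA", {
  cfg <- simulation_config(seed = 9L)
  etho <- generate_ethogram(cfg)
  na_gilt <- etho$gilt_id[is.na(etho$latency_contact_s)]
  expect_length(na_gilt, 1L)
  done <- impute_missing(etho)
  expect_false(anyNA(done))
  pca <- run_pca(done)
  expect_true(na_gilt %in% pca$gilt_id)
  expect_equal(nrow(pca$scores), nrow(etho))
})

test_that("correlation PCA has the expected spectral structure", {
  cfg <- simulation_config(seed = 51L)
  pca <- run_pca(impute_missing(generate_ethogram(cfg)))
  expect_equal(sum(pca$eigenvalues), 6, tolerance = 1e-8)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_equal(pca$var_explained, pca$eigenvalues / 6)
  expect_true(all(abs(pca$loadings) <= 1 + 1e-8))
  # scores are centred with variance equal to the eigenvalues
  expect_equal(unname(colMeans(pca$scores)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(pca$scores, 2, var)), unname(pca$eigenvalues),
               tolerance = 1e-8)
  # sign convention: latency anchors Comp.1, nose-object anchors Comp.2,
  # later components orient their dominant behaviour positively
  expect_gt(pca$loadings["latency_contact_s", 1L], 0)
  expect_gt(pca$loadings["nose_object_s", 2L], 0)
  for (j in 3:6)
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("two-variable PCA eigenvalues are 1 +/- r", {
  set.seed(53)
  x <- MASS::mvrnorm(60, c(0, 0), matrix(c(1, 0.4, 0.4, 1), 2, 2))
  df <- data.frame(a = x[, 1L], b = x[, 2L])
  r <- abs(cor(df$a, df$b))
  pca <- run_pca(df, run_adequacy = FALSE)
  expect_equal(unname(pca$eigenvalues), c(1 + r, 1 - r), tolerance = 1e-10)
})

test_that("loadings are invariant to affine rescaling of behaviours", {
  cfg <- simulation_config(n_trios = 5L, seed = 57L)
  etho <- impute_missing(generate_ethogram(cfg))
  scaled <- etho
  scaled$nose_floor_s <- scaled$nose_floor_s / 60 + 2   # minutes, offset
  scaled$lines_crossed <- scaled$lines_crossed * 10
  p1 <- run_pca(etho, run_adequacy = FALSE)
  p2 <- suppressWarnings(run_pca(scaled, run_adequacy = FALSE))
  expect_equal(p1$loadings, p2$loadings, tolerance = 1e-8)
})

test_that("trait retention applies the eigenvalue and loading thresholds", {
  fake <- structure(list(
    eigenvalues = c(2.4, 1.4, 0.8, 0.6, 0.5, 0.3),
    loadings = matrix(c(0.77, -0.67, 0.83, -0.73, 0.2, 0.1,
                        0.1, -0.50, 0.05, 0.2, 0.87, -0.3),
                      6, 2, dimnames = list(
                        c("latency_contact_s", "nose_wall_s", "nose_floor_s",
                          "lines_crossed", "nose_object_s", "lie_down_s"),
                        c("Comp.1", "Comp.2"))),
    scores = matrix(rnorm(12), 6, 2,
                    dimnames = list(NULL, c("Comp.1", "Comp.2"))),
    gilt_id = sprintf("G%d", 1:6)), class = "pca_result")
  tr <- score_traits(fake)
  expect_equal(tr$retained, c(1L, 2L))
  expect_equal(tr$trait_names, c("Passivity", "Engagement"))
  # the +/-0.5 boundary is inclusive
  expect_true("nose_wall_s" %in% names(tr$groupings$Engagement))
  expect_equal(names(tr$scores), c("gilt_id", "passivity", "engagement"))

  fake$eigenvalues <- c(1.01, rep(0.9, 5))
  expect_equal(score_traits(fake)$retained, 1L)

  fake$eigenvalues <- rep(0.9, 6)
  expect_warning(empty <- score_traits(fake), "no component")
  expect_length(empty$retained, 0L)
})
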