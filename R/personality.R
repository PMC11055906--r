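# Pull the behaviour columns out of an ethogram-like table: the six
# standard behaviours when present, otherwise every numeric non-id column.
behaviour_matrix <- function(etho) {
  etho <- as.data.frame(etho)
  cols <- if (all(ETHOGRAM_BEHAVIOURS %in% names(etho))) ETHOGRAM_BEHAVIOURS else {
    num <- names(etho)[vapply(etho, is.numeric, logical(1L))]
    setdiff(num, "gilt_id")
  }
  if (length(cols) < 2L)
    stop("need at least two numeric behaviour columns", call. = FALSE)
  as.matrix(etho[cols])
}

#' Factorability checks for the ethogram correlation matrix
#'
#' Computes Bartlett's test of sphericity and the Kaiser-Meyer-Olkin
#' measure of sampling adequacy on the six-behaviour correlation matrix
#' (pairwise-complete observations). Bartlett tests that the correlation
#' matrix is the identity, with statistic
#' `-(n - 1 - (2p + 5) / 6) * log det(R)` on `p (p - 1) / 2` degrees of
#' freedom; a significant result plus an acceptable overall MSA (rule of
#' thumb: > 0.5) supports running a PCA.
#'
#' @param etho An `ethogram_table` (missing entries allowed; correlations
#'   use pairwise-complete observations).
#' @return List with `bartlett_stat`, `bartlett_df`, `bartlett_p`,
#'   `kmo_msa` (overall) and `kmo_per_variable`.
#' @export
adequacy_checks <- function(etho) {
  x <- behaviour_matrix(etho)
  n <- nrow(x)
  p <- ncol(x)
  if (n < p + 1L)
    stop("need more rows than behaviours to assess factorability", call. = FALSE)
  R <- stats::cor(x, use = "pairwise.complete.obs")
  if (anyNA(R)) stop("correlation matrix contains NA; inspect variables", call. = FALSE)
  detR <- det(R)
  if (detR <= .Machine$double.eps)
    stop("singular correlation matrix (det ~ 0); inspect variables for ",
         "duplicates or exact linear dependence", call. = FALSE)
  bartlett_stat <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  bartlett_df <- p * (p - 1) / 2
  bartlett_p <- stats::pchisq(bartlett_stat, df = bartlett_df, lower.tail = FALSE)

  # KMO from anti-image (partial) correlations
  Rinv <- solve(R)
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)   # partial correlations, off-diagonal
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  sum_r2 <- colSums(R0^2)
  sum_q2 <- colSums(Q^2)
  kmo_per_variable <- sum_r2 / (sum_r2 + sum_q2)
  kmo_msa <- sum(sum_r2) / (sum(sum_r2) + sum(sum_q2))
  list(bartlett_stat = bartlett_stat, bartlett_df = bartlett_df,
       bartlett_p = bartlett_p, kmo_msa = kmo_msa,
       kmo_per_variable = stats::setNames(kmo_per_variable, colnames(R)))
}

#' Impute missing ethogram entries by regularized iterative PCA
#'
#' Completes missing behaviour values (typically the latency of an animal
#' that never approached the novel object) with the regularized iterative
#' PCA algorithm: starting from column means, alternate a truncated SVD of
#' the standardized data (with singular values shrunk by the estimated
#' noise variance of the discarded dimensions) and replacement of the
#' missing cells by their fitted values, until the imputed cells change by
#' less than `tol`. Complete rows are returned unchanged; the animal with
#' the missing value is retained, not dropped.
#'
#' @param etho An `ethogram_table` with missing entries.
#' @param ncp Number of components of the underlying signal (default 2,
#'   the number of traits the analysis extracts).
#' @param tol Convergence tolerance on the imputed values (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return The completed `ethogram_table`.
#' @export
impute_missing <- function(etho, ncp = 2L, tol = 1e-6, max_iter = 1000L) {
  ncp <- check_count(ncp, "ncp")
  etho <- as.data.frame(etho)
  x <- as.matrix(etho[ETHOGRAM_BEHAVIOURS])
  miss <- is.na(x)
  if (!any(miss)) {
    class(etho) <- c("ethogram_table", "data.frame")
    return(etho)
  }
  if (any(colSums(!miss) == 0L))
    stop("a behaviour column is entirely missing; cannot impute", call. = FALSE)
  extra <- miss
  extra[, "latency_contact_s" == colnames(x)] <- FALSE
  if (any(extra))
    warning("missing values outside latency_contact_s; imputing them as well")
  if (ncp >= min(dim(x)))
    stop_field("ncp", "must be smaller than both dimensions of the table")

  # initialize missing cells at column means
  mu0 <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[miss[, j], j] <- mu0[j]
  p <- ncol(x)
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(x)
    sdev <- apply(x, 2L, stats::sd)
    if (any(sdev == 0)) sdev[sdev == 0] <- 1
    z <- sweep(sweep(x, 2L, mu), 2L, sdev, `/`)
    sv <- svd(z)
    d2 <- sv$d^2
    # noise variance from the discarded dimensions; shrink retained
    # singular values toward zero (regularized reconstruction)
    sigma2 <- if (p > ncp) mean(d2[(ncp + 1L):length(d2)]) else 0
    d_shrunk <- pmax(sv$d[seq_len(ncp)] - sigma2 / pmax(sv$d[seq_len(ncp)], 1e-12), 0)
    fit_z <- sv$u[, seq_len(ncp), drop = FALSE] %*%
      (d_shrunk * t(sv$v[, seq_len(ncp), drop = FALSE]))
    fit <- sweep(sweep(fit_z, 2L, sdev, `*`), 2L, mu, `+`)
    new_vals <- fit[miss]
    delta <- max(abs(new_vals - x[miss]))
    x[miss] <- new_vals
    if (delta < tol) break
  }
  etho[ETHOGRAM_BEHAVIOURS] <- as.data.frame(x)
  class(etho) <- c("ethogram_table", "data.frame")
  etho
}

#' Unrotated PCA of the six test behaviours
#'
#' Principal component analysis of the standardized behaviours (correlation
#' matrix, no rotation). Eigenvalues sum to the number of behaviours;
#' loadings are reported as variable-component correlations
#' (`rotation * sdev`), and per-animal component scores are returned for
#' downstream modelling. PCA signs are arbitrary, so they are fixed by
#' convention: for the standard ethogram the approach latency anchors the
#' first component positively (passive animals score high) and the
#' nose-object duration the second (engaged animals score high); any other
#' component, or any non-standard input, is oriented so its largest
#' absolute loading is positive. Repeated runs are therefore sign-stable.
#'
#' @param etho A complete `ethogram_table` (impute first if needed).
#' @param run_adequacy Also run [adequacy_checks()] and store the results
#'   (default `TRUE`).
#' @return Object of class `pca_result`: `eigenvalues`, `var_explained`,
#'   `loadings` (behaviour x component correlations), `scores` (animal x
#'   component), `gilt_id`, and the adequacy statistics.
#' @export
run_pca <- function(etho, run_adequacy = TRUE) {
  etho <- as.data.frame(etho)
  x <- behaviour_matrix(etho)
  if (anyNA(x))
    stop("ethogram has missing values; run impute_missing() first", call. = FALSE)
  if (nrow(x) <= ncol(x))
    stop("need more animals than behaviours for the PCA (>= 7 for the ",
         "standard 6-behaviour ethogram)", call. = FALSE)
  zero_var <- apply(x, 2L, stats::sd) == 0
  if (any(zero_var))
    stop("zero-variance behaviour column(s): ",
         paste(colnames(x)[zero_var], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  k <- length(eig)
  loadings <- pc$rotation %*% diag(pc$sdev, k, k)  # variable-PC correlations
  scores <- pc$x
  # sign convention: anchor behaviours orient the first two components of a
  # standard ethogram; elsewhere the dominant behaviour loads positively
  anchors <- c("latency_contact_s", "nose_object_s")
  standard <- all(anchors %in% rownames(loadings))
  for (j in seq_len(k)) {
    anchor_load <- if (standard && j <= 2L) loadings[anchors[j], j] else 0
    s <- if (abs(anchor_load) > 1e-8) sign(anchor_load) else
      sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(loadings) <- colnames(scores) <- sprintf("Comp.%d", seq_len(k))
  res <- list(
    eigenvalues = eig,
    var_explained = eig / sum(eig),
    loadings = loadings,
    scores = scores,
    gilt_id = etho$gilt_id %||% as.character(seq_len(nrow(x)))
  )
  if (run_adequacy) res <- c(res, adequacy_checks(etho))
  class(res) <- "pca_result"
  res
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Unrotated PCA of", nrow(x$loadings), "behaviours,",
      nrow(x$scores), "animals\n")
  ev <- rbind(eigenvalue = x$eigenvalues,
              `% variance` = 100 * x$var_explained)
  colnames(ev) <- colnames(x$loadings)
  print(round(ev, 2))
  if (!is.null(x$bartlett_stat))
    cat(sprintf("Bartlett K^2 = %.1f (df %d, P = %.3g); KMO MSA = %.2f\n",
                x$bartlett_stat, x$bartlett_df, x$bartlett_p, x$kmo_msa))
  invisible(x)
}

#' Retain components and score personality traits
#'
#' Applies the retention and labelling rules: keep components with
#' eigenvalue above `eig_threshold` (Kaiser rule, default 1); on each
#' retained component group the behaviours whose loading magnitude is at
#' least `loading_threshold` (default 0.5, boundary included); label the
#' first retained component `Passivity` and the second `Engagement`
#' (further components are `Trait3`, ...). Per-animal scores on the
#' retained components are returned for downstream models.
#'
#' @param pca A `pca_result`.
#' @param eig_threshold Retention threshold on eigenvalues (strict `>`).
#' @param loading_threshold Magnitude threshold for grouping behaviours
#'   (`>=`).
#' @return List of class `trait_scores`: `retained` (component indices),
#'   `trait_names`, `groupings` (named list of signed loadings per trait)
#'   and `scores` (data frame, `gilt_id` plus one lower-case column per
#'   trait).
#' @export
score_traits <- function(pca, eig_threshold = 1.0, loading_threshold = 0.5) {
  stopifnot(inherits(pca, "pca_result"))
  retained <- which(pca$eigenvalues > eig_threshold)
  if (!length(retained)) {
    warning("no component passes the eigenvalue threshold; empty trait table")
    return(structure(list(retained = integer(), trait_names = character(),
                          groupings = list(),
                          scores = data.frame(gilt_id = pca$gilt_id)),
                     class = "trait_scores"))
  }
  trait_names <- c("Passivity", "Engagement",
                   sprintf("Trait%d", seq_len(max(0L, length(retained) - 2L)) + 2L))
  trait_names <- trait_names[seq_along(retained)]
  groupings <- lapply(retained, function(j) {
    l <- pca$loadings[, j]
    sort(l[abs(l) >= loading_threshold], decreasing = TRUE)
  })
  names(groupings) <- trait_names
  scores <- data.frame(gilt_id = pca$gilt_id, stringsAsFactors = FALSE)
  for (i in seq_along(retained))
    scores[[tolower(trait_names[i])]] <- unname(pca$scores[, retained[i]])
  structure(list(retained = retained, trait_names = trait_names,
                 groupings = groupings, scores = scores),
            class = "trait_scores")
}

#' @export
print.trait_scores <- function(x, ...) {
  if (!length(x$retained)) {
    cat("No retained components\n")
    return(invisible(x))
  }
  for (i in seq_along(x$retained)) {
    cat(sprintf("%s (Comp.%d):\n", x$trait_names[i], x$retained[i]))
    g <- x$groupings[[i]]
    for (b in names(g)) cat(sprintf("  %-18s r = %+.2f\n", b, g[[b]]))
  }
  invisible(x)
}
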