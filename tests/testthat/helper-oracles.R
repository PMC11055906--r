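# Test-side oracles, independent of the package's implementation paths.

# Simulate one IN/OUT sequence from explicit transition probabilities by a
# plain scalar loop (oracle for the package's vectorized simulator).
rchain <- function(p_in_out, p_out_out, n, init_p_out) {
  s <- integer(n)
  s[1L] <- as.integer(stats::runif(1L) < init_p_out)
  for (t in 2:n) {
    p <- if (s[t - 1L] == 1L) p_out_out else p_in_out
    s[t] <- as.integer(stats::runif(1L) < p)
  }
  ifelse(s == 1L, "OUT", "IN")
}

# Wrap explicit probabilities as a transition_matrix object.
mk_tm <- function(p_in_out, p_out_out, alpha = 0) {
  structure(list(
    p = matrix(c(1 - p_in_out, 1 - p_out_out, p_in_out, p_out_out), 2L, 2L,
               dimnames = list(from = c("IN", "OUT"), to = c("IN", "OUT"))),
    counts = matrix(0L, 2L, 2L,
                    dimnames = list(from = c("IN", "OUT"), to = c("IN", "OUT"))),
    alpha = alpha), class = "transition_matrix")
}

# Brute-force transition-count ratios (the MLE) by explicit enumeration.
brute_force_ratios <- function(seq) {
  states <- c("IN", "OUT")
  counts <- matrix(0L, 2L, 2L, dimnames = list(states, states))
  for (t in seq_len(length(seq) - 1L)) {
    a <- seq[t]; b <- seq[t + 1L]
    if (!is.na(a) && !is.na(b)) counts[a, b] <- counts[a, b] + 1L
  }
  p <- counts / rowSums(counts)
  p[rowSums(counts) == 0L, ] <- NA_real_
  p
}

# Expand a 2x2 confusion matrix (rows = rater A, cols = rater B) into the
# two raters' label vectors.
labels_from_confusion <- function(m, labels = c("A", "B")) {
  a <- character(0); b <- character(0)
  for (i in 1:2) for (j in 1:2) {
    a <- c(a, rep(labels[i], m[i, j]))
    b <- c(b, rep(labels[j], m[i, j]))
  }
  list(a = a, b = b)
}

# Small scan table built by hand for schema tests.
tiny_scans <- function(n_gilts = 2L, n_days = 2L, hours = 0:23) {
  g <- expand.grid(hour = hours, day = seq_len(n_days),
                   gilt = seq_len(n_gilts), KEEP.OUT.ATTRS = FALSE)
  data.frame(
    trio_id = "T01",
    gilt_id = sprintf("T01_G%d", g$gilt),
    side = "LEFT", season = "SUMMER",
    day = g$day, hour = g$hour,
    location = "OUT", stringsAsFactors = FALSE
  )
}
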