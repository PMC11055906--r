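# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# probability in the open interval (0, 1)
check_prob_open <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop_field(field, "must be a single probability strictly between 0 and 1")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single finite number")
  x
}

# logistic helpers used by the generator and the Markov module
plogis_ <- stats::plogis
qlogis_ <- stats::qlogis
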