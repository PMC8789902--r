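# internal helpers shared across modules

# elementwise log(exp(a) + exp(b)) without overflow
log_add <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: log(0 + 0) = -Inf, avoid NaN from Inf - Inf
  d <- ifelse(is.infinite(m) & m < 0, 0, pmin(a, b) - m)
  m + log1p(exp(d))
}

# log of the two-component binomial mixture  log(t * b(y;K,p1) + (1-t) * b(y;K,p0))
log_binom_mix <- function(y, K, t, p1, p0) {
  log_add(log(t) + stats::dbinom(y, K, p1, log = TRUE),
          log1p(-t) + stats::dbinom(y, K, p0, log = TRUE))
}

check_prob <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x))
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (bad)
    stop(sprintf("'%s' must lie in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
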