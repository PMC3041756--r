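# internal helpers shared across modules

# run expr under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL falls through to the session RNG
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).",
      name, if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be an integer (got %g).", name, x))
  invisible(as.integer(x))
}

# Truncated Poisson probability vector over m = m_min .. m_max, where m_max is
# the smallest count whose remaining upper-tail mass drops below `cutoff`.
# The truncated vector is renormalized to sum to exactly 1; when m_min = 1 the
# zero-truncated (screen-conditioned) distribution is returned.
truncated_poisson <- function(lambda, m_min = 0L, cutoff = 1e-10) {
  assert_scalar_number(lambda, "lambda", lower = 0)
  assert_scalar_number(cutoff, "cutoff", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  # qpois gives a near-tight bound; walk the last few steps exactly
  m_max <- max(m_min, qpois(cutoff, lambda, lower.tail = FALSE))
  while (ppois(m_max, lambda, lower.tail = FALSE) >= cutoff) {
    m_max <- m_max + 1L
  }
  m <- m_min:m_max
  p <- dpois(m, lambda)
  tibble(m = m, prob = p / sum(p))
}

# column-wise standard error of the mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
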