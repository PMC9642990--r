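# internal numerical helpers

# row-wise log-sum-exp of a matrix, guarded against -Inf rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

# normalize a probability vector, complaining if badly off
normalize_probs <- function(p, what = "probabilities", tol = 0.05) {
  if (any(!is.finite(p)) || any(p < 0)) {
    abort(sprintf("%s must be finite and non-negative", what))
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    abort(sprintf("%s sum to %.3f, not 1", what, s))
  }
  p / s
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_count <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

# deterministic child seed streams derived from one master seed
child_seed <- function(seed, i) {
  (as.integer(seed) * 48271L + as.integer(i) * 1013L) %% 2147483563L
}
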