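# Internal helpers shared across modules.

# Deterministic per-field sub-stream seed. Each generated field draws under its
# own seed derived from (survey seed, field name), so adding a new field to the
# generator cannot perturb the draws of existing fields.
field_seed <- function(seed, field) {
  h <- 0
  for (k in utf8ToInt(field)) h <- (h * 131 + k) %% 2147483647L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

with_field_seed <- function(seed, field, expr) {
  set.seed(field_seed(seed, field))
  expr
}

# Validate a probability vector that must sum to one.
check_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1].", what))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", what, sum(p)))
  }
  invisible(p)
}

check_scalar_prob <- function(p, what) {
  if (length(p) != 1 || !is.finite(p) || p < 0 || p > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", what))
  }
  invisible(p)
}

# Draw categorical values from a named probability vector.
draw_categorical <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Weighted mean with explicit NA policy (all values used; NA propagates).
weighted_mean <- function(x, w) sum(w * x) / sum(w)
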