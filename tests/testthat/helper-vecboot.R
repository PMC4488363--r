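# Shared helpers: Monte-Carlo standard errors used to set test tolerances.

# MC standard error of the mean of `reps`.
mc_se_mean <- function(reps) stats::sd(reps) / sqrt(length(reps))

# Exact variance of the sample variance of B i.i.d. draws from a
# distribution with central moments m2, m4. The leading term (m4 - m2^2)/B
# vanishes for symmetric two-point distributions, so the O(1/B^2) terms
# matter and are kept.
var_of_sample_var <- function(m2, m4, b) {
  max(m4 / b - m2^2 * (b - 3) / (b * (b - 1)), 0)
}

# MC standard error of the standard deviation of `reps` (delta method on
# the sample variance, using the empirical central moments).
mc_se_sd <- function(reps) {
  b <- length(reps)
  m <- mean(reps)
  m2 <- mean((reps - m)^2)
  m4 <- mean((reps - m)^4)
  sqrt(var_of_sample_var(m2, m4, b)) / (2 * sqrt(m2))
}

# MC standard error of the variance of `reps`.
mc_se_var <- function(reps) {
  b <- length(reps)
  m <- mean(reps)
  m2 <- mean((reps - m)^2)
  m4 <- mean((reps - m)^4)
  sqrt(var_of_sample_var(m2, m4, b))
}

# Exact SE of the sample SD of B draws from a discrete distribution given
# as (value, probability), via the same delta method but with exact
# moments.
exact_se_sd <- function(values, probs, b) {
  m <- sum(probs * values)
  m2 <- sum(probs * (values - m)^2)
  m4 <- sum(probs * (values - m)^4)
  sqrt(var_of_sample_var(m2, m4, b)) / (2 * sqrt(m2))
}

# Build a weight_matrix by hand (for tests that need specific columns).
manual_weights <- function(values, scheme) {
  vecboot:::new_weight_matrix(as.matrix(values), scheme)
}

# Plug-in (denominator N) variance.
plugin_var <- function(x) mean((x - mean(x))^2)
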