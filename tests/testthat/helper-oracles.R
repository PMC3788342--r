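# Brute-force oracles, kept deliberately independent of the package's
# summation / convolution code paths.

# P(X >= x) for X ~ Binomial(n, 1/m) by enumerating all m^n outcome vectors
# (uniform item choice per trial, success = choosing the target).
bf_uniform_choice_upper <- function(x, n, m) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  successes <- rowSums(grid == 1)
  mean(successes >= x)
}

# Exact Poisson-binomial upper tail by enumerating all 2^n inclusion patterns
# and summing their product probabilities.
bf_pb_upper <- function(probs, x) {
  n <- length(probs)
  if (n == 0) return(as.numeric(x <= 0))
  patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  pat_prob <- apply(patterns, 1, function(z) {
    prod(ifelse(z == 1, probs, 1 - probs))
  })
  sum(pat_prob[rowSums(patterns) >= x])
}

# Convenience: the bundled free-design k-profiles as plain vectors.
fixture_k_profiles <- function() {
  prof <- k_profile(ape_exchange_trials("free"))
  split(prof$k, prof$subject)
}
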