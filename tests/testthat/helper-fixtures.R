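# Small fixtures shared across test files; everything is generated in code.

# A windowed profile built directly from values (bypasses sequence counting).
make_profile <- function(values, window = 10000L, kind = "gc_skew") {
  L <- as.integer(length(values)) * window
  replimode:::windowed_profile(values, window, window,
                               (seq_along(values) - 1L) * window, L, kind)
}

# Ideal two-segment ("tent") profile values: +s over the first half of the
# circle, -s over the second half, giving a perfect cumulative V/Lambda.
tent_values <- function(n, s = 0.3) {
  c(rep(s, n %/% 2), rep(-s, n - n %/% 2))
}

# Noiseless MFA profile for a model, via expectation-only depth profiles.
noiseless_mfa <- function(model, fine = 10000L, coarse = 50000L,
                          depth = 500) {
  dp <- simulate_depth_profiles(model, fine, depth, poisson_noise = FALSE)
  mfa_ratio(dp$exponential, dp$stationary, coarse_window = coarse)
}

# Default small skewed genome used by several skew tests (100 kb keeps the
# suite fast; tests needing the spec-scale 1 Mb genome build their own).
small_skewed_genome <- function(seed = 1L, s = 0.3, L = 100000L) {
  generate_skewed_genome(
    skewed_genome_spec(L, ori_position = 0, ter_position = L %/% 2L,
                       skew_strength = s, gc_content = 0.5, seed = seed),
    min_length = 2L * 1000L
  )
}
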