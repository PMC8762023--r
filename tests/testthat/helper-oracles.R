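# Independent oracles, kept deliberately separate from the package's own
# code paths.

# Literal Fisher enumeration: probability of every admissible table computed
# directly from choose() products, two-tailed by the probability-mass rule.
fisher_oracle <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  if (n == 0) return(1)
  r1 <- a + b
  c1 <- a + c_
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[(lo:hi) == a]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# Two-pass mean/SD (sample SD, n-1)
mean_sd_oracle <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  c(mean = m, sd = s)
}

# A small hand-built family roster used in de-duplication tests: two sporadic
# patients, one two-patient family (mirroring a multi-case family with an
# unaffected sibling), one healthy control.
mini_roster <- function() {
  tibble::tibble(
    individual_id = c("S1", "S2", "F1-01", "F1-02", "F1-03", "H1"),
    group = c("SLE", "SLE", "SLE", "SLE", "family_non_SLE", "HC"),
    family_id = c(NA, NA, "F1", "F1", "F1", NA),
    sex = c("F", "F", "F", "F", "M", "F"),
    age = c(30L, 35L, 28L, 33L, 40L, 45L)
  )
}

quick_config <- function(seed = 1, ...) {
  sim_config(n_sporadic = 6, n_hc = 6, families = 3,
             n_somatic_carriers = 2L, seed = seed, ...)
}
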