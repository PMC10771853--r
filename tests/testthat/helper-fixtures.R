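# shared fixtures, built in code so every test run regenerates them

small_references <- function(seed = 1) {
  generate_reference_profiles(60, 10, seed = seed)
}

# a modest cohort reused by several suites; regenerated per call so tests
# cannot interfere through shared state
small_cohort <- function(seed = 3, n_probes = 500, n_informative = 10,
                         n_snp = 10, ...) {
  refs <- small_references()
  cfg <- generator_config(n_probes = n_probes, n_informative = n_informative,
                          n_snp_probes = n_snp, seed = seed, ...)
  c(generate_cohort(cfg, refs), list(references = refs, config = cfg))
}

# closed-form chi-square for a 2x2 table without continuity correction
chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  pchisq(stat, df = 1, lower.tail = FALSE)
}
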