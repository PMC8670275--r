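# Shared fixtures, built in code. The small cohort is generated once per
# test run and reused across files.

small_cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(small_cohort_cache$coh))
    small_cohort_cache$coh <-
      generate_cohort(generator_config(master_seed = 101, n_cpgs = 800))
  small_cohort_cache$coh
}

# Minimal hand-built series: a list shaped like generate_beta_series()
# output, for constructed QC fixtures.
make_series <- function(values, individual = "A", tissue = "PBMC") {
  colnames(values) <- sprintf("T%02d", seq_len(ncol(values)))
  list(series_key = list(individual = individual, tissue = tissue),
       days = seq_len(ncol(values)) - 1L,
       values = values)
}

# Independent percentile oracle: sort + linear interpolation at rank
# 1 + (n - 1) q, written without quantile().
ri_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  at <- function(q) {
    r <- 1 + (n - 1) * q
    lo <- floor(r)
    hi <- min(lo + 1, n)
    s[lo] + (r - lo) * (s[hi] - s[lo])
  }
  at(0.95) - at(0.05)
}

# Independent two-sided Fisher p oracle: enumerate every table with the
# observed margins via binomial coefficients and sum the probabilities of
# tables at most as probable as the observed one.
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  supp <- max(0, c1 - r2):min(c1, r1)
  pr <- choose(r1, supp) * choose(r2, c1 - supp) / choose(r1 + r2, c1)
  pobs <- pr[match(a, supp)]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}
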