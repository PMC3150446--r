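# Independent oracles used across tests.

# Exact HWE p-value by full enumeration with binomial-coefficient arithmetic
# (Levene's conditional distribution of the heterozygote count).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  m <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  ks <- seq(m %% 2, m, by = 2)
  pr <- vapply(ks, function(k) {
    a <- (m - k) / 2
    choose(n, a) * choose(n - a, k) * 2^k / choose(2 * n, m)
  }, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[ks == n_Aa]
  sum(pr[pr <= p_obs * (1 + 1e-10)])
}

# Full vector of oracle p-values over every heterozygote count for (n, m).
hwe_oracle_all <- function(n, m) {
  ks <- seq(m %% 2, m, by = 2)
  pr <- vapply(ks, function(k) {
    a <- (m - k) / 2
    exp(lchoose(n, a) + lchoose(n - a, k) + k * log(2) - lchoose(2 * n, m))
  }, numeric(1))
  pr <- pr / sum(pr)
  vapply(seq_along(ks), function(i) sum(pr[pr <= pr[i] * (1 + 1e-10)]),
         numeric(1))
}

# Cached small default two-platform study shared by slower tests.
cached_study <- local({
  env <- new.env()
  function() {
    if (is.null(env$st)) {
      cfg <- sim_config(n_samples = 300, n_snps = 60, n_probes = 50,
                        n_batch_components = 2, batch_sd = 1, seed = 42)
      env$st <- simulate_study(cfg, n_cis = 5, n_trans = 3,
                               n_convergent_pairs = 1)
    }
    env$st
  }
})
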