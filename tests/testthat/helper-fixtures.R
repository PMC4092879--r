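# Small fixtures built in code, shared across test files.

# A tiny two-group NB experiment with known truth.
tiny_experiment <- function(n_genes = 200, n_per_group = 5, seed = 101,
                            prop_de = 0.1) {
  cfg <- scenario_config(
    name = "tiny", n_per_group = n_per_group, prop_de = prop_de,
    n_genes = n_genes, n_datasets = 1, depth_lower_bound = 5, seed = seed
  )
  simulate_scenario(cfg, panel_args = list(mu_sdlog = 1))[[1]]
}

# Independent oracle for the exact conditional NB test: explicit NB pmf
# through gamma functions, full enumeration over all splits of the total.
oracle_exact_p <- function(k1, s, n1, n2, phi) {
  mu0 <- s / (n1 + n2)
  lpmf <- function(y, mu, n) {
    r <- n / phi
    lgamma(y + r) - lgamma(r) - lfactorial(y) +
      r * log(r / (r + mu)) + y * log(mu / (r + mu))
  }
  x <- 0:s
  lp <- lpmf(x, n1 * mu0, n1) + lpmf(s - x, n2 * mu0, n2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[x == k1] * (1 + 1e-12)])
}

# Brute-force AUC: all DE/null pairs, ties counted half.
bruteforce_auc <- function(scores, de) {
  s1 <- scores[de]
  s0 <- scores[!de]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}
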