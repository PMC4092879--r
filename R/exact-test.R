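# Exact conditional negative binomial test.
#
# Under the null of equal per-sample means, the group-1 sum S1 of n1
# NB(mu, phi) samples is NB(n1 * mu, dispersion phi / n1) and the test
# conditions on the total s = k1 + k2. The two-sided p-value sums the
# conditional probabilities of all splits of s no more likely than the
# observed one (minimum-likelihood two-sided rule). phi = 0 reduces to the
# conditional binomial (Poisson) test.

# p-values for vectors of group sums; phi recycled per gene.
nb_exact_pvalue <- function(k1, k2, n1, n2, phi,
                            full_limit = 4000, tail_eps = 1e-14) {
  G <- length(k1)
  phi <- rep_len(phi, G)
  p <- numeric(G)
  for (g in seq_len(G)) {
    p[g] <- nb_exact_pvalue_one(k1[g], k2[g], n1, n2, phi[g],
                                full_limit, tail_eps)
  }
  p
}

nb_exact_pvalue_one <- function(k1, k2, n1, n2, phi,
                                full_limit = 4000, tail_eps = 1e-14) {
  s <- k1 + k2
  if (s == 0) {
    return(1)
  }
  mu0 <- s / (n1 + n2)
  mu_a <- n1 * mu0
  mu_b <- n2 * mu0
  poisson <- phi <= 1e-12
  if (poisson) {
    lpmf_a <- function(x) dpois(x, mu_a, log = TRUE)
    lpmf_b <- function(x) dpois(x, mu_b, log = TRUE)
    qlo_a <- qpois(tail_eps, mu_a)
    qhi_a <- qpois(tail_eps, mu_a, lower.tail = FALSE)
    qlo_b <- qpois(tail_eps, mu_b)
    qhi_b <- qpois(tail_eps, mu_b, lower.tail = FALSE)
  } else {
    size_a <- n1 / phi
    size_b <- n2 / phi
    lpmf_a <- function(x) dnbinom(x, mu = mu_a, size = size_a, log = TRUE)
    lpmf_b <- function(x) dnbinom(x, mu = mu_b, size = size_b, log = TRUE)
    qlo_a <- qnbinom(tail_eps, mu = mu_a, size = size_a)
    qhi_a <- qnbinom(tail_eps, mu = mu_a, size = size_a, lower.tail = FALSE)
    qlo_b <- qnbinom(tail_eps, mu = mu_b, size = size_b)
    qhi_b <- qnbinom(tail_eps, mu = mu_b, size = size_b, lower.tail = FALSE)
  }
  if (s <= full_limit) {
    x <- 0:s
  } else {
    lo <- max(0, qlo_a, s - qhi_b)
    hi <- min(s, qhi_a, s - qlo_b)
    lo <- min(lo, k1)
    hi <- max(hi, k1)
    x <- lo:hi
  }
  lg <- lpmf_a(x) + lpmf_b(s - x)
  lg <- lg - max(lg)
  prob <- exp(lg)
  prob <- prob / sum(prob)
  obs <- prob[match(k1, x)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}
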