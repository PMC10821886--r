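# Shared fixture builders. All randomized fixtures take an explicit seed so
# every test is reproducible in isolation.

two_species_model <- function(mu = c(0.5, 0.4), mu0 = 0.5, gamma = 0.9,
                              eta = 0.1, kappa = 0.005, D = 0.2, ...) {
  community_model(2, mu = mu, mu0 = mu0, gamma = gamma, eta = eta,
                  kappa = kappa, D = D, ...)
}

random_hgt_model <- function(m, seed, eta = 0.1, gamma = 0.9,
                             mu_range = c(0.4, 0.6)) {
  set.seed(seed)
  community_model(m, mu = runif(m, mu_range[1], mu_range[2]), mu0 = 0.5,
                  gamma = gamma, eta = eta, kappa = 0.005, D = 0.2)
}

random_state <- function(m, seed) {
  set.seed(seed)
  s <- runif(m, 0.05, 0.8)
  p <- matrix(runif(m * m), m, m) * s # p[i, j] <= s[i] row-wise
  community_state(s, p)
}

# Independent evaluation of the two-species extended model, written directly
# from the four printed per-subpopulation equations (not via the package's
# tensor form). Used as the oracle for hgt_rhs at m = 2.
two_species_rhs_oracle <- function(s1, s2, p1, p2, mu1, mu2, lam1, lam2,
                                   g1, g2, eta1, eta2, k1, k2, D) {
  mu1e <- mu1 * (1 + lam2 * p1 / s1)
  mu2e <- mu2 * (1 + lam1 * p2 / s2)
  c(
    ds1 = mu1e * s1 * (1 - s1 - g2 * s2) - D * s1,
    ds2 = mu2e * s2 * (1 - s2 - g1 * s1) - D * s2,
    dp1 = mu1 * (1 + lam2) * p1 * (1 - s1 - g2 * s2) +
      eta1 * (s2 + p1) * (s1 - p1) - (D + k1) * p1,
    dp2 = mu2 * (1 + lam1) * p2 * (1 - s2 - g1 * s1) +
      eta2 * (s1 + p2) * (s2 - p2) - (D + k2) * p2
  )
}
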