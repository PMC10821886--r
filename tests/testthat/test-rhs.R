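test_that("classic dynamics vanish at known fixed points", {
  # single species: logistic with dilution, equilibrium (mu - D)/mu
  mod1 <- community_model(1, mu = 0.5, eta = 0, kappa = 0, D = 0.2)
  expect_equal(classic_rhs(community_state(0.6), mod1), 0)
  # extinction is absorbing
  mod3 <- random_hgt_model(3, seed = 1, eta = 0)
  expect_equal(classic_rhs(community_state(rep(0, 3)), mod3), rep(0, 3))
  # symmetric two-species interior point from an independent linear solve
  g <- 0.9; phi <- (0.5 - 0.2) / 0.5
  s_star <- solve(matrix(c(1, g, g, 1), 2), c(phi, phi))
  mod2 <- community_model(2, mu = 0.5, gamma = g, eta = 0)
  expect_equal(classic_rhs(community_state(s_star), mod2), c(0, 0),
               tolerance = 1e-12)
})

test_that("two-species extended dynamics match the printed four-equation form", {
  # fixed hand-checked state
  mod <- two_species_model()
  st <- community_state(c(0.5, 0.5), matrix(c(0.5, 0.1, 0.1, 0.5), 2))
  d <- hgt_rhs(st, mod)
  expect_equal(d$ds, c(-0.088, -0.090), tolerance = 1e-12)
  expect_equal(c(d$dp[1, 2], d$dp[2, 1]), c(0.0055, 0.0055), tolerance = 1e-12)
  # randomized states against the independently coded pairwise oracle
  for (seed in 1:5) {
    set.seed(seed)
    mu <- runif(2, 0.3, 0.9)
    st <- random_state(2, seed + 100)
    mod <- two_species_model(mu = mu, eta = c(0.1, 0.05)[1 + seed %% 2])
    o <- two_species_rhs_oracle(
      st$s[1], st$s[2], st$p[1, 2], st$p[2, 1],
      mu[1], mu[2], mod$lambda[2, 1], mod$lambda[1, 2],
      g1 = mod$gamma[1, 2], g2 = mod$gamma[2, 1],
      eta1 = mod$eta[1, 1], eta2 = mod$eta[1, 2],
      k1 = mod$kappa[1, 2], k2 = mod$kappa[2, 1], D = mod$D
    )
    d <- hgt_rhs(st, mod)
    expect_equal(c(d$ds, d$dp[1, 2], d$dp[2, 1]), unname(o), tolerance = 1e-12)
  }
})

test_that("extended dynamics reduce to the classic model without gene flow", {
  mod <- random_hgt_model(4, seed = 3, eta = 0)
  st <- community_state(runif(4, 0.1, 0.4)) # no transconjugants
  d <- hgt_rhs(st, mod)
  expect_identical(d$ds, classic_rhs(st, mod))
  expect_equal(d$dp[row(d$dp) != col(d$dp)], rep(0, 12))
})

test_that("transfer vanishes at full penetrance p = s", {
  mod <- random_hgt_model(3, seed = 7, eta = 0.3)
  s <- c(0.3, 0.2, 0.4)
  st <- community_state(s, matrix(s, 3, 3)) # p[i, j] = s[i] everywhere
  d <- hgt_rhs(st, mod)
  # remaining dynamics are growth and loss only: recompute them directly
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    comp <- 1 - sum(mod$gamma[, i] * s)
    growth <- mod$mu[i] * prod(1 + mod$lambda[i, -i]) * s[i] * comp
    expect_equal(d$dp[i, j], growth - (mod$D + mod$kappa[i, j]) * s[i],
                 tolerance = 1e-10)
  }
})

test_that("effective growth rates follow the penetrance-weighted product", {
  # gene 2 burdens host 1 only (host-dependent effect); diagonals neutral
  mod <- two_species_model(mu = c(0.5, 0.5), mu0 = 0.5,
                           lambda = matrix(c(0, 0, -0.2, 0), 2))
  st <- community_state(c(0.4, 0.4), matrix(c(0.4, 0, 0.2, 0.4), 2))
  # species 1 carries gene 2 at penetrance 0.5: mu1e = 0.5 * (1 - 0.2 * 0.5)
  expect_equal(effective_growth_rates(st, mod), c(0.45, 0.5))
  # all-zero effects are neutral for any penetrance
  modn <- community_model(2, mu = 0.5, mu0 = 0.5, eta = 0.1)
  expect_equal(effective_growth_rates(random_state(2, 9), modn), c(0.5, 0.5))
  # full penetrance: product over all foreign effects
  m3 <- random_hgt_model(3, seed = 4)
  s <- c(0.2, 0.3, 0.25)
  stf <- community_state(s, matrix(s, 3, 3))
  expect_equal(effective_growth_rates(stf, m3),
               m3$mu * sapply(1:3, function(i) prod(1 + m3$lambda[i, -i])))
  # extinct species keep their static rate by convention
  st0 <- community_state(c(0, 0.5), matrix(c(0, 0, 0, 0.5), 2))
  expect_equal(effective_growth_rates(st0, mod), c(0.5, 0.5))
})

test_that("species growth is the exact sum of its subpopulations' growth", {
  # mu_i^e s_i = mu_i (s_i - p_i) + mu_i (1 + lambda_j) p_i, the bookkeeping
  # identity behind the species-level equation
  for (seed in 1:10) {
    set.seed(seed)
    mu <- runif(2, 0.3, 0.9)
    mod <- two_species_model(mu = mu)
    st <- random_state(2, seed + 50)
    mue <- effective_growth_rates(st, mod)
    lhs <- mue * st$s
    rhs <- c(
      mu[1] * (st$s[1] - st$p[1, 2]) + mu[1] * (1 + mod$lambda[1, 2]) * st$p[1, 2],
      mu[2] * (st$s[2] - st$p[2, 1]) + mu[2] * (1 + mod$lambda[2, 1]) * st$p[2, 1]
    )
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("derivatives are equivariant under species relabeling", {
  m <- 4
  mod <- random_hgt_model(m, seed = 21, eta = 0.15)
  st <- random_state(m, seed = 22)
  perm <- c(3, 1, 4, 2)
  inv <- order(perm)
  mod_p <- community_model(
    m, mu = mod$mu[perm], mu0 = mod$mu0[perm],
    gamma = mod$gamma[perm, perm], eta = mod$eta[perm, perm],
    kappa = mod$kappa[perm, perm], D = mod$D,
    lambda = mod$lambda[perm, perm]
  )
  st_p <- community_state(st$s[perm], st$p[perm, perm])
  d <- hgt_rhs(st, mod)
  d_p <- hgt_rhs(st_p, mod_p)
  expect_equal(d_p$ds, d$ds[perm], tolerance = 1e-12)
  expect_equal(d_p$dp, d$dp[perm, perm], tolerance = 1e-12)
})

test_that("no derivative drives a zero component negative", {
  for (seed in 1:5) {
    m <- 2 + seed %% 3
    mod <- random_hgt_model(m, seed = seed + 30, eta = 0.2)
    set.seed(seed)
    s <- runif(m, 0, 0.5)
    s[1] <- 0 # one extinct species
    p <- matrix(runif(m * m), m, m) * s
    p[, m] <- 0 # one absent gene
    st <- community_state(s, p)
    d <- hgt_rhs(st, mod)
    expect_equal(d$ds[1], 0)
    off <- which(row(p) != col(p) & p == 0, arr.ind = FALSE)
    expect_true(all(d$dp[off] >= -1e-12))
  }
})

test_that("invariant violations in the state are rejected", {
  mod <- two_species_model()
  bad <- community_state(c(0.5, 0.5))
  bad$p[1, 2] <- 0.7 # beyond s_1
  expect_error(hgt_rhs(bad, mod), class = "hgtcoex_invariant_error")
  expect_error(classic_rhs(community_state(c(0.5, 0.5, 0.5)), mod),
               class = "hgtcoex_parameter_error")
})

test_that("the compiled integrator kernel matches the reference dynamics", {
  for (seed in 1:5) {
    m <- 2 + seed
    mod <- random_hgt_model(m, seed = seed + 60, eta = 0.15)
    st <- random_state(m, seed + 70)
    y <- pack_state(st)
    f_c <- make_rhs_hgt(mod, compiled = TRUE)
    f_r <- make_rhs_hgt(mod, compiled = FALSE)
    expect_equal(f_c(0, y, NULL)[[1]], f_r(0, y, NULL)[[1]], tolerance = 1e-13)
    g_c <- make_rhs_classic(mod, compiled = TRUE)
    g_r <- make_rhs_classic(mod, compiled = FALSE)
    expect_equal(g_c(0, st$s, NULL)[[1]], g_r(0, st$s, NULL)[[1]],
                 tolerance = 1e-13)
    # clipping parity for out-of-cone integrator excursions
    y_neg <- y - 0.05
    expect_equal(f_c(0, y_neg, NULL)[[1]], f_r(0, y_neg, NULL)[[1]],
                 tolerance = 1e-13)
  }
  # additive composition
  set.seed(91)
  mu <- runif(4, 0.4, 0.6)
  mod_a <- community_model(4, mu = mu, mu0 = 0.5, gamma = 0.9, eta = 0.1,
                           kappa = 0.005, D = 0.2, composition = "additive")
  y <- pack_state(random_state(4, 92))
  expect_equal(make_rhs_hgt(mod_a, TRUE)(0, y, NULL)[[1]],
               make_rhs_hgt(mod_a, FALSE)(0, y, NULL)[[1]], tolerance = 1e-13)
  # gene-dependent transfer tensor
  arr <- array(runif(27, 0, 0.3), dim = c(3, 3, 3))
  mod_t <- community_model(3, mu = c(0.5, 0.45, 0.55), mu0 = 0.5, eta = arr)
  y3 <- pack_state(random_state(3, 93))
  expect_equal(make_rhs_hgt(mod_t, TRUE)(0, y3, NULL)[[1]],
               make_rhs_hgt(mod_t, FALSE)(0, y3, NULL)[[1]], tolerance = 1e-13)
})
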