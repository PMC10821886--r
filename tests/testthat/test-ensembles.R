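test_that("growth-rate draws are reproducible and correctly distributed", {
  spec <- ensemble_spec(m = 2, n_draws = 400, mu_range = c(0.4, 0.6), seed = 5)
  mus <- sample_growth_rates(spec)
  expect_equal(dim(mus), c(400, 2))
  expect_true(all(mus >= 0.4 & mus <= 0.6))
  # LLN: sample mean within 3 standard errors of the distribution mean
  se <- sqrt(0.2^2 / 12) / sqrt(length(mus))
  expect_lt(abs(mean(mus) - 0.5), 3 * se)
  # identical draws across calls, and per-draw streams independent of subsets
  expect_identical(mus, sample_growth_rates(spec))
  expect_identical(mus[7, ], sample_growth_rates(spec, draws = 7)[1, ])
  # gaussian variant: ~99.7% within 3 sd
  spg <- ensemble_spec(m = 20, n_draws = 100, distribution = "gaussian",
                       mu_mean = 0.5, mu_sd = 0.05, seed = 5)
  g <- sample_growth_rates(spg)
  expect_gt(mean(g > 0.35 & g < 0.65), 0.985)
  expect_true(all(g > 0))
})

test_that("fitness effects derive from rates with the chosen host dependence", {
  mu <- c(0.6, 0.5, 0.45)
  L <- fitness_effects_from_rates(mu, 0.5)
  expect_equal(L, matrix(c(0.2, 0, -0.1), 3, 3, byrow = TRUE))
  expect_equal(fitness_effects_from_rates(c(0.5, 0.5), 0.5),
               matrix(0, 2, 2))
  expect_equal(fitness_effects_from_rates(mu, 0.5, composition = "additive"),
               matrix(c(0.1, 0, -0.05), 3, 3, byrow = TRUE))
  # sign epistasis with certain flips inverts every off-host effect
  set.seed(1)
  Ls <- fitness_effects_from_rates(mu, 0.5, epistasis = "sign", flip_prob = 1)
  expect_equal(diag(Ls), diag(L))
  off <- row(L) != col(L)
  expect_equal(Ls[off], -L[off])
  # magnitude epistasis rescales but never changes sign
  set.seed(2)
  Lm <- fitness_effects_from_rates(mu, 0.5, epistasis = "magnitude", spread = 0.5)
  expect_equal(diag(Lm), diag(L))
  expect_true(all(sign(Lm[off]) == sign(L[off])))
  expect_true(all(abs(Lm[off]) <= 1.5 * abs(L[off]) + 1e-12))
})

test_that("feasibility is 1 without competition and reproducible bit-exactly", {
  spec <- ensemble_spec(m = 2, n_draws = 40, mu_range = c(0.4, 0.6),
                        gamma = 0, eta = 0, seed = 3)
  est <- estimate_feasibility(spec)
  expect_equal(est$feasibility, 1)
  expect_equal(est$se, 0)
  est2 <- estimate_feasibility(spec)
  expect_identical(tidy(est), tidy(est2))
  gl <- glance(est)
  expect_equal(gl$n_coexist, 40L)
  expect_equal(gl$se, sqrt(1 * 0 / 40))
})

test_that("feasibility is invariant under relabeling of uniform ensembles", {
  # with exchangeable constants, feasibility depends only on the draw seed
  s1 <- ensemble_spec(m = 3, n_draws = 60, mu_range = c(0.4, 0.6),
                      gamma = 0.9, eta = 0.1, seed = 11)
  est <- estimate_feasibility(s1)
  # relabeling species permutes each drawn community; outcome counts match
  draws <- tidy(est)
  perm_coexist <- purrr::map_lgl(seq_len(nrow(draws)), function(k) {
    mu <- draws$mu[[k]][c(3, 1, 2)]
    L <- fitness_effects_from_rates(mu, 0.5)
    mod <- community_model(3, mu = mu, mu0 = 0.5, gamma = 0.9, eta = 0.1,
                           kappa = 0.005, D = 0.2, lambda = L)
    sim <- simulate_community(mod, max_extend = 6400, dt = Inf)
    all(sim$final_state$s > 0.01)
  })
  expect_equal(perm_coexist, draws$coexist)
})

test_that("species-number scans nest the single-point estimator", {
  spec <- ensemble_spec(n_draws = 30, mu_range = c(0.4, 0.6), gamma = 0.9,
                        seed = 9)
  curve <- feasibility_vs_species_number(spec, m_values = c(2, 3), eta = c(0, 0.1))
  expect_equal(nrow(curve), 4)
  point <- spec
  point$m <- 2L
  point$eta <- 0
  expect_equal(curve$feasibility[curve$m == 2 & curve$eta == 0],
               estimate_feasibility(point)$feasibility)
  expect_true(all(curve$se >= 0))
  expect_true(all(is.finite(curve$mean_shannon)))
})

test_that("the diversity limit is the first crossing below epsilon", {
  curve <- tibble::tibble(
    m = rep(2:5, 2), eta = rep(c(0, 0.2), each = 4),
    feasibility = c(1, 0.5, 0, 0, 1, 1, 0.5, 0.2), n_draws = 100
  )
  nl <- diversity_limit(curve, epsilon = 0.01)
  expect_equal(nl$N_star[nl$eta == 0], 4)
  expect_equal(nl$N_star[nl$eta == 0.2], Inf) # never crosses: beyond range
  all_zero <- tibble::tibble(m = 2:4, eta = 0, feasibility = 0, n_draws = 100)
  expect_equal(diversity_limit(all_zero)$N_star, 2)
  # default epsilon is one observed coexistence event in n_draws
  near_zero <- tibble::tibble(m = 2:4, eta = 0,
                              feasibility = c(0.5, 1 / 100, 0.5 / 100),
                              n_draws = 100)
  expect_equal(diversity_limit(near_zero)$N_star, 4)
})

test_that("zero-width growth-rate draws give perfectly neutral communities", {
  sp <- diversity_vs_rate_spread(m = 8, n_draws = 3, width_range = c(0, 0),
                                 seed = 2, max_extend = NULL)
  expect_equal(sp$sd_mu, rep(0, 3))
  expect_equal(sp$shannon, rep(8, 3), tolerance = 1e-6)
  expect_equal(sp$n_survivors, rep(8L, 3))
  # reproducible under the same seed
  sp2 <- diversity_vs_rate_spread(m = 8, n_draws = 3, width_range = c(0, 0),
                                  seed = 2, max_extend = NULL)
  expect_identical(sp, sp2)
})

test_that("without transfer the effective rates equal the drawn rates", {
  rc <- rate_convergence_experiment(m = 6, eta = c(0, 0.2), n_draws = 4,
                                    seed = 4, t_max = 100, max_extend = NULL)
  expect_equal(rc$sd_mu_e[rc$eta == 0], rc$sd_mu[rc$eta == 0])
  # the same draws are reused across eta values
  expect_equal(rc$sd_mu[rc$eta == 0], rc$sd_mu[rc$eta == 0.2])
})
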