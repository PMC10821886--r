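test_that("integration reaches known equilibria", {
  mod1 <- community_model(1, mu = 0.5, eta = 0, kappa = 0, D = 0.2)
  sim <- simulate_community(mod1, init = 0.1)
  expect_equal(sim$final_state$s, 0.6, tolerance = 1e-6)
  expect_true(sim$reached_steady)
  expect_lt(sim$rhs_norm, 1e-8)

  mod2 <- community_model(2, mu = 0.5, gamma = 0.9, eta = 0)
  sim2 <- simulate_community(mod2, max_extend = 6400)
  expect_equal(sim2$final_state$s, rep(0.06 / 0.19, 2), tolerance = 1e-5)
})

test_that("neutral elements leave the abundance dynamics unchanged", {
  # all lambda = 0: transfer shuffles neutral genes, s is untouched
  mod_hgt <- community_model(4, mu = 0.5, mu0 = 0.5, gamma = 0.9, eta = 0.2)
  mod_lv <- community_model(4, mu = 0.5, mu0 = 0.5, gamma = 0.9, eta = 0)
  init <- community_state(c(0.4, 0.3, 0.2, 0.1))
  s_hgt <- simulate_community(mod_hgt, init = init)$final_state$s
  s_lv <- simulate_community(mod_lv, init = init)$final_state$s
  expect_equal(s_hgt, s_lv, tolerance = 1e-7)
  # and the full trajectories agree on the output grid
  y1 <- simulate_community(mod_hgt, init = init, dt = 10)$y[, 1:4]
  y2 <- simulate_community(mod_lv, init = init, dt = 10)$y[, 1:4]
  expect_equal(y1, y2, tolerance = 1e-7)
})

test_that("without transfer, transconjugant pools stay empty", {
  mod <- random_hgt_model(3, seed = 2, eta = 0)
  sim <- simulate_community(mod, dt = 20)
  expect_true(all(sim$y[, 4:9] == 0))
})

test_that("survivor classification applies the 0.01 threshold semantics", {
  mk <- function(s) {
    structure(list(final_state = community_state(s), m = length(s)),
              class = "community_sim")
  }
  expect_equal(as.integer(classify_outcome(mk(c(0.3158, 0.3158)))), c(1L, 2L))
  expect_true(attr(classify_outcome(mk(c(0.3158, 0.3158))), "coexist"))
  expect_equal(as.integer(classify_outcome(mk(c(0.6, 1e-5)))), 1L)
  # positivity below threshold is not survival
  expect_length(classify_outcome(mk(c(0.009, 0.009))), 0)
})

test_that("integration is deterministic and preserves trajectory invariants", {
  mod <- random_hgt_model(5, seed = 13, eta = 0.25)
  s1 <- simulate_community(mod, dt = 5)
  s2 <- simulate_community(mod, dt = 5)
  expect_identical(s1$y, s2$y) # no hidden randomness
  m <- 5
  s_traj <- s1$y[, 1:m]
  expect_true(all(s_traj >= -1e-8))
  # subpopulation bound along the whole trajectory; the packed layout is
  # row-major, so column k of the p block belongs to host ceiling(k/(m-1))
  p_traj <- s1$y[, -(1:m), drop = FALSE]
  host <- rep(seq_len(m), each = m - 1)
  expect_true(all(p_traj <= s_traj[, host] + 1e-8))
  expect_true(all(p_traj >= -1e-8))
})

test_that("steady-state extension resolves slow competitive exclusion", {
  # just outside the coexistence band at gamma = 0.99: exclusion is too slow
  # for the 200 h horizon but certain at steady state
  mod <- community_model(2, mu = c(0.55, 0.5), gamma = 0.99, eta = 0)
  plain <- simulate_community(mod, t_max = 200)
  extended <- simulate_community(mod, t_max = 200, max_extend = 6400)
  expect_false(plain$reached_steady)
  expect_identical(classify_two_species(0.55, 0.5, 0.99, 0.99, 0.2), "s1_wins")
  expect_gt(plain$final_state$s[2], 0.01) # transient still above threshold
  expect_lt(extended$final_state$s[2], 0.01) # resolved by extension
  expect_gt(extended$t_end, 200)
})

test_that("phase diagrams match the analytic condition away from boundaries", {
  grid <- c(0.3, 0.45, 0.6, 0.75, 0.9)
  pd <- phase_diagram(grid, grid, gamma1 = 0.99, gamma2 = 0.99, eta = 0)
  analytic <- classify_two_species(pd$mu1, pd$mu2, 0.99, 0.99, 0.2)
  expect_equal(as.character(pd$label), analytic)
  expect_false(any(pd$error))
  # without competition, coexistence wherever both rates beat dilution
  pd0 <- phase_diagram(c(0.1, 0.5), c(0.15, 0.7), gamma1 = 0, gamma2 = 0,
                       eta = 0, max_extend = 6400)
  expect_equal(as.character(pd0$label),
               classify_two_species(pd0$mu1, pd0$mu2, 0, 0, 0.2))
  # transfer enlarges the coexistence region (cell-wise superset)
  pdh <- phase_diagram(grid, grid, gamma1 = 0.99, gamma2 = 0.99, eta = 0.1)
  was_coex <- pd$label == "coexist"
  expect_true(all(pdh$label[was_coex] == "coexist"))
  expect_gt(sum(pdh$label == "coexist"), sum(was_coex))
})

test_that("tidy and glance expose trajectories and summaries", {
  mod <- two_species_model()
  sim <- simulate_community(mod, dt = 50)
  td <- tidy(sim, subpopulations = TRUE)
  expect_named(td, c("time", "species", "kind", "origin", "abundance"))
  expect_setequal(unique(td$kind), c("s", "p"))
  gl <- glance(sim)
  expect_equal(gl$m, 2)
  expect_true(gl$shannon >= 1 && gl$shannon <= 2)
})
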