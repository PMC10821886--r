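#' Specify a randomized-parameter coexistence ensemble
#'
#' An ensemble draws `n_draws` growth-rate vectors for a community of `m`
#' species, simulates each community to steady state, and scores the
#' fraction that coexists (all species above the survival threshold). The
#' defaults encode the standard two-species protocol: `mu ~ U(0, 1)^2`,
#' 2000 draws, `mu0 = 0.5`, `kappa = 0.005`, `D = 0.2`. Multi-species
#' scans typically use `mu_range = c(0.4, 0.6)` and `gamma = 0.9`.
#'
#' MGE fitness effects are derived from the drawn rates with
#' [fitness_effects_from_rates()]; `epistasis` selects the host dependence
#' of the effects (none by default: each element has the same effect in
#' every host).
#'
#' @param m species number.
#' @param n_draws number of randomized communities.
#' @param distribution growth-rate distribution: `"uniform"` over
#'   `mu_range`, or `"gaussian"` with moments `mu_mean`, `mu_sd`
#'   (truncated at 0; the moments are a documented convention).
#' @param mu_range uniform support for the growth rates (1/h).
#' @param mu_mean,mu_sd Gaussian variant moments.
#' @param seed master seed; per-draw streams are derived from it.
#' @param mu0 basal growth rate (scalar or length `m`).
#' @param gamma,eta,kappa,D shared model constants (see [community_model()]).
#' @param composition growth-rate composition mode.
#' @param epistasis host dependence of MGE fitness effects: `"none"`,
#'   `"magnitude"` (per-host rescaling of the magnitude, sign preserved),
#'   or `"sign"` (per-host random sign flips).
#' @param epistasis_spread half-width of the multiplicative magnitude
#'   jitter, `U(1 - spread, 1 + spread)`.
#' @param sign_flip_prob probability of inverting the effect sign in a
#'   foreign host (sign mode).
#' @param threshold survival threshold for coexistence.
#' @param t_max,max_extend,steady_tol integration protocol (see
#'   [simulate_community()]); ensembles extend past `t_max` by default so
#'   that slow competitive exclusion is resolved rather than mistaken for
#'   coexistence.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(m = 2, n_draws = 2000,
                          distribution = c("uniform", "gaussian"),
                          mu_range = c(0, 1), mu_mean = 0.5, mu_sd = 0.1,
                          seed = 1, mu0 = 0.5, gamma = 0.9, eta = 0,
                          kappa = 0.005, D = 0.2,
                          composition = c("multiplicative", "additive"),
                          epistasis = c("none", "magnitude", "sign"),
                          epistasis_spread = 0.5, sign_flip_prob = 0.5,
                          threshold = 0.01, t_max = 200, max_extend = 6400,
                          steady_tol = 1e-8) {
  distribution <- match.arg(distribution)
  composition <- match.arg(composition)
  epistasis <- match.arg(epistasis)
  if (n_draws < 1) abort("`n_draws` must be >= 1.", class = "hgtcoex_parameter_error")
  if (distribution == "uniform" &&
      (length(mu_range) != 2 || mu_range[2] <= mu_range[1] || mu_range[1] < 0)) {
    abort("`mu_range` must be an increasing non-negative pair.",
          class = "hgtcoex_parameter_error")
  }
  if (distribution == "gaussian" && mu_sd <= 0) {
    abort("`mu_sd` must be positive.", class = "hgtcoex_parameter_error")
  }
  structure(
    list(m = as.integer(m), n_draws = as.integer(n_draws),
         distribution = distribution, mu_range = mu_range,
         mu_mean = mu_mean, mu_sd = mu_sd, seed = seed, mu0 = mu0,
         gamma = gamma, eta = eta, kappa = kappa, D = D,
         composition = composition, epistasis = epistasis,
         epistasis_spread = epistasis_spread,
         sign_flip_prob = sign_flip_prob, threshold = threshold,
         t_max = t_max, max_extend = max_extend, steady_tol = steady_tol),
    class = "ensemble_spec"
  )
}

#' Draw growth-rate vectors for ensemble draws
#'
#' Each draw has its own random stream derived from the master seed and the
#' draw index, so any subset of draws reproduces bit-exactly in any order.
#'
#' @param spec an [ensemble_spec()].
#' @param draws draw indices (default all).
#' @return matrix with one row per draw and `m` columns.
#' @export
sample_growth_rates <- function(spec, draws = seq_len(spec$n_draws)) {
  stopifnot(inherits(spec, "ensemble_spec"))
  out <- matrix(NA_real_, length(draws), spec$m)
  for (k in seq_along(draws)) {
    out[k, ] <- with_seed(derive_seed(spec$seed, draws[k], "mu"), {
      draw_mu(spec)
    })
  }
  out
}

draw_mu <- function(spec) {
  if (spec$distribution == "uniform") {
    runif(spec$m, spec$mu_range[1], spec$mu_range[2])
  } else {
    x <- rnorm(spec$m, spec$mu_mean, spec$mu_sd)
    while (any(x <= 0)) {
      x[x <= 0] <- rnorm(sum(x <= 0), spec$mu_mean, spec$mu_sd)
    }
    x
  }
}

#' MGE fitness-effect matrix implied by drawn growth rates
#'
#' Given static rates `mu` and basal rates `mu0`, the fitness effect of the
#' species-`j` element is `lambda_j = mu_j/mu0_j - 1` (multiplicative) or
#' `mu_j - mu0_j` (additive). With `epistasis = "none"` every host `i`
#' experiences the same effect (`lambda[i, j] = lambda_j`). Magnitude
#' epistasis rescales the effect per foreign host by a multiplicative jitter
#' `U(1 - spread, 1 + spread)` (sign preserved); sign epistasis inverts the
#' sign in a foreign host with probability `flip_prob`. Host-specific
#' randomness is consumed from the current RNG stream; within an ensemble
#' this is the per-draw stream.
#'
#' @param mu,mu0 static and basal growth rates (length `m`).
#' @param composition `"multiplicative"` or `"additive"`.
#' @param epistasis `"none"`, `"magnitude"`, or `"sign"`.
#' @param spread magnitude-jitter half-width.
#' @param flip_prob sign-flip probability.
#' @return `m x m` matrix `lambda[i, j]`.
#' @export
fitness_effects_from_rates <- function(mu, mu0,
                                       composition = c("multiplicative", "additive"),
                                       epistasis = c("none", "magnitude", "sign"),
                                       spread = 0.5, flip_prob = 0.5) {
  composition <- match.arg(composition)
  epistasis <- match.arg(epistasis)
  m <- length(mu)
  mu0 <- rep_len(mu0, m)
  if (any(mu0 <= 0)) abort("`mu0` must be positive.", class = "hgtcoex_parameter_error")
  lam <- switch(composition,
    multiplicative = mu / mu0 - 1,
    additive = mu - mu0
  )
  L <- matrix(lam, m, m, byrow = TRUE)
  if (epistasis == "magnitude" && m > 1) {
    jit <- matrix(runif(m * m, 1 - spread, 1 + spread), m, m)
    diag(jit) <- 1
    L <- L * jit
  } else if (epistasis == "sign" && m > 1) {
    flip <- matrix(runif(m * m) < flip_prob, m, m)
    diag(flip) <- FALSE
    L[flip] <- -L[flip]
  }
  L
}

# Simulate one randomized community; returns the per-draw record.
run_ensemble_draw <- function(spec, draw, mu = NULL) {
  seed_k <- derive_seed(spec$seed, draw, "mu")
  rec <- with_seed(seed_k, {
    mu_k <- if (is.null(mu)) draw_mu(spec) else mu
    L <- fitness_effects_from_rates(mu_k, spec$mu0, spec$composition,
                                    spec$epistasis, spec$epistasis_spread,
                                    spec$sign_flip_prob)
    mod <- community_model(spec$m, mu = mu_k, mu0 = spec$mu0,
                           gamma = spec$gamma, eta = spec$eta,
                           kappa = spec$kappa, D = spec$D, lambda = L,
                           composition = spec$composition)
    sim <- try(simulate_community(mod, t_max = spec$t_max,
                                  max_extend = spec$max_extend,
                                  steady_tol = spec$steady_tol, dt = Inf),
               silent = TRUE)
    if (inherits(sim, "try-error")) {
      list(mu = mu_k, failed = TRUE)
    } else {
      s_fin <- sim$final_state$s
      list(mu = mu_k, failed = FALSE, final_s = s_fin,
           survivors = which(s_fin > spec$threshold),
           reached_steady = sim$reached_steady, t_end = sim$t_end,
           mu_e = effective_growth_rates(sim$final_state, mod))
    }
  })
  rec
}

#' Monte-Carlo coexistence feasibility of randomized communities
#'
#' Draws `n_draws` growth-rate vectors, simulates each community to steady
#' state, and estimates the coexistence feasibility as the fraction of draws
#' in which every species ends above the survival threshold, with the
#' binomial standard error `sqrt(f(1 - f)/n)`. Per-draw records (drawn
#' rates, survivors, final abundances, Shannon diversity raw and
#' thresholded, steady-state flags) are retained for audit via [tidy()].
#'
#' @param spec an [ensemble_spec()].
#' @return an object of class `feasibility_estimate`; see [glance()] for the
#'   one-row summary and [tidy()] for per-draw records.
#' @export
estimate_feasibility <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  recs <- purrr::map(seq_len(spec$n_draws), function(k) run_ensemble_draw(spec, k))
  failed <- purrr::map_lgl(recs, "failed")
  if (mean(failed) > 0.01) {
    abort(sprintf("%d of %d draws failed to integrate.",
                  sum(failed), spec$n_draws),
          class = "hgtcoex_ensemble_error")
  }
  ok <- recs[!failed]
  draws <- tibble(
    draw = which(!failed),
    mu = purrr::map(ok, "mu"),
    final_s = purrr::map(ok, "final_s"),
    survivors = purrr::map(ok, "survivors"),
    n_survivors = purrr::map_int(ok, ~ length(.x$survivors)),
    coexist = purrr::map_lgl(ok, ~ length(.x$survivors) == spec$m),
    shannon = purrr::map_dbl(ok, ~ safe_shannon(.x$final_s)),
    shannon_thresholded = purrr::map_dbl(
      ok, ~ safe_shannon(.x$final_s, spec$threshold)),
    mu_e = purrr::map(ok, "mu_e"),
    reached_steady = purrr::map_lgl(ok, "reached_steady"),
    t_end = purrr::map_dbl(ok, "t_end")
  )
  n <- nrow(draws)
  f <- mean(draws$coexist)
  structure(
    list(spec = spec, draws = draws, n_draws = n,
         n_failed = sum(failed), n_coexist = sum(draws$coexist),
         feasibility = f, se = sqrt(f * (1 - f) / n)),
    class = "feasibility_estimate"
  )
}

safe_shannon <- function(s, threshold = NULL) {
  if (sum(if (is.null(threshold)) s else s * (s > threshold)) <= 0) {
    return(NA_real_)
  }
  shannon_index(s, threshold)
}

#' @export
print.feasibility_estimate <- function(x, ...) {
  cat(sprintf(
    "<feasibility_estimate> m = %d, eta = %s: %d / %d coexist, feasibility = %.4f (SE %.4f)\n",
    x$spec$m, summary_num(x$spec$eta), x$n_coexist, x$n_draws,
    x$feasibility, x$se))
  invisible(x)
}

#' Coexistence feasibility across gene transfer rates
#'
#' Re-estimates the feasibility of the same randomized ensemble (identical
#' growth-rate draws, shared seed) for each transfer rate, the protocol
#' behind the feasibility-versus-eta curves.
#'
#' @param spec an [ensemble_spec()] (its `eta` is overridden).
#' @param eta transfer rates to scan (1/h).
#' @return a tibble (class `feasibility_scan`): `eta`, `n_draws`,
#'   `n_coexist`, `feasibility`, `se`, and the estimates in a list column.
#' @export
feasibility_vs_transfer_rate <- function(spec, eta = c(0, 0.05, 0.1, 0.15, 0.2)) {
  ests <- purrr::map(eta, function(e) {
    sp <- spec; sp$eta <- e
    estimate_feasibility(sp)
  })
  out <- tibble(
    eta = eta,
    n_draws = purrr::map_int(ests, "n_draws"),
    n_coexist = purrr::map_int(ests, "n_coexist"),
    feasibility = purrr::map_dbl(ests, "feasibility"),
    se = purrr::map_dbl(ests, "se"),
    estimate = ests
  )
  class(out) <- c("feasibility_scan", class(out))
  out
}

#' Coexistence feasibility as a function of species number
#'
#' Sweeps the community size for each transfer rate and estimates the
#' feasibility at every `(m, eta)` combination, the protocol behind the
#' diversity-limit analysis: without gene flow the curve collapses to zero
#' beyond a modest species number, while transfer shifts or removes the
#' limit. Shannon-diversity distributions over the final states accompany
#' each point (available per draw via the `estimate` list column).
#'
#' @param spec template [ensemble_spec()]; its `m` and `eta` are overridden.
#' @param m_values community sizes to scan.
#' @param eta transfer rates to scan.
#' @return a tibble (class `feasibility_curve`) with one row per `(m, eta)`:
#'   `feasibility`, `se`, counts, mean Shannon diversity (raw and
#'   thresholded), and the full estimates in a list column.
#' @export
feasibility_vs_species_number <- function(spec, m_values = seq(2, 26, by = 2),
                                          eta = c(0, 0.1, 0.2)) {
  grid <- expand.grid(m = m_values, eta = eta, KEEP.OUT.ATTRS = FALSE)
  ests <- purrr::pmap(grid, function(m, eta) {
    sp <- spec; sp$m <- as.integer(m); sp$eta <- eta
    estimate_feasibility(sp)
  })
  out <- tibble(
    m = as.integer(grid$m), eta = grid$eta,
    n_draws = purrr::map_int(ests, "n_draws"),
    n_coexist = purrr::map_int(ests, "n_coexist"),
    feasibility = purrr::map_dbl(ests, "feasibility"),
    se = purrr::map_dbl(ests, "se"),
    mean_shannon = purrr::map_dbl(ests, ~ mean(.x$draws$shannon, na.rm = TRUE)),
    mean_shannon_thresholded = purrr::map_dbl(
      ests, ~ mean(.x$draws$shannon_thresholded, na.rm = TRUE)),
    estimate = ests
  )
  class(out) <- c("feasibility_curve", class(out))
  out
}

#' Diversity limit of a feasibility-versus-species-number curve
#'
#' The diversity limit `N*` is the smallest community size at which the
#' coexistence feasibility drops below `epsilon` (by default `1/n_draws`,
#' i.e. zero observed coexistence). `Inf` marks a curve that never crosses
#' within the scanned range.
#'
#' @param curve a [feasibility_vs_species_number()] result, or any data
#'   frame with columns `m`, `eta`, `feasibility`, `n_draws`.
#' @param epsilon feasibility cutoff; `NULL` uses `1/n_draws` per row.
#' @return a tibble with one row per `eta`: `eta`, `N_star`.
#' @export
diversity_limit <- function(curve, epsilon = NULL) {
  stopifnot(all(c("m", "eta", "feasibility", "n_draws") %in% names(curve)))
  curve |>
    as_tibble() |>
    dplyr::group_by(.data$eta) |>
    dplyr::arrange(.data$m, .by_group = TRUE) |>
    dplyr::summarise(N_star = {
      eps <- if (is.null(epsilon)) 1 / .data$n_draws else rep_len(epsilon, length(.data$m))
      below <- .data$feasibility < eps
      if (any(below)) as.numeric(.data$m[which(below)[1]]) else Inf
    }, .groups = "drop")
}

#' Steady-state diversity versus growth-rate spread (no gene flow)
#'
#' The classic-model experiment relating fitness variability to diversity:
#' for each draw, the width `w` of the growth-rate distribution is itself
#' randomized (uniform on `width_range`), rates are drawn from
#' `U(center - w/2, center + w/2)`, the community is integrated without
#' HGT, and the realized standard deviation of the rates is recorded
#' together with the steady-state Shannon diversity. Diversity declines
#' with the spread: similar competitors coexist, dissimilar ones collapse
#' to the fastest few.
#'
#' @param m species number (20 in the standard protocol).
#' @param n_draws number of randomized communities (5000 in the standard
#'   protocol).
#' @param width_range range of the full distribution width (1/h).
#' @param center center of the growth-rate distribution (1/h).
#' @param gamma,D model constants.
#' @param seed master seed.
#' @param threshold survival threshold for the survivor count.
#' @param t_max,max_extend integration protocol.
#' @return a tibble (class `spread_experiment`) with one row per draw:
#'   `width`, `sd_mu`, `shannon`, `shannon_thresholded`, `n_survivors`.
#' @export
diversity_vs_rate_spread <- function(m = 20, n_draws = 5000,
                                     width_range = c(0, 0.5), center = 0.5,
                                     gamma = 0.9, D = 0.2, seed = 1,
                                     threshold = 0.01,
                                     t_max = 200, max_extend = 6400) {
  recs <- purrr::map(seq_len(n_draws), function(k) {
    with_seed(derive_seed(seed, k, "width"), {
      w <- runif(1, width_range[1], width_range[2])
      mu <- runif(m, center - w / 2, center + w / 2)
      # classic model: no gene flow, so mobile-element bookkeeping is inert
      mod <- community_model(m, mu = mu, mu0 = mu, gamma = gamma,
                             eta = 0, kappa = 0, D = D)
      sim <- simulate_community(mod, t_max = t_max, max_extend = max_extend,
                                dt = Inf)
      s_fin <- sim$final_state$s
      list(width = w, sd_mu = sd(mu),
           shannon = safe_shannon(s_fin),
           shannon_thresholded = safe_shannon(s_fin, threshold),
           n_survivors = survivor_count(s_fin, threshold))
    })
  })
  out <- tibble(
    draw = seq_len(n_draws),
    width = purrr::map_dbl(recs, "width"),
    sd_mu = purrr::map_dbl(recs, "sd_mu"),
    shannon = purrr::map_dbl(recs, "shannon"),
    shannon_thresholded = purrr::map_dbl(recs, "shannon_thresholded"),
    n_survivors = purrr::map_int(recs, "n_survivors")
  )
  class(out) <- c("spread_experiment", class(out))
  out
}

#' Convergence of effective growth rates under gene flow
#'
#' For each transfer rate, randomized HGT communities are integrated to
#' steady state and the across-species standard deviation of the effective
#' growth rates [effective_growth_rates()] is recorded and compared with the
#' standard deviation of the drawn static rates. Gene flow homogenizes
#' realized fitness (dynamic neutrality): the residual spread of `mu^e`
#' shrinks as `eta` grows.
#'
#' @param m species number.
#' @param eta transfer rates to compare (1/h).
#' @param n_draws randomized communities per transfer rate.
#' @param mu_range uniform growth-rate support (1/h).
#' @param gamma,kappa,D,mu0 model constants.
#' @param seed master seed (shared draws across `eta` values).
#' @param t_max,max_extend integration protocol.
#' @return a tibble (class `rate_convergence`) with one row per
#'   `(eta, draw)`: `sd_mu` (static rates) and `sd_mu_e` (effective rates
#'   at steady state, across all species).
#' @export
rate_convergence_experiment <- function(m = 20, eta = c(0.05, 0.1, 0.2),
                                        n_draws = 50, mu_range = c(0.4, 0.6),
                                        gamma = 0.9, kappa = 0.005, D = 0.2,
                                        mu0 = 0.5, seed = 1,
                                        t_max = 200, max_extend = 6400) {
  base <- ensemble_spec(m = m, n_draws = n_draws, mu_range = mu_range,
                        seed = seed, mu0 = mu0, gamma = gamma, eta = 0,
                        kappa = kappa, D = D, t_max = t_max,
                        max_extend = max_extend)
  out <- purrr::map_dfr(eta, function(e) {
    sp <- base; sp$eta <- e
    est <- estimate_feasibility(sp)
    tibble(
      eta = e, draw = est$draws$draw,
      sd_mu = purrr::map_dbl(est$draws$mu, sd),
      sd_mu_e = purrr::map_dbl(est$draws$mu_e, sd),
      n_survivors = est$draws$n_survivors
    )
  })
  class(out) <- c("rate_convergence", class(out))
  out
}
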