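#' Protocol for growth-rate perturbation experiments
#'
#' Defines the piecewise-deterministic protocol used to test whether gene
#' flow stabilizes diversity against environmental fluctuations. A
#' simulation starts from perfect neutrality (all species share the growth
#' rate `mu_init` and equal abundances) and is split into sequential
#' intervals of random duration (exponential with mean `mean_interval`,
#' truncated to `interval_bounds`); within an interval the dynamics are
#' deterministic, and at each interval end every species' growth rate is
#' multiplied by an independent `1 + U(-magnitude, +magnitude)` factor
#' (relative perturbations of magnitude below 5% by default).
#'
#' The perturbation schedule of a replicate (interval durations and
#' perturbation factors) is drawn from a stream derived from `(seed,
#' replicate)` before any dynamics run, so the with- and without-HGT arms of
#' a paired comparison experience identical environments.
#'
#' @param m species number.
#' @param horizon total simulated time (h).
#' @param magnitude relative perturbation bound, in `[0, 1)`.
#' @param n_replicates number of repeated simulations.
#' @param seed master seed.
#' @param eta transfer rate of the with-HGT arm (1/h).
#' @param gamma,kappa,D,mu0 model constants.
#' @param mu_init initial common growth rate (1/h).
#' @param mean_interval mean interval duration (h).
#' @param interval_bounds truncation bounds on interval durations (h).
#' @param perturb_target perturb the static rates `"mu"` (default) or the
#'   basal rates `"mu0"`.
#' @param recompute_lambda recompute MGE fitness effects from the perturbed
#'   rates after each perturbation (default) or keep them frozen at their
#'   initial values.
#' @param extinction_floor abundances below this are held at zero between
#'   intervals to prevent numerically extinct species from reviving.
#' @param threshold survival threshold for survivor counts.
#' @param rtol,atol integrator tolerances.
#' @return an object of class `fluctuation_protocol`.
#' @export
fluctuation_protocol <- function(m = 20, horizon = 2000, magnitude = 0.05,
                                 n_replicates = 50, seed = 1, eta = 0.2,
                                 gamma = 0.9, kappa = 0.005, D = 0.2,
                                 mu0 = 0.5, mu_init = 0.5,
                                 mean_interval = 25,
                                 interval_bounds = c(1, 100),
                                 perturb_target = c("mu", "mu0"),
                                 recompute_lambda = TRUE,
                                 extinction_floor = 1e-6, threshold = 0.01,
                                 rtol = 1e-8, atol = 1e-10) {
  perturb_target <- match.arg(perturb_target)
  if (magnitude < 0 || magnitude >= 1) {
    abort("`magnitude` must lie in [0, 1).", class = "hgtcoex_parameter_error")
  }
  if (horizon <= 0 || n_replicates < 1) {
    abort("`horizon` must be positive and `n_replicates` >= 1.",
          class = "hgtcoex_parameter_error")
  }
  structure(
    list(m = as.integer(m), horizon = horizon, magnitude = magnitude,
         n_replicates = as.integer(n_replicates), seed = seed, eta = eta,
         gamma = gamma, kappa = kappa, D = D, mu0 = mu0, mu_init = mu_init,
         mean_interval = mean_interval, interval_bounds = interval_bounds,
         perturb_target = perturb_target,
         recompute_lambda = recompute_lambda,
         extinction_floor = extinction_floor, threshold = threshold,
         rtol = rtol, atol = atol),
    class = "fluctuation_protocol"
  )
}

#' Apply one random relative perturbation to growth rates
#'
#' `mu_i' = mu_i (1 + u_i)` with `u_i ~ U(-magnitude, +magnitude)` i.i.d.;
#' rates stay positive for any magnitude below 1. Randomness is consumed
#' from the current RNG stream.
#'
#' @param mu growth-rate vector (1/h).
#' @param magnitude relative bound in `[0, 1)`.
#' @return perturbed growth-rate vector.
#' @export
perturb_growth_rates <- function(mu, magnitude) {
  if (magnitude < 0 || magnitude >= 1) {
    abort("`magnitude` must lie in [0, 1).", class = "hgtcoex_parameter_error")
  }
  mu * (1 + runif(length(mu), -magnitude, magnitude))
}

# Pre-draw the environmental schedule of one replicate: interval durations
# covering the horizon, then one perturbation-factor vector per interval end.
draw_schedule <- function(protocol, replicate) {
  with_seed(derive_seed(protocol$seed, replicate, "perturb"), {
    durations <- numeric(0)
    total <- 0
    while (total < protocol$horizon) {
      d <- stats::rexp(1, rate = 1 / protocol$mean_interval)
      d <- min(max(d, protocol$interval_bounds[1]), protocol$interval_bounds[2])
      d <- min(d, protocol$horizon - total)
      durations <- c(durations, d)
      total <- total + d
    }
    factors <- matrix(
      runif(length(durations) * protocol$m,
            -protocol$magnitude, protocol$magnitude),
      nrow = length(durations)
    )
    list(durations = durations, factors = 1 + factors)
  })
}

#' Run one replicate of the growth-rate perturbation protocol
#'
#' Alternates deterministic integration over an interval with a random
#' perturbation of all growth rates, carrying the full community state
#' (abundances and transconjugant subpopulations) across intervals. MGE
#' fitness effects track the perturbed rates when `recompute_lambda` is set
#' (the default), so the mobile elements always carry the current
#' fitness (dis)advantage of their origin species. Shannon diversity and
#' survivor counts are recorded at every interval boundary.
#'
#' @param protocol a [fluctuation_protocol()].
#' @param with_hgt logical: run the arm with gene flow (`eta` from the
#'   protocol) or the no-transfer control. Both arms consume the identical
#'   perturbation schedule for a given replicate.
#' @param replicate replicate index (selects the perturbation stream).
#' @return a tibble (class `diversity_trajectory`) with columns `time`,
#'   `shannon`, `n_survivors`, plus attributes `final_state`, `mu_final`,
#'   `schedule`, `failed`.
#' @export
run_fluctuation_replicate <- function(protocol, with_hgt = TRUE,
                                      replicate = 1) {
  stopifnot(inherits(protocol, "fluctuation_protocol"))
  sched <- draw_schedule(protocol, replicate)
  m <- protocol$m
  eta <- if (with_hgt) protocol$eta else 0
  mu <- rep(protocol$mu_init, m)
  mu0 <- rep_len(protocol$mu0, m)
  lam0_own <- mu / mu0 - 1 # own-MGE effects at perfect neutrality
  lambda_frozen <- fitness_effects_from_rates(mu, mu0)
  state <- community_state(rep(1 / m, m))
  times <- 0
  shannon <- shannon_index(state$s)
  n_surv <- survivor_count(state$s, protocol$threshold)
  t_now <- 0
  failed <- FALSE
  for (k in seq_along(sched$durations)) {
    if (protocol$perturb_target == "mu") {
      mu_static <- mu
      L <- if (protocol$recompute_lambda) {
        fitness_effects_from_rates(mu, mu0)
      } else {
        lambda_frozen
      }
      if (!protocol$recompute_lambda) {
        # frozen effects: the diagonal must still match the perturbed rates
        diag(L) <- mu_static / mu0 - 1
      }
    } else {
      # basal rates perturbed; relative MGE effects stay at their t = 0 values
      mu_static <- mu0 * (1 + lam0_own)
      L <- matrix(lam0_own, m, m, byrow = TRUE)
    }
    mod <- community_model(m, mu = mu_static, mu0 = mu0, gamma = protocol$gamma,
                           eta = eta, kappa = protocol$kappa, D = protocol$D,
                           lambda = L)
    sim <- try(simulate_community(mod, init = state,
                                  t_max = sched$durations[k], dt = Inf,
                                  rtol = protocol$rtol, atol = protocol$atol),
               silent = TRUE)
    if (inherits(sim, "try-error")) {
      failed <- TRUE
      break
    }
    state <- sim$final_state
    # hold numerically extinct species at zero
    dead <- state$s < protocol$extinction_floor
    if (any(dead)) {
      s_new <- state$s
      s_new[dead] <- 0
      p_new <- state$p
      p_new[dead, ] <- 0
      state <- community_state(s_new, p_new, tol = Inf)
    }
    t_now <- t_now + sched$durations[k]
    times <- c(times, t_now)
    shannon <- c(shannon, safe_shannon(state$s))
    n_surv <- c(n_surv, survivor_count(state$s, protocol$threshold))
    if (protocol$perturb_target == "mu") {
      mu <- mu * sched$factors[k, ]
    } else {
      mu0 <- mu0 * sched$factors[k, ]
    }
  }
  out <- tibble(time = times, shannon = shannon, n_survivors = n_surv)
  class(out) <- c("diversity_trajectory", class(out))
  attr(out, "final_state") <- state
  attr(out, "mu_final") <- if (protocol$perturb_target == "mu") mu else mu0
  attr(out, "schedule") <- sched
  attr(out, "failed") <- failed
  attr(out, "with_hgt") <- with_hgt
  attr(out, "replicate") <- replicate
  out
}

#' Paired perturbation ensemble with and without gene flow
#'
#' Runs `n_replicates` of the perturbation protocol in two arms — with gene
#' flow at the protocol's `eta` and without — using identical perturbation
#' schedules within each replicate (a paired design: toggling the arm does
#' not change the random environment). Failed replicates are flagged, never
#' silently dropped.
#'
#' @param protocol a [fluctuation_protocol()].
#' @return an object of class `fluctuation_ensemble`: a tibble with columns
#'   `arm` (`"hgt"`/`"no_hgt"`), `replicate`, `time`, `shannon`,
#'   `n_survivors`, `failed`. [glance()] summarizes final diversity per arm
#'   and the paired difference.
#' @export
run_fluctuation_ensemble <- function(protocol) {
  stopifnot(inherits(protocol, "fluctuation_protocol"))
  runs <- purrr::map_dfr(seq_len(protocol$n_replicates), function(r) {
    purrr::map_dfr(c(TRUE, FALSE), function(arm) {
      tr <- run_fluctuation_replicate(protocol, with_hgt = arm, replicate = r)
      tibble(arm = if (arm) "hgt" else "no_hgt", replicate = r,
             time = tr$time, shannon = tr$shannon,
             n_survivors = tr$n_survivors,
             failed = attr(tr, "failed"))
    })
  })
  class(runs) <- c("fluctuation_ensemble", class(runs))
  attr(runs, "protocol") <- protocol
  runs
}

#' Arm summaries of a fluctuation ensemble on a common time grid
#'
#' Interpolates each replicate's diversity trajectory (step-wise constant
#' between records) onto a regular grid and returns the mean and standard
#' deviation per arm and time.
#'
#' @param ensemble a [run_fluctuation_ensemble()] result.
#' @param dt grid spacing (h).
#' @return tibble with `arm`, `time`, `mean_shannon`, `sd_shannon`, `n`.
#' @export
summarize_fluctuation_ensemble <- function(ensemble, dt = 50) {
  protocol <- attr(ensemble, "protocol")
  grid <- seq(0, protocol$horizon, by = dt)
  ensemble |>
    as_tibble() |>
    dplyr::group_by(.data$arm, .data$replicate) |>
    dplyr::reframe(shannon = approx(.data$time, .data$shannon, xout = grid,
                                    method = "constant", rule = 2)$y,
                   time = grid) |>
    dplyr::group_by(.data$arm, .data$time) |>
    dplyr::summarise(mean_shannon = mean(.data$shannon),
                     sd_shannon = sd(.data$shannon),
                     n = dplyr::n(), .groups = "drop")
}
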