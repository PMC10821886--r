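#' Integrate a community to (or toward) steady state
#'
#' Integrates the HGT-extended model (or the classic model, to which it
#' reduces exactly when all transfer rates are zero and no transconjugants
#' are present initially) with an adaptive-step solver (deSolve's `lsoda`,
#' `rtol = 1e-8`, `atol = 1e-10`). By default the community of two species
#' starts at `s = (0.5, 0.5)` and larger communities at equal abundances
#' `1/m`, with no transconjugants.
#'
#' The default protocol integrates for a fixed horizon `t_max = 200` h.
#' Competitive exclusion near a phase boundary can be slower than any fixed
#' horizon, so for steady-state classification `max_extend` may be set
#' (e.g. 6400 h): the integration then continues past `t_max` in geometrically
#' growing chunks until the maximum absolute derivative falls below
#' `steady_tol` or the cap is reached. `reached_steady` records whether the
#' certificate `max |d/dt| < steady_tol` holds at the final state.
#'
#' @param model a [community_model()].
#' @param init initial [community_state()] or abundance vector; `NULL` for
#'   the equal-abundance default.
#' @param t_max integration horizon in hours.
#' @param max_extend if greater than `t_max`, keep integrating in doubling
#'   chunks up to this total time until steady; `NULL` disables extension.
#' @param steady_tol steady-state certificate on `max |d/dt|` (per hour).
#' @param dt output-grid spacing in hours; `NULL` stores `t_max/200`-spaced
#'   output, `Inf` stores only the chunk endpoints (cheapest, used by the
#'   ensemble layer). Extension chunks always store endpoints only.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @return an object of class `community_sim` with elements `times`, `y`
#'   (trajectory matrix, one packed state per row), `final_state`,
#'   `reached_steady`, `rhs_norm`, `t_end`, and the `model`.
#' @examples
#' mod <- community_model(1, mu = 0.5, eta = 0, kappa = 0)
#' sim <- simulate_community(mod, init = 0.1)
#' sim$final_state$s # approaches (mu - D)/mu = 0.6
#' @export
simulate_community <- function(model, init = NULL, t_max = 200,
                               max_extend = NULL, steady_tol = 1e-8,
                               dt = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "community_model"))
  if (t_max <= 0) abort("`t_max` must be positive.", class = "hgtcoex_parameter_error")
  m <- model$m
  state0 <- if (is.null(init)) {
    community_state(rep(if (m == 2) 0.5 else 1 / m, m))
  } else {
    as_state(init, m)
  }
  classic <- all(model$eta == 0) &&
    (m == 1 || all(state0$p[offdiag_idx(m)] == 0))
  f <- if (classic) make_rhs_classic(model) else make_rhs_hgt(model)
  y0 <- if (classic) state0$s else pack_state(state0)

  grid_times <- if (is.null(dt)) {
    seq(0, t_max, length.out = 201)
  } else if (is.infinite(dt)) {
    c(0, t_max)
  } else {
    unique(c(seq(0, t_max, by = dt), t_max))
  }

  out <- run_lsoda(f, y0, grid_times, rtol, atol)
  times <- out[, 1]
  traj <- out[, -1, drop = FALSE]
  t_end <- t_max
  if (!is.null(max_extend) && max_extend > t_max) {
    norm_now <- max(abs(unlist(f(t_end, traj[nrow(traj), ], NULL))))
    if (norm_now >= steady_tol) {
      # one continued integration, stopped by a root exactly at steadiness
      root <- function(t, y, parms) {
        max(abs(unlist(f(t, y, parms)))) - steady_tol
      }
      ext <- try(deSolve::lsodar(y = traj[nrow(traj), ],
                                 times = c(0, max_extend - t_max), func = f,
                                 parms = NULL, rtol = rtol, atol = atol,
                                 rootfunc = root),
                 silent = TRUE)
      if (inherits(ext, "try-error") || any(!is.finite(tail(ext, 1)))) {
        abort("integrator failure during steady-state extension.",
              class = "hgtcoex_numerical_error")
      }
      traj <- rbind(traj, ext[nrow(ext), -1])
      t_end <- t_max + ext[nrow(ext), 1]
      times <- c(times, t_end)
    }
  }
  y_end <- traj[nrow(traj), ]
  rhs_norm <- max(abs(unlist(f(t_end, y_end, NULL))))
  final_state <- if (classic) {
    community_state(pmax(y_end, 0))
  } else {
    unpack_state(y_end, m)
  }
  y_full <- if (classic) {
    cbind(traj, matrix(0, nrow(traj), m * (m - 1)))
  } else {
    traj
  }
  structure(
    list(times = times, y = unname(y_full), m = m, model = model,
         final_state = final_state, reached_steady = rhs_norm < steady_tol,
         rhs_norm = rhs_norm, t_end = t_end, classic_path = classic),
    class = "community_sim"
  )
}

run_lsoda <- function(f, y0, times, rtol, atol) {
  out <- try(deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(out, "try-error") || any(!is.finite(tail(out, 1)))) {
    abort(paste0("integrator failure: ", attr(out, "condition")$message %||%
                   "non-finite state"),
          class = "hgtcoex_numerical_error")
  }
  unclass(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surviving species at the end of a simulation
#'
#' A species counts as surviving when its final abundance exceeds the
#' survival threshold (0.01 by default, on the carrying-capacity scale); a
#' community coexists when all species survive.
#'
#' @param result a [simulate_community()] result.
#' @param threshold survival threshold on abundance.
#' @return integer vector of surviving species indices with attribute
#'   `coexist` (logical: all species above threshold).
#' @export
classify_outcome <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "community_sim"))
  s <- result$final_state$s
  surv <- which(s > threshold)
  structure(surv, coexist = length(surv) == result$m)
}

# Map a two-species survivor set to the analytic outcome labels.
label_from_survivors <- function(surv) {
  if (length(surv) == 2) "coexist"
  else if (identical(as.integer(surv), 1L)) "s1_wins"
  else if (identical(as.integer(surv), 2L)) "s2_wins"
  else "washout"
}

#' Simulated two-species phase diagram over a growth-rate grid
#'
#' Runs the two-species model for every combination of growth rates and
#' classifies the steady-state outcome. With `eta = 0` the diagram matches
#' the closed-form condition of [classify_two_species()] away from phase
#' boundaries; positive transfer rates enlarge the coexistence region.
#'
#' @param mu1,mu2 growth-rate grids (1/h), values in (0, 1].
#' @param gamma1,gamma2 competition strengths (species 2 on 1, 1 on 2).
#' @param D dilution rate (1/h).
#' @param eta,kappa transfer and loss rates (1/h).
#' @param mu0 basal growth rate (1/h) used to derive MGE fitness effects.
#' @param threshold survival threshold.
#' @param t_max,max_extend integration horizon and steady-state extension cap.
#' @return a tibble (class `phase_diagram`) with columns `mu1`, `mu2`,
#'   `label` (factor: coexist, s1_wins, s2_wins, washout), `reached_steady`,
#'   and `error` (integration failures recorded per cell, not propagated).
#' @export
phase_diagram <- function(mu1, mu2, gamma1 = 0.99, gamma2 = 0.99, D = 0.2,
                          eta = 0, kappa = 0.005, mu0 = 0.5,
                          threshold = 0.01, t_max = 200, max_extend = 6400) {
  grid <- expand.grid(mu1 = mu1, mu2 = mu2, KEEP.OUT.ATTRS = FALSE)
  res <- purrr::pmap(grid, function(mu1, mu2) {
    # gamma[j, i] is the effect of species j on species i
    mod <- community_model(2, mu = c(mu1, mu2), mu0 = mu0,
                           gamma = matrix(c(1, gamma2, gamma1, 1), 2), eta = eta,
                           kappa = kappa, D = D)
    sim <- try(simulate_community(mod, t_max = t_max, max_extend = max_extend,
                                  dt = Inf), silent = TRUE)
    if (inherits(sim, "try-error")) {
      return(list(label = NA_character_, steady = NA, error = TRUE))
    }
    list(label = label_from_survivors(classify_outcome(sim, threshold)),
         steady = sim$reached_steady, error = FALSE)
  })
  out <- tibble(
    mu1 = grid$mu1, mu2 = grid$mu2,
    label = factor(purrr::map_chr(res, "label"),
                   levels = c("coexist", "s1_wins", "s2_wins", "washout")),
    reached_steady = purrr::map_lgl(res, "steady"),
    error = purrr::map_lgl(res, "error")
  )
  class(out) <- c("phase_diagram", class(out))
  out
}
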