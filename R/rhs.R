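#' Right-hand side of the classic Lotka-Volterra competition model
#'
#' Computes `ds_i/dt = mu_i s_i (1 - s_i - sum_{j != i} gamma_ji s_j) - D s_i`
#' for every species, ignoring gene flow (`eta`, `lambda`, and the
#' subpopulation matrix play no role).
#'
#' @param state a [community_state()] (only `s` is used).
#' @param model a [community_model()].
#' @return numeric vector `ds/dt` of length `m`.
#' @examples
#' m <- community_model(1, mu = 0.5, D = 0.2)
#' classic_rhs(community_state(0.6), m) # at the equilibrium (mu - D)/mu
#' @export
classic_rhs <- function(state, model) {
  state <- as_state(state, model$m)
  check_shapes(state, model)
  sc <- pmax(state$s, 0)
  comp <- 1 - drop(sc %*% model$gamma)
  model$mu * state$s * comp - model$D * state$s
}

#' Right-hand side of the HGT-extended Lotka-Volterra model
#'
#' Species-level dynamics follow the competition model with the static growth
#' rate replaced by the effective rate of [effective_growth_rates()]. Each
#' off-diagonal subpopulation `p[i, j]` (species-`i` cells carrying the
#' species-`j` element) changes through three terms: growth of the carrier
#' subpopulation (its growth rate includes the full effect of the focal
#' element plus the fractional effects of all other elements present in the
#' species), gene inflow `(s_i - p_ij) * sum_k eta[j, k, i] p[k, j]` from all
#' carriers of the element (including carriers within species `i` itself),
#' and first-order removal by dilution and segregation loss
#' `(D + kappa_ij) p_ij`.
#'
#' @param state a [community_state()].
#' @param model a [community_model()].
#' @param check validate the subpopulation bound `p[i, j] <= s[i]` before
#'   evaluating (an invariant violation beyond `tol` is an error).
#' @param tol tolerance for the invariant check.
#' @return a list with components `ds` (length `m`) and `dp` (`m x m` matrix;
#'   the diagonal duplicates `ds` since `p[i, i] = s[i]` by convention).
#' @export
hgt_rhs <- function(state, model, check = TRUE, tol = 1e-8) {
  state <- as_state(state, model$m)
  check_shapes(state, model)
  if (check && any(state$p - state$s > tol)) {
    abort("subpopulation bound violated: p[i, j] > s[i] beyond tolerance.",
          class = "hgtcoex_invariant_error")
  }
  f <- make_rhs_hgt(model, compiled = FALSE)
  y <- c(state$s, state$p[offdiag_idx(model$m)])
  d <- f(0, y, NULL)[[1]]
  ds <- d[seq_len(model$m)]
  dp <- matrix(0, model$m, model$m)
  dp[offdiag_idx(model$m)] <- d[-seq_len(model$m)]
  diag(dp) <- ds
  list(ds = ds, dp = dp)
}

#' Effective (realized) growth rates under gene flow
#'
#' The effective growth rate of species `i` aggregates the fitness effects of
#' all foreign mobile elements it currently carries, weighted by their
#' penetrance `p_ij / s_i`:
#' multiplicative composition
#' `mu_i^e = mu_i * prod_{j != i} (1 + lambda_ij p_ij / s_i)`,
#' additive composition
#' `mu_i^e = mu_i + sum_{j != i} lambda_ij p_ij / s_i`.
#' For an extinct species (`s_i = 0`) the effective rate is defined as
#' `mu_i`.
#'
#' @inheritParams classic_rhs
#' @return numeric vector `mu^e` of length `m`.
#' @examples
#' mod <- community_model(2, mu = c(0.5, 0.4), mu0 = 0.5)
#' st <- community_state(c(0.5, 0.5), matrix(c(0.5, 0.25, 0.25, 0.5), 2))
#' effective_growth_rates(st, mod) # mu1 reduced by the burdensome gene 2
#' @export
effective_growth_rates <- function(state, model) {
  state <- as_state(state, model$m)
  check_shapes(state, model)
  sc <- state$s
  r <- ratio_matrix(state$p, sc)
  if (model$composition == "multiplicative") {
    one <- 1 + model$lambda * r
    one <- pmax(one, 1e-300)
    model$mu * exp(rowSums(log(one)) - log(diag(one)))
  } else {
    model$mu + rowSums(model$lambda * r) - diag(model$lambda * r)
  }
}

as_state <- function(state, m) {
  if (inherits(state, "community_state")) return(state)
  if (is.numeric(state) && is.null(dim(state)) && length(state) == m) {
    return(community_state(state))
  }
  abort("`state` must be a community_state or an abundance vector.",
        class = "hgtcoex_parameter_error")
}

check_shapes <- function(state, model) {
  if (state$m != model$m) {
    abort(sprintf("state has %d species but model has %d.", state$m, model$m),
          class = "hgtcoex_parameter_error")
  }
}

# penetrance p_ij / s_i with empty species contributing zero,
# clamped to [0, 1] so growth factors stay positive for lambda > -1
ratio_matrix <- function(p, s) {
  denom <- ifelse(s > 0, s, 1)
  r <- pmin(pmax(p / denom, 0), 1)
  r[s <= 0, ] <- 0
  if (length(s) >= 1) diag(r)[s > 0] <- 1
  r
}

# Closure evaluating the flat-vector HGT right-hand side for deSolve.
# Negative integrator excursions are clipped only inside the evaluation;
# the stored trajectory keeps the raw integrator values. The compiled
# evaluator (src/rhs.cpp) is the default for integration speed; the pure-R
# form below is the readable reference the two are tested against.
make_rhs_hgt <- function(model, compiled = TRUE) {
  if (compiled) {
    mu <- model$mu
    L <- model$lambda
    G <- model$gamma
    Dk <- model$D + model$kappa
    D <- model$D
    eta_vec <- as.numeric(model$eta)
    eta_is_matrix <- model$eta_form == "matrix"
    multiplicative <- model$composition == "multiplicative"
    return(function(t, y, parms) {
      list(rhs_hgt_flat(y, mu, L, G, Dk, D, eta_vec, eta_is_matrix,
                        multiplicative))
    })
  }
  make_rhs_hgt_r(model)
}

make_rhs_hgt_r <- function(model) {
  m <- model$m
  mu <- model$mu
  L <- model$lambda
  G <- model$gamma
  Dk <- model$D + model$kappa
  D <- model$D
  off <- offdiag_idx(m)
  s_idx <- seq_len(m)
  eta_form <- model$eta_form
  E <- model$eta
  multiplicative <- model$composition == "multiplicative"

  function(t, y, parms) {
    s <- y[s_idx]
    sc <- pmax(s, 0)
    P <- matrix(0, m, m)
    P[off] <- pmax(y[-s_idx], 0)
    diag(P) <- sc
    r <- ratio_matrix(P, sc)
    comp <- 1 - drop(sc %*% G)
    if (multiplicative) {
      one <- pmax(1 + L * r, 1e-300)
      lg <- log(one)
      rp <- exp(rowSums(lg))          # prod over all j incl. diagonal
      mue <- mu * rp / diag(one)      # exclude the own-gene factor
      pref <- (mu * (1 + L)) * (rp / (diag(one) * one))
    } else {
      tot <- rowSums(L * r) - diag(L * r) # sum over j != i of lambda_ij r_ij
      mue <- mu + tot
      pref <- mu + L + (tot - L * r)
    }
    # clipped abundances everywhere: a negative integrator excursion must
    # not feed an exponential runaway through the growth term
    ds <- mue * sc * comp - D * sc
    Tm <- if (eta_form == "matrix") {
      crossprod(E, P)                 # T[i, j] = sum_k E[k, i] p_kj
    } else {
      Tj <- matrix(0, m, m)
      for (j in seq_len(m)) Tj[, j] <- crossprod(E[j, , ], P[, j])
      Tj
    }
    dP <- pref * P * comp + (sc - P) * Tm - Dk * P
    list(c(ds, dP[off]))
  }
}

make_rhs_classic <- function(model, compiled = TRUE) {
  mu <- model$mu
  G <- model$gamma
  D <- model$D
  if (compiled) {
    return(function(t, y, parms) list(rhs_classic_flat(y, mu, G, D)))
  }
  function(t, y, parms) {
    sc <- pmax(y, 0)
    list(mu * sc * (1 - drop(sc %*% G)) - D * sc)
  }
}
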