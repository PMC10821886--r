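#' Closed-form outcome of two-species Lotka-Volterra competition
#'
#' Without gene flow the steady-state outcome of two competing species is
#' fully determined by the net growth fractions `phi_i = (mu_i - D)/mu_i`
#' and the competition strengths: the species coexist stably if and only if
#' `gamma1 < phi2/phi1 < 1/gamma2` (with both `phi > 0`). Species 2 excludes
#' species 1 when `phi2/phi1 > 1/gamma2`; species 1 excludes species 2 when
#' `phi2/phi1 < gamma1`. When a species cannot sustain itself even alone
#' (`mu_i <= D`, i.e. `phi_i <= 0`) it washes out; if both do, nothing
#' survives. Boundary ties are classified as non-coexistence (a measure-zero,
#' deterministic tie-break).
#'
#' @param mu1,mu2 growth rates (1/h), strictly positive; vectorized.
#' @param gamma1 competition strength of species 1 on species 2.
#' @param gamma2 competition strength of species 2 on species 1.
#' @param D dilution rate (1/h).
#' @return character vector of labels among `"coexist"`, `"s1_wins"`,
#'   `"s2_wins"`, `"washout"`.
#' @examples
#' classify_two_species(0.5, 0.5, 0.9, 0.9, 0.2) # symmetric: coexist
#' @export
classify_two_species <- function(mu1, mu2, gamma1, gamma2, D = 0.2) {
  if (any(mu1 <= 0) || any(mu2 <= 0)) {
    abort("growth rates must be strictly positive.",
          class = "hgtcoex_parameter_error")
  }
  n <- max(length(mu1), length(mu2))
  mu1 <- rep_len(mu1, n); mu2 <- rep_len(mu2, n)
  phi1 <- (mu1 - D) / mu1
  phi2 <- (mu2 - D) / mu2
  out <- rep("washout", n)
  only1 <- phi1 > 0 & phi2 <= 0
  only2 <- phi2 > 0 & phi1 <= 0
  both <- phi1 > 0 & phi2 > 0
  out[only1] <- "s1_wins"
  out[only2] <- "s2_wins"
  ratio <- phi2[both] / phi1[both]
  out[both] <- ifelse(ratio > gamma1 & ratio < 1 / gamma2, "coexist",
                      ifelse(ratio >= 1 / gamma2, "s2_wins", "s1_wins"))
  out
}

#' Interior coexistence fixed point of the two-species model
#'
#' Solves `s1 + gamma2 s2 = phi1`, `gamma1 s1 + s2 = phi2`, the steady state
#' of the classic two-species model when both species persist.
#'
#' @inheritParams classify_two_species
#' @return named numeric vector `c(s1, s2)`, both positive.
#' @examples
#' coexistence_steady_state(0.5, 0.5, 0.9, 0.9, 0.2) # 0.06/0.19 each
#' @export
coexistence_steady_state <- function(mu1, mu2, gamma1, gamma2, D = 0.2) {
  if (classify_two_species(mu1, mu2, gamma1, gamma2, D) != "coexist") {
    abort("parameters do not admit stable coexistence.",
          class = "hgtcoex_state_error")
  }
  phi1 <- (mu1 - D) / mu1
  phi2 <- (mu2 - D) / mu2
  det <- 1 - gamma1 * gamma2
  c(s1 = (phi1 - gamma2 * phi2) / det, s2 = (phi2 - gamma1 * phi1) / det)
}

#' Analytic coexistence feasibility of two competing species
#'
#' The coexistence feasibility is the probability mass of growth-rate pairs
#' `(mu1, mu2)` that satisfy the closed-form coexistence condition, under a
#' stated sampling distribution. It is evaluated by deterministic dense-grid
#' integration in the probability domain (midpoint rule on the marginal
#' quantiles at step `step`, absolute accuracy about `1e-4` at the default
#' step), and serves as the exact oracle against which the Monte-Carlo
#' estimator [estimate_feasibility()] is validated at `eta = 0`.
#'
#' @param gamma1,gamma2 competition strengths.
#' @param D dilution rate (1/h).
#' @param distribution `"uniform"` on `[lower, upper]^2`, or `"gaussian"`
#'   (independent normals truncated at 0).
#' @param lower,upper uniform support bounds.
#' @param mean,sd Gaussian moments (before truncation at 0).
#' @param step probability-domain grid step.
#' @return feasibility fraction in `[0, 1]`.
#' @examples
#' analytic_feasibility_2sp(0, 0, D = 0.2) # P(mu1 > D) * P(mu2 > D) = 0.64
#' @export
analytic_feasibility_2sp <- function(gamma1, gamma2, D = 0.2,
                                     distribution = c("uniform", "gaussian"),
                                     lower = 0, upper = 1,
                                     mean = 0.5, sd = 0.1, step = 1e-3) {
  distribution <- match.arg(distribution)
  u <- seq(step / 2, 1 - step / 2, by = step)
  q <- switch(distribution,
    uniform = {
      if (upper <= lower) abort("`upper` must exceed `lower`.",
                                class = "hgtcoex_parameter_error")
      lower + u * (upper - lower)
    },
    gaussian = {
      f0 <- pnorm(0, mean, sd)
      qnorm(f0 + u * (1 - f0), mean, sd)
    }
  )
  q <- pmax(q, .Machine$double.eps)
  phi <- (q - D) / q
  pos <- phi > 0
  # P(coexist) = sum over mu1 cells of P(phi2 in (gamma1 phi1, phi1/gamma2))
  phi_sorted <- sort(phi)
  cdf_phi <- function(x) {
    # P(phi <= x) on the quantile grid, via monotone phi(q)
    findInterval(x, phi_sorted) / length(phi_sorted)
  }
  lo <- gamma1 * phi
  hi <- if (gamma2 > 0) phi / gamma2 else rep(Inf, length(phi))
  mass <- pmax(cdf_phi(pmin(hi, 1)) - cdf_phi(lo), 0)
  # strictly-positive phi2 required; cdf treats boundary ties as excluded
  mean(ifelse(pos, mass, 0))
}
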