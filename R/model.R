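#' Parameterize a community of competing species with gene flow
#'
#' Builds the full parameter set of the generalized Lotka-Volterra model of
#' `m` competing species extended with horizontal gene transfer (HGT). Each
#' species `i` carries a mobile genetic element (MGE) whose fitness effect on
#' host `j` is `lambda[j, i]`; gene flow creates transconjugant subpopulations
#' `p[i, j]` (cells of species `i` carrying the species-`j` MGE) whose
#' dynamics are governed by the transfer rates `eta`, the loss rate `kappa`,
#' and the shared dilution rate `D`. Setting `eta = 0` and starting with no
#' transconjugants recovers the classic Lotka-Volterra competition model.
#'
#' Growth rates are split into a basal component `mu0` (non-mobilizable genes)
#' and the MGE fitness effect: under the default multiplicative composition
#' `mu[i] = mu0[i] * (1 + lambda[i, i])`, under the additive variant
#' `mu[i] = mu0[i] + lambda[i, i]`. When `lambda` is not supplied it is
#' derived from `mu` and `mu0` with host-independent effects: every host
#' experiences the species-`j` MGE with the same effect
#' `lambda_j = mu[j]/mu0[j] - 1` (multiplicative) or `mu[j] - mu0[j]`
#' (additive).
#'
#' @param m number of species (positive integer).
#' @param mu static growth rates (1/h), length `m` or scalar. The growth rate
#'   of species `i` when it carries only its own MGE.
#' @param mu0 basal growth rates (1/h), scalar or length `m`.
#' @param gamma competition strengths. Scalar (applied to all ordered pairs),
#'   or an `m x m` matrix with `gamma[j, i]` the per-capita inhibition that
#'   species `j` exerts on species `i`; the diagonal is fixed at 1
#'   (self-limitation sets the carrying-capacity scale).
#' @param eta gene transfer rates (1/h). Scalar (uniform fully connected
#'   network), an `m x m` donor-by-recipient matrix `E[k, i]` (applied to
#'   every gene, e.g. a scalar times an adjacency mask for partially
#'   connected networks), or a full `m x m x m` array `eta[j, k, i]`: the
#'   rate at which the species-`j`-originated gene moves from carrier
#'   species `k` to recipient species `i`. Carriers within the recipient
#'   species itself (`k == i`) donate to their MGE-free kin, so the
#'   diagonal of the donor-recipient matrix is meaningful and kept.
#' @param kappa MGE loss (segregation) rates (1/h), scalar, length `m`, or
#'   `m x m` matrix `kappa[i, j]` (loss of the species-`j` gene from host `i`).
#' @param D dilution rate (1/h), shared by all populations.
#' @param lambda optional MGE fitness effects: scalar, length-`m` vector of
#'   per-origin effects (column-constant), or full `m x m` matrix
#'   `lambda[i, j]` (effect of the species-`j` MGE in host `i`; values > -1).
#'   When supplied together with `mu`, the diagonal must be consistent with
#'   `mu` and `mu0` under the chosen composition.
#' @param composition how basal rate and fitness effect combine:
#'   `"multiplicative"` (default) or `"additive"`.
#' @return an object of class `community_model`.
#' @seealso [community_state()], [simulate_community()], [hgt_rhs()]
#' @examples
#' community_model(2, mu = c(0.5, 0.4), gamma = 0.9, eta = 0.1)
#' @export
community_model <- function(m, mu = 0.5, mu0 = 0.5, gamma = 0.9, eta = 0,
                            kappa = 0.005, D = 0.2, lambda = NULL,
                            composition = c("multiplicative", "additive")) {
  composition <- match.arg(composition)
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    abort("`m` must be a single positive integer.", class = "hgtcoex_parameter_error")
  }
  m <- as.integer(m)
  mu <- broadcast_vec(mu, m, "mu")
  mu0 <- broadcast_vec(mu0, m, "mu0")
  check_nonneg(mu, "mu"); check_nonneg(mu0, "mu0"); check_nonneg(D, "D")
  if (any(mu0 <= 0)) {
    abort("`mu0` must be strictly positive.", class = "hgtcoex_parameter_error")
  }

  lam_own <- switch(composition,
    multiplicative = mu / mu0 - 1,
    additive = mu - mu0
  )
  if (is.null(lambda)) {
    lambda <- matrix(lam_own, m, m, byrow = TRUE)
  } else {
    if (length(lambda) == 1) lambda <- rep(lambda, m)
    if (is.null(dim(lambda)) && length(lambda) == m) {
      lambda <- matrix(lambda, m, m, byrow = TRUE)
    }
    lambda <- check_matrix(lambda, m, "lambda")
    if (max(abs(diag(lambda) - lam_own)) > 1e-8) {
      abort(paste0(
        "diag(lambda) must equal the own-MGE effect implied by `mu` and `mu0` (",
        if (composition == "multiplicative") "mu/mu0 - 1" else "mu - mu0", ")."
      ), class = "hgtcoex_parameter_error")
    }
  }
  if (composition == "multiplicative" && any(lambda <= -1)) {
    abort("`lambda` entries must be > -1 under multiplicative composition.",
          class = "hgtcoex_parameter_error")
  }

  if (length(gamma) == 1) {
    gamma <- matrix(gamma, m, m)
  }
  gamma <- check_matrix(gamma, m, "gamma")
  check_nonneg(gamma, "gamma")
  diag(gamma) <- 1

  eta <- normalize_eta(eta, m)
  if (length(kappa) == 1) kappa <- matrix(kappa, m, m)
  if (is.null(dim(kappa)) && length(kappa) == m) kappa <- matrix(kappa, m, m)
  kappa <- check_matrix(kappa, m, "kappa")
  check_nonneg(kappa, "kappa")

  structure(
    list(m = m, mu = mu, mu0 = mu0, lambda = lambda, gamma = gamma,
         eta = eta$eta, eta_form = eta$form, kappa = kappa, D = D,
         composition = composition),
    class = "community_model"
  )
}

broadcast_vec <- function(x, m, name) {
  if (length(x) == 1) x <- rep(x, m)
  if (length(x) != m || !is.numeric(x)) {
    abort(sprintf("`%s` must be numeric of length 1 or %d.", name, m),
          class = "hgtcoex_parameter_error")
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and non-negative.", name),
          class = "hgtcoex_parameter_error")
  }
  invisible(x)
}

check_matrix <- function(x, m, name) {
  if (!is.matrix(x) || !all(dim(x) == c(m, m)) || !is.numeric(x)) {
    abort(sprintf("`%s` must be an %d x %d numeric matrix.", name, m, m),
          class = "hgtcoex_parameter_error")
  }
  x
}

# Canonicalize eta input; keep the cheap donor-by-recipient matrix form
# whenever the rates do not depend on which gene is moving.
normalize_eta <- function(eta, m) {
  if (is.array(eta) && length(dim(eta)) == 3) {
    if (!all(dim(eta) == m)) {
      abort(sprintf("`eta` array must be %d x %d x %d.", m, m, m),
            class = "hgtcoex_parameter_error")
    }
    check_nonneg(eta, "eta")
    slices <- vapply(seq_len(m), function(j) eta[j, , ], numeric(m * m))
    if (m == 1 || max(abs(slices - slices[, 1])) == 0) {
      return(list(eta = matrix(slices[, 1], m, m), form = "matrix"))
    }
    return(list(eta = eta, form = "array"))
  }
  if (length(eta) == 1) {
    check_nonneg(eta, "eta")
    return(list(eta = matrix(as.numeric(eta), m, m), form = "matrix"))
  }
  eta <- check_matrix(eta, m, "eta")
  check_nonneg(eta, "eta")
  list(eta = eta, form = "matrix")
}

#' Transfer rate of the species-j gene from carrier k to recipient i
#'
#' Accessor resolving the stored transfer-rate representation (scalar/matrix
#' broadcast or full array) to the tensor entry `eta[j, k, i]`.
#'
#' @param model a [community_model()].
#' @param j,k,i gene origin, donor species, recipient species indices.
#' @return transfer rate in 1/h.
#' @export
eta_rate <- function(model, j, k, i) {
  if (model$eta_form == "matrix") model$eta[k, i] else model$eta[j, k, i]
}

#' Convert an empirically measured transfer rate to the model scale
#'
#' Conjugation rates estimated in the laboratory are expressed per donor-
#' recipient encounter (mL per cell per hour). The model works with
#' carrying-capacity-normalized abundances, so the empirical rate must be
#' multiplied by the maximum carrying capacity `N_m` (cells per mL) to obtain
#' the model transfer rate in 1/h.
#'
#' @param eta_c empirical transfer rate (mL cell^-1 h^-1), non-negative.
#' @param N_m carrying capacity (cells mL^-1), non-negative.
#' @return model transfer rate `eta = eta_c * N_m` (1/h).
#' @examples
#' convert_empirical_rate(2e-10, 1e9) # 0.2/h, an ecologically potent rate
#' @export
convert_empirical_rate <- function(eta_c, N_m) {
  if (any(eta_c < 0) || any(N_m < 0)) {
    abort("`eta_c` and `N_m` must be non-negative.",
          class = "hgtcoex_parameter_error")
  }
  eta_c * N_m
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> %d species, %s composition\n", x$m, x$composition))
  cat(sprintf("  mu:    %s\n", summary_num(x$mu)))
  cat(sprintf("  gamma: %s (off-diagonal), D = %g/h, kappa: %s\n",
              summary_num(offdiag_values(x$gamma)), x$D,
              summary_num(x$kappa)))
  eta_vals <- if (x$eta_form == "matrix") x$eta else x$eta
  cat(sprintf("  eta:   %s (%s form)\n", summary_num(eta_vals), x$eta_form))
  invisible(x)
}

summary_num <- function(x) {
  r <- range(x)
  if (diff(r) == 0) format(r[1], digits = 4)
  else sprintf("[%s, %s]", format(r[1], digits = 4), format(r[2], digits = 4))
}

offdiag_values <- function(x) if (nrow(x) == 1) diag(x) else x[row(x) != col(x)]
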