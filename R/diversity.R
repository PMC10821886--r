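#' Shannon diversity as an effective species number
#'
#' The diversity of an abundance vector is quantified as the exponential of
#' the Shannon entropy of the relative abundances (natural logarithm), i.e.
#' the Hill number of order 1:
#' `H = exp(-sum_i (s_i/s_T) log(s_i/s_T))` with `s_T = sum_i s_i`.
#' `H` ranges from 1 (single species) to `m` (all `m` species equally
#' abundant) and is invariant to rescaling and to zero-abundance species.
#' Zero entries contribute zero to the entropy (the `x log x -> 0` limit).
#'
#' @param abundances non-negative abundance vector with positive total.
#' @param threshold optional survival threshold: abundances at or below it
#'   are zeroed before the index is computed (the thresholded variant used
#'   for survivor-based reporting).
#' @return effective species number, a scalar in `[1, length(abundances)]`.
#' @examples
#' shannon_index(rep(1, 20)) # 20 equally abundant species
#' shannon_index(c(0.5, 0.25, 0.25)) # 2^1.5
#' @export
shannon_index <- function(abundances, threshold = NULL) {
  x <- as.numeric(abundances)
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`abundances` must be finite and non-negative.",
          class = "hgtcoex_parameter_error")
  }
  if (!is.null(threshold)) x[x <= threshold] <- 0
  tot <- sum(x)
  if (tot <= 0) {
    abort("diversity is undefined for an all-zero abundance vector.",
          class = "hgtcoex_parameter_error")
  }
  q <- x[x > 0] / tot
  exp(-sum(q * log(q)))
}

#' Number of species above the survival threshold
#'
#' @param abundances non-negative abundance vector.
#' @param threshold survival threshold (0.01 by default).
#' @return integer count.
#' @export
survivor_count <- function(abundances, threshold = 0.01) {
  sum(abundances > threshold)
}
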