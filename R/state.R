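#' Community state: species abundances and transconjugant subpopulations
#'
#' A state of the HGT-extended competition model holds the species abundance
#' vector `s` (carrying-capacity-normalized, dimensionless) and the
#' subpopulation matrix `p`, where `p[i, j]` is the abundance of cells of
#' species `i` that carry the species-`j`-originated mobile element. By
#' convention every cell of species `i` carries its own element, so
#' `p[i, i] = s[i]` identically; the diagonal is an alias of `s`, never
#' integrated separately.
#'
#' @param s abundance vector (non-negative).
#' @param p optional subpopulation matrix; defaults to no transconjugants
#'   (off-diagonal zero). The diagonal is overwritten with `s`.
#' @param tol tolerance for the `0 <= p[i, j] <= s[i]` invariant check.
#' @return an object of class `community_state`.
#' @examples
#' community_state(c(0.5, 0.5))
#' @export
community_state <- function(s, p = NULL, tol = 1e-8) {
  s <- as.numeric(s)
  m <- length(s)
  if (m < 1 || any(!is.finite(s)) || any(s < -tol)) {
    abort("`s` must be a non-negative numeric vector.",
          class = "hgtcoex_parameter_error")
  }
  s <- pmax(s, 0)
  if (is.null(p)) {
    p <- matrix(0, m, m)
  } else {
    p <- check_matrix(p, m, "p")
    if (any(p < -tol) || any(p - s > tol)) {
      abort("`p[i, j]` must satisfy 0 <= p[i, j] <= s[i].",
            class = "hgtcoex_invariant_error")
    }
    p <- pmin(pmax(p, 0), s)
  }
  diag(p) <- s
  structure(list(s = s, p = p, m = m), class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("<community_state> %d species\n  s: %s\n", x$m,
              paste(format(x$s, digits = 4), collapse = " ")))
  if (x$m > 1) {
    cat(sprintf("  transconjugant load (off-diag p): %s\n",
                summary_num(offdiag_values(x$p))))
  }
  invisible(x)
}

# Row-major traversal of the off-diagonal entries of an m x m matrix:
# linear (column-major) indices in the order (i=1,j=2), (i=1,j=3), ...
offdiag_idx <- function(m) {
  ij <- expand.grid(j = seq_len(m), i = seq_len(m))
  ij <- ij[ij$i != ij$j, c("i", "j")]
  ij$i + (ij$j - 1L) * m
}

#' Flatten a community state for the integrator
#'
#' The integrator state is the vector `c(s, p_offdiag)` of length
#' `m + m*(m-1)`: species abundances first, then the off-diagonal
#' subpopulations in row-major order. The diagonal `p[i, i] = s[i]` is
#' redundant and excluded.
#'
#' @param state a [community_state()].
#' @return numeric vector of length `m + m*(m-1)`.
#' @export
pack_state <- function(state) {
  stopifnot(inherits(state, "community_state"))
  c(state$s, state$p[offdiag_idx(state$m)])
}

#' Rebuild a community state from a flat integrator vector
#'
#' @param y numeric vector of length `m + m*(m-1)` (see [pack_state()]).
#' @param m number of species.
#' @param clamp clamp tiny negative integrator excursions to 0 and
#'   `p[i, j]` to at most `s[i]` (used when reconstructing accepted states).
#' @return a [community_state()].
#' @export
unpack_state <- function(y, m, clamp = TRUE) {
  stopifnot(length(y) == m + m * (m - 1))
  s <- y[seq_len(m)]
  p <- matrix(0, m, m)
  p[offdiag_idx(m)] <- y[-seq_len(m)]
  if (clamp) {
    s <- pmax(s, 0)
    p <- pmin(pmax(p, 0), s)
  }
  diag(p) <- s
  community_state(s, p, tol = Inf)
}
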