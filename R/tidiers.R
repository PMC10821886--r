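#' Tidy a community simulation into a long trajectory table
#'
#' @param x a [simulate_community()] result.
#' @param subpopulations include the off-diagonal transconjugant
#'   subpopulations as rows (`kind = "p"`, with `origin` the gene's source
#'   species) in addition to species abundances (`kind = "s"`).
#' @param ... unused.
#' @return tibble with columns `time`, `species`, `kind`, `origin`,
#'   `abundance`.
#' @method tidy community_sim
#' @export
tidy.community_sim <- function(x, subpopulations = FALSE, ...) {
  m <- x$m
  s_tab <- tibble(
    time = rep(x$times, m),
    species = rep(seq_len(m), each = length(x$times)),
    kind = "s",
    origin = NA_integer_,
    abundance = as.vector(x$y[, seq_len(m), drop = FALSE])
  )
  if (!subpopulations || m == 1) return(s_tab)
  idx <- offdiag_idx(m)
  ij <- arrayInd(idx, c(m, m))
  p_tab <- tibble(
    time = rep(x$times, length(idx)),
    species = rep(ij[, 1], each = length(x$times)),
    kind = "p",
    origin = rep(ij[, 2], each = length(x$times)),
    abundance = as.vector(x$y[, m + seq_along(idx), drop = FALSE])
  )
  dplyr::bind_rows(s_tab, p_tab)
}

#' One-row summary of a community simulation
#'
#' @param x a [simulate_community()] result.
#' @param threshold survival threshold.
#' @param ... unused.
#' @return tibble with `m`, `t_end`, `reached_steady`, `rhs_norm`,
#'   `n_survivors`, `shannon`.
#' @method glance community_sim
#' @export
glance.community_sim <- function(x, threshold = 0.01, ...) {
  tibble(
    m = x$m, t_end = x$t_end, reached_steady = x$reached_steady,
    rhs_norm = x$rhs_norm,
    n_survivors = survivor_count(x$final_state$s, threshold),
    shannon = safe_shannon(x$final_state$s)
  )
}

#' Per-draw records of a feasibility estimate
#'
#' @param x an [estimate_feasibility()] result.
#' @param ... unused.
#' @return the per-draw tibble (drawn rates and final abundances as list
#'   columns; survivor counts, coexistence flags, Shannon diversity).
#' @method tidy feasibility_estimate
#' @export
tidy.feasibility_estimate <- function(x, ...) x$draws

#' One-row summary of a feasibility estimate
#'
#' @param x an [estimate_feasibility()] result.
#' @param ... unused.
#' @return tibble with `m`, `eta` (uniform rate or range), `n_draws`,
#'   `n_failed`, `n_coexist`, `feasibility`, `se`.
#' @method glance feasibility_estimate
#' @export
glance.feasibility_estimate <- function(x, ...) {
  tibble(
    m = x$spec$m,
    eta = if (length(x$spec$eta) == 1) x$spec$eta else NA_real_,
    n_draws = x$n_draws, n_failed = x$n_failed,
    n_coexist = x$n_coexist, feasibility = x$feasibility, se = x$se
  )
}

#' Arm-level summary of a paired fluctuation ensemble
#'
#' Summarizes the final Shannon diversity of each arm and the paired
#' (per-replicate) difference between the with- and without-HGT arms, with
#' a normal-approximation 95% confidence interval on the paired mean.
#'
#' @param x a [run_fluctuation_ensemble()] result.
#' @param ... unused.
#' @return tibble with one row per arm plus one `"paired_diff"` row.
#' @method glance fluctuation_ensemble
#' @export
glance.fluctuation_ensemble <- function(x, ...) {
  finals <- x |>
    as_tibble() |>
    dplyr::group_by(.data$arm, .data$replicate) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  arms <- finals |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n = dplyr::n(), mean_final_shannon = mean(.data$shannon),
                     sd_final_shannon = sd(.data$shannon), .groups = "drop")
  wide <- finals |>
    dplyr::select("arm", "replicate", "shannon") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "shannon")
  d <- wide$hgt - wide$no_hgt
  half <- if (length(d) > 1) {
    stats::qt(0.975, df = length(d) - 1) * sd(d) / sqrt(length(d))
  } else {
    NA_real_
  }
  dplyr::bind_rows(
    arms,
    tibble(arm = "paired_diff", n = length(d), mean_final_shannon = mean(d),
           sd_final_shannon = sd(d), ci_low = mean(d) - half,
           ci_high = mean(d) + half)
  )
}
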