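#' Derive a per-draw random seed from a master seed
#'
#' Every randomized routine in the package draws from a stream seeded by a
#' deterministic mix of the master seed, a draw (or replicate) index, and a
#' role tag. One stream per draw means results are reproducible bit-exactly
#' regardless of evaluation order or chunking of the ensemble.
#'
#' @param master master seed, a non-negative integer below 2^31.
#' @param index draw or replicate index (integer >= 0).
#' @param role short string naming the consumer (e.g. "mu", "perturb").
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index = 0L, role = "draw") {
  stopifnot(is.numeric(master), length(master) == 1, master >= 0)
  role_num <- sum(utf8ToInt(role) * seq_along(utf8ToInt(role)))
  # modular mix kept in double precision; all intermediates < 2^53
  p <- 2147483629
  h <- (master %% p) * 48271
  h <- (h + index * 9973 + role_num * 7919) %% p
  as.integer(h + 1)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
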