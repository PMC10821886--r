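#' Standard model constants
#'
#' The default configuration used across the package: dilution `D = 0.2`/h,
#' gene loss `kappa = 0.005`/h, competition strength `gamma = 0.9`, basal
#' growth rate `mu0 = 0.5`/h, survival threshold 0.01, and a 200 h
#' integration horizon with steady-state extension up to 6400 h.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    m = 2, mu = 0.5, mu0 = 0.5, gamma = 0.9, eta = 0, kappa = 0.005,
    D = 0.2, composition = "multiplicative", threshold = 0.01,
    t_max = 200, max_extend = 6400, seed = 1
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML document (by file extension), fills unset fields
#' with [default_config()], and validates the result. All validation errors
#' are collected and reported together, each naming the offending field.
#'
#' @param path path to a `.json`, `.yaml`, or `.yml` file; `NULL` returns
#'   the pure defaults.
#' @return named list: the resolved configuration.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path),
            class = "hgtcoex_config_error")
    }
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (!is.list(user)) {
      abort("config must parse to a mapping of fields.",
            class = "hgtcoex_config_error")
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")),
            class = "hgtcoex_config_error")
    }
    cfg <- modifyList(cfg, user)
  }
  errors <- character(0)
  req_nonneg <- c("mu", "mu0", "gamma", "eta", "kappa", "D", "threshold")
  for (f in req_nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      errors <- c(errors, sprintf("`%s` must be numeric and non-negative", f))
    }
  }
  if (!is.numeric(cfg$m) || length(cfg$m) != 1 || cfg$m < 1 ||
      cfg$m != round(cfg$m)) {
    errors <- c(errors, "`m` must be a positive integer")
  }
  if (!is.numeric(cfg$t_max) || cfg$t_max <= 0) {
    errors <- c(errors, "`t_max` must be positive")
  }
  if (!cfg$composition %in% c("multiplicative", "additive")) {
    errors <- c(errors, "`composition` must be \"multiplicative\" or \"additive\"")
  }
  if (length(errors)) {
    abort(paste0("invalid configuration:\n", paste0("- ", errors, collapse = "\n")),
          class = "hgtcoex_config_error")
  }
  cfg
}

#' Build a run manifest
#'
#' A manifest records everything needed to re-execute a run bit-exactly:
#' the command, the fully resolved configuration, the master seed, the
#' package and R versions, a timestamp, and the output file inventory.
#'
#' @param command name of the command or experiment.
#' @param config resolved configuration list.
#' @param seed master seed.
#' @param outputs character vector of output file names.
#' @return named list (class `run_manifest`).
#' @export
run_manifest <- function(command, config, seed, outputs = character(0)) {
  structure(
    list(command = command, config = config, seed = seed,
         package = "hgtcoex",
         package_version = as.character(packageVersion("hgtcoex")),
         r_version = as.character(getRversion()),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         outputs = as.character(outputs)),
    class = "run_manifest"
  )
}

#' Write result tables and a manifest to a directory
#'
#' Every table is written as a CSV (header-only when empty, never absent),
#' rows in their given order; the manifest, including the file inventory, is
#' written as `manifest.json`. List columns are dropped from the CSVs with
#' a message, since they have no flat representation.
#'
#' @param tables named list of data frames.
#' @param manifest a [run_manifest()] (its `outputs` field is filled in).
#' @param out_dir output directory, created if needed.
#' @return invisible tibble inventory (`file`, `rows`).
#' @export
write_results <- function(tables, manifest, out_dir) {
  stopifnot(is.list(tables), all(nzchar(names(tables))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    is_flat <- !vapply(tab, is.list, logical(1))
    if (!all(is_flat)) {
      message(sprintf("dropping list columns from `%s`: %s", nm,
                      paste(names(tab)[!is_flat], collapse = ", ")))
      tab <- tab[, is_flat, drop = FALSE]
    }
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tab, f, row.names = FALSE)
    files <- c(files, basename(f))
    rows <- c(rows, nrow(tab))
  }
  manifest$outputs <- c(files, "manifest.json")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tibble(file = manifest$outputs,
                   rows = c(rows, NA_integer_)))
}
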