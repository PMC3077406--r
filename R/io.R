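# Allowed configuration schema: NULL marks "any scalar/vector leaf"; nested
# lists are validated recursively so that a typo anywhere is caught by name.
config_schema <- list(
  command = NULL,
  seed = NULL,
  out = NULL,
  estimator = list(
    slant_prior_sigma = NULL,
    rotation = list(kind = NULL, omega_e = NULL, sigma = NULL, bounds = NULL),
    likelihood = list(mode = NULL, sigma = NULL, cv = NULL, sigma_min = NULL),
    grid = list(n_sigma = NULL, n_omega = NULL, sigma_max = NULL, omega_max = NULL),
    refine = NULL
  ),
  design = list(
    slants_deg = NULL, omegas_rad_s = NULL, models = NULL,
    sigma_sigma = NULL, io_sigma_omega = NULL, io_sigma_omega_frac = NULL,
    retinal_sigma_omega = NULL, noise_sd = NULL, replicates = NULL, grid_n = NULL
  ),
  experiment = list(
    n_subjects = NULL, k_by_condition = NULL, noise_sd_tan = NULL
  )
)

config_defaults <- list(
  command = "simulate",
  seed = 1L,
  out = ".",
  estimator = list(
    slant_prior_sigma = 3,
    rotation = list(kind = "noninformative", omega_e = NULL, sigma = 1, bounds = c(0, 2)),
    likelihood = list(mode = "cv", sigma = NULL, cv = 0.05, sigma_min = 1e-4),
    grid = list(n_sigma = 512, n_omega = 512, sigma_max = 10, omega_max = NULL),
    refine = TRUE
  ),
  design = list(
    slants_deg = c(20, 35, 50, 65, 80),
    omegas_rad_s = c(285.6 / 860, 57.7 / 860),
    models = c("inverse_optics", "retinal"),
    sigma_sigma = 3, io_sigma_omega = NULL, io_sigma_omega_frac = 0.5,
    retinal_sigma_omega = 1, noise_sd = 0, replicates = 1, grid_n = 512
  ),
  experiment = list(
    n_subjects = 34,
    k_by_condition = c(PVV = 1.04, AVV = 1.88, AVP = 2.41),
    noise_sd_tan = 0.218
  )
)

check_config_keys <- function(x, schema, path = "") {
  if (!is.list(x)) {
    return(invisible(TRUE))
  }
  for (key in names(x)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(schema)) {
      abort(sprintf("Unknown configuration key '%s'.", full))
    }
    sub <- schema[[key]]
    if (is.list(sub)) check_config_keys(x[[key]], sub, full)
  }
  invisible(TRUE)
}

merge_defaults <- function(defaults, x) {
  for (key in names(x)) {
    if (is.list(defaults[[key]]) && is.list(x[[key]])) {
      defaults[[key]] <- merge_defaults(defaults[[key]], x[[key]])
    } else {
      # `[<-` with a wrapped list keeps explicit NULL values instead of
      # deleting the element
      defaults[key] <- list(x[[key]])
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration, validates every key
#' against the package schema (unknown keys raise an error naming the
#' offending key), and fills unset fields with the defaults.
#'
#' @param path Path to a YAML or JSON file.
#' @return A `slantflow_run_config` list with fields `command`, `seed`, `out`,
#'   `estimator`, `design`, `experiment`.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Configuration file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw %||% list()
  check_config_keys(raw, config_schema)
  cfg <- merge_defaults(config_defaults, raw)
  if (!is.null(cfg$experiment$k_by_condition)) {
    cfg$experiment$k_by_condition <- unlist(cfg$experiment$k_by_condition)
  }
  structure(cfg, class = "slantflow_run_config")
}

#' Save a run configuration
#'
#' @param config A `slantflow_run_config` (or plain list matching the schema).
#' @param path Destination path; format chosen by extension (`.json` or YAML).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  check_config_keys(unclass(config), config_schema)
  # named atomic vectors must become maps, or YAML drops their names
  prep <- function(x) {
    if (is.list(x)) {
      lapply(x, prep)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  out <- prep(unclass(config))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Build an estimator config from a run configuration
#'
#' @param config A `slantflow_run_config`.
#' @return An [estimator_config()].
#' @export
as_estimator_config <- function(config) {
  est <- config$estimator
  rp <- switch(est$rotation$kind,
    stationarity = rotation_prior("stationarity",
      omega_e = est$rotation$omega_e, sigma = est$rotation$sigma
    ),
    noninformative = rotation_prior("noninformative", sigma = est$rotation$sigma),
    uniform = rotation_prior("uniform", bounds = est$rotation$bounds),
    abort(sprintf("Unknown rotation prior kind '%s'.", est$rotation$kind))
  )
  lik <- if (identical(est$likelihood$mode, "absolute")) {
    def_likelihood(sigma = est$likelihood$sigma)
  } else {
    def_likelihood(cv = est$likelihood$cv, sigma_min = est$likelihood$sigma_min)
  }
  estimator_config(
    slant_prior = slant_prior(est$slant_prior_sigma),
    rotation_prior = rp,
    likelihood = lik,
    n_sigma = est$grid$n_sigma, n_omega = est$grid$n_omega,
    sigma_max = est$grid$sigma_max, omega_max = est$grid$omega_max,
    refine = isTRUE(est$refine)
  )
}

#' Build a simulation design from a run configuration
#'
#' @param config A `slantflow_run_config`.
#' @return A [simulation_design()].
#' @export
as_simulation_design <- function(config) {
  d <- config$design
  simulation_design(
    slants_deg = d$slants_deg, omegas_rad_s = d$omegas_rad_s,
    models = d$models, sigma_sigma = d$sigma_sigma,
    io_sigma_omega = d$io_sigma_omega,
    io_sigma_omega_frac = d$io_sigma_omega_frac,
    retinal_sigma_omega = d$retinal_sigma_omega,
    noise_sd = d$noise_sd, replicates = d$replicates,
    seed = config$seed, grid_n = d$grid_n
  )
}

# Short deterministic fingerprint of a configuration-like object.
config_hash <- function(x) substr(rlang::hash(x), 1, 12)

#' Write a table as CSV with a provenance header
#'
#' Every table the package emits carries a comment header recording the
#' package version, the seed and a hash of the generating configuration, so a
#' result file can always be traced to the run that produced it.
#'
#' @param table Data frame to write.
#' @param path Destination path.
#' @param seed Integer seed recorded in the header.
#' @param config Object hashed into the header (may be `NULL`).
#' @return `path`, invisibly.
#' @seealso [read_slantflow_csv()]
#' @export
write_slantflow_csv <- function(table, path, seed = NA, config = NULL) {
  header <- c(
    sprintf("# slantflow %s", as.character(utils::packageVersion("slantflow"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", config_hash(config))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a slantflow CSV (skipping the provenance header)
#'
#' @param path Path written by [write_slantflow_csv()] (plain CSVs without the
#'   header also load).
#' @return A tibble.
#' @export
read_slantflow_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Export a posterior grid as long-format CSV
#'
#' @param posterior A `slantflow_posterior`.
#' @param path Destination path.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(posterior, path, seed = NA) {
  write_slantflow_csv(
    as_tibble(posterior), path,
    seed = seed, config = posterior$config
  )
}
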