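# Run configuration, validation and shared table writers.

default_config <- function() {
  list(
    factors = lapply(gp_factors(), function(f)
      list(low = f$low, high = f$high, integer_valued = f$integer_valued,
           operability_min = f$operability_min,
           operability_max = f$operability_max)),
    genome = list(n_chromosomes = 10, map_length = 1),
    replication = list(n_datasets = 20, n_splits = 25),
    predictor = list(cost = 1, gamma = NULL, epsilon = 0.1,
                     kernel = "radial"),
    rsm = list(basis_step = 0.25, k_max = 9, compat = FALSE,
               direction = "ascent"),
    seed = 1,
    output_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads YAML or JSON (by extension), fills defaults, rejects unknown
#' keys, and validates cross-field constraints (e.g. a `qtl` region must
#' not exceed the `m` region: the number of QTL cannot exceed the number
#' of markers).
#'
#' @param path configuration file (`.yaml`, `.yml` or `.json`).
#' @return validated configuration of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw %||% list())
}

#' @rdname load_config
#' @param config a named list of overrides on the defaults.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    stop_config("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  # YAML/JSON serializers may carry infinities as strings; normalize the
  # numeric factor fields so configurations round-trip losslessly
  cfg$factors <- lapply(cfg$factors, function(f) {
    for (k in c("low", "high", "operability_min", "operability_max"))
      if (!is.null(f[[k]])) f[[k]] <- as.numeric(f[[k]])
    f
  })
  rep <- cfg$replication
  if (rep$n_datasets < 1 || rep$n_splits < 1)
    stop_config("replication.n_datasets and .n_splits must be positive")
  fl <- cfg$factors
  if (!is.null(fl$qtl) && !is.null(fl$m) && fl$qtl$high > fl$m$high)
    stop_config(
      "factors.qtl.high (%s) exceeds factors.m.high (%s): qtl <= m",
      fl$qtl$high, fl$m$high)
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Materialize configuration factors as rsm_factor objects
#'
#' @param cfg a `run_config`.
#' @return named list of [rsm_factor()]s.
#' @export
config_factors <- function(cfg) {
  out <- lapply(names(cfg$factors), function(nm) {
    f <- cfg$factors[[nm]]
    rsm_factor(nm, f$low, f$high, isTRUE(f$integer_valued),
               f$operability_min %||% -Inf, f$operability_max %||% Inf)
  })
  names(out) <- names(cfg$factors)
  out
}

#' Write homogeneous records as CSV or JSON
#'
#' Deterministic column order; full numeric precision by default, with an
#' optional presentation rounding (e.g. 2 decimals for accuracies).
#'
#' @param records data.frame (or list coercible to one).
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @param digits optional presentation rounding applied to numeric
#'   columns.
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path, format = c("csv", "json"),
                        digits = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(records)
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
  }
  ok <- tryCatch({
    if (format == "csv") utils::write.csv(df, path, row.names = FALSE)
    else jsonlite::write_json(df, path, dataframe = "rows",
                              auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e)
    stop_config("failed writing %s: %s", path, conditionMessage(e)))
  invisible(path)
}
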