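# Delimited-text readers/writers, run configuration, and small lab-data
# utilities. All artifacts are plain text: the problem scale is tiny and
# inspectability matters more than compactness.

#' Write a time series as delimited text
#'
#' CSV with ISO-8601 UTC timestamps and an optional `#`-prefixed header block
#' recording run metadata (for example the seed and a configuration hash).
#' Numeric columns are written with 15 significant digits so that
#' write-then-read is an identity to well below 1e-9.
#'
#' @param x A data frame with a POSIXct `time` column.
#' @param path Output file path.
#' @param meta Named list of metadata written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, meta = list()) {
  if (!"time" %in% names(x)) stop("x must have a time column")
  out <- as.data.frame(x)
  out$time <- strftime(out$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- formatC(out[[nm]], digits = 15,
                                                    format = "g")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(paste0("# ", nm, ": ", format(meta[[nm]])), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#'
#' @param path File path.
#' @param required Column names that must be present; a missing one is
#'   rejected by name.
#' @return A tibble with a parsed POSIXct `time` column; `#` metadata lines
#'   are returned in the `meta` attribute.
#' @export
read_timeseries <- function(path, required = character(0)) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("file has no time column: ", path)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("file is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  time <- as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (any(is.na(time))) stop("unparseable timestamps in ", path)
  df$time <- time
  out <- tibble::as_tibble(df)
  attr(out, "meta") <- meta
  out
}

#' Default run configuration
#'
#' The full nested configuration of a model run: geometry, kinetic
#' parameters, optical coefficients, source endmembers, external loads,
#' forcing climate, scenario/optimization settings, integration settings and
#' seed. Round-trips losslessly through YAML; unknown keys are rejected on
#' read.
#'
#' @return A nested list of class `run_config`.
#' @export
run_config <- function() {
  structure(list(
    geometry = unclass(lake_geometry()),
    eco = unclass(eco_params()),
    optics = unclass(optical_coefficients())[
      setdiff(names(optical_coefficients()), "wavelength_note")],
    endmembers = list(sw = unclass(sw_quality()), rw = unclass(rw_quality()),
                      om_to_c = 0.5, iss_fraction = 0.75),
    loads = list(runoff_area = 67000, runoff_coefficient = 0.9,
                 runoff_conc = list(nh4 = 2.5, no3 = 4, ip = 0.64)),
    forcing = unclass(forcing_config()),
    scenario = list(p_grid_step = 0.05, q_min = 0.05, q_max = 0.77,
                    q_step = 0.03, resolution = 0.005, sd_target_cm = 70,
                    drift_tol = 0.01, chunk_days = 28, max_days = 365),
    integration = list(dt = 1800, output_dt = 5400),
    seed = 1
  ), class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config` (nested list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# recursively verify that `x` introduces no keys absent from `template`
assert_known_keys <- function(x, template, prefix = "") {
  if (!is.list(x) || !is.list(template)) return(invisible(TRUE))
  unknown <- setdiff(names(x), names(template))
  if (length(unknown)) {
    stop("unknown configuration keys: ",
         paste0(prefix, unknown, collapse = ", "))
  }
  for (nm in names(x)) {
    if (is.list(template[[nm]])) {
      assert_known_keys(x[[nm]], template[[nm]], paste0(prefix, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Read a run configuration from YAML
#'
#' Values are merged onto [run_config()] defaults; any key not present in the
#' default schema is rejected, listing the offending keys.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- unclass(run_config())
  assert_known_keys(raw, defaults)
  merged <- utils::modifyList(defaults, raw)
  structure(merged, class = "run_config")
}

#' Configuration hash for run manifests
#'
#' @param config Any configuration object.
#' @return A short stable hash string.
#' @export
config_hash <- function(config) rlang::hash(config)

#' Chlorophyll-a from trichromatic optical densities
#'
#' Spectrophotometric determination from 90% acetone extracts:
#' `11.64 * OD663 - 2.16 * OD645 + 0.1 * (OD630 - OD750)`, floored at zero
#' (with a warning) should the linear combination come out negative.
#'
#' @param od663,od645,od630,od750 Optical densities, non-negative.
#' @return Chlorophyll-a concentration (µg/L), vectorized.
#' @examples
#' chl_a_from_od(0.1, 0, 0, 0) # 1.164
#' @export
chl_a_from_od <- function(od663, od645, od630 = 0, od750 = 0) {
  if (any(c(od663, od645, od630, od750) < 0)) {
    stop("optical densities must be non-negative")
  }
  out <- 11.64 * od663 - 2.16 * od645 + 0.1 * (od630 - od750)
  if (any(out < 0)) {
    warning("negative chlorophyll-a estimate floored at 0")
    out <- pmax(out, 0)
  }
  out
}
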