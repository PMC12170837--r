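# Flat-file interchange: CSV tables with documented headers, ISO-8601 dates,
# a "# key=value" metadata comment line carrying the seed, and a JSON run
# manifest. Schema violations are reported with offending columns/rows.

required_cols <- list(
  nightly_panel = c("user", "date", "osa", "tst", "tmean"),
  daily_series = c("date", "tmean"),
  country_params = c("label", "p0", "apop", "mva_death_rate", "rle",
                     "labor_force", "pt_share", "gdp_pc", "gdp_pc_employed")
)

read_checked_csv <- function(path, kind) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- required_cols[[kind]]
  miss <- setdiff(need, names(df))
  stop_if(length(miss) > 0,
          sprintf("%s: missing mandatory column(s): %s", basename(path),
                  paste(miss, collapse = ", ")))
  known <- switch(kind,
    nightly_panel = c(need, "osa_severe", "miss_ahi", "tmin", "tmax",
                      paste0("tlag", 1:10), "cloud_cover", "rel_humidity",
                      "pressure", "precipitation", "wind_speed", "pm25"),
    daily_series = c(need, "tmin", "tmax", "leap", "cloud_cover",
                     "rel_humidity", "pressure", "precipitation",
                     "wind_speed", "pm25"),
    country_params = need
  )
  extra <- setdiff(names(df), known)
  if (length(extra) > 0) {
    warning(sprintf("%s: unknown column(s) kept as-is: %s", basename(path),
                    paste(extra, collapse = ", ")))
  }
  if ("date" %in% names(df)) {
    d <- as.Date(df$date, format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(df$date))
    stop_if(length(bad) > 0,
            sprintf("%s: unparseable ISO-8601 date(s) at data row(s) %s",
                    basename(path),
                    paste(utils::head(bad, 5L), collapse = ", ")))
    df$date <- d
  }
  df
}

write_with_meta <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s written=%s",
                     seed %||% "NA", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read and write the flat-file tables
#'
#' CSV with documented headers and ISO-8601 dates; a leading `# seed=...`
#' metadata comment line records provenance. Missing mandatory columns fail
#' naming the column; unknown columns warn; unparseable dates fail with row
#' numbers.
#'
#' @param path File path.
#' @param panel,series,params Objects to write.
#' @return Readers return the validated typed object; writers the path,
#'   invisibly.
#' @export
read_nightly_panel <- function(path) {
  df <- read_checked_csv(path, "nightly_panel")
  class(df) <- c("nightly_panel", "data.frame")
  df
}

#' @rdname read_nightly_panel
#' @export
write_nightly_panel <- function(panel, path) {
  write_with_meta(as.data.frame(panel), path, seed = attr(panel, "seed"))
}

#' @rdname read_nightly_panel
#' @export
read_daily_series <- function(path) {
  validate_daily_series(read_checked_csv(path, "daily_series"))
}

#' @rdname read_nightly_panel
#' @export
write_daily_series <- function(series, path) {
  write_with_meta(as.data.frame(series), path, seed = attr(series, "seed"))
}

#' @rdname read_nightly_panel
#' @export
read_country_params <- function(path) {
  df <- read_checked_csv(path, "country_params")
  lapply(seq_len(nrow(df)), function(i) {
    do.call(country_params, as.list(df[i, required_cols$country_params]))
  })
}

#' @rdname read_nightly_panel
#' @export
write_country_params <- function(params, path) {
  if (inherits(params, "country_params")) params <- list(params)
  df <- do.call(rbind, lapply(params, function(p) {
    as.data.frame(p[required_cols$country_params])
  }))
  write_with_meta(df, path)
}

#' Read and write a pipeline run configuration
#'
#' A flat JSON key-value file holding the options shared across pipeline
#' stages: input/output paths, the exposure column (`tmean`, `tmin` or
#' `tmax`, supporting the min/max-temperature sensitivity analyses), the
#' maximum lag, spline degrees of freedom, the reference percentile, the
#' climatology window, and the seed. Unknown keys are kept; invalid values
#' fail with the offending key.
#'
#' @param path JSON file path.
#' @param config Named list of options.
#' @return `read_run_config` the validated list; `write_run_config` the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(exposure = "tmean", max_lag = 4L, exposure_df = 4L,
                   covariate_df = 4L, reference_percentile = 0.25,
                   climatology_window = c(1950L, 1990L), seed = 1L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  stop_if(!cfg$exposure %in% c("tmean", "tmin", "tmax"),
          "config 'exposure' must be one of tmean, tmin, tmax")
  stop_if(cfg$max_lag < 0, "config 'max_lag' must be >= 0")
  stop_if(cfg$reference_percentile <= 0 || cfg$reference_percentile >= 1,
          "config 'reference_percentile' must be in (0, 1)")
  for (p in unlist(cfg[grepl("_path$", names(cfg))])) {
    stop_if(!file.exists(p), sprintf("config references a missing file: %s", p))
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records, per pipeline stage, the inputs, the configuration, the seed, and
#' package/R versions, so every output file is reproducible from its
#' manifest alone.
#'
#' @param path Output path (`.json`).
#' @param stage Stage name.
#' @param inputs Named list or character vector of input paths.
#' @param config Named list of options used.
#' @param seed Integer seed.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, stage, inputs = list(), config = list(),
                           seed = NA_integer_) {
  manifest <- list(
    stage = stage,
    inputs = inputs,
    config = config,
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("osaheat")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
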