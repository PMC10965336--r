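# Plain-CSV / JSON / YAML plumbing and the end-to-end pipeline.
#
# All tabular artifacts are comma-separated UTF-8 with a mandatory header
# row and "." as decimal mark; dates are exclusively integer or real
# day-of-year. Every run writes a machine-readable manifest recording the
# configuration hash, per-stage seeds and record counts, so a rerun with the
# same configuration is byte-identical.

.table_schemas <- list(
  catches = c("year", "doy_start", "doy_end", "plot", "trap", "taxon",
              "life_stage", "count"),
  lengths = c("taxon", "life_stage", "length_mm"),
  allometry = c("taxon", "coeff_a", "exponent_b"),
  nests = c("year", "hatch_doy"),
  chicks = c("chick_id", "age_days", "mass_g"),
  daily_series = c("year", "currency", "doy", "value", "n_active_traps"),
  phenology = c("year", "currency", "median_doy", "total", "defined")
)

#' Read a pipeline table with schema validation
#'
#' @param path CSV file path.
#' @param table Schema name: one of "catches", "lengths", "allometry",
#'   "nests", "chicks", "daily_series", "phenology".
#' @return data.frame with at least the schema columns.
#' @export
read_table_csv <- function(path, table = names(.table_schemas)) {
  table <- match.arg(table)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, .table_schemas[[table]], basename(path))
  df
}

#' Write a pipeline table as CSV
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param table Schema name (see [read_table_csv()]); validated before write.
#' @export
write_table_csv <- function(df, path, table = names(.table_schemas)) {
  table <- match.arg(table)
  .check_columns(df, .table_schemas[[table]], table)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a set of pipeline input tables
#'
#' Checks schemas, value ranges and referential integrity: every
#' (taxon, life_stage) appearing in the catches must be covered by the
#' length table, and every taxon by the allometry table. Fatal issues
#' (orphan taxa, negative counts, malformed intervals) raise an error
#' listing each problem; informational counts are returned.
#'
#' @param catches,lengths,allometry,nests Input tables (nests optional).
#' @param stop_on_fatal Raise an error on fatal issues (default `TRUE`).
#' @return data.frame (level, message) of issues (invisible when empty and
#'   `stop_on_fatal`), plus attribute `counts` with per-table row counts.
#' @export
validate_tables <- function(catches, lengths, allometry, nests = NULL,
                            stop_on_fatal = TRUE) {
  issues <- data.frame(level = character(0L), message = character(0L),
                       stringsAsFactors = FALSE)
  add <- function(level, msg) {
    issues[nrow(issues) + 1L, ] <<- list(level, msg)
  }
  .check_columns(catches, .table_schemas$catches, "catch table")
  .check_columns(lengths, .table_schemas$lengths, "length table")
  .check_columns(allometry, .table_schemas$allometry, "allometry table")
  if (!is.null(nests)) .check_columns(nests, .table_schemas$nests, "nest table")

  bad <- which(catches$count < 0)
  for (i in bad) add("fatal", paste0("negative count at catch row ", i))
  bad <- which(catches$doy_end < catches$doy_start)
  for (i in bad) add("fatal", paste0("doy_end < doy_start at catch row ", i))
  if (any(lengths$length_mm <= 0)) add("fatal", "nonpositive length in length table")
  if (any(allometry$coeff_a <= 0)) add("fatal", "nonpositive coeff_a in allometry table")

  present <- unique(catches[catches$count > 0, c("taxon", "life_stage")])
  have_len <- unique(paste(lengths$taxon, lengths$life_stage))
  for (i in seq_len(nrow(present))) {
    key <- paste(present$taxon[i], present$life_stage[i])
    if (!key %in% have_len) {
      add("fatal", paste0("taxon '", present$taxon[i], "' (",
                          present$life_stage[i], ") has no length data"))
    }
    if (!present$taxon[i] %in% allometry$taxon) {
      add("fatal", paste0("taxon '", present$taxon[i],
                          "' has no allometric coefficients"))
    }
  }

  attr(issues, "counts") <- c(catches = nrow(catches), lengths = nrow(lengths),
                              allometry = nrow(allometry),
                              nests = if (is.null(nests)) NA_integer_ else nrow(nests))
  if (stop_on_fatal && any(issues$level == "fatal")) {
    stop("input validation failed:\n  ",
         paste(issues$message[issues$level == "fatal"], collapse = "\n  "))
  }
  issues
}

.config_defaults <- function() {
  list(
    seed = 1L,
    window = list(start = 157L, end = 238L),
    exclude_years = integer(0L),
    taxon_allowlist = NULL,
    community = list(years = 1996:2015, plots = 6L, traps_per_plot = 4L,
                     sampling_interval_days = 7L,
                     annual_advance_days_per_year = 0.5),
    nests = list(mean_hatch_doy_year0 = 181, hatch_trend_days_per_year = 0.1,
                 hatch_sd_days = 4, nests_per_year = 20L),
    reconstruction = list(mode = "expected", n_reps = 1L),
    trends = list(n_boot = 10000L),
    phenology = list(threshold = 0.5)
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Unknown keys (at the top level or within a section) are rejected so that
#' typos cannot silently fall back to defaults.
#'
#' @param config Named list of overrides (possibly nested), e.g. from
#'   [read_pipeline_config()].
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      sub_unknown <- setdiff(names(config[[key]]), names(defaults[[key]]))
      if (length(sub_unknown) > 0L) {
        stop("unknown key(s) in '", key, "': ",
             paste(sub_unknown, collapse = ", "))
      }
      defaults[[key]][names(config[[key]])] <- config[[key]]
    } else {
      defaults[[key]] <- config[[key]]
    }
  }
  stopifnot(defaults$window$start < defaults$window$end)
  if (!defaults$reconstruction$mode %in% c("expected", "stochastic")) {
    stop("reconstruction mode must be 'expected' or 'stochastic'")
  }
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full synthetic-data pipeline
#'
#' Stages, in order: generate the synthetic trap and nest datasets (with
#' analytic ground truth); validate the tables; reconstruct daily abundance
#' and biomass series; compute 50%-threshold phenology dates; build mismatch
#' series against yearly median hatch dates; fit linear trends with
#' case-bootstrap confidence intervals. All artifacts are written under
#' `outdir` as plain CSV/JSON plus a run manifest, and a rerun with the same
#' configuration is byte-identical.
#'
#' @param config A `pipeline_config` (or a named list of overrides).
#' @param outdir Output directory (created if needed).
#' @param community_spec Optional [community_spec()] overriding the
#'   community section (the default community is used otherwise).
#' @param quiet Suppress progress messages.
#' @return List with all in-memory artifacts: `dataset`, `daily_series`,
#'   `phenology`, `hatch`, `mismatch` (list by currency), `trends` (list of
#'   `trend_fit` by currency), `truth`, and `outdir`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL,
                         community_spec = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  say <- function(...) if (!quiet) message(...)
  seeds <- derive_seeds(config$seed, 4L)

  spec <- community_spec %||% do.call(
    default_community_spec,
    c(config$community,
      list(window_start_doy = config$window$start,
           window_end_doy = config$window$end)))
  window <- c(config$window$start, config$window$end)

  say("[generate] community: ", length(spec$taxa), " taxa, ",
      length(spec$years), " years, seed ", seeds[1L])
  dataset <- generate_trap_dataset(spec, seed = seeds[1L])
  nests <- generate_nest_dataset(do.call(nest_spec, config$nests),
                                 spec$years, seed = seeds[2L])

  keep_years <- !(dataset$catches$year %in% config$exclude_years)
  catches <- dataset$catches[keep_years, , drop = FALSE]
  if (!is.null(config$taxon_allowlist)) {
    catches <- catches[catches$taxon %in% config$taxon_allowlist, , drop = FALSE]
  }
  nests <- nests[!(nests$year %in% config$exclude_years), , drop = FALSE]

  say("[validate] ", nrow(catches), " catch records, ",
      nrow(dataset$lengths), " length records, ", nrow(nests), " nests")
  validate_tables(catches, dataset$lengths, dataset$allometry, nests)

  say("[reconstruct] mode ", config$reconstruction$mode)
  daily <- reconstruct_daily_series(catches, dataset$lengths,
                                    dataset$allometry, window,
                                    mode = config$reconstruction$mode,
                                    seed = seeds[3L],
                                    n_reps = config$reconstruction$n_reps)

  phen <- phenology_estimates(daily, threshold = config$phenology$threshold)
  n_undef <- sum(!phen$defined)
  if (n_undef > 0L) say("[phenology] ", n_undef, " undefined year-currency cell(s)")

  hm <- hatch_medians(nests)
  hm_df <- hm[c("year", "hatch_median_doy")]
  mismatch <- list(
    abundance = mismatch_series(hm_df, phen, "abundance"),
    biomass = mismatch_series(hm_df, phen, "biomass")
  )
  say("[trends] case bootstrap, B = ", config$trends$n_boot,
      ", seed ", seeds[4L])
  trends <- lapply(mismatch, trend_with_ci, n_boot = config$trends$n_boot,
                   seed = seeds[4L])

  result <- list(dataset = dataset, daily_series = daily, phenology = phen,
                 hatch = hm, mismatch = mismatch, trends = trends,
                 truth = dataset$truth, config = config, outdir = outdir)
  if (!is.null(outdir)) {
    .write_pipeline_artifacts(result, nests, outdir, seeds)
  }
  invisible(result)
}

.write_pipeline_artifacts <- function(result, nests, outdir, seeds) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(result$dataset$catches, file.path(outdir, "catches.csv"), "catches")
  write_table_csv(result$dataset$lengths, file.path(outdir, "lengths.csv"), "lengths")
  write_table_csv(result$dataset$allometry, file.path(outdir, "allometry.csv"), "allometry")
  write_table_csv(nests, file.path(outdir, "nests.csv"), "nests")
  write_table_csv(result$daily_series, file.path(outdir, "daily_series.csv"),
                  "daily_series")
  write_table_csv(result$phenology, file.path(outdir, "phenology.csv"), "phenology")
  jsonlite::write_json(
    list(per_year = result$truth$per_year,
         mean_lag_days = result$truth$mean_lag_days,
         abundance_trend = result$truth$abundance_trend,
         biomass_trend = result$truth$biomass_trend),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(result$trends, function(t) list(
      currency = t$currency, slope = t$slope, intercept = t$intercept,
      mean_mismatch = t$mean_mismatch,
      ci = list(slope = as.numeric(t$ci["slope", ]),
                intercept = as.numeric(t$ci["intercept", ]),
                mean_mismatch = as.numeric(t$ci["mean_mismatch", ])),
      n_years = t$n_years, n_boot = t$n_boot,
      n_discarded = t$n_discarded, seed = t$seed)),
    file.path(outdir, "trends.json"), auto_unbox = TRUE, digits = NA)

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(result$config), cfg_path)
  manifest <- list(
    package = "phenocurrency",
    version = as.character(utils::packageVersion("phenocurrency")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    master_seed = result$config$seed,
    stage_seeds = list(generate = seeds[1L], nests = seeds[2L],
                       lengths = seeds[3L], bootstrap = seeds[4L]),
    record_counts = list(catches = nrow(result$dataset$catches),
                         lengths = nrow(result$dataset$lengths),
                         nests = nrow(nests),
                         daily_series = nrow(result$daily_series))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
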