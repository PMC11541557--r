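# CSV files written by the package carry a schema-version comment on the
# first line; readers skip any leading '#' comment lines.
.schema_header <- "# reefheat-schema 1.0"

write_reef_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.schema_header, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_reef_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read per-site daily SST series from a long CSV
#'
#' Expected columns: `site_id`, `date` (ISO-8601) and `sst` (degC). Each
#' site's record is validated on ingest (strictly increasing daily dates --
#' duplicates are an error -- plausible temperature range, short gaps
#' interpolated).
#'
#' @param path CSV file path.
#' @param max_gap Longest gap (days) repaired by interpolation.
#' @return Named list of [sst_series].
#' @export
read_sst <- function(path, max_gap = 3) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read_reef_csv(path)
  need <- c("site_id", "date", "sst")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  out <- lapply(split(df, df$site_id), function(d) {
    if (anyDuplicated(d$date)) {
      stopf("site '%s': duplicate dates (e.g. %s)", d$site_id[1],
            d$date[anyDuplicated(d$date)])
    }
    d <- d[order(as.Date(d$date)), ]
    sst_series(d$site_id[1], d$date, d$sst, max_gap = max_gap)
  })
  out
}

#' Write per-site SST series to a long CSV
#'
#' @param sst Named list of [sst_series] (or a single series).
#' @param path Output path.
#' @export
write_sst <- function(sst, path) {
  if (inherits(sst, "sst_series")) sst <- list(sst)
  df <- do.call(rbind, lapply(sst, function(s) {
    data.frame(site_id = s$site_id, date = format(s$dates), sst = s$sst,
               stringsAsFactors = FALSE)
  }))
  write_reef_csv(df, path)
}

#' Read a colony-level bleaching survey table
#'
#' Expected columns: `site_id`, `date`, `lat`, `lon`, `depth_m`, `species`,
#' `category`, `count`. Categories are normalized (trimmed, lower-cased,
#' spaces to underscores) with a warning and must then be one of `normal`,
#' `pale`, `partially_bleached`, `fully_bleached`; unknown categories are an
#' error.
#'
#' @param path CSV path.
#' @return Validated survey `data.frame`.
#' @export
read_surveys <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read_reef_csv(path)
  if (nrow(df) == 0L) stopf("%s: empty survey file", path)
  need <- c("site_id", "date", "lat", "lon", "depth_m", "species",
            "category", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  norm <- gsub("[ -]+", "_", tolower(trimws(df$category)))
  if (any(norm != df$category)) {
    warnf("normalized %d non-canonical category value(s)",
          sum(norm != df$category))
  }
  bad <- setdiff(unique(norm), names(bleach_categories()))
  if (length(bad)) stopf("%s: unknown bleaching categories: %s", path,
                         paste(bad, collapse = ", "))
  df$category <- norm
  if (any(df$count < 1)) stopf("%s: colony counts must be >= 1", path)
  if (any(df$depth_m <= 0)) stopf("%s: depths must be > 0", path)
  df$date <- as.Date(df$date)
  df
}

#' Read a species functional coefficient table
#'
#' Expected columns: `species`, `fc` (> 0); an optional `source_species`
#' column documents congener fallbacks in externally curated tables.
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_fc_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read_reef_csv(path)
  miss <- setdiff(c("species", "fc"), names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  if (any(!is.finite(df$fc) | df$fc <= 0)) stopf("%s: fc must be > 0", path)
  df
}

#' Pipeline configuration files
#'
#' A pipeline configuration bundles the file paths, climatology baseline,
#' model settings and seed of an end-to-end run, and round-trips losslessly
#' through a YAML file. Unknown keys are rejected so typos surface early.
#'
#' @param sst,surveys,fc_table,out_dir File paths (fc_table may be `NULL`).
#' @param baseline Two baseline years.
#' @param model A [model_config] (or a list of its fields).
#' @param seed Integer seed for every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sst, surveys, fc_table = NULL, out_dir = "out",
                            baseline = c(1985, 2012), model = model_config(),
                            seed = 1) {
  if (length(baseline) != 2 || baseline[1] >= baseline[2]) {
    stopf("baseline must be two increasing years (got %s)",
          paste(baseline, collapse = ", "))
  }
  if (!inherits(model, "model_config")) {
    model <- do.call(model_config, model)
  }
  structure(list(sst = sst, surveys = surveys, fc_table = fc_table,
                 out_dir = out_dir, baseline = as.integer(baseline),
                 model = model, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- c("sst", "surveys", "fc_table", "out_dir", "baseline", "model",
             "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("%s: unknown configuration key(s): %s", path,
                         paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$model <- unclass(out$model)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a generated dataset to a directory
#'
#' Writes `surveys.csv`, `sst.csv`, `sites.csv`, `metrics.csv` and
#' `ground_truth.json` under `dir`.
#'
#' @param dataset A `reef_dataset` from [gen_dataset].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sv <- dataset$surveys
  sv$date <- format(as_date(sv$date))
  write_reef_csv(sv, file.path(dir, "surveys.csv"))
  write_sst(dataset$sst, file.path(dir, "sst.csv"))
  write_reef_csv(dataset$sites, file.path(dir, "sites.csv"))
  mt <- dataset$metrics
  mt$sample_date <- format(as_date(mt$sample_date))
  write_reef_csv(mt, file.path(dir, "metrics.csv"))
  gt <- dataset$ground_truth
  gt$species_sensitivity <- as.list(gt$species_sensitivity)
  gt$true_drivers <- as.list(gt$true_drivers)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
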