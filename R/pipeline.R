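#' Thermal metrics table for a set of observations
#'
#' Runs [climatology] once per site and [exposure_metrics] for every
#' observation (site, sampling date) pair.
#'
#' @param sst Named list of [sst_series].
#' @param observations `data.frame` with columns `site_id` and `date`.
#' @param baseline Climatology baseline years.
#' @return `data.frame`: one row per observation, the seventeen thermal
#'   metric columns of [exposure_metrics].
#' @export
metrics_table <- function(sst, observations, baseline = c(1985, 2012)) {
  obs <- unique(observations[c("site_id", "date")])
  prof <- lapply(sst, climatology, baseline = baseline)
  rows <- lapply(seq_len(nrow(obs)), function(k) {
    sid <- obs$site_id[k]
    if (!sid %in% names(sst)) stopf("no SST series for site '%s'", sid)
    exposure_metrics(sst[[sid]], prof[[sid]], obs$date[k])
  })
  do.call(rbind, rows)
}

#' Field-based index table for a set of surveys
#'
#' Computes the species sensitivity table (from the surveys themselves, or
#' supplied externally), the site x species matrix and its ordination, and
#' every per-observation reef index.
#'
#' @param surveys Tidy colony table (see [read_surveys]).
#' @param fc_table Functional coefficient table or `NULL` (RFI skipped with a
#'   warning).
#' @param si_table Optional externally supplied [species_bsi_table]; default
#'   is to derive it from `surveys` (the acknowledged circular design of
#'   sensitivity indices derived from the event they score). Set
#'   `leave_one_site_out = TRUE` for an honest per-site table.
#' @param min_colonies Pooling floor for the sensitivity table.
#' @param leave_one_site_out Recompute the sensitivity table without the
#'   focal site for each observation.
#' @return `data.frame`: one row per observation with `site_id`, `date`,
#'   `depth`, `bsi`, `si_reef`, `rfi`, `richness`, `diversity_n1`, `dca1`.
#' @export
indices_table <- function(surveys, fc_table = NULL, si_table = NULL,
                          min_colonies = 50, leave_one_site_out = FALSE) {
  if (is.null(fc_table)) warnf("no functional coefficient table: RFI skipped")
  key <- interaction(surveys$site_id, format(as_date(surveys$date)), drop = TRUE)
  obs <- split(surveys, key)
  full_si <- si_table %||% species_bsi_table(surveys, min_colonies)
  comm <- t(vapply(obs, function(d) {
    ab <- tapply(d$count, factor(d$species, levels = sort(unique(surveys$species))),
                 sum, default = 0)
    ab / sum(ab)
  }, numeric(length(unique(surveys$species)))))
  rownames(comm) <- names(obs)
  dca <- tryCatch(dca_axis1(comm), error = function(e) {
    warnf("ordination failed (%s); dca1 set to NA", conditionMessage(e))
    setNames(rep(NA_real_, nrow(comm)), rownames(comm))
  })
  rows <- lapply(names(obs), function(k) {
    d <- obs[[k]]
    n_col <- sum(d$count)
    if (n_col < 150 || n_col > 200) {
      warnf("observation %s: %d colonies, outside the 150-200 protocol target",
            k, n_col)
    }
    si_tab <- full_si
    if (leave_one_site_out && is.null(si_table)) {
      si_tab <- species_bsi_table(surveys[surveys$site_id != d$site_id[1], ],
                                  min_colonies)
    }
    reef_index_set(d, si_tab, fc_table,
                   dca_score = unname(dca[k]),
                   site_id = d$site_id[1], date = d$date[1],
                   depth = d$depth_m[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge thermal metrics and reef indices into a model table
#'
#' @param metrics Output of [metrics_table].
#' @param indices Output of [indices_table].
#' @return Merged `data.frame` keyed by `site_id` x date, with the
#'   severity response `bsi` and all candidate predictors.
#' @export
merge_model_table <- function(metrics, indices) {
  m <- metrics
  m$date <- as_date(m$sample_date)
  m$sample_date <- NULL
  ix <- indices
  ix$date <- as_date(ix$date)
  out <- merge(ix, m, by = c("site_id", "date"))
  if (nrow(out) != nrow(ix)) {
    warnf("%d observation(s) lacked matching thermal metrics",
          nrow(ix) - nrow(out))
  }
  out
}

#' Candidate predictor columns of a merged model table
#'
#' The driver-model vocabulary present in a merged metrics/indices table:
#' the seventeen thermal metrics plus depth, diversity, richness, the
#' sensitivity and functional indices and the ordination score. Columns with
#' missing values (e.g. RFI when no coefficient table was supplied) are
#' excluded.
#'
#' @param table Output of [merge_model_table].
#' @return Character vector of column names.
#' @export
model_predictor_names <- function(table) {
  cand <- c("depth", "diversity_n1", "richness", "si_reef", "rfi", "dca1",
            "mmm", "rotc_clim", "rotc_84days", "sd_84days", "hs_3days",
            "hs_28days", "hs_84days", "hs_555days", "hs1_28days",
            "hs1_84days", "hs2_28days", "hs2_84days", "dhw_28days", "dhw",
            "dhw_555days", "trend_dhw", "delta_dhw")
  keep <- intersect(cand, names(table))
  keep[vapply(table[keep], function(v) !anyNA(v), TRUE)]
}

#' Run the full vulnerability pipeline
#'
#' Thermal metrics, reef indices, merged model table, driver model with
#' simplification, and a residual spatial-autocorrelation check, in one call.
#'
#' @param sst Named list of [sst_series].
#' @param surveys Tidy colony table.
#' @param fc_table Functional coefficient table or `NULL`.
#' @param config A [model_config].
#' @param baseline Climatology baseline.
#' @param correlogram Also compute the spline correlogram of the model
#'   residuals (needs >= 10 distinct sites).
#' @param n_boot Bootstrap replicates for the correlogram envelope.
#' @param out_dir Optional directory to persist the stage outputs
#'   (metrics/indices/model tables as CSV, the model report as JSON).
#' @return List of class `reef_pipeline_result`: `metrics`, `indices`,
#'   `model_table`, `model` (a [simplify_model] result), `correlogram`
#'   (or `NULL`).
#' @export
run_pipeline <- function(sst, surveys, fc_table = NULL,
                         config = model_config(), baseline = c(1985, 2012),
                         correlogram = TRUE, n_boot = 300, out_dir = NULL) {
  obs <- unique(surveys[c("site_id", "date")])
  message(sprintf("[reefheat] %d observations at %d sites", nrow(obs),
                  length(unique(obs$site_id))))
  metrics <- metrics_table(sst, obs, baseline)
  message(sprintf("[reefheat] thermal metrics: %d rows", nrow(metrics)))
  indices <- suppressWarnings(indices_table(surveys, fc_table))
  message(sprintf("[reefheat] reef indices: %d rows", nrow(indices)))
  tab <- merge_model_table(metrics, indices)
  preds <- model_predictor_names(tab)
  model <- simplify_model(tab[preds], tab$bsi, config)
  message(sprintf("[reefheat] driver model: %d predictors selected, CV R2 = %.3f",
                  length(model$selected_predictors), model$cv_r2))
  cg <- NULL
  if (correlogram) {
    coords <- surveys[!duplicated(surveys$site_id), c("site_id", "lat", "lon")]
    site_res <- tapply(model$residuals, tab$site_id, mean)
    coords <- coords[match(names(site_res), coords$site_id), ]
    cg <- tryCatch(
      spline_correlogram(coords$lat, coords$lon, as.numeric(site_res),
                         n_boot = n_boot, seed = config$seed),
      error = function(e) {
        warnf("correlogram skipped: %s", conditionMessage(e))
        NULL
      })
  }
  res <- structure(list(metrics = metrics, indices = indices,
                        model_table = tab, model = model, correlogram = cg),
                   class = "reef_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' Persist pipeline outputs
#'
#' Writes `metrics.csv`, `indices.csv`, `model_table.csv`, `residuals.csv`,
#' `pd_curves.csv` and `model_report.json` under `dir`.
#' @param result A `reef_pipeline_result`.
#' @param dir Output directory.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mt <- result$metrics
  mt$sample_date <- format(as_date(mt$sample_date))
  write_reef_csv(mt, file.path(dir, "metrics.csv"))
  ix <- result$indices
  ix$date <- format(as_date(ix$date))
  write_reef_csv(ix, file.path(dir, "indices.csv"))
  tab <- result$model_table
  tab$date <- format(as_date(tab$date))
  write_reef_csv(tab, file.path(dir, "model_table.csv"))
  m <- result$model
  write_reef_csv(data.frame(site_id = result$model_table$site_id,
                            date = format(as_date(result$model_table$date)),
                            fitted = m$fitted, residual = m$residuals),
                 file.path(dir, "residuals.csv"))
  pd <- do.call(rbind, lapply(names(m$pd_curves), function(v) {
    data.frame(predictor = v, m$pd_curves[[v]])
  }))
  write_reef_csv(pd, file.path(dir, "pd_curves.csv"))
  report <- list(
    selected_predictors = m$selected_predictors,
    relative_influence = as.list(m$relative_influence),
    cv_r2 = m$cv_r2, global_cv_r2 = m$global_cv_r2, n_trees = m$n_trees,
    eta = m$model$eta, depth = m$model$depth,
    h_matrix = m$h_matrix,
    screen = list(collinearity = m$screen$collinearity,
                  vif = m$screen$vif, contribution = m$screen$contribution)
  )
  jsonlite::write_json(report, file.path(dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
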