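# End-to-end orchestration: simulate -> normalize -> weights -> index ->
# perceive -> change -> compare, with a manifest for bit-reproducibility.

#' Pipeline configuration
#'
#' Bundles the synthetic-landscape configuration with the analysis choices of
#' every downstream stage. Defaults follow the package's documented design
#' decisions (pooled normalization, score-aggregated AHP, zero-propagating
#' capacity aggregation normalized by the scale maximum).
#'
#' @param synthetic A [synthetic_config()].
#' @param n_zones Number of zones for zonal aggregation.
#' @param true_importance Named 0-9 vector of true ES importances driving the
#'   synthetic stakeholder scores.
#' @param weight_method Passed to [ahp_weights()].
#' @param normalization Passed to [normalize_stack()].
#' @param capacity_zero_policy,capacity_normalization Passed to
#'   [aggregate_capacity()].
#' @param baseline_epoch,final_epoch Epoch pair for the change index;
#'   defaults to the first and last configured epoch.
#' @param perception_inflation Added to the true capacities (clipped to
#'   \[0, 1\]) before generating stakeholder capacity scores, emulating
#'   systematic stakeholder over- (positive) or under-rating of ES potential
#'   relative to the models. Default 0.2.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            n_zones = 23,
                            true_importance = c(CR = 6, WP = 7, HQ = 6, DR = 8,
                                                R = 1, FP = 5, EP = 5, P = 4),
                            weight_method = "aggregate_scores",
                            normalization = "pooled",
                            capacity_zero_policy = "propagate",
                            capacity_normalization = "scale_max",
                            baseline_epoch = NULL, final_epoch = NULL,
                            perception_inflation = 0.2) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  if (!setequal(names(true_importance), es_ids())) {
    stop("`true_importance` must be named by the eight ES ids.", call. = FALSE)
  }
  baseline_epoch <- baseline_epoch %||% synthetic$epochs[1]
  final_epoch <- final_epoch %||% synthetic$epochs[length(synthetic$epochs)]
  if (!all(c(baseline_epoch, final_epoch) %in% synthetic$epochs)) {
    stop("Change epochs must be among the configured epochs.", call. = FALSE)
  }
  structure(list(
    synthetic = synthetic, n_zones = n_zones,
    true_importance = true_importance[es_ids()],
    weight_method = weight_method, normalization = normalization,
    capacity_zero_policy = capacity_zero_policy,
    capacity_normalization = capacity_normalization,
    baseline_epoch = baseline_epoch, final_epoch = final_epoch,
    perception_inflation = perception_inflation
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return The path (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  syn <- config$synthetic
  payload <- list(
    synthetic = list(
      grid_rows = syn$grid_rows, grid_cols = syn$grid_cols,
      cell_size = syn$cell_size, epochs = as.list(syn$epochs),
      class_codes = as.list(syn$class_codes),
      class_affinity = as.list(syn$class_affinity),
      smoothing_scale = syn$smoothing_scale,
      transition_rate = syn$transition_rate, noise_sd = syn$noise_sd,
      n_stakeholders = syn$n_stakeholders,
      score_dispersion = syn$score_dispersion, seed = syn$seed
    ),
    n_zones = config$n_zones,
    true_importance = as.list(config$true_importance),
    weight_method = config$weight_method,
    normalization = config$normalization,
    capacity_zero_policy = config$capacity_zero_policy,
    capacity_normalization = config$capacity_normalization,
    baseline_epoch = config$baseline_epoch,
    final_epoch = config$final_epoch,
    perception_inflation = config$perception_inflation
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  p <- yaml::read_yaml(path)
  syn <- p$synthetic
  pipeline_config(
    synthetic = synthetic_config(
      grid_rows = syn$grid_rows, grid_cols = syn$grid_cols,
      cell_size = syn$cell_size, epochs = unlist(syn$epochs),
      class_codes = unlist(syn$class_codes),
      class_affinity = unlist(syn$class_affinity),
      smoothing_scale = syn$smoothing_scale,
      transition_rate = syn$transition_rate, noise_sd = syn$noise_sd,
      n_stakeholders = syn$n_stakeholders,
      score_dispersion = syn$score_dispersion, seed = syn$seed
    ),
    n_zones = p$n_zones, true_importance = unlist(p$true_importance),
    weight_method = p$weight_method, normalization = p$normalization,
    capacity_zero_policy = p$capacity_zero_policy,
    capacity_normalization = p$capacity_normalization,
    baseline_epoch = p$baseline_epoch, final_epoch = p$final_epoch,
    perception_inflation = p$perception_inflation
  )
}

# deterministic pseudo-biophysical units per ES so the normalization stage
# has real work to do: raw = normalized * scale + offset
raw_unit_params <- function(seed) {
  with_seed(seed + 4L, {
    tibble::tibble(es_id = es_ids(),
                   scale = round(stats::runif(8, 5, 200), 2),
                   offset = round(stats::runif(8, 0, 20), 2))
  })
}

#' Run the full assessment pipeline on a synthetic landscape
#'
#' Executes every stage in order: landscape + ES simulation, pooled min-max
#' normalization, AHP weights from simulated stakeholder importance scores,
#' composite index per epoch, perception mapping from simulated capacity
#' scores, the baseline-to-final change index with SD classification and
#' zonal means, and the model-versus-stakeholder comparison report. With
#' `out_dir` set, all products are written (ASCII grids, CSV tables, JSON)
#' together with a manifest of MD5 checksums; re-running with the same
#' configuration reproduces the checksums bit-for-bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list of all in-memory products (`landcover`, `truth`,
#'   `raw_layers`, `es_layers`, `weights`, `index_layers`, `distribution`,
#'   `perceived_layers`, `perception_index`, `change`, `zonal`, `report`,
#'   `anova`, and `manifest` when written).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  syn <- config$synthetic
  epochs <- syn$epochs
  esv <- es_ids()

  # --- simulate -------------------------------------------------------------
  truth <- random_capacity_table(syn$class_codes, esv, seed = syn$seed + 3L)
  landcover <- generate_landcover(syn)
  zones <- generate_zones(syn, config$n_zones)
  units <- raw_unit_params(syn$seed)
  raw_layers <- list()
  for (es in esv) {
    u <- units[units$es_id == es, ]
    raw_layers[[es]] <- purrr::imap(landcover, function(lc, ep) {
      l <- generate_es_layer(lc, truth, es, syn$noise_sd,
                             seed = syn$seed + 100L * match(es, esv) +
                               match(ep, epochs))
      es_layer(l$values * u$scale + u$offset, es, ep, syn$cell_size,
               normalized = FALSE)
    })
  }
  truth_perceived <- dplyr::mutate(
    truth, capacity = pmin(pmax(.data$capacity + config$perception_inflation, 0), 1)
  )
  scores <- generate_stakeholder_scores(syn, config$true_importance,
                                        truth_perceived)

  # --- normalize ------------------------------------------------------------
  es_layers <- purrr::map(raw_layers, normalize_stack, mode = config$normalization)

  # --- weights --------------------------------------------------------------
  weights <- ahp_weights(scores$importance, method = config$weight_method)

  # --- index ----------------------------------------------------------------
  index_layers <- purrr::map(epochs, function(ep) {
    compute_index(purrr::map(es_layers, ep), weights)
  })
  names(index_layers) <- epochs
  distribution <- index_distribution(index_layers)
  contributions <- purrr::map(epochs, function(ep) {
    dplyr::mutate(es_contribution(purrr::map(es_layers, ep), weights),
                  epoch = ep)
  }) |> dplyr::bind_rows()
  lc_contrib <- landcover_contribution(index_layers[[config$final_epoch]],
                                       landcover[[config$final_epoch]])

  # --- perceive -------------------------------------------------------------
  capacity <- aggregate_capacity(scores$capacity,
                                 zero_policy = config$capacity_zero_policy,
                                 normalization = config$capacity_normalization)
  lc_final <- landcover[[config$final_epoch]]
  perceived_layers <- purrr::map(esv, function(es) apply_matrix(lc_final, capacity, es))
  names(perceived_layers) <- esv
  perception_index <- combined_perception_index(perceived_layers, weights)

  # --- change ---------------------------------------------------------------
  change <- purrr::map(esv, function(es) {
    ch <- change_index(es_layers[[es]][[config$baseline_epoch]],
                       es_layers[[es]][[config$final_epoch]])
    list(change = ch, classes = classify_change(ch))
  })
  names(change) <- esv
  zonal <- purrr::imap(change, function(ch, es) {
    dplyr::mutate(zonal_mean(ch$change, zones), es_id = es)
  }) |> dplyr::bind_rows() |>
    dplyr::select("zone_id", "es_id", mean_change_pct = "mean", "count", "empty")

  # --- compare --------------------------------------------------------------
  model_final <- purrr::map(es_layers, config$final_epoch)
  report <- comparison_report(model_final, perceived_layers,
                              index_layers[[config$final_epoch]],
                              perception_index, lc_final)
  idx_values <- purrr::imap(index_layers, function(l, ep) {
    tibble::tibble(epoch = ep, value = valid_values(l))
  }) |> dplyr::bind_rows()
  anova <- anova_across_epochs(idx_values$value, idx_values$epoch)

  out <- list(
    config = config, truth = truth, landcover = landcover, zones = zones,
    raw_layers = raw_layers, es_layers = es_layers, scores = scores,
    weights = weights, index_layers = index_layers,
    distribution = distribution, contributions = contributions,
    landcover_contribution = lc_contrib, capacity = capacity,
    perceived_layers = perceived_layers, perception_index = perception_index,
    change = change, zonal = zonal, report = report, anova = anova
  )
  if (!is.null(out_dir)) out$manifest <- write_pipeline_outputs(out, out_dir)
  invisible(out)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- out$config
  p <- function(...) file.path(out_dir, ...)
  write_pipeline_config(cfg, p("config.yaml"))
  for (ep in names(out$landcover)) {
    write_lc_layer(out$landcover[[ep]], p(sprintf("landcover_%s.asc", ep)),
                   labels = default_class_labels())
  }
  write_zone_map(out$zones, p("zones.asc"))
  for (es in names(out$es_layers)) {
    for (ep in names(out$es_layers[[es]])) {
      write_es_layer(out$es_layers[[es]][[ep]],
                     p(sprintf("es_%s_%s.asc", es, ep)))
    }
  }
  readr::write_csv(out$truth, p("true_capacity.csv"))
  readr::write_csv(out$scores$importance, p("importance_scores.csv"))
  readr::write_csv(out$scores$capacity, p("capacity_scores.csv"))
  write_weights_json(out$weights, p("weights.json"))
  for (ep in names(out$index_layers)) {
    write_asc(out$index_layers[[ep]]$values, p(sprintf("index_%s.asc", ep)),
              out$index_layers[[ep]]$cell_size)
  }
  readr::write_csv(out$distribution, p("index_distribution.csv"))
  readr::write_csv(out$contributions, p("es_contributions.csv"))
  readr::write_csv(out$landcover_contribution, p("landcover_contribution.csv"))
  readr::write_csv(out$capacity, p("capacity_matrix.csv"))
  write_asc(out$perception_index$values, p("perception_index.asc"),
            out$perception_index$cell_size)
  for (es in names(out$change)) {
    write_asc(out$change[[es]]$change$values, p(sprintf("change_%s.asc", es)),
              out$change[[es]]$change$cell_size)
    cls <- out$change[[es]]$classes
    ids <- matrix(match(cls$values, change_class_levels()), nrow(cls$values))
    write_asc(ids, p(sprintf("change_class_%s.asc", es)), cls$cell_size)
  }
  readr::write_csv(tibble::tibble(code_id = seq_along(change_class_levels()),
                                  class = change_class_levels(),
                                  color = unname(attr(out$change[[1]]$classes,
                                                      "palette"))),
                   p("change_class_legend.csv"))
  readr::write_csv(out$zonal, p("zonal_change.csv"))
  report_json <- list(
    overall_percent_difference = out$report$overall_percent_difference,
    paired_t = as.list(out$report$paired_t),
    per_es = out$report$per_es,
    cross_correlations = as.list(out$report$correlations$cross),
    correlation_support = out$report$correlations$support,
    anova = as.list(out$anova$anova)
  )
  jsonlite::write_json(report_json, p("comparison_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = cfg$synthetic$seed,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = unname(tools::md5sum(p("config.yaml"))),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files
    ))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  manifest
}
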