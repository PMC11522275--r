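# Normalization of raw ES layers to the [0, 1] potential scale and
# class-by-epoch summaries.

#' Min-max normalize an ES stack to \[0, 1\]
#'
#' Scales the raw biophysical layers of one ES using the pooled minimum and
#' maximum across all epochs (default), so that the temporal change index and
#' class trajectories are not distorted by per-year rescaling; a per-epoch
#' mode is available for sensitivity analysis. Observed extremes define the
#' scaling (raw model outputs have no universal bounds); nodata pixels are
#' excluded everywhere.
#'
#' @param layers List of raw [es_layer()] objects for a single ES, one per
#'   epoch.
#' @param mode `"pooled"` (one min/max across all epochs) or `"per_epoch"`.
#' @return List of normalized [es_layer()] objects in matching order.
#' @export
normalize_stack <- function(layers, mode = c("pooled", "per_epoch")) {
  mode <- match.arg(mode)
  if (!length(layers)) stop("Need at least one layer.", call. = FALSE)
  ids <- unique(vapply(layers, function(l) l$es_id, ""))
  if (length(ids) != 1) {
    stop("All layers in a stack must share one es_id; got: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  for (l in layers[-1]) check_aligned(layers[[1]], l, "ES stack")
  rescale <- function(l, lo, hi) {
    if (hi - lo <= 0) {
      stop(sprintf("Constant stack for ES %s: pooled range is zero.", ids),
           call. = FALSE)
    }
    es_layer((l$values - lo) / (hi - lo), l$es_id, l$epoch, l$cell_size,
             normalized = TRUE)
  }
  if (mode == "pooled") {
    pooled <- unlist(lapply(layers, valid_values))
    if (!length(pooled)) stop("No valid pixels in stack for ES ", ids, call. = FALSE)
    out <- lapply(layers, rescale, lo = min(pooled), hi = max(pooled))
  } else {
    out <- lapply(layers, function(l) {
      v <- valid_values(l)
      rescale(l, min(v), max(v))
    })
  }
  names(out) <- names(layers)
  out
}

#' Mean ES potential by land-cover class and epoch
#'
#' For each (class, ES, epoch) combination, the mean normalized potential over
#' valid pixels plus the pixel count. Classes absent in an epoch are reported
#' with count 0 and `NA` mean so trajectories keep a complete class axis.
#'
#' @param es_layers List of [es_layer()] objects (any mix of ES/epoch).
#' @param lc_layers List of [lc_layer()] objects named/matched by epoch.
#' @return Tibble `class_code`, `es_id`, `epoch`, `mean`, `count`.
#' @export
class_potential_summary <- function(es_layers, lc_layers) {
  if (inherits(es_layers, "es_layer")) es_layers <- list(es_layers)
  if (inherits(lc_layers, "lc_layer")) lc_layers <- list(lc_layers)
  lc_by_epoch <- stats::setNames(lc_layers,
                                 vapply(lc_layers, function(l) l$epoch, ""))
  all_classes <- sort(unique(unlist(
    lapply(lc_layers, function(l) unique(l$values[!is.na(l$values)]))
  )))
  rows <- purrr::map(es_layers, function(es) {
    lc <- lc_by_epoch[[es$epoch]]
    if (is.null(lc)) {
      stop("No land-cover layer for epoch ", es$epoch, call. = FALSE)
    }
    check_aligned(es, lc, "ES vs land cover")
    ok <- !is.na(es$values) & !is.na(lc$values)
    tibble::tibble(class_code = as.vector(lc$values[ok]),
                   value = as.vector(es$values[ok])) |>
      dplyr::summarise(mean = mean(.data$value), count = dplyr::n(),
                       .by = "class_code") |>
      dplyr::full_join(tibble::tibble(class_code = all_classes),
                       by = "class_code") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                    es_id = es$es_id, epoch = es$epoch)
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("class_code", "es_id", "epoch", "mean", "count") |>
    dplyr::arrange(.data$es_id, .data$epoch, .data$class_code)
}

#' Class potential trajectories plot
#'
#' Line plot of mean class potential across epochs, faceted by ES — the
#' class-trajectory view of how each land-cover class's ES potential evolves.
#'
#' @param summary Output of [class_potential_summary()].
#' @return A ggplot object.
#' @export
plot_class_potential <- function(summary) {
  ggplot2::ggplot(
    dplyr::filter(summary, .data$count > 0),
    ggplot2::aes(x = .data$epoch, y = .data$mean,
                 colour = .data$class_code, group = .data$class_code)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~es_id) +
    ggplot2::labs(x = "Epoch", y = "Mean normalized potential",
                  colour = "Land cover") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
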