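# Temporal percent-change index between a baseline and final epoch, its
# standard-deviation classification, and zonal aggregation.

#' Percent change in ES potential between two epochs
#'
#' Per-pixel percent change `(final - baseline) / baseline * 100`. The ratio
#' is undefined where the baseline is zero: such pixels (baseline below
#' `tolerance`) are masked invalid rather than patched with an epsilon, and
#' their count is reported in the `masked_zero_baseline` attribute.
#'
#' @param baseline,final Normalized [es_layer()] objects for the same ES on
#'   aligned grids; the baseline epoch must precede the final.
#' @param tolerance Baseline values at or below this are treated as zero.
#' @return A `change_layer` grid of percent changes.
#' @export
#' @examples
#' b <- es_layer(matrix(0.5, 2, 2), "CR", "1990", normalized = TRUE)
#' f <- es_layer(matrix(0.75, 2, 2), "CR", "2018", normalized = TRUE)
#' change_index(b, f)$values[1, 1]  # 50
change_index <- function(baseline, final, tolerance = 1e-12) {
  stopifnot(inherits(baseline, "es_layer"), inherits(final, "es_layer"))
  if (baseline$es_id != final$es_id) {
    stop(sprintf("es_id mismatch: %s vs %s.", baseline$es_id, final$es_id),
         call. = FALSE)
  }
  if (as.character(baseline$epoch) >= as.character(final$epoch)) {
    stop("Baseline epoch must precede the final epoch.", call. = FALSE)
  }
  check_aligned(baseline, final, "change epochs")
  b <- baseline$values; f <- final$values
  ok <- !is.na(b) & !is.na(f)
  zero_b <- ok & b <= tolerance
  ces <- matrix(NA_real_, nrow(b), ncol(b))
  use <- ok & !zero_b
  ces[use] <- (f[use] - b[use]) / b[use] * 100
  out <- new_grid_layer(ces, baseline$cell_size, "change_layer",
                        list(es_id = baseline$es_id,
                             baseline_epoch = baseline$epoch,
                             final_epoch = final$epoch))
  attr(out, "masked_zero_baseline") <- sum(zero_b)
  out
}

change_class_levels <- function() {
  c("strong_decline", "decline", "stable", "improvement", "strong_improvement")
}

#' Classify percent change into five standard-deviation classes
#'
#' The change values are standardized per ES over valid pixels
#' (`z = (CES - mean) / sd`) and labelled: strong decline `z <= -1.5`, decline
#' `-1.5 < z <= -0.5`, stable `-0.5 < z < 0.5`, improvement
#' `0.5 <= z < 1.5`, strong improvement `z >= 1.5`. Boundaries are closed on
#' the outer side of each non-stable class, mirrored about zero.
#'
#' @param change A `change_layer` from [change_index()].
#' @return A `change_class_layer` grid of factor labels (stored as a
#'   character matrix) with the class palette as the `palette` attribute.
#' @export
classify_change <- function(change) {
  stopifnot(inherits(change, "change_layer"))
  v <- valid_values(change)
  if (length(v) < 2) stop("Need at least 2 valid pixels.", call. = FALSE)
  s <- stats::sd(v)
  if (s == 0) stop("Zero spread: change values are constant.", call. = FALSE)
  z <- (change$values - mean(v)) / s
  lab <- matrix(NA_character_, nrow(z), ncol(z))
  lab[!is.na(z)] <- "stable"
  lab[!is.na(z) & z <= -0.5] <- "decline"
  lab[!is.na(z) & z <= -1.5] <- "strong_decline"
  lab[!is.na(z) & z >= 0.5] <- "improvement"
  lab[!is.na(z) & z >= 1.5] <- "strong_improvement"
  out <- new_grid_layer(lab, change$cell_size, "change_class_layer",
                        list(es_id = change$es_id,
                             baseline_epoch = change$baseline_epoch,
                             final_epoch = change$final_epoch))
  attr(out, "palette") <- c(
    strong_decline = "#8B0000", decline = "#E69F00", stable = "#BEBEBE",
    improvement = "#90EE90", strong_improvement = "#006400"
  )
  out
}

#' Tabulate change classes
#'
#' @param class_layer A `change_class_layer`.
#' @return Tibble `class`, `count`, `share` over valid pixels, with all five
#'   classes present.
#' @export
change_class_table <- function(class_layer) {
  stopifnot(inherits(class_layer, "change_class_layer"))
  v <- valid_values(class_layer)
  counts <- table(factor(v, levels = change_class_levels()))
  tibble::tibble(class = names(counts), count = as.integer(counts),
                 share = as.integer(counts) / length(v))
}

#' Zonal means of a layer
#'
#' Mean of valid pixels per zone on the common equal-area grid. Zones with no
#' valid pixel are flagged (`NA` mean, `empty = TRUE`) rather than reported
#' as zero.
#'
#' @param layer Any numeric grid layer (`es_layer`, `index_layer`,
#'   `change_layer`).
#' @param zones A [zone_map()] aligned with `layer`.
#' @return Tibble `zone_id`, `mean`, `count`, `empty`.
#' @export
zonal_mean <- function(layer, zones) {
  stopifnot(inherits(zones, "zone_map"))
  check_aligned(layer, zones, "layer vs zones")
  all_zones <- sort(unique(zones$values[!is.na(zones$values)]))
  ok <- !is.na(layer$values) & !is.na(zones$values)
  agg <- tibble::tibble(zone_id = as.vector(zones$values[ok]),
                        value = as.vector(layer$values[ok])) |>
    dplyr::summarise(mean = mean(.data$value), count = dplyr::n(),
                     .by = "zone_id")
  tibble::tibble(zone_id = all_zones) |>
    dplyr::left_join(agg, by = "zone_id") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  empty = .data$count == 0L)
}

#' Change-class map plot
#'
#' @param class_layer A `change_class_layer`.
#' @return A ggplot tile map using the decline-to-improvement palette.
#' @exportS3Method ggplot2::autoplot
autoplot.change_class_layer <- function(class_layer, ...) {
  df <- as_tibble(class_layer) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(value = factor(.data$value, levels = change_class_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = attr(class_layer, "palette"),
                               drop = FALSE, name = "Change class") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
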