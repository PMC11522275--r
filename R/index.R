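# The composite weighted-overlay index: per-pixel weighted sum of the
# normalized ES layers with stakeholder-derived weights.

check_weights <- function(weights) {
  if (!is.data.frame(weights) || !all(c("es_id", "weight") %in% names(weights))) {
    stop("`weights` must be a tibble with columns es_id, weight.", call. = FALSE)
  }
  if (any(weights$weight < 0)) stop("Weights must be non-negative.", call. = FALSE)
  if (abs(sum(weights$weight) - 1) > 1e-9) {
    stop("Weights must sum to 1 (got ", format(sum(weights$weight)), ").",
         call. = FALSE)
  }
  invisible(TRUE)
}

match_layers_weights <- function(es_layers, weights, allow_subset,
                                 renormalize_missing) {
  ids <- vapply(es_layers, function(l) l$es_id, "")
  if (anyDuplicated(ids)) stop("Duplicate ES layers supplied.", call. = FALSE)
  names(es_layers) <- ids
  missing <- setdiff(weights$es_id, ids)
  if (length(missing)) {
    if (!allow_subset) {
      stop("Missing ES layer(s): ", paste(missing, collapse = ", "),
           ". Pass allow_subset = TRUE to combine a subset with re-normalized weights.",
           call. = FALSE)
    }
    weights <- dplyr::filter(weights, .data$es_id %in% ids)
    weights$weight <- weights$weight / sum(weights$weight)
  }
  extra <- setdiff(ids, weights$es_id)
  if (length(extra)) {
    stop("No weight for ES layer(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  list(layers = es_layers[weights$es_id], weights = weights)
}

#' Compute the composite ES index for one epoch
#'
#' Per-pixel weighted sum of the normalized ES layers,
#' `index = sum_i w_i * ES_i`, with weights summing to 1. A pixel is invalid
#' if any contributing ES is invalid there (no spatially varying effective
#' weights); set `renormalize_missing = TRUE` to instead re-normalize weights
#' over the ES valid at each pixel.
#'
#' @param es_layers List of normalized [es_layer()] objects, one per ES, all
#'   for one epoch on aligned grids.
#' @param weights Tibble `es_id`, `weight` (e.g. from [ahp_weights()] or
#'   [default_weights()]).
#' @param allow_subset Allow fewer ES than weights rows; the matching weights
#'   are re-normalized to sum to 1.
#' @param renormalize_missing Per-pixel weight re-normalization over valid ES.
#' @return An [index_layer()].
#' @export
compute_index <- function(es_layers, weights, allow_subset = FALSE,
                          renormalize_missing = FALSE) {
  check_weights(weights)
  m <- match_layers_weights(es_layers, weights, allow_subset, renormalize_missing)
  layers <- m$layers; weights <- m$weights
  epochs <- unique(vapply(layers, function(l) l$epoch, ""))
  if (length(epochs) != 1) {
    stop("All layers must share one epoch; got: ",
         paste(epochs, collapse = ", "), call. = FALSE)
  }
  for (l in layers) {
    if (!isTRUE(l$normalized)) {
      stop("ES layer ", l$es_id, " is not normalized.", call. = FALSE)
    }
  }
  for (l in layers[-1]) check_aligned(layers[[1]], l, "index inputs")
  d <- dim(layers[[1]]$values)
  acc <- matrix(0, d[1], d[2])
  wsum <- matrix(0, d[1], d[2])
  any_na <- matrix(FALSE, d[1], d[2])
  for (i in seq_along(layers)) {
    v <- layers[[i]]$values
    na <- is.na(v)
    any_na <- any_na | na
    v[na] <- 0
    acc <- acc + weights$weight[i] * v
    wsum <- wsum + weights$weight[i] * !na
  }
  if (renormalize_missing) {
    vals <- ifelse(wsum > 0, acc / wsum, NA_real_)
  } else {
    vals <- acc
    vals[any_na] <- NA_real_
  }
  index_layer(vals, epochs, weights, layers[[1]]$cell_size)
}

#' Distribution summary of index layers across epochs
#'
#' Per-epoch median, lower and upper quartiles (linear-interpolation
#' convention, `stats::quantile` type 7), minimum and maximum over valid
#' pixels — the boxplot statistics of the index.
#'
#' @param index_layers List of [index_layer()] objects.
#' @return An `index_distribution` tibble: `epoch`, `median`, `q1`, `q3`,
#'   `min`, `max`, `n`.
#' @export
index_distribution <- function(index_layers) {
  if (inherits(index_layers, "index_layer")) index_layers <- list(index_layers)
  if (!length(index_layers)) stop("Need at least one epoch.", call. = FALSE)
  out <- purrr::map(index_layers, function(l) {
    v <- valid_values(l)
    if (!length(v)) stop("No valid pixels in epoch ", l$epoch, call. = FALSE)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(epoch = l$epoch, median = q[2], q1 = q[1], q3 = q[3],
                   min = min(v), max = max(v), n = length(v))
  }) |> dplyr::bind_rows()
  class(out) <- c("index_distribution", class(out))
  out
}

#' Per-ES contribution shares to the index mean
#'
#' `share_i = w_i * mean(ES_i) / sum_j w_j * mean(ES_j)` over jointly valid
#' pixels; shares sum to 1 and identify which ES drives the composite index.
#'
#' @inheritParams compute_index
#' @return Tibble `es_id`, `weight`, `es_mean`, `contribution`, `share`.
#' @export
es_contribution <- function(es_layers, weights, allow_subset = FALSE) {
  check_weights(weights)
  m <- match_layers_weights(es_layers, weights, allow_subset, FALSE)
  layers <- m$layers; weights <- m$weights
  ok <- Reduce(`&`, lapply(layers, grid_mask))
  means <- vapply(layers, function(l) mean(l$values[ok]), 0)
  contrib <- weights$weight * means
  total <- sum(contrib)
  if (total <= 0) stop("Index mean is zero; shares undefined.", call. = FALSE)
  tibble::tibble(es_id = weights$es_id, weight = weights$weight,
                 es_mean = unname(means), contribution = unname(contrib),
                 share = unname(contrib) / total)
}

#' Mean index by land-cover class
#'
#' Average index value per land-cover class code with pixel counts — the
#' land-cover contribution view of the composite index.
#'
#' @param index An [index_layer()].
#' @param landcover An aligned [lc_layer()].
#' @return Tibble `class_code`, `mean`, `count`.
#' @export
landcover_contribution <- function(index, landcover) {
  stopifnot(inherits(index, "index_layer"), inherits(landcover, "lc_layer"))
  check_aligned(index, landcover, "index vs land cover")
  ok <- grid_mask(index) & grid_mask(landcover)
  tibble::tibble(class_code = as.vector(landcover$values[ok]),
                 value = as.vector(index$values[ok])) |>
    dplyr::summarise(mean = mean(.data$value), count = dplyr::n(),
                     .by = "class_code") |>
    dplyr::arrange(.data$class_code)
}

#' Boxplot-style plot of the index distribution across epochs
#'
#' @param object An `index_distribution` tibble.
#' @param ... Unused.
#' @return A ggplot object drawing median, quartile box and min-max whiskers
#'   per epoch from the precomputed statistics.
#' @exportS3Method ggplot2::autoplot
autoplot.index_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                           width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3),
                           fill = "grey85", width = 0.6) +
    ggplot2::labs(x = "Epoch", y = "Composite index") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
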