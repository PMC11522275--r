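# Stakeholder capacity-matrix machinery: aggregate 0-5 expert scores of each
# land-cover class's capacity to supply each ES, map them over a land-cover
# layer, and combine the perceived layers with the same weights as the
# composite index.

#' Aggregate stakeholder capacity scores
#'
#' Geometric mean of the 0-5 scores across stakeholders for each
#' (class, ES) cell, then normalized to \[0, 1\]. By default a single
#' "no potential at all" (0) judgment zeroes the cell (geometric-mean
#' zero-propagation); `zero_policy = "floor"` replaces 0 by 0.5 instead,
#' mirroring the AHP importance policy. Normalization divides by the fixed
#' scale maximum 5 (preserving the absolute anchor meaning); min-max over
#' observed cells per ES is available via `normalization = "minmax"`.
#'
#' @param raw Tibble `stakeholder`, `class_code`, `es_id`, `score` with
#'   integer scores in 0-5.
#' @param zero_policy `"propagate"` (default) or `"floor"`.
#' @param normalization `"scale_max"` (default, divide by 5) or `"minmax"`
#'   (per-ES min-max over class cells).
#' @return Tibble `class_code`, `es_id`, `value` (aggregated capacity in
#'   \[0, 1\]) and `gm` (geometric mean on the 0-5 scale).
#' @export
aggregate_capacity <- function(raw, zero_policy = c("propagate", "floor"),
                               normalization = c("scale_max", "minmax")) {
  zero_policy <- match.arg(zero_policy)
  normalization <- match.arg(normalization)
  if (!nrow(raw)) stop("Empty capacity score table.", call. = FALSE)
  if (any(raw$score < 0 | raw$score > 5)) {
    stop("Capacity scores must lie in [0, 5].", call. = FALSE)
  }
  agg <- raw |>
    dplyr::mutate(score = if (zero_policy == "floor") {
      ifelse(.data$score == 0, 0.5, .data$score)
    } else .data$score) |>
    dplyr::summarise(
      gm = if (any(.data$score == 0)) 0 else exp(mean(log(.data$score))),
      .by = c("class_code", "es_id")
    )
  if (normalization == "scale_max") {
    agg$value <- agg$gm / 5
  } else {
    agg <- agg |>
      dplyr::mutate(value = {
        rng <- range(.data$gm)
        if (diff(rng) == 0) rep(0, length(.data$gm))
        else (.data$gm - rng[1]) / diff(rng)
      }, .by = "es_id")
  }
  dplyr::select(agg, "class_code", "es_id", "value", "gm")
}

#' Map a capacity matrix over a land-cover layer
#'
#' Per-pixel lookup of the aggregated capacity of the pixel's land-cover
#' class for one ES, producing a perceived-ES potential layer. Nodata
#' propagates; an unmapped class code is an error naming the code.
#'
#' @param landcover An [lc_layer()].
#' @param matrix Aggregated capacity tibble (`class_code`, `es_id`, `value`)
#'   from [aggregate_capacity()].
#' @param es_id The ES column to apply.
#' @return A normalized [es_layer()] that is piecewise constant on land-cover
#'   patches.
#' @export
apply_matrix <- function(landcover, matrix, es_id) {
  stopifnot(inherits(landcover, "lc_layer"))
  es_id <- match.arg(es_id, es_ids())
  col <- dplyr::filter(matrix, .data$es_id == !!es_id)
  present <- unique(landcover$values[!is.na(landcover$values)])
  unmapped <- setdiff(present, col$class_code)
  if (length(unmapped)) {
    stop("Land-cover class(es) not in capacity matrix: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  lut <- stats::setNames(col$value, col$class_code)
  vals <- base::matrix(lut[landcover$values], nrow(landcover$values))
  es_layer(vals, es_id, landcover$epoch, landcover$cell_size, normalized = TRUE)
}

#' Combined stakeholder perception index
#'
#' Weighted sum of the perceived-ES layers with the same weight vector and
#' the same contract as [compute_index()] — the stakeholder counterpart of
#' the composite model index.
#'
#' @param perceived_layers List of perceived [es_layer()] objects from
#'   [apply_matrix()].
#' @inheritParams compute_index
#' @return An [index_layer()].
#' @export
combined_perception_index <- function(perceived_layers, weights,
                                      allow_subset = FALSE,
                                      renormalize_missing = FALSE) {
  compute_index(perceived_layers, weights, allow_subset, renormalize_missing)
}

#' Dispersion diagnostics of stakeholder capacity judgments
#'
#' Agreement among stakeholders is summarized by the coefficient of variation
#' (sd/mean across stakeholders, sample sd) per (class, ES) cell and its
#' per-ES mean. When `pairwise = TRUE`, an AHP consistency ratio per ES is
#' added by treating the per-class mean scores as aggregate scores and
#' building a class-by-class pairwise ratio matrix.
#'
#' @param raw Tibble `stakeholder`, `class_code`, `es_id`, `score`.
#' @param pairwise Also compute an AHP-style consistency ratio per ES.
#' @return List with tibbles `by_cell` (`class_code`, `es_id`, `mean`, `sd`,
#'   `cv`) and `by_es` (`es_id`, `mean_cv` and, if requested,
#'   `consistency_ratio`).
#' @export
judgment_consistency <- function(raw, pairwise = FALSE) {
  n_st <- dplyr::n_distinct(raw$stakeholder)
  if (n_st < 2) stop("Need at least 2 stakeholders.", call. = FALSE)
  by_cell <- raw |>
    dplyr::summarise(mean = mean(.data$score), sd = stats::sd(.data$score),
                     .by = c("class_code", "es_id")) |>
    dplyr::mutate(cv = ifelse(.data$mean > 0, .data$sd / .data$mean,
                              ifelse(.data$sd == 0, 0, NA_real_)))
  by_es <- by_cell |>
    dplyr::summarise(mean_cv = mean(.data$cv, na.rm = TRUE), .by = "es_id")
  if (pairwise) {
    crs <- raw |>
      dplyr::summarise(mean = mean(.data$score), .by = c("es_id", "class_code")) |>
      dplyr::group_split(.data$es_id) |>
      purrr::map(function(d) {
        s <- pmax(d$mean, 0.5)  # keep ratios finite for all-zero classes
        pm <- build_pairwise_matrix(stats::setNames(s, d$class_code))
        tibble::tibble(es_id = d$es_id[1], consistency_ratio = consistency_ratio(pm))
      }) |>
      dplyr::bind_rows()
    by_es <- dplyr::left_join(by_es, crs, by = "es_id")
  }
  list(by_cell = by_cell, by_es = by_es)
}
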