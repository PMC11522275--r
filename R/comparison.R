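# Agreement between the model-based composite index products and the
# stakeholder perception products: correlation matrices, per-ES mean
# differences, overall percent difference, paired t-test and one-way ANOVA.

#' Pearson correlation between two raster layers
#'
#' Pearson r over jointly valid pixels. Requires at least 3 overlapping
#' pixels and non-degenerate variance in both layers.
#'
#' @param a,b Aligned numeric grid layers.
#' @return Scalar in \[-1, 1\].
#' @export
raster_correlation <- function(a, b) {
  check_aligned(a, b, "correlation layers")
  ok <- grid_mask(a) & grid_mask(b)
  if (sum(ok) < 3) stop("Fewer than 3 jointly valid pixels.", call. = FALSE)
  x <- a$values[ok]; y <- b$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Zero variance in one of the layers.", call. = FALSE)
  }
  stats::cor(x, y)
}

# per-ES value vectors on the requested support
comparison_support <- function(layers, landcover, support) {
  if (support == "pixel") {
    ok <- Reduce(`&`, lapply(layers, grid_mask))
    lapply(layers, function(l) l$values[ok])
  } else {
    if (is.null(landcover)) {
      stop("Class-mean support needs a land-cover layer.", call. = FALSE)
    }
    lapply(layers, function(l) {
      cs <- class_potential_summary(list(l), list(landcover))
      stats::setNames(cs$mean, cs$class_code)
    })
  }
}

#' Within- and cross-approach correlation matrices
#'
#' Three matrices quantifying trade-offs and agreement: pairwise Pearson
#' correlations among the model ES layers, among the perceived ES layers, and
#' between each model/perceived pair. Default support is one point per
#' land-cover class (the class-mean view of the landscape); pixel support is
#' available via `support = "pixel"`.
#'
#' @param model_layers,perceived_layers Lists of normalized [es_layer()]
#'   objects covering the same ES set, same epoch.
#' @param landcover [lc_layer()] defining the class support (required for the
#'   default support).
#' @param support `"class_mean"` or `"pixel"`.
#' @return List with `within_model` and `within_perceived` (symmetric
#'   unit-diagonal matrices), `cross` (named vector of per-ES model-vs-
#'   perceived correlations), and `support`.
#' @export
correlation_matrices <- function(model_layers, perceived_layers,
                                 landcover = NULL,
                                 support = c("class_mean", "pixel")) {
  support <- match.arg(support)
  ids_m <- unname(vapply(model_layers, function(l) l$es_id, ""))
  ids_p <- unname(vapply(perceived_layers, function(l) l$es_id, ""))
  if (!setequal(ids_m, ids_p)) {
    stop("Model and perceived layer sets cover different ES.", call. = FALSE)
  }
  names(model_layers) <- ids_m
  perceived_layers <- stats::setNames(perceived_layers, ids_p)[ids_m]
  vm <- comparison_support(model_layers, landcover, support)
  vp <- comparison_support(perceived_layers, landcover, support)
  cor_of <- function(vals) {
    n <- length(vals)
    m <- diag(n)
    dimnames(m) <- list(ids_m, ids_m)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      r <- tryCatch(stats::cor(vals[[i]], vals[[j]]), error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- r
    }
    m
  }
  cross <- vapply(seq_along(vm), function(i) stats::cor(vm[[i]], vp[[i]]), 0)
  list(within_model = cor_of(vm), within_perceived = cor_of(vp),
       cross = stats::setNames(cross, ids_m), support = support)
}

#' Per-ES difference between stakeholder and model means
#'
#' Plain difference `stakeholder_mean - model_mean` on the common \[0, 1\]
#' scale, reported at full precision and rounded to 2 decimals (the precision
#' of published comparison tables). Positive values mean stakeholders rate
#' the ES higher than the models.
#'
#' @param model_means,stakeholder_means Named numeric vectors (per ES) in
#'   \[0, 1\], or tibbles with `es_id` and `mean` columns.
#' @return Tibble `es_id`, `model_mean`, `stakeholder_mean`, `difference`,
#'   `difference_2dp`.
#' @export
per_es_difference <- function(model_means, stakeholder_means) {
  as_named <- function(x, what) {
    if (is.data.frame(x)) x <- stats::setNames(x$mean, x$es_id)
    if (is.null(names(x))) stop(what, " must be named by ES id.", call. = FALSE)
    x
  }
  m <- as_named(model_means, "model_means")
  s <- as_named(stakeholder_means, "stakeholder_means")
  if (!setequal(names(m), names(s))) {
    stop("Mean vectors cover different ES sets.", call. = FALSE)
  }
  s <- s[names(m)]
  if (any(m < 0 | m > 1 | s < 0 | s > 1)) {
    stop("Means must lie on the [0, 1] normalized scale.", call. = FALSE)
  }
  d <- s - m
  tibble::tibble(es_id = names(m), model_mean = unname(m),
                 stakeholder_mean = unname(s), difference = unname(d),
                 difference_2dp = round(unname(d), 2))
}

#' Overall percent difference between two index layers
#'
#' `100 * (mean_perceived - mean_model) / mean_model` over jointly valid
#' pixels: how much higher (positive) or lower the stakeholder-perceived
#' index is than the model index on average. `denominator = "perceived"`
#' gives the alternative reading.
#'
#' @param model_index,perceived_index Aligned [index_layer()] objects.
#' @param denominator Which mean divides the difference.
#' @return Percent (scalar).
#' @export
overall_percent_difference <- function(model_index, perceived_index,
                                       denominator = c("model", "perceived")) {
  denominator <- match.arg(denominator)
  check_aligned(model_index, perceived_index, "index layers")
  ok <- grid_mask(model_index) & grid_mask(perceived_index)
  if (!any(ok)) stop("No jointly valid pixels.", call. = FALSE)
  mm <- mean(model_index$values[ok])
  mp <- mean(perceived_index$values[ok])
  den <- if (denominator == "model") mm else mp
  if (den <= 0) stop("Zero denominator mean.", call. = FALSE)
  100 * (mp - mm) / den
}

#' Paired t-test between per-ES mean vectors
#'
#' Classical paired t-test (two-sided, Student t with n-1 degrees of
#' freedom) of stakeholder versus model per-ES means.
#'
#' @param model_means,stakeholder_means Equal-length numeric vectors.
#' @return Tibble `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(model_means, stakeholder_means) {
  if (length(model_means) != length(stakeholder_means)) {
    stop("Vectors must have equal length.", call. = FALSE)
  }
  if (length(model_means) < 2) stop("Need n >= 2 pairs.", call. = FALSE)
  d <- as.numeric(stakeholder_means) - as.numeric(model_means)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, p = 1, df = length(d) - 1, mean_difference = 0))
    }
    stop("Zero variance of differences.", call. = FALSE)
  }
  ht <- stats::t.test(stakeholder_means, model_means, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), p = ht$p.value,
                 df = unname(ht$parameter), mean_difference = mean(d))
}

#' One-way ANOVA across epochs with per-group normality checks
#'
#' Equal-variance one-way ANOVA of the values grouped by epoch, plus a
#' Shapiro-Wilk normality test per group. Shapiro-Wilk is limited to 5,000
#' observations; larger groups are subsampled deterministically (seeded by
#' group index) before testing, which is recorded in the output.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (epoch labels) of the same length.
#' @return List with `anova` (tibble `F`, `p`, `df_between`, `df_within`) and
#'   `shapiro` (tibble `group`, `W`, `p`, `n`, `subsampled`).
#' @export
anova_across_epochs <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("Need >= 2 groups.", call. = FALSE)
  sizes <- table(droplevels(groups))
  if (any(sizes < 2)) {
    stop("Each group needs >= 2 values; degenerate group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  if (stats::var(values) == 0) {
    # no variation at all: between-group mean square is zero
    k <- nlevels(droplevels(groups))
    ow <- list(statistic = c(F = 0), p.value = 1,
               parameter = c(k - 1, length(values) - k))
  } else {
    ow <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  }
  shapiro <- purrr::imap(split(values, droplevels(groups)), function(v, g) {
    sub <- length(v) > 5000
    if (sub) v <- with_seed(match(g, levels(droplevels(groups))),
                            sample(v, 5000))
    if (stats::sd(v) == 0) {
      tibble::tibble(group = g, W = NA_real_, p = NA_real_,
                     n = length(v), subsampled = sub)
    } else {
      sw <- stats::shapiro.test(v)
      tibble::tibble(group = g, W = unname(sw$statistic), p = sw$p.value,
                     n = length(v), subsampled = sub)
    }
  }) |> dplyr::bind_rows()
  list(
    anova = tibble::tibble(F = unname(ow$statistic), p = ow$p.value,
                           df_between = unname(ow$parameter[1]),
                           df_within = unname(ow$parameter[2])),
    shapiro = shapiro
  )
}

#' Model-versus-stakeholder comparison report
#'
#' One-call wrapper producing the full agreement report for one epoch:
#' correlation matrices (class-mean support), per-ES mean differences on the
#' chosen support, overall percent difference of the two composite indices,
#' and the paired t-test over the per-ES means.
#'
#' @param model_layers,perceived_layers Lists of normalized [es_layer()]
#'   objects for the same ES set and epoch.
#' @param model_index,perceived_index The two composite [index_layer()]s.
#' @param landcover [lc_layer()] for the class-mean correlation support.
#' @return A `comparison_report` list.
#' @export
comparison_report <- function(model_layers, perceived_layers,
                              model_index, perceived_index, landcover) {
  ids <- vapply(model_layers, function(l) l$es_id, "")
  ok <- Reduce(`&`, c(lapply(model_layers, grid_mask),
                      lapply(perceived_layers, grid_mask)))
  mean_on <- function(l) mean(l$values[ok])
  m_means <- stats::setNames(vapply(model_layers, mean_on, 0), ids)
  p_means <- stats::setNames(
    vapply(perceived_layers, mean_on, 0),
    vapply(perceived_layers, function(l) l$es_id, "")
  )[ids]
  out <- list(
    correlations = correlation_matrices(model_layers, perceived_layers,
                                        landcover),
    per_es = per_es_difference(m_means, p_means),
    overall_percent_difference =
      overall_percent_difference(model_index, perceived_index),
    paired_t = paired_t_test(m_means, p_means)
  )
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  overall percent difference: %+.1f%%\n",
              x$overall_percent_difference))
  cat(sprintf("  paired t: t = %.3f, df = %d, p = %.4g\n",
              x$paired_t$t, x$paired_t$df, x$paired_t$p))
  cat("  per-ES differences (stakeholder - model):\n")
  print(x$per_es)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.comparison_report <- function(x, ...) {
  x$per_es
}

#' @exportS3Method generics::glance
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    overall_percent_difference = x$overall_percent_difference,
    t = x$paired_t$t, p = x$paired_t$p, df = x$paired_t$df,
    mean_cross_correlation = mean(x$correlations$cross)
  )
}

#' Correlation-matrix heat map
#'
#' @param m A correlation matrix (e.g. `within_model` from
#'   [correlation_matrices()]).
#' @return A ggplot tile plot with the correlation values printed.
#' @export
plot_correlation_matrix <- function(m) {
  df <- tibble::tibble(
    a = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    b = factor(rep(colnames(m), each = nrow(m)), levels = rev(colnames(m))),
    r = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#B2182B",
                                  mid = "white", high = "#2166AC", name = "r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
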