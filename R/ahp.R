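# Analytic Hierarchy Process: stakeholder importance scores -> per-ES weights
# with a Saaty consistency ratio.

# Saaty random consistency indices for n = 1..10
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Aggregate stakeholder importance scores per ES
#'
#' Geometric mean of the 0-9 importance scores across stakeholders for each
#' ES. Zeros would annihilate the geometric mean; by default they are floored
#' to 0.5 (half the minimal positive step), preserving "near-zero importance"
#' while keeping downstream comparison ratios finite.
#'
#' @param importance Tibble with columns `stakeholder`, `es_id`, `score`
#'   (integer 0-9).
#' @param zero_policy `"floor"` replaces 0 by 0.5 before the geometric mean;
#'   `"propagate"` lets a single 0 zero the aggregate.
#' @return Tibble with columns `es_id`, `aggregate`.
#' @export
#' @examples
#' imp <- tibble::tibble(stakeholder = c(1, 2), es_id = "CR", score = c(2, 8))
#' aggregate_importance(imp)  # geometric mean 4
aggregate_importance <- function(importance, zero_policy = c("floor", "propagate")) {
  zero_policy <- match.arg(zero_policy)
  if (!nrow(importance)) stop("Empty importance table.", call. = FALSE)
  if (any(importance$score < 0 | importance$score > 9)) {
    stop("Importance scores must lie in [0, 9].", call. = FALSE)
  }
  importance |>
    dplyr::mutate(score = if (zero_policy == "floor") {
      ifelse(.data$score == 0, 0.5, .data$score)
    } else .data$score) |>
    dplyr::summarise(aggregate = exp(mean(log(pmax(.data$score, 0)))),
                     .by = "es_id") |>
    dplyr::mutate(aggregate = ifelse(is.nan(.data$aggregate) |
                                       .data$aggregate < 0, 0, .data$aggregate))
}

#' Build a pairwise comparison matrix from aggregate scores
#'
#' Entries are the score ratios `s_i / s_j`, clipped symmetrically to Saaty's
#' \[1/9, 9\] scale so the matrix stays reciprocal after clipping.
#'
#' @param aggregate Tibble (`es_id`, `aggregate`) or a named numeric vector of
#'   positive scores.
#' @return A reciprocal square matrix with ES ids as dimnames.
#' @export
build_pairwise_matrix <- function(aggregate) {
  if (is.data.frame(aggregate)) {
    s <- stats::setNames(aggregate$aggregate, aggregate$es_id)
  } else {
    s <- aggregate
  }
  if (any(s <= 0)) stop("Aggregate scores must be positive.", call. = FALSE)
  a <- outer(s, s, "/")
  a <- pmin(pmax(a, 1 / 9), 9)
  # enforce exact reciprocity after clipping
  a[lower.tri(a)] <- 1 / t(a)[lower.tri(a)]
  diag(a) <- 1
  dimnames(a) <- list(names(s), names(s))
  a
}

validate_pairwise <- function(pm) {
  if (!is.matrix(pm) || nrow(pm) != ncol(pm)) {
    stop("Pairwise matrix must be square.", call. = FALSE)
  }
  if (any(pm <= 0)) stop("Pairwise entries must be positive.", call. = FALSE)
  if (max(abs(pm * t(pm) - 1)) > 1e-8) {
    stop("Pairwise matrix must be reciprocal (a_ij * a_ji = 1).", call. = FALSE)
  }
  invisible(TRUE)
}

#' Principal-eigenvector weights of a pairwise matrix
#'
#' Canonical Saaty prioritisation: the normalized principal right eigenvector,
#' found by power iteration (relative tolerance 1e-10, at most 10,000
#' iterations), together with the principal eigenvalue and consistency ratio.
#'
#' @param pm A reciprocal pairwise comparison matrix.
#' @return An `ahp_weights` object: tibble of `es_id`, `weight` with
#'   attributes `lambda_max` and `consistency_ratio`.
#' @export
compute_weights <- function(pm) {
  validate_pairwise(pm)
  n <- nrow(pm)
  w <- rep(1 / n, n)
  lambda <- n
  for (it in seq_len(10000L)) {
    v <- as.vector(pm %*% w)
    lambda_new <- sum(v) / sum(w)
    v <- v / sum(v)
    if (max(abs(v - w)) < 1e-10 && abs(lambda_new - lambda) < 1e-10) {
      w <- v; lambda <- lambda_new
      break
    }
    w <- v; lambda <- lambda_new
    if (it == 10000L) stop("Power iteration failed to converge.", call. = FALSE)
  }
  ids <- rownames(pm) %||% paste0("C", seq_len(n))
  out <- tibble::tibble(es_id = ids, weight = w)
  attr(out, "lambda_max") <- lambda
  attr(out, "consistency_ratio") <- cr_from_lambda(lambda, n)
  class(out) <- c("ahp_weights", class(out))
  out
}

cr_from_lambda <- function(lambda_max, n) {
  if (n <= 2) return(0)
  # lambda_max >= n for reciprocal matrices; guard the tiny numerical negatives
  ci <- max(lambda_max - n, 0) / (n - 1)
  ri <- if (n <= length(saaty_ri)) saaty_ri[n] else 1.49
  ci / ri
}

#' Consistency ratio of a pairwise matrix
#'
#' `CR = CI / RI` with `CI = (lambda_max - n)/(n - 1)` and `RI` Saaty's random
#' index. Matrices of order 2 or less are consistent by construction, so
#' `CR = 0` there.
#'
#' @param pm A reciprocal pairwise comparison matrix with `n >= 2`.
#' @return Non-negative scalar.
#' @export
consistency_ratio <- function(pm) {
  if (nrow(pm) < 2) stop("Consistency ratio needs n >= 2.", call. = FALSE)
  attr(compute_weights(pm), "consistency_ratio")
}

#' Stakeholder importance scores to AHP weights, end to end
#'
#' Convenience wrapper: aggregate the 0-9 importance scores, build the
#' pairwise ratio matrix, and extract principal-eigenvector weights. The
#' default aggregates scores first and builds one matrix
#' (`method = "aggregate_scores"`); `method = "per_stakeholder"` instead
#' builds one pairwise matrix per stakeholder and combines them by
#' element-wise geometric mean before prioritisation, the usual group-AHP
#' alternative.
#'
#' @param importance Tibble `stakeholder`, `es_id`, `score`.
#' @param method Aggregation order, see Details.
#' @param zero_policy Passed to [aggregate_importance()].
#' @return An `ahp_weights` object.
#' @export
ahp_weights <- function(importance,
                        method = c("aggregate_scores", "per_stakeholder"),
                        zero_policy = "floor") {
  method <- match.arg(method)
  if (method == "aggregate_scores") {
    pm <- build_pairwise_matrix(aggregate_importance(importance, zero_policy))
  } else {
    mats <- importance |>
      dplyr::group_split(.data$stakeholder) |>
      purrr::map(function(d) {
        s <- aggregate_importance(dplyr::mutate(d, stakeholder = 1), zero_policy)
        build_pairwise_matrix(s)
      })
    logsum <- purrr::reduce(purrr::map(mats, log), `+`)
    pm <- exp(logsum / length(mats))
    pm <- pmin(pmax(pm, 1 / 9), 9)
    pm[lower.tri(pm)] <- 1 / t(pm)[lower.tri(pm)]
    diag(pm) <- 1
  }
  compute_weights(pm)
}

#' The study's published default weight configuration
#'
#' The stakeholder-derived AHP weights reported for the eight ES: drought
#' regulation 0.17 (highest) and recreation 0.04 (lowest) are published; the
#' remaining mass (0.79) is split equally over the other six ES as a
#' documented placeholder, since those six weights were not published.
#'
#' @return Tibble `es_id`, `weight` summing to 1.
#' @export
default_weights <- function() {
  w <- stats::setNames(rep(0.79 / 6, 8), es_ids())
  w["DR"] <- 0.17
  w["R"] <- 0.04
  tibble::tibble(es_id = es_ids(), weight = unname(w[es_ids()]))
}

#' @export
print.ahp_weights <- function(x, ...) {
  cat(sprintf("<ahp_weights> n = %d, lambda_max = %.6f, CR = %.4f\n",
              nrow(x), attr(x, "lambda_max"), attr(x, "consistency_ratio")))
  print(tibble::as_tibble(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ahp_weights <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.ahp_weights <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    lambda_max = attr(x, "lambda_max"),
    consistency_index = (attr(x, "lambda_max") - nrow(x)) / max(nrow(x) - 1, 1),
    consistency_ratio = attr(x, "consistency_ratio")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
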