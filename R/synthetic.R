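# Synthetic CORINE-like landscapes, ES layers, stakeholder score tables and
# zone maps. Everything is seeded so downstream stages can be tested against
# known ground truth without any external data.

#' Default land-cover class set
#'
#' A 12-code subset of the CORINE level-3 nomenclature spanning all five
#' level-1 categories (artificial, agricultural, forest/semi-natural,
#' wetlands, water).
#'
#' @return Character vector of 12 class codes.
#' @export
default_class_codes <- function() {
  c("1.2.2", "1.2.3", "1.4.1",           # artificial surfaces
    "2.1.3", "2.4.3", "2.4.4",           # agricultural areas
    "3.1.1", "3.1.2", "3.2.2", "3.3.3",  # forest and semi-natural
    "4.1.1",                             # wetlands
    "5.1.2")                             # water bodies
}

#' Human-readable labels for the default class set
#' @return Tibble with columns `class_code`, `label`.
#' @export
default_class_labels <- function() {
  tibble::tibble(
    class_code = default_class_codes(),
    label = c(
      "Road and rail networks", "Port areas", "Green urban areas",
      "Rice fields", "Agriculture with natural vegetation", "Agro-forestry areas",
      "Broad-leaved forest", "Coniferous forest", "Moors and heathland",
      "Sparsely vegetated areas", "Inland marshes", "Water bodies"
    )
  )
}

#' Configuration for the synthetic-landscape generator
#'
#' Bundles every knob of the generator. Defaults emulate the study setting:
#' 100 m cells, the five CORINE epochs 1990-2018, a 12-class CORINE subset,
#' 30 stakeholders, and patch-scale spatial autocorrelation.
#'
#' @param grid_rows,grid_cols Grid dimensions (positive integers).
#' @param cell_size Cell size in metres.
#' @param epochs Ordered character vector of epoch labels.
#' @param class_codes Land-cover class codes to use.
#' @param class_affinity Named positive weights controlling each class's
#'   expected areal share (share is proportional to affinity).
#' @param smoothing_scale Gaussian smoothing length in cells; larger values
#'   give larger land-cover patches.
#' @param transition_rate Fraction of pixels eligible to change class per
#'   epoch step, in \[0, 1\].
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   synthetic ES layers.
#' @param n_stakeholders Number of stakeholders in the score tables.
#' @param score_dispersion Standard deviation of stakeholder score noise
#'   around the true scores (integer scales).
#' @param seed Integer seed from which all generator randomness flows.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(grid_rows = 200, grid_cols = 200, cell_size = 100,
                             epochs = c("1990", "2000", "2006", "2012", "2018"),
                             class_codes = default_class_codes(),
                             class_affinity = NULL,
                             smoothing_scale = 5, transition_rate = 0.05,
                             noise_sd = 0.1, n_stakeholders = 30,
                             score_dispersion = 1, seed = 42) {
  if (length(class_codes) < 1) stop("`class_codes` must not be empty.", call. = FALSE)
  if (grid_rows < 1 || grid_cols < 1) {
    stop("Grid dimensions must be positive.", call. = FALSE)
  }
  if (anyDuplicated(class_codes)) stop("`class_codes` must be unique.", call. = FALSE)
  if (is.null(class_affinity)) {
    class_affinity <- stats::setNames(rep(1, length(class_codes)), class_codes)
  }
  if (is.null(names(class_affinity)) ||
      !setequal(names(class_affinity), class_codes)) {
    stop("`class_affinity` must be named by `class_codes`.", call. = FALSE)
  }
  if (any(class_affinity <= 0)) stop("`class_affinity` entries must be > 0.", call. = FALSE)
  if (transition_rate < 0 || transition_rate > 1) {
    stop("`transition_rate` must be in [0, 1].", call. = FALSE)
  }
  epochs <- as.character(epochs)
  if (length(epochs) < 1 || anyDuplicated(epochs) || is.unsorted(epochs)) {
    stop("`epochs` must be a strictly ordered set of labels.", call. = FALSE)
  }
  if (n_stakeholders < 1) stop("`n_stakeholders` must be positive.", call. = FALSE)
  if (score_dispersion < 0 || noise_sd < 0) {
    stop("Dispersion parameters must be non-negative.", call. = FALSE)
  }
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    cell_size = cell_size, epochs = epochs, class_codes = class_codes,
    class_affinity = class_affinity[class_codes],
    smoothing_scale = smoothing_scale, transition_rate = transition_rate,
    noise_sd = noise_sd, n_stakeholders = as.integer(n_stakeholders),
    score_dispersion = score_dispersion, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# run code under a seed without touching the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gaussian smoothing of a matrix along both axes (row-normalized banded
# weights, so edges stay unbiased).
smooth_field <- function(m, scale) {
  if (scale <= 0) return(m)
  band <- function(n) {
    w <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = scale)
    w[w < stats::dnorm(3 * scale, sd = scale)] <- 0
    sweep(w, 1, rowSums(w), "/")
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate autocorrelated land-cover layers for each epoch
#'
#' One independent Gaussian random field per class is smoothed to the
#' configured autocorrelation length, mapped through its marginal CDF to a
#' Gumbel variate, and the per-pixel class is `argmax(log(affinity) + gumbel)`,
#' so expected areal shares are proportional to `class_affinity` while classes
#' form contiguous patches. Later epochs are derived from the first by
#' flipping a `transition_rate` fraction of patch-boundary pixels to a
#' neighbouring patch's class, mimicking gradual land-cover change.
#'
#' @param config A [synthetic_config()].
#' @param mask Optional logical matrix; `FALSE` cells become nodata.
#' @return Named list of [lc_layer()] objects, one per epoch.
#' @export
generate_landcover <- function(config, mask = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  codes <- config$class_codes
  aff <- config$class_affinity
  with_seed(config$seed, {
    score_best <- matrix(-Inf, nr, nc)
    pick <- matrix(1L, nr, nc)
    for (k in seq_along(codes)) {
      f <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                        config$smoothing_scale)
      z <- (f - mean(f)) / stats::sd(f)
      u <- pmin(pmax(stats::pnorm(z), 1e-12), 1 - 1e-12)
      s <- log(aff[[k]]) - log(-log(u))   # Gumbel-max trick
      upd <- s > score_best
      score_best[upd] <- s[upd]
      pick[upd] <- k
    }
    lc <- matrix(codes[pick], nr, nc)
    if (!is.null(mask)) lc[!mask] <- NA_character_
    layers <- vector("list", length(config$epochs))
    names(layers) <- config$epochs
    layers[[1]] <- lc_layer(lc, config$epochs[1], config$cell_size)
    for (t in seq_along(config$epochs)[-1]) {
      lc <- transition_step(lc, config$transition_rate)
      layers[[t]] <- lc_layer(lc, config$epochs[t], config$cell_size)
    }
    layers
  })
}

# Flip a fraction of patch-boundary pixels to a random differing neighbour's
# class; changes are computed from the input map and applied simultaneously.
transition_step <- function(lc, rate) {
  if (rate <= 0) return(lc)
  nr <- nrow(lc); nc <- ncol(lc)
  shift <- function(m, dr, dc) {
    out <- matrix(NA_character_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  nb <- list(shift(lc, -1, 0), shift(lc, 1, 0), shift(lc, 0, -1), shift(lc, 0, 1))
  differs <- vapply(nb, function(n) !is.na(n) & !is.na(lc) & n != lc,
                    matrix(TRUE, nr, nc))
  dim(differs) <- c(nr * nc, 4L)
  boundary <- which(rowSums(differs) > 0)
  n_valid <- sum(!is.na(lc))
  budget <- floor(rate * n_valid)
  if (budget < 1 || !length(boundary)) return(lc)
  flip <- if (length(boundary) <= budget) boundary else {
    sample(boundary, budget)
  }
  new_lc <- lc
  for (i in flip) {
    opts <- which(differs[i, ])
    j <- if (length(opts) == 1L) opts else sample(opts, 1L)
    new_lc[i] <- nb[[j]][i]
  }
  new_lc
}

#' Random true capacity table
#'
#' Ground-truth capacity of each land-cover class to supply each ES, drawn
#' uniformly in \[0.05, 0.95\] (away from the scale anchors so additive noise
#' has room before clipping). Used as the known truth for parameter-recovery
#' tests and as the class-conditional mean of synthetic ES layers.
#'
#' @param class_codes Land-cover class codes.
#' @param es Vector of ES ids.
#' @param seed Integer seed.
#' @return Tibble with columns `class_code`, `es_id`, `capacity`.
#' @export
random_capacity_table <- function(class_codes = default_class_codes(),
                                  es = es_ids(), seed = 1) {
  with_seed(seed, {
    tidyr::expand_grid(class_code = class_codes, es_id = es) |>
      dplyr::mutate(capacity = round(stats::runif(dplyr::n(), 0.05, 0.95), 3))
  })
}

#' Generate a synthetic ES potential layer
#'
#' Each pixel's value is the true capacity of its land-cover class for the
#' requested ES plus Gaussian noise, clipped to \[0, 1\]; nodata propagates.
#' Stands in for the outputs of external biophysical models.
#'
#' @param landcover An [lc_layer()].
#' @param truth Capacity tibble (`class_code`, `es_id`, `capacity`) covering
#'   every class present in `landcover`.
#' @param es_id The ES to generate.
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer seed.
#' @return A normalized [es_layer()].
#' @export
generate_es_layer <- function(landcover, truth, es_id, noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(landcover, "lc_layer"))
  es_id <- match.arg(es_id, es_ids())
  tr <- dplyr::filter(truth, .data$es_id == !!es_id)
  present <- unique(landcover$values[!is.na(landcover$values)])
  missing <- setdiff(present, tr$class_code)
  if (length(missing)) {
    stop("Class(es) missing from capacity table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cap <- stats::setNames(tr$capacity, tr$class_code)
  vals <- matrix(cap[landcover$values], nrow(landcover$values))
  with_seed(seed, {
    if (noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd), nrow(vals))
    }
    vals <- pmin(pmax(vals, 0), 1)
    vals[is.na(landcover$values)] <- NA_real_
    es_layer(vals, es_id, landcover$epoch, landcover$cell_size, normalized = TRUE)
  })
}

#' Generate stakeholder importance and capacity score tables
#'
#' Integer scores centred on the true values with dispersion
#' `config$score_dispersion`: importance on the 0-9 scale, land-cover capacity
#' on the 0-5 scale (the true \[0, 1\] capacity is mapped to 0-5 before
#' rounding).
#'
#' @param config A [synthetic_config()].
#' @param true_importance Named numeric vector (per ES) of true importance on
#'   the 0-9 scale.
#' @param truth Capacity tibble as in [generate_es_layer()].
#' @return List with tibbles `importance` (stakeholder, es_id, score) and
#'   `capacity` (stakeholder, class_code, es_id, score).
#' @export
generate_stakeholder_scores <- function(config, true_importance, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(true_importance < 0 | true_importance > 9)) {
    stop("`true_importance` must be within [0, 9].", call. = FALSE)
  }
  n <- config$n_stakeholders
  disp <- config$score_dispersion
  noisy_int <- function(mu, hi) {
    x <- if (disp > 0) mu + stats::rnorm(length(mu), 0, disp) else mu
    as.integer(pmin(pmax(round(x), 0), hi))
  }
  with_seed(config$seed + 1L, {
    imp <- tidyr::expand_grid(stakeholder = seq_len(n),
                              es_id = names(true_importance)) |>
      dplyr::mutate(score = noisy_int(true_importance[.data$es_id], 9L))
    cap <- tidyr::expand_grid(stakeholder = seq_len(n),
                              dplyr::distinct(truth, .data$class_code, .data$es_id)) |>
      dplyr::left_join(truth, by = c("class_code", "es_id")) |>
      dplyr::mutate(score = noisy_int(.data$capacity * 5, 5L)) |>
      dplyr::select("stakeholder", "class_code", "es_id", "score")
    list(importance = imp, capacity = cap)
  })
}

#' Generate contiguous zones (NUTS-3 analogue)
#'
#' Seeds `n_zones` random valid pixels and grows them by breadth-first
#' expansion until every valid pixel belongs to exactly one contiguous zone.
#'
#' @param config A [synthetic_config()].
#' @param n_zones Number of zones (default 23, a mainland-Portugal-like count).
#' @param mask Optional logical validity matrix.
#' @return A [zone_map()].
#' @export
generate_zones <- function(config, n_zones = 23, mask = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  n_valid <- sum(mask)
  if (n_zones < 1 || n_zones > n_valid) {
    stop("`n_zones` must be between 1 and the number of valid pixels.",
         call. = FALSE)
  }
  with_seed(config$seed + 2L, {
    zones <- matrix(NA_integer_, nr, nc)
    seeds <- sample(which(mask), n_zones)
    zones[seeds] <- seq_len(n_zones)
    shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    repeat {
      todo <- mask & is.na(zones)
      if (!any(todo)) break
      assigned_any <- FALSE
      for (s in sample(shifts)) {
        src <- matrix(NA_integer_, nr, nc)
        rs <- seq_len(nr) + s[1]; cs <- seq_len(nc) + s[2]
        ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
        src[ok_r, ok_c] <- zones[rs[ok_r], cs[ok_c]]
        take <- todo & !is.na(src)
        if (any(take)) {
          zones[take] <- src[take]
          todo[take] <- FALSE
          assigned_any <- TRUE
        }
      }
      if (!assigned_any) {
        # disconnected mask component: seed a fresh growth point in it
        left <- which(todo)
        zones[left[1]] <- zones[seeds[1]]
      }
    }
    zone_map(zones, config$cell_size)
  })
}

#' Mean 4-neighbour class agreement of a land-cover layer
#'
#' Diagnostic used to verify spatial autocorrelation: the share of valid
#' 4-neighbour pixel pairs with identical class.
#'
#' @param landcover An [lc_layer()].
#' @return Proportion in \[0, 1\].
#' @export
neighbor_agreement <- function(landcover) {
  m <- landcover$values
  pairs_same <- 0L; pairs_all <- 0L
  h <- !is.na(m[, -ncol(m), drop = FALSE]) & !is.na(m[, -1, drop = FALSE])
  v <- !is.na(m[-nrow(m), , drop = FALSE]) & !is.na(m[-1, , drop = FALSE])
  pairs_all <- sum(h) + sum(v)
  pairs_same <- sum(h & m[, -ncol(m)] == m[, -1], na.rm = TRUE) +
    sum(v & m[-nrow(m), ] == m[-1, ], na.rm = TRUE)
  if (pairs_all == 0) return(NA_real_)
  pairs_same / pairs_all
}
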