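# Shared fixture builders; everything is generated in code under fixed seeds.

# small landscape configuration used across tests
small_config <- function(seed = 11, ...) {
  synthetic_config(grid_rows = 40, grid_cols = 40, smoothing_scale = 3,
                   seed = seed, ...)
}

# an ES layer from an explicit value matrix
make_es <- function(values, es_id = "CR", epoch = "1990", normalized = FALSE) {
  es_layer(values, es_id, epoch, cell_size = 100, normalized = normalized)
}

# random normalized 8-layer stack for one epoch
rand_stack <- function(nr = 25, nc = 30, epoch = "2018", seed = 5) {
  set.seed(seed)
  out <- lapply(es_ids(), function(es) {
    make_es(matrix(runif(nr * nc), nr, nc), es, epoch, normalized = TRUE)
  })
  names(out) <- es_ids()
  out
}

# truth table with mid-range capacities (>= 4 noise sd away from the [0, 1]
# clip bounds at noise_sd = 0.1, so clipping cannot bias class means)
midrange_truth <- function(class_codes = default_class_codes(),
                           es = es_ids(), seed = 3) {
  asebio:::with_seed(seed, {
    tidyr::expand_grid(class_code = class_codes, es_id = es) |>
      dplyr::mutate(capacity = round(stats::runif(dplyr::n(), 0.4, 0.6), 3))
  })
}

# random reciprocal pairwise matrix on Saaty's scale
rand_pairwise <- function(n, seed = 1) {
  set.seed(seed)
  a <- diag(n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a[i, j] <- exp(runif(1, -log(9), log(9)))
    a[j, i] <- 1 / a[i, j]
  }
  dimnames(a) <- list(head(es_ids(), n), head(es_ids(), n))
  a
}

# dense-eigensolver oracle for AHP weights
eigen_oracle <- function(pm) {
  e <- eigen(pm)
  k <- which.max(Re(e$values))
  w <- Re(e$vectors[, k])
  list(weights = w / sum(w), lambda_max = Re(e$values[k]))
}
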