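test_that("capacity aggregation is the geometric mean scaled by 5", {
  raw <- tibble::tibble(stakeholder = c(1, 2), class_code = "3.1.1",
                        es_id = "CR", score = c(1, 4))
  agg <- aggregate_capacity(raw)
  expect_equal(agg$gm, 2)       # sqrt(1 * 4)
  expect_equal(agg$value, 0.4)

  all5 <- dplyr::mutate(raw, score = 5)
  expect_equal(aggregate_capacity(all5)$value, 1)

  with_zero <- dplyr::mutate(raw, score = c(0, 4))
  expect_equal(aggregate_capacity(with_zero)$value, 0)  # zero propagates
  expect_equal(aggregate_capacity(with_zero, zero_policy = "floor")$gm,
               sqrt(0.5 * 4))

  expect_error(aggregate_capacity(dplyr::mutate(raw, score = 7)), "\\[0, 5\\]")
})

test_that("min-max normalization mode rescales within each ES", {
  raw <- tidyr::expand_grid(stakeholder = 1, class_code = c("A", "B", "C"),
                            es_id = "WP") |>
    dplyr::mutate(score = c(1, 3, 5))
  agg <- aggregate_capacity(raw, normalization = "minmax")
  expect_equal(agg$value, c(0, 0.5, 1))
})

test_that("geometric mean never exceeds the arithmetic mean (AM-GM)", {
  set.seed(15)
  raw <- tidyr::expand_grid(stakeholder = 1:7,
                            class_code = default_class_codes(),
                            es_id = es_ids()) |>
    dplyr::mutate(score = sample(1:5, dplyr::n(), replace = TRUE))
  agg <- aggregate_capacity(raw)
  am <- dplyr::summarise(raw, am = mean(score), .by = c(class_code, es_id))
  j <- dplyr::left_join(agg, am, by = c("class_code", "es_id"))
  expect_true(all(j$gm <= j$am + 1e-12))
})

test_that("apply_matrix performs an exact per-pixel lookup", {
  lut <- tibble::tibble(class_code = c("1.2.2", "5.1.2"), es_id = "R",
                        value = c(0.6, 0.2))
  uni <- lc_layer(matrix("1.2.2", 4, 4), "2018")
  expect_true(all(apply_matrix(uni, lut, "R")$values == 0.6))

  set.seed(3)
  m <- matrix(sample(c("1.2.2", "5.1.2", NA), 36, replace = TRUE), 6, 6)
  lc <- lc_layer(m, "2018")
  got <- apply_matrix(lc, lut, "R")
  dict <- c("1.2.2" = 0.6, "5.1.2" = 0.2)
  for (i in seq_along(m)) {
    if (is.na(m[i])) expect_true(is.na(got$values[i]))
    else expect_equal(got$values[i], unname(dict[m[i]]))
  }
  expect_true(got$normalized)

  expect_error(apply_matrix(lc_layer(matrix("9.9.9", 2, 2), "2018"), lut, "R"),
               "9.9.9")
})

test_that("apply_matrix then class summary returns the matrix column exactly", {
  cfg <- small_config(seed = 31)
  lc <- generate_landcover(cfg)[[1]]
  truth <- random_capacity_table(cfg$class_codes, seed = 9)
  scores <- generate_stakeholder_scores(small_config(score_dispersion = 0),
                                        setNames(rep(5, 8), es_ids()), truth)
  agg <- aggregate_capacity(scores$capacity)
  for (es in c("CR", "FP")) {
    layer <- apply_matrix(lc, agg, es)
    back <- class_potential_summary(list(layer), list(lc)) |>
      dplyr::filter(count > 0)
    want <- dplyr::filter(agg, es_id == es)
    j <- dplyr::left_join(back, want, by = "class_code")
    expect_equal(j$mean, j$value, tolerance = 1e-12)
  }
})

test_that("the combined perception index is piecewise constant on land-cover classes", {
  cfg <- small_config(seed = 37)
  lc <- generate_landcover(cfg)[[1]]
  truth <- random_capacity_table(cfg$class_codes, seed = 10)
  agg <- aggregate_capacity(
    generate_stakeholder_scores(small_config(score_dispersion = 0),
                                setNames(rep(5, 8), es_ids()), truth)$capacity
  )
  layers <- lapply(es_ids(), function(es) apply_matrix(lc, agg, es))
  w <- default_weights()
  idx <- combined_perception_index(layers, w)

  # per-class constancy and the Eq.-2 composition oracle on looked-up values
  for (code in unique(as.vector(lc$values))) {
    vals <- idx$values[lc$values == code]
    expect_equal(max(vals) - min(vals), 0)
    oracle <- sum(vapply(seq_len(8), function(i) {
      w$weight[i] * agg$value[agg$class_code == code & agg$es_id == w$es_id[i]]
    }, 0))
    expect_equal(vals[1], oracle, tolerance = 1e-12)
  }
})

test_that("judgment dispersion diagnostics follow their closed forms", {
  raw <- tibble::tibble(stakeholder = c(1, 2), class_code = "2.1.3",
                        es_id = "DR", score = c(1, 3))
  d <- judgment_consistency(raw)
  expect_equal(d$by_cell$sd, sqrt(2))
  expect_equal(d$by_cell$cv, sqrt(2) / 2)

  same <- tidyr::expand_grid(stakeholder = 1:4, class_code = c("A", "B"),
                             es_id = c("CR", "WP")) |>
    dplyr::mutate(score = 3)
  expect_true(all(judgment_consistency(same)$by_cell$cv == 0))

  expect_error(judgment_consistency(dplyr::filter(raw, stakeholder == 1)),
               "2 stakeholders")
})

test_that("dispersed cohorts show strictly larger mean CV than exact cohorts", {
  truth <- random_capacity_table(seed = 20)
  imp <- setNames(rep(5, 8), es_ids())
  worse <- vapply(1:20, function(s) {
    noisy <- generate_stakeholder_scores(small_config(seed = s), imp, truth)
    exact <- generate_stakeholder_scores(
      small_config(seed = s, score_dispersion = 0), imp, truth)
    mean(judgment_consistency(noisy$capacity)$by_es$mean_cv) >
      mean(judgment_consistency(exact$capacity)$by_es$mean_cv)
  }, TRUE)
  expect_true(all(worse))
})

test_that("pairwise consistency diagnostics add a finite AHP ratio per ES", {
  truth <- random_capacity_table(seed = 22)
  sc <- generate_stakeholder_scores(small_config(seed = 41),
                                    setNames(rep(5, 8), es_ids()), truth)
  d <- judgment_consistency(sc$capacity, pairwise = TRUE)
  expect_true(all(is.finite(d$by_es$consistency_ratio)))
  expect_true(all(d$by_es$consistency_ratio >= 0))
})
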