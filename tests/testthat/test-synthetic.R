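test_that("land-cover generation is deterministic and honours the no-change limit", {
  cfg <- small_config()
  a <- generate_landcover(cfg)
  b <- generate_landcover(cfg)
  expect_identical(a, b)

  frozen <- small_config(transition_rate = 0)
  layers <- generate_landcover(frozen)
  for (l in layers[-1]) expect_identical(l$values, layers[[1]]$values)

  # epoch-to-epoch change never exceeds the transition budget
  cfg2 <- small_config(transition_rate = 0.1)
  layers2 <- generate_landcover(cfg2)
  for (t in seq_along(layers2)[-1]) {
    changed <- sum(layers2[[t]]$values != layers2[[t - 1]]$values, na.rm = TRUE)
    expect_lte(changed, 0.1 * sum(!is.na(layers2[[t]]$values)))
  }
})

test_that("a single class code gives a constant map with full neighbour agreement", {
  cfg <- small_config(class_codes = "3.2.2")
  l <- generate_landcover(cfg)[[1]]
  expect_true(all(l$values == "3.2.2"))
  expect_equal(neighbor_agreement(l), 1.0)
})

test_that("land-cover maps are spatially autocorrelated above the shuffled baseline", {
  cfg <- small_config(seed = 21)
  l <- generate_landcover(cfg)[[1]]
  obs <- neighbor_agreement(l)
  set.seed(99)
  shuffled <- lc_layer(matrix(sample(l$values), nrow(l$values)), l$epoch)
  expect_gt(obs, neighbor_agreement(shuffled) + 0.2)
})

test_that("areal shares track class affinity (3:1 mix near 75/25)", {
  shares <- vapply(1:20, function(s) {
    cfg <- synthetic_config(grid_rows = 200, grid_cols = 200,
                            epochs = "2018", class_codes = c("A", "B"),
                            class_affinity = c(A = 3, B = 1),
                            smoothing_scale = 5, seed = s)
    l <- generate_landcover(cfg)[[1]]
    mean(l$values == "A")
  }, 0)
  expect_lt(abs(mean(shares) - 0.75), 0.05)
})

test_that("class shares sum to one over valid pixels (conservation)", {
  cfg <- small_config(seed = 4)
  mask <- matrix(TRUE, 40, 40); mask[1:5, 1:10] <- FALSE
  layers <- generate_landcover(cfg, mask = mask)
  for (l in layers) {
    tab <- table(l$values)
    expect_equal(sum(tab), sum(mask))
    expect_equal(sum(tab / sum(mask)), 1)
    expect_true(all(is.na(l$values[!mask])))
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(class_codes = character(0)), "empty")
  expect_error(synthetic_config(grid_rows = 0), "positive")
  expect_error(synthetic_config(transition_rate = 1.2), "transition_rate")
  expect_error(synthetic_config(class_codes = c("A", "B"),
                                class_affinity = c(A = 1, B = -1)),
               "> 0")
})

test_that("noise-free ES layers reproduce the capacity table exactly", {
  cfg <- small_config(seed = 8)
  lc <- generate_landcover(cfg)[[1]]
  truth <- random_capacity_table(cfg$class_codes, seed = 2)
  l <- generate_es_layer(lc, truth, "WP", noise_sd = 0, seed = 1)
  lut <- setNames(truth$capacity[truth$es_id == "WP"],
                  truth$class_code[truth$es_id == "WP"])
  expect_equal(as.vector(l$values), unname(lut[as.vector(lc$values)]))

  flat <- dplyr::mutate(truth, capacity = 0.5)
  l2 <- generate_es_layer(lc, flat, "CR", noise_sd = 0, seed = 1)
  expect_true(all(l2$values == 0.5))
})

test_that("ES-layer class means satisfy the CLT bound at noise_sd = 0.1", {
  cfg <- synthetic_config(grid_rows = 200, grid_cols = 200, epochs = "2018",
                          smoothing_scale = 5, seed = 31)
  lc <- generate_landcover(cfg)[[1]]
  truth <- midrange_truth(seed = 7)
  l <- generate_es_layer(lc, truth, "HQ", noise_sd = 0.1, seed = 12)
  cs <- class_potential_summary(list(l), list(lc)) |>
    dplyr::filter(count > 0) |>
    dplyr::left_join(truth, by = c("class_code", "es_id"))
  expect_true(all(abs(cs$mean - cs$capacity) <= 3 * 0.1 / sqrt(cs$count)))
})

test_that("ES generation fails when a land-cover class is missing from the truth", {
  cfg <- small_config(seed = 8)
  lc <- generate_landcover(cfg)[[1]]
  truth <- random_capacity_table(cfg$class_codes[-1], seed = 2)
  expect_error(generate_es_layer(lc, truth, "CR"), cfg$class_codes[1])
})

test_that("stakeholder scores are centred on the truths", {
  truth <- random_capacity_table(seed = 5)
  imp_truth <- c(CR = 6, WP = 7, HQ = 6, DR = 8, R = 1, FP = 5, EP = 5, P = 4)

  exact <- generate_stakeholder_scores(small_config(score_dispersion = 0),
                                       imp_truth, truth)
  expect_true(all(exact$importance$score ==
                    round(imp_truth[exact$importance$es_id])))
  expect_true(all(exact$capacity$score == round(
    5 * truth$capacity[match(paste(exact$capacity$class_code, exact$capacity$es_id),
                             paste(truth$class_code, truth$es_id))]
  )))

  one <- generate_stakeholder_scores(small_config(n_stakeholders = 1),
                                     imp_truth, truth)
  expect_equal(unique(one$importance$stakeholder), 1)
  expect_equal(nrow(one$importance), 8)

  # dispersion 1, 30 stakeholders: per-ES mean importance close to truth
  means <- purrr::map(1:20, function(s) {
    sc <- generate_stakeholder_scores(small_config(seed = s), imp_truth, truth)
    dplyr::summarise(sc$importance, m = mean(score), .by = es_id)
  }) |>
    dplyr::bind_rows() |>
    dplyr::summarise(m = mean(m), .by = es_id)
  expect_true(all(abs(means$m - imp_truth[means$es_id]) <= 0.75))
})

test_that("zones partition the valid pixels into contiguous regions", {
  cfg <- small_config(seed = 13)
  z1 <- generate_zones(cfg, 1)
  expect_true(all(z1$values == 1L))

  # flood-fill oracle for contiguity
  flood_size <- function(m, id) {
    cells <- which(m == id)
    seen <- rep(FALSE, length(m))
    queue <- cells[1]; seen[queue] <- TRUE; n <- 0L
    nr <- nrow(m)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]; n <- n + 1L
      r <- (cur - 1L) %% nr + 1L; cc <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= ncol(m)) {
          idx <- (c2 - 1L) * nr + rr
          if (!seen[idx] && !is.na(m[idx]) && m[idx] == id) {
            seen[idx] <- TRUE; queue <- c(queue, idx)
          }
        }
      }
    }
    n
  }
  cfg23 <- synthetic_config(grid_rows = 60, grid_cols = 60, seed = 17)
  z <- generate_zones(cfg23, 23)
  sizes <- table(z$values)
  expect_equal(length(sizes), 23L)
  expect_true(all(sizes >= 1))
  expect_equal(sum(sizes), 60L * 60L)
  for (id in as.integer(names(sizes))) {
    expect_equal(flood_size(z$values, id), unname(sizes[as.character(id)]))
  }

  expect_error(generate_zones(cfg, 40 * 40 + 1), "n_zones")
})
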