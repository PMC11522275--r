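test_that("raster correlation hits its fixed points and the null bound", {
  set.seed(1)
  a <- make_es(matrix(runif(400), 20, 20), normalized = TRUE)
  expect_equal(raster_correlation(a, a), 1.0)

  neg <- make_es(1 - a$values, "WP", "1990", normalized = TRUE)
  expect_equal(raster_correlation(a, neg), -1.0)

  # two independent layers, n = 40,000: |r| below 4 / sqrt(n) in 19/20 seeds
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    x <- make_es(matrix(runif(40000), 200, 200), normalized = TRUE)
    y <- make_es(matrix(runif(40000), 200, 200), "HQ", "1990", normalized = TRUE)
    abs(raster_correlation(x, y)) < 0.02
  }, TRUE)
  expect_gte(sum(ok), 19)

  expect_error(raster_correlation(a, make_es(matrix(0.5, 20, 20),
                                             normalized = TRUE)), "variance")
})

test_that("correlation matrices are symmetric, unit-diagonal and equivariant", {
  cfg <- small_config(seed = 43)
  lc <- generate_landcover(cfg)[[1]]
  model <- rand_stack(nr = 40, nc = 40, epoch = lc$epoch, seed = 8)
  perceived <- rand_stack(nr = 40, nc = 40, epoch = lc$epoch, seed = 9)

  cm <- correlation_matrices(model, perceived, lc)
  for (m in list(cm$within_model, cm$within_perceived)) {
    expect_equal(diag(m), setNames(rep(1, 8), es_ids()))
    expect_equal(m, t(m))
    expect_true(all(m >= -1 & m <= 1))
  }

  # identical stacks: cross-approach correlations are all 1
  self <- correlation_matrices(model, model, lc)
  expect_equal(unname(self$cross), rep(1, 8), tolerance = 1e-12)

  # permuting the ES order permutes rows and columns identically
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  cmp <- correlation_matrices(model[perm], perceived[perm], lc)
  expect_equal(cmp$within_model, cm$within_model[perm, perm])
  expect_equal(cmp$cross, cm$cross[perm])

  # pixel support agrees with direct correlation of the pixel vectors
  cpx <- correlation_matrices(model, perceived, support = "pixel")
  expect_equal(cpx$cross[["CR"]],
               cor(as.vector(model$CR$values), as.vector(perceived$CR$values)),
               tolerance = 1e-12)
})

test_that("per-ES differences reproduce published-table arithmetic at 2 decimals", {
  model <- c(CR = 0.43, WP = 0.66, HQ = 0.46, DR = 0.22,
             R = 0.49, FP = 0.48, EP = 0.16, P = 0.42)
  stake <- c(CR = 0.73, WP = 0.68, HQ = 0.73, DR = 0.70,
             R = 0.66, FP = 0.59, EP = 0.67, P = 0.77)
  d <- per_es_difference(model, stake)
  reproducible <- c(CR = 0.30, WP = 0.02, R = 0.17, FP = 0.11, EP = 0.51, P = 0.35)
  for (es in names(reproducible)) {
    expect_equal(d$difference_2dp[d$es_id == es], reproducible[[es]])
  }
  expect_equal(d$difference, unname(stake - model)[match(d$es_id, names(model))],
               tolerance = 1e-12)

  eq <- per_es_difference(model, model)
  expect_true(all(eq$difference == 0))
  expect_error(per_es_difference(c(CR = 1.2), c(CR = 0.5)), "\\[0, 1\\]")
})

test_that("overall percent difference follows its definition and sign convention", {
  a <- index_layer(matrix(0.4, 5, 5), "2018")
  b <- index_layer(matrix(0.6, 5, 5), "2018")
  expect_equal(overall_percent_difference(a, b), 50)
  expect_equal(overall_percent_difference(a, a), 0)

  set.seed(21)
  x <- index_layer(matrix(runif(100, 0.2, 0.8), 10, 10), "2018")
  y <- index_layer(matrix(runif(100, 0.2, 0.8), 10, 10), "2018")
  expect_equal(overall_percent_difference(x, y),
               100 * (mean(y$values) - mean(x$values)) / mean(x$values),
               tolerance = 1e-9)
  # both sign conventions agree in direction
  expect_equal(sign(overall_percent_difference(x, y)),
               sign(overall_percent_difference(x, y, denominator = "perceived")))
})

test_that("paired t matches its closed form and is antisymmetric", {
  ident <- paired_t_test(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  # differences {1, 2, 3}: t = 2 / (1 / sqrt(3)) = 2 * sqrt(3), df = 2
  res <- paired_t_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)

  set.seed(33)
  m <- runif(8); s <- runif(8)
  got <- paired_t_test(m, s)
  d <- s - m
  t_manual <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(got$t, t_manual, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(-abs(t_manual), 7), tolerance = 1e-10)
  swapped <- paired_t_test(s, m)
  expect_equal(swapped$t, -got$t, tolerance = 1e-12)
})

test_that("one-way ANOVA reduces to the squared pooled t for two groups", {
  set.seed(44)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  res <- anova_across_epochs(c(x, y), rep(c("1990", "2018"), c(12, 15)))
  t2 <- t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(res$anova$F, unname(t2), tolerance = 1e-9)
  expect_equal(res$anova$df_between, 1)
  expect_equal(nrow(res$shapiro), 2)
  expect_true(all(res$shapiro$W <= 1))

  flat <- anova_across_epochs(rep(1, 10), rep(c("a", "b"), 5))
  expect_equal(flat$anova$F, 0)
  expect_error(anova_across_epochs(1:3, c("a", "a", "b")), "degenerate|>= 2")
})

test_that("ANOVA holds its nominal type-I error rate", {
  set.seed(77)
  rejections <- vapply(seq_len(1000), function(i) {
    v <- rnorm(50)
    g <- rep(c("1990", "2000", "2006", "2012", "2018"), each = 10)
    anova_across_epochs(v, g)$anova$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("the comparison report glues the pieces together coherently", {
  cfg <- small_config(seed = 47)
  lc <- generate_landcover(cfg)[[1]]
  model <- rand_stack(nr = 40, nc = 40, epoch = lc$epoch, seed = 10)
  perceived <- purrr::map(model, function(l) {
    make_es(pmin(l$values + 0.1, 1), l$es_id, l$epoch, normalized = TRUE)
  })
  w <- default_weights()
  rep <- comparison_report(model, perceived, compute_index(model, w),
                           compute_index(perceived, w), lc)
  expect_s3_class(generics::tidy(rep), "tbl_df")
  expect_gt(rep$overall_percent_difference, 0)
  expect_true(all(rep$per_es$difference > 0))
  gl <- generics::glance(rep)
  expect_named(gl, c("overall_percent_difference", "t", "p", "df",
                     "mean_cross_correlation"))
})
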