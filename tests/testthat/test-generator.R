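test_that("generator is reproducible from its seed and validates its config", {
  d1 <- generate_dataset(generator_config(seed = 7))
  d2 <- generate_dataset(generator_config(seed = 7))
  expect_identical(d1, d2)
  d3 <- generate_dataset(generator_config(seed = 8))
  expect_false(identical(d1$mean_970, d3$mean_970))

  expect_error(generator_config(n_informative = 25), "n_informative")
  expect_error(generator_config(outlier_rate = 1.5), "outlier_rate")
  expect_error(generator_config(n_train = c(0, 5)), "n_train")
  expect_error(generator_config(informative_bands = c(1, 1, 2, 3)),
               "informative_bands")
})

test_that("planted class signal lands in the configured features", {
  cfg <- generator_config(n_informative = 4, class_separation = 3,
                          n_train = c(200, 200), seed = 11)
  d <- generate_dataset(cfg)
  tr <- d[d$split == "train", ]
  x <- as.matrix(tr[, -(1:5)])
  fds <- oracle_fds(x, tr$class)$fds
  top4 <- sort(order(fds, decreasing = TRUE)[1:4])
  expect_identical(top4, attr(d, "informative"))
  # informative bands default to the highest wavelengths (NIR mean features)
  expect_identical(attr(d, "informative"), 15:18)
})

test_that("with zero separation no feature group is preferentially ranked", {
  cfg <- generator_config(class_separation = 0, n_train = c(300, 300),
                          seed = 5)
  d <- generate_dataset(cfg)
  tr <- d[d$split == "train", ]
  fds <- fisher_scores(as.matrix(tr[, -(1:5)]), tr$class)$fds
  inf <- attr(d, "informative")
  wt <- wilcox.test(rank(fds)[inf], rank(fds)[-inf])
  expect_gt(wt$p.value, 0.01)
})

test_that("empirical moments converge to the configured generative values", {
  cfg <- generator_config(n_train = c(5000, 5000), class_separation = 2,
                          seed = 3)
  d <- generate_dataset(cfg)
  tr <- d[d$split == "train", ]
  x <- as.matrix(tr[, -(1:5)])
  m0 <- colMeans(x[tr$class == 0, ])
  expect_equal(unname(m0[1:18]), rep(cfg$mean_level, 18), tolerance = 0.01)
  expect_equal(unname(m0[19:36]), rep(cfg$sd_level, 18), tolerance = 0.01)
  sds <- apply(x[tr$class == 0, ], 2, sd)
  expect_equal(unname(sds[1:18]), rep(cfg$mean_sd, 18), tolerance = 0.05)
  gap <- colMeans(x[tr$class == 1, 15:18]) - m0[15:18]
  expect_equal(unname(gap), rep(2 * cfg$mean_sd, 4), tolerance = 0.05)
})

test_that("all features lie in [0, 1] regardless of contamination", {
  cfg <- generator_config(outlier_rate = 0.5, outlier_shift = 30,
                          drift_slope = 0.05, batch_shift_sd = 2, seed = 9)
  d <- generate_dataset(cfg)
  x <- as.matrix(d[, -(1:5)])
  expect_true(all(x >= 0 & x <= 1))
})

test_that("outlier ground truth marks cells that were actually perturbed", {
  cfg <- generator_config(outlier_rate = 0.3, seed = 13,
                          drift_slope = 0, batch_shift_sd = 0)
  d <- generate_dataset(cfg)
  om <- attr(d, "outlier_matrix")
  expect_equal(sum(rowSums(om) > 0), round(0.3 * sum(cfg$n_test)))
  expect_true(all(rowSums(om) %in% c(0L, cfg$outlier_n_features)))
  # outlier cells sit far (several SD) from the clean class distribution
  te <- d[d$split == "test", ]
  x <- as.matrix(te[, -(1:5)])
  mu0 <- c(rep(cfg$mean_level, 18), rep(cfg$sd_level, 18))
  mu1 <- mu0
  mu1[attr(d, "informative")] <- mu0[attr(d, "informative")] +
    cfg$class_separation * attr(d, "feature_sd")[attr(d, "informative")]
  mu <- ifelse(te$class == 1, 1, 0) %o% mu1 + ifelse(te$class == 0, 1, 0) %o% mu0
  z <- abs(x - mu) / rep(attr(d, "feature_sd"), each = nrow(x))
  expect_gt(median(z[om]), 4)
  expect_lt(median(z[!om]), 2)
})

test_that("image cubes have the configured geometry and band statistics", {
  cfg <- generator_config(seed = 2)
  cube1 <- generate_image_cube(cfg, class_label = 1, seed = 21,
                               m = 64, n = 64, radius = 16)
  cube2 <- generate_image_cube(cfg, class_label = 1, seed = 21,
                               m = 64, n = 64, radius = 16)
  expect_identical(cube1, cube2)
  expect_equal(sum(cube1$mask), pi * 16^2, tolerance = 0.01)
  # masked per-band means recover the class band means within 3 SE
  n_fg <- sum(cube1$mask)
  for (b in c(1, 10, 18)) {
    se <- cfg$sd_level / sqrt(n_fg)
    expect_lt(abs(mean(cube1$cube[, , b][cube1$mask]) - cube1$band_means[b]),
              3 * se + 1e-9)
  }
  expect_error(generate_image_cube(cfg, 1, 1, radius = 0), "radius")
  expect_error(generate_image_cube(cfg, 1, 1, m = 10, n = 64), "32")
})
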