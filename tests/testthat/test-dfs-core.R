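# two tiny fixed training sets used across the stage tests
toy_train <- function() {
  # feature 1: class means 0 and 1, population variance 0.25 in each class
  # feature 2: identical class means
  x <- cbind(c(-0.5, 0.5, 0.5, 1.5), c(1, 3, 1, 3))
  y <- c(0L, 0L, 1L, 1L)
  list(x = x, y = y)
}

test_that("Fisher scores reproduce the hand-computed two-class example", {
  tt <- toy_train()
  f <- fisher_scores(tt$x, tt$y)
  # class means 0 and 1, within-class variances 0.25 each:
  # SB = (0 - 0.5)^2 + (1 - 0.5)^2 = 0.5, SW = 0.25 + 0.25 = 0.5, FDS = 1
  expect_equal(f$sb[1], 0.5)
  expect_equal(f$sw[1], 0.5)
  expect_equal(f$fds[1], 1.0)
  expect_equal(f$fds[2], 0)  # identical class means -> SB = 0
  expect_equal(f$fds_norm, c(1, 0))
  # matches the loop oracle
  o <- oracle_fds(tt$x, tt$y)
  expect_equal(f$fds, o$fds, tolerance = 1e-14)
})

test_that("Fisher scores are invariant to positive rescaling and shifts", {
  set.seed(10)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c(0L, 1L), each = 10)
  f0 <- fisher_scores(x, y)$fds
  x2 <- sweep(sweep(x, 2, c(3, 0.5, 10), "*"), 2, c(1, -2, 0), "+")
  expect_equal(fisher_scores(x2, y)$fds, f0, tolerance = 1e-12)
})

test_that("degenerate variance cases follow the stated conventions", {
  # SW = 0 with SB > 0: perfectly separating constant-within-class feature
  x <- cbind(rep(c(0, 1), each = 3), rnorm(6))
  y <- rep(c(0L, 1L), each = 3)
  f <- fisher_scores(x, y)
  expect_identical(f$fds[1], Inf)
  expect_equal(f$fds_norm[1], 1)
  expect_lt(f$fds_norm[2], 1)
  # SB = SW = 0: globally constant feature scores 0
  x2 <- cbind(rep(1, 6), rnorm(6))
  expect_equal(fisher_scores(x2, y)$fds[1], 0)
  # all features constant: undefined
  expect_error(fisher_scores(matrix(1, 6, 2), y), "zero variance")
  # single-class input refused
  expect_error(fisher_scores(x, rep(0L, 6)), "at least 2")
})

test_that("FDS filter applies its threshold with a never-empty guarantee", {
  scores <- c(0.9, 0.2, 0.15)
  expect_equal(fds_filter(scores, 0)$selected, 1:3)
  expect_equal(fds_filter(scores, 1)$selected, 1L)
  expect_equal(fds_filter(scores, 0.17)$selected, c(1L, 2L))
  fb <- fds_filter(c(0.5, 0.3), 0.9)
  expect_equal(fb$selected, 1L)
  expect_true(fb$fallback_used)
  expect_false(fds_filter(scores, 0.17)$fallback_used)
})

test_that("Mahalanobis ratio matches hand computation and edge conventions", {
  # class means (0, 1), sample variances (1, 1)
  x <- cbind(c(-1.5, 1.5, 0, -0.5, 2.5, 1), c(0, 2, 1, 5, 7, 6))
  y <- rep(c(0L, 1L), each = 3)
  st <- class_stats(x, y)
  expect_equal(unname(st$mean[, 1]), c(0, 1))
  expect_equal(unname(st$var_sample[, 1]), c(2.25, 2.25))
  # hand case: means (0,1), variances (1,1), s = 0.25
  xs <- cbind(c(-1, 0, 1, 0, 1, 2))  # class 0 mean 0 var 1; class 1 mean 1 var 1
  stx <- class_stats(xs, y)
  mr <- mahalanobis_ratio(stx, 0.25, 1)
  expect_equal(mr, 0.0625 / 0.5625)   # = 1/9
  # on a class mean: MR = 0
  expect_equal(mahalanobis_ratio(stx, 0, 1), 0)
  # equidistant in SD units: MR = 1
  expect_equal(mahalanobis_ratio(stx, 0.5, 1), 1)
  # asymmetric printed variant: M1^2 / M2
  m1 <- 0.0625; m2 <- 0.5625
  expect_equal(mahalanobis_ratio(stx, 0.25, 1, form = "asymmetric"),
               m1 * m1 / m2)
  # zero class variance: non-evaluable
  xz <- cbind(c(1, 1, 1, 2, 3, 4))
  expect_true(is.na(mahalanobis_ratio(class_stats(xz, y), 1.5, 1)))
})

test_that("class probability equals the maximum univariate normal density", {
  y <- rep(c(0L, 1L), each = 3)
  xs <- cbind(c(-1, 0, 1, 0, 1, 2) * 0.1)  # means (0, 0.1), sd 0.1
  st <- class_stats(xs, y)
  expect_equal(class_probability(st, 0.05, 1), dnorm(0.05, 0.1, 0.1))
  # peak of a unit-height density: class sd = 1/sqrt(2*pi), sample on the mean
  v <- 1 / sqrt(2 * pi)  # sample sd of (-v, 0, v) is exactly v
  xs2 <- cbind(c(-v, 0, v, 10 - v, 10, 10 + v))
  st2 <- class_stats(xs2, y)
  expect_equal(class_probability(st2, 0, 1), 1)
  # far tails vanish
  expect_lt(class_probability(st, 100, 1), 1e-12)
})

test_that("MR and P filters apply their thresholds over the surviving set", {
  set.seed(2)
  x <- matrix(rnorm(40), 10, 4)
  y <- rep(c(0L, 1L), each = 5)
  st <- class_stats(x, y)
  s <- rnorm(4)
  mr <- mahalanobis_ratio(st, s)
  expect_equal(mr_filter(st, s, 1:4, 1), which(!is.na(mr)))
  expect_equal(mr_filter(st, s, 1:4, 0), which(!is.na(mr) & mr == 0))
  keep <- mr_filter(st, s, 1:4, 0.5)
  expect_true(all(mr[keep] <= 0.5))
  p <- class_probability(st, s)
  pf <- p_filter(st, s, 1:4, 0)
  expect_equal(pf$selected, which(!is.na(p)))
  expect_false(pf$fallback_used)
  hi <- p_filter(st, s, 1:4, max(p, na.rm = TRUE) * 2)
  expect_equal(hi$selected, which.max(p))
  expect_true(hi$fallback_used)
  expect_error(mr_filter(st, s, integer(0), 0.5), "non-empty")
})

test_that("every cascade stage matches the loop oracle on random instances", {
  set.seed(123)
  for (rep in 1:100) {
    inst <- random_instance()
    st <- class_stats(inst$x, inst$y)
    f <- fisher_scores(inst$x, inst$y)
    o <- oracle_fds(inst$x, inst$y)
    expect_equal(f$fds, o$fds, tolerance = 1e-12)
    th <- list(fd = runif(1), mr = runif(1), p = runif(1, 0, 2))
    osel <- oracle_select(inst$x, inst$y, inst$s, th$fd, th$mr, th$p)
    tr <- select_features(st, f$fds_norm, inst$s,
                          threshold_triple(th$fd, th$mr, th$p))
    expect_identical(tr$surviving_after_fds, osel$s1)
    expect_identical(tr$surviving_after_mr, osel$s2)
    expect_identical(tr$surviving_after_p, osel$s3)
    for (k in tr$surviving_after_fds) {
      expect_equal(unname(tr$mr[as.character(k)]),
                   oracle_mr(inst$x, inst$y, inst$s, k), tolerance = 1e-12)
      expect_equal(unname(tr$p[as.character(k)]),
                   oracle_p(inst$x, inst$y, inst$s, k), tolerance = 1e-12)
    }
  }
})

test_that("the cascade is monotone and threshold-monotone", {
  set.seed(77)
  for (rep in 1:20) {
    inst <- random_instance(n_features = 8, n_per_class = 12)
    st <- class_stats(inst$x, inst$y)
    f <- fisher_scores(inst$x, inst$y)
    th <- threshold_triple(runif(1, 0, 0.5), runif(1, 0.3, 1), runif(1, 0, 0.3))
    tr <- select_features(st, f$fds_norm, inst$s, th)
    expect_true(all(tr$surviving_after_mr %in% tr$surviving_after_fds))
    expect_true(all(tr$surviving_after_p %in% tr$surviving_after_mr))
    expect_gt(length(tr$selected), 0)
    # raising a threshold never enlarges its stage's surviving set
    th2 <- threshold_triple(min(th$th_fd + 0.2, 1), max(th$th_mr - 0.2, 0),
                            th$th_p + 0.2)
    tr2 <- select_features(st, f$fds_norm, inst$s, th2)
    expect_true(all(tr2$surviving_after_fds %in% tr$surviving_after_fds) ||
                  tr2$fallback_used)
    expect_true(all(tr2$surviving_after_p %in% tr$surviving_after_p) ||
                  tr2$fallback_used)
  }
})

test_that("selection is stateless: identical samples yield identical traces", {
  set.seed(8)
  inst <- random_instance(n_features = 6, n_per_class = 10)
  st <- class_stats(inst$x, inst$y)
  f <- fisher_scores(inst$x, inst$y)
  th <- threshold_triple(0.15, 0.75, 0.1)
  t1 <- select_features(st, f$fds_norm, inst$s, th, sample_id = "a")
  t2 <- select_features(st, f$fds_norm, inst$s, th, sample_id = "a")
  expect_identical(t1, t2)
  # permissive limit retains every evaluable feature at every stage
  tp <- select_features(st, f$fds_norm, inst$s, threshold_triple(0, 1, 0))
  p <- class_probability(st, inst$s)
  expect_identical(tp$selected, which(!is.na(p)))
})

test_that("features carrying injected outliers are rejected preferentially", {
  cfg <- generator_config(outlier_rate = 1, outlier_n_features = 4,
                          outlier_shift = 8, drift_slope = 0,
                          batch_shift_sd = 0, n_informative = 10,
                          class_separation = 2.5,
                          n_test = c(100, 100), seed = 31)
  d <- generate_dataset(cfg)
  tr <- d[d$split == "train", ]
  x <- as.matrix(tr[, -(1:5)]); yy <- tr$class
  st <- class_stats(x, yy); f <- fisher_scores(x, yy)
  om <- attr(d, "outlier_matrix")
  te <- d[d$split == "test", ]
  tx <- as.matrix(te[, -(1:5)])
  th <- threshold_triple(0, 1, 0.1)  # online rejection via the P criterion only
  rej_out <- rej_clean <- integer(0)
  for (i in seq_len(nrow(tx))) {
    trace <- select_features(st, f$fds_norm, tx[i, ], th)
    rejected <- setdiff(seq_len(ncol(tx)), trace$selected)
    rej_out <- c(rej_out, sum(om[i, ] & seq_len(ncol(tx)) %in% rejected))
    rej_clean <- c(rej_clean, sum(!om[i, ] & seq_len(ncol(tx)) %in% rejected))
  }
  rate_out <- sum(rej_out) / sum(om)
  rate_clean <- sum(rej_clean) / sum(!om)
  expect_gt(rate_out, 2 * rate_clean)
})
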