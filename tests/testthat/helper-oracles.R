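# Independent straight-loop implementations of the cascade criteria, used to
# cross-check the vectorized package code. Deliberately naive: explicit loops,
# no shared code with the package internals.

oracle_fds <- function(x, y, global_mean = "class_means") {
  p <- ncol(x)
  fds <- sb <- sw <- numeric(p)
  for (k in seq_len(p)) {
    m0 <- mean(x[y == 0, k]); m1 <- mean(x[y == 1, k])
    gk <- if (global_mean == "class_means") (m0 + m1) / 2 else mean(x[, k])
    sbk <- (m0 - gk)^2 + (m1 - gk)^2
    swk <- 0
    for (d in 0:1) {
      xd <- x[y == d, k]
      acc <- 0
      for (v in xd) acc <- acc + (v - mean(xd))^2
      swk <- swk + acc / length(xd)
    }
    sb[k] <- sbk; sw[k] <- swk
    fds[k] <- if (swk > 0) sbk / swk else if (sbk > 0) Inf else 0
  }
  list(fds = fds, sb = sb, sw = sw)
}

oracle_mr <- function(x, y, s, k) {
  m <- numeric(2)
  for (d in 0:1) {
    xd <- x[y == d, k]
    v <- stats::var(xd)  # sample variance
    if (v == 0) return(NA_real_)
    m[d + 1] <- (s[k] - mean(xd))^2 / v
  }
  if (max(m) == 0) return(1)
  min(m) / max(m)
}

oracle_p <- function(x, y, s, k) {
  best <- -Inf
  for (d in 0:1) {
    xd <- x[y == d, k]
    sdd <- stats::sd(xd)
    if (sdd == 0) return(NA_real_)
    dens <- 1 / (sqrt(2 * pi) * sdd) * exp(-(s[k] - mean(xd))^2 / (2 * sdd^2))
    if (dens > best) best <- dens
  }
  best
}

# full three-stage cascade by brute force, thresholds on the same scales
oracle_select <- function(x, y, s, th_fd, th_mr, th_p) {
  fds <- oracle_fds(x, y)$fds
  fn <- if (any(is.infinite(fds))) {
    o <- ifelse(is.infinite(fds), 1, 0)
    mx <- max(fds[is.finite(fds)], 0)
    if (mx > 0) o[is.finite(fds) & fds > 0] <-
        fds[is.finite(fds) & fds > 0] / mx * (1 - 1e-12)
    o
  } else if (max(fds) == 0) rep(0, length(fds)) else fds / max(fds)
  s1 <- which(fn >= th_fd)
  if (length(s1) == 0) s1 <- which.max(fn)
  s2 <- integer(0)
  for (k in s1) {
    mr <- oracle_mr(x, y, s, k)
    if (!is.na(mr) && mr <= th_mr) s2 <- c(s2, k)
  }
  s3 <- integer(0)
  for (k in s2) {
    p <- oracle_p(x, y, s, k)
    if (!is.na(p) && p >= th_p) s3 <- c(s3, k)
  }
  list(s1 = s1, s2 = s2, s3 = s3)
}

# small random two-class instance with occasional degenerate columns
random_instance <- function(n_features = NULL, n_per_class = NULL) {
  p <- if (is.null(n_features)) sample(2:10, 1) else n_features
  n <- if (is.null(n_per_class)) sample(3:10, 1) else n_per_class
  x <- matrix(rnorm(2 * n * p), 2 * n, p)
  if (runif(1) < 0.2) x[, sample(p, 1)] <- 1  # constant column
  y <- rep(c(0L, 1L), each = n)
  list(x = x, y = y, s = rnorm(p))
}
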