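# Synthetic multispectral data with the statistical structure the DFS cascade
# assumes: two quality classes separated mainly in the NIR bands, batch-level
# mean shifts, per-sample drift and sporadic gross feature outliers.

#' Wavelengths (nm) of the 18 acquisition bands
#'
#' Band centres of the multispectral instrument emulated by the generator,
#' from UV (405 nm) to short-wave NIR (970 nm).
#'
#' @return Numeric vector of length 18.
#' @export
msi_wavelengths <- function() {
  c(405, 435, 450, 470, 505, 525, 570, 590, 630, 645,
    660, 700, 780, 850, 870, 890, 940, 970)
}

#' Configuration for the synthetic multispectral generator
#'
#' Defines the generative model for per-sample feature vectors (per-band mean
#' reflectance and per-band standard deviation, each normalized to [0, 1]).
#' Class 0 ("fresh") and class 1 ("spoiled") share the distribution of every
#' non-informative feature; the `n_informative` informative band means are
#' separated by `class_separation` within-class standard deviations, placed in
#' the highest-wavelength (NIR) bands unless `informative_bands` says
#' otherwise. Test samples additionally receive batch-level mean shifts, a
#' linear drift trend on a fixed random subset of features, and gross outlier
#' perturbations on a random subset of samples.
#'
#' @param n_bands Number of spectral bands (features are 2 * n_bands).
#' @param band_wavelengths Band centres in nm; length must equal `n_bands`.
#' @param n_informative Number of bands whose class means differ.
#' @param class_separation Class-mean separation of informative band means, in
#'   units of the within-class standard deviation.
#' @param n_train,n_val,n_test Length-2 integer vectors: samples per class
#'   (fresh, spoiled) in each split. Defaults follow a two-class study design
#'   with imbalanced splits (29/36 training, 7/41 validation, 106/8 test).
#' @param n_batches Number of test-set batches receiving distinct mean shifts.
#' @param batch_shift_sd SD of the per-batch, per-feature additive mean shift,
#'   in units of the feature's within-class SD. Applied to test samples only.
#' @param outlier_rate Fraction of test samples receiving gross perturbations.
#' @param outlier_shift Magnitude of each outlier perturbation in feature-SD
#'   units (at least 5 to be unambiguous).
#' @param outlier_n_features Number of features perturbed per outlier sample.
#' @param drift_slope Additive trend per test-sample index, in feature-SD
#'   units, applied to the drifting feature subset.
#' @param drift_fraction Fraction of features subject to the drift trend.
#' @param informative_bands Optional integer band indices to plant the class
#'   signal in; default: the `n_informative` highest wavelengths.
#' @param mean_level,mean_sd Baseline level and within-class SD of the band
#'   mean features.
#' @param sd_level,sd_sd Baseline level and within-class SD of the band
#'   standard-deviation features.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#'
#' @return An object of class `uosdfs_config` (a validated list).
#' @export
generator_config <- function(n_bands = 18L,
                             band_wavelengths = msi_wavelengths(),
                             n_informative = 4L,
                             class_separation = 3,
                             n_train = c(29L, 36L),
                             n_val = c(7L, 41L),
                             n_test = c(106L, 8L),
                             n_batches = 2L,
                             batch_shift_sd = 0.5,
                             outlier_rate = 0.1,
                             outlier_shift = 6,
                             outlier_n_features = 3L,
                             drift_slope = 0.01,
                             drift_fraction = 0.5,
                             informative_bands = NULL,
                             mean_level = 0.45,
                             mean_sd = 0.04,
                             sd_level = 0.05,
                             sd_sd = 0.01,
                             seed = 1L) {
  cfg <- list(
    n_bands = as.integer(n_bands), band_wavelengths = band_wavelengths,
    n_informative = as.integer(n_informative),
    class_separation = class_separation,
    n_train = as.integer(n_train), n_val = as.integer(n_val),
    n_test = as.integer(n_test), n_batches = as.integer(n_batches),
    batch_shift_sd = batch_shift_sd, outlier_rate = outlier_rate,
    outlier_shift = outlier_shift,
    outlier_n_features = as.integer(outlier_n_features),
    drift_slope = drift_slope, drift_fraction = drift_fraction,
    informative_bands = informative_bands,
    mean_level = mean_level, mean_sd = mean_sd,
    sd_level = sd_level, sd_sd = sd_sd, seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  class(cfg) <- "uosdfs_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stop_field <- function(field, why)
    stop(sprintf("invalid generator configuration: field '%s' %s", field, why),
         call. = FALSE)
  if (cfg$n_bands < 1L) stop_field("n_bands", "must be >= 1")
  if (length(cfg$band_wavelengths) != cfg$n_bands)
    stop_field("band_wavelengths", "must have length n_bands")
  if (cfg$n_informative < 0L || cfg$n_informative > cfg$n_bands)
    stop_field("n_informative", "must be in [0, n_bands]")
  if (cfg$class_separation < 0) stop_field("class_separation", "must be >= 0")
  for (f in c("n_train", "n_val", "n_test")) {
    v <- cfg[[f]]
    if (length(v) != 2L || any(v < 1L))
      stop_field(f, "must be two per-class counts, each >= 1")
  }
  if (cfg$n_batches < 1L) stop_field("n_batches", "must be >= 1")
  for (f in c("outlier_rate", "drift_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_field(f, "must be in [0, 1]")
  }
  if (cfg$batch_shift_sd < 0) stop_field("batch_shift_sd", "must be >= 0")
  if (cfg$outlier_shift < 0) stop_field("outlier_shift", "must be >= 0")
  if (cfg$outlier_n_features < 1L ||
      cfg$outlier_n_features > 2L * cfg$n_bands)
    stop_field("outlier_n_features", "must be in [1, 2 * n_bands]")
  if (!is.null(cfg$informative_bands)) {
    ib <- cfg$informative_bands
    if (length(ib) != cfg$n_informative ||
        any(ib < 1L | ib > cfg$n_bands) || anyDuplicated(ib))
      stop_field("informative_bands",
                 "must be n_informative distinct band indices")
  }
  if (cfg$mean_sd <= 0 || cfg$sd_sd <= 0)
    stop_field("mean_sd/sd_sd", "must be > 0")
  invisible(cfg)
}

#' Feature column names for a band layout
#'
#' Mean features come first (one per band), then standard-deviation features,
#' matching the 18-mean + 18-SD layout of the extracted spectra.
#'
#' @param wavelengths Band centres in nm.
#' @return Character vector of 2 * length(wavelengths) column names.
#' @export
feature_names <- function(wavelengths = msi_wavelengths()) {
  c(paste0("mean_", wavelengths), paste0("sd_", wavelengths))
}

# Generative per-class feature means and shared within-class SDs.
# Informative band means of class 1 sit class_separation SDs above class 0.
generator_moments <- function(cfg) {
  p <- 2L * cfg$n_bands
  mu0 <- c(rep(cfg$mean_level, cfg$n_bands), rep(cfg$sd_level, cfg$n_bands))
  sds <- c(rep(cfg$mean_sd, cfg$n_bands), rep(cfg$sd_sd, cfg$n_bands))
  informative_bands <- cfg$informative_bands
  if (is.null(informative_bands) && cfg$n_informative > 0L) {
    informative_bands <-
      order(cfg$band_wavelengths, decreasing = TRUE)[seq_len(cfg$n_informative)]
  }
  mu1 <- mu0
  informative <- integer(0)
  if (cfg$n_informative > 0L) {
    informative <- sort(informative_bands)  # mean-feature indices
    mu1[informative] <- mu0[informative] + cfg$class_separation * sds[informative]
  }
  list(mu0 = mu0, mu1 = mu1, sds = sds, informative = informative, p = p)
}

#' Generate a synthetic multispectral dataset
#'
#' Draws train/validation/test splits of 36-feature samples from the two-class
#' generative model described in [generator_config()]. Training and validation
#' samples are clean draws from the class distributions; test samples receive,
#' in order, a per-batch mean shift, a linear drift trend on the drifting
#' feature subset, and gross outlier perturbations on a random subset of
#' samples, after which all features are clipped to [0, 1].
#'
#' @param config A `uosdfs_config` object.
#'
#' @return A data.frame with columns `sample_id`, `split`, `batch`, `tvc`,
#'   `class`, then the 2 * n_bands feature columns. Ground truth is attached
#'   as attributes: `config`, `informative` (indices of informative features),
#'   `drift_features` (indices subject to drift), `outlier_matrix` (logical,
#'   test rows x features: which cells carry injected outliers), and
#'   `feature_sd` (the generative within-class SDs).
#' @export
#' @examples
#' d <- generate_dataset(generator_config(seed = 7))
#' table(d$split, d$class)
generate_dataset <- function(config) {
  validate_generator_config(config)
  mom <- generator_moments(config)
  p <- mom$p
  set.seed(config$seed)

  draw_split <- function(split, n_per_class) {
    n <- sum(n_per_class)
    cls <- rep(c(0L, 1L), n_per_class)
    x <- matrix(stats::rnorm(n * p), n, p) * rep(mom$sds, each = n)
    x <- x + ifelse(cls == 1L, 1, 0) %o% mom$mu1 +
      ifelse(cls == 0L, 1, 0) %o% mom$mu0
    tvc <- ifelse(cls == 0L, stats::runif(n, 0, 2), stats::runif(n, 6, 8))
    list(x = x, cls = cls, tvc = tvc, split = rep(split, n))
  }

  tr <- draw_split("train", config$n_train)
  va <- draw_split("validation", config$n_val)
  te <- draw_split("test", config$n_test)

  # test-set contamination: batch shifts, drift trend, gross outliers
  n_test <- nrow(te$x)
  batch <- rep_len(seq_len(config$n_batches), n_test)
  shift <- matrix(stats::rnorm(config$n_batches * p,
                               sd = config$batch_shift_sd), config$n_batches, p) *
    rep(mom$sds, each = config$n_batches)
  te$x <- te$x + shift[batch, , drop = FALSE]

  n_drift <- round(config$drift_fraction * p)
  drift_features <- sort(sample.int(p, n_drift))
  if (n_drift > 0L && config$drift_slope != 0) {
    trend <- (seq_len(n_test) - 1L) %o% (config$drift_slope * mom$sds[drift_features])
    te$x[, drift_features] <- te$x[, drift_features] + trend
  }

  outlier_matrix <- matrix(FALSE, n_test, p)
  n_out <- round(config$outlier_rate * n_test)
  if (n_out > 0L) {
    out_rows <- sample.int(n_test, n_out)
    for (i in out_rows) {
      ks <- sample.int(p, config$outlier_n_features)
      sgn <- sample(c(-1, 1), length(ks), replace = TRUE)
      te$x[i, ks] <- te$x[i, ks] + sgn * config$outlier_shift * mom$sds[ks]
      outlier_matrix[i, ks] <- TRUE
    }
  }
  x <- rbind(tr$x, va$x, te$x)
  x <- pmin(pmax(x, 0), 1)
  colnames(x) <- feature_names(config$band_wavelengths)
  n_all <- nrow(x)
  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_all)),
    split = c(tr$split, va$split, te$split),
    batch = c(rep(NA_integer_, nrow(tr$x) + nrow(va$x)), batch),
    tvc = round(c(tr$tvc, va$tvc, te$tvc), 4),
    class = c(tr$cls, va$cls, te$cls),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(x))
  rownames(outlier_matrix) <- out$sample_id[out$split == "test"]
  structure(out,
            config = config,
            informative = mom$informative,
            drift_features = drift_features,
            outlier_matrix = outlier_matrix,
            feature_sd = mom$sds)
}

#' Generate a synthetic multispectral image cube
#'
#' Builds an m x n x n_bands reflectance cube containing a dark background and
#' a bright circular foreground disk whose per-band pixel intensities follow
#' the class's band distribution (mean from the generative class mean, pixel
#' SD from the band's SD-feature level). This is the image-path counterpart of
#' the fast feature-vector path: per-band mean and SD inside the true mask
#' recover the class's 36-feature vector.
#'
#' @param config A `uosdfs_config` object.
#' @param class_label 0 (fresh) or 1 (spoiled).
#' @param seed Integer seed.
#' @param m,n Image dimensions in pixels (each at least 32).
#' @param radius Foreground disk radius in pixels; default `min(m, n) / 4`.
#'
#' @return A list with `cube` (array m x n x n_bands), `mask` (logical m x n,
#'   ground-truth foreground), and `band_means` (the generative class means).
#' @export
generate_image_cube <- function(config, class_label, seed,
                                m = 64L, n = 64L, radius = min(m, n) / 4) {
  validate_generator_config(config)
  if (m < 32L || n < 32L) stop("image dimensions must be at least 32 x 32")
  if (radius <= 0) stop("foreground radius must be positive")
  if (!class_label %in% c(0L, 1L)) stop("class_label must be 0 or 1")
  mom <- generator_moments(config)
  band_mu <- if (class_label == 1L) mom$mu1[seq_len(config$n_bands)]
             else mom$mu0[seq_len(config$n_bands)]
  # pixel-population SD per band = the band's SD-feature level
  band_sd <- mom$mu0[config$n_bands + seq_len(config$n_bands)]

  set.seed(seed)
  cx <- (m + 1) / 2; cy <- (n + 1) / 2
  dist2 <- outer(seq_len(m), seq_len(n),
                 function(i, j) (i - cx)^2 + (j - cy)^2)
  mask <- dist2 <= radius^2
  if (!any(mask)) stop("foreground radius too small: empty mask")

  cube <- array(0, dim = c(m, n, config$n_bands))
  n_fg <- sum(mask)
  n_bg <- m * n - n_fg
  for (b in seq_len(config$n_bands)) {
    band <- matrix(0, m, n)
    band[!mask] <- stats::rnorm(n_bg, mean = 0.08, sd = 0.02)
    band[mask] <- stats::rnorm(n_fg, mean = band_mu[b], sd = band_sd[b])
    cube[, , b] <- pmin(pmax(band, 0), 1)
  }
  list(cube = cube, mask = mask, band_means = band_mu)
}
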