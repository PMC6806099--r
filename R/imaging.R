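# From multispectral cube to 36-element feature vector: pick the most bimodal
# band, threshold it at the two-component Gaussian-mixture posterior crossing,
# keep the largest connected foreground region, then compute per-band mean and
# SD of min-max-normalized pixels inside the mask.

#' Segment the sample region of a multispectral cube
#'
#' Fits a two-component univariate Gaussian mixture to each band's pixel
#' values and selects the band with the largest between-component variance
#' (the most bimodal band). The band is thresholded where the two component
#' posteriors cross; the foreground is the larger connected bright region. If
#' the bright side covers more than half the frame the polarity is inverted
#' (the sample disk is the minority region).
#'
#' @param cube Numeric array m x n x n_bands with at least 2 bands.
#' @param max_pixels_fit Pixels subsampled per band for the mixture fit.
#'
#' @return A list of class `uosdfs_segmentation`: `mask` (logical m x n),
#'   `channel_used` (band index), `threshold`, `foreground_fraction`.
#' @importFrom mclust Mclust mclustBIC
#' @export
segment_cube <- function(cube, max_pixels_fit = 4000L) {
  if (length(dim(cube)) != 3L || dim(cube)[3] < 2L)
    stop("cube must be an m x n x bands array with at least 2 bands")
  if (!all(is.finite(cube))) stop("cube contains non-finite pixel values")
  nb <- dim(cube)[3]

  fit_band <- function(v) {
    if (length(v) > max_pixels_fit)
      v <- v[round(seq(1, length(v), length.out = max_pixels_fit))]
    if (stats::sd(v) < 1e-10) return(NULL)
    fit <- tryCatch(
      Mclust(v, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    mu <- fit$parameters$mean
    sg <- sqrt(fit$parameters$variance$sigmasq)
    pi <- fit$parameters$pro
    # degenerate (unimodal) fit: components not separated
    if (abs(diff(mu)) < 2 * sum(sg)) return(NULL)
    list(mu = mu, sg = sg, pi = pi,
         between_var = pi[1] * pi[2] * diff(mu)^2)
  }

  fits <- lapply(seq_len(nb), function(b) fit_band(as.vector(cube[, , b])))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("Gaussian-mixture fit is degenerate on every band (no bimodal ",
         "channel found); supply a manual threshold")
  bvar <- rep(-Inf, nb)
  bvar[ok] <- vapply(fits[ok], `[[`, numeric(1), "between_var")
  channel <- which.max(bvar)
  f <- fits[[channel]]

  # threshold at the posterior crossing between the component means
  lo <- min(f$mu); hi <- max(f$mu)
  logratio <- function(x)
    log(f$pi[1]) + stats::dnorm(x, f$mu[1], f$sg[1], log = TRUE) -
    log(f$pi[2]) - stats::dnorm(x, f$mu[2], f$sg[2], log = TRUE)
  thr <- tryCatch(stats::uniroot(logratio, c(lo, hi))$root,
                  error = function(e) mean(f$mu))

  band <- cube[, , channel]
  bright <- band > thr
  if (mean(bright) > 0.5) bright <- !bright  # dark disk on bright background
  mask <- largest_component(bright)
  if (!any(mask) || all(mask))
    stop("segmentation produced an empty or full-frame mask; ",
         "supply a manual threshold")
  structure(list(mask = mask, channel_used = channel, threshold = thr,
                 foreground_fraction = mean(mask)),
            class = "uosdfs_segmentation")
}

# largest 4-connected TRUE region of a logical matrix
largest_component <- function(x) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    lab <- EBImage::bwlabel(x)
    tab <- tabulate(lab[lab > 0])
    if (length(tab) == 0L) return(x & FALSE)
    return(lab == which.max(tab))
  }
  # fallback: iterative label propagation
  m <- nrow(x); n <- ncol(x)
  lab <- matrix(0L, m, n)
  lab[x] <- seq_len(sum(x))
  repeat {
    new <- lab
    new[-1, ] <- pmax(new[-1, ], lab[-m, ] * x[-1, ])
    new[-m, ] <- pmax(new[-m, ], lab[-1, ] * x[-m, ])
    new[, -1] <- pmax(new[, -1], lab[, -n] * x[, -1])
    new[, -n] <- pmax(new[, -n], lab[, -1] * x[, -n])
    if (identical(new, lab)) break
    lab <- new
  }
  tab <- tabulate(lab[lab > 0])
  if (length(tab) == 0L) return(x & FALSE)
  lab == which.max(tab)
}

#' Extract the mean/SD reflectance feature vector from a cube
#'
#' Each band is min-max normalized to [0, 1] over the whole frame (a constant
#' band maps to all zeros), then the mean and the population standard
#' deviation of the normalized pixels inside the mask are computed. Output
#' ordering is all band means followed by all band SDs.
#'
#' @param cube Numeric array m x n x n_bands.
#' @param mask Logical m x n foreground mask; must select at least one pixel.
#' @param wavelengths Optional band centres used to name the features;
#'   defaults to [msi_wavelengths()] when the cube has 18 bands.
#'
#' @return Named numeric vector of length 2 * n_bands.
#' @export
extract_features <- function(cube, mask, wavelengths = NULL) {
  if (length(dim(cube)) != 3L) stop("cube must be a 3-d array")
  nb <- dim(cube)[3]
  if (!is.logical(mask) || !identical(dim(mask), dim(cube)[1:2]))
    stop("mask must be a logical matrix matching the cube's spatial size")
  if (!any(mask)) stop("mask is empty: no foreground pixels to summarize")
  if (is.null(wavelengths))
    wavelengths <- if (nb == 18L) msi_wavelengths() else seq_len(nb)

  means <- numeric(nb); sds <- numeric(nb)
  for (b in seq_len(nb)) {
    v <- cube[, , b]
    rng <- range(v)
    vn <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
    px <- vn[mask]
    means[b] <- mean(px)
    sds[b] <- sqrt(mean((px - means[b])^2))  # population SD
  }
  stats::setNames(c(means, sds), feature_names(wavelengths))
}

#' Write / read a multispectral cube as multi-page TIFF
#'
#' One 32-bit float page per band. `write_cube` optionally stores ground truth
#' (the foreground mask) in a JSON sidecar next to the TIFF.
#'
#' @param cube Numeric array m x n x n_bands with values in [0, 1].
#' @param path Output TIFF path.
#' @param mask Optional logical ground-truth mask saved to `<path>.json`.
#' @return `write_cube`: the path, invisibly. `read_cube`: a list with `cube`
#'   and `mask` (NULL when no sidecar exists).
#' @export
write_cube <- function(cube, path, mask = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to write cubes")
  pages <- lapply(seq_len(dim(cube)[3]), function(b) cube[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  if (!is.null(mask)) {
    sidecar <- list(dim = dim(mask), mask_idx = which(mask))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to read cubes")
  pages <- tiff::readTIFF(path, all = TRUE)
  cube <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) cube[, , b] <- pages[[b]]
  mask <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    mask <- matrix(FALSE, sc$dim[1], sc$dim[2])
    mask[sc$mask_idx] <- TRUE
  }
  list(cube = cube, mask = mask)
}
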