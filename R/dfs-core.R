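# The three-stage dynamic feature selection cascade: training-dependent
# Fisher-score elimination, then two per-test-sample online criteria — a
# per-feature Mahalanobis distance ratio (rejects features where the sample is
# ambiguous or an outlier) and a maximum Gaussian class probability (rejects
# features where the sample fits neither class). Each test sample gets its own
# feature subset; nothing carries over between samples.

#' Per-class, per-feature training summaries
#'
#' Computes the class means, variances and counts the online criteria need.
#' Both variance conventions are kept: the population variance (divide by the
#' class count) feeds the within-class scatter of the Fisher score, while the
#' sample variance (divide by count - 1) is used as the class dispersion in
#' the Mahalanobis and Gaussian-probability criteria.
#'
#' @param x Numeric matrix, samples x features (training split only).
#' @param y Binary labels (0 = fresh, 1 = spoiled), length nrow(x).
#'
#' @return An object of class `uosdfs_class_stats`: `mean`, `var_pop`,
#'   `var_sample` (2 x p matrices, row 1 = class 0), `counts`, and two global
#'   per-feature means (`global_class_means`, the unweighted mean of the two
#'   class means; `global_pooled`, the mean over all samples).
#' @export
class_stats <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  counts <- c(sum(y == 0L), sum(y == 1L))
  if (any(counts < 2L))
    stop("each class needs at least 2 training samples (got ",
         counts[1], " and ", counts[2], ")")
  p <- ncol(x)
  mu <- rbind(colMeans(x[y == 0L, , drop = FALSE]),
              colMeans(x[y == 1L, , drop = FALSE]))
  var_pop <- var_samp <- matrix(0, 2, p)
  for (d in 1:2) {
    xd <- x[y == (d - 1L), , drop = FALSE]
    centered <- sweep(xd, 2, mu[d, ])
    ss <- colSums(centered^2)
    var_pop[d, ] <- ss / counts[d]
    var_samp[d, ] <- ss / (counts[d] - 1L)
  }
  structure(list(mean = mu, var_pop = var_pop, var_sample = var_samp,
                 counts = counts,
                 global_class_means = colMeans(mu),
                 global_pooled = colMeans(x),
                 feature_names = colnames(x)),
            class = "uosdfs_class_stats")
}

#' Fisher discriminant scores of the training features
#'
#' For each feature k, FDS_k = SB_k / SW_k where SB_k is the between-class
#' scatter of the two class means about the global feature mean and SW_k is
#' the sum of the two within-class (population) variances. High FDS marks a
#' feature whose class means are well separated relative to the within-class
#' spread. Scores are also returned max-normalized to [0, 1], the scale the
#' FDS threshold operates on.
#'
#' A zero within-class scatter with positive between-class scatter yields an
#' infinite score (the feature separates the classes perfectly and is
#' retained); zero scatter both between and within yields 0.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Binary labels 0/1; each class needs at least 2 samples.
#' @param global_mean Convention for the global feature mean in SB: the
#'   unweighted mean of the two class means (default, makes SB depend only on
#'   the class-mean gap) or the pooled mean over all samples.
#'
#' @return List of class `uosdfs_fds`: `fds` (raw scores), `fds_norm`
#'   (max-normalized), `sb`, `sw`.
#' @export
fisher_scores <- function(x, y, global_mean = c("class_means", "pooled")) {
  global_mean <- match.arg(global_mean)
  st <- class_stats(x, y)
  gm <- if (global_mean == "class_means") st$global_class_means
        else st$global_pooled
  sb <- (st$mean[1, ] - gm)^2 + (st$mean[2, ] - gm)^2
  sw <- st$var_pop[1, ] + st$var_pop[2, ]
  if (all(sw == 0) && all(sb == 0))
    stop("all features have zero variance; Fisher scores undefined")
  fds <- ifelse(sw > 0, sb / sw, ifelse(sb > 0, Inf, 0))
  fds_norm <- normalize_fds(fds)
  structure(list(fds = fds, fds_norm = fds_norm, sb = sb, sw = sw,
                 global_mean = global_mean),
            class = "uosdfs_fds")
}

normalize_fds <- function(fds) {
  if (any(is.infinite(fds))) {
    out <- rep(0, length(fds))
    out[is.infinite(fds)] <- 1
    fin <- is.finite(fds) & fds > 0
    mx <- max(fds[is.finite(fds)], 0)
    if (mx > 0) out[fin] <- fds[fin] / mx * (1 - 1e-12)  # strictly below the Inf group
    return(out)
  }
  mx <- max(fds)
  if (mx == 0) rep(0, length(fds)) else fds / mx
}

#' Stage 1: eliminate low-Fisher-score features
#'
#' Retains features whose max-normalized Fisher score is at least `th_fd`.
#' Never returns an empty set: if the threshold rejects everything, the single
#' top-ranked feature is kept and the fallback flag is raised.
#'
#' @param fds_norm Max-normalized Fisher scores in [0, 1].
#' @param th_fd Threshold on the normalized score.
#' @return List: `selected` (integer feature indices), `fallback_used`.
#' @export
fds_filter <- function(fds_norm, th_fd) {
  keep <- which(fds_norm >= th_fd)
  fallback <- length(keep) == 0L
  if (fallback) keep <- which.max(fds_norm)
  list(selected = keep, fallback_used = fallback)
}

#' Stage 2 criterion: per-feature Mahalanobis distance ratio
#'
#' For feature k with test value s_k, the squared one-dimensional Mahalanobis
#' distances to the two class distributions are M_d = (s_k - mean_dk)^2 /
#' var_dk (sample variance). The ratio MR_k = min(M_1, M_2) / max(M_1, M_2)
#' lies in [0, 1]: near 0 the sample sits close to exactly one class (the
#' feature discriminates for this sample), near 1 it is equidistant from both
#' (ambiguous, or an outlier far from both). `form = "asymmetric"` exposes the
#' class-order-dependent variant M_1^2 / M_2 for auditing.
#'
#' @param stats A `uosdfs_class_stats` object.
#' @param s Numeric test feature vector (full length).
#' @param features Feature indices to evaluate (default all).
#' @param form `"minmax"` (default) or `"asymmetric"`.
#' @return Numeric vector of MR values over `features`; NA where either class
#'   variance is zero (feature non-evaluable for this sample).
#' @export
mahalanobis_ratio <- function(stats, s, features = seq_along(s),
                              form = c("minmax", "asymmetric")) {
  form <- match.arg(form)
  m1 <- (s[features] - stats$mean[1, features])^2 / stats$var_sample[1, features]
  m2 <- (s[features] - stats$mean[2, features])^2 / stats$var_sample[2, features]
  bad <- stats$var_sample[1, features] == 0 | stats$var_sample[2, features] == 0
  mr <- if (form == "minmax") {
    lo <- pmin(m1, m2); hi <- pmax(m1, m2)
    ifelse(hi == 0, 1, lo / hi)  # on both means at once: equidistant
  } else {
    ifelse(m2 == 0, Inf, m1 * m1 / m2)
  }
  mr[bad] <- NA_real_
  mr
}

#' Stage 2: reject features with a high Mahalanobis ratio
#'
#' Keeps the features of `surviving` whose MR is at most `th_mr`;
#' non-evaluable features (zero class variance) are rejected.
#'
#' @param stats A `uosdfs_class_stats` object.
#' @param s Test feature vector.
#' @param surviving Candidate feature indices (stage-1 survivors).
#' @param th_mr Threshold in [0, 1].
#' @param form Passed to [mahalanobis_ratio()].
#' @return Integer vector of surviving feature indices (possibly empty).
#' @export
mr_filter <- function(stats, s, surviving, th_mr, form = "minmax") {
  if (length(surviving) == 0L) stop("surviving set must be non-empty")
  mr <- mahalanobis_ratio(stats, s, surviving, form = form)
  surviving[!is.na(mr) & mr <= th_mr]
}

#' Stage 3 criterion: maximum Gaussian class probability
#'
#' P_k = max over the two classes of the univariate normal density with that
#' class's training mean and (sample) standard deviation, evaluated at the
#' test value. Low P_k means the sample value fits neither class distribution
#' on this feature — an outlier value to be rejected.
#'
#' @inheritParams mahalanobis_ratio
#' @return Numeric vector of density values; NA where a class SD is zero.
#' @export
class_probability <- function(stats, s, features = seq_along(s)) {
  sd1 <- sqrt(stats$var_sample[1, features])
  sd2 <- sqrt(stats$var_sample[2, features])
  bad <- sd1 == 0 | sd2 == 0
  p <- pmax(stats::dnorm(s[features], stats$mean[1, features], sd1),
            stats::dnorm(s[features], stats$mean[2, features], sd2))
  p[bad] <- NA_real_
  p
}

#' Stage 3: reject features with low class-fit probability
#'
#' Keeps features whose maximum class density is at least `th_p`. If nothing
#' survives, the single feature with the highest density is retained and the
#' fallback flag raised.
#'
#' @inheritParams mr_filter
#' @param th_p Density threshold (> 0 rejects; 0 retains everything
#'   evaluable).
#' @return List: `selected`, `fallback_used`.
#' @export
p_filter <- function(stats, s, surviving, th_p) {
  if (length(surviving) == 0L) stop("surviving set must be non-empty")
  p <- class_probability(stats, s, surviving)
  keep <- surviving[!is.na(p) & p >= th_p]
  fallback <- length(keep) == 0L
  if (fallback && any(!is.na(p))) keep <- surviving[which.max(p)]
  list(selected = keep, fallback_used = fallback)
}

#' Threshold triple for the DFS cascade
#'
#' @param th_fd Cutoff on max-normalized Fisher scores, in [0, 1].
#' @param th_mr Cutoff on the Mahalanobis ratio, in [0, 1].
#' @param th_p Cutoff on the maximum class density, non-negative.
#' @return Object of class `uosdfs_thresholds`.
#' @export
threshold_triple <- function(th_fd, th_mr, th_p) {
  if (!all(is.finite(c(th_fd, th_mr, th_p))))
    stop("thresholds must be finite")
  if (th_mr < 0 || th_mr > 1) stop("th_mr must lie in [0, 1]")
  if (th_p < 0) stop("th_p must be non-negative")
  structure(list(th_fd = th_fd, th_mr = th_mr, th_p = th_p),
            class = "uosdfs_thresholds")
}

#' Run the full DFS cascade for one test sample
#'
#' Applies, in order, the Fisher-score filter (training-dependent), the
#' Mahalanobis-ratio filter and the class-probability filter (both computed
#' against this sample). Selection is stateless: every test sample starts from
#' the full training feature pool, which realizes the re-insertion of features
#' dropped for earlier samples.
#'
#' Should all three stages leave nothing, the single best feature by (lowest
#' MR, then highest P, then highest Fisher score) among the stage-1 survivors
#' is retained and `fallback_used` is set.
#'
#' @param stats A `uosdfs_class_stats` object (training split only).
#' @param fds_norm Max-normalized Fisher scores of the training features.
#' @param s Test feature vector.
#' @param thresholds A `uosdfs_thresholds` object.
#' @param sample_id Optional identifier carried into the trace.
#' @param mr_form Mahalanobis-ratio variant, see [mahalanobis_ratio()].
#'
#' @return Object of class `uosdfs_trace`: `sample_id`,
#'   `surviving_after_fds`, `surviving_after_mr`, `surviving_after_p`
#'   (each an integer index set), `selected` (the final non-empty set),
#'   `fallback_used`, and the per-feature `mr` and `p` values over the stage-1
#'   survivors.
#' @export
select_features <- function(stats, fds_norm, s, thresholds,
                            sample_id = NA_character_, mr_form = "minmax") {
  stage1 <- fds_filter(fds_norm, thresholds$th_fd)
  fallback <- stage1$fallback_used
  surv1 <- stage1$selected

  mr <- mahalanobis_ratio(stats, s, surv1, form = mr_form)
  surv2 <- surv1[!is.na(mr) & mr <= thresholds$th_mr]
  p_all <- class_probability(stats, s, surv1)
  surv3 <- if (length(surv2) == 0L) integer(0) else {
    p2 <- p_all[match(surv2, surv1)]
    surv2[!is.na(p2) & p2 >= thresholds$th_p]
  }

  selected <- surv3
  if (length(selected) == 0L) {
    fallback <- TRUE
    ord <- order(mr, -p_all, -fds_norm[surv1], na.last = TRUE)
    selected <- surv1[ord[1L]]
  }
  structure(list(sample_id = sample_id,
                 surviving_after_fds = surv1,
                 surviving_after_mr = surv2,
                 surviving_after_p = surv3,
                 selected = selected,
                 fallback_used = fallback,
                 mr = stats::setNames(mr, surv1),
                 p = stats::setNames(p_all, surv1)),
            class = "uosdfs_trace")
}
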