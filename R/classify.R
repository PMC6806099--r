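# Classifier layer: one model per test sample, trained on the training set
# restricted to that sample's selected features. Families: linear-kernel SVM
# (default), LDA, QDA. Models are memoized by selected-feature set, so samples
# sharing a subset share one fit.

#' Classifier specification
#'
#' @param family `"linear_max_margin"` (linear-kernel support vector machine,
#'   the default), `"linear_discriminant"` or `"quadratic_discriminant"`.
#' @param regularization Margin trade-off (SVM cost) for the max-margin
#'   family; ignored by the discriminant families.
#' @param standardize Standardize feature columns before fitting. Off by
#'   default: extracted features are already normalized to [0, 1] and the
#'   selection criteria are variance-aware.
#' @param random_seed Seed recorded for provenance; the fits themselves are
#'   deterministic.
#' @return Object of class `uosdfs_model_spec`.
#' @export
model_spec <- function(family = c("linear_max_margin", "linear_discriminant",
                                  "quadratic_discriminant"),
                       regularization = 1.0, standardize = FALSE,
                       random_seed = 1L) {
  family <- match.arg(family)
  if (regularization <= 0) stop("regularization must be positive")
  structure(list(family = family, regularization = regularization,
                 standardize = standardize,
                 random_seed = as.integer(random_seed)),
            class = "uosdfs_model_spec")
}

# fit one model on the selected columns; returns closure predicting
# (label, score) for a feature vector. Decision score is oriented so that
# positive favours class 1 (spoiled); exact zero resolves to class 0.
fit_model <- function(x, y, selected, spec) {
  if (length(selected) == 0L) stop("selected feature set must be non-empty")
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; cannot fit a classifier")
  xs <- x[, selected, drop = FALSE]
  colnames(xs) <- paste0("f", selected)
  ctr <- rep(0, ncol(xs)); scl <- rep(1, ncol(xs))
  if (spec$standardize) {
    ctr <- colMeans(xs)
    scl <- apply(xs, 2, stats::sd)
    scl[scl == 0] <- 1
    xs <- scale(xs, ctr, scl)
  }
  yf <- factor(y, levels = c(0, 1))

  if (spec$family == "linear_max_margin") {
    fit <- e1071::svm(xs, yf, kernel = "linear", cost = spec$regularization,
                      scale = FALSE)
    # e1071 orients decision values toward the first of its internal labels
    positive_first <- fit$levels[fit$labels[1]] == "1"
    function(s) {
      z <- matrix((s[selected] - ctr) / scl, 1,
                  dimnames = list(NULL, colnames(xs)))
      dv <- attr(stats::predict(fit, z, decision.values = TRUE),
                 "decision.values")[1]
      score <- if (positive_first) dv else -dv
      list(label = if (score > 0) 1L else 0L, score = score)
    }
  } else if (spec$family == "linear_discriminant") {
    fit <- MASS::lda(xs, grouping = yf)
    function(s) {
      z <- matrix((s[selected] - ctr) / scl, 1,
                  dimnames = list(NULL, colnames(xs)))
      pr <- stats::predict(fit, as.data.frame(z))
      score <- log(pr$posterior[1, "1"]) - log(pr$posterior[1, "0"])
      list(label = if (score > 0) 1L else 0L, score = score)
    }
  } else {
    fit <- tryCatch(MASS::qda(xs, grouping = yf), error = function(e) NULL)
    if (is.null(fit)) {
      warning("QDA class covariance singular on the selected features; ",
              "falling back to a ridge-regularized Gaussian discriminant")
      fit <- rqda_fit(xs, yf)
      return(function(s) {
        z <- (s[selected] - ctr) / scl
        score <- rqda_score(fit, z)
        list(label = if (score > 0) 1L else 0L, score = score)
      })
    }
    function(s) {
      z <- matrix((s[selected] - ctr) / scl, 1,
                  dimnames = list(NULL, colnames(xs)))
      pr <- stats::predict(fit, as.data.frame(z))
      score <- log(pr$posterior[1, "1"]) - log(pr$posterior[1, "0"])
      list(label = if (score > 0) 1L else 0L, score = score)
    }
  }
}

# Gaussian discriminant with ridge-stabilized class covariances
rqda_fit <- function(x, yf) {
  cls <- levels(yf)
  fits <- lapply(cls, function(cl) {
    xc <- x[yf == cl, , drop = FALSE]
    S <- stats::cov(xc)
    eps <- 1e-6 * mean(diag(S)) + 1e-12
    S <- S + diag(eps, ncol(x))
    list(mu = colMeans(xc), Sinv = solve(S),
         logdet = determinant(S, logarithm = TRUE)$modulus,
         logprior = log(mean(yf == cl)))
  })
  names(fits) <- cls
  fits
}

rqda_score <- function(fit, z) {
  lp <- vapply(fit, function(f) {
    d <- z - f$mu
    as.numeric(f$logprior - 0.5 * f$logdet - 0.5 * t(d) %*% f$Sinv %*% d)
  }, numeric(1))
  lp[["1"]] - lp[["0"]]
}

#' Train on a sample's selected features and predict its label
#'
#' Fits the requested model family on the training rows restricted to the
#' selected feature columns and scores one test sample. The decision score is
#' signed so that positive values indicate class 1 (spoiled); an exact zero is
#' resolved conservatively to class 0 (fresh).
#'
#' @param x Training feature matrix (samples x features).
#' @param y Binary training labels 0/1.
#' @param selected Integer indices of the features to use.
#' @param s Test feature vector (full length; columns are subset internally).
#' @param spec A `uosdfs_model_spec`.
#' @return List: `label` (0/1), `score` (signed decision value).
#' @export
fit_predict_one <- function(x, y, selected, s, spec = model_spec()) {
  fit_model(as.matrix(x), y, selected, spec)(s)
}

#' Classify a test set with per-sample dynamic feature selection
#'
#' For every test sample: run the DFS cascade against the training statistics,
#' fit the classifier on the selected columns, and predict. Each prediction
#' depends only on the fixed training split and that sample's features, so
#' results are independent of test-set order. Fits are cached by
#' selected-feature set.
#'
#' @param train_x,train_y Training features and binary labels.
#' @param test_x Test feature matrix.
#' @param thresholds A `uosdfs_thresholds` triple.
#' @param spec A `uosdfs_model_spec`.
#' @param sample_ids Optional test sample identifiers.
#' @param mr_form Mahalanobis-ratio variant, see [mahalanobis_ratio()].
#' @param fds Optional precomputed `uosdfs_fds` for the training split.
#' @param stats Optional precomputed `uosdfs_class_stats`.
#' @param cache Optional environment reused across calls to share model fits
#'   (e.g. across a threshold grid).
#'
#' @return List of class `uosdfs_predictions`: `label` (integer vector),
#'   `score`, `n_selected`, `fallback_used`, `traces` (list of
#'   `uosdfs_trace`), `thresholds`, `spec`.
#' @export
classify_testset <- function(train_x, train_y, test_x, thresholds,
                             spec = model_spec(), sample_ids = NULL,
                             mr_form = "minmax", fds = NULL, stats = NULL,
                             cache = NULL) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (is.null(stats)) stats <- class_stats(train_x, train_y)
  if (is.null(fds)) fds <- fisher_scores(train_x, train_y)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  n <- nrow(test_x)
  if (is.null(sample_ids)) sample_ids <- rownames(test_x)
  if (is.null(sample_ids)) sample_ids <- sprintf("T%04d", seq_len(n))

  labels <- integer(n); scores <- numeric(n)
  nsel <- integer(n); fb <- logical(n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- select_features(stats, fds$fds_norm, test_x[i, ], thresholds,
                          sample_id = sample_ids[i], mr_form = mr_form)
    key <- paste(tr$selected, collapse = ",")
    predictor <- cache[[key]]
    if (is.null(predictor)) {
      predictor <- fit_model(train_x, train_y, tr$selected, spec)
      cache[[key]] <- predictor
    }
    pred <- predictor(test_x[i, ])
    labels[i] <- pred$label; scores[i] <- pred$score
    nsel[i] <- length(tr$selected); fb[i] <- tr$fallback_used
    traces[[i]] <- tr
  }
  structure(list(sample_id = sample_ids, label = labels, score = scores,
                 n_selected = nsel, fallback_used = fb, traces = traces,
                 thresholds = thresholds, spec = spec),
            class = "uosdfs_predictions")
}
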