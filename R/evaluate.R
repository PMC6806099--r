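# Labeling rules, confusion metrics, microbial-load bin tables, feature
# selection-rate summaries, leave-one-out training selection, and the static
# top-k baseline the dynamic cascade is compared against.

#' Microbiological quality class from total viable counts
#'
#' TVC at or below 2 log CFU/g marks a releasable (fresh) product; at or above
#' 6 log CFU/g the common spoilage guideline is exceeded. The open interval
#' between is a transition zone: such samples are excluded from training and
#' validation but kept in the test set.
#'
#' @param tvc Total viable counts in log CFU/g (non-negative).
#' @return Character vector over {"fresh", "intermediate", "spoiled"}.
#' @export
assign_class <- function(tvc) {
  if (any(!is.finite(tvc)) || any(tvc < 0))
    stop("tvc must be non-negative and finite (log CFU/g)")
  ifelse(tvc <= 2, "fresh", ifelse(tvc >= 6, "spoiled", "intermediate"))
}

#' Binary label (0 fresh / 1 spoiled / NA intermediate) from TVC
#' @inheritParams assign_class
#' @return Integer vector with NA for transition-zone samples.
#' @export
assign_label <- function(tvc) {
  cls <- assign_class(tvc)
  ifelse(cls == "fresh", 0L, ifelse(cls == "spoiled", 1L, NA_integer_))
}

#' Confusion matrix with derived rates
#'
#' Spoiled (label 1) is the positive class. Sensitivity is the true-positive
#' rate tp / (tp + fn), specificity the true-negative rate tn / (tn + fp),
#' accuracy the overall fraction correct.
#'
#' @param truth,predicted Equal-length binary (0/1) vectors.
#' @return Object of class `uosdfs_confusion`: counts `tn`, `fp`, `fn`, `tp`
#'   and derived `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!all(c(truth, predicted) %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  tn <- sum(truth == 0 & predicted == 0)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  tp <- sum(truth == 1 & predicted == 1)
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / (tn + fp + fn + tp)),
            class = "uosdfs_confusion")
}

#' Build a confusion object directly from the four cell counts
#' @param tn,fp,fn,tp Non-negative cell counts (spoiled = positive).
#' @return An `uosdfs_confusion` object.
#' @export
confusion_from_counts <- function(tn, fp, fn, tp) {
  if (any(c(tn, fp, fn, tp) < 0)) stop("counts must be non-negative")
  confusion(rep(c(0L, 0L, 1L, 1L), c(tn, fp, fn, tp)),
            rep(c(0L, 1L, 0L, 1L), c(tn, fp, fn, tp)))
}

#' @export
print.uosdfs_confusion <- function(x, ...) {
  cat("Confusion matrix (positive = spoiled)\n")
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("fresh", "spoiled"),
                              truth = c("fresh", "spoiled")))
  print(m)
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' Classification outcome per TVC bin
#'
#' Cross-tabulates predicted labels against the microbial-load bins
#' [0,2), [2,3), [3,4), [4,5), [5,6), [6, Inf) — lower-closed, upper-open
#' (the report's fresh bin is TVC < 2, slightly narrower than the <=2 training
#' definition). Percentages are count ratios; empty bins report NA.
#'
#' @param tvc TVC values (log CFU/g), aligned with `predicted`.
#' @param predicted Binary predicted labels (1 = spoiled assignment).
#' @return Object of class `uosdfs_bin_table`: data.frame with bin, n,
#'   positive, negative, positive_pct, negative_pct.
#' @export
tvc_bin_table <- function(tvc, predicted) {
  if (length(tvc) != length(predicted))
    stop("tvc and predicted must have equal length")
  edges <- c(0, 2, 3, 4, 5, 6, Inf)
  labs <- c("TVC < 2", "TVC in [2,3)", "TVC in [3,4)", "TVC in [4,5)",
            "TVC in [5,6)", "TVC >= 6")
  bin <- cut(tvc, edges, right = FALSE, labels = labs)
  n <- as.integer(table(bin))
  pos <- as.integer(tapply(predicted == 1L, bin, sum, default = 0L))
  neg <- n - pos
  out <- data.frame(bin = labs, n = n, positive = pos, negative = neg,
                    positive_pct = ifelse(n > 0, 100 * pos / n, NA_real_),
                    negative_pct = ifelse(n > 0, 100 * neg / n, NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("uosdfs_bin_table", "data.frame")
  out
}

#' @export
print.uosdfs_bin_table <- function(x, ...) {
  cat("Assignments per TVC bin (positive = spoiled)\n")
  fmt <- function(k, n, pct)
    ifelse(n > 0, sprintf("%d/%d (%.0f%%)", k, n, pct), "-")
  print(data.frame(bin = x$bin,
                   positive = fmt(x$positive, x$n, x$positive_pct),
                   negative = fmt(x$negative, x$n, x$negative_pct)),
        row.names = FALSE)
  invisible(x)
}

#' Per-feature selection rates from cascade traces
#'
#' The selection rate of a feature is the fraction of traces whose final
#' selected set contains it, reported separately for the band-mean features
#' and the band-SD features.
#'
#' @param traces List of `uosdfs_trace` objects (e.g. from
#'   [classify_testset()]).
#' @param n_features Total feature count (default 36).
#' @param feature_labels Optional feature names.
#' @return Data.frame of class `uosdfs_selection_rates`: feature index, name,
#'   group ("mean"/"sd", first half vs second half), rate.
#' @export
selection_rates <- function(traces, n_features = 36L, feature_labels = NULL) {
  if (length(traces) == 0L) stop("no traces supplied")
  counts <- integer(n_features)
  for (tr in traces) counts[tr$selected] <- counts[tr$selected] + 1L
  if (is.null(feature_labels)) {
    feature_labels <- if (n_features == 36L) feature_names()
                      else paste0("feature_", seq_len(n_features))
  }
  half <- n_features %/% 2L
  out <- data.frame(feature = seq_len(n_features), name = feature_labels,
                    group = rep(c("mean", "sd"),
                                c(half, n_features - half)),
                    rate = counts / length(traces),
                    stringsAsFactors = FALSE)
  class(out) <- c("uosdfs_selection_rates", "data.frame")
  out
}

#' Leave-one-out selection rates on the training split
#'
#' For each training sample, class statistics and Fisher scores are recomputed
#' on the remaining samples, the held-out sample is pushed through the DFS
#' cascade, and selection rates are aggregated over all folds.
#'
#' @param train_x,train_y Training features and binary labels (at least 3
#'   samples per class).
#' @param thresholds A `uosdfs_thresholds`.
#' @param mr_form Mahalanobis-ratio variant.
#' @return A `uosdfs_selection_rates` data.frame, with the fold traces
#'   attached as attribute `traces`.
#' @export
loo_training_selection <- function(train_x, train_y, thresholds,
                                   mr_form = "minmax") {
  train_x <- as.matrix(train_x)
  if (min(table(factor(train_y, c(0, 1)))) < 3L)
    stop("leave-one-out needs at least 3 training samples per class")
  n <- nrow(train_x)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    xr <- train_x[-i, , drop = FALSE]; yr <- train_y[-i]
    st <- class_stats(xr, yr)
    fd <- fisher_scores(xr, yr)
    traces[[i]] <- select_features(st, fd$fds_norm, train_x[i, ], thresholds,
                                   sample_id = paste0("fold", i),
                                   mr_form = mr_form)
  }
  rates <- selection_rates(traces, n_features = ncol(train_x),
                           feature_labels = colnames(train_x))
  attr(rates, "traces") <- traces
  rates
}

#' Static top-k feature-selection baseline
#'
#' The counterpoint to the dynamic cascade: the top k features by training
#' Fisher score are chosen once, a single classifier is fitted, and every test
#' sample is predicted with that same model.
#'
#' @param train_x,train_y Training features and binary labels.
#' @param test_x Test feature matrix.
#' @param k Number of features to keep (1 to n_features).
#' @param spec A `uosdfs_model_spec`.
#' @return List: `label`, `score`, `selected` (the fixed feature set).
#' @export
static_baseline <- function(train_x, train_y, test_x, k, spec = model_spec()) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (k < 1L || k > ncol(train_x)) stop("k must be in [1, n_features]")
  fds <- fisher_scores(train_x, train_y)
  selected <- order(fds$fds, decreasing = TRUE)[seq_len(k)]
  predictor <- fit_model(train_x, train_y, selected, spec)
  preds <- apply(test_x, 1, predictor)
  list(label = vapply(preds, `[[`, integer(1), "label"),
       score = vapply(preds, `[[`, numeric(1), "score"),
       selected = sort(selected))
}
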