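# Exhaustive nested grid search over the three cascade thresholds, minimizing
# the count of misclassified validation samples.

#' Threshold grid specification
#'
#' Inclusive ranges and steps for the three thresholds. The defaults span
#' th_fd in [0.13, 0.17], th_mr in [0.74, 0.77] and th_p in [0.08, 0.12], all
#' with step 0.01 — a 5 x 4 x 5 = 100-point grid. Grid points are materialized
#' by index arithmetic (`low + i * step`) so floating-point accumulation never
#' drops an endpoint.
#'
#' @param th_fd_range,th_mr_range,th_p_range Length-2 numeric (low, high).
#' @param th_fd_step,th_mr_step,th_p_step Positive step sizes.
#' @return Object of class `uosdfs_grid`: numeric vectors `th_fd`, `th_mr`,
#'   `th_p`.
#' @export
grid_spec <- function(th_fd_range = c(0.13, 0.17), th_fd_step = 0.01,
                      th_mr_range = c(0.74, 0.77), th_mr_step = 0.01,
                      th_p_range = c(0.08, 0.12), th_p_step = 0.01) {
  axis <- function(range, step, name) {
    if (length(range) != 2L || range[1] > range[2])
      stop("invalid range for ", name)
    if (step <= 0) stop("step for ", name, " must be positive")
    k <- floor((range[2] - range[1]) / step + 1e-9)
    range[1] + step * (0:k)
  }
  structure(list(th_fd = axis(th_fd_range, th_fd_step, "th_fd"),
                 th_mr = axis(th_mr_range, th_mr_step, "th_mr"),
                 th_p = axis(th_p_range, th_p_step, "th_p")),
            class = "uosdfs_grid")
}

#' Exhaustive threshold optimization on a validation split
#'
#' Evaluates every (th_fd, th_mr, th_p) combination of the grid by running the
#' per-sample DFS cascade plus classifier on the validation split and counting
#' label mismatches. Returns the minimizing triple and the full error surface.
#' Ties are broken toward the sparser cascade: higher th_fd, then higher
#' th_mr, then lower th_p.
#'
#' @param train_x,train_y Training features and binary labels.
#' @param val_x,val_y Validation features and binary labels (both classes
#'   required).
#' @param grid A `uosdfs_grid`.
#' @param spec A `uosdfs_model_spec`.
#' @param mr_form Mahalanobis-ratio variant.
#'
#' @return List of class `uosdfs_gridsearch`: `best` (a `uosdfs_thresholds`),
#'   `best_errors` (validation mismatch count at the optimum), and `surface`
#'   (data.frame th_fd, th_mr, th_p, val_errors over all grid points).
#' @export
grid_search <- function(train_x, train_y, val_x, val_y, grid = grid_spec(),
                        spec = model_spec(), mr_form = "minmax") {
  if (length(unique(val_y)) < 2L)
    stop("validation split must contain both classes")
  pts <- expand.grid(th_fd = grid$th_fd, th_mr = grid$th_mr, th_p = grid$th_p,
                     KEEP.OUT.ATTRS = FALSE)
  if (nrow(pts) == 0L) stop("threshold grid is empty")
  train_x <- as.matrix(train_x); val_x <- as.matrix(val_x)
  stats <- class_stats(train_x, train_y)
  fds <- fisher_scores(train_x, train_y)
  cache <- new.env(parent = emptyenv())  # model fits shared across the grid

  errs <- integer(nrow(pts))
  for (j in seq_len(nrow(pts))) {
    th <- threshold_triple(pts$th_fd[j], pts$th_mr[j], pts$th_p[j])
    pred <- classify_testset(train_x, train_y, val_x, th, spec,
                             mr_form = mr_form, fds = fds, stats = stats,
                             cache = cache)
    errs[j] <- sum(pred$label != val_y)
  }
  # sparser-model tie-break: higher th_fd, higher th_mr, lower th_p
  ord <- order(errs, -pts$th_fd, -pts$th_mr, pts$th_p)
  best_j <- ord[1L]
  structure(list(
    best = threshold_triple(pts$th_fd[best_j], pts$th_mr[best_j],
                            pts$th_p[best_j]),
    best_errors = errs[best_j],
    surface = cbind(pts, val_errors = errs)),
    class = "uosdfs_gridsearch")
}
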