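# Format plumbing and the end-to-end pipeline: delimited feature tables,
# JSON-lines selection traces, and a run manifest that makes every run
# reproducible from its recorded configuration.

#' Read / write delimited feature tables
#'
#' Tab-separated, one row per sample: `sample_id`, `split`, `tvc`, `class`,
#' then the feature columns (2 x n_bands of them). `tvc` and `class` may be
#' empty on test rows (prediction-only mode). Malformed input is rejected with
#' the offending line numbers.
#'
#' @param path File path.
#' @param n_features Expected feature column count.
#' @return `read_feature_table`: a data.frame shaped like the output of
#'   [generate_dataset()]. `write_feature_table`: the path, invisibly.
#' @export
read_feature_table <- function(path, n_features = 36L) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("sample_id", "split", "tvc", "class")
  missing_meta <- setdiff(meta, names(d))
  if (length(missing_meta) > 0L)
    stop("feature table ", path, " lacks required column(s): ",
         paste(missing_meta, collapse = ", "))
  feat_cols <- setdiff(names(d), c(meta, "batch"))
  if (length(feat_cols) != n_features)
    stop("feature table ", path, " has ", length(feat_cols),
         " feature columns; expected ", n_features,
         " (deficit of ", n_features - length(feat_cols), ")")
  bad <- which(!vapply(d[feat_cols], is.numeric, logical(1)))
  if (length(bad) > 0L)
    stop("non-numeric feature column(s) in ", path, ": ",
         paste(feat_cols[bad], collapse = ", "))
  nf <- !stats::complete.cases(d[feat_cols])
  if (any(nf))
    stop("missing feature values in ", path, " at data line(s): ",
         paste(which(nf), collapse = ", "))
  dup <- duplicated(d$sample_id)
  if (any(dup))
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(d$sample_id[dup]), collapse = ", "))
  d
}

#' @rdname read_feature_table
#' @param x Data.frame with the table's columns.
#' @export
write_feature_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize selection traces as JSON lines
#'
#' One JSON record per test sample: the surviving index sets after each
#' cascade stage, the final selection and the fallback flag.
#'
#' @param traces List of `uosdfs_trace` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_traces <- function(traces, path) {
  lines <- vapply(traces, function(tr) {
    jsonlite::toJSON(list(
      sample_id = tr$sample_id,
      surviving_after_fds = tr$surviving_after_fds,
      surviving_after_mr = tr$surviving_after_mr,
      surviving_after_p = tr$surviving_after_p,
      selected = tr$selected,
      fallback_used = tr$fallback_used), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# split a feature-table data.frame into matrices the cascade consumes
split_table <- function(d) {
  meta <- intersect(c("sample_id", "split", "batch", "tvc", "class"), names(d))
  x <- as.matrix(d[, setdiff(names(d), meta), drop = FALSE])
  rownames(x) <- d$sample_id
  pick <- function(s) d$split == s
  list(
    train_x = x[pick("train"), , drop = FALSE],
    train_y = d$class[pick("train")],
    val_x = x[pick("validation"), , drop = FALSE],
    val_y = d$class[pick("validation")],
    test_x = x[pick("test"), , drop = FALSE],
    test_y = d$class[pick("test")],
    test_tvc = d$tvc[pick("test")]
  )
}

#' Run the full pipeline: tune, classify, evaluate
#'
#' Optimizes the three cascade thresholds on the validation split by
#' exhaustive grid search, classifies the test split with per-sample dynamic
#' feature selection at the optimum, and computes the evaluation reports
#' (confusion metrics, TVC bin table, selection rates). When `out_dir` is
#' given, writes predictions (delimited text), selection traces (JSON lines),
#' the error surface, and a JSON manifest recording configuration, seed,
#' chosen thresholds and metrics.
#'
#' @param data Feature-table data.frame with train/validation/test splits
#'   (from [generate_dataset()] or [read_feature_table()]).
#' @param grid A `uosdfs_grid`.
#' @param spec A `uosdfs_model_spec`.
#' @param mr_form Mahalanobis-ratio variant.
#' @param out_dir Optional output directory for artifacts.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given the data).
#'
#' @return List of class `uosdfs_run`: `thresholds`, `val_errors`, `surface`,
#'   `predictions`, `confusion`, `bin_table`, `rates`, `manifest`.
#' @export
run_pipeline <- function(data, grid = grid_spec(), spec = model_spec(),
                         mr_form = "minmax", out_dir = NULL, seed = 1L) {
  sp <- split_table(data)
  gs <- grid_search(sp$train_x, sp$train_y, sp$val_x, sp$val_y, grid, spec,
                    mr_form = mr_form)
  pred <- classify_testset(sp$train_x, sp$train_y, sp$test_x, gs$best, spec,
                           mr_form = mr_form)
  labeled <- !is.na(sp$test_y)
  cm <- if (any(labeled))
    confusion(sp$test_y[labeled], pred$label[labeled]) else NULL
  bins <- if (!all(is.na(sp$test_tvc)))
    tvc_bin_table(sp$test_tvc[!is.na(sp$test_tvc)],
                  pred$label[!is.na(sp$test_tvc)]) else NULL
  rates <- selection_rates(pred$traces, n_features = ncol(sp$test_x),
                           feature_labels = colnames(sp$test_x))

  manifest <- list(
    seed = seed,
    model = unclass(spec),
    grid = lapply(unclass(grid), as.numeric),
    mr_form = mr_form,
    thresholds = unclass(gs$best),
    val_errors = gs$best_errors,
    n_train = nrow(sp$train_x), n_validation = nrow(sp$val_x),
    n_test = nrow(sp$test_x),
    metrics = if (is.null(cm)) NULL else
      list(sensitivity = cm$sensitivity, specificity = cm$specificity,
           accuracy = cm$accuracy),
    package_version = as.character(utils::packageVersion("uosdfs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    preds_df <- data.frame(
      sample_id = pred$sample_id,
      true_tvc = sp$test_tvc, true_class = sp$test_y,
      predicted_class = pred$label, decision_score = pred$score,
      n_selected_features = pred$n_selected,
      fallback_used = pred$fallback_used)
    write_feature_table(preds_df, file.path(out_dir, "predictions.tsv"))
    write_traces(pred$traces, file.path(out_dir, "traces.jsonl"))
    utils::write.table(gs$surface, file.path(out_dir, "error_surface.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(thresholds = gs$best, val_errors = gs$best_errors,
                 surface = gs$surface, predictions = pred, confusion = cm,
                 bin_table = bins, rates = rates, manifest = manifest),
            class = "uosdfs_run")
}
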