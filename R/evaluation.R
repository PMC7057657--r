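#' Leaf/stem confusion counts with flower exclusion
#'
#' Tallies the 2x2 confusion between ground-truth and predicted leaf/stem
#' labels. Points whose ground truth is not leaf or stem (flower, pot, tag,
#' background) are excluded from the counts and reported in `n_ignored` —
#' predictions made on flower parts are ignored by the protocol.
#'
#' @param gt_labels Ground-truth organ codes.
#' @param pred_labels Predicted codes, each leaf (2) or stem (1).
#' @return A list with `confusion` (2x2 integer matrix, rows = truth,
#'   columns = prediction, classes leaf/stem) and `n_ignored`.
#' @export
#' @examples
#' confusion_counts(c(2, 2, 1, 3), c(2, 1, 1, 2))
confusion_counts <- function(gt_labels, pred_labels) {
  if (length(gt_labels) != length(pred_labels)) {
    stop_validation("ground truth and prediction lengths differ (",
                    length(gt_labels), " vs ", length(pred_labels), ")")
  }
  validate_organ_labels(gt_labels)
  if (!all(pred_labels %in% organ_code(c("leaf", "stem")))) {
    stop_validation("predictions must be leaf (2) or stem (1) codes")
  }
  keep <- gt_labels %in% organ_code(c("leaf", "stem"))
  gt <- factor(organ_name(gt_labels[keep]), levels = c("leaf", "stem"))
  pr <- factor(organ_name(pred_labels[keep]), levels = c("leaf", "stem"))
  conf <- table(truth = gt, prediction = pr)
  list(
    confusion = matrix(as.integer(conf), 2, 2,
                       dimnames = list(truth = c("leaf", "stem"),
                                       prediction = c("leaf", "stem"))),
    n_ignored = sum(!keep)
  )
}

#' Per-class precision, recall and IoU from confusion counts
#'
#' For each class, `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `IoU = TP / (TP + FN + FP)`. A zero denominator (class absent from both
#' truth and prediction) yields `NA`, deliberately distinct from 0, and such
#' values are dropped from averages downstream.
#'
#' @param counts Output of [confusion_counts()], or a 2x2 matrix.
#' @return A tibble with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `iou`.
#' @export
metrics_from_confusion <- function(counts) {
  conf <- if (is.list(counts)) counts$confusion else counts
  stopifnot(is.matrix(conf), all(dim(conf) == 2), all(conf >= 0))
  rows <- lapply(1:2, function(k) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    safe <- function(num, den) if (den > 0) num / den else NA_real_
    tibble::tibble(
      class = c("leaf", "stem")[k], tp = tp, fp = fp, fn = fn,
      precision = safe(tp, tp + fp),
      recall = safe(tp, tp + fn),
      iou = safe(tp, tp + fn + fp)
    )
  })
  dplyr::bind_rows(rows)
}

#' Evaluate a leaf/stem prediction against ground truth
#'
#' @param gt_labels Ground-truth organ codes.
#' @param pred_labels Predicted leaf/stem codes.
#' @return A `segmentation_report`: list with `confusion`, `n_ignored`,
#'   `metrics` (per-class tibble) and `mean_iou` (over defined classes).
#' @export
evaluate_labels <- function(gt_labels, pred_labels) {
  cc <- confusion_counts(gt_labels, pred_labels)
  metrics <- metrics_from_confusion(cc)
  structure(
    list(
      confusion = cc$confusion, n_ignored = cc$n_ignored, metrics = metrics,
      mean_iou = mean(metrics$iou, na.rm = TRUE)
    ),
    class = "segmentation_report"
  )
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat("Leaf/stem segmentation report (", sum(x$confusion), " points, ",
      x$n_ignored, " ignored)\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Evaluate predictions over a benchmark manifest
#'
#' Applies the train-on-one / test-on-the-rest protocol bookkeeping: given a
#' manifest (see [make_benchmark_suite()]) and per-model predictions for the
#' test models, computes per-model per-class metrics and their mean and
#' standard deviation across test models. Undefined (`NA`) metrics are
#' excluded from averages with a warning.
#'
#' @param manifest Manifest tibble with `model_id`, `cloud`, `volume`, `role`.
#' @param predictions Named list (by `model_id`) of predicted leaf/stem code
#'   vectors for clouds, or label [voxel_grid()]s for volumes.
#' @param on `"cloud"` (ground truth from the PLY labels) or `"volume"`
#'   (from the label volume, evaluated on its nonzero voxels of the
#'   prediction grid mask).
#' @return A list with `per_model` (tibble) and `summary` (per-class mean
#'   and sd of each metric across test models).
#' @export
evaluate_manifest <- function(manifest, predictions, on = c("cloud", "volume")) {
  on <- match.arg(on)
  test <- manifest[manifest$role == "test", ]
  missing_pred <- setdiff(test$model_id, names(predictions))
  if (length(missing_pred) > 0) {
    stop_validation("missing predictions for model(s): ",
                    paste(missing_pred, collapse = ", "))
  }
  per_model <- dplyr::bind_rows(lapply(seq_len(nrow(test)), function(i) {
    id <- test$model_id[i]
    if (on == "cloud") {
      path <- test$cloud[i]
      if (!file.exists(path)) stop("missing manifest entry file: ", path)
      gt <- read_point_cloud(path)$label
      pred <- predictions[[id]]
    } else {
      path <- test$volume[i]
      if (!file.exists(path)) stop("missing manifest entry file: ", path)
      gt_grid <- read_volume(path)
      pred_grid <- predictions[[id]]
      stopifnot(is_voxel_grid(pred_grid))
      idx <- which(pred_grid$values != 0)
      gt <- as.integer(gt_grid$values[idx])
      pred <- as.integer(pred_grid$values[idx])
    }
    rep <- evaluate_labels(gt, pred)
    dplyr::mutate(rep$metrics, model_id = id, .before = 1)
  }))
  if (anyNA(per_model[, c("precision", "recall", "iou")])) {
    warning("undefined metrics (absent class) excluded from averages")
  }
  summary <- per_model |>
    tidyr::pivot_longer(c("precision", "recall", "iou"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$class, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n_models = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  list(per_model = per_model, summary = summary)
}

#' Average per-fold summaries into a cross-fold report
#'
#' When several folds are run (a different model reserved for training in
#' each), the protocol reports the mean and standard deviation across the
#' fold means.
#'
#' @param fold_summaries List of `summary` tibbles from [evaluate_manifest()].
#' @return A tibble with per-class, per-metric `mean` and `sd` across folds.
#' @export
summarise_folds <- function(fold_summaries) {
  dplyr::bind_rows(fold_summaries, .id = "fold") |>
    dplyr::group_by(.data$class, .data$metric) |>
    dplyr::summarise(
      sd = stats::sd(.data$mean, na.rm = TRUE),
      mean = mean(.data$mean, na.rm = TRUE),
      n_folds = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("class", "metric", "mean", "sd", "n_folds")
}
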