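#' Train the multi-scale eigen-feature linear SVM segmenter
#'
#' Fits a two-class linear SVM on the concatenated multi-scale eigenvalue
#' ratio features of a labeled training cloud (default radii 2-7 mm, 24
#' features). Only stem and leaf points are used for training; both classes
#' must be present. Features are standardized (zero mean, unit variance from
#' the training data) by default because the raw ratios have heterogeneous
#' ranges and linear SVMs are scale-sensitive; disable with
#' `standardize = FALSE` for ablation. Training is deterministic given the
#' data and `seed`.
#'
#' @param cloud A labeled point-cloud tibble (organ codes in `label`), or a
#'   feature tibble/matrix from [multiscale_features()] if `labels` is given.
#' @param labels Optional organ codes aligned with `cloud` rows when `cloud`
#'   is already a feature table.
#' @param radii Neighbourhood radii in mm.
#' @param standardize Standardize features from training statistics.
#' @param cost SVM regularization constant C.
#' @param class_weights Use inverse-frequency class weights (default off).
#' @param subsample Optional per-class cap on training points (balanced
#'   random subsample); `NULL` uses all points.
#' @param seed Seed controlling the optional subsample.
#' @return An object of class `lfpc_s`.
#' @export
fit_lfpc_s <- function(cloud, labels = NULL, radii = c(2, 3, 4, 5, 6, 7),
                       standardize = TRUE, cost = 1, class_weights = FALSE,
                       subsample = NULL, seed = 1) {
  if (is.null(labels)) {
    cloud <- validate_point_cloud(cloud)
    if (!"label" %in% names(cloud)) {
      stop_validation("training cloud must carry a label column")
    }
    labels <- cloud$label
    feats <- as.matrix(multiscale_features(cloud, radii))
  } else {
    feats <- as.matrix(cloud)
  }
  if (is.null(colnames(feats))) {
    colnames(feats) <- paste0("V", seq_len(ncol(feats)))
  }
  keep <- labels %in% organ_code(c("stem", "leaf"))
  feats <- feats[keep, , drop = FALSE]
  y <- factor(organ_name(labels[keep]), levels = c("leaf", "stem"))
  if (nlevels(droplevels(y)) < 2) {
    stop_validation("training data must contain both leaf and stem points")
  }
  if (anyNA(feats) || !all(is.finite(feats))) {
    stop_validation("training features contain NaN or non-finite values")
  }
  if (!is.null(subsample)) {
    idx <- with_seed(derive_seed(seed, "svm_subsample"), {
      unlist(lapply(levels(y), function(lv) {
        pool <- which(y == lv)
        if (length(pool) > subsample) sort(sample(pool, subsample)) else pool
      }))
    })
    feats <- feats[idx, , drop = FALSE]
    y <- y[idx]
  }
  if (standardize) {
    mu <- colMeans(feats)
    sg <- apply(feats, 2, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    feats <- scale(feats, center = mu, scale = sg)
  } else {
    mu <- rep(0, ncol(feats))
    sg <- rep(1, ncol(feats))
  }
  cw <- if (isTRUE(class_weights)) {
    tab <- table(y)
    stats::setNames(as.numeric(sum(tab) / (length(tab) * tab)), names(tab))
  } else NULL
  fit <- e1071::svm(
    x = feats, y = y, kernel = "linear", cost = cost, scale = FALSE,
    class.weights = cw
  )
  structure(
    list(
      svm = fit, radii = radii, standardize = standardize,
      center = mu, scale_sd = sg, cost = cost,
      feature_names = colnames(feats), n_train = length(y),
      class_counts = table(y), seed = seed
    ),
    class = "lfpc_s"
  )
}

#' @export
print.lfpc_s <- function(x, ...) {
  cat(sprintf(
    "<lfpc_s linear SVM: %d training points (%s), radii %s mm, cost %g>\n",
    x$n_train,
    paste(names(x$class_counts), as.integer(x$class_counts),
          sep = "=", collapse = ", "),
    paste(x$radii, collapse = ","), x$cost
  ))
  invisible(x)
}

lfpc_s_features <- function(object, newdata) {
  if (is.data.frame(newdata) && all(c("x", "y", "z") %in% names(newdata))) {
    feats <- as.matrix(multiscale_features(newdata, object$radii))
  } else {
    feats <- as.matrix(newdata)
  }
  if (ncol(feats) != length(object$feature_names)) {
    stop_validation(
      "feature column count (", ncol(feats), ") does not match the model (",
      length(object$feature_names), ")"
    )
  }
  feats
}

#' Predict leaf/stem labels with a fitted SVM segmenter
#'
#' Predictions are per-point and deterministic; no spatial smoothing is
#' applied, so isolated label flips along stems and leaves are possible and
#' left as-is.
#'
#' @param object A fitted [fit_lfpc_s()] model.
#' @param newdata A point-cloud tibble or a feature table matching the model.
#' @param ... Unused.
#' @return Integer organ codes (leaf = 2, stem = 1), one per row.
#' @export
predict.lfpc_s <- function(object, newdata, ...) {
  feats <- lfpc_s_features(object, newdata)
  if (nrow(feats) == 0) return(integer(0))
  feats <- scale(feats, center = object$center, scale = object$scale_sd)
  cls <- predict(object$svm, feats)
  organ_code(as.character(cls))
}

#' @rdname predict.lfpc_s
#' @param model A fitted `lfpc_s` model.
#' @param cloud A point-cloud tibble.
#' @return `segment_lfpc_s()` returns the cloud with a `pred` column.
#' @export
segment_lfpc_s <- function(model, cloud) {
  cloud <- validate_point_cloud(cloud)
  cloud$pred <- predict(model, cloud)
  cloud
}

#' @export
tidy.lfpc_s <- function(x, ...) {
  w <- drop(crossprod(x$svm$coefs, x$svm$SV))
  tibble::tibble(
    term = x$feature_names %||% paste0("V", seq_along(w)),
    estimate = as.numeric(w)
  )
}

#' @export
glance.lfpc_s <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_support = nrow(x$svm$SV),
    cost = x$cost,
    standardize = x$standardize,
    n_features = length(x$feature_names)
  )
}

#' Save / load fitted segmenter models
#'
#' Serialized to an RDS container; reloading reproduces identical
#' predictions.
#'
#' @param model A fitted `lfpc_s` or `lfvd` model.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
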