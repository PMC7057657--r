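#' Default filter-bank scales (mm)
#'
#' The Gaussian smoothing scales, in mm, at which all volumetric channels
#' are computed.
#' @return Numeric vector of scales.
#' @export
lfvd_scales <- function() c(0.7, 1.0, 1.6, 3.5, 5.0, 10.0)

# Sampled Gaussian (derivative) kernel. `order` 0, 1 or 2; `spacing` converts
# voxel derivatives to physical per-mm units. Kernels are normalized by the
# order-0 sample sum; order-2 kernels get an exact zero-sum correction so
# constants map to exactly zero. Signs are chosen for the correlation
# convention out(x) = sum_t k(t) f(x + t), so that the order-1 kernel yields
# +d/dx of the smoothed field.
gaussian_kernel <- function(sigma_vox, order = 0, spacing = 1, truncate = 4) {
  # second-derivative tails decay slower; half a sigma more support keeps the
  # truncation bias well below the smoothing channels'
  if (order == 2) truncate <- truncate + 0.5
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  x <- (-r):r
  w <- exp(-x^2 / (2 * sigma_vox^2))
  z <- sum(w)
  k <- switch(as.character(order),
    "0" = w / z,
    "1" = (x / sigma_vox^2) * w / z / spacing,
    "2" = {
      k2 <- ((x^2 - sigma_vox^2) / sigma_vox^4) * w / z
      (k2 - mean(k2)) / spacing^2
    },
    stop("order must be 0, 1 or 2")
  )
  k
}

conv3_sep <- function(vol, kx, ky, kz) {
  d <- dim(vol)
  out <- cpp_conv3_axis(as.double(vol), d, kx, 1L)
  out <- cpp_conv3_axis(out, d, ky, 2L)
  cpp_conv3_axis(out, d, kz, 3L)
}

# Gaussian-derivative filtering of a 3D array at physical scale s (mm):
# derivative orders (ox, oy, oz) per axis, per-axis sigma = s / spacing.
gaussian_derivative <- function(vol, spacing, s, orders = c(0, 0, 0),
                                truncate = 4) {
  sig <- s / spacing
  conv3_sep(
    vol,
    gaussian_kernel(sig[1], orders[1], spacing[1], truncate),
    gaussian_kernel(sig[2], orders[2], spacing[2], truncate),
    gaussian_kernel(sig[3], orders[3], spacing[3], truncate)
  )
}

# Box-average downsampling by integer factor f per axis (edge-replicated to
# a multiple of f). Preserves the mean, so Gaussian responses on the coarse
# grid approximate fine-grid responses at sigma/f.
downsample_box <- function(vol, f) {
  if (f == 1) return(vol)
  for (ax in 1:3) {
    d <- dim(vol)
    n <- d[1]
    nc <- ceiling(n / f)
    if (nc * f != n) {
      idx <- pmin(seq_len(nc * f), n)
      vol <- array(vol[idx, , ], c(nc * f, d[2], d[3]))
    }
    m <- matrix(as.vector(vol), nrow = f)
    vol <- array(colMeans(m), c(nc, d[2], d[3]))
    vol <- aperm(vol, c(2, 3, 1))
  }
  vol
}

# Trilinear interpolation of a 3D grid at continuous 1-based index points.
trilinear_sample <- function(grid, pts) {
  d <- dim(grid)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- cl(floor(pts[, 1]), d[1] - 1); fx <- cl(pts[, 1], d[1]) - x0
  y0 <- cl(floor(pts[, 2]), d[2] - 1); fy <- cl(pts[, 2], d[2]) - y0
  z0 <- cl(floor(pts[, 3]), d[3] - 1); fz <- cl(pts[, 3], d[3]) - z0
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1); fz <- pmin(pmax(fz, 0), 1)
  g <- function(i, j, k) grid[cbind(x0 + i, y0 + j, z0 + k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * g(0, 0, 0) + fx * g(1, 0, 0)) +
                fy * ((1 - fx) * g(0, 1, 0) + fx * g(1, 1, 0))) +
    fz * ((1 - fy) * ((1 - fx) * g(0, 0, 1) + fx * g(1, 0, 1)) +
            fy * ((1 - fx) * g(0, 1, 1) + fx * g(1, 1, 1)))
}

# All 22 channels of one scale. `sampler(grid)` extracts the per-voxel
# feature values at the target positions from a full channel grid.
scale_channels <- function(vol, spacing, s, sampler, truncate = 4) {
  d <- dim(vol)
  sig <- s / spacing
  k0 <- lapply(1:3, function(a) gaussian_kernel(sig[a], 0, spacing[a], truncate))
  k1 <- lapply(1:3, function(a) gaussian_kernel(sig[a], 1, spacing[a], truncate))
  k2 <- lapply(1:3, function(a) gaussian_kernel(sig[a], 2, spacing[a], truncate))
  cx <- function(v, k) cpp_conv3_axis(v, d, k, 1L)
  cy <- function(v, k) cpp_conv3_axis(v, d, k, 2L)
  cz <- function(v, k) cpp_conv3_axis(v, d, k, 3L)

  v <- as.double(vol)
  a0 <- cx(v, k0[[1]])
  a1 <- cx(v, k1[[1]])
  a2 <- cx(v, k2[[1]])
  b00 <- cy(a0, k0[[2]]); b01 <- cy(a0, k1[[2]]); b02 <- cy(a0, k2[[2]])
  b10 <- cy(a1, k0[[2]]); b11 <- cy(a1, k1[[2]])
  b20 <- cy(a2, k0[[2]])
  rm(a0, a1, a2)

  smoothed <- cz(b00, k0[[3]])
  gz <- cz(b00, k1[[3]])
  hzz_at <- sampler(cz(b00, k2[[3]]))
  gy <- cz(b01, k0[[3]])
  hyz_at <- sampler(cz(b01, k1[[3]]))
  hyy_at <- sampler(cz(b02, k0[[3]]))
  gx <- cz(b10, k0[[3]])
  hxz_at <- sampler(cz(b10, k1[[3]]))
  hxy_at <- sampler(cz(b11, k0[[3]]))
  hxx_at <- sampler(cz(b20, k0[[3]]))
  rm(b00, b01, b02, b10, b11, b20)

  gx_at <- sampler(gx); gy_at <- sampler(gy); gz_at <- sampler(gz)
  grad_at <- sqrt(gx_at^2 + gy_at^2 + gz_at^2)
  log_at <- hxx_at + hyy_at + hzz_at
  dog_at <- sampler(smoothed) -
    sampler(gaussian_derivative(vol, spacing, 1.6 * s, c(0, 0, 0), truncate))

  # structure tensor: outer scale = inner scale = s
  st_at <- matrix(0, length(grad_at), 6)
  prods <- list(
    c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3)
  )
  gl <- list(gx, gy, gz)
  for (p in seq_along(prods)) {
    pr <- gl[[prods[[p]][1]]] * gl[[prods[[p]][2]]]
    st_at[, p] <- sampler(conv3_sep(pr, k0[[1]], k0[[2]], k0[[3]]))
  }
  rm(gx, gy, gz, gl)

  hess_at <- cbind(hxx_at, hyy_at, hzz_at, hxy_at, hxz_at, hyz_at)
  st_ev <- cpp_sym3_eigs(st_at)
  hess_ev <- cpp_sym3_eigs(hess_at)

  out <- cbind(
    sampler(smoothed), grad_at, log_at, dog_at,
    st_ev, hess_ev, st_at, hess_at
  )
  colnames(out) <- paste0(
    c(
      "gauss", "gradmag", "log", "dog",
      paste0("st_ev", 1:3), paste0("hess_ev", 1:3),
      paste0("st_", c("xx", "yy", "zz", "xy", "xz", "yz")),
      paste0("hess_", c("xx", "yy", "zz", "xy", "xz", "yz"))
    ),
    sprintf("_s%g", s)
  )
  out
}

#' Multi-scale volumetric filter-bank features
#'
#' Computes, for each requested voxel of a binary surface volume, 22 channels
#' per scale by separable Gaussian-derivative filtering with replicate
#' boundary handling: the Gaussian-smoothed value, the gradient magnitude,
#' the Laplacian of Gaussian, the difference of Gaussians (sigmas `s` and
#' `1.6 s`), the eigenvalues (ascending) of the structure tensor (inner and
#' outer scale `s`) and of the Hessian, and the raw structure-tensor and
#' Hessian entries. Scales are physical (mm); per-axis sigma is
#' `scale / spacing`, so anisotropic volumes are handled. Default scales
#' give `6 * 22 = 132` features.
#'
#' Large scales (per-axis sigma above `pyramid_sigma` voxels) are evaluated
#' on a box-downsampled pyramid level chosen so the effective sigma stays
#' near 2-3 voxels, and sampled back at the requested voxels by trilinear
#' interpolation; small scales are filtered directly at full resolution.
#' This keeps the cost of the 10 mm scale comparable to the sub-mm ones at
#' negligible accuracy cost for fields that smooth.
#'
#' @param grid A `binary_mask` [voxel_grid()] (typically the shoot surface).
#' @param scales Gaussian scales in mm.
#' @param at Linear voxel indices to sample; default all nonzero voxels.
#' @param truncate Kernel support radius in sigmas.
#' @param pyramid_sigma Sigma (voxels) above which the pyramid path is used;
#'   `Inf` forces direct filtering at every scale.
#' @return A tibble with a `.voxel` index column followed by the feature
#'   columns, scales in the `"scales"` attribute.
#' @export
feature_bank <- function(grid, scales = lfvd_scales(), at = NULL,
                         truncate = 4, pyramid_sigma = 3) {
  stopifnot(is_voxel_grid(grid))
  if (grid$kind != "binary_mask" || !all(grid$values %in% c(0, 1))) {
    stop_validation("feature_bank() needs a binary_mask grid of 0/1 values")
  }
  if (is.null(at)) at <- which(grid$values != 0)
  at <- as.integer(at)
  vol <- grid$values
  storage.mode(vol) <- "double"
  d <- dim(vol)
  at_ijk <- cbind(
    (at - 1L) %% d[1],
    ((at - 1L) %/% d[1]) %% d[2],
    (at - 1L) %/% (d[1] * d[2])
  ) + 1L
  levels <- list() # cached pyramid levels by factor
  blocks <- lapply(scales, function(s) {
    sig_min <- min(s / grid$spacing)
    # pyramid factor keeps the coarse-level sigma near 3 voxels
    f <- max(2L, as.integer(floor(sig_min / 3)))
    if (sig_min <= pyramid_sigma) {
      sampler <- function(g) g[at]
      scale_channels(vol, grid$spacing, s, sampler, truncate)
    } else {
      key <- as.character(f)
      if (is.null(levels[[key]])) levels[[key]] <<- downsample_box(vol, f)
      cvol <- levels[[key]]
      # continuous coarse index of each fine voxel centre
      pts <- sweep(at_ijk - 0.5, 2, rep(1 / f, 3), `*`) + 0.5
      sampler <- function(g) trilinear_sample(g, pts)
      scale_channels(cvol, grid$spacing * f, s, sampler, truncate)
    }
  })
  out <- tibble::as_tibble(do.call(cbind, blocks))
  out <- dplyr::bind_cols(tibble::tibble(.voxel = at), out)
  attr(out, "scales") <- scales
  out
}

#' Train the volumetric random-forest voxel classifier
#'
#' Fits a random forest on filter-bank features of leaf/stem voxels.
#' Voxels whose ground truth is not leaf or stem (flower, pot, tag,
#' background) are excluded from training. Reproducible for a fixed seed;
#' prediction is deterministic.
#'
#' @param bank A feature table from [feature_bank()].
#' @param labels Organ codes aligned with the rows of `bank`.
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `sqrt(n_features)`.
#' @param seed Forest seed.
#' @return An object of class `lfvd`.
#' @export
fit_lfvd <- function(bank, labels, n_trees = 100, mtry = NULL, seed = 1) {
  feats <- as.data.frame(bank[setdiff(names(bank), ".voxel")])
  stopifnot(nrow(feats) == length(labels))
  keep <- labels %in% organ_code(c("stem", "leaf"))
  feats <- feats[keep, , drop = FALSE]
  y <- factor(organ_name(labels[keep]), levels = c("leaf", "stem"))
  if (nlevels(droplevels(y)) < 2) {
    stop_validation("training data must contain both leaf and stem voxels")
  }
  if (!all(vapply(feats, function(c) all(is.finite(c)), logical(1)))) {
    stop_validation("training features contain non-finite values")
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(feats))))
  fit <- ranger::ranger(
    x = feats, y = y, num.trees = n_trees, mtry = mtry,
    seed = seed, num.threads = 1, importance = "impurity"
  )
  structure(
    list(
      rf = fit, feature_names = names(feats), n_trees = n_trees,
      mtry = mtry, seed = seed, n_train = length(y),
      oob_error = fit$prediction.error,
      scales = attr(bank, "scales")
    ),
    class = "lfvd"
  )
}

#' @export
print.lfvd <- function(x, ...) {
  cat(sprintf(
    "<lfvd random forest: %d trees, %d training voxels, OOB accuracy %.3f>\n",
    x$n_trees, x$n_train, 1 - x$oob_error
  ))
  invisible(x)
}

#' Predict leaf/stem codes for filter-bank feature rows
#'
#' @param object A fitted [fit_lfvd()] model.
#' @param bank A feature table from [feature_bank()] with the same schema.
#' @param ... Unused.
#' @return Integer organ codes (leaf = 2, stem = 1), one per row of `bank`.
#' @export
predict.lfvd <- function(object, bank, ...) {
  feats <- as.data.frame(bank[setdiff(names(bank), ".voxel")])
  if (!identical(names(feats), object$feature_names)) {
    stop_validation("feature schema does not match the fitted model")
  }
  if (nrow(feats) == 0) return(integer(0))
  # the prediction seed pins ranger's tie-breaking of split votes, so
  # predictions are reproducible independent of the caller's RNG state
  cls <- predict(object$rf, data = feats, num.threads = 1,
                 seed = object$seed)$predictions
  organ_code(as.character(cls))
}

#' Segment a binary surface volume with a fitted forest
#'
#' Classifies the masked voxels of a binary surface volume and returns a
#' label grid: predicted organ codes on the mask, 0 elsewhere. Background
#' is untouched.
#'
#' @param model A fitted [fit_lfvd()] model.
#' @param grid A `binary_mask` [voxel_grid()].
#' @param mask Linear indices of voxels to classify; default all nonzero
#'   voxels of `grid`.
#' @param truncate Kernel support radius in sigmas.
#' @return A label [voxel_grid()].
#' @export
segment_lfvd <- function(model, grid, mask = NULL, truncate = 4) {
  stopifnot(is_voxel_grid(grid))
  if (is.null(mask)) mask <- which(grid$values != 0)
  out <- array(0L, dim(grid))
  if (length(mask) > 0) {
    bank <- feature_bank(grid, scales = model$scales, at = mask,
                         truncate = truncate)
    out[mask] <- predict(model, bank)
  }
  voxel_grid(out, spacing = grid$spacing, kind = "label")
}

#' Train an LFVD model straight from a labeled volume
#'
#' Convenience wrapper: masks the shoot, keeps its surface voxels, computes
#' the filter bank there and fits the forest on the leaf/stem voxels.
#'
#' @param label_grid A label [voxel_grid()].
#' @param scales Gaussian scales in mm.
#' @param ... Passed to [fit_lfvd()].
#' @return A fitted `lfvd` model.
#' @export
train_lfvd <- function(label_grid, scales = lfvd_scales(), ...) {
  surf <- extract_surface(shoot_mask(label_grid))
  at <- which(surf$values != 0)
  bank <- feature_bank(surf, scales = scales, at = at)
  fit_lfvd(bank, labels = as.integer(label_grid$values[at]), ...)
}

#' @export
tidy.lfvd <- function(x, ...) {
  imp <- x$rf$variable.importance
  tibble::tibble(term = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
glance.lfvd <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train, n_trees = x$n_trees, mtry = x$mtry,
    oob_accuracy = 1 - x$oob_error, n_features = length(x$feature_names)
  )
}
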