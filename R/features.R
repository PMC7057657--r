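#' Fixed-radius neighbourhood of a point
#'
#' Returns the indices of all points strictly closer than `d` mm to the query
#' point, the query point itself included (its distance 0 satisfies the strict
#' inequality). This is the neighbourhood definition every covariance feature
#' in the package is built on.
#'
#' @param cloud A point-cloud tibble.
#' @param index 1-based index of the query point.
#' @param d Neighbourhood radius in mm (strict `<`).
#' @return Sorted integer vector of neighbour indices.
#' @export
#' @examples
#' cl <- point_cloud(cbind(0:3, 0, 0))
#' radius_neighbors(cl, 1, 1.5)
radius_neighbors <- function(cloud, index, d) {
  cloud <- validate_point_cloud(cloud)
  stopifnot(d > 0, index >= 1, index <= nrow(cloud))
  xyz <- cloud_coords(cloud)
  q <- xyz[index, ]
  d2 <- (xyz[, 1] - q[1])^2 + (xyz[, 2] - q[2])^2 + (xyz[, 3] - q[3])^2
  which(d2 < d^2)
}

#' Eigenvalues of a neighbourhood covariance matrix
#'
#' Computes the unbiased (n-1 denominator) sample covariance of a set of
#' neighbour coordinates and returns its eigenvalues sorted ascending,
#' `lambda1 <= lambda2 <= lambda3` (units mm^2). Tiny negative eigenvalues
#' from roundoff are clamped to zero.
#'
#' @param neighbor_coords An n x 3 matrix of coordinates, n >= 2.
#' @return Numeric length-3 vector of ascending eigenvalues.
#' @export
#' @examples
#' covariance_eigenvalues(cbind(0:3, 0, 0)) # collinear: (0, 0, 5/3)
covariance_eigenvalues <- function(neighbor_coords) {
  neighbor_coords <- as.matrix(neighbor_coords)
  stopifnot(ncol(neighbor_coords) == 3)
  if (nrow(neighbor_coords) < 2) {
    stop_validation("degenerate neighbourhood: need at least 2 points for a covariance")
  }
  ev <- rev(eigen(stats::cov(neighbor_coords), symmetric = TRUE,
                  only.values = TRUE)$values)
  ev[ev < 0 & ev > -1e-9] <- 0
  ev
}

#' Curvature (surface variation) from covariance eigenvalues
#'
#' `lambda1 / (lambda1 + lambda2 + lambda3)`, in `[0, 1/3]`: 0 for flat
#' sheets, 1/3 for isotropic neighbourhoods. A zero eigenvalue sum (all
#' neighbours coincident, or a degenerate neighbourhood) returns 0.
#'
#' @param lambda Ascending eigenvalues: a length-3 vector or an N x 3 matrix.
#' @return Curvature value(s) in `[0, 1/3]`.
#' @export
curvature <- function(lambda) {
  if (is.matrix(lambda)) {
    s <- rowSums(lambda)
    ifelse(s > 0, lambda[, 1] / s, 0)
  } else {
    s <- sum(lambda)
    if (s > 0) lambda[1] / s else 0
  }
}

#' Flatness: log of floored curvature
#'
#' `R(x) = ln(max(C(x), c_eps))`, the unary evidence used by the graph-cut
#' segmenter. With the default floor `c_eps = 0.015` the value lies in
#' `[ln(0.015), ln(1/3)]`, low for flat (leaf-like) neighbourhoods and high
#' for isotropic (stem-like) ones. Natural log is used; the choice of base
#' only rescales the data term, which the weight `w_D` absorbs.
#'
#' @param curvature_value Curvature value(s) in `[0, 1/3]`.
#' @param c_eps Curvature floor (default 0.015).
#' @return Flatness value(s).
#' @export
#' @examples
#' flatness(c(0, 1/3)) # the range end points R_L, R_S
flatness <- function(curvature_value, c_eps = 0.015) {
  stopifnot(all(curvature_value >= 0), all(curvature_value <= 1 / 3 + 1e-12))
  log(pmax(curvature_value, c_eps))
}

# Range [R_L, R_S] of the flatness feature for a given curvature floor.
flatness_limits <- function(c_eps = 0.015) {
  c(R_L = log(c_eps), R_S = log(1 / 3))
}

#' Eigenvalue ratio features
#'
#' The four scale-dependent local shape features computed from ascending
#' covariance eigenvalues:
#' `F1 = lambda1 / sqrt(lambda2 * lambda3)`, `F2 = lambda2 / lambda3`,
#' `F3 = lambda1 / sqrt(lambda1 * lambda2 * lambda3)`,
#' `F4 = lambda1 / lambda2`.
#' Denominators are floored at `eps`; a zero numerator short-circuits to
#' exactly 0, which keeps F3 continuous as `lambda1 -> 0`.
#'
#' @param lambda Ascending eigenvalues: length-3 vector or N x 3 matrix.
#' @param eps Denominator floor.
#' @return Length-4 vector `c(F1, F2, F3, F4)` or an N x 4 matrix.
#' @export
#' @examples
#' eigen_features(c(1, 4, 9)) # (1/6, 4/9, 1/6, 1/4)
eigen_features <- function(lambda, eps = 1e-12) {
  vec <- !is.matrix(lambda)
  if (vec) lambda <- matrix(lambda, nrow = 1)
  l1 <- lambda[, 1]; l2 <- lambda[, 2]; l3 <- lambda[, 3]
  f <- cbind(
    F1 = ifelse(l1 == 0, 0, l1 / pmax(sqrt(l2 * l3), eps)),
    F2 = ifelse(l2 == 0, 0, l2 / pmax(l3, eps)),
    F3 = ifelse(l1 == 0, 0, l1 / pmax(sqrt(l1 * l2 * l3), eps)),
    F4 = ifelse(l1 == 0, 0, l1 / pmax(l2, eps))
  )
  if (vec) f[1, ] else f
}

#' Per-point curvature and flatness descriptors
#'
#' Computes neighbourhood covariance eigenvalues for every point (exact
#' strict-radius search through a uniform cell index) and derives the
#' curvature and flatness descriptors that drive the unsupervised graph-cut
#' segmenter. Points with fewer than 2 neighbours get curvature 0.
#'
#' @param cloud A point-cloud tibble.
#' @param d Neighbourhood radius in mm (default 3).
#' @param c_eps Curvature floor for the flatness feature.
#' @return The cloud with added columns `curvature`, `flatness`,
#'   `n_neighbors`.
#' @export
point_descriptors <- function(cloud, d = 3, c_eps = 0.015) {
  cloud <- validate_point_cloud(cloud)
  stopifnot(d > 0)
  res <- cpp_multiscale_eigen(cloud_coords(cloud), d)[[1]]
  cv <- curvature(res$lambda)
  cloud$curvature <- cv
  cloud$flatness <- flatness(cv, c_eps)
  cloud$n_neighbors <- res$n_neighbors
  cloud
}

#' Multi-scale eigenvalue features for a point cloud
#'
#' For each point and each neighbourhood radius, computes the four
#' eigenvalue ratio features (see [eigen_features()]) and concatenates them
#' over the radii into one feature vector per point. Default radii are
#' 2, 3, 4, 5, 6, 7 mm, giving 24 features. Neighbourhoods with fewer than
#' `min_neighbors` points (default 4, the minimum to span 3D) yield an
#' all-zero feature block at that radius. Features are invariant to rigid
#' motion of the cloud.
#'
#' @param cloud A point-cloud tibble.
#' @param radii Neighbourhood radii in mm, ascending.
#' @param min_neighbors Minimum neighbourhood size for a non-degenerate block.
#' @return A tibble with `4 * length(radii)` columns named `F1_r2 ... F4_r7`,
#'   one row per point, with the radii stored in the `"radii"` attribute.
#' @export
multiscale_features <- function(cloud, radii = c(2, 3, 4, 5, 6, 7),
                                min_neighbors = 4) {
  cloud <- validate_point_cloud(cloud)
  stopifnot(length(radii) >= 1, all(radii > 0), !is.unsorted(radii))
  res <- cpp_multiscale_eigen(cloud_coords(cloud), as.numeric(radii))
  blocks <- lapply(seq_along(radii), function(ri) {
    f <- eigen_features(res[[ri]]$lambda)
    f[res[[ri]]$n_neighbors < min_neighbors, ] <- 0
    colnames(f) <- sprintf("F%d_r%g", 1:4, radii[ri])
    f
  })
  out <- tibble::as_tibble(do.call(cbind, blocks))
  attr(out, "radii") <- radii
  out
}
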