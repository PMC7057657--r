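#' Binary mask of the plant shoot
#'
#' The shoot is the union of the stem, leaf and flower classes; pot, tag and
#' background voxels are masked out.
#'
#' @param grid A label [voxel_grid()].
#' @return A `binary_mask` voxel grid of the same shape and spacing.
#' @export
shoot_mask <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  if (grid$kind != "label") {
    stop_validation("shoot_mask() needs a label grid, got kind '", grid$kind, "'")
  }
  m <- array(as.integer(grid$values %in% shoot_codes()), dim(grid))
  voxel_grid(m, spacing = grid$spacing, kind = "binary_mask")
}

neighbor_offsets <- function(connectivity = 26) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  off
}

#' Extract surface voxels of a binary volume
#'
#' A foreground voxel is kept iff at least one of its neighbours (26- or
#' 6-connectivity; out-of-bounds positions count as background) is background.
#' Interior voxels are removed. Thin plant organs (leaves, petioles) are
#' almost entirely surface, so this typically retains most shoot voxels.
#' The operation is idempotent.
#'
#' @param grid A `binary_mask` [voxel_grid()].
#' @param connectivity 26 (default) or 6.
#' @return A `binary_mask` voxel grid of the surface voxels.
#' @export
extract_surface <- function(grid, connectivity = c(26, 6)) {
  stopifnot(is_voxel_grid(grid))
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  if (grid$kind != "binary_mask") {
    stop_validation("extract_surface() needs a binary_mask grid, got kind '",
                    grid$kind, "'")
  }
  d <- dim(grid)
  fg <- grid$values != 0
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  any_bg <- array(FALSE, d)
  ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
  off <- neighbor_offsets(as.integer(connectivity))
  for (k in seq_len(nrow(off))) {
    any_bg <- any_bg | !pad[ix + off[k, 1], iy + off[k, 2], iz + off[k, 3]]
  }
  voxel_grid(array(as.integer(fg & any_bg), d),
             spacing = grid$spacing, kind = "binary_mask")
}

#' Convert nonzero voxels to a labeled point cloud
#'
#' Emits one point per nonzero voxel at the voxel centre in physical
#' millimetres, i.e. `(index + 0.5) * spacing` per axis with 0-based indices.
#' For label grids the organ code is carried over to a `label` column.
#'
#' @param grid A label or `binary_mask` [voxel_grid()].
#' @return A point-cloud tibble (see [point_cloud()]).
#' @export
#' @examples
#' g <- voxel_grid(array(c(1L, rep(0L, 7)), c(2, 2, 2)), 0.5, kind = "label")
#' voxels_to_points(g)
voxels_to_points <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  if (grid$kind == "intensity") {
    stop_validation("voxels_to_points() needs a label or binary_mask grid")
  }
  idx <- which(grid$values != 0, arr.ind = TRUE)
  coords <- sweep(idx - 0.5, 2, grid$spacing, `*`)
  label <- if (grid$kind == "label") as.integer(grid$values[idx]) else NULL
  point_cloud(coords, label = label)
}
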