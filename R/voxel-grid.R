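#' Construct a voxel grid
#'
#' A `voxel_grid` wraps a dense 3D array of values with the physical spacing
#' of its axes (mm per voxel) and the kind of values it holds: `"intensity"`
#' (arbitrary reals), `"label"` (organ codes 0-5, see [organ_codes()]), or
#' `"binary_mask"` (0/1). Axis order is x, y, z with z the slice index;
#' indices are interpreted 0-based when converting to physical coordinates.
#'
#' @param values A 3D numeric array.
#' @param spacing Numeric length-3, mm per voxel along x, y, z (strictly
#'   positive). A scalar is recycled.
#' @param kind One of `"intensity"`, `"label"`, `"binary_mask"`.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(array(0L, c(4, 4, 4)), spacing = 0.5, kind = "label")
#' dim(g)
voxel_grid <- function(values, spacing = c(0.5, 0.5, 0.5),
                       kind = c("intensity", "label", "binary_mask")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3) {
    stop_validation("voxel grid values must be a 3D array")
  }
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop_validation("spacing must be 3 strictly positive reals (mm/voxel)")
  }
  if (kind == "label") {
    validate_organ_labels(as.vector(values))
  } else if (kind == "binary_mask") {
    if (!all(values %in% c(0, 1))) {
      stop_validation("binary_mask grid may contain only 0 and 1")
    }
  }
  structure(
    list(values = values, spacing = spacing, kind = kind),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<voxel_grid [%d x %d x %d] %s, spacing %s mm, %d nonzero>\n",
    d[1], d[2], d[3], x$kind,
    paste(format(x$spacing, trim = TRUE), collapse = " x "),
    sum(x$values != 0)
  ))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Read / write voxel volumes
#'
#' Volumes are stored either as multi-page TIFF stacks (one page per z slice,
#' 8-bit for labels and masks, 32-bit float for intensities) with a JSON
#' sidecar `<name>.json` holding `{"spacing_mm":[sx,sy,sz],"kind":...}`, or
#' as a native serialized container (`.rds`) for lossless scratch storage.
#' The format is chosen by file extension.
#'
#' @param path File path ending in `.tif`/`.tiff` or `.rds`.
#' @return `read_volume()` returns a [voxel_grid()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    g <- readRDS(path)
    if (!is_voxel_grid(g)) stop_validation("file does not contain a voxel_grid: ", path)
    return(g)
  }
  if (!ext %in% c("tif", "tiff")) {
    stop_validation("unsupported volume format: .", ext)
  }
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("cannot read volume: missing JSON sidecar: ", side)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  kind <- meta$kind %||% "intensity"
  scale <- meta$scale %||% 1
  discrete <- kind %in% c("label", "binary_mask")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = discrete)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_validation("TIFF stack has pages of differing size: ", path)
  }
  # page z is stored with rows = y, cols = x; 8-bit integer pages come back
  # as raw stored integers (as.is = TRUE), float pages as stored value/scale
  nz <- length(pages)
  ny <- dims[1, 1]
  nx <- dims[2, 1]
  vals <- array(0, c(nx, ny, nz))
  if (discrete) {
    for (z in seq_len(nz)) vals[, , z] <- t(pages[[z]])
    vals <- array(as.integer(round(vals)), dim(vals))
  } else {
    for (z in seq_len(nz)) vals[, , z] <- t(pages[[z]]) * scale
  }
  voxel_grid(vals, spacing = as.numeric(meta$spacing_mm), kind = kind)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @param grid A [voxel_grid()].
#' @rdname read_volume
#' @export
write_volume <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(grid, path, version = 2)
    return(invisible(path))
  }
  if (!ext %in% c("tif", "tiff")) {
    stop_validation("unsupported volume format: .", ext)
  }
  if (grid$kind == "intensity") {
    if (min(grid$values) < 0) {
      stop_validation("negative intensities cannot be stored as TIFF; use .rds")
    }
    mx <- max(grid$values, 1e-300)
    scale <- if (mx > 1) mx else 1
    bits <- 32L
  } else {
    scale <- 255
    bits <- 8L
    if (max(grid$values) > 255 || min(grid$values) < 0) {
      stop_validation("label values outside 0..255 cannot be stored as 8-bit TIFF")
    }
  }
  pages <- lapply(seq_len(dim(grid)[3]), function(z) t(grid$values[, , z]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  jsonlite::write_json(
    list(spacing_mm = grid$spacing, kind = grid$kind, scale = scale),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
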