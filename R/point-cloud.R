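#' Construct and validate a labeled point cloud
#'
#' A point cloud is an ordinary tibble with numeric columns `x`, `y`, `z`
#' (coordinates in millimetres) and an optional integer `label` column of
#' organ codes (see [organ_codes()]). All point-based methods in the package
#' consume and return this shape, so clouds compose directly with dplyr verbs.
#'
#' @param coords An N x 3 numeric matrix or a data frame with columns
#'   `x`, `y`, `z`.
#' @param label Optional integer vector of organ codes, length N.
#' @return A tibble with columns `x`, `y`, `z` and optionally `label`.
#' @export
#' @examples
#' point_cloud(matrix(runif(30), ncol = 3), label = rep(c(1L, 2L), 5))
point_cloud <- function(coords, label = NULL) {
  if (is.data.frame(coords)) {
    coords <- as.matrix(coords[, c("x", "y", "z")])
  }
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  cloud <- tibble::tibble(
    x = as.numeric(coords[, 1]),
    y = as.numeric(coords[, 2]),
    z = as.numeric(coords[, 3])
  )
  if (!is.null(label)) cloud$label <- as.integer(label)
  validate_point_cloud(cloud)
}

#' @rdname point_cloud
#' @param cloud A data frame with columns `x`, `y`, `z` and optionally `label`.
#' @export
validate_point_cloud <- function(cloud) {
  if (!is.data.frame(cloud)) stop_validation("a point cloud must be a data frame")
  miss <- setdiff(c("x", "y", "z"), names(cloud))
  if (length(miss) > 0) {
    stop_validation("point cloud is missing column(s): ", paste(miss, collapse = ", "))
  }
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  if (nrow(xyz) > 0 && !all(is.finite(xyz))) {
    stop_validation("point cloud contains non-finite coordinates")
  }
  if ("label" %in% names(cloud)) {
    if (length(cloud$label) != nrow(cloud)) {
      stop_validation("label length does not match number of points")
    }
    validate_organ_labels(cloud$label)
  }
  tibble::as_tibble(cloud)
}

cloud_coords <- function(cloud) {
  unname(as.matrix(cloud[, c("x", "y", "z")]))
}

# ---------------------------------------------------------------------------
# PLY and XYZ readers / writers.
#
# Minimal PLY support tailored to labeled vertex clouds: ascii and
# binary_little_endian, vertex element with x/y/z (float or double), an
# optional integer "label" property (the canonical label channel), and
# optional uchar red/green/blue which can be decoded to labels through a
# user-supplied colour map.

.ply_type_size <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

.ply_type_what <- function(type) {
  if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
}

.ply_type_signed <- function(type) {
  !type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32")
}

#' Read a point cloud from PLY or XYZ text
#'
#' PLY files may be ascii or binary little-endian; the vertex element must
#' carry `x`, `y`, `z` properties and may carry an integer `label` property
#' or `red`/`green`/`blue` colours. Colour-coded labels are decoded through
#' `color_map`. XYZ text has one `x y z [label]` row per point.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"ply"`, or `"xyz"`.
#' @param color_map Optional data frame with columns `red`, `green`, `blue`,
#'   `label` mapping 0-255 colours to organ codes, used when a PLY file has
#'   colours but no explicit label property.
#' @return A point-cloud tibble (see [point_cloud()]).
#' @seealso [write_point_cloud()]
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz"),
                             color_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") "ply" else "xyz"
  }
  if (format == "ply") read_ply(path, color_map) else read_xyz(path)
}

read_xyz <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame(V1 = numeric(0), V2 = numeric(0), V3 = numeric(0)))
      }
      stop("cannot parse XYZ file ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  if (ncol(df) < 3) stop_validation("XYZ file must have at least 3 columns: ", path)
  label <- if (ncol(df) >= 4) as.integer(df[[4]]) else NULL
  point_cloud(cbind(df[[1]], df[[2]], df[[3]]), label = label)
}

read_ply <- function(path, color_map = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop_validation("not a PLY file: ", path)
  fmt <- NULL
  n_vertex <- NULL
  props <- list() # vertex properties in order: list(name=, type=)
  in_vertex <- FALSE
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop_validation("unterminated PLY header: ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stop_validation("list properties on vertices are not supported")
      props[[length(props) + 1]] <- list(name = tok[3], type = tok[2])
    } else if (tok[1] == "end_header") {
      break
    }
  }
  if (is.null(fmt) || is.null(n_vertex)) {
    stop_validation("PLY header lacks format or vertex element: ", path)
  }
  pnames <- vapply(props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames)) {
    stop_validation("PLY vertex element lacks x/y/z properties: ", path)
  }
  cols <- if (fmt == "ascii") {
    ply_read_ascii(con, n_vertex, props)
  } else if (fmt == "binary_little_endian") {
    ply_read_binary(con, n_vertex, props)
  } else {
    stop_validation("unsupported PLY format: ", fmt)
  }
  label <- NULL
  if ("label" %in% pnames) {
    label <- as.integer(cols[["label"]])
  } else if (!is.null(color_map) && all(c("red", "green", "blue") %in% pnames)) {
    key <- paste(cols[["red"]], cols[["green"]], cols[["blue"]])
    mkey <- paste(color_map$red, color_map$green, color_map$blue)
    hit <- match(key, mkey)
    if (anyNA(hit)) {
      bad <- unique(key[is.na(hit)])[1]
      stop_validation("PLY colour (", bad, ") not present in color_map")
    }
    label <- as.integer(color_map$label[hit])
  }
  point_cloud(cbind(cols[["x"]], cols[["y"]], cols[["z"]]), label = label)
}

ply_read_ascii <- function(con, n_vertex, props) {
  pnames <- vapply(props, `[[`, "", "name")
  if (n_vertex == 0) {
    out <- rep(list(numeric(0)), length(props))
    names(out) <- pnames
    return(out)
  }
  lines <- readLines(con, n = n_vertex)
  mat <- matrix(
    as.numeric(unlist(strsplit(trimws(lines), "\\s+"), use.names = FALSE)),
    nrow = n_vertex, byrow = TRUE
  )
  if (ncol(mat) != length(props)) {
    stop_validation("PLY ascii row width does not match declared properties")
  }
  out <- lapply(seq_along(props), function(i) mat[, i])
  names(out) <- pnames
  out
}

ply_read_binary <- function(con, n_vertex, props) {
  sizes <- .ply_type_size[vapply(props, `[[`, "", "type")]
  if (anyNA(sizes)) stop_validation("unknown PLY property type")
  stride <- sum(sizes)
  raw <- readBin(con, "raw", n = stride * n_vertex)
  if (length(raw) < stride * n_vertex) {
    stop_validation("PLY binary payload shorter than declared vertex count")
  }
  offsets <- c(0L, cumsum(sizes))[seq_along(props)]
  base <- rep((seq_len(n_vertex) - 1L) * stride, each = 1L)
  out <- vector("list", length(props))
  for (i in seq_along(props)) {
    sz <- sizes[i]
    pick <- rep(base * 1, each = sz) + offsets[i] + seq_len(sz)
    bytes <- raw[pick]
    type <- props[[i]]$type
    out[[i]] <- readBin(bytes, .ply_type_what(type),
      n = n_vertex, size = sz,
      signed = .ply_type_signed(type) || sz >= 4, endian = "little"
    )
  }
  names(out) <- vapply(props, `[[`, "", "name")
  out
}

#' Write a point cloud to PLY or XYZ text
#'
#' The canonical label channel in PLY output is an explicit integer vertex
#' property `label`; clouds without labels produce files without it.
#' Coordinates are written as 8-byte doubles (binary) or full-precision text,
#' so a save/load round trip is bit-exact.
#'
#' @param cloud A point-cloud tibble.
#' @param path Output path.
#' @param format `"ply"` or `"xyz"`.
#' @param binary Write binary little-endian PLY (default) or ascii.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("ply", "xyz"),
                              binary = TRUE) {
  cloud <- validate_point_cloud(cloud)
  format <- match.arg(format)
  if (format == "xyz") {
    cols <- c(
      sprintf("%.17g", cloud$x), sprintf("%.17g", cloud$y),
      sprintf("%.17g", cloud$z)
    )
    m <- matrix(cols, ncol = 3)
    if ("label" %in% names(cloud)) m <- cbind(m, as.character(cloud$label))
    writeLines(apply(m, 1, paste, collapse = " "), path)
    return(invisible(path))
  }
  has_label <- "label" %in% names(cloud)
  n <- nrow(cloud)
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    "comment shootseg labeled point cloud (mm)",
    sprintf("element vertex %d", n),
    "property double x",
    "property double y",
    "property double z",
    if (has_label) "property uchar label",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (n == 0) return(invisible(path))
  if (binary) {
    coord_raw <- writeBin(as.vector(t(cloud_coords(cloud))), raw(),
      size = 8, endian = "little"
    )
    if (has_label) {
      m <- matrix(coord_raw, nrow = 24L)
      m <- rbind(m, matrix(as.raw(cloud$label), nrow = 1L))
      writeBin(as.vector(m), con)
    } else {
      writeBin(coord_raw, con)
    }
  } else {
    rows <- sprintf("%.17g %.17g %.17g", cloud$x, cloud$y, cloud$z)
    if (has_label) rows <- paste(rows, cloud$label)
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}
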