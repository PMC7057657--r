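#' Organ label convention
#'
#' Voxels and points carry an integer organ code following the labeling
#' convention of annotated rosebush CT models: 0 = background (air),
#' 1 = stem, 2 = leaf, 3 = flower, 4 = pot, 5 = tag. The stem class covers
#' both the main branches and the petioles (they are geometrically similar
#' and spatially connected). The plant *shoot* is the union of the stem,
#' leaf and flower classes.
#'
#' @return `organ_codes()` returns the named integer code vector;
#'   `shoot_codes()` the codes making up the plant shoot;
#'   `organ_name()`/`organ_code()` translate between codes and names.
#' @export
#' @examples
#' organ_codes()
#' organ_name(c(1, 2))
organ_codes <- function() {
  c(background = 0L, stem = 1L, leaf = 2L, flower = 3L, pot = 4L, tag = 5L)
}

#' @rdname organ_codes
#' @export
shoot_codes <- function() c(stem = 1L, leaf = 2L, flower = 3L)

#' @param code Integer organ code(s).
#' @rdname organ_codes
#' @export
organ_name <- function(code) {
  codes <- organ_codes()
  out <- names(codes)[match(code, codes)]
  if (anyNA(out) && !anyNA(code)) {
    bad <- unique(code[is.na(match(code, codes))])
    stop_validation("unknown organ label code(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' @param name Organ class name(s).
#' @rdname organ_codes
#' @export
organ_code <- function(name) {
  codes <- organ_codes()
  out <- unname(codes[match(name, names(codes))])
  if (anyNA(out) && !anyNA(name)) {
    bad <- unique(name[is.na(match(name, names(codes)))])
    stop_validation("unknown organ class name(s): ", paste(bad, collapse = ", "))
  }
  out
}

# Validate a vector of organ label codes; error names the offending value.
validate_organ_labels <- function(labels) {
  if (is.null(labels)) return(invisible(NULL))
  if (anyNA(labels)) stop_validation("organ labels contain missing values")
  bad <- setdiff(unique(labels), organ_codes())
  if (length(bad) > 0) {
    stop_validation("unknown organ label code(s): ", paste(sort(bad), collapse = ", "))
  }
  invisible(NULL)
}
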