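## Binary mask refinement: fill holes, clear borders, erode.
## All three operate on logical matrices (TRUE = foreground) and are the
## standard post-processing applied to a raw graph-cut mask before its area
## is measured.

#' Fill enclosed background holes
#'
#' Every background connected component that is not connected to the frame
#' border is set to foreground. Foreground never shrinks; the operation is
#' idempotent.
#'
#' @param mask Logical mask matrix.
#' @return Logical mask with holes filled.
#' @export
fill_holes <- function(mask) {
  mask <- check_mask(mask)
  as_mask(EBImage::fillHull(mask * 1L)) | mask
}

#' Remove foreground components touching the frame border
#'
#' Connected foreground components (4-connectivity) that touch any frame
#' edge are removed; interior components are untouched. Idempotent.
#'
#' @param mask Logical mask matrix.
#' @return Logical mask with border components removed.
#' @export
clear_borders <- function(mask) {
  mask <- check_mask(mask)
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0]
  out <- mask
  if (length(border) > 0) out[lab %in% border] <- FALSE
  out
}

#' Erode a mask with a Euclidean disk
#'
#' Morphological erosion with a disk structuring element of the given
#' radius (offsets with \eqn{dx^2 + dy^2 \le r^2}). Anti-extensive: the
#' output is a subset of the input. Radius 0 is the identity.
#'
#' @param mask Logical mask matrix.
#' @param radius Disk radius in pixels, >= 0.
#' @return Eroded logical mask.
#' @export
erode_mask <- function(mask, radius = 1L) {
  mask <- check_mask(mask)
  if (radius < 0) stop_pulseroi("erosion radius must be >= 0")
  if (radius == 0 || !any(mask)) return(mask)
  as_mask(EBImage::erode(mask * 1L, disc_kernel(radius))) & mask
}

#' Refine a raw segmentation mask
#'
#' The fixed composition `fill_holes` then `clear_borders` then
#' `erode_mask(erode_radius)`, smoothing the region boundary before its
#' area is measured.
#'
#' @param mask Logical mask matrix.
#' @param erode_radius Disk radius of the final erosion (default 1 px).
#' @return Refined logical mask.
#' @export
refine_mask <- function(mask, erode_radius = 1L) {
  erode_mask(clear_borders(fill_holes(mask)), erode_radius)
}
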