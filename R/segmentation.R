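#' Automatically remove small unconnected exudates from a raw mask
#'
#' Alveolar exudates stain like tissue but must not contribute septal
#' points or intersections. Following the size rule of the original
#' workflow, every 8-connected tissue component of 1 to 1000 pixels that
#' does not touch the image border is set to air. Larger particles and
#' particles in contact with septal tissue (hence part of a larger or
#' border-touching component) require manual selection.
#'
#' @param mask a raw-stage [binary_mask()]
#' @return list with `mask` (exudate_filtered stage) and `removed`
#'   (data.frame of removed components: label, area, centroid_x/y) for the
#'   QC overlay
#' @export
remove_auto_exudates <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$stage != "raw")
    stop_lungmorph("remove_auto_exudates expects a raw-stage mask",
                   "lungmorph_usage_error")
  lab <- label_components(mask$tissue, 8L)
  stats <- component_stats(lab)
  drop <- stats$area >= 1L & stats$area <= 1000L & !stats$on_border
  tissue <- mask$tissue
  if (any(drop)) tissue[lab %in% stats$label[drop]] <- FALSE
  list(mask = binary_mask(tissue, "exudate_filtered"),
       removed = stats[drop, c("label", "area", "centroid_x", "centroid_y")])
}

#' Blank manually selected regions out of the mask
#'
#' Pixels inside manual exudate polygons and inside non-parenchyma polygons
#' are set to air, so neither contributes septal points or edges. The
#' operation is an order-independent union and is idempotent.
#'
#' @param mask an exudate_filtered [binary_mask()]
#' @param rois a [roi_set()]
#' @return the mask with selected regions blanked (stage unchanged)
#' @export
apply_manual_selections <- function(mask, rois) {
  stopifnot(inherits(mask, "binary_mask"), inherits(rois, "roi_set"))
  if (mask$stage != "exudate_filtered")
    stop_lungmorph("apply_manual_selections expects an exudate_filtered mask",
                   "lungmorph_usage_error")
  sel <- roi_mask(rois, "non_parenchyma", nrow(mask$tissue), ncol(mask$tissue)) |
    roi_mask(rois, "manual_exudates", nrow(mask$tissue), ncol(mask$tissue))
  tissue <- mask$tissue
  tissue[sel] <- FALSE
  binary_mask(tissue, "exudate_filtered")
}

#' Clean the tissue mask
#'
#' Three steps, in order: (a) air holes of 1 to 200 pixels fully enclosed
#' by tissue (4-connected air components without border contact) are filled
#' to tissue; (b) outlier removal: a binary median (majority) filter of
#' radius 2 suppresses salt-and-pepper pixels, applied only where the
#' center pixel deviates from the local median; (c) one morphological
#' closing (dilate then erode) with a 3x3 square element smooths the septal
#' outline. Ties in the majority filter keep the center pixel; at image
#' borders the structuring element is clipped.
#'
#' @param mask an exudate_filtered [binary_mask()]
#' @param closing_iter number of closing passes (default 1)
#' @return a clean-stage [binary_mask()]
#' @export
clean_mask <- function(mask, closing_iter = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$stage != "exudate_filtered")
    stop_lungmorph("clean_mask expects an exudate_filtered mask",
                   "lungmorph_usage_error")
  tissue <- mask$tissue

  # (a) size-bounded hole filling
  air_lab <- label_components(!tissue, 4L)
  stats <- component_stats(air_lab)
  fill <- stats$area >= 1L & stats$area <= 200L & !stats$on_border
  if (any(fill)) tissue[air_lab %in% stats$label[fill]] <- TRUE

  # (b) binary median filter, radius 2 (5x5), clipped at borders
  cnt <- matrix(0L, nrow(tissue), ncol(tissue))
  tot <- matrix(0L, nrow(tissue), ncol(tissue))
  for (dr in -2:2) for (dc in -2:2) {
    cnt <- cnt + shift_mat(tissue, dr, dc, FALSE)
    tot <- tot + shift_mat(matrix(TRUE, nrow(tissue), ncol(tissue)), dr, dc, FALSE)
  }
  maj <- 2L * cnt
  tissue <- ifelse(maj > tot, TRUE, ifelse(maj < tot, FALSE, tissue))

  # (c) closing with a 3x3 box (EBImage clips the element at borders)
  brush <- EBImage::makeBrush(3, "box")
  m <- tissue * 1
  for (i in seq_len(closing_iter)) m <- EBImage::closing(m, brush)
  binary_mask(m > 0.5, "clean")
}

#' Extract the air-tissue interface of a clean mask
#'
#' The edge image is the inner tissue boundary: tissue pixels with at least
#' one 4-neighbour that is air, equivalently the mask minus its erosion by
#' the 3x3 cross. Neighbours outside the image do not count as air, so the
#' image border itself is never an edge.
#'
#' @param mask a clean-stage [binary_mask()]
#' @return an object of class `edge_mask`: list with logical matrix `edge`
#' @export
extract_edges <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$stage != "clean")
    stop_lungmorph("extract_edges expects a clean-stage mask",
                   "lungmorph_usage_error")
  edge <- mask$tissue & air_neighbour_count(mask$tissue) > 0L
  structure(list(edge = edge), class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %dx%d, %d edge pixel(s)\n",
              nrow(x$edge), ncol(x$edge), sum(x$edge)))
  invisible(x)
}
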