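#' Construct a set of manual regions of interest
#'
#' ROIs replace the interactive freehand selections of the original
#' workflow: polygons outlining non-parenchymal tissue (conducting airways,
#' arteries, veins, pleura) and alveolar exudates that escaped the automatic
#' size filter. Coordinates are in standardized-field pixels, x right /
#' y down, continuous in \[0, 680\]; pixel (r, c) has its center at
#' (c - 0.5, r - 0.5). Vertices outside the field are clipped on
#' construction. Where an exudate polygon overlaps a non-parenchyma
#' polygon the non-parenchyma role wins.
#'
#' @param non_parenchyma list of polygons; each polygon is a 2-column
#'   (x, y) numeric matrix with >= 3 vertices, implicitly closed
#' @param manual_exudates list of polygons in the same format
#' @param np_mask,ex_mask optional logical matrices: raster-encoded
#'   alternatives to the polygon lists (TRUE = selected)
#' @return an object of class `roi_set`
#' @export
roi_set <- function(non_parenchyma = list(), manual_exudates = list(),
                    np_mask = NULL, ex_mask = NULL) {
  check_poly <- function(p, role, i) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L || !is.numeric(p) || any(!is.finite(p)))
      stop_lungmorph(sprintf("degenerate %s polygon #%d (need >= 3 finite xy vertices)",
                             role, i), "lungmorph_parse_error")
    pmin(pmax(p, 0), FIELD_PX)  # clip to the standardized field
  }
  non_parenchyma <- lapply(seq_along(non_parenchyma), function(i)
    check_poly(non_parenchyma[[i]], "non_parenchyma", i))
  manual_exudates <- lapply(seq_along(manual_exudates), function(i)
    check_poly(manual_exudates[[i]], "manual_exudates", i))
  structure(list(non_parenchyma = non_parenchyma,
                 manual_exudates = manual_exudates,
                 np_mask = np_mask, ex_mask = ex_mask),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d non-parenchyma, %d manual exudate polygon(s)%s\n",
              length(x$non_parenchyma), length(x$manual_exudates),
              if (!is.null(x$np_mask) || !is.null(x$ex_mask)) " + raster mask(s)" else ""))
  invisible(x)
}

#' Load a ROI file
#'
#' JSON dialect: an object with optional arrays `non_parenchyma` and
#' `manual_exudates`, each an array of polygons, each polygon an array of
#' \[x, y\] pairs (implicitly closed). A PNG file is accepted as an
#' alternative raster encoding of the non-parenchyma selection (non-zero =
#' selected); `exudate_path` may supply a second PNG for exudates. An
#' absent path yields an empty ROI set.
#'
#' @param path ROI file (JSON or PNG), or a non-existent path
#' @param exudate_path optional PNG mask of manual exudates
#' @return a [roi_set()]
#' @export
load_roiset <- function(path, exudate_path = NULL) {
  np_mask <- ex_mask <- NULL
  np <- ex <- list()
  if (!is.null(path) && file.exists(path)) {
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      np_mask <- read_roi_mask(path)
    } else {
      doc <- tryCatch(
        jsonlite::read_json(path, simplifyVector = FALSE),
        error = function(e) stop_lungmorph(
          sprintf("malformed ROI JSON '%s': %s", path, conditionMessage(e)),
          "lungmorph_parse_error"))
      np <- parse_polys(doc[["non_parenchyma"]])
      ex <- parse_polys(doc[["manual_exudates"]])
    }
  }
  if (!is.null(exudate_path) && file.exists(exudate_path))
    ex_mask <- read_roi_mask(exudate_path)
  roi_set(np, ex, np_mask = np_mask, ex_mask = ex_mask)
}

read_roi_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px > 0
}

parse_polys <- function(lst) {
  if (is.null(lst)) return(list())
  lapply(lst, function(poly) {
    m <- try(do.call(rbind, lapply(poly, function(v) as.numeric(unlist(v)))),
             silent = TRUE)
    if (inherits(m, "try-error") || is.null(m))
      stop_lungmorph("malformed polygon in ROI file", "lungmorph_parse_error")
    m
  })
}

#' Save a ROI set to the JSON dialect
#'
#' @param rois a [roi_set()] (polygon lists only; raster masks are not
#'   serialized)
#' @param path output file
#' @return `path`, invisibly
#' @export
save_roiset <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  to_pairs <- function(p) lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
  doc <- list(non_parenchyma = lapply(rois$non_parenchyma, to_pairs),
              manual_exudates = lapply(rois$manual_exudates, to_pairs))
  jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Boundary-inclusive even-odd point-in-polygon test.
# pts: n x 2 (x, y); poly: m x 2, implicitly closed. Returns logical n.
point_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(pts)
  m <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:m, 1), 1]; y2 <- poly[c(2:m, 1), 2]
  eps <- 1e-9
  out <- logical(n)
  for (i in seq_len(n)) {
    px <- pts[i, 1]; py <- pts[i, 2]
    # on-edge check: collinear and within the segment bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_edge <- abs(cross) <= eps * pmax(1, sqrt(seglen2)) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    if (any(on_edge)) { out[i] <- TRUE; next }
    # even-odd ray casting, half-open in y to handle vertices
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    out[i] <- (sum(crosses) %% 2L) == 1L
  }
  out
}

# Scanline rasterization of one polygon into an nr x nc logical matrix:
# a pixel is selected when its center falls inside (even-odd rule).
rasterize_polygon <- function(poly, nr = FIELD_PX, nc = FIELD_PX) {
  out <- matrix(FALSE, nr, nc)
  m <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:m, 1), 1]; y2 <- poly[c(2:m, 1), 2]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (length(x1) == 0L) return(out)
  for (r in seq_len(nr)) {
    yc <- r - 0.5
    hit <- (pmin(y1, y2) < yc) & (yc <= pmax(y1, y2))
    if (!any(hit)) next
    xs <- sort(x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
    np <- length(xs) %/% 2L
    for (j in seq_len(np)) {
      lo <- floor(xs[2 * j - 1] + 0.5) + 1
      hi <- ceiling(xs[2 * j] + 0.5) - 1
      if (hi >= lo) out[r, max(1, lo):min(nc, hi)] <- TRUE
    }
  }
  out
}

# Rasterized union of a ROI role ("non_parenchyma" or "manual_exudates"),
# merging polygon and raster encodings.
roi_mask <- function(rois, role, nr = FIELD_PX, nc = FIELD_PX) {
  out <- matrix(FALSE, nr, nc)
  for (p in rois[[role]]) out <- out | rasterize_polygon(p, nr, nc)
  raster <- if (role == "non_parenchyma") rois$np_mask else rois$ex_mask
  if (!is.null(raster)) out <- out | raster
  out
}

# Boundary-inclusive membership of points (n x 2 xy) in the non-parenchyma
# selection; raster-encoded selections are tested at the containing pixel.
points_in_nonparenchyma <- function(rois, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  inside <- logical(nrow(pts))
  for (p in rois$non_parenchyma)
    inside <- inside | point_in_polygon(pts, p)
  if (!is.null(rois$np_mask)) {
    r <- pmin(pmax(ceiling(pts[, 2]), 1L), nrow(rois$np_mask))
    c <- pmin(pmax(ceiling(pts[, 1]), 1L), ncol(rois$np_mask))
    inside <- inside | rois$np_mask[cbind(r, c)]
  }
  inside
}
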