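#' Build the stereological test system
#'
#' The default system matches the manual counting geometry: a central
#' 567x567 px counting frame (56 px inset in the 680 px field), 8 horizontal
#' and 8 vertical test lines of 567 px, and the 64 grid points at their
#' crossings. Line k (k = 0..n-1) sits at pixel 56 + round((k + 0.5) * 567 / n),
#' centring each line in one of n equal strips; any fixed placement is
#' stereologically valid for batch comparison, this one is frozen for
#' symmetry. The unit test-line length per point is d = 104 um (141.75 px;
#' 141.75 x 0.735 = 104.19 um, the nominal 104 is kept for read-outs). A
#' `density` multiplier (n = 8 * density lines per orientation, d scaled by
#' 1/density) supports convergence checks.
#'
#' @param scale_um_per_px physical scale (default 0.735)
#' @param density integer line-density multiplier (default 1)
#' @param d_um unit test-line length per point at density 1 (default 104)
#' @return object of class `test_system`: counting-frame geometry, line
#'   pixel coordinates (`h_rows`, `v_cols`, 1-based), the grid points, and
#'   the unit length in um and px
#' @export
test_system <- function(scale_um_per_px = DEFAULT_SCALE, density = 1L,
                        d_um = 104) {
  stopifnot(scale_um_per_px > 0, density >= 1L, d_um > 0)
  density <- as.integer(density)
  frame_px <- 567L
  offset <- as.integer(floor((FIELD_PX - frame_px) / 2))  # 56
  n <- 8L * density
  pos <- offset + as.integer(round((seq_len(n) - 0.5) * frame_px / n))
  frame_cols <- (offset + 1L):(offset + frame_px)
  grid <- as.matrix(expand.grid(row = pos, col = pos))
  structure(list(frame_px = frame_px, offset = offset,
                 frame_range = c(offset + 1L, offset + frame_px),
                 h_rows = pos, v_cols = pos, frame_span = frame_cols,
                 grid = grid, n_points = nrow(grid),
                 # geometric unit length: total line length / n points
                 d_um = d_um / density,
                 d_px = 2 * frame_px / n,
                 scale_um_per_px = scale_um_per_px, density = density),
            class = "test_system")
}

#' @export
print.test_system <- function(x, ...) {
  cat(sprintf(paste0("<test_system> %d points, %d+%d lines of %d px, ",
                     "d = %.2f um (%.2f px), frame inset %d px\n"),
              x$n_points, length(x$h_rows), length(x$v_cols), x$frame_px,
              x$d_um, x$d_px, x$offset))
  invisible(x)
}

# Continuous (x, y) coordinates of the grid point pixel centers.
grid_xy <- function(ts) cbind(x = ts$grid[, "col"] - 0.5, y = ts$grid[, "row"] - 0.5)

#' Count reference points
#'
#' Grid points falling on manually selected non-parenchymal tissue are
#' deleted from the grid (boundary of a polygon counts as inside); the
#' remainder are the reference points.
#'
#' @param rois a [roi_set()]
#' @param ts a [test_system()]
#' @return list with `p_nonpar` and `p_ref` (`p_nonpar + p_ref = n_points`)
#' @export
count_pref <- function(rois, ts) {
  stopifnot(inherits(rois, "roi_set"), inherits(ts, "test_system"))
  p_nonpar <- sum(points_in_nonparenchyma(rois, grid_xy(ts)))
  list(p_nonpar = as.integer(p_nonpar),
       p_ref = as.integer(ts$n_points - p_nonpar))
}

#' Count septal points
#'
#' Septal points are grid points whose pixel is tissue in the clean mask
#' and which do not fall on non-parenchymal selections.
#'
#' @param mask a clean-stage [binary_mask()]
#' @param rois a [roi_set()]
#' @param ts a [test_system()]
#' @return integer count
#' @export
count_psep <- function(mask, rois, ts) {
  stopifnot(inherits(mask, "binary_mask"), inherits(ts, "test_system"))
  if (mask$stage != "clean")
    stop_lungmorph("count_psep expects a clean-stage mask", "lungmorph_usage_error")
  on_tissue <- mask$tissue[ts$grid]
  excluded <- points_in_nonparenchyma(rois, grid_xy(ts))
  as.integer(sum(on_tissue & !excluded))
}

#' Count intersections of the air-tissue interface with the test lines
#'
#' For each orientation the intersection image is the conjunction of the
#' edge image with the one-pixel-thick test lines; one maximal contiguous
#' run of intersection pixels along a line counts as one intersection. Runs
#' lying entirely inside the non-parenchyma selection are excluded.
#'
#' @param edge an `edge_mask` from [extract_edges()]
#' @param rois a [roi_set()]
#' @param ts a [test_system()]
#' @return list with `i_h`, `i_v` and `i_total`
#' @export
count_intersections <- function(edge, rois, ts) {
  stopifnot(inherits(edge, "edge_mask"), inherits(ts, "test_system"))
  np <- roi_mask(rois, "non_parenchyma", nrow(edge$edge), ncol(edge$edge))
  span <- ts$frame_span
  count_line <- function(vals, np_vals) {
    r <- rle(vals)
    if (!any(r$values)) return(0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    keep <- vapply(runs, function(i) !all(np_vals[starts[i]:ends[i]]), logical(1))
    sum(keep)
  }
  i_h <- sum(vapply(ts$h_rows, function(r)
    count_line(edge$edge[r, span], np[r, span]), integer(1)))
  i_v <- sum(vapply(ts$v_cols, function(c)
    count_line(edge$edge[span, c], np[span, c]), integer(1)))
  list(i_h = as.integer(i_h), i_v = as.integer(i_v),
       i_total = as.integer(i_h + i_v))
}

#' Assemble the per-field stereology counts
#'
#' Runs the full per-field pipeline: threshold, automatic exudate removal,
#' manual selections, mask cleaning, edge extraction and the three
#' counters. With `binary = TRUE` the image is taken as an already-binary
#' mask (tissue = intensity <= t) and the exudate-removal and cleaning
#' steps are skipped — the variant used for synthetic ground-truth images.
#'
#' @param img a [field_image()]
#' @param rois a [roi_set()]
#' @param t intensity threshold in \[0, 255\]
#' @param ts a [test_system()]
#' @param binary skip exudate filtering and mask cleaning (default FALSE)
#' @return object of class `field_counts`: source_id, threshold, p_nonpar,
#'   p_ref, p_sep, i_h, i_v, i_total, n_auto_exudates
#' @export
count_field <- function(img, rois = roi_set(), t, ts = test_system(),
                        binary = FALSE) {
  stopifnot(inherits(img, "field_image"))
  raw <- apply_threshold(img, t)
  if (binary) {
    clean <- binary_mask(raw$tissue, "clean")
    n_removed <- 0L
  } else {
    filt <- remove_auto_exudates(raw)
    n_removed <- nrow(filt$removed)
    clean <- clean_mask(apply_manual_selections(filt$mask, rois))
  }
  edges <- extract_edges(clean)
  pr <- count_pref(rois, ts)
  ps <- count_psep(clean, rois, ts)
  ii <- count_intersections(edges, rois, ts)
  structure(list(source_id = img$source_id, threshold = t,
                 p_nonpar = pr$p_nonpar, p_ref = pr$p_ref, p_sep = ps,
                 i_h = ii$i_h, i_v = ii$i_v, i_total = ii$i_total,
                 n_auto_exudates = n_removed),
            class = "field_counts")
}

#' @export
print.field_counts <- function(x, ...) {
  cat(sprintf("<field_counts> %s: Pref %d, Psep %d, I %d (t = %s)\n",
              x$source_id, x$p_ref, x$p_sep, x$i_total, format(x$threshold)))
  invisible(x)
}

#' @export
as.data.frame.field_counts <- function(x, ...) {
  data.frame(source_id = x$source_id, p_nonpar = x$p_nonpar,
             p_ref = x$p_ref, p_sep = x$p_sep, i_h = x$i_h, i_v = x$i_v,
             i_total = x$i_total, threshold = x$threshold,
             n_auto_exudates = x$n_auto_exudates,
             stringsAsFactors = FALSE)
}

# Bind a list of field_counts (or a data.frame) into the canonical
# counts data.frame used by the stereology read-outs.
counts_table <- function(counts) {
  if (is.data.frame(counts)) return(counts)
  if (inherits(counts, "field_counts")) counts <- list(counts)
  do.call(rbind, lapply(counts, as.data.frame))
}
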