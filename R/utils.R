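# Internal helpers: structured errors, matrix shifts, binary morphology.

stop_lungmorph <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lungmorph_error", "error")))
}

#' @title Shift a matrix by whole pixels
#' @description Shift `m` by `dr` rows and `dc` columns, padding exposed
#'   cells with `fill`. Used for neighbourhood operations on masks.
#' @noRd
shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Number of 4-neighbours of each pixel that are air (!mask); neighbours
# outside the image do not count as air.
air_neighbour_count <- function(tissue) {
  air <- !tissue
  shift_mat(air, 1L, 0L, FALSE) + shift_mat(air, -1L, 0L, FALSE) +
    shift_mat(air, 0L, 1L, FALSE) + shift_mat(air, 0L, -1L, FALSE)
}

# Component areas and border contact from a label matrix.
component_stats <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(label = integer(), area = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      on_border = logical()))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- ((idx - 1L) %% nrow(lab)) + 1L
  c <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(l, nbins = n)
  cx <- rowsum(c - 0.5, l)[, 1] / area
  cy <- rowsum(r - 0.5, l)[, 1] / area
  border <- r == 1L | r == nrow(lab) | c == 1L | c == ncol(lab)
  on_border <- as.logical(rowsum(as.integer(border), l)[, 1] > 0L)
  data.frame(label = seq_len(n), area = area, centroid_x = cx,
             centroid_y = cy, on_border = on_border)
}

label_components <- function(mask, connectivity = 8L) {
  .cc_label(mask, as.integer(connectivity))
}
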