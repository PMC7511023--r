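# Independent oracles and fixture builders used across the suite.

# Brute-force Otsu: between-class variance at every 8-bit cut point.
# Histogram gaps make the maximizer a plateau, so oracle comparisons check
# attained variance, not the argmax index.
otsu_variance_curve <- function(px) {
  h <- tabulate(as.integer(px) + 1L, nbins = 256L)
  p <- h / sum(h)
  lv <- 0:255
  vapply(0:254, function(t) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    mu0 <- sum(lv[1:(t + 1)] * p[1:(t + 1)]) / w0
    mu1 <- sum(lv[(t + 2):256] * p[(t + 2):256]) / w1
    w0 * w1 * (mu0 - mu1)^2
  }, numeric(1))
}

# Intersections as mask sign changes along the test lines: for axis-aligned
# air figures strictly inside the counting frame, every air<->tissue
# transition corresponds to exactly one edge run.
sign_change_intersections <- function(tissue, ts) {
  span <- ts$frame_span
  n_h <- sum(vapply(ts$h_rows, function(r)
    sum(diff(tissue[r, span]) != 0), numeric(1)))
  n_v <- sum(vapply(ts$v_cols, function(c)
    sum(diff(tissue[span, c]) != 0), numeric(1)))
  c(i_h = n_h, i_v = n_v, i_total = n_h + n_v)
}

# ICC(2,1) through stats::aov mean squares (independent of the direct
# sums-of-squares arithmetic in the package).
aov_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Queue-based flood-fill component labelling for small masks (oracle for
# the union-find labeller).
bfs_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- cur
    while (nrow(queue) > 0L) {
      r <- queue[1, 1]; c <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (j in seq_len(nrow(nb))) {
        rr <- r + nb[j, 1]; cc <- c + nb[j, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# An all-air 680 field with axis-aligned tissue/air features, as a matrix.
blank_mask <- function(value = FALSE) matrix(value, 680L, 680L)

# Rectangle helper (1-based inclusive pixel ranges).
set_rect <- function(m, r0, r1, c0, c1, value = TRUE) {
  m[r0:r1, c0:c1] <- value
  m
}

# Write a field_image-compatible PNG; intensities 0-255.
write_gray_png <- function(px, path) {
  png::writePNG(px / 255, path)
  path
}

# Closed square polygon (x, y continuous coordinates).
square_poly <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}
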