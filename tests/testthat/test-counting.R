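test_that("test system geometry matches the counting convention", {
  ts <- test_system()
  expect_identical(ts$n_points, 64L)
  expect_identical(length(ts$h_rows), 8L)
  expect_identical(length(ts$v_cols), 8L)
  expect_identical(ts$offset, 56L)
  expect_identical(ts$frame_px, 567L)
  # total test-line length 16 x 567 px
  expect_identical(16L * ts$frame_px, 9072L)
  # unit length: d_px * scale within 0.5 um of the nominal d_um
  expect_equal(ts$d_px, 141.75)
  expect_lt(abs(ts$d_px * ts$scale_um_per_px - ts$d_um), 0.5)
  # grid points are exactly the h x v line crossings, all inside the frame
  expect_identical(nrow(ts$grid), 64L)
  crossings <- expand.grid(row = ts$h_rows, col = ts$v_cols)
  expect_setequal(paste(ts$grid[, "row"], ts$grid[, "col"]),
                  paste(crossings$row, crossings$col))
  expect_true(all(ts$grid >= ts$frame_range[1] & ts$grid <= ts$frame_range[2]))

  # densified system scales points, lines and unit length consistently
  ts4 <- test_system(density = 4)
  expect_identical(ts4$n_points, 1024L)
  expect_equal(ts4$d_um, 104 / 4)
  expect_equal(ts4$d_px, 141.75 / 4)
})

test_that("reference point counting excludes non-parenchyma polygons", {
  ts <- test_system()
  # nothing excluded
  pr0 <- count_pref(roi_set(), ts)
  expect_identical(pr0, list(p_nonpar = 0L, p_ref = 64L))

  # polygon covering the whole frame
  prall <- count_pref(roi_set(non_parenchyma = list(square_poly(0, 0, 680))), ts)
  expect_identical(prall, list(p_nonpar = 64L, p_ref = 0L))

  # left half of the frame, split between the 4th and 5th vertical lines
  half <- roi_set(non_parenchyma = list(cbind(c(0, 339.5, 339.5, 0),
                                              c(0, 0, 680, 680))))
  prh <- count_pref(half, ts)
  expect_identical(prh, list(p_nonpar = 32L, p_ref = 32L))

  # p_nonpar + p_ref = 64 and monotonicity under polygon growth
  set.seed(4)
  for (i in 1:5) {
    s <- runif(1, 50, 300)
    x0 <- runif(1, 0, 680 - s); y0 <- runif(1, 0, 680 - s)
    small <- roi_set(non_parenchyma = list(square_poly(x0, y0, s)))
    big <- roi_set(non_parenchyma = list(square_poly(x0, y0, min(s * 1.8, 680))))
    ps <- count_pref(small, ts); pb <- count_pref(big, ts)
    expect_identical(ps$p_nonpar + ps$p_ref, 64L)
    expect_identical(pb$p_nonpar + pb$p_ref, 64L)
    expect_lte(pb$p_ref, ps$p_ref)
  }
})

test_that("septal point counting hits tissue pixels outside exclusions", {
  ts <- test_system()
  all_t <- binary_mask(blank_mask(TRUE), "clean")
  expect_identical(count_psep(all_t, roi_set(), ts), 64L)
  expect_identical(count_psep(binary_mask(blank_mask(), "clean"), roi_set(), ts), 0L)

  left <- binary_mask(set_rect(blank_mask(), 1, 680, 1, 340), "clean")
  expect_identical(count_psep(left, roi_set(), ts), 32L)

  # non-parenchyma exclusion also removes septal points
  half <- roi_set(non_parenchyma = list(cbind(c(0, 339.5, 339.5, 0),
                                              c(0, 0, 680, 680))))
  expect_identical(count_psep(all_t, half, ts), 32L)
  expect_error(count_psep(binary_mask(blank_mask(TRUE), "raw"), roi_set(), ts),
               class = "lungmorph_usage_error")
})

test_that("intersection counting counts edge runs along the test lines", {
  ts <- test_system()
  # empty edge
  e0 <- extract_edges(binary_mask(blank_mask(), "clean"))
  expect_identical(count_intersections(e0, roi_set(), ts),
                   list(i_h = 0L, i_v = 0L, i_total = 0L))

  # full-height vertical tissue stripe, width 100, centered: every h-line
  # crosses two boundaries, v-lines lie wholly inside or outside
  stripe <- binary_mask(set_rect(blank_mask(), 1, 680, 290, 389), "clean")
  ii <- count_intersections(extract_edges(stripe), roi_set(), ts)
  expect_identical(ii, list(i_h = 16L, i_v = 0L, i_total = 16L))

  # tissue square crossed by exactly 3 h-lines and 3 v-lines: 12 crossings
  # (rows/cols 233, 304, 375 inside; 162 and 446 outside)
  sq <- binary_mask(set_rect(blank_mask(), 200, 400, 200, 400), "clean")
  ii2 <- count_intersections(extract_edges(sq), roi_set(), ts)
  expect_identical(ii2$i_total, 12L)

  # runs fully inside non-parenchyma are excluded
  cover <- roi_set(non_parenchyma = list(square_poly(150, 150, 300)))
  ii3 <- count_intersections(extract_edges(sq), cover, ts)
  expect_identical(ii3$i_total, 0L)
})

test_that("intersections match the sign-change oracle on rectangles", {
  ts <- test_system()
  # disjoint air rectangles strictly inside the frame, with boundaries kept
  # off the test lines (a line running along a rectangle edge merges runs,
  # which the run-counting convention counts once by design)
  cells <- list(c(70, 330), c(350, 610))
  set.seed(12)
  for (i in 1:8) {
    m <- blank_mask(TRUE)  # tissue background
    for (cr in cells) for (cc in cells) {
      if (runif(1) < 0.3) next
      repeat {
        h <- sample(40:180, 1); w <- sample(40:180, 1)
        r0 <- sample(cr[1]:(cr[2] - h), 1); c0 <- sample(cc[1]:(cc[2] - w), 1)
        clear <- function(lines, lo, hi)
          !any(lines %in% c(lo - 1L, lo, hi, hi + 1L))
        if (clear(ts$h_rows, r0, r0 + h - 1L) &&
            clear(ts$v_cols, c0, c0 + w - 1L)) break
      }
      m <- set_rect(m, r0, r0 + h - 1, c0, c0 + w - 1, FALSE)
    }
    ii <- count_intersections(extract_edges(binary_mask(m, "clean")),
                              roi_set(), ts)
    oracle <- sign_change_intersections(m, ts)
    expect_identical(ii$i_total, as.integer(oracle["i_total"]))
    expect_identical(ii$i_h, as.integer(oracle["i_h"]))
    expect_identical(ii$i_v, as.integer(oracle["i_v"]))
  }
})

test_that("count_field composes the pipeline deterministically", {
  ts <- test_system()
  dark <- field_image(matrix(20, 680, 680))
  fc <- count_field(dark, roi_set(), t = 128, ts)
  expect_identical(c(fc$p_ref, fc$p_sep, fc$i_total), c(64L, 64L, 0L))

  bright <- field_image(matrix(240, 680, 680))
  fc2 <- count_field(bright, roi_set(), t = 128, ts)
  expect_identical(c(fc2$p_ref, fc2$p_sep, fc2$i_total), c(64L, 0L, 0L))

  # binary wallpaper field: composition equals the stand-alone counters
  wp <- make_wallpaper(default_wallpaper_specs(seed = 2)[[4]])
  f <- sample_fields(wp, 1, seed = 3)[[1]]
  fc3 <- count_field(f, roi_set(), t = 128, ts, binary = TRUE)
  mask <- binary_mask(f$pixels <= 128, "clean")
  expect_identical(fc3$p_sep, count_psep(mask, roi_set(), ts))
  ii <- count_intersections(extract_edges(mask), roi_set(), ts)
  expect_identical(fc3$i_total, ii$i_total)
  expect_identical(fc3$p_ref, 64L)

  # determinism
  fc4 <- count_field(f, roi_set(), t = 128, ts, binary = TRUE)
  expect_identical(as.data.frame(fc3), as.data.frame(fc4))
})
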