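test_that("component labeller agrees with flood-fill oracle", {
  set.seed(3)
  for (conn in c(4L, 8L)) {
    for (i in 1:5) {
      m <- matrix(runif(30 * 30) < 0.4, 30, 30)
      ours <- lungmorph:::label_components(m, conn)
      ref <- bfs_label(m, conn)
      expect_identical(ours, ref)
    }
  }
})

test_that("automatic exudate removal follows the size and border rules", {
  # interior 5x5 (25 px) removed
  m <- set_rect(blank_mask(), 300, 304, 300, 304)
  r <- remove_auto_exudates(binary_mask(m, "raw"))
  expect_identical(sum(r$mask$tissue), 0L)
  expect_identical(nrow(r$removed), 1L)
  expect_identical(r$removed$area, 25L)
  expect_identical(r$mask$stage, "exudate_filtered")

  # interior 40x40 (1600 px) untouched: too large for the automatic filter
  m2 <- set_rect(blank_mask(), 300, 339, 300, 339)
  r2 <- remove_auto_exudates(binary_mask(m2, "raw"))
  expect_identical(r2$mask$tissue, m2)
  expect_identical(nrow(r2$removed), 0L)

  # border-touching 10x10 untouched
  m3 <- set_rect(blank_mask(), 100, 109, 1, 10)
  r3 <- remove_auto_exudates(binary_mask(m3, "raw"))
  expect_identical(r3$mask$tissue, m3)

  expect_error(remove_auto_exudates(binary_mask(m3, "clean")),
               class = "lungmorph_usage_error")
})

test_that("exactly the planted sub-1000-px interior particles are removed", {
  # plant disjoint squares of known sizes, including >1000 px and border cases
  m <- blank_mask()
  m <- set_rect(m, 50, 59, 50, 59)      # 100 px, interior -> removed
  m <- set_rect(m, 200, 230, 200, 230)  # 961 px, interior -> removed
  m <- set_rect(m, 400, 432, 400, 432)  # 1089 px -> kept
  m <- set_rect(m, 1, 20, 600, 619)     # border contact -> kept
  m <- set_rect(m, 650, 650, 50, 50)    # single pixel -> removed
  r <- remove_auto_exudates(binary_mask(m, "raw"))
  expect_identical(sort(r$removed$area), c(1L, 100L, 961L))
  keep <- blank_mask()
  keep <- set_rect(keep, 400, 432, 400, 432)
  keep <- set_rect(keep, 1, 20, 600, 619)
  expect_identical(r$mask$tissue, keep)
  # never adds tissue
  expect_true(all(m[r$mask$tissue]))
})

test_that("manual selections blank polygons to air, idempotently", {
  all_tissue <- binary_mask(blank_mask(TRUE), "exudate_filtered")
  # 10x10 px square polygon covers exactly 100 pixels
  rois <- roi_set(manual_exudates = list(square_poly(100, 200, 10)))
  out <- apply_manual_selections(all_tissue, rois)
  expect_identical(sum(!out$tissue), 100L)

  # empty ROI set is the identity
  out0 <- apply_manual_selections(all_tissue, roi_set())
  expect_identical(out0$tissue, all_tissue$tissue)

  # overlapping exudate and non-parenchyma polygons: order-independent union
  r1 <- roi_set(non_parenchyma = list(square_poly(100, 200, 10)),
                manual_exudates = list(square_poly(105, 205, 10)))
  o1 <- apply_manual_selections(all_tissue, r1)
  o2 <- apply_manual_selections(o1, r1)  # idempotent
  expect_identical(o1$tissue, o2$tissue)
  expect_identical(sum(!o1$tissue), 175L)  # union of two offset 10x10 squares
})

test_that("mask cleaning fills small holes, removes outliers, closes", {
  # 50-px enclosed air hole filled
  m <- set_rect(blank_mask(TRUE), 300, 309, 300, 304, FALSE)
  cm <- clean_mask(binary_mask(m, "exudate_filtered"))
  expect_identical(sum(!cm$tissue), 0L)
  expect_identical(cm$stage, "clean")

  # 500-px hole preserved (above the 200-px bound); closing may round the rim
  m2 <- set_rect(blank_mask(TRUE), 300, 324, 300, 319, FALSE)
  cm2 <- clean_mask(binary_mask(m2, "exudate_filtered"))
  expect_gt(sum(!cm2$tissue), 400)

  # isolated tissue pixel suppressed by the majority filter
  m3 <- blank_mask()
  m3[340, 340] <- TRUE
  cm3 <- clean_mask(binary_mask(m3, "exudate_filtered"))
  expect_identical(sum(cm3$tissue), 0L)

  # every small enclosed hole of the input ends up as tissue in the output
  set.seed(8)
  blob <- EBImage::gblur(matrix(runif(680 * 680), 680, 680), sigma = 8) > 0.5
  cmb <- clean_mask(binary_mask(blob, "exudate_filtered"))
  holes <- lungmorph:::label_components(!blob, 4L)
  st <- lungmorph:::component_stats(holes)
  small <- st$label[st$area <= 200 & !st$on_border]
  expect_gt(length(small), 0)
  expect_true(all(cmb$tissue[holes %in% small]))
})

test_that("closing is idempotent within the cleaning pipeline", {
  set.seed(9)
  for (i in 1:3) {
    blob <- EBImage::gblur(matrix(runif(680 * 680), 680, 680), sigma = 5) > 0.52
    once <- clean_mask(binary_mask(blob, "exudate_filtered"), closing_iter = 1L)
    twice <- clean_mask(binary_mask(blob, "exudate_filtered"), closing_iter = 2L)
    expect_identical(once$tissue, twice$tissue)
  }
})

test_that("edge extraction yields the one-pixel inner tissue boundary", {
  # all tissue: the image border is not an edge
  expect_identical(sum(extract_edges(binary_mask(blank_mask(TRUE), "clean"))$edge), 0L)
  # all air
  expect_identical(sum(extract_edges(binary_mask(blank_mask(), "clean"))$edge), 0L)
  # single tissue pixel is its own edge
  m1 <- blank_mask(); m1[10, 10] <- TRUE
  expect_identical(which(extract_edges(binary_mask(m1, "clean"))$edge), which(m1))

  # a x a square has 4a - 4 edge pixels
  for (a in c(2L, 5L, 17L, 100L)) {
    m <- set_rect(blank_mask(), 200, 200 + a - 1, 300, 300 + a - 1)
    e <- extract_edges(binary_mask(m, "clean"))
    expect_identical(sum(e$edge), 4L * a - 4L)
    # every edge pixel is a tissue pixel touching air
    expect_true(all(m[e$edge]))
  }
  expect_error(extract_edges(binary_mask(m1, "raw")),
               class = "lungmorph_usage_error")
})
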