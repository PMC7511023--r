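#' Describe a synthetic "wallpaper" validation image
#'
#' Validation images are large binary rasters composed of wallpaper-like
#' square tiles; within every tile the same combination of white geometric
#' figures (the "airspaces") is placed at random, non-overlapping positions
#' against a black background (the "septal" phase). Because figure areas
#' and perimeters are known exactly, the theoretical read-outs are
#' VVsep = (W^2 - sum(area)) / W^2 and Lm = 4 * (1 - VVsep) * W^2 /
#' sum(perimeter) = 4 * sum(area) / sum(perimeter) (in px; multiplied by
#' the field scale for um). For axis-aligned squares and rectangles drawn
#' without anti-aliasing both the rasterized area and the 4A/P formula are
#' exact; circles are supported but carry a systematic discrepancy between
#' axis-aligned intercept counting and 4A/P (a factor pi/4 on the chord
#' length), documented rather than corrected.
#'
#' @param tile tile edge length in px; must divide `width`
#' @param figures list of figure descriptors placed in every tile:
#'   `list(kind = "square", side =)`, `list(kind = "rect", w =, h =)` or
#'   `list(kind = "circle", r =)`
#' @param seed RNG seed for figure placement
#' @param width image edge length in px (default 2040)
#' @return object of class `wallpaper_spec`, including exact `sum_area`,
#'   `sum_perimeter` (px over the whole image), `vv_sep_theory`,
#'   `lm_theory_px` and `lm_theory_um`
#' @export
wallpaper_spec <- function(tile, figures, seed = 1L, width = 2040L) {
  width <- as.integer(width); tile <- as.integer(tile)
  if (width %% tile != 0L)
    stop_lungmorph("tile size must divide image width", "lungmorph_generation_error")
  dims <- lapply(figures, figure_dims)
  for (d in dims) if (d["w"] > tile || d["h"] > tile)
    stop_lungmorph("figure does not fit in tile", "lungmorph_generation_error")
  n_tiles <- (width %/% tile)^2
  a <- sum(vapply(figures, figure_area, numeric(1))) * n_tiles
  p <- sum(vapply(figures, figure_perimeter, numeric(1))) * n_tiles
  vv <- (width^2 - a) / width^2
  lm_px <- if (p > 0) 4 * a / p else 0
  structure(list(width = width, tile = tile, figures = figures,
                 seed = as.integer(seed), n_tiles = n_tiles,
                 sum_area = a, sum_perimeter = p, vv_sep_theory = vv,
                 lm_theory_px = lm_px,
                 lm_theory_um = lm_px * DEFAULT_SCALE),
            class = "wallpaper_spec")
}

figure_dims <- function(f) {
  switch(f$kind,
         square = c(w = f$side, h = f$side),
         rect = c(w = f$w, h = f$h),
         circle = c(w = 2 * f$r, h = 2 * f$r),
         stop_lungmorph(sprintf("unknown figure kind '%s'", f$kind),
                        "lungmorph_generation_error"))
}

figure_area <- function(f) {
  switch(f$kind, square = f$side^2, rect = f$w * f$h, circle = pi * f$r^2)
}

figure_perimeter <- function(f) {
  switch(f$kind, square = 4 * f$side, rect = 2 * (f$w + f$h), circle = 2 * pi * f$r)
}

#' @export
print.wallpaper_spec <- function(x, ...) {
  cat(sprintf("<wallpaper_spec> %dx%d px, %d tiles of %d px, %d figure(s)/tile\n",
              x$width, x$width, x$n_tiles, x$tile, length(x$figures)))
  cat(sprintf("  theory: VVsep %.4f, Lm %.1f px (%.1f um)\n",
              x$vv_sep_theory, x$lm_theory_px, x$lm_theory_um))
  invisible(x)
}

#' Render a wallpaper validation image
#'
#' Figures are placed independently per tile: each figure's bounding box is
#' drawn uniformly inside the tile and rejected on overlap with figures
#' already placed in that tile (bounding-box test); a tile is restarted
#' when a figure cannot be placed, and generation fails after a bounded
#' number of restarts. White (255) = airspace figures, black (0) = septal
#' phase. Deterministic given the spec seed.
#'
#' @param spec a [wallpaper_spec()]
#' @param max_restarts per-tile restart budget (default 200)
#' @return object of class `wallpaper`: integer matrix `image` (0/255),
#'   the `spec` with realized `placements`, and the theory values
#' @export
make_wallpaper <- function(spec, max_restarts = 200L) {
  stopifnot(inherits(spec, "wallpaper_spec"))
  set.seed(spec$seed)
  w <- spec$width
  img <- matrix(0L, w, w)
  per_side <- w %/% spec$tile
  dims <- lapply(spec$figures, figure_dims)
  placements <- vector("list", spec$n_tiles * length(spec$figures))
  pi_ <- 0L
  for (tr in seq_len(per_side)) for (tc in seq_len(per_side)) {
    oy <- (tr - 1L) * spec$tile  # 0-based tile origin in the image
    ox <- (tc - 1L) * spec$tile
    for (restart in seq_len(max_restarts)) {
      placed <- matrix(numeric(0), 0, 4)  # x0, y0, w, h (0-based in tile)
      ok <- TRUE
      for (j in seq_along(spec$figures)) {
        d <- dims[[j]]
        hit <- FALSE
        for (try in 1:100) {
          x0 <- sample.int(spec$tile - d["w"] + 1L, 1L) - 1L
          y0 <- sample.int(spec$tile - d["h"] + 1L, 1L) - 1L
          if (nrow(placed) == 0L ||
              !any(x0 < placed[, 1] + placed[, 3] & placed[, 1] < x0 + d["w"] &
                   y0 < placed[, 2] + placed[, 4] & placed[, 2] < y0 + d["h"])) {
            placed <- rbind(placed, c(x0, y0, d["w"], d["h"]))
            hit <- TRUE
            break
          }
        }
        if (!hit) { ok <- FALSE; break }
      }
      if (ok) break
      if (restart == max_restarts)
        stop_lungmorph("infeasible figure packing for tile", "lungmorph_generation_error")
    }
    for (j in seq_along(spec$figures)) {
      f <- spec$figures[[j]]
      x0 <- placed[j, 1] + ox; y0 <- placed[j, 2] + oy
      img <- draw_figure(img, f, x0, y0)
      pi_ <- pi_ + 1L
      placements[[pi_]] <- data.frame(tile_row = tr, tile_col = tc,
                                      kind = f$kind, x0 = x0, y0 = y0,
                                      w = placed[j, 3], h = placed[j, 4])
    }
  }
  spec$placements <- do.call(rbind, placements)
  structure(list(image = img, spec = spec,
                 vv_sep_theory = spec$vv_sep_theory,
                 lm_theory_px = spec$lm_theory_px,
                 lm_theory_um = spec$lm_theory_um),
            class = "wallpaper")
}

# x0, y0: 0-based top-left of the figure bounding box in image coordinates
draw_figure <- function(img, f, x0, y0) {
  d <- figure_dims(f)
  if (f$kind == "circle") {
    r <- f$r
    cx <- x0 + r; cy <- y0 + r  # continuous center
    rows <- (y0 + 1):(y0 + d["h"])
    cols <- (x0 + 1):(x0 + d["w"])
    dy2 <- (rows - 0.5 - cy)^2
    dx2 <- (cols - 0.5 - cx)^2
    img[rows, cols][outer(dy2, dx2, "+") <= r^2] <- 255L
  } else {
    img[(y0 + 1):(y0 + d["h"]), (x0 + 1):(x0 + d["w"])] <- 255L
  }
  img
}

#' @export
print.wallpaper <- function(x, ...) {
  cat(sprintf("<wallpaper> %dx%d px, white fraction %.4f (theory %.4f air)\n",
              nrow(x$image), ncol(x$image), mean(x$image > 0),
              1 - x$vv_sep_theory))
  invisible(x)
}

#' Randomly sample fields from a larger raster
#'
#' Draws `n` top-left coordinates uniformly (with replacement; fields may
#' overlap) and cuts out size x size fields, emulating random field
#' sampling from a whole image. An optional low-resolution tissue mask
#' restricts sampling: a candidate is accepted only when the field center
#' falls on tissue (bounded rejection sampling).
#'
#' @param image a `wallpaper`, or a numeric matrix of intensities
#' @param n number of fields
#' @param size field edge length in px (default 680)
#' @param seed RNG seed
#' @param tissue_constraint optional logical matrix (any resolution)
#' @param scale physical scale assigned to the fields (default 0.735)
#' @return list of [field_image()]s; source ids carry the 0-based
#'   top-left sampling coordinates
#' @export
sample_fields <- function(image, n, size = FIELD_PX, seed = 1L,
                          tissue_constraint = NULL, scale = DEFAULT_SCALE) {
  if (inherits(image, "wallpaper")) image <- image$image
  image <- as.matrix(image)
  if (nrow(image) < size || ncol(image) < size)
    stop_lungmorph("image smaller than the requested field size",
                   "lungmorph_sampling_error")
  if (n < 1L)
    stop_lungmorph("n must be >= 1", "lungmorph_sampling_error")
  set.seed(seed)
  max_x <- ncol(image) - size
  max_y <- nrow(image) - size
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      x0 <- sample.int(max_x + 1L, 1L) - 1L
      y0 <- sample.int(max_y + 1L, 1L) - 1L
      if (is.null(tissue_constraint)) break
      mr <- pmin(pmax(ceiling((y0 + size / 2) / nrow(image) *
                                nrow(tissue_constraint)), 1L),
                 nrow(tissue_constraint))
      mc <- pmin(pmax(ceiling((x0 + size / 2) / ncol(image) *
                                ncol(tissue_constraint)), 1L),
                 ncol(tissue_constraint))
      if (tissue_constraint[mr, mc]) break
      if (try == 1000)
        stop_lungmorph("tissue constraint unsatisfiable within retry budget",
                       "lungmorph_sampling_error")
    }
    out[[i]] <- field_image(image[(y0 + 1):(y0 + size), (x0 + 1):(x0 + size)],
                            scale_um_per_px = scale,
                            source_id = sprintf("sample[%d,%d]", x0, y0))
  }
  out
}

#' Default wallpaper specifications for the validation experiment
#'
#' Eleven axis-aligned square/rectangle compositions on a 340-px tile,
#' spanning theoretical VVsep from about 0.30 to 0.90 and theoretical Lm
#' from about 46 to 209 um — the density range of the validation study and
#' a realistic alveolar size range.
#'
#' @param seed base RNG seed; spec i receives seed + i
#' @return list of 11 [wallpaper_spec()]s ordered by decreasing VVsep
#' @export
default_wallpaper_specs <- function(seed = 1L) {
  sq <- function(a) list(kind = "square", side = a)
  rc <- function(w, h) list(kind = "rect", w = w, h = h)
  figs <- list(
    list(sq(62), sq(62), sq(62)),       # VVsep 0.900
    list(sq(79), sq(79), sq(79)),       # 0.838
    list(sq(92), sq(92), sq(92)),       # 0.780
    list(sq(104), sq(104), sq(104)),    # 0.719
    list(sq(140), rc(160, 120)),        # 0.664
    list(sq(170), rc(150, 115)),        # 0.601
    list(sq(230)),                      # 0.542
    list(sq(245)),                      # 0.481
    list(sq(259)),                      # 0.420
    list(sq(272)),                      # 0.360
    list(sq(284))                       # 0.302
  )
  lapply(seq_along(figs), function(i)
    wallpaper_spec(tile = 340L, figures = figs[[i]], seed = seed + i))
}

#' Generate a histology-like phantom field with ground truth
#'
#' Emulates an H&E lung field: a septal network built by dilating the
#' ridges of a seeded nearest-point partition of the field (airspace
#' "cells"), large vessel-like discs and small exudate-like discs planted
#' in the airspaces with a guaranteed 2-px gap from other structures, and
#' per-phase intensities (tissue-like phases dark, air bright) with
#' additive Gaussian noise. Truth masks are pairwise disjoint and every
#' planted exudate's pixel area lies within the configured range.
#'
#' @param n_cells number of airspace cells (default 45)
#' @param wall_px septal wall thickness in px (odd, default 7)
#' @param n_vessels number of vessel-like discs (default 2)
#' @param vessel_r radius range in px (default c(25, 50); areas stay above
#'   the 1000-px automatic exudate bound)
#' @param n_exudates number of exudate-like discs (default 5)
#' @param exudate_area pixel-area range for exudates (default c(100, 900))
#' @param mean_tissue,mean_air phase intensity means (defaults 90 / 220)
#' @param noise_sd Gaussian intensity noise sd (default 12)
#' @param seed RNG seed
#' @return object of class `histology_phantom`: `image` ([field_image()]),
#'   logical truth masks `truth_septa`, `truth_vessels`, `truth_exudates`,
#'   and the parameters
#' @export
make_histology_phantom <- function(n_cells = 45L, wall_px = 7L,
                                   n_vessels = 2L, vessel_r = c(25, 50),
                                   n_exudates = 5L, exudate_area = c(100, 900),
                                   mean_tissue = 90, mean_air = 220,
                                   noise_sd = 12, seed = 1L) {
  stopifnot(n_cells >= 2L, wall_px >= 1L, wall_px %% 2L == 1L,
            n_vessels >= 0L, n_exudates >= 0L,
            length(exudate_area) == 2L, exudate_area[1] >= 1,
            diff(exudate_area) >= 0, mean_tissue < mean_air, noise_sd >= 0)
  set.seed(seed)
  npx <- FIELD_PX
  sx <- runif(n_cells, 0, npx); sy <- runif(n_cells, 0, npx)
  best <- matrix(Inf, npx, npx)
  id <- matrix(0L, npx, npx)
  yc <- seq_len(npx) - 0.5; xc <- seq_len(npx) - 0.5
  for (i in seq_len(n_cells)) {
    d2 <- outer((yc - sy[i])^2, (xc - sx[i])^2, "+")
    upd <- d2 < best
    best[upd] <- d2[upd]
    id[upd] <- i
  }
  ridge <- id != id[c(2:npx, npx), ] | id != id[, c(2:npx, npx)]
  walls <- EBImage::dilate(ridge * 1, EBImage::makeBrush(wall_px, "disc")) > 0.5

  vessels <- matrix(FALSE, npx, npx)
  for (v in seq_len(n_vessels)) {
    r <- runif(1, vessel_r[1], vessel_r[2])
    cx <- runif(1, r + 2, npx - r - 2); cy <- runif(1, r + 2, npx - r - 2)
    vessels <- vessels | outer((yc - cy)^2, (xc - cx)^2, "+") <= r^2
  }
  septa <- walls & !vessels

  occupied <- EBImage::dilate((walls | vessels) * 1,
                              EBImage::makeBrush(5, "box")) > 0.5
  exudates <- matrix(FALSE, npx, npx)
  disc_count <- function(r) {
    k <- ceiling(r)
    sum(outer((-k:k)^2, (-k:k)^2, "+") <= r^2)
  }
  for (e in seq_len(n_exudates)) {
    target <- runif(1, exudate_area[1], exudate_area[2])
    r <- sqrt(target / pi)
    while (disc_count(r) < exudate_area[1]) r <- r + 0.05
    while (disc_count(r) > exudate_area[2]) r <- r - 0.05
    placed <- FALSE
    for (try in 1:500) {
      cx <- runif(1, r + 3, npx - r - 3); cy <- runif(1, r + 3, npx - r - 3)
      disc <- outer((yc - cy)^2, (xc - cx)^2, "+") <= r^2
      halo <- EBImage::dilate(disc * 1, EBImage::makeBrush(5, "box")) > 0.5
      if (!any(halo & (occupied | exudates))) {
        exudates <- exudates | disc
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_lungmorph("could not place exudate without contact; relax parameters",
                     "lungmorph_generation_error")
  }

  dark <- septa | vessels | exudates
  img <- matrix(mean_air, npx, npx)
  img[dark] <- mean_tissue
  if (noise_sd > 0) img <- img + rnorm(npx * npx, 0, noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  structure(list(
    image = field_image(img, source_id = sprintf("phantom[seed=%d]", seed)),
    truth_septa = septa, truth_vessels = vessels, truth_exudates = exudates,
    params = list(n_cells = n_cells, wall_px = wall_px, n_vessels = n_vessels,
                  vessel_r = vessel_r, n_exudates = n_exudates,
                  exudate_area = exudate_area, mean_tissue = mean_tissue,
                  mean_air = mean_air, noise_sd = noise_sd, seed = seed)),
    class = "histology_phantom")
}

#' @export
print.histology_phantom <- function(x, ...) {
  cat(sprintf("<histology_phantom> seed %d: septa %.3f, %d vessel px, %d exudate px\n",
              x$params$seed, mean(x$truth_septa), sum(x$truth_vessels),
              sum(x$truth_exudates)))
  invisible(x)
}

#' Write a wallpaper or phantom as PNG plus a JSON sidecar
#'
#' @param x a `wallpaper` or `histology_phantom`
#' @param path output PNG path; the sidecar takes the same stem with
#'   extension .json
#' @return `path`, invisibly
#' @export
write_synthetic <- function(x, path) {
  side <- sub("\\.png$", ".json", path, ignore.case = TRUE)
  if (inherits(x, "wallpaper")) {
    png::writePNG(x$image / 255, path)
    jsonlite::write_json(list(kind = "wallpaper", seed = x$spec$seed,
                              tile = x$spec$tile, width = x$spec$width,
                              sum_area = x$spec$sum_area,
                              sum_perimeter = x$spec$sum_perimeter,
                              vv_sep_theory = x$vv_sep_theory,
                              lm_theory_px = x$lm_theory_px,
                              lm_theory_um = x$lm_theory_um),
                         side, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "histology_phantom")) {
    png::writePNG(x$image$pixels / 255, path)
    jsonlite::write_json(x$params, side, auto_unbox = TRUE, digits = NA)
  } else {
    stop_lungmorph("unsupported object", "lungmorph_usage_error")
  }
  invisible(path)
}
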