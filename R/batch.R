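#' Configure a batch run
#'
#' One threshold applies per batch, honouring the workflow contract that
#' the tissue/air threshold is set only on the first image of a batch
#' (valid when all images of a batch share staining and microscope
#' settings). ROI files are matched by filename stem: `field.png` pairs
#' with `field.rois.json` (or `field.rois.png`) in `roi_dir`.
#'
#' @param input_dir directory of PNG fields
#' @param output_dir directory for CSVs, QC overlays and the log
#' @param roi_dir directory of ROI files (default `input_dir`)
#' @param threshold integer threshold in \[0, 255\], or `"otsu-first"` to
#'   suggest one from the first image (alphabetical) and apply it batch-wide
#' @param scale_um_per_px physical scale (default 0.735)
#' @param d_um unit test-line length (default 104)
#' @param binary treat inputs as already-binary masks and skip exudate
#'   filtering / cleaning (synthetic ground-truth mode)
#' @param qc write per-field QC overlay PNGs (default FALSE)
#' @param subject_pattern regex with one capture group extracting the
#'   subject id from the file stem; stems without a match form one subject
#'   each (default `"^(.*?)_"` — everything before the first underscore)
#' @return object of class `batch_config`
#' @export
batch_config <- function(input_dir, output_dir, roi_dir = input_dir,
                         threshold = "otsu-first",
                         scale_um_per_px = DEFAULT_SCALE, d_um = 104,
                         binary = FALSE, qc = FALSE,
                         subject_pattern = "^(.*?)_") {
  if (!is.character(threshold) || threshold != "otsu-first") {
    if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
      stop_lungmorph("threshold must be in [0, 255] or \"otsu-first\"",
                     "lungmorph_usage_error")
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 roi_dir = roi_dir, threshold = threshold,
                 scale_um_per_px = scale_um_per_px, d_um = d_um,
                 binary = isTRUE(binary), qc = isTRUE(qc),
                 subject_pattern = subject_pattern),
            class = "batch_config")
}

subject_of <- function(stem, pattern) {
  m <- regmatches(stem, regexec(pattern, stem))[[1]]
  if (length(m) >= 2L && nzchar(m[2])) m[2] else stem
}

#' Process a folder of lung fields
#'
#' Runs the counting pipeline on every PNG field in the input directory and
#' writes `fields.csv` (one row per field: counts and threshold used),
#' `subjects.csv` (per-subject ratio-of-sums read-outs), a plain-text log
#' recording every automatic exudate removal and manual exclusion, and,
#' when enabled, per-field QC overlays (edge image and test system over the
#' original field, manual selections blanked). Deterministic given the
#' configuration; per-field failures are logged and skipped.
#'
#' @param config a [batch_config()]
#' @return object of class `batch_report`: the per-field and per-subject
#'   data frames, the threshold used, and the number of failed fields
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  paths <- sort(list.files(config$input_dir, pattern = "\\.png$",
                           ignore.case = TRUE, full.names = TRUE))
  paths <- paths[!grepl("\\.rois\\.png$", paths, ignore.case = TRUE)]
  if (length(paths) == 0L)
    stop_lungmorph(sprintf("no PNG fields found in '%s'", config$input_dir),
                   "lungmorph_usage_error")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  t_used <- config$threshold
  if (identical(t_used, "otsu-first"))
    t_used <- suggest_threshold(load_field(paths[1], config$scale_um_per_px))

  ts <- test_system(config$scale_um_per_px, d_um = config$d_um)
  log_lines <- c(sprintf("batch threshold: %d", t_used))
  rows <- list()
  failed <- 0L
  for (p in paths) {
    stem <- sub("\\.png$", "", basename(p), ignore.case = TRUE)
    roi_json <- file.path(config$roi_dir, paste0(stem, ".rois.json"))
    roi_png <- file.path(config$roi_dir, paste0(stem, ".rois.png"))
    roi_path <- if (file.exists(roi_json)) roi_json else roi_png
    res <- tryCatch({
      img <- load_field(p, config$scale_um_per_px)
      rois <- load_roiset(roi_path)
      fc <- count_field(img, rois, t_used, ts, binary = config$binary)
      log_lines <- c(log_lines, sprintf(
        "%s: %d auto-removed exudate(s), %d non-parenchyma + %d manual exudate polygon(s)",
        stem, fc$n_auto_exudates, length(rois$non_parenchyma),
        length(rois$manual_exudates)))
      if (config$qc)
        write_qc_overlay(img, rois, t_used, ts,
                         file.path(config$output_dir, paste0(stem, ".qc.png")),
                         binary = config$binary)
      as.data.frame(fc)
    }, lungmorph_error = function(e) {
      log_lines <<- c(log_lines, sprintf("%s: FAILED (%s)", stem,
                                         conditionMessage(e)))
      failed <<- failed + 1L
      NULL
    })
    if (!is.null(res)) rows[[stem]] <- res
  }
  if (length(rows) == 0L)
    stop_lungmorph("every field failed to process", "lungmorph_usage_error")
  fields <- do.call(rbind, rows)
  rownames(fields) <- NULL

  stems <- sub("\\.png$", "", fields$source_id, ignore.case = TRUE)
  subj <- vapply(stems, subject_of, character(1),
                 pattern = config$subject_pattern)
  groups <- split(fields, subj)
  subjects <- do.call(rbind, lapply(names(groups), function(s)
    as.data.frame(subject_summary(groups[[s]], subject_id = s,
                                  d = config$d_um))))
  rownames(subjects) <- NULL
  subjects <- subjects[order(subjects$subject_id), , drop = FALSE]

  write.csv(fields, file.path(config$output_dir, "fields.csv"),
            row.names = FALSE)
  write.csv(subjects, file.path(config$output_dir, "subjects.csv"),
            row.names = FALSE)
  writeLines(log_lines, file.path(config$output_dir, "batch.log"))
  structure(list(fields = fields, subjects = subjects, threshold = t_used,
                 n_failed = failed, output_dir = config$output_dir),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("<batch_report> %d field(s), %d subject(s), threshold %d, %d failure(s)\n",
              nrow(x$fields), nrow(x$subjects), x$threshold, x$n_failed))
  cat(sprintf("  outputs in %s\n", x$output_dir))
  invisible(x)
}

#' QC overlay: segmentation and test system over the original field
#'
#' Writes an RGB PNG with the original field as background, the clean-mask
#' edge in blue, the test lines and grid points in yellow, and manual
#' selections blanked to white — the per-field visual check of the
#' segmentation.
#'
#' @param img a [field_image()]
#' @param rois a [roi_set()]
#' @param t threshold
#' @param ts a [test_system()]
#' @param path output PNG
#' @param binary skip cleaning (synthetic mode)
#' @return `path`, invisibly
#' @export
write_qc_overlay <- function(img, rois, t, ts, path, binary = FALSE) {
  raw <- apply_threshold(img, t)
  clean <- if (binary) binary_mask(raw$tissue, "clean") else
    clean_mask(apply_manual_selections(remove_auto_exudates(raw)$mask, rois))
  edge <- extract_edges(clean)$edge
  sel <- roi_mask(rois, "non_parenchyma") | roi_mask(rois, "manual_exudates")
  base <- img$pixels / 255
  rgb_arr <- array(rep(base, 3), dim = c(nrow(base), ncol(base), 3))
  paint <- function(arr, mask, col) {
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[mask] <- col[ch]
      arr[, , ch] <- plane
    }
    arr
  }
  rgb_arr <- paint(rgb_arr, sel, c(1, 1, 1))
  lines <- matrix(FALSE, nrow(base), ncol(base))
  lines[ts$h_rows, ts$frame_span] <- TRUE
  lines[ts$frame_span, ts$v_cols] <- TRUE
  rgb_arr <- paint(rgb_arr, lines, c(0.9, 0.85, 0.1))
  rgb_arr <- paint(rgb_arr, edge, c(0.1, 0.3, 1))
  png::writePNG(rgb_arr, path)
  invisible(path)
}

#' Run the synthetic validation experiment
#'
#' Regenerates the artificial-image validation: `n_images` wallpaper images
#' spanning a range of densities, `fields_per_image` randomly sampled
#' 680x680 fields each, counted with the binary-input pipeline variant
#' (the image is already a binary mask, so exudate filtering and cleaning
#' are skipped). Per-image VVsep and Lm are ratio-of-sums aggregates over
#' the sampled fields and are compared with the exact theoretical values by
#' regression against identity and Bland-Altman on relative differences
#' (computed minus theoretical over the pairwise average, in percent).
#'
#' @param n_images number of wallpaper images (>= 3; default 11). Up to 11
#'   distinct density specs are available; `n_images` takes the first
#'   `n_images` of them.
#' @param fields_per_image sampled fields per image (default 20)
#' @param seed base seed controlling placement and sampling
#' @param specs optional list of [wallpaper_spec()]s overriding the default
#'   densities (length >= `n_images`)
#' @return object of class `validation_experiment`: per-image table and an
#'   [agreement_result] for VVsep and for Lm
#' @export
run_validation_experiment <- function(n_images = 11L, fields_per_image = 20L,
                                      seed = 1L, specs = NULL) {
  if (n_images < 3L)
    stop_lungmorph("need at least 3 images for regression", "lungmorph_usage_error")
  if (is.null(specs)) specs <- default_wallpaper_specs(seed = seed)
  if (n_images > length(specs))
    stop_lungmorph(sprintf("only %d density specs available", length(specs)),
                   "lungmorph_usage_error")
  specs <- specs[seq_len(n_images)]
  ts <- test_system()
  rois <- roi_set()
  per_image <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    wp <- make_wallpaper(specs[[i]])
    fields <- sample_fields(wp, n = fields_per_image, seed = seed + 5000L + i)
    counts <- lapply(fields, function(f)
      count_field(f, rois, t = 128, ts = ts, binary = TRUE))
    tab <- counts_table(counts)
    per_image[[i]] <- data.frame(
      image = i,
      vv_sep_theory = wp$vv_sep_theory, lm_theory_um = wp$lm_theory_um,
      vv_sep_computed = vv_sep(tab), lm_computed_um = lm_intercept(tab),
      sum_p_ref = sum(tab$p_ref), sum_p_sep = sum(tab$p_sep),
      sum_i = sum(tab$i_total))
  }
  tab <- do.call(rbind, per_image)
  structure(list(
    per_image = tab,
    vv_sep = agreement_result(tab$vv_sep_theory, tab$vv_sep_computed, "VVsep"),
    lm = agreement_result(tab$lm_theory_um, tab$lm_computed_um, "Lm"),
    n_images = n_images, fields_per_image = fields_per_image, seed = seed),
    class = "validation_experiment")
}

#' @export
print.validation_experiment <- function(x, ...) {
  cat(sprintf("<validation_experiment> %d images x %d fields (seed %d)\n",
              x$n_images, x$fields_per_image, x$seed))
  print(x$vv_sep)
  print(x$lm)
  invisible(x)
}
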