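#' Septal volume density
#'
#' VVsep = sum(Psep) / sum(Pref): the fraction of the reference
#' (parenchymal) volume occupied by alveolar septa, aggregated across
#' fields as a ratio of sums, never as a mean of per-field ratios.
#'
#' @param counts a `field_counts`, list of them, or a data.frame with
#'   columns `p_ref` and `p_sep`
#' @return dimensionless density in \[0, 1\]
#' @export
vv_sep <- function(counts) {
  tab <- counts_table(counts)
  s_ref <- sum(tab$p_ref)
  if (s_ref <= 0)
    stop_lungmorph("undefined read-out: no reference points (all fields non-parenchymal)",
                   "lungmorph_readout_error")
  sum(tab$p_sep) / s_ref
}

#' Mean linear intercept of the airspaces
#'
#' Lm = 2 * d * (sum(Pref) - sum(Psep)) / sum(I), in micrometres: the
#' average airspace chord along the test lines, the standard read-out for
#' alveolar size (increases with alveolar enlargement).
#'
#' @inheritParams vv_sep
#' @param d unit test-line length per grid point in um (default 104)
#' @return Lm in um; 0 when there are no air points and no intersections
#' @export
lm_intercept <- function(counts, d = 104) {
  stopifnot(d > 0)
  tab <- counts_table(counts)
  air <- sum(tab$p_ref) - sum(tab$p_sep)
  s_i <- sum(tab$i_total)
  if (s_i == 0) {
    if (air == 0) return(0)
    stop_lungmorph("undefined read-out: air points present but no intersections",
                   "lungmorph_readout_error")
  }
  2 * d * air / s_i
}

#' Mean transsectional wall length
#'
#' Lmw = 2 * d * sum(Psep) / sum(I): the wall analogue of the mean linear
#' intercept (mean septal chord along the test lines). The identity
#' Lm + Lmw = 2 * d * sum(Pref) / sum(I) holds exactly.
#'
#' @inheritParams lm_intercept
#' @return Lmw in um; 0 when there are no septal points and no intersections
#' @export
lmw <- function(counts, d = 104) {
  stopifnot(d > 0)
  tab <- counts_table(counts)
  s_sep <- sum(tab$p_sep)
  s_i <- sum(tab$i_total)
  if (s_i == 0) {
    if (s_sep == 0) return(0)
    stop_lungmorph("undefined read-out: septal points present but no intersections",
                   "lungmorph_readout_error")
  }
  2 * d * s_sep / s_i
}

#' Airspace surface density
#'
#' SVair = 2 * sum(I) / (d * sum(Pref)): surface area of the air-tissue
#' interface per unit reference volume, with total test-line length
#' L = d * sum(Pref).
#'
#' @inheritParams lm_intercept
#' @return surface density in 1/um
#' @export
sv_air <- function(counts, d = 104) {
  stopifnot(d > 0)
  tab <- counts_table(counts)
  s_ref <- sum(tab$p_ref)
  if (s_ref <= 0)
    stop_lungmorph("undefined read-out: no reference points",
                   "lungmorph_readout_error")
  2 * sum(tab$i_total) / (d * s_ref)
}

#' Absolute septal volume and airspace surface
#'
#' Converts densities to absolute quantities when a total lung volume is
#' available: V_sep = VVsep * V_lung and S_air = SVair * V_lung.
#'
#' @param summary a [subject_summary()]
#' @param lung_volume total lung volume in um^3
#' @return list with `v_sep` (um^3) and `s_air` (um^2)
#' @export
absolute_quantities <- function(summary, lung_volume) {
  stopifnot(inherits(summary, "subject_summary"))
  if (!is.numeric(lung_volume) || length(lung_volume) != 1L || lung_volume <= 0)
    stop_lungmorph("lung_volume must be a positive number", "lungmorph_readout_error")
  list(v_sep = summary$vv_sep * lung_volume,
       s_air = summary$sv_air * lung_volume)
}

#' Aggregate fields of one subject into the morphometric read-outs
#'
#' Per-subject aggregation is ratio-of-sums across all counted fields.
#'
#' @inheritParams lm_intercept
#' @param subject_id identifier carried into reports
#' @param lung_volume optional total lung volume (um^3) for absolute
#'   quantities
#' @return object of class `subject_summary` with the count sums, `vv_sep`,
#'   `lm` (um), `lmw` (um), `sv_air` (1/um) and, when volume is given,
#'   `v_sep` and `s_air`
#' @export
subject_summary <- function(counts, subject_id = "subject", d = 104,
                            lung_volume = NULL) {
  tab <- counts_table(counts)
  out <- structure(list(
    subject_id = as.character(subject_id),
    n_fields = nrow(tab),
    sum_p_nonpar = sum(tab$p_nonpar), sum_p_ref = sum(tab$p_ref),
    sum_p_sep = sum(tab$p_sep), sum_i = sum(tab$i_total),
    vv_sep = vv_sep(tab), lm = lm_intercept(tab, d), lmw = lmw(tab, d),
    sv_air = sv_air(tab, d), v_sep = NA_real_, s_air = NA_real_),
    class = "subject_summary")
  if (!is.null(lung_volume)) {
    abs_q <- absolute_quantities(out, lung_volume)
    out$v_sep <- abs_q$v_sep
    out$s_air <- abs_q$s_air
  }
  out
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf("<subject_summary> %s (%d fields)\n", x$subject_id, x$n_fields))
  cat(sprintf("  sums: Pnonpar %d, Pref %d, Psep %d, I %d\n",
              x$sum_p_nonpar, x$sum_p_ref, x$sum_p_sep, x$sum_i))
  cat(sprintf("  VVsep %.4f | Lm %.1f um | Lmw %.1f um | SVair %.5f /um\n",
              x$vv_sep, x$lm, x$lmw, x$sv_air))
  if (!is.na(x$v_sep))
    cat(sprintf("  Vsep %.4g um^3 | Sair %.4g um^2\n", x$v_sep, x$s_air))
  invisible(x)
}

#' @export
as.data.frame.subject_summary <- function(x, ...) {
  data.frame(subject_id = x$subject_id, n_fields = x$n_fields,
             sum_p_nonpar = x$sum_p_nonpar, sum_p_ref = x$sum_p_ref,
             sum_p_sep = x$sum_p_sep, sum_i = x$sum_i,
             vv_sep = x$vv_sep, lm = x$lm, lmw = x$lmw, sv_air = x$sv_air,
             v_sep = x$v_sep, s_air = x$s_air, stringsAsFactors = FALSE)
}
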