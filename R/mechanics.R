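#' Per-contraction shortening and fluorescence metrics
#'
#' Computes, for each activation event, the normalized maximum shortening
#' `dL/L = 100 * (length_onset - length_min) / length_onset` (percent; the
#' minimum length within the event window, regardless of whether it
#' coincides with peak fluorescence) and the fluorescence rise
#' `dF/F = 100 * (f_max - f_onset) / f_onset` (percent). Lengthening events
#' (negative dL/L) are retained and flagged, not clipped.
#'
#' @param events data.frame with `f_onset`, `f_max`, `length_onset_um`,
#'   `length_min_um` (plus any grouping columns, carried through).
#' @return the input with added columns `dll_pct`, `dff_pct`,
#'   `lengthening` (logical).
#' @examples
#' contraction_metrics(data.frame(f_onset = 50, f_max = 150,
#'                                length_onset_um = 100,
#'                                length_min_um = 75))[, c("dll_pct", "dff_pct")]
#' @export
contraction_metrics <- function(events) {
  stopifnot_data(all(events$f_onset > 0),
                 "f_onset must be positive")
  stopifnot_data(all(events$length_onset_um > 0),
                 "onset length must be positive")
  events$dll_pct <- 100 * (events$length_onset_um - events$length_min_um) /
    events$length_onset_um
  events$dff_pct <- 100 * (events$f_max - events$f_onset) / events$f_onset
  events$lengthening <- events$dll_pct < 0
  events
}

#' Aggregate contraction metrics by muscle, hemisegment, and/or phase
#'
#' @param metrics output of [contraction_metrics()].
#' @param by character vector of grouping columns, any of `"muscle"`,
#'   `"segment"`, `"phase"` (or other columns present).
#' @return data.frame with one row per group: grouping columns, `n`,
#'   `mean_dll_pct`, `sd_dll_pct`, `mean_dff_pct`, `sd_dff_pct`. Empty
#'   groups do not occur (groups are formed from the data); group counts
#'   sum to the number of contractions.
#' @export
aggregate_metrics <- function(metrics, by = c("muscle", "segment", "phase")) {
  stopifnot_data(all(by %in% names(metrics)),
                 "grouping columns missing from metrics")
  key <- interaction(metrics[by], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    g <- metrics[key == k, ]
    lab <- strsplit(k, "\r", fixed = TRUE)[[1]]
    out <- as.data.frame(as.list(stats::setNames(lab, by)),
                         stringsAsFactors = FALSE)
    out$n <- nrow(g)
    out$mean_dll_pct <- mean(g$dll_pct)
    out$sd_dll_pct <- if (nrow(g) >= 2) stats::sd(g$dll_pct) else NA_real_
    out$mean_dff_pct <- mean(g$dff_pct)
    out$sd_dff_pct <- if (nrow(g) >= 2) stats::sd(g$dff_pct) else NA_real_
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Correlation between fluorescence rise and shortening
#'
#' Pearson correlation over contractions between dF/F and shortening, under
#' both variable codings: `r_shortening` correlates dF/F with positive
#' shortening (dL/L), `r_signed_length` correlates dF/F with the signed
#' length change (negative when the muscle shortens), so
#' `r_signed_length = -r_shortening`. Fluorescence that rises with stronger
#' shortening therefore gives a positive `r_shortening` and a negative
#' `r_signed_length` (the coding under which reported couplings in this system are negative).
#'
#' @param metrics output of [contraction_metrics()] (>= 3 rows).
#' @return list `r_shortening`, `r_signed_length`, `n`. Zero variance in
#'   either variable warns (`ecdysim_undefined_correlation`) and returns
#'   NAs.
#' @export
shortening_fluorescence_correlation <- function(metrics) {
  stopifnot_data(nrow(metrics) >= 3, "need >= 3 contractions")
  if (stats::var(metrics$dff_pct) == 0 || stats::var(metrics$dll_pct) == 0) {
    val <- signal_undefined("zero variance: correlation undefined",
                            "ecdysim_undefined_correlation")
    return(list(r_shortening = val, r_signed_length = val,
                n = nrow(metrics)))
  }
  r <- stats::cor(metrics$dff_pct, metrics$dll_pct)
  list(r_shortening = r, r_signed_length = -r, n = nrow(metrics))
}
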