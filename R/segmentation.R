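#' Segment activation onsets into bouts and inter-bout intervals
#'
#' A bout is a maximal run of activation onsets in which consecutive
#' onset-bearing frames are separated by fewer than `min_gap` onset-free
#' frames; runs separated by `min_gap` or more onset-free frames are split.
#' The rule operates on onsets only: an event may remain above baseline
#' across a gap without joining bouts. Bout extents are half-open
#' `[first onset, last onset + 1)`.
#'
#' @param onsets 0-based activation onset frames (any order; duplicates
#'   allowed - several muscles may activate in one frame).
#' @param min_gap minimum number of onset-free frames defining an
#'   inter-bout interval.
#' @param n_frames optional recording length; when given, leading and
#'   trailing rest spans are included in the returned intervals.
#' @return list with `bouts` (data.frame `bout_id`, `start_frame`,
#'   `end_frame`) and `interbout` (data.frame `start_frame`, `end_frame`),
#'   both half-open. No onsets yield zero bouts (and, if `n_frames` is
#'   given, one full-length rest interval).
#' @examples
#' segment_bouts(c(3, 4, 5, 8, 9))$bouts   # two bouts: [3,6) and [8,10)
#' segment_bouts(c(3, 4, 6))$bouts         # one bout: [3,7)
#' @export
segment_bouts <- function(onsets, min_gap = 2, n_frames = NULL) {
  stopifnot_config(min_gap >= 1, "min_gap must be >= 1")
  if (length(onsets) == 0) {
    interbout <- if (is.null(n_frames)) {
      data.frame(start_frame = integer(0), end_frame = integer(0))
    } else {
      data.frame(start_frame = 0L, end_frame = as.integer(n_frames))
    }
    return(list(bouts = data.frame(bout_id = integer(0),
                                   start_frame = integer(0),
                                   end_frame = integer(0)),
                interbout = interbout))
  }
  stopifnot_data(all(onsets >= 0), "onsets must be non-negative frames")
  u <- sort(unique(as.integer(onsets)))
  # split where the count of onset-free frames between successive onsets
  # reaches min_gap: frames u[i]+1 .. u[i+1]-1 are onset-free
  gaps <- diff(u) - 1L
  brk <- which(gaps >= min_gap)
  starts <- u[c(1L, brk + 1L)]
  ends <- u[c(brk, length(u))] + 1L
  bouts <- data.frame(bout_id = seq_along(starts),
                      start_frame = starts, end_frame = ends)
  ib_start <- ends[-length(ends)]
  ib_end <- starts[-1]
  interbout <- data.frame(start_frame = ib_start, end_frame = ib_end)
  if (!is.null(n_frames)) {
    if (starts[1] > 0) {
      interbout <- rbind(data.frame(start_frame = 0L,
                                    end_frame = starts[1]), interbout)
    }
    if (ends[length(ends)] < n_frames) {
      interbout <- rbind(interbout,
                         data.frame(start_frame = ends[length(ends)],
                                    end_frame = as.integer(n_frames)))
    }
  }
  rownames(interbout) <- NULL
  list(bouts = bouts, interbout = interbout)
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. A zero mean
#' makes the CV undefined: the function warns with class
#' `ecdysim_undefined_cv` and returns `NA`.
#'
#' @param values numeric vector, length >= 2.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 3))  # 70.71068
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) {
    abort_ecdysim("need at least 2 values for a CV",
                  "ecdysim_insufficient_data")
  }
  m <- mean(values)
  if (m == 0) {
    return(signal_undefined("mean is zero: CV undefined",
                            "ecdysim_undefined_cv"))
  }
  100 * stats::sd(values) / m
}

#' Per-phase variability summary of bouts
#'
#' Groups bouts by phase and summarizes bout durations, inter-bout interval
#' durations, and per-animal bout counts with mean, sample SD, and CV.
#'
#' @param bouts data.frame with columns `phase`, `start_frame`, `end_frame`,
#'   and (for the count summary) `animal_id`.
#' @param interbout optional data.frame with columns `phase`, `start_frame`,
#'   `end_frame` of inter-bout intervals.
#' @return data.frame with one row per phase x metric: columns `phase`,
#'   `metric` (`bout_duration`, `interbout_duration`, `bout_count`), `n`,
#'   `mean`, `sd`, `cv_pct`.
#' @export
summarize_phases <- function(bouts, interbout = NULL) {
  stopifnot_data(!is.null(bouts$phase) && !any(is.na(bouts$phase)),
                 "every bout must carry a phase label")
  one <- function(phase, metric, values) {
    if (length(values) == 0) return(NULL)
    cv <- if (length(values) >= 2 && mean(values) != 0) {
      100 * stats::sd(values) / mean(values)
    } else NA_real_
    data.frame(phase = phase, metric = metric, n = length(values),
               mean = mean(values),
               sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
               cv_pct = cv, stringsAsFactors = FALSE)
  }
  out <- list()
  for (ph in unique(bouts$phase)) {
    b <- bouts[bouts$phase == ph, ]
    out[[length(out) + 1L]] <-
      one(ph, "bout_duration", b$end_frame - b$start_frame)
    if (!is.null(interbout) && !is.null(interbout$phase)) {
      ib <- interbout[interbout$phase == ph, ]
      out[[length(out) + 1L]] <-
        one(ph, "interbout_duration", ib$end_frame - ib$start_frame)
    }
    if (!is.null(b$animal_id)) {
      counts <- as.numeric(table(b$animal_id))
      out[[length(out) + 1L]] <- one(ph, "bout_count", counts)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
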