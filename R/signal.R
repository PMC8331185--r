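#' Normalize a fluorescence trace to baseline (dF/F)
#'
#' F0 is the mean of the first `f0_frames` values; the output is
#' `(F - F0) / F0`.
#'
#' @param values numeric fluorescence trace.
#' @param f0_frames number of leading frames defining the baseline.
#' @return unitless dF/F trace of the same length.
#' @examples
#' delta_f_over_f(c(rep(10, 50), 15))[51]  # 0.5
#' @export
delta_f_over_f <- function(values, f0_frames = 50) {
  stopifnot_data(all(is.finite(values)), "trace must be finite")
  if (length(values) < f0_frames) {
    abort_ecdysim("trace shorter than f0_frames", "ecdysim_insufficient_data")
  }
  f0 <- mean(values[seq_len(f0_frames)])
  if (f0 == 0) {
    abort_ecdysim("F0 is zero: degenerate baseline",
                  "ecdysim_degenerate_baseline")
  }
  (values - f0) / f0
}

#' Centered moving average with shrunken edge windows
#'
#' Each output value is the mean of the input over a window centered on that
#' frame; near the edges the window shrinks symmetrically-as-possible rather
#' than padding, so no data are invented and length is preserved.
#'
#' @param values numeric trace.
#' @param window window width in frames.
#' @return smoothed trace, same length.
#' @export
moving_average <- function(values, window = 100) {
  stopifnot_config(window >= 1, "window must be >= 1")
  n <- length(values)
  if (window > n) {
    abort_ecdysim("window longer than trace", "ecdysim_insufficient_data")
  }
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect peaks in a trace
#'
#' Local maxima above a threshold, at least `min_separation` frames apart.
#' The default threshold is `k` median absolute deviations above a running
#' median baseline (window `baseline_window`), per the package's default
#' peak policy; an absolute threshold can be supplied instead.
#'
#' Greedy selection by descending height enforces the separation, so the
#' detector is deterministic and idempotent.
#'
#' @param values numeric trace.
#' @param threshold either a single absolute value, or `NULL` to use the
#'   running-median MAD rule.
#' @param k MAD multiplier for the adaptive threshold.
#' @param baseline_window running-median window (frames; forced odd).
#' @param min_separation minimum frame distance between reported peaks.
#' @return integer vector of strictly increasing 0-based peak frames, with
#'   attribute `threshold_used` (per-frame numeric threshold).
#' @export
detect_peaks <- function(values, threshold = NULL, k = 3,
                         baseline_window = 201, min_separation = 1) {
  stopifnot_data(all(is.finite(values)), "trace must be finite")
  stopifnot_config(min_separation >= 1, "min_separation must be >= 1")
  n <- length(values)
  if (is.null(threshold)) {
    w <- min(baseline_window, if (n %% 2 == 1) n else n - 1)
    if (w < 3) {
      base <- rep(stats::median(values), n)
    } else {
      if (w %% 2 == 0) w <- w - 1
      base <- stats::runmed(values, w)
    }
    thr <- base + k * stats::mad(values - base)
  } else {
    thr <- rep(threshold, n)
  }
  if (n < 3) {
    out <- integer(0)
    attr(out, "threshold_used") <- thr
    return(out)
  }
  mid <- 2:(n - 1)
  is_peak <- values[mid] > values[mid - 1] & values[mid] >= values[mid + 1] &
    values[mid] > thr[mid]
  cand <- mid[is_peak]
  # greedy by height, enforce separation
  cand <- cand[order(-values[cand], cand)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(kept - p) >= min_separation)) kept <- c(kept, p)
  }
  out <- sort(kept) - 1L  # 0-based
  attr(out, "threshold_used") <- thr
  out
}

#' Build a binary raster from peak trains
#'
#' @param trains named list of 0-based peak-frame vectors (each strictly
#'   increasing).
#' @param n_frames raster width.
#' @return binary matrix (train x frame) with rownames in input order.
#' @export
build_raster <- function(trains, n_frames) {
  mat <- matrix(0L, nrow = length(trains), ncol = n_frames,
                dimnames = list(names(trains), NULL))
  for (i in seq_along(trains)) {
    tr <- trains[[i]]
    stopifnot_data(!is.unsorted(tr, strictly = TRUE),
                   "peak frames must be strictly increasing")
    stopifnot_data(length(tr) == 0 || (min(tr) >= 0 && max(tr) < n_frames),
                   "peak frame out of range")
    mat[i, tr + 1L] <- 1L
  }
  mat
}

#' Plot a peak raster
#'
#' @param raster binary matrix from [build_raster()].
#' @param fps frames per second (x axis in seconds).
#' @param ... passed to [graphics::image()].
#' @export
plot_raster <- function(raster, fps = 2, ...) {
  graphics::image(x = (seq_len(ncol(raster)) - 1) / fps,
                  y = seq_len(nrow(raster)),
                  z = t(raster), col = c("white", "black"),
                  xlab = "time (s)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(raster)), labels = rownames(raster),
                 las = 2, cex.axis = 0.7)
}

#' Pearson correlation between two peak trains
#'
#' Each train is binarized over `n_frames`, dilated by `tolerance` frames on
#' each side, and the Pearson correlation of the two indicator vectors is
#' returned. A zero-variance indicator (no peaks, or peaks everywhere after
#' dilation) is an undefined correlation: the function warns with class
#' `ecdysim_undefined_correlation` and returns `NA`.
#'
#' @param train_a,train_b 0-based strictly increasing peak frames.
#' @param n_frames number of frames spanned.
#' @param tolerance dilation half-width (frames).
#' @return Pearson r in `[-1, 1]`, or NA with a classed warning.
#' @export
peak_correlation <- function(train_a, train_b, n_frames, tolerance = 0) {
  stopifnot_config(n_frames > 1, "n_frames must be > 1")
  ind <- function(train) {
    v <- rep(0L, n_frames)
    if (length(train) > 0) {
      stopifnot_data(min(train) >= 0 && max(train) < n_frames,
                     "peak frame out of range")
      idx <- unique(unlist(lapply(train, function(p)
        max(0, p - tolerance):min(n_frames - 1, p + tolerance))))
      v[idx + 1L] <- 1L
    }
    v
  }
  a <- ind(train_a)
  b <- ind(train_b)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    return(signal_undefined("zero-variance peak indicator: correlation undefined",
                            "ecdysim_undefined_correlation"))
  }
  stats::cor(a, b)
}

#' Assign pre-ecdysis events to early/mid/late epochs
#'
#' Partitions `[p0_start, p1_onset)` into bins (tertiles by default) and
#' assigns each event by its frame, half-open: an event exactly on a
#' boundary belongs to the later bin. Events at or after `p1_onset` are
#' excluded; their count is returned as attribute `n_excluded` along with a
#' warning.
#'
#' @param frames 0-based event frames.
#' @param p0_start,p1_onset phase bounds (frames).
#' @param boundaries optional interior boundary frames (ascending); default
#'   tertiles of the span.
#' @return factor of bin labels (`early`, `mid`, `late`, or `bin1`... for
#'   custom boundary counts) for the retained events, with attributes
#'   `n_excluded` and `kept` (logical index into `frames`).
#' @export
bin_epochs <- function(frames, p0_start, p1_onset, boundaries = NULL) {
  stopifnot_config(p1_onset > p0_start, "p1_onset must follow p0_start")
  if (is.null(boundaries)) {
    span <- p1_onset - p0_start
    boundaries <- p0_start + span * c(1, 2) / 3
  }
  stopifnot_config(!is.unsorted(boundaries, strictly = TRUE),
                   "boundaries must be ascending")
  keep <- frames >= p0_start & frames < p1_onset
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    warning(warningCondition(
      sprintf("%d events outside [p0_start, p1_onset) excluded", n_excl),
      class = c("ecdysim_excluded_events", "ecdysim_warning")))
  }
  edges <- c(p0_start, boundaries, p1_onset)
  labels <- if (length(boundaries) == 2) c("early", "mid", "late")
            else paste0("bin", seq_len(length(edges) - 1))
  idx <- findInterval(frames[keep], edges, left.open = FALSE,
                      rightmost.closed = FALSE)
  out <- factor(labels[idx], levels = labels)
  attr(out, "n_excluded") <- n_excl
  attr(out, "kept") <- keep
  out
}
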