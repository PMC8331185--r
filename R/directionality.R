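#' Per-frame maximum-intensity-projection mode trajectory
#'
#' For each frame, the stack is projected across columns by maximum
#' intensity, yielding a profile along the body axis (length = frame
#' height); the mode is the row index of the profile maximum (ties broken
#' toward the lowest index, i.e. anterior). Frames whose profile maximum is
#' below `activity_floor` carry no mode and are flagged inactive.
#'
#' @param stack numeric array rows x cols x frames; row 0 = anterior.
#' @param activity_floor minimum profile maximum for a frame to count as
#'   active.
#' @return data.frame with `frame` (0-based), `mode_row` (0-based, NA when
#'   inactive), `active` (logical), plus attribute `height`.
#' @export
frame_mode_profile <- function(stack, activity_floor = 0) {
  stopifnot_data(length(dim(stack)) == 3 && all(dim(stack) > 0),
                 "stack must be a non-empty rows x cols x frames array")
  n <- dim(stack)[3]
  mode_row <- rep(NA_integer_, n)
  active <- logical(n)
  for (f in seq_len(n)) {
    mip <- apply(stack[, , f, drop = FALSE], 1, max)
    mx <- max(mip)
    if (mx >= activity_floor) {
      active[f] <- TRUE
      mode_row[f] <- which.max(mip) - 1L  # which.max takes the lowest index
    }
  }
  if (!any(active)) {
    warning(warningCondition("all frames inactive: empty mode trajectory",
                             class = c("ecdysim_empty_trajectory",
                                       "ecdysim_warning")))
  }
  out <- data.frame(frame = seq_len(n) - 1L, mode_row = mode_row,
                    active = active)
  attr(out, "height") <- dim(stack)[1]
  out
}

#' Classify the direction of an activity wave
#'
#' With row 0 anterior, a wave whose mode trajectory moves toward smaller
#' rows propagates posterior-to-anterior.
#'
#' `method = "slope"` (default) fits a robust Theil-Sen line (median of
#' pairwise slopes) to mode row vs frame over the active frames of the
#' window: negative slope = `P_to_A`, positive = `A_to_P`, |slope| below
#' `slope_tol` = `indeterminate`.
#'
#' `method = "mode_ratio"` reproduces the count-based rule: the threshold is
#' the median of active-frame modes, frames at the median are excluded, and
#' the ratio of modes below the median line (toward posterior, larger row
#' index) to modes above it is compared to decision bands. The rule is
#' retained for fidelity but is near-degenerate (counts around a median are
#' balanced by construction); the slope method is the default.
#'
#' @param traj data.frame from [frame_mode_profile()].
#' @param method `"slope"` or `"mode_ratio"`.
#' @param window optional half-open frame interval `c(start, end)`
#'   restricting the call to one bout.
#' @param slope_tol absolute slope (rows/frame) below which the call is
#'   indeterminate.
#' @param ratio_bands decision bands for `mode_ratio`: within the bands the
#'   call is indeterminate; above the upper band `P_to_A`; below the lower
#'   band `A_to_P`.
#' @return list of class `direction_call`: `call` (`P_to_A`, `A_to_P`, or
#'   `indeterminate`), `method`, `value` (slope or ratio), `threshold`.
#' @export
classify_direction <- function(traj, method = c("slope", "mode_ratio"),
                               window = NULL, slope_tol = 1e-9,
                               ratio_bands = c(2 / 3, 3 / 2)) {
  method <- match.arg(method)
  d <- traj[traj$active, ]
  if (!is.null(window)) {
    d <- d[d$frame >= window[1] & d$frame < window[2], ]
  }
  if (nrow(d) < 3) {
    abort_ecdysim("need >= 3 active frames to classify direction",
                  "ecdysim_insufficient_data")
  }
  if (method == "slope") {
    slope <- theil_sen_slope(d$frame, d$mode_row)
    call <- if (abs(slope) <= slope_tol) "indeterminate"
            else if (slope < 0) "P_to_A" else "A_to_P"
    out <- list(call = call, method = method, value = slope,
                threshold = slope_tol)
  } else {
    med <- stats::median(d$mode_row)
    below <- sum(d$mode_row > med)   # below the median line = posterior rows
    above <- sum(d$mode_row < med)
    ratio <- if (above == 0) Inf else below / above
    call <- if (is.finite(ratio) && ratio > ratio_bands[1] &&
                ratio < ratio_bands[2]) "indeterminate"
            else if (ratio >= ratio_bands[2]) "P_to_A" else "A_to_P"
    out <- list(call = call, method = method, value = ratio,
                threshold = ratio_bands)
  }
  class(out) <- "direction_call"
  out
}

theil_sen_slope <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    ok <- dx != 0
    slopes <- c(slopes, dy[ok] / dx[ok])
  }
  stats::median(slopes)
}

#' Fraction of bouts per phase with posterior-to-anterior calls
#'
#' @param calls character vector of per-bout calls (`P_to_A`, `A_to_P`,
#'   `indeterminate`).
#' @param phases phase label per bout.
#' @return data.frame `phase`, `n_bouts`, `frac_p_to_a`. Phases with zero
#'   bouts are omitted (with a warning if named in `levels`).
#' @export
phase_direction_summary <- function(calls, phases) {
  stopifnot_data(length(calls) == length(phases),
                 "calls and phases must align")
  out <- do.call(rbind, lapply(unique(phases), function(ph) {
    cc <- calls[phases == ph]
    data.frame(phase = ph, n_bouts = length(cc),
               frac_p_to_a = mean(cc == "P_to_A"))
  }))
  rownames(out) <- NULL
  out
}
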