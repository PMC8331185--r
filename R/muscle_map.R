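#' Hemisegmental pupal muscle map
#'
#' Builds the roster of persistent pupal body-wall muscles, one instance per
#' (label, hemisegment, side). Each muscle carries a dorso-ventral compartment
#' tag (`dorsal`, `lateral`, `ventral`) and an anterior-posterior tag derived
#' from its hemisegment (A1-A4 anterior, A5-A7 posterior; the A-P boundary
#' lies between A4 and A5). Two muscles are restricted to anterior segments:
#' M12 and M5 are absent from posterior hemisegments.
#'
#' Optionally attaches rectangular ROI geometry for frame rendering: rows
#' encode the body axis (row 0 = anterior), columns encode side x
#' dorso-ventral compartment, with one column slot per muscle within a
#' compartment.
#'
#' @param n_segments number of abdominal hemisegments to include (1-7,
#'   labelled A1..A7).
#' @param sides character vector, subset of `c("L","R")`.
#' @param with_rois logical; attach per-muscle ROI rectangles.
#' @param rows_per_segment,cols_per_slot ROI geometry (pixels) when
#'   `with_rois = TRUE`.
#' @param margin blank border (pixels) around the ROI block.
#' @return A `muscle_map`: a data.frame with columns `muscle`, `segment`,
#'   `side`, `dv`, `ap` (+ `roi_row0`, `roi_row1`, `roi_col0`, `roi_col1`,
#'   half-open pixel ranges, when `with_rois`), with attributes `segments`,
#'   `ap_boundary`, and `frame_shape` (rows, cols) when ROIs are present.
#' @examples
#' m <- make_muscle_map(7)
#' table(m$ap, m$dv)
#' @export
make_muscle_map <- function(n_segments = 7, sides = c("L", "R"),
                            with_rois = FALSE,
                            rows_per_segment = 6, cols_per_slot = 3,
                            margin = 2) {
  stopifnot_config(is.numeric(n_segments) && length(n_segments) == 1 &&
                     n_segments >= 1, "n_segments must be >= 1")
  stopifnot_config(n_segments <= 7, "n_segments must be <= 7")
  stopifnot_config(all(sides %in% c("L", "R")) && length(sides) >= 1,
                   "sides must be a subset of c('L','R')")

  roster <- muscle_roster()
  segments <- paste0("A", seq_len(n_segments))
  ap_boundary <- 4L  # anterior = A1..A4, posterior = A5..A7

  rows <- list()
  for (side in sides) {
    for (si in seq_along(segments)) {
      ap <- if (si <= ap_boundary) "anterior" else "posterior"
      r <- roster
      if (ap == "posterior") r <- r[!r$anterior_only, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        muscle = r$muscle, segment = segments[si], side = side,
        dv = r$dv, ap = ap, stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL

  attr(map, "segments") <- segments
  attr(map, "ap_boundary") <- ap_boundary
  class(map) <- c("muscle_map", "data.frame")

  if (with_rois) map <- add_rois(map, rows_per_segment, cols_per_slot, margin)
  map
}

# Persistent pupal muscle roster for one hemisegment, with dorso-ventral
# compartments. M12 and M5 are anterior-only.
muscle_roster <- function() {
  data.frame(
    muscle = c("M1", "M2", "M3", "M5",
               "M8", "M9", "M10", "M21", "M22", "M23",
               "M12", "M13", "M15", "M26"),
    dv = c(rep("dorsal", 4), rep("lateral", 6), rep("ventral", 4)),
    anterior_only = c(FALSE, FALSE, FALSE, TRUE,
                      rep(FALSE, 6),
                      TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

add_rois <- function(map, rows_per_segment, cols_per_slot, margin) {
  roster <- muscle_roster()
  segments <- attr(map, "segments")
  sides <- sort(unique(map$side))
  # Column layout: for each side, dorsal | lateral | ventral blocks, one slot
  # per roster muscle of that compartment.
  dv_order <- c("dorsal", "lateral", "ventral")
  slot_of <- list()
  col0 <- margin
  for (side in sides) {
    for (dv in dv_order) {
      labs <- roster$muscle[roster$dv == dv]
      for (i in seq_along(labs)) {
        slot_of[[paste(side, labs[i])]] <- col0 + (i - 1L) * cols_per_slot
      }
      col0 <- col0 + length(labs) * cols_per_slot
    }
  }
  n_cols <- col0 + margin
  n_rows <- margin + length(segments) * rows_per_segment + margin

  seg_idx <- match(map$segment, segments)
  map$roi_row0 <- margin + (seg_idx - 1L) * rows_per_segment
  map$roi_row1 <- map$roi_row0 + rows_per_segment
  map$roi_col0 <- vapply(paste(map$side, map$muscle), function(k)
    slot_of[[k]], numeric(1))
  map$roi_col1 <- map$roi_col0 + cols_per_slot
  attr(map, "frame_shape") <- c(rows = n_rows, cols = n_cols)
  map
}

#' Validate a muscle map's structural invariants
#'
#' Checks compartment tags, the anterior-only restrictions (M12/M5), the
#' uniqueness of (muscle, segment, side), and ROI sanity when ROIs are
#' attached. Called internally by the generator; exported because the checks
#' double as a schema validator for externally supplied maps.
#'
#' @param map a `muscle_map`.
#' @return `TRUE` invisibly; aborts with a classed error on violation.
#' @export
validate_muscle_map <- function(map) {
  stopifnot_data(all(map$dv %in% c("dorsal", "lateral", "ventral")),
                 "dv compartment must be dorsal/lateral/ventral")
  stopifnot_data(all(map$ap %in% c("anterior", "posterior")),
                 "ap compartment must be anterior/posterior")
  post <- map[map$ap == "posterior", ]
  stopifnot_data(!any(post$muscle %in% c("M12", "M5")),
                 "M12 and M5 must be absent from posterior segments")
  key <- paste(map$muscle, map$segment, map$side)
  stopifnot_data(!anyDuplicated(key),
                 "(muscle, segment, side) must be unique")
  if (!is.null(map$roi_row0)) {
    fs <- attr(map, "frame_shape")
    stopifnot_data(all(map$roi_row1 > map$roi_row0) &&
                     all(map$roi_col1 > map$roi_col0),
                   "ROIs must be non-empty")
    stopifnot_data(all(map$roi_row0 >= 0) && all(map$roi_row1 <= fs["rows"]) &&
                     all(map$roi_col0 >= 0) && all(map$roi_col1 <= fs["cols"]),
                   "ROIs must lie inside the frame")
  }
  invisible(TRUE)
}
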