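#' Render a recording to an image stack
#'
#' Converts per-muscle dF/F traces to a schematic 2D fluorescence movie:
#' inside each muscle's ROI rectangle, pixel intensity at frame t equals
#' `background + gain * trace[t]` (plus optional Gaussian pixel noise).
#' Row 0 is anterior and the last row posterior, so anteriorly propagating
#' activity moves toward smaller row indices.
#'
#' @param recording an `ecdysis_recording` (from [simulate_recording()]),
#'   or any list with a `traces` matrix whose rownames are
#'   `muscle.segment.side` instances matching `map`.
#' @param map a muscle map built with `with_rois = TRUE`.
#' @param background baseline intensity.
#' @param gain intensity per unit dF/F.
#' @param noise_sd per-pixel Gaussian noise sd (0 = noise free).
#' @param frames optional 0-based frame indices to render (default all).
#' @return numeric array `rows x cols x n_frames`.
#' @export
render_frames <- function(recording, map, background = 100, gain = 100,
                          noise_sd = 0, frames = NULL) {
  stopifnot_config(!is.null(map$roi_row0),
                   "map has no ROIs; build it with with_rois = TRUE")
  validate_muscle_map(map)
  tr <- recording$traces
  fs <- attr(map, "frame_shape")
  if (is.null(frames)) frames <- seq_len(ncol(tr)) - 1L
  stopifnot_data(all(frames >= 0 & frames < ncol(tr)),
                 "frames out of range")
  inst <- paste(map$muscle, map$segment, map$side, sep = ".")
  rows_in <- match(inst, rownames(tr))
  stack <- array(background, dim = c(fs[["rows"]], fs[["cols"]],
                                     length(frames)))
  for (k in seq_len(nrow(map))) {
    if (is.na(rows_in[k])) next
    rr <- (map$roi_row0[k] + 1L):map$roi_row1[k]
    cc <- (map$roi_col0[k] + 1L):map$roi_col1[k]
    v <- background + gain * tr[rows_in[k], frames + 1L]
    stack[rr, cc, ] <- rep(v, each = length(rr) * length(cc))
  }
  if (noise_sd > 0) {
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd),
                           dim = dim(stack))
  }
  stack
}

#' Write an image stack as a multi-page TIFF with a JSON metadata sidecar
#'
#' Intensities are clipped to `[0, 2^16 - 1]` and stored as 16-bit. The
#' sidecar (same path with `.json` appended) records fps, frame shape, and
#' the orientation convention (row 0 = anterior).
#'
#' @param stack numeric array rows x cols x frames.
#' @param path output `.tif` path.
#' @param fps frames per second recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, fps = 2) {
  pages <- lapply(seq_len(dim(stack)[3]), function(i) {
    pmin(pmax(stack[, , i], 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(fps = fps,
               frame_shape = list(rows = dim(stack)[1], cols = dim(stack)[2]),
               n_frames = dim(stack)[3],
               orientation = "row0_anterior")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#'
#' @param path `.tif` path.
#' @return list with `stack` (numeric array, original intensity scale) and
#'   `meta` (sidecar list, or NULL if absent).
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                            length(pages)))
  for (i in seq_along(pages)) stack[, , i] <- pages[[i]] * 65535
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  list(stack = stack, meta = meta)
}
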