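EVENT_COLUMNS <- c("animal_id", "phase", "bout_id", "movement", "muscle",
                   "segment", "side", "onset_frame", "offset_frame",
                   "peak_frame", "f_onset", "f_max", "length_onset_um",
                   "length_min_um")

#' Read and validate an activation-event table
#'
#' Events are expected in the canonical CSV schema (see
#' [write_events()]), with 0-based frames and half-open
#' `[onset, offset)` intervals. Tables annotated with 1-based frames can be
#' converted on read.
#'
#' @param path CSV path.
#' @param one_based logical; `TRUE` converts 1-based frame columns to the
#'   package's 0-based convention.
#' @return validated data.frame.
#' @export
read_events <- function(path, one_based = FALSE) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVENT_COLUMNS, names(ev))
  if (length(missing_cols) > 0) {
    abort_ecdysim(paste("missing columns:",
                        paste(missing_cols, collapse = ", ")),
                  "ecdysim_schema_error")
  }
  if (one_based) {
    for (cc in c("onset_frame", "offset_frame", "peak_frame")) {
      ev[[cc]] <- ev[[cc]] - 1L
    }
  }
  bad <- which(ev$offset_frame <= ev$onset_frame)
  if (length(bad) > 0) {
    abort_ecdysim(paste("non-monotone intervals (offset <= onset) at rows:",
                        paste(utils::head(bad, 20), collapse = ", ")),
                  "ecdysim_schema_error")
  }
  bad <- which(ev$onset_frame < 0)
  if (length(bad) > 0) {
    abort_ecdysim(paste("negative onset frames at rows:",
                        paste(utils::head(bad, 20), collapse = ", ")),
                  "ecdysim_schema_error")
  }
  ev
}

#' Write an activation-event table
#'
#' @param events data.frame in the canonical schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, EVENT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Simulates a cohort, then runs bout segmentation, ensemble discovery,
#' stereotypy scoring at the muscle and syllable levels, contraction
#' mechanics, and (optionally) per-bout wave directionality on rendered
#' movies. Every stage is seeded from `config$seed`; a provenance manifest
#' records parameters and seeds so the run is reproducible.
#'
#' @param config a [sim_config()].
#' @param n_animals cohort size.
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV/JSON.
#' @param directionality logical; render movies and call wave direction
#'   (slower).
#' @param n_perm permutations for the shuffled null.
#' @return list: `events`, `bouts`, `phase_summary`, `catalog`,
#'   `ss` (per-level `ss_result` + null), `mechanics`, `direction`
#'   (or NULL), `manifest`.
#' @export
run_pipeline <- function(config, n_animals = 10, out_dir = NULL,
                         directionality = FALSE, n_perm = 200) {
  map <- make_muscle_map(7, with_rois = TRUE)
  recs <- simulate_cohort(config, map, n_animals)
  events <- do.call(rbind, lapply(recs, function(r) r$events))
  rownames(events) <- NULL

  # segmentation (per animal), pooled phase summary
  bouts <- list(); interbouts <- list()
  for (r in recs) {
    seg <- segment_bouts(r$events$onset_frame, min_gap = 2,
                         n_frames = r$n_frames)
    b <- seg$bouts
    b$animal_id <- r$events$animal_id[1]
    b$phase <- phase_of_frames(b$start_frame, r$truth$phase_intervals)
    bouts[[length(bouts) + 1L]] <- b
    ib <- seg$interbout
    if (nrow(ib) > 0) {
      ib$animal_id <- r$events$animal_id[1]
      ib$phase <- phase_of_frames(ib$start_frame, r$truth$phase_intervals)
      interbouts[[length(interbouts) + 1L]] <- ib
    }
  }
  bouts <- do.call(rbind, bouts)
  interbouts <- do.call(rbind, interbouts)
  phase_summary <- summarize_phases(bouts, interbouts)

  # ensembles + syllable annotation
  catalog <- discover_pmes(events)
  catalog <- single_muscle_syllables(events, catalog)

  # sequences: muscle- and syllable-level stereotypy with shuffled null
  key <- paste(events$animal_id, events$bout_id)
  mus_seqs <- lapply(split(events, key), activation_order, level = "muscle")
  grp <- vapply(split(events$animal_id, key), `[`, character(1), 1)
  syl_seqs <- lapply(split(events, key), function(e) {
    activation_order(annotate_syllables(e, catalog)$syllable_events,
                     level = "syllable")
  })
  ss <- list(
    muscle = pairwise_ss(mus_seqs, grp),
    syllable = pairwise_ss(syl_seqs, grp),
    null_muscle = shuffled_null(mus_seqs, n_perm = n_perm,
                                seed = config$seed, group = grp)
  )

  mech <- contraction_metrics(events)
  mech_corr <- shortening_fluorescence_correlation(mech)

  direction <- NULL
  if (directionality) {
    r1 <- recs[[1]]
    stack <- render_frames(r1, map, noise_sd = 0)
    traj <- frame_mode_profile(stack, activity_floor = 110)
    tb <- r1$truth$bouts
    calls <- character(0); phases <- character(0)
    for (i in seq_len(nrow(tb))) {
      win <- c(tb$start_frame[i], tb$activity_end_frame[i])
      res <- tryCatch(classify_direction(traj, window = win)$call,
                      error = function(e) NA_character_)
      calls <- c(calls, res); phases <- c(phases, tb$phase[i])
    }
    ok <- !is.na(calls)
    direction <- phase_direction_summary(calls[ok], phases[ok])
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecdysim")),
    seed = config$seed, n_animals = n_animals,
    perturbation = config$perturbation,
    parameters = config[c("fps", "syllable_support", "recruitment_jitter_sd",
                          "within_ensemble_jitter", "idiosyncratic_rate",
                          "syllable_spacing", "event_duration",
                          "idio_duration", "noise_sd")],
    n_events = nrow(events), n_bouts = nrow(bouts),
    timestamp = format(Sys.time(), tz = "UTC"))

  out <- list(events = events, bouts = bouts, phase_summary = phase_summary,
              catalog = catalog, ss = ss,
              mechanics = list(metrics = mech, correlation = mech_corr),
              direction = direction, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(events, file.path(out_dir, "events.csv"))
    utils::write.csv(bouts, file.path(out_dir, "bouts.csv"),
                     row.names = FALSE)
    utils::write.csv(phase_summary, file.path(out_dir, "phase_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(catalog_to_list(catalog),
                         file.path(out_dir, "catalog.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

phase_of_frames <- function(frames, phase_intervals) {
  out <- rep(NA_character_, length(frames))
  for (i in seq_len(nrow(phase_intervals))) {
    hit <- frames >= phase_intervals$start_frame[i] &
      frames < phase_intervals$end_frame[i]
    out[hit] <- phase_intervals$phase[i]
  }
  # frames past the last interval belong to the last phase
  last <- nrow(phase_intervals)
  out[is.na(out) & frames >= phase_intervals$end_frame[last]] <-
    phase_intervals$phase[last]
  out
}

catalog_to_list <- function(catalog) {
  list(pmes = lapply(catalog$pmes, function(p)
         list(id = p$id, muscles = p$muscles,
              mean_support = mean(p$support),
              animal_frac = p$animal_frac)),
       singles = lapply(catalog$singles, function(s)
         list(muscle = s$muscle, mean_support = mean(s$support),
              animal_frac = s$animal_frac)),
       criteria = catalog$criteria)
}
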