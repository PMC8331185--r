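#' Simulate a ground-truthed pupal-ecdysis recording
#'
#' Generates one animal's worth of synthetic single-muscle Ca++ activity:
#' an activation-event table (the annotation-table schema used throughout
#' the package), per-muscle-instance dF/F traces, and a ground-truth list
#' holding the planted phase intervals, bouts, syllable catalog, recruitment
#' orders, wave directions, and frame-wise movement labels.
#'
#' Each bout schedules its movements' syllables as dense clusters (see
#' [sim_config()] for the timing model), perturbs cluster onsets with
#' Gaussian recruitment jitter and member onsets with the smaller
#' within-ensemble jitter, places successive clusters in hemisegments
#' ordered along the body axis for movements with a planted propagation
#' direction (posterior-first for P-to-A waves), bridges any jitter-induced
#' onset gaps with deterministic filler re-activations of already-active
#' muscles (continuous recruitment), and injects idiosyncratic off-syllable
#' twitches so their expected fraction of all activations equals
#' `idiosyncratic_rate`. Traces are sums of instant-rise
#' exponential-decay kernels plus Gaussian noise. All frames are 0-based;
#' event intervals are half-open `[onset, offset)`.
#'
#' @param config a [sim_config()].
#' @param map a [make_muscle_map()] muscle map.
#' @param animal_id label stamped into the event table.
#' @return object of class `ecdysis_recording`: list with `events`
#'   (data.frame in the canonical schema), `traces` (matrix, one row per
#'   muscle instance `muscle.segment.side`, one column per frame), `truth`
#'   (ground truth list; its `events` copy carries the hidden `syllable`,
#'   `idiosyncratic`, and `filler` columns), `map`, `config`, `n_frames`.
#' @export
simulate_recording <- function(config, map, animal_id = "A01") {
  stopifnot_config(inherits(config, "sim_config"), "config must be sim_config")
  validate_muscle_map(map)
  extra <- setdiff(unlist(config$syllabary$pmes), unique(map$muscle))
  stopifnot_config(length(extra) == 0,
                   paste("syllabary references muscles missing from map:",
                         paste(extra, collapse = ", ")))
  set.seed(config$seed)

  sides <- unique(map$side)
  state <- new.env(parent = emptyenv())
  state$events <- list()       # per-bout event data.frames (hidden columns)
  state$bouts <- list()
  state$orders <- list()       # planted syllable order per bout
  state$phase_rows <- list()
  state$cursor <- 0L
  state$bout_id <- 0L
  state$side_now <- sample(sides, 1)

  plan <- config$phase_plan
  for (ph in names(plan)) {
    p <- plan[[ph]]
    phase_start <- state$cursor
    n_b <- if (p$count_sdlog > 0) {
      max(1L, as.integer(round(p$n_bouts *
                                 stats::rlnorm(1, 0, p$count_sdlog))))
    } else {
      as.integer(p$n_bouts)
    }
    for (b in seq_len(n_b)) {
      if (is.null(p$movements)) {
        emit_twitch_bout(state, config, map, ph)
      } else {
        mvs <- p$movements[[((b - 1L) %% length(p$movements)) + 1L]]
        if (p$repeat_last_p > 0 && stats::runif(1) < p$repeat_last_p) {
          mvs <- c(mvs, mvs[length(mvs)])
        }
        if (p$drop_last_p > 0 && length(mvs) > 1 &&
            stats::runif(1) < p$drop_last_p) {
          mvs <- mvs[-length(mvs)]
        }
        emit_movement_bout(state, config, map, ph, mvs)
      }
      gap <- max(4, round(stats::rlnorm(1, p$interbout_meanlog,
                                        p$interbout_sdlog)))
      state$cursor <- state$cursor + gap
      # strict L/R alternation with occasional switch failure
      if (length(sides) > 1 && stats::runif(1) >= config$lr_switch_fail) {
        state$side_now <- setdiff(sides, state$side_now)[1]
      }
    }
    # perturbation-specific insertions at phase boundaries
    if (ph == "P1" && identical(config$partial_swing, "posterior_only")) {
      emit_movement_bout(state, config, map, "P1", "Swing",
                         force_extent = "posterior", dv_desync = TRUE)
      state$cursor <- state$cursor + 8L
      for (k in 1:2) {
        emit_movement_bout(state, config, map, "P1", c("Lift", "RollCon"))
        state$cursor <- state$cursor + 10L
      }
    }
    if (ph == "P1" && identical(config$partial_swing, "full_length")) {
      p2_start <- state$cursor  # P2 pseudo-phase: single attempted swing
      emit_movement_bout(state, config, map, "P2", "Swing",
                         force_extent = "both", dv_desync = TRUE)
      state$cursor <- state$cursor + 10L
      state$phase_rows[["P2"]] <- c(start = p2_start, end = state$cursor)
    }
    if (is.null(state$phase_rows[[ph]])) {
      state$phase_rows[[ph]] <- c(start = phase_start, end = state$cursor)
    }
  }

  ev <- do.call(rbind, state$events)
  rownames(ev) <- NULL
  n_frames <- state$cursor + 10L
  ev$animal_id <- animal_id

  ev <- attach_mechanics(ev, config)
  traces <- build_traces(ev, map, config, n_frames)
  truth <- build_truth(state, ev, config, n_frames, animal_id)

  events <- ev[, c("animal_id", "phase", "bout_id", "movement", "muscle",
                   "segment", "side", "onset_frame", "offset_frame",
                   "peak_frame", "f_onset", "f_max", "length_onset_um",
                   "length_min_um")]
  out <- list(events = events, traces = traces, truth = truth,
              map = map, config = config, n_frames = n_frames)
  class(out) <- "ecdysis_recording"
  out
}

# -- bout emitters -----------------------------------------------------------

emit_twitch_bout <- function(state, config, map, phase) {
  state$bout_id <- state$bout_id + 1L
  sustained <- isTRUE(config$p0_sustained)
  n_tw <- 4L + stats::rpois(1, 3) + if (sustained) 8L else 0L
  dur <- if (sustained) 3L * config$coactive_window else config$idio_duration
  start <- state$cursor
  onsets <- start + c(0L, cumsum(sample(1:2, n_tw - 1L, replace = TRUE)))
  inst <- map[sample.int(nrow(map), n_tw, replace = TRUE), ]
  rows <- data.frame(
    phase = phase, bout_id = state$bout_id, movement = "Rest",
    muscle = inst$muscle, segment = inst$segment, side = inst$side,
    onset_frame = onsets, offset_frame = onsets + dur, peak_frame = onsets,
    syllable = NA_character_, idiosyncratic = TRUE, filler = FALSE,
    movement_instance = 1L, stringsAsFactors = FALSE)
  state$events[[length(state$events) + 1L]] <- rows
  end <- max(rows$offset_frame)
  state$bouts[[state$bout_id]] <- list(bout_id = state$bout_id, phase = phase,
                                       movements = "Rest",
                                       start = min(onsets), end = end,
                                       onset_end = max(onsets) + 1L,
                                       side = state$side_now,
                                       move_spans = NULL)
  state$orders[[state$bout_id]] <- character(0)
  state$cursor <- end
}

emit_movement_bout <- function(state, config, map, phase, movements,
                               force_extent = NULL, dv_desync = FALSE) {
  state$bout_id <- state$bout_id + 1L
  syl <- config$syllabary
  sgm <- attr(map, "segments")
  n_seg_total <- length(sgm)
  w <- config$coactive_window
  start <- state$cursor
  cl_cursor <- start
  all_rows <- list()
  planted_order <- character(0)
  roster <- muscle_roster()
  dv_off <- c(dorsal = 0L, lateral = 0L, ventral = 0L)
  use_dv_desync <- dv_desync || isTRUE(config$dv_desync)
  if (use_dv_desync) {
    dv_off <- c(dorsal = 0L, lateral = w + 2L, ventral = 2L * (w + 2L))
  }

  for (mi in seq_along(movements)) {
    mv <- movements[mi]
    mdef <- syl$movements[[mv]]
    syls <- mdef$syllables
    keep <- stats::runif(length(syls)) < config$syllable_support
    if (!any(keep)) keep[1] <- TRUE
    syls <- syls[keep]
    extent <- if (!is.null(force_extent)) force_extent else mdef$ap_extent
    seg_pool <- switch(extent,
                       anterior = seq_len(min(4L, n_seg_total)),
                       posterior = if (n_seg_total < 5L) seq_len(n_seg_total)
                                   else seq.int(5L, n_seg_total),
                       seq_len(n_seg_total))
    seg_order <- switch(mdef$direction,
                        P_to_A = rev(seg_pool),
                        A_to_P = seg_pool,
                        sample(seg_pool))
    # Per-segment movements (the Swing's compression wave) activate their
    # swept ensembles in every traversed hemisegment, in axis order, with a
    # wider advance (the wave dwells in each hemisegment; fillers keep the
    # bout dense); remaining syllables are placed once along the axis.
    swept <- character(0)
    if (!is.null(mdef$per_segment)) {
      swept <- intersect(syls, mdef$per_segment)
    }
    rest <- setdiff(syls, swept)
    if (length(swept) > 0) {
      sched_syl <- rep(swept, times = length(seg_order))
      sched_seg <- rep(seg_order, each = length(swept))
      if (length(rest) > 0) {
        idx <- round(seq(1, length(seg_order), length.out = length(rest)))
        sched_syl <- c(sched_syl, rest)
        sched_seg <- c(sched_seg, seg_order[idx])
      }
    } else {
      idx <- round(seq(1, length(seg_order), length.out = length(syls)))
      sched_syl <- syls
      sched_seg <- seg_order[idx]
    }
    mv_rows <- list()
    for (k in seq_along(sched_syl)) {
      s_name <- sched_syl[k]
      seg_k <- sched_seg[k]
      in_sweep <- k <= length(swept) * length(seg_order)
      onset_s <- cl_cursor +
        round(stats::rnorm(1, 0, config$recruitment_jitter_sd))
      onset_s <- max(onset_s, start)
      members <- syllable_members(s_name, syl)
      n_m <- length(members)
      spread <- n_m - 1L
      # within-ensemble jitter is a bounded displacement (uniform integer
      # on [-j, j]); kept within the co-activity window it perturbs member
      # order without destroying co-activity
      wj <- as.integer(round(config$within_ensemble_jitter))
      if (s_name %in% config$desync_pmes && phase == "P1") {
        wj <- as.integer(w + 2)
      }
      # members share a common planned offset (the ensemble releases
      # together), so member-onset jitter widens durations rather than
      # breaking the co-active window
      common_off <- onset_s + spread + w
      for (i in seq_len(n_m)) {
        m <- members[i]
        onset_m <- onset_s + (i - 1L) +
          if (wj > 0) sample((-wj):wj, 1) else 0L
        off_m <- common_off
        if (use_dv_desync && mv == "Swing") {
          dv_m <- roster$dv[match(m, roster$muscle)]
          onset_m <- onset_m + dv_off[[dv_m]]
          off_m <- off_m + dv_off[[dv_m]]
        }
        onset_m <- max(onset_m, start)
        if (n_m < 2) off_m <- onset_m + config$single_duration
        off_m <- max(off_m, onset_m + 1L)
        seg_m <- resolve_segment(m, seg_k, map, state$side_now)
        if (is.na(seg_m)) next
        mv_rows[[length(mv_rows) + 1L]] <- data.frame(
          phase = phase, bout_id = state$bout_id, movement = mv,
          muscle = m, segment = sgm[seg_m], side = state$side_now,
          onset_frame = onset_m, offset_frame = off_m,
          peak_frame = onset_m,
          syllable = s_name, idiosyncratic = FALSE, filler = FALSE,
          movement_instance = mi, stringsAsFactors = FALSE)
      }
      planted_order <- c(planted_order, s_name)
      # advance past the full co-activity window so neighboring clusters
      # do not overlap it under typical jitter; deterministic fillers
      # bridge the resulting onset gaps so bouts stay dense. Swept wave
      # clusters dwell 2 extra frames per hemisegment.
      adv <- if (n_m >= 2) spread + w else 2L
      if (in_sweep) adv <- adv + 2L
      cl_cursor <- cl_cursor + adv
    }
    mv_df <- do.call(rbind, mv_rows)
    if (!is.null(mv_df) && nrow(mv_df) > 0) {
      # ethrb: named muscles silent during P1
      if (phase == "P1" && length(config$suppressed_muscles_p1) > 0) {
        mv_df <- mv_df[!(mv_df$muscle %in% config$suppressed_muscles_p1), ,
                       drop = FALSE]
      }
      if (nrow(mv_df) > 0) {
        all_rows[[length(all_rows) + 1L]] <- mv_df
      }
    }
  }

  ev <- do.call(rbind, all_rows)
  if (is.null(ev) || nrow(ev) == 0) {  # fully suppressed bout
    state$bout_id <- state$bout_id - 1L
    return(invisible(NULL))
  }

  ev <- add_fillers(ev, config)
  ev <- add_idiosyncratic(ev, config, map, movements[1], phase,
                          state$bout_id)
  mnum <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", ev$muscle)))
  ev <- ev[order(ev$onset_frame, mnum, ev$muscle), ]
  rownames(ev) <- NULL
  state$events[[length(state$events) + 1L]] <- ev

  move_spans <- lapply(unique(ev$movement[!ev$idiosyncratic]), function(m) {
    em <- ev[ev$movement == m & !ev$idiosyncratic, ]
    list(movement = m, start = min(em$onset_frame),
         end = max(em$offset_frame))
  })
  end <- max(ev$offset_frame)
  state$bouts[[state$bout_id]] <- list(
    bout_id = state$bout_id, phase = phase, movements = movements,
    start = min(ev$onset_frame), end = end,
    onset_end = max(ev$onset_frame) + 1L,
    side = state$side_now, move_spans = move_spans)
  state$orders[[state$bout_id]] <- planted_order
  state$cursor <- end
  invisible(NULL)
}

# Deterministic filler re-activations: wherever consecutive new-activation
# frames would be >= min bout gap apart, re-activate an already-active
# muscle (continuous recruitment) so bouts stay dense in onsets.
add_fillers <- function(ev, config) {
  on <- sort(unique(ev$onset_frame))
  fillers <- list()
  for (g in which(diff(on) >= 3L)) {
    for (f in seq(on[g] + 2L, on[g + 1L] - 1L, by = 2L)) {
      cand <- which(ev$onset_frame <= f & ev$offset_frame > f &
                      !ev$idiosyncratic)
      if (length(cand) == 0) cand <- which(ev$onset_frame <= f)
      src <- cand[which.max(ev$offset_frame[cand])]
      dur <- max(1L, min(2L, ev$offset_frame[src] - f))
      fillers[[length(fillers) + 1L]] <- data.frame(
        phase = ev$phase[src], bout_id = ev$bout_id[src],
        movement = ev$movement[src], muscle = ev$muscle[src],
        segment = ev$segment[src], side = ev$side[src],
        onset_frame = f, offset_frame = f + dur, peak_frame = f,
        syllable = ev$syllable[src], idiosyncratic = FALSE, filler = TRUE,
        movement_instance = ev$movement_instance[src],
        stringsAsFactors = FALSE)
    }
  }
  if (length(fillers) > 0) ev <- rbind(ev, do.call(rbind, fillers))
  ev
}

add_idiosyncratic <- function(ev, config, map, movement, phase, bout_id) {
  r <- config$idiosyncratic_rate
  if (r <= 0) return(ev)
  p_extra <- min(1, r / (1 - r))
  n_idio <- stats::rbinom(1, nrow(ev), p_extra)
  if (n_idio == 0) return(ev)
  lo <- min(ev$onset_frame)
  hi <- max(ev$onset_frame)
  pool <- map
  if (phase == "P1" && length(config$suppressed_muscles_p1) > 0) {
    pool <- pool[!(pool$muscle %in% config$suppressed_muscles_p1), ,
                 drop = FALSE]
  }
  inst <- pool[sample.int(nrow(pool), n_idio, replace = TRUE), ]
  onsets <- lo + sample.int(max(1L, hi - lo + 1L), n_idio,
                            replace = TRUE) - 1L
  # attribute each twitch to the movement instance active at its onset
  inst_of <- vapply(onsets, function(f) {
    cover <- which(ev$onset_frame <= f & ev$offset_frame > f)
    if (length(cover) == 0) cover <- which.min(abs(ev$onset_frame - f))
    ev$movement_instance[cover[1]]
  }, numeric(1))
  mv_of <- vapply(onsets, function(f) {
    cover <- which(ev$onset_frame <= f & ev$offset_frame > f)
    if (length(cover) == 0) cover <- which.min(abs(ev$onset_frame - f))
    ev$movement[cover[1]]
  }, character(1))
  idio <- data.frame(
    phase = phase, bout_id = bout_id, movement = mv_of,
    muscle = inst$muscle, segment = inst$segment, side = inst$side,
    onset_frame = onsets, offset_frame = onsets + config$idio_duration,
    peak_frame = onsets,
    syllable = NA_character_, idiosyncratic = TRUE, filler = FALSE,
    movement_instance = inst_of, stringsAsFactors = FALSE)
  rbind(ev, idio)
}

# Fall back to the nearest allowed segment for anterior-only muscles.
resolve_segment <- function(muscle, seg_idx, map, side) {
  sgm <- attr(map, "segments")
  ok <- map$segment[map$muscle == muscle & map$side == side]
  if (length(ok) == 0) return(NA_integer_)
  ok_idx <- match(ok, sgm)
  if (seg_idx %in% ok_idx) return(seg_idx)
  ok_idx[which.min(abs(ok_idx - seg_idx))]
}

# -- mechanics, traces, truth ------------------------------------------------

attach_mechanics <- function(ev, config) {
  m <- config$mech
  n <- nrow(ev)
  rho <- m$coupling
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  dff <- pmax(10, m$dff_mean + m$dff_sd * z1)
  short <- m$shortening_mean +
    m$shortening_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  # planted posterior-to-anterior shortening gradient for the lateral
  # transverse ensemble (PME2): strongest in A5, weaker in A4, A3
  grad <- m$pme2_segment_gradient
  if (is.null(grad)) grad <- 0
  seg_num <- as.integer(sub("^A", "", ev$segment))
  is_pme2 <- ev$muscle %in% c("M21", "M22", "M23")
  short <- short * ifelse(is_pme2, 1 + grad * (seg_num - 4L), 1)
  short <- pmin(pmax(short, 0), 60)
  len0 <- pmax(50, stats::rnorm(n, m$length_mean_um, m$length_sd_um))
  ev$f_onset <- round(stats::runif(n, 90, 110), 2)
  ev$f_max <- round(ev$f_onset * (1 + dff / 100), 2)
  ev$length_onset_um <- round(len0, 2)
  ev$length_min_um <- round(len0 * (1 - short / 100), 2)
  ev
}

build_traces <- function(ev, map, config, n_frames) {
  inst <- paste(map$muscle, map$segment, map$side, sep = ".")
  tr <- matrix(0, nrow = nrow(map), ncol = n_frames,
               dimnames = list(inst, NULL))
  tau <- config$kinetics$tau_decay
  amps <- stats::rlnorm(nrow(ev), config$kinetics$amp_meanlog,
                        config$kinetics$amp_sdlog)
  tt <- seq_len(n_frames) - 1L
  for (i in seq_len(nrow(ev))) {
    row <- match(paste(ev$muscle[i], ev$segment[i], ev$side[i], sep = "."),
                 inst)
    if (is.na(row)) next
    on <- ev$onset_frame[i]
    idx <- which(tt >= on)
    tr[row, idx] <- tr[row, idx] + amps[i] * exp(-(tt[idx] - on) / tau)
  }
  if (config$noise_sd > 0) {
    tr <- tr + matrix(stats::rnorm(length(tr), 0, config$noise_sd),
                      nrow = nrow(tr))
  }
  tr
}

build_truth <- function(state, ev, config, n_frames, animal_id) {
  bouts <- do.call(rbind, lapply(state$bouts, function(b) data.frame(
    animal_id = animal_id, bout_id = b$bout_id, phase = b$phase,
    start_frame = b$start, end_frame = b$onset_end,
    activity_end_frame = b$end, side = b$side,
    movements = paste(b$movements, collapse = ";"),
    stringsAsFactors = FALSE)))
  phase_intervals <- do.call(rbind, lapply(names(state$phase_rows),
    function(ph) data.frame(phase = ph,
                            start_frame = state$phase_rows[[ph]][["start"]],
                            end_frame = state$phase_rows[[ph]][["end"]],
                            stringsAsFactors = FALSE)))
  phase_intervals <- phase_intervals[order(phase_intervals$start_frame), ]
  rownames(phase_intervals) <- NULL

  frame_labels <- rep("Rest", n_frames)
  for (b in state$bouts) {
    if (is.null(b$move_spans)) next
    for (ms in b$move_spans) {
      if (ms$movement == "Rest") next
      lo <- ms$start + 1L
      hi <- min(ms$end, n_frames)
      if (hi >= lo) frame_labels[lo:hi] <- ms$movement
    }
  }

  directions <- vapply(config$syllabary$movements, function(m) m$direction,
                       character(1))
  list(phase_intervals = phase_intervals,
       bouts = bouts,
       planted_syllables = config$syllabary$pmes,
       recruitment_orders = state$orders,
       directions = directions,
       frame_labels = frame_labels,
       events = ev)
}

#' Simulate a cohort of animals
#'
#' Runs [simulate_recording()] once per animal with per-animal seeds derived
#' deterministically from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param map a muscle map.
#' @param n_animals number of animals.
#' @return named list of `ecdysis_recording` objects (animal ids `A01`...).
#' @export
simulate_cohort <- function(config, map, n_animals = 10) {
  recs <- vector("list", n_animals)
  ids <- sprintf("A%02d", seq_len(n_animals))
  for (i in seq_len(n_animals)) {
    ci <- config
    ci$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    recs[[i]] <- simulate_recording(ci, map, animal_id = ids[i])
  }
  names(recs) <- ids
  recs
}

#' Combined event table of a cohort
#'
#' @param recordings list from [simulate_cohort()].
#' @param truth logical; `TRUE` returns the ground-truth event copies (with
#'   `syllable`/`idiosyncratic`/`filler` columns) instead of the canonical
#'   schema.
#' @return row-bound event data.frame.
#' @export
cohort_events <- function(recordings, truth = FALSE) {
  out <- do.call(rbind, lapply(recordings, function(r)
    if (truth) r$truth$events else r$events))
  rownames(out) <- NULL
  out
}

#' Simulate coupled muscle/NMJ peak trains
#'
#' Emulates paired imaging of muscle Ca++ and its neuromuscular-junction
#' input during the pre-ecdysis phase: NMJ peaks occur at a fixed per-frame
#' density and each is transmitted to the muscle with probability
#' `coupling_p`; the muscle additionally fires independent peaks so its
#' overall density stays comparable across coupling levels.
#'
#' @param n_frames recording length.
#' @param density per-frame peak probability of the NMJ train.
#' @param coupling_p probability that an NMJ peak is echoed by the muscle.
#' @param seed integer seed.
#' @return list with sorted 0-based `nmj` and `muscle` peak frames.
#' @export
simulate_coupled_trains <- function(n_frames, density = 0.05,
                                    coupling_p = 0.5, seed = 1) {
  stopifnot_config(coupling_p >= 0 && coupling_p <= 1,
                   "coupling_p must be in [0,1]")
  set.seed(seed)
  nmj <- which(stats::runif(n_frames) < density) - 1L
  echoed <- nmj[stats::runif(length(nmj)) < coupling_p]
  indep <- which(stats::runif(n_frames) < density * (1 - coupling_p)) - 1L
  muscle <- sort(unique(c(echoed, indep)))
  list(nmj = nmj, muscle = muscle)
}

#' Simulate an ensemble-recovery benchmark cohort
#'
#' A stripped-down cohort for parameter-recovery studies of the ensemble
#' criteria: every bout is a generic composite movement in which each of
#' the planted ensembles appears with exact planted support (each PME is
#' scheduled in exactly `round(support * n_bouts)` randomly chosen bouts of
#' each animal), in random order, with recruitment and within-ensemble
#' jitter and idiosyncratic twitches as configured. The cluster timing
#' model matches [simulate_recording()].
#'
#' @param seed integer seed.
#' @param n_animals,n_bouts cohort dimensions.
#' @param support planted per-bout inclusion fraction of each ensemble.
#' @param pmes named list of ensembles (muscle label vectors).
#' @param recruitment_jitter_sd Gaussian sd (frames) on cluster onsets.
#' @param within_ensemble_jitter bounded member displacement (frames).
#' @param idiosyncratic_rate target off-syllable activation fraction.
#' @param coactive_window,idio_duration timing as in [sim_config()].
#' @param map muscle map providing instances for idiosyncratic twitches.
#' @return list with `events` (combined table: `animal_id`, `bout_id`,
#'   `movement`, `muscle`, `segment`, `side`, `onset_frame`,
#'   `offset_frame`, `idiosyncratic`) and `planted` (the ensemble list).
#' @export
simulate_pme_recovery <- function(seed, n_animals = 10, n_bouts = 20,
                                  support = 0.9,
                                  pmes = benchmark_ensembles(),
                                  recruitment_jitter_sd = 1,
                                  within_ensemble_jitter = 1,
                                  idiosyncratic_rate = 0.1,
                                  coactive_window = 4,
                                  idio_duration = 2,
                                  map = make_muscle_map(7)) {
  set.seed(seed)
  w <- coactive_window
  wj <- as.integer(round(within_ensemble_jitter))
  n_in <- round(support * n_bouts)
  out <- list()
  for (a in seq_len(n_animals)) {
    aid <- sprintf("A%02d", a)
    # exact planted support: each ensemble in n_in of the n_bouts
    in_bout <- lapply(pmes, function(p) sample.int(n_bouts, n_in))
    cursor <- 0L
    for (b in seq_len(n_bouts)) {
      present <- names(pmes)[vapply(in_bout, function(x) b %in% x,
                                    logical(1))]
      present <- sample(present)
      start <- cursor
      cl <- start
      rows <- list()
      for (s_name in present) {
        members <- pmes[[s_name]]
        spread <- length(members) - 1L
        onset_s <- max(start,
                       cl + round(stats::rnorm(1, 0, recruitment_jitter_sd)))
        common_off <- onset_s + spread + w
        seg <- sample(attr(map, "segments"), 1)
        for (i in seq_along(members)) {
          onset_m <- onset_s + (i - 1L) +
            if (wj > 0) sample((-wj):wj, 1) else 0L
          onset_m <- max(onset_m, start)
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = aid, bout_id = b, movement = "Composite",
            muscle = members[i], segment = seg, side = "L",
            onset_frame = onset_m,
            offset_frame = max(common_off, onset_m + 1L),
            idiosyncratic = FALSE, stringsAsFactors = FALSE)
        }
        cl <- cl + spread + w - 2L
      }
      ev <- do.call(rbind, rows)
      r <- idiosyncratic_rate
      if (r > 0 && !is.null(ev)) {
        n_idio <- stats::rbinom(1, nrow(ev), min(1, r / (1 - r)))
        if (n_idio > 0) {
          lo <- min(ev$onset_frame); hi <- max(ev$onset_frame)
          inst <- map[sample.int(nrow(map), n_idio, replace = TRUE), ]
          onsets <- lo + sample.int(max(1L, hi - lo + 1L), n_idio,
                                    replace = TRUE) - 1L
          ev <- rbind(ev, data.frame(
            animal_id = aid, bout_id = b, movement = "Composite",
            muscle = inst$muscle, segment = inst$segment, side = inst$side,
            onset_frame = onsets, offset_frame = onsets + idio_duration,
            idiosyncratic = TRUE, stringsAsFactors = FALSE))
        }
      }
      out[[length(out) + 1L]] <- ev
      cursor <- max(ev$offset_frame) + 6L
    }
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  list(events = events, planted = pmes)
}

#' Non-nested benchmark ensembles for recovery studies
#'
#' Eight muscle sets from the roster with no subset relations between any
#' pair. Used as the planted truth of [simulate_pme_recovery()]: in its
#' uniform composite bouts nested ensembles (like the dorsal-longitudinal
#' pair of the real catalog) are separable only through movement structure,
#' which the benchmark deliberately lacks, so its planted sets avoid
#' nesting. Members may still be shared across sets.
#'
#' @return named list of 8 character vectors.
#' @export
benchmark_ensembles <- function() {
  list(B1 = c("M1", "M2", "M3"),
       B2 = c("M21", "M22", "M23"),
       B3 = c("M8", "M13", "M26"),
       B4 = c("M5", "M9"),
       B5 = c("M10", "M12"),
       B6 = c("M15", "M26"),
       B7 = c("M1", "M21"),
       B8 = c("M9", "M13"))
}
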