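# Shared fixtures for the suite. Everything is generated in code.

default_map <- function(with_rois = FALSE) make_muscle_map(7, with_rois = with_rois)

# planted catalog: the generator's syllabary as a known-truth catalog
planted_catalog <- function() {
  syl <- default_syllabary()
  singles <- setdiff(
    unique(unlist(lapply(syl$movements, function(m) m$syllables))),
    names(syl$pmes))
  syllable_catalog(syl$pmes, singles)
}

# single-phase plan used to isolate sequence behavior
p1_only_plan <- function(n_bouts = 6) {
  list(P1 = list(n_bouts = n_bouts, movements = list(c("Lift", "RollCon")),
                 count_sdlog = 0, repeat_last_p = 0, drop_last_p = 0,
                 interbout_meanlog = log(10), interbout_sdlog = 0.2))
}

# single clean wave bout (deterministic timing, fixed amplitudes)
wave_config <- function(seed, movement) {
  plan <- list(P2 = list(n_bouts = 1, movements = list(movement),
                         count_sdlog = 0, repeat_last_p = 0, drop_last_p = 0,
                         interbout_meanlog = log(8), interbout_sdlog = 0))
  sim_config(seed = seed, phase_plan = plan, recruitment_jitter_sd = 0,
             within_ensemble_jitter = 0, idiosyncratic_rate = 0,
             noise_sd = 0,
             kinetics = list(tau_decay = 6, amp_meanlog = 0.3, amp_sdlog = 0))
}

wave_direction_call <- function(seed, movement, noise_sd = 0, flip = FALSE,
                                gain = 100) {
  map <- make_muscle_map(7, with_rois = TRUE)
  rec <- simulate_recording(wave_config(seed, movement), map)
  st <- render_frames(rec, map, background = 100, gain = gain,
                      noise_sd = noise_sd)
  if (flip) st <- st[dim(st)[1]:1, , , drop = FALSE]
  b <- rec$truth$bouts
  traj <- frame_mode_profile(st, activity_floor = 100 + 0.4 * gain)
  classify_direction(traj,
                     window = c(b$start_frame[1], b$activity_end_frame[1]))
}

# all token sequences over an alphabet up to a maximum length
enumerate_sequences <- function(alphabet, max_len) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      out[[length(out) + 1L]] <- as.character(unlist(grid[i, ]))
    }
  }
  out
}
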