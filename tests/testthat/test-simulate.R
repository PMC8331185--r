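test_that("identical seeds give byte-identical recordings", {
  map <- default_map()
  cfg <- sim_config(seed = 31)
  r1 <- simulate_recording(cfg, map)
  r2 <- simulate_recording(cfg, map)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$truth$frame_labels, r2$truth$frame_labels)
  r3 <- simulate_recording(sim_config(seed = 32), map)
  expect_false(identical(r1$events, r3$events))
})

test_that("event counts decompose into planted + fillers + idiosyncratic", {
  map <- default_map()
  rec <- simulate_recording(sim_config(seed = 33), map)
  ev <- rec$truth$events
  expect_equal(nrow(rec$events), nrow(ev))
  expect_equal(nrow(ev),
               sum(!ev$idiosyncratic & !ev$filler) +
                 sum(ev$filler) + sum(ev$idiosyncratic))
  # every emitted event names a valid muscle instance
  key <- paste(ev$muscle, ev$segment, ev$side)
  expect_true(all(key %in% paste(map$muscle, map$segment, map$side)))
  # intervals half-open and sane
  expect_true(all(ev$offset_frame > ev$onset_frame))
  expect_true(all(ev$onset_frame >= 0))
})

test_that("ground truth is internally consistent", {
  map <- default_map()
  rec <- simulate_recording(sim_config(seed = 34), map)
  tr <- rec$truth
  # phase intervals ordered and non-overlapping
  pi <- tr$phase_intervals
  expect_true(all(diff(pi$start_frame) > 0))
  expect_true(all(pi$end_frame[-nrow(pi)] <= pi$start_frame[-1]))
  # frame labels cover all frames with known classes
  expect_length(tr$frame_labels, rec$n_frames)
  expect_true(all(tr$frame_labels %in%
                    default_syllabary()$movement_classes))
  # every event lies inside its bout's activity span
  for (b in unique(tr$events$bout_id)) {
    eb <- tr$events[tr$events$bout_id == b, ]
    tb <- tr$bouts[tr$bouts$bout_id == b, ]
    expect_gte(min(eb$onset_frame), tb$start_frame)
    expect_lte(max(eb$offset_frame), tb$activity_end_frame)
  }
})

test_that("traces respond at onsets with exponential decay", {
  map <- default_map()
  cfg <- sim_config(seed = 35, noise_sd = 0,
                    kinetics = list(tau_decay = 6, amp_meanlog = 0.3,
                                    amp_sdlog = 0))
  rec <- simulate_recording(cfg, map)
  ev <- rec$truth$events[1, ]
  row <- paste(ev$muscle, ev$segment, ev$side, sep = ".")
  tr <- rec$traces[row, ]
  on <- ev$onset_frame + 1L
  expect_gt(tr[on], 0)
  # decay by a factor e^(-1/6) per frame where no new event interferes
  expect_equal(tr[on + 1] / tr[on], exp(-1 / 6), tolerance = 1e-6)
})

test_that("idiosyncratic injection matches its binomial design", {
  map <- default_map()
  # fraction across seeds concentrates on the configured rate
  fr <- vapply(1:10, function(s) {
    rec <- simulate_recording(sim_config(seed = 40 + s,
                                         idiosyncratic_rate = 0.3), map)
    ev <- rec$truth$events
    mean(ev$idiosyncratic[ev$movement != "Rest"])
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
  # rate 0 injects nothing outside P0 twitching
  rec0 <- simulate_recording(sim_config(seed = 44, idiosyncratic_rate = 0),
                             map)
  ev0 <- rec0$truth$events
  expect_equal(sum(ev0$idiosyncratic[ev0$movement != "Rest"]), 0)
})

test_that("perturbation contracts hold across seeds", {
  map <- default_map()
  base <- sim_config(seed = 1)
  expect_identical(apply_perturbation(base, "none"), base)
  expect_error(apply_perturbation(base, "mystery"),
               class = "ecdysim_invalid_config")

  for (s in 1:20) {
    # ETHRB suppression: no Lift, no M1/M15 activity in P1
    re <- simulate_recording(
      apply_perturbation(sim_config(seed = 100 + s), "ethrb_suppressed"),
      map)
    p1 <- re$truth$events[re$truth$events$phase == "P1", ]
    expect_false(any(p1$muscle %in% c("M1", "M15")))
    expect_false(any(p1$movement == "Lift"))

    # CCAP suppression: no P2/P3 intervals, exactly one swing-like bout
    rc <- simulate_recording(
      apply_perturbation(sim_config(seed = 200 + s), "ccap_suppressed"),
      map)
    expect_false(any(c("P2", "P3") %in% rc$truth$phase_intervals$phase))
    swing_bouts <- unique(rc$truth$events$bout_id[
      rc$truth$events$movement == "Swing"])
    expect_length(swing_bouts, 1L)
    # the partial swing reaches only posterior segments
    sw <- rc$truth$events[rc$truth$events$movement == "Swing" &
                            !rc$truth$events$idiosyncratic, ]
    expect_true(all(as.integer(sub("A", "", sw$segment)) >= 4))
  }

  # Bursicon suppression: one full-length swing-like wave plus sparse
  # P3-like movements; class I da suppression: sustained P0 only
  for (s in 1:20) {
    rb <- simulate_recording(
      apply_perturbation(sim_config(seed = 300 + s), "burs_suppressed"),
      map)
    swing_bouts <- unique(rb$truth$events$bout_id[
      rb$truth$events$movement == "Swing"])
    expect_length(swing_bouts, 1L)
    sw <- rb$truth$events[rb$truth$events$movement == "Swing" &
                            !rb$truth$events$idiosyncratic &
                            !rb$truth$events$filler, ]
    segs <- as.integer(sub("A", "", sw$segment))
    expect_true(min(segs) <= 2 && max(segs) >= 6)  # full-length wave
    expect_false("P2" %in% rb$truth$bouts$phase[
      rb$truth$bouts$movements != "Swing"])
    expect_true(any(rb$truth$events$phase == "P3"))

    rd <- simulate_recording(
      apply_perturbation(sim_config(seed = 400 + s),
                         "class1da_suppressed"), map)
    expect_identical(unique(rd$truth$events$phase), "P0")
  }
})

test_that("rendering places intensity inside the active muscle's ROI", {
  map <- make_muscle_map(7, with_rois = TRUE)
  inst <- paste(map$muscle, map$segment, map$side, sep = ".")
  tr <- matrix(0, nrow = nrow(map), ncol = 4, dimnames = list(inst, NULL))
  k <- 37
  tr[k, 2] <- 1.5
  st <- render_frames(list(traces = tr), map, background = 100, gain = 100)
  # silent frame: uniform background
  expect_true(all(st[, , 1] == 100))
  # active frame: argmax inside the muscle's ROI
  idx <- which(st[, , 2] == max(st[, , 2]), arr.ind = TRUE)
  expect_true(all(idx[, 1] - 1 >= map$roi_row0[k] &
                    idx[, 1] - 1 < map$roi_row1[k]))
  expect_true(all(idx[, 2] - 1 >= map$roi_col0[k] &
                    idx[, 2] - 1 < map$roi_col1[k]))
  expect_error(render_frames(list(traces = tr), default_map()),
               class = "ecdysim_invalid_config")
})

test_that("a planted P-to-A wave moves ROI row centroids anteriorly", {
  map <- make_muscle_map(7, with_rois = TRUE)
  rec <- simulate_recording(wave_config(5, "Swing"), map)
  ev <- rec$truth$events
  # follow one swept compression ensemble through the wave: its successive
  # occurrences move to smaller (more anterior) ROI rows
  ev <- ev[!ev$idiosyncratic & !ev$filler & ev$syllable == "PME2", ]
  occ_key <- paste(ev$syllable, ev$segment)
  rows_mid <- (map$roi_row0 + map$roi_row1)[
    match(paste(ev$muscle, ev$segment, ev$side),
          paste(map$muscle, map$segment, map$side))] / 2
  centroid <- tapply(rows_mid, occ_key, mean)
  onset <- tapply(ev$onset_frame, occ_key, min)
  centroids <- centroid[order(onset)]
  expect_gte(length(centroids), 5)
  expect_true(all(diff(centroids) < 0))
})

test_that("TIFF round trip preserves the stack and its metadata", {
  map <- make_muscle_map(7, with_rois = TRUE)
  rec <- simulate_recording(wave_config(6, "Swing"), map)
  st <- render_frames(rec, map, frames = 0:9)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(st, path, fps = 2)
  back <- read_stack_tiff(path)
  expect_equal(dim(back$stack), dim(st))
  expect_lt(max(abs(back$stack - st)), 1)  # 16-bit quantization
  expect_equal(back$meta$fps, 2)
  expect_equal(back$meta$orientation, "row0_anterior")
})

test_that("coupled peak trains echo NMJ input at the planted probability", {
  tr <- simulate_coupled_trains(5000, density = 0.05, coupling_p = 0.8,
                                seed = 3)
  expect_true(!is.unsorted(tr$nmj, strictly = TRUE))
  expect_true(!is.unsorted(tr$muscle, strictly = TRUE))
  frac <- mean(tr$nmj %in% tr$muscle)
  expect_lt(abs(frac - 0.8 - 0.2 * 0.05 * (1 - 0.8)), 0.06)
})
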