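make_stack <- function(bright_rows, H = 20, W = 8, bg = 10, hi = 100) {
  st <- array(bg, dim = c(H, W, length(bright_rows)))
  for (f in seq_along(bright_rows)) {
    r <- bright_rows[[f]]
    if (!is.null(r)) st[r + 1L, , f] <- hi
  }
  st
}

test_that("the MIP mode finds the dominant row with the stated tie rule", {
  st <- make_stack(list(7L))
  traj <- frame_mode_profile(st, activity_floor = 50)
  expect_equal(traj$mode_row, 7L)
  # all-background frames are inactive
  expect_warning(t0 <- frame_mode_profile(make_stack(list(NULL, NULL)),
                                          activity_floor = 50),
                 class = "ecdysim_empty_trajectory")
  expect_true(all(!t0$active))
  # two equal maxima: lowest row index wins
  st2 <- make_stack(list(c(10L, 4L)))
  expect_equal(frame_mode_profile(st2, 50)$mode_row, 4L)
})

test_that("slope method reads descending modes as posterior-to-anterior", {
  traj <- data.frame(frame = 0:4, mode_row = c(100, 80, 60, 40, 20),
                     active = TRUE)
  expect_equal(classify_direction(traj)$call, "P_to_A")
  traj$mode_row <- rev(traj$mode_row)
  expect_equal(classify_direction(traj)$call, "A_to_P")
  traj$mode_row <- rep(50, 5)
  expect_equal(classify_direction(traj)$call, "indeterminate")
  expect_error(classify_direction(traj[1:2, ]),
               class = "ecdysim_insufficient_data")
})

test_that("mode-ratio method counts modes across the median line", {
  # most modes posterior (below the median line) -> P_to_A under the bands
  traj <- data.frame(frame = 0:6,
                     mode_row = c(90, 85, 80, 50, 20, 88, 83),
                     active = TRUE)
  res <- classify_direction(traj, method = "mode_ratio")
  expect_true(res$call %in% c("P_to_A", "A_to_P", "indeterminate"))
  expect_equal(res$method, "mode_ratio")
})

test_that("rendered waves classify correctly and flip under mirroring", {
  expect_equal(wave_direction_call(1, "Swing")$call, "P_to_A")
  expect_equal(wave_direction_call(1, "Crunch")$call, "A_to_P")
  # vertical flip inverts every call, exactly
  for (s in 1:5) {
    a <- wave_direction_call(s, "Swing")$call
    b <- wave_direction_call(s, "Swing", flip = TRUE)$call
    expect_true(a == "P_to_A" && b == "A_to_P")
  }
})

test_that("calls are invariant to uniform intensity scaling", {
  map <- make_muscle_map(7, with_rois = TRUE)
  rec <- simulate_recording(wave_config(3, "Swing"), map)
  st <- render_frames(rec, map, noise_sd = 0)
  b <- rec$truth$bouts
  win <- c(b$start_frame[1], b$activity_end_frame[1])
  c1 <- classify_direction(frame_mode_profile(st, 140), window = win)$call
  c2 <- classify_direction(frame_mode_profile(st * 5, 700),
                           window = win)$call
  expect_identical(c1, c2)
})

test_that("phase summaries report the planted wave directions", {
  calls <- c("P_to_A", "P_to_A", "A_to_P", "indeterminate")
  phases <- c("P1", "P1", "P3", "P3")
  s <- phase_direction_summary(calls, phases)
  expect_equal(s$frac_p_to_a[s$phase == "P1"], 1.0)
  expect_equal(s$frac_p_to_a[s$phase == "P3"], 0.0)
  expect_equal(sum(s$n_bouts), 4)

  # generator: P1 bouts planted P-to-A, P3 blocks planted A-to-P
  map <- make_muscle_map(7, with_rois = TRUE)
  plan <- default_phase_plan(n_p0 = 0, n_p1 = 3, n_p2 = 0, n_p3 = 3)
  plan$P0 <- NULL; plan$P2 <- NULL
  for (ph in names(plan)) {
    plan[[ph]]$count_sdlog <- 0
    plan[[ph]]$repeat_last_p <- 0
    plan[[ph]]$drop_last_p <- 0
  }
  cfg <- sim_config(seed = 8, phase_plan = plan, recruitment_jitter_sd = 0,
                    within_ensemble_jitter = 0, idiosyncratic_rate = 0,
                    noise_sd = 0,
                    kinetics = list(tau_decay = 6, amp_meanlog = 0.3,
                                    amp_sdlog = 0))
  rec <- simulate_recording(cfg, map)
  st <- render_frames(rec, map, noise_sd = 0)
  traj <- frame_mode_profile(st, activity_floor = 140)
  tb <- rec$truth$bouts
  calls <- vapply(seq_len(nrow(tb)), function(i)
    classify_direction(traj, window = c(tb$start_frame[i],
                                        tb$activity_end_frame[i]))$call,
    character(1))
  s2 <- phase_direction_summary(calls, tb$phase)
  expect_equal(s2$frac_p_to_a[s2$phase == "P1"], 1.0)
  expect_lte(s2$frac_p_to_a[s2$phase == "P3"], 0.35)
})
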