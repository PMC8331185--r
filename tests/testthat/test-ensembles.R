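test_that("co-active groups come from interval intersections of >= 3 frames", {
  ev <- data.frame(muscle = c("M21", "M22", "M23"),
                   onset_frame = c(10, 11, 9),
                   offset_frame = c(16, 15, 14))
  cg <- coactive_groups(ev)
  expect_equal(cg$muscles, "M21+M22+M23")
  expect_equal(cg$start_frame, 11)
  expect_equal(cg$end_frame, 14)

  # two muscles overlapping only 2 frames do not qualify
  ev2 <- data.frame(muscle = c("M1", "M2"),
                    onset_frame = c(0, 4), offset_frame = c(6, 10))
  expect_equal(nrow(coactive_groups(ev2)), 0L)

  # single event: no candidates
  ev3 <- data.frame(muscle = "M1", onset_frame = 0, offset_frame = 9)
  expect_equal(nrow(coactive_groups(ev3)), 0L)

  expect_error(coactive_groups(data.frame(muscle = "M1", onset_frame = 5,
                                          offset_frame = 5)),
               class = "ecdysim_invalid_data")
})

test_that("a subset is reported separately only in disjoint intervals", {
  # {M1,M2} qualifies alone late in the bout, after a triple occurrence
  ev <- data.frame(muscle = c("M1", "M2", "M3", "M1", "M2"),
                   onset_frame = c(0, 0, 0, 20, 20),
                   offset_frame = c(5, 5, 5, 25, 25))
  cg <- coactive_groups(ev)
  expect_setequal(cg$muscles, c("M1+M2+M3", "M1+M2"))
  pair <- cg[cg$muscles == "M1+M2", ]
  expect_equal(pair$start_frame, 20)
})

# build a toy cohort where one planted pair appears in a controlled
# fraction of bouts per animal
toy_cohort <- function(n_animals, n_bouts, hit_bouts) {
  rows <- list()
  for (a in seq_len(n_animals)) {
    for (b in seq_len(n_bouts)) {
      base <- (b - 1) * 50
      if (b <= hit_bouts[a]) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("A%02d", a), bout_id = b, movement = "Mv",
          muscle = c("M1", "M2"), onset_frame = base + c(0, 1),
          offset_frame = base + c(6, 6))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("A%02d", a), bout_id = b, movement = "Mv",
          muscle = c("M1", "M8"), onset_frame = base + c(0, 10),
          offset_frame = base + c(2, 12))
      }
    }
  }
  do.call(rbind, rows)
}

test_that("the 80%/80% thresholds act exactly on planted supports", {
  # pair in 9/10 bouts for 9/10 animals -> retained
  ev <- toy_cohort(10, 10, c(rep(9, 9), 0))
  cat1 <- discover_pmes(ev)
  expect_equal(length(cat1$pmes), 1L)
  expect_setequal(cat1$pmes[[1]]$muscles, c("M1", "M2"))
  # pair passing in only 7/10 animals -> rejected
  ev2 <- toy_cohort(10, 10, c(rep(9, 7), 0, 0, 0))
  expect_equal(length(discover_pmes(ev2)$pmes), 0L)
})

test_that("raising either support threshold never enlarges the catalog", {
  sim <- simulate_pme_recovery(seed = 42, n_animals = 4, n_bouts = 8)
  sets_at <- function(wf, af) {
    sapply(discover_pmes(sim$events, within_animal_frac = wf,
                         across_animal_frac = af)$pmes,
           function(p) paste(sort(p$muscles), collapse = "+"))
  }
  base <- sets_at(0.6, 0.6)
  expect_true(all(sets_at(0.8, 0.6) %in% base))
  expect_true(all(sets_at(0.6, 0.8) %in% base))
  expect_true(all(sets_at(0.9, 0.9) %in% sets_at(0.8, 0.8)))
})

test_that("recovery degrades monotonically as within-ensemble jitter grows", {
  recov <- vapply(c(0, 2, 5), function(j) {
    hits <- vapply(1:3, function(s) {
      sim <- simulate_pme_recovery(seed = 50 + s, n_animals = 4,
                                   n_bouts = 10,
                                   within_ensemble_jitter = j)
      found <- vapply(discover_pmes(sim$events)$pmes,
                      function(p) paste(sort(p$muscles), collapse = "+"),
                      character(1))
      planted <- vapply(sim$planted,
                        function(m) paste(sort(m), collapse = "+"),
                        character(1))
      sum(planted %in% found)
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(recov[1] >= recov[2])
  expect_true(recov[2] >= recov[3])
  expect_lt(recov[3], recov[1])  # strict degradation overall
})

test_that("single syllables require support and PME exclusion", {
  # M12 active in most Swing bouts, never grouped; M13 sits inside a PME
  rows <- list()
  for (a in 1:10) {
    for (b in 1:10) {
      base <- (b - 1) * 60
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("A%02d", a), bout_id = b, movement = "Swing",
        muscle = c("M13", "M15", if (b <= 9 || a > 9) "M12"),
        onset_frame = base + c(0, 1, 12)[seq_len(2 + (b <= 9 || a > 9))],
        offset_frame = base + c(6, 6, 14)[seq_len(2 + (b <= 9 || a > 9))])
    }
  }
  ev <- do.call(rbind, rows)
  cat_ <- discover_pmes(ev)
  expect_equal(length(cat_$pmes), 1L)  # {M13,M15}
  cat_ <- single_muscle_syllables(ev, cat_)
  singles <- vapply(cat_$singles, function(s) s$muscle, character(1))
  expect_true("M12" %in% singles)
  expect_false(any(c("M13", "M15") %in% singles))
})

test_that("annotation assigns activations and measures off-syllable share", {
  catalog <- syllable_catalog(list(P1 = c("M1", "M2")), singles = "M12")
  ev <- data.frame(
    muscle = c("M1", "M2", "M12", "M9"),
    onset_frame = c(0, 1, 10, 20),
    offset_frame = c(6, 6, 12, 22))
  ann <- annotate_syllables(ev, catalog)
  expect_equal(ann$assignment, c("P1", "P1", "M12", NA))
  expect_equal(ann$off_syllable_fraction, 0.25)
  # fully annotated bout
  ann2 <- annotate_syllables(ev[1:3, ], catalog)
  expect_equal(ann2$off_syllable_fraction, 0)
})

test_that("generator off-syllable fraction tracks the idiosyncratic rate", {
  map <- default_map()
  # planted off-syllable fraction (ground-truth flags) ~ rate, binomially
  fracs <- vapply(1:20, function(s) {
    rec <- simulate_recording(sim_config(seed = 600 + s,
                                         idiosyncratic_rate = 0.3), map)
    ev <- rec$truth$events
    ev <- ev[ev$movement != "Rest", ]
    mean(ev$idiosyncratic)
  }, numeric(1))
  n_typ <- 400  # typical activations per recording
  expect_lt(abs(mean(fracs) - 0.3), 3 * sqrt(0.3 * 0.7 / n_typ))

  # annotation-based off fraction: idiosyncratic twitches of muscles that
  # are themselves single syllables are legitimately annotated, so the
  # measured fraction is bounded by the planted rate and stays well above
  # zero for rate 0.3
  catalog <- planted_catalog()
  rec <- simulate_recording(sim_config(seed = 601,
                                       idiosyncratic_rate = 0.3), map)
  ev <- rec$truth$events
  ev <- ev[ev$movement != "Rest", ]
  key <- paste(ev$bout_id, ev$movement_instance)
  offs <- vapply(split(ev, key), function(e)
    c(sum(is.na(annotate_syllables(e, catalog)$assignment)), nrow(e)),
    numeric(2))
  frac_ann <- sum(offs[1, ]) / sum(offs[2, ])
  expect_gt(frac_ann, 0.05)
  expect_lt(frac_ann, 0.35)
})

test_that("co-active duration share follows its arithmetic definition", {
  se <- data.frame(syllable = "P", onset_frame = 0,
                   coactive_start = c(0, 10), coactive_end = c(3, 13))
  expect_equal(coactive_duration_share(se, 3), 1.0)
  se2 <- data.frame(coactive_start = c(0, 50), coactive_end = c(20, 70))
  expect_equal(coactive_duration_share(se2, 3), 0.15)
  se3 <- data.frame(coactive_start = c(0, 10), coactive_end = c(3, 16))
  expect_equal(coactive_duration_share(se3, 3), 0.75)
})

test_that("no muscle is both a PME member and a single syllable", {
  sim <- simulate_pme_recovery(seed = 7, n_animals = 4, n_bouts = 10)
  cat_ <- discover_pmes(sim$events)
  cat_ <- single_muscle_syllables(sim$events, cat_)
  members <- unlist(lapply(cat_$pmes, function(p) p$muscles))
  singles <- vapply(cat_$singles, function(s) s$muscle, character(1))
  expect_length(intersect(members, singles), 0)
})
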