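test_that("contraction metrics follow the onset-anchored percent formulas", {
  m <- contraction_metrics(data.frame(f_onset = 50, f_max = 150,
                                      length_onset_um = 100,
                                      length_min_um = 75))
  expect_equal(m$dll_pct, 25)
  expect_equal(m$dff_pct, 200)
  iso <- contraction_metrics(data.frame(f_onset = 80, f_max = 90,
                                        length_onset_um = 120,
                                        length_min_um = 120))
  expect_equal(iso$dll_pct, 0)
  expect_false(iso$lengthening)
  # lengthening flagged, not clipped
  len <- contraction_metrics(data.frame(f_onset = 80, f_max = 90,
                                        length_onset_um = 100,
                                        length_min_um = 110))
  expect_equal(len$dll_pct, -10)
  expect_true(len$lengthening)
  expect_error(contraction_metrics(data.frame(f_onset = 0, f_max = 1,
                                              length_onset_um = 10,
                                              length_min_um = 9)),
               class = "ecdysim_invalid_data")
})

test_that("metrics are invariant to length units and fluorescence gain", {
  ev <- data.frame(f_onset = 50, f_max = 130, length_onset_um = 100,
                   length_min_um = 70)
  base <- contraction_metrics(ev)
  px <- ev
  px$length_onset_um <- ev$length_onset_um * 3.2
  px$length_min_um <- ev$length_min_um * 3.2
  expect_equal(contraction_metrics(px)$dll_pct, base$dll_pct)
  g <- ev
  g$f_onset <- ev$f_onset * 1.7
  g$f_max <- ev$f_max * 1.7
  expect_equal(contraction_metrics(g)$dff_pct, base$dff_pct)
})

test_that("aggregation conserves contraction counts", {
  set.seed(4)
  ev <- data.frame(muscle = sample(c("M1", "M21"), 40, TRUE),
                   segment = sample(c("A3", "A4", "A5"), 40, TRUE),
                   phase = "P2",
                   f_onset = 100, f_max = runif(40, 150, 300),
                   length_onset_um = 100,
                   length_min_um = runif(40, 60, 95))
  met <- contraction_metrics(ev)
  agg <- aggregate_metrics(met, by = c("muscle", "segment"))
  expect_equal(sum(agg$n), 40)
  expect_lte(nrow(agg), 6)
  one <- aggregate_metrics(
    contraction_metrics(data.frame(muscle = "M1", f_onset = 100,
                                   f_max = c(110, 120),
                                   length_onset_um = 100,
                                   length_min_um = c(90, 80))),
    by = "muscle")
  expect_equal(one$mean_dll_pct, 15)
})

test_that("generator plants the posterior-to-anterior PME2 shortening gradient", {
  map <- default_map()
  ev <- do.call(rbind, lapply(1:5, function(s)
    simulate_recording(sim_config(seed = 700 + s), map)$events))
  p2 <- ev[ev$phase == "P2" & ev$muscle %in% c("M21", "M22", "M23") &
             ev$segment %in% c("A3", "A4", "A5"), ]
  expect_gte(min(table(p2$segment)[c("A3", "A4", "A5")]), 5)
  agg <- aggregate_metrics(contraction_metrics(p2), by = "segment")
  m <- stats::setNames(agg$mean_dll_pct, agg$segment)
  expect_gt(m["A5"], m["A4"])
  expect_gt(m["A4"], m["A3"])
})

test_that("fluorescence-shortening correlation behaves across regimes", {
  # exact linear relation
  met <- data.frame(dff_pct = 1:20, dll_pct = 3 * (1:20) + 2)
  expect_equal(abs(shortening_fluorescence_correlation(met)$r_shortening), 1)
  # the two codings are sign-mirrored
  r <- shortening_fluorescence_correlation(
    data.frame(dff_pct = rnorm(50), dll_pct = rnorm(50)))
  expect_equal(r$r_signed_length, -r$r_shortening)
  # independence: |r| < 0.15 in at least 95% of 100 seeded replicates
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    abs(cor(rnorm(500), rnorm(500))) < 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # planted effect size: |r| within 0.1 of sqrt(0.3) over 50 replicates
  rho <- sqrt(0.3)
  rs <- vapply(1:50, function(s) {
    set.seed(s)
    z <- rnorm(400)
    x <- 150 + 50 * z
    y <- 25 + 8 * (rho * z + sqrt(1 - rho^2) * rnorm(400))
    shortening_fluorescence_correlation(
      data.frame(dff_pct = x, dll_pct = y))$r_shortening
  }, numeric(1))
  expect_lt(abs(mean(rs) - rho), 0.1)
  # degenerate variance signals, not errors
  expect_warning(
    und <- shortening_fluorescence_correlation(
      data.frame(dff_pct = rep(1, 5), dll_pct = 1:5)),
    class = "ecdysim_undefined_correlation")
  expect_true(is.na(und$r_shortening))
})

test_that("the default recording carries the planted |r| = 0.54 coupling", {
  map <- default_map()
  rs <- vapply(1:5, function(s) {
    rec <- simulate_recording(sim_config(seed = 710 + s), map)
    met <- contraction_metrics(rec$events)
    shortening_fluorescence_correlation(met)$r_shortening
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.54), 0.1)
  # signed length-change coding is negative by construction
  expect_lt(-mean(rs), 0)
})
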