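toy_stack <- function(n_frames, seed = 1) {
  set.seed(seed)
  array(runif(12 * 8 * n_frames), dim = c(12, 8, n_frames))
}

test_that("window extraction follows the 25-frame center-label contract", {
  labs <- rep(c("Rest", "Lift"), length.out = 25)
  ds <- make_windows(toy_stack(25), labs)
  expect_equal(length(ds$centers), 1L)
  expect_equal(ds$centers, 12L)
  expect_equal(ds$labels, labs[13])

  labs100 <- sample(c("Rest", "Swing"), 100, TRUE)
  ds100 <- make_windows(toy_stack(100), labs100)
  expect_equal(length(ds100$centers), 76L)
  expect_equal(ds100$labels, labs100[ds100$centers + 1L])

  expect_error(make_windows(toy_stack(24), rep("Rest", 24)),
               class = "ecdysim_insufficient_data")
})

test_that("window counts are conserved across animals", {
  ns <- c(40, 63, 25)
  total <- sum(vapply(seq_along(ns), function(i) {
    ds <- make_windows(toy_stack(ns[i], seed = i),
                       rep(c("Rest", "Lift"), length.out = ns[i]))
    length(ds$centers)
  }, numeric(1)))
  expect_equal(total, sum(ns - 24))
})

test_that("training rejects degenerate single-class data", {
  ds <- make_windows(toy_stack(60), rep("Rest", 60))
  expect_error(train_classifier(ds), class = "ecdysim_invalid_data")
})

test_that("early stopping keeps the best weights after `patience` epochs", {
  set.seed(11)
  labs <- rep(c("Rest", "Lift", "Swing"), length.out = 80)
  ds1 <- make_windows(toy_stack(80, 1), labs, animal_id = "A01")
  ds2 <- make_windows(toy_stack(80, 2), labs, animal_id = "A02")
  cfg <- classifier_config(patience = 5, max_epochs = 300, seed = 3)
  model <- train_classifier(list(ds1, ds2), cfg, val_animals = "A02")
  log <- model$log
  if (model$stopped_epoch < cfg$max_epochs) {
    best <- which.min(log$val_loss)
    expect_equal(model$stopped_epoch, best + cfg$patience)
    expect_true(all(log$val_loss[(best + 1):nrow(log)] >=
                      min(log$val_loss) - 1e-9))
  } else {
    succeed("training ran to max_epochs without a patience stop")
  }
})

test_that("predictions are a probability simplex and deterministic", {
  map <- make_muscle_map(7, with_rois = TRUE)
  rec <- simulate_recording(sim_config(seed = 801), map, "A01")
  st <- render_frames(rec, map, noise_sd = 10)
  ds <- make_windows(st, rec$truth$frame_labels, "A01")
  rec2 <- simulate_recording(sim_config(seed = 802), map, "A02")
  st2 <- render_frames(rec2, map, noise_sd = 10)
  ds2 <- make_windows(st2, rec2$truth$frame_labels, "A02")
  model <- train_classifier(list(ds, ds2),
                            classifier_config(max_epochs = 60, seed = 1),
                            val_animals = "A02")
  pred <- predict_movements(model, st2)
  expect_equal(unname(rowSums(pred$probs)), rep(1, dim(st2)[3]),
               tolerance = 1e-6)
  pred_again <- predict_movements(model, st2)
  expect_identical(pred$labels, pred_again$labels)
  # edge frames inherit the nearest valid window's prediction
  expect_identical(pred$labels[1], pred$labels[13])
  expect_identical(pred$labels[dim(st2)[3]],
                   pred$labels[dim(st2)[3] - 12])
})

test_that("evaluation aggregates confusion, accuracy, and durations", {
  classes <- default_syllabary()$movement_classes
  truth <- sample(classes, 200, TRUE)
  ev1 <- evaluate_predictions(truth, truth)
  expect_equal(ev1$accuracy, 1)
  expect_equal(sum(diag(ev1$confusion)), 200)
  # constant Rest prediction scores the Rest prevalence
  ev2 <- evaluate_predictions(rep("Rest", 200), truth)
  expect_equal(ev2$accuracy, mean(truth == "Rest"))
  # duration table conserves per-class frame counts (at 2 Hz)
  pred <- sample(classes, 200, TRUE)
  ev3 <- evaluate_predictions(pred, truth, fps = 2)
  expect_equal(sum(ev3$durations$total_s), 200 / 2)
  for (cl in classes) {
    expect_equal(ev3$durations$total_s[ev3$durations$class == cl],
                 sum(pred == cl) / 2)
  }
  expect_error(evaluate_predictions(pred[1:10], truth),
               class = "ecdysim_invalid_data")
})
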