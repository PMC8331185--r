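#!/usr/bin/env Rscript
# Train the sliding-window frame-wise movement classifier on rendered
# movies of four animals and evaluate on a held-out animal.

suppressPackageStartupMessages(library(ecdysim))

seed <- 1L
map <- make_muscle_map(7, with_rois = TRUE)
sets <- lapply(1:5, function(i) {
  rec <- simulate_recording(sim_config(seed = seed + 6000L + i), map,
                            sprintf("A%02d", i))
  st <- render_frames(rec, map, noise_sd = 10)
  list(ds = make_windows(st, rec$truth$frame_labels, sprintf("A%02d", i)),
       stack = st, labels = rec$truth$frame_labels)
})

model <- train_classifier(lapply(sets[1:4], `[[`, "ds"),
                          classifier_config(seed = seed),
                          val_animals = "A04")
cat(sprintf("training stopped after %d epochs (patience %d)\n",
            model$stopped_epoch, model$config$patience))
utils::write.csv(model$log, "results/classifier_training_log.csv",
                 row.names = FALSE)

pred <- predict_movements(model, sets[[5]]$stack)
ev <- evaluate_predictions(pred$labels, sets[[5]]$labels)
cat(sprintf("held-out animal frame accuracy: %.3f\n", ev$accuracy))
print(ev$per_class, row.names = FALSE)
utils::write.csv(ev$per_class, "results/classifier_per_class.csv",
                 row.names = FALSE)
utils::write.csv(ev$durations, "results/movement_durations.csv",
                 row.names = FALSE)
utils::write.csv(data.frame(frame = seq_along(pred$labels) - 1L,
                            label = pred$labels,
                            max_prob = pred$max_prob),
                 "results/predictions_heldout.csv", row.names = FALSE)
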