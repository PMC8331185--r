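# ecdysim

Muscle-level simulation and analysis of Drosophila pupal ecdysis
behavior.

During pupal ecdysis a fly pupa sheds its old cuticle through a staged
motor sequence — a pre-ecdysis twitching phase (P0) followed by three
motor programs (P1–P3) built from eight canonical movements. Pan-muscle
Ca++ imaging resolves every body-wall muscle, and `ecdysim` implements
the quantitative pipeline for describing behavior from that signal, for
researchers in computational ethology and motor-systems neuroscience:

- **signal**: ΔF/F normalization (`(F − F0)/F0`, F0 = mean of the first
  50 frames), moving averages, peak detection, rasters, and Pearson
  correlation of dilated peak trains;
- **segmentation**: bouts as maximal runs of activation onsets flanked by
  ≥ 2 onset-free frames, with per-phase mean/SD/CV summaries;
- **ensembles**: pupal muscle ensembles (PMEs) — muscle sets co-active
  for ≥ 3 consecutive frames in ≥ 80% of a movement's instances in
  ≥ 80% of animals — plus single-muscle syllables and off-syllable
  quantification;
- **sequences**: activation-order stereotypy scored by the gestalt
  (Ratcliff–Obershelp) similarity `SS = 2M/T` at muscle, syllable, and
  compartment levels, against a shuffled-sequence permutation null;
- **directionality**: posterior-to-anterior vs anterior-to-posterior wave
  calls from the per-frame mode of the horizontal maximum-intensity
  projection (robust Theil–Sen slope by default);
- **mechanics**: per-contraction shortening `ΔL/L` and fluorescence rise
  `ΔF/F` (percent, onset-anchored) and their correlation under both sign
  codings;
- **classifier**: a sliding-window (25-frame) frame-wise movement
  classifier over 9 classes with Adam, categorical cross-entropy, and
  patience-based early stopping;
- **synthetic_data**: a ground-truthed generator of pupal-ecdysis
  recordings (event tables, GCaMP-like traces, rendered multi-page TIFF
  movies) with configurable jitter, idiosyncratic activity, and
  neuromodulator-suppression perturbation modes, so every analysis is
  testable by parameter recovery.

## Worked example

```r
library(ecdysim)

map  <- make_muscle_map(7, with_rois = TRUE)
recs <- simulate_cohort(sim_config(seed = 1), map, n_animals = 8)
events <- cohort_events(recs, truth = TRUE)

# discover ensembles at the 3-frame / 80% / 80% criteria
catalog <- discover_pmes(events)
length(catalog$pmes)
#> [1] 8

# P1 muscle-activation-order stereotypy vs shuffled sequences
p1 <- events[events$phase == "P1", ]
ms <- movement_sequences(p1, "muscle")
nl <- shuffled_null(ms$sequences, n_perm = 1000, seed = 1, group = ms$group)
round(c(observed = nl$observed_mean, shuffled = nl$null_mean), 3)
#>  observed  shuffled
#>     0.554     0.358
nl$p_value
#> [1] 0.000999001
```

The discovered catalog recovers the eight planted ensembles; the observed
mean similarity of P1 muscle sequences (0.55) is modest — muscle
recruitment order is variable — but far above its shuffled-sequence null
(0.36, p ≈ 0.001): the sequences are not random. Running the similarity
at coarser levels of description (`"syllable"`, `"compartment"`) raises
the mean score (0.54 → 0.61 → 0.66 with the default generator), the
package's version of the finding that stereotypy grows with the
spatiotemporal level of description.

The `analysis/` directory contains the full workflow as numbered scripts
(`01_simulate.R` … `08_perturbations.R`); each writes its tables under
`results/`.

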