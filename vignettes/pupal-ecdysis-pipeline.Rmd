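---
title: "Quantifying pupal ecdysis behavior from single-muscle calcium activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pupal ecdysis behavior from single-muscle calcium activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdysim)
```

## The problem

During pupal ecdysis, a Drosophila pupa sheds its old cuticle through a
fixed succession of behavioral phases: a pre-ecdysis period of apparently
random muscle twitching (P0) followed by three motor programs (P1-P3)
built from eight canonical movements (Lift, RollCon, Swing, Brace, Crunch,
AntComp, PostCon, PostSwing). Pan-muscle Ca++ imaging at 2 Hz resolves
every body-wall muscle individually, which makes the sequence an unusually
complete testbed for a question at the heart of computational ethology:
at which level of description - individual muscles, muscle ensembles
(syllables), movements, phases - does stereotypy emerge?

`ecdysim` implements the full quantitative pipeline for that question:

1. trace processing (dF/F, smoothing, peak detection, rasters, peak-train
   correlation),
2. bout segmentation and per-phase variability,
3. co-activation mining of pupal muscle ensembles (PMEs) and single-muscle
   syllables,
4. activation-order stereotypy scored by gestalt sequence similarity
   against a shuffled-sequence permutation null,
5. anterior-posterior wave direction from intensity-projection modes,
6. contraction mechanics (shortening vs fluorescence),
7. a sliding-window frame-wise movement classifier,

together with a ground-truthed synthetic recording generator, so that
every stage can be validated by parameter recovery without the original
imaging data.

## The synthetic generator

### What it emulates

`make_muscle_map()` builds the hemisegmental muscle roster (A1-A7, both
sides, dorsal/lateral/ventral compartments, anterior-posterior boundary
between A4 and A5; M12 and M5 are absent from posterior segments).
`sim_config()` + `simulate_recording()` produce one animal: an
activation-event table in the package's canonical schema, per-muscle dF/F
traces (instant rise, exponential decay with a 6-frame time constant -
a GCaMP6s-like kernel at 2 Hz), and a complete ground truth (phase
intervals, bouts, planted syllable catalog, recruitment orders, wave
directions, frame-wise movement labels).

The movement vocabulary is the eight-movement syllabary with PME
memberships PME1 = {M26, M13, M8}, PME2 = {M21, M22, M23}, PME3 =
{M2, M3}, PME4 = {M1, M2, M3} (note the nesting: PME3 is contained in
PME4; the two are distinguishable because they drive different
movements). Memberships of PME5-PME8 are not documented; the defaults are
explicit placeholders from the roster and are configurable.

### The cluster timing model

Within a bout, syllables are scheduled as dense clusters. Ensemble
members onset on successive frames (1-frame stagger) and share a common
planned offset `coactive_window` (default 4) frames after the last
member's planned onset, so bounded member-onset jitter widens individual
durations instead of shattering the co-active window ("the ensemble
releases together"). Successive clusters advance by the full window
(`spread + coactive_window` frames) so that neighboring clusters do not
overlap a window for 3 or more frames under typical jitter; wherever
jitter still opens a gap of 2+ frames between new activations,
deterministic *filler* re-activations of already-active muscles bridge it
(continuous recruitment), which keeps the 2-frame bout rule valid without
affecting co-activity structure. Single-muscle syllables and
idiosyncratic twitches last 2 frames - deliberately below the 3-frame
co-activity window, so they can never masquerade as ensemble members.

The Swing is modeled as what it is anatomically: a hemisegment-by-
hemisegment compression wave. Its three dorsoventral compression
ensembles (PME1 ventral, PME2 lateral, PME4 dorsal) sweep every
hemisegment from posterior to anterior, which makes P2 bouts long and
temporally regular.

This timing model is a compression of the real timescale: real co-active
ensembles overlap for tens of frames (the 3-frame criterion is roughly
15% of real co-active durations), whereas the generator's windows are
3-4 frames. The compression keeps desk-scale simulations fast but means
two things for interpretation: the co-active-duration share on generator
output is far above the ~15% seen in real annotations, and jitter
tolerances are tighter than in real data. Passing tests therefore
demonstrate correctness of the algorithms under the generator's
conditions, not effect sizes on real recordings.

### Variability model

* **Recruitment jitter** (`recruitment_jitter_sd`, Gaussian, default 2
  frames) perturbs cluster onsets and is the main source of
  activation-order variability.
* **Within-ensemble jitter** (`within_ensemble_jitter`, uniform integer
  on [-j, j], default 1 frame) perturbs member onsets inside an ensemble;
  the perturbation modes raise it beyond the window to destroy ensemble
  co-activity.
* **Idiosyncratic twitches** (`idiosyncratic_rate`, default 0.2): extra
  off-syllable activations injected as Binomial(n, r/(1-r)) so the
  expected off-syllable *fraction* equals r (valid for r < 0.5).
* **Composition noise**: P1 bouts sometimes gain a second RollCon, P3
  blocks sometimes lack the PostSwing, and per-animal bout counts are
  log-normally dispersed. Duration variability is therefore
  compositional; token order is unaffected, which preserves the
  zero-noise identity (recruitment jitter 0 + idiosyncratic rate 0 gives
  pairwise similarity exactly 1 within each movement type).
* P2 is deliberately the most tightly regulated phase - always exactly
  one Swing, near-fixed counts and inter-bout intervals - so its
  coefficients of variation come out lowest, mirroring the biology.

Default sizes (8 animals, P0:6 / P1:8 / P2:5 / P3:8 bouts) keep a full
cohort simulation plus discovery under half a minute on one CPU; they are
the problem sizes used throughout the tests and the acceptance script.

### Perturbation modes

`apply_perturbation()` encodes the neuromodulator-suppression phenotypes:
ETHRB-neuron silencing removes the Lift, silences M1/M15 during P1, and
desynchronizes PME1; CCAP-neuron silencing removes P2/P3 except for one
partial swing-like movement confined to posterior segments with
dorsoventral desynchronization; Bursicon-neuron silencing produces one
full-length desynchronized swing-like wave plus sparse P3-like movements;
class I dendritic-arbor silencing arrests the animal in a sustained,
widespread P0. These are contracts tested across 20 seeds each.

## Analysis methods and their choices

### Bouts and variability

A bout is a maximal run of activation *onsets* in which consecutive
onset-bearing frames are separated by fewer than 2 onset-free frames
(events may stay above baseline across a gap without joining bouts);
extents are half-open `[first onset, last onset + 1)`. CVs use the
sample (n-1) standard deviation; a zero mean is an undefined CV and is
signaled (classed warning + NA), never silently zero.

### Ensemble discovery

`coactive_groups()` reports maximal muscle sets co-active for at least 3
consecutive frames, built from sliding-window intersections of the
per-frame active sets; a subset occurrence is not reported where a strict
superset overlaps it, which prevents combinatorial double counting.

`discover_pmes()` applies the 3-frame / 80%-of-units / 80%-of-animals
criteria. Three choices matter:

* **Unit = movement type** (default). Support is the fraction of a
  movement type's instances containing the group. In phase-structured
  recordings no movement-specific ensemble can appear in 80% of *all*
  bouts, so the bout denominator (available as `unit = "bout"`) cannot
  reproduce a movement-resolved catalog.
* **Containment credit**: a set is counted in a unit when any maximal
  candidate contains it. An incidental extra muscle drifting into an
  ensemble's window then cannot erase the ensemble's occurrence.
* **Support dominance with an independence escape**: a set whose strict
  superset is nearly as regular (>= 0.8 of its support in the same unit
  type) is treated as the same ensemble with occasional member dropout -
  unless the subset also occurs *independently* (candidates missing a
  superset member) at the same thresholds, which is exactly how genuinely
  nested ensembles (PME3 inside PME4) behave. The 0.8 factor reflects
  that member dropout is rare (windows stay intact in well over 90% of
  occurrences), so a true parent ensemble tracks its subset's support
  closely, while incidental unions do not.

One identified limitation: in uniform bouts with no movement structure
(as in the recovery benchmark), nested ensembles that share members merge
whenever they are scheduled adjacently and are then provably
inseparable; the recovery benchmark (`simulate_pme_recovery()`,
`benchmark_ensembles()`) therefore plants eight pairwise non-nested sets.

### Sequence stereotypy

Sequences order activations by onset frame, ties broken by natural label
collation (M2 before M12). The similarity score is the gestalt
(Ratcliff-Obershelp) ratio `2M/T` - recursive longest-common-block
matching with ties broken by earliest start in the first sequence, then
the second, no junk heuristics - implemented in C++ and verified
exhaustively (all 1.19 million ordered pairs of length <= 6 over a
3-token alphabet) against an algorithmically independent brute-force
recursion, and against Python's `difflib.SequenceMatcher` on the
exhaustive length <= 4 suite. The ratio is order-dependent in rare
block-tie cases (the reference implementation behaves identically), so
pairs are always scored in a fixed canonical order; the score is a pure
function of the ordered pair.

Levels of description: *muscle* sequences use every activation including
idiosyncratic ones; *syllable* sequences use annotated syllable events
(off-syllable activity drops out); *compartment* sequences map
syllable-assigned activity to dorsoventral x anteroposterior tags and
emit one token per compartment activity onset (merged union intervals),
since compartments aggregate syllable activity. This gives the
level-ordering property - compartment >= syllable >= muscle mean
similarity - a mechanical basis: successive coarsening of the same
backbone.

The shuffled null permutes each sequence's own tokens (length and
multiset preserved; the within-sequence reading of the shuffle, chosen
over label-shuffling across sequences) and uses the add-one permutation
p-value `(1 + #{null >= observed}) / (n_perm + 1)`.

### Wave direction

Each frame is projected across columns by maximum intensity; the mode is
the argmax row (ties toward anterior), read as the location of the most
dominant activation. The default call is the sign of a Theil-Sen (median
of pairwise slopes) fit of mode row against frame within the bout -
robust to the outlier modes that pixel noise produces. The count-based
mode-ratio rule is retained for fidelity (`method = "mode_ratio"`) but is
near-degenerate by construction (counts around a median are balanced),
which is why the slope method is the default. Frames whose projection
maximum falls below `activity_floor` carry no mode; bouts with fewer than
3 active frames are refused rather than guessed.

### Mechanics

Shortening is measured to the minimum length within the event window
regardless of whether it coincides with peak fluorescence; lengthening
events are flagged, not clipped. Because the sign of this correlation
depends on variable coding, both codings are always reported:
`r_shortening` (dF/F vs positive shortening) and `r_signed_length`
(dF/F vs signed length change; the negative of the former). The
generator plants a coupling of magnitude 0.54 (negative under the signed
coding); truncation of the simulated percentages attenuates the
recovered value slightly (typically |r| around 0.45-0.50 at the
defaults).

### Movement classifier

The contract is the windowing, the loss, the early stopping, and the
decoding - not the architecture. Windows are 25 frames (12 before, the
center, 12 after), one per valid center, labelled by the center frame's
movement class (9 classes including Rest). A fixed average-pooling front
end (7 row bands x 6 column bands x 5 time bands) stands in for a
convolutional feature extractor at desk scale; the learned part is a
softmax head (optionally one tanh hidden layer) trained with Adam on
categorical cross-entropy, stopping when validation loss has not improved
for `patience` (default 10) epochs, with the best-validation weights
kept. Splits are by animal. Edge frames (first/last 12) take the nearest
valid window's prediction. Chance-level controls use balanced accuracy
(mean per-class recall), which is 1/9 for any classifier that has learned
only class priors - raw accuracy would instead reflect the movies' class
imbalance.

## Numerical conventions

Frames are 0-based and intervals half-open everywhere; external tables
declared 1-based are converted on read. Undefined statistics
(zero-variance correlations, zero-mean CVs) return NA with a classed
warning; contract violations abort with classed errors
(`ecdysim_invalid_config`, `ecdysim_invalid_data`,
`ecdysim_schema_error`, ...). All randomness flows from explicit integer
seeds; identical configurations are byte-identical.

## What the tests do and do not show

The suite demonstrates: exact oracle equivalence of the similarity
kernel; exact recovery of planted bouts and ensembles under the stated
conditions; monotone degradation of stereotypy with recruitment jitter
and of ensemble recovery with within-ensemble jitter; the level-ordering
property; perfect and noise-robust wave-direction calls with exact
mirror symmetry; recovery of planted mechanical couplings; and classifier
separation of the nine classes with chance-level shuffled controls.

It does not show: that real imaging data meet the generator's
assumptions (no motion artifacts, no bleaching, rectangular ROIs, a
compressed timescale, simplified left-right structure), nor effect
sizes measured on real recordings. Reproducing such numbers requires an
annotated imaging dataset and is outside the desk-scale scope of this
package; the package's readers
for the canonical CSV schema (with a 1-based conversion flag) are the
intended entry point for such data.

## The workflow scripts

The `analysis/` directory strings the package into the full study
workflow - `01_simulate.R` through `08_perturbations.R` - each a thin
driver that calls the functions above and writes its tables under
`results/`. `run_pipeline()` wraps the same stages as a single call with
a provenance manifest. The package's functions and these scripts are the
interface; there is no separate shell tool.
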