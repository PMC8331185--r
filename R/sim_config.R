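#' Simulation configuration for synthetic pupal-ecdysis recordings
#'
#' Bundles every tunable of the generator. Defaults encode the study
#' conditions the analyses assume: imaging at 2 Hz; a phase plan of P0
#' twitch bouts, P1 bouts of a Lift followed by one (sometimes two)
#' RollCons, P2 bouts containing only a Swing, and P3 blocks of
#' Crunch/Brace/AntComp/PostCon (usually with a PostSwing); GCaMP6s-like
#' instant-rise single-exponential-decay kinetics (decay 6 frames = 3 s at
#' 2 Hz); recruitment-order jitter between syllables; small within-ensemble
#' onset jitter; idiosyncratic (off-syllable) activations; and a planted
#' fluorescence-shortening coupling of magnitude 0.54 for the mechanics
#' tables.
#'
#' Within a bout, syllables are scheduled as dense clusters: ensemble
#' members onset on successive frames (1-frame stagger) and share a common
#' offset `coactive_window` frames after the last member's planned onset;
#' successive clusters advance by 3 frames after an ensemble and 2 after a
#' single-muscle syllable. This keeps every within-bout gap between new
#' activations below the 2-frame bout-splitting rule while keeping the
#' co-activity overlap between *different* ensembles below the 3-frame
#' window, so ensembles remain separable by co-activity mining. Singles and
#' idiosyncratic twitches last `single_duration`/`idio_duration` frames
#' (default 2, below the co-activity window, so they can never masquerade
#' as ensemble members).
#'
#' @param seed integer; mandatory source of all randomness.
#' @param fps frames per second (sampling rate).
#' @param phase_plan named list (`P0`..`P3`); see [default_phase_plan()].
#' @param syllabary see [default_syllabary()].
#' @param syllable_support probability that each syllable of a movement is
#'   recruited in a given bout (1 = fully deterministic vocabulary).
#' @param recruitment_jitter_sd sd (frames) of Gaussian jitter on syllable
#'   cluster onsets within a bout; 0 gives perfectly stereotyped order.
#' @param within_ensemble_jitter maximum member-onset displacement within
#'   an ensemble (frames; drawn uniformly on `[-j, j]`). Keep at or below
#'   the co-activity window for stereotyped ensembles; larger values (as in
#'   the desynchronization perturbations) destroy ensemble co-activity.
#' @param idiosyncratic_rate target fraction of activations that are
#'   off-syllable twitches (valid below 0.5; injected as
#'   Binomial(n_planted, r/(1-r)) extra events so the expected off-syllable
#'   fraction equals the rate).
#' @param coactive_window planned common co-activity span of ensemble
#'   members (frames).
#' @param single_duration duration (frames) of single-muscle syllable
#'   events.
#' @param idio_duration duration (frames) of idiosyncratic twitches.
#' @param kinetics list: `tau_decay` (frames), `amp_meanlog`, `amp_sdlog`
#'   (log-normal dF/F event amplitudes).
#' @param noise_sd Gaussian noise sd added to traces (dF/F units).
#' @param mech mechanics parameters: `dff_mean`, `dff_sd` (percent
#'   fluorescence rise at peak), `shortening_mean`, `shortening_sd`
#'   (percent), `coupling` (Pearson correlation magnitude between dF/F and
#'   shortening; negative under the signed length-change coding),
#'   `pme2_segment_gradient` (relative shortening gradient of the lateral
#'   transverse ensemble along A5 > A4 > A3), `length_mean_um`,
#'   `length_sd_um`.
#' @param lr_switch_fail probability that the strict left-right alternation
#'   of bouts fails to switch.
#' @param perturbation one of `"none"`, `"ethrb_suppressed"`,
#'   `"ccap_suppressed"`, `"burs_suppressed"`, `"class1da_suppressed"`;
#'   set via [apply_perturbation()].
#' @return object of class `sim_config` (a validated list).
#' @seealso [simulate_recording()], [apply_perturbation()]
#' @export
sim_config <- function(seed,
                       fps = 2,
                       phase_plan = default_phase_plan(),
                       syllabary = default_syllabary(),
                       syllable_support = 1.0,
                       recruitment_jitter_sd = 2,
                       within_ensemble_jitter = 1,
                       idiosyncratic_rate = 0.2,
                       coactive_window = 4,
                       single_duration = 2,
                       idio_duration = 2,
                       kinetics = list(tau_decay = 6, amp_meanlog = 0.3,
                                       amp_sdlog = 0.3),
                       noise_sd = 0.02,
                       mech = list(dff_mean = 150, dff_sd = 50,
                                   shortening_mean = 25, shortening_sd = 8,
                                   coupling = 0.54,
                                   pme2_segment_gradient = 0.15,
                                   length_mean_um = 120, length_sd_um = 10),
                       lr_switch_fail = 0.05,
                       perturbation = "none") {
  stopifnot_config(!missing(seed) && is.numeric(seed) && length(seed) == 1 &&
                     is.finite(seed), "seed is mandatory")
  stopifnot_config(fps > 0, "fps must be > 0")
  stopifnot_config(syllable_support >= 0 && syllable_support <= 1,
                   "syllable_support must be in [0,1]")
  stopifnot_config(idiosyncratic_rate >= 0 && idiosyncratic_rate <= 1,
                   "idiosyncratic_rate must be in [0,1]")
  stopifnot_config(recruitment_jitter_sd >= 0 && within_ensemble_jitter >= 0,
                   "jitters must be non-negative")
  stopifnot_config(coactive_window >= 3 && coactive_window <= 4,
                   "coactive_window must be 3 or 4 (cluster timing constraint)")
  stopifnot_config(single_duration > 0 &&
                     idio_duration > 0, "durations must be positive")
  stopifnot_config(perturbation %in% c("none", "ethrb_suppressed",
                                       "ccap_suppressed", "burs_suppressed",
                                       "class1da_suppressed"),
                   "unknown perturbation mode")
  for (ph in names(phase_plan)) {
    p <- phase_plan[[ph]]
    stopifnot_config(p$n_bouts >= 0, "n_bouts must be non-negative")
    if (!is.null(p$movements)) {
      for (mv in unique(unlist(p$movements))) {
        stopifnot_config(mv %in% names(syllabary$movements),
                         paste0("movement '", mv, "' missing from syllabary"))
        stopifnot_config(length(syllabary$movements[[mv]]$syllables) > 0,
                         paste0("empty syllabary for movement '", mv, "'"))
      }
    }
  }
  cfg <- list(seed = as.integer(seed), fps = fps, phase_plan = phase_plan,
              syllabary = syllabary, syllable_support = syllable_support,
              recruitment_jitter_sd = recruitment_jitter_sd,
              within_ensemble_jitter = within_ensemble_jitter,
              idiosyncratic_rate = idiosyncratic_rate,
              coactive_window = coactive_window,
              single_duration = single_duration,
              idio_duration = idio_duration,
              kinetics = kinetics, noise_sd = noise_sd, mech = mech,
              lr_switch_fail = lr_switch_fail,
              perturbation = perturbation,
              # perturbation-internal switches (set by apply_perturbation)
              suppressed_muscles_p1 = character(0),
              desync_pmes = character(0),
              dv_desync = FALSE,
              partial_swing = FALSE,
              p0_sustained = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Default phase plan
#'
#' Bout counts, composition noise, and inter-bout duration distributions
#' per phase. Bout-duration variability is compositional: P1 bouts carry an
#' optional second RollCon (`repeat_last_p`), P3 blocks occasionally lack
#' the PostSwing (`drop_last_p`), per-animal bout counts are dispersed
#' (`count_sdlog`), and inter-bout intervals are log-normal. P2 is the most
#' tightly regulated phase - always a single Swing, near-fixed bout count
#' and inter-bout interval - so its coefficients of variation are the
#' lowest, as observed.
#'
#' @param n_p0,n_p1,n_p2,n_p3 mean bout (or movement-block) counts.
#' @return named list suitable for the `phase_plan` argument of
#'   [sim_config()].
#' @export
default_phase_plan <- function(n_p0 = 6, n_p1 = 8, n_p2 = 5, n_p3 = 8) {
  list(
    P0 = list(n_bouts = n_p0, movements = NULL,
              count_sdlog = 0.20, repeat_last_p = 0, drop_last_p = 0,
              interbout_meanlog = log(12), interbout_sdlog = 0.35),
    P1 = list(n_bouts = n_p1,
              movements = list(c("Lift", "RollCon")),
              count_sdlog = 0.20, repeat_last_p = 0.3, drop_last_p = 0,
              interbout_meanlog = log(10), interbout_sdlog = 0.30),
    P2 = list(n_bouts = n_p2,
              movements = list("Swing"),
              count_sdlog = 0.04, repeat_last_p = 0, drop_last_p = 0,
              interbout_meanlog = log(8), interbout_sdlog = 0.05),
    P3 = list(n_bouts = n_p3,
              movements = list(c("Crunch", "Brace", "AntComp",
                                 "PostCon", "PostSwing")),
              count_sdlog = 0.20, repeat_last_p = 0, drop_last_p = 0.4,
              interbout_meanlog = log(14), interbout_sdlog = 0.30)
  )
}

#' Apply a neuromodulator-suppression perturbation to a configuration
#'
#' Encodes the behavioral phenotypes of silencing specific neuronal
#' populations:
#' \describe{
#'   \item{ethrb_suppressed}{ETH-receptor-B neurons silenced: Lift movements
#'     are removed from P1, M1 and M15 are inactive during P1, and PME1
#'     members are de-synchronized (within-ensemble jitter pushed beyond the
#'     co-activity window), so PME1 no longer shows ensemble activity.}
#'   \item{ccap_suppressed}{CCAP neurons silenced: P2 and P3 are absent; a
#'     single partial swing-like movement reaches only posterior segments
#'     with dorso-ventral desynchronization; P1-like bouts continue and then
#'     truncate.}
#'   \item{burs_suppressed}{Bursicon neurons silenced: a single full-length
#'     swing-like wave with D-V desynchronization, followed by sparse
#'     P3-like movements.}
#'   \item{class1da_suppressed}{Class I dendritic-arbor proprioceptors
#'     silenced: P0 activity becomes sustained and widespread and the
#'     recording terminates before P1.}
#' }
#'
#' @param config a [sim_config()].
#' @param mode perturbation mode (see above), or `"none"` (identity).
#' @return modified `sim_config`.
#' @export
apply_perturbation <- function(config, mode = "none") {
  stopifnot_config(inherits(config, "sim_config"), "config must be sim_config")
  modes <- c("none", "ethrb_suppressed", "ccap_suppressed",
             "burs_suppressed", "class1da_suppressed")
  stopifnot_config(length(mode) == 1 && mode %in% modes,
                   paste0("unknown perturbation mode: ", mode))
  if (mode == "none") return(config)
  config$perturbation <- mode
  if (mode == "ethrb_suppressed") {
    # No Lift; M1/M15 silent in P1; PME1 desynchronized.
    p1 <- config$phase_plan$P1
    p1$movements <- list("RollCon")
    p1$repeat_last_p <- 0
    config$phase_plan$P1 <- p1
    config$suppressed_muscles_p1 <- c("M1", "M15")
    config$desync_pmes <- "PME1"
  } else if (mode == "ccap_suppressed") {
    # P2/P3 absent; persistent P1-like bouts then a single partial swing.
    config$phase_plan$P2 <- NULL
    config$phase_plan$P3 <- NULL
    config$partial_swing <- "posterior_only"
    config$dv_desync <- TRUE
  } else if (mode == "burs_suppressed") {
    # Single full-length swing-like wave with D-V desynchronization, then
    # sparse P3-like movements.
    config$phase_plan$P2 <- NULL
    p3 <- config$phase_plan$P3
    p3$n_bouts <- max(1, floor(p3$n_bouts / 2))
    p3$movements <- list("Crunch", "AntComp", "Brace", "PostSwing")
    p3$drop_last_p <- 0
    config$phase_plan$P3 <- p3
    config$partial_swing <- "full_length"
    config$dv_desync <- TRUE
  } else if (mode == "class1da_suppressed") {
    # Sustained, widespread P0; recording ends before P1.
    config$phase_plan <- config$phase_plan["P0"]
    config$phase_plan$P0$n_bouts <- config$phase_plan$P0$n_bouts + 2
    config$p0_sustained <- TRUE
  }
  config
}
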