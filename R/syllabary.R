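#' Default pupal ecdysis syllabary
#'
#' The movement vocabulary: each of the eight canonical movements (plus the
#' stochastic pre-ecdysis twitching of P0) is composed of syllables - pupal
#' muscle ensembles (PMEs, sets of >= 2 muscles that co-activate) and
#' single-muscle syllables.
#'
#' PME memberships PME1-PME4 follow the catalog described for this system
#' (PME1 = M26/M13/M8 ventral-lateral, PME2 = the lateral transverse
#' M21-M23, PME3 = M2/M3, PME4 = the dorsal longitudinal M1-M3; note
#' PME3 is nested inside PME4 - the two occur as maximal co-active groups in
#' different movements). PME5-PME8 memberships are not documented;
#' the defaults here are explicit placeholders drawn from the roster and can
#' be overridden.
#'
#' Each movement also carries its anatomical compartment (anterior/posterior
#' extent) and its A-P rhythm (direction of wave propagation, if any).
#'
#' @return list with elements `pmes` (named list of character vectors),
#'   `movements` (named list; each has `syllables`, `ap_extent`,
#'   `direction`), and `movement_classes` (the 9 frame-wise classes,
#'   including Rest).
#' @export
default_syllabary <- function() {
  pmes <- list(
    PME1 = c("M26", "M13", "M8"),
    PME2 = c("M21", "M22", "M23"),
    PME3 = c("M2", "M3"),
    PME4 = c("M1", "M2", "M3"),
    # placeholder memberships (not part of the documented catalog):
    PME5 = c("M9", "M10"),
    PME6 = c("M13", "M15"),
    PME7 = c("M5", "M9"),
    PME8 = c("M8", "M10")
  )
  movements <- list(
    Lift      = list(syllables = c("PME1", "PME4", "PME6", "M8", "M15"),
                     ap_extent = "posterior", direction = "P_to_A"),
    RollCon   = list(syllables = c("PME2", "PME3", "PME6", "M2", "M8"),
                     ap_extent = "both", direction = "P_to_A"),
    Swing     = list(syllables = c("PME1", "PME2", "PME4", "PME6", "M12", "M15"),
                     ap_extent = "both", direction = "P_to_A",
                     per_segment = c("PME1", "PME2", "PME4")),
    Brace     = list(syllables = c("PME2", "M8"),
                     ap_extent = "both", direction = "A_to_P"),
    Crunch    = list(syllables = c("PME1", "PME2", "PME6", "M2", "M8", "M13"),
                     ap_extent = "both", direction = "A_to_P"),
    AntComp   = list(syllables = c("PME2", "PME3", "PME4", "PME5", "PME6",
                                   "PME7", "PME8", "M1", "M12"),
                     ap_extent = "anterior", direction = "A_to_P"),
    PostCon   = list(syllables = c("PME2", "PME3", "PME6", "M8", "M26"),
                     ap_extent = "posterior", direction = "none"),
    PostSwing = list(syllables = c("PME1", "PME2", "PME3", "PME6", "M15"),
                     ap_extent = "posterior", direction = "A_to_P")
  )
  list(pmes = pmes, movements = movements,
       movement_classes = c("AntComp", "PostSwing", "Brace", "Crunch",
                            "RollCon", "Lift", "PostCon", "Rest", "Swing"))
}

# Expand a syllable name to member muscle labels.
syllable_members <- function(syllable, syllabary) {
  if (syllable %in% names(syllabary$pmes)) syllabary$pmes[[syllable]]
  else syllable
}

# Compartment tag of a syllable: majority dorso-ventral compartment of its
# members (ties broken dorsal > lateral > ventral).
syllable_dv <- function(syllable, syllabary) {
  members <- syllable_members(syllable, syllabary)
  roster <- muscle_roster()
  dv <- roster$dv[match(members, roster$muscle)]
  levels <- c("dorsal", "lateral", "ventral")
  counts <- table(factor(dv, levels = levels))
  levels[which.max(counts)]
}
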