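#' Maximal co-active muscle groups within a bout
#'
#' Finds every maximal set of muscles whose common activity interval spans
#' at least `min_overlap_frames` consecutive frames. Candidates are built
#' from sliding-window intersections of the per-frame active-muscle sets
#' (any set co-active for a full window is a subset of some window
#' intersection, and each window intersection is itself co-active for the
#' window), so the maximal qualifying sets are exactly the maximal elements
#' of the window-intersection family. A subset occurrence is suppressed when
#' a strict superset's co-active interval overlaps it; the same subset
#' occurring in a disjoint interval is still reported.
#'
#' @param events data.frame for one bout with columns `muscle`,
#'   `onset_frame`, `offset_frame` (half-open).
#' @param min_overlap_frames minimum common co-activity span.
#' @return data.frame of group occurrences: `muscles` (member labels joined
#'   by `+` in natural order), `n_muscles`, `start_frame`, `end_frame`
#'   (the co-active interval, half-open). Zero rows when no group
#'   qualifies.
#' @examples
#' ev <- data.frame(muscle = c("M21", "M22", "M23"),
#'                  onset_frame = c(10, 11, 9),
#'                  offset_frame = c(16, 15, 14))
#' coactive_groups(ev)  # {M21+M22+M23} co-active over [11, 14)
#' @export
coactive_groups <- function(events, min_overlap_frames = 3) {
  stopifnot_data(all(events$offset_frame > events$onset_frame),
                 "events must have offset > onset")
  empty <- data.frame(muscles = character(0), n_muscles = integer(0),
                      start_frame = integer(0), end_frame = integer(0))
  if (nrow(events) < 2) return(empty)
  w <- as.integer(min_overlap_frames)
  lo <- min(events$onset_frame)
  hi <- max(events$offset_frame)
  frames <- lo:(hi - 1L)
  muscles <- natural_sort(unique(events$muscle))
  act <- matrix(FALSE, nrow = length(muscles), ncol = length(frames),
                dimnames = list(muscles, NULL))
  for (i in seq_len(nrow(events))) {
    cols <- (events$onset_frame[i] - lo + 1L):(events$offset_frame[i] - lo)
    act[events$muscle[i], cols] <- TRUE
  }
  n_win <- length(frames) - w + 1L
  if (n_win < 1) return(empty)
  # window intersections via run-length of consecutive active frames
  sets <- character(0)
  for (t in seq_len(n_win)) {
    alive <- rowSums(act[, t:(t + w - 1L), drop = FALSE]) == w
    if (sum(alive) >= 2) {
      sets <- c(sets, paste(muscles[alive], collapse = "+"))
    }
  }
  sets <- unique(sets)
  if (length(sets) == 0) return(empty)

  occ <- list()
  for (s in sets) {
    members <- strsplit(s, "+", fixed = TRUE)[[1]]
    all_on <- colSums(act[members, , drop = FALSE]) == length(members)
    r <- rle(all_on)
    ends_rel <- cumsum(r$lengths)
    starts_rel <- ends_rel - r$lengths + 1L
    for (j in which(r$values & r$lengths >= w)) {
      occ[[length(occ) + 1L]] <- data.frame(
        muscles = s, n_muscles = length(members),
        start_frame = frames[starts_rel[j]],
        end_frame = frames[ends_rel[j]] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  occ <- do.call(rbind, occ)
  # suppress subset occurrences overlapped by a strict superset occurrence
  keep <- rep(TRUE, nrow(occ))
  mem <- strsplit(occ$muscles, "+", fixed = TRUE)
  for (i in seq_len(nrow(occ))) {
    for (j in seq_len(nrow(occ))) {
      if (i == j || !keep[i]) next
      if (occ$n_muscles[j] > occ$n_muscles[i] &&
          all(mem[[i]] %in% mem[[j]]) &&
          occ$start_frame[i] < occ$end_frame[j] &&
          occ$start_frame[j] < occ$end_frame[i]) {
        keep[i] <- FALSE
      }
    }
  }
  out <- occ[keep, , drop = FALSE]
  out <- out[order(out$start_frame, out$muscles), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discover pupal muscle ensembles (PMEs) from a cohort's event table
#'
#' Applies the ensemble criteria: a muscle set qualifies as a PME when (a)
#' all members are co-active for at least `min_overlap_frames` consecutive
#' frames, (b) the set occurs as a maximal co-active group in at least
#' `within_animal_frac` of the units (bouts or movements) of an animal, and
#' (c) that holds for at least `across_animal_frac` of animals. Counting
#' maximal groups (rather than all subsets) keeps nested ensembles
#' distinguishable: a set and its strict superset can both qualify when each
#' is the maximal co-active group in different units.
#'
#' With `unit = "movement"` (default), within-animal support is computed
#' separately for each movement type - the fraction of that movement's
#' instances in which the group occurs - and a group is retained when some
#' movement type passes the threshold in enough animals. This is what makes
#' movement-specific ensembles discoverable in phase-structured recordings,
#' where no ensemble appears in 80% of *all* bouts. With `unit = "bout"`
#' the denominator is all bouts of the animal.
#'
#' @param events combined event table with columns `animal_id`, `bout_id`,
#'   `movement`, `muscle`, `onset_frame`, `offset_frame`.
#' @param min_overlap_frames co-activity window (frames).
#' @param within_animal_frac minimum fraction of units per animal.
#' @param across_animal_frac minimum fraction of animals.
#' @param unit `"movement"` (default) or `"bout"`: the denominator of the
#'   within-animal support.
#' @return object of class `syllable_catalog`: list with `pmes` (list of
#'   `list(id, muscles, support, animal_frac, movement)` where `support` is
#'   the named per-animal support vector of the best movement type),
#'   `singles` (filled by [single_muscle_syllables()]), and `criteria`.
#' @export
discover_pmes <- function(events, min_overlap_frames = 3,
                          within_animal_frac = 0.8,
                          across_animal_frac = 0.8,
                          unit = c("movement", "bout")) {
  unit <- match.arg(unit)
  animals <- unique(events$animal_id)
  stopifnot_data(length(animals) >= 2, "need at least 2 animals")

  # Candidate maximal groups per unit, across the cohort. A set is credited
  # in a unit when some maximal candidate *contains* it (its members were
  # then co-active for >= the window there); this keeps a regular group
  # countable when an incidental extra muscle happens to overlap its
  # interval. Strict subsets of an equally regular group are absorbed by
  # the maximality filter below.
  unit_cands <- list()  # animal -> unit key -> list of candidate member sets
  for (a in animals) {
    ea <- events[events$animal_id == a, ]
    bouts <- unique(ea$bout_id)
    stopifnot_data(length(bouts) >= 1, paste("animal", a, "has zero units"))
    ua <- list()
    for (bt in bouts) {
      eb <- ea[ea$bout_id == bt, ]
      if (unit == "bout") {
        cand <- coactive_groups(eb, min_overlap_frames)
        ua[[paste("bout", bt, sep = "\r")]] <-
          lapply(unique(cand$muscles), function(s)
            strsplit(s, "+", fixed = TRUE)[[1]])
      } else {
        for (mv in unique(eb$movement)) {
          cand <- coactive_groups(eb[eb$movement == mv, ],
                                  min_overlap_frames)
          ua[[paste(mv, bt, sep = "\r")]] <-
            lapply(unique(cand$muscles), function(s)
              strsplit(s, "+", fixed = TRUE)[[1]])
        }
      }
    }
    unit_cands[[a]] <- ua
  }

  # universe of sets to evaluate = all distinct candidates observed
  universe <- unique(unlist(lapply(unit_cands, function(ua)
    lapply(unlist(ua, recursive = FALSE), function(m)
      paste(natural_sort(m), collapse = "+")))))
  if (length(universe) == 0) universe <- character(0)

  # per-animal containment support for every universe set and unit type
  types_all <- unique(unlist(lapply(unit_cands, function(ua)
    sub("\r.*$", "", names(ua)))))
  members_of <- lapply(universe, function(s)
    strsplit(s, "+", fixed = TRUE)[[1]])
  names(members_of) <- universe
  sup_tab <- list()  # [[type]][[set]] = named per-animal support
  for (tp in types_all) {
    st <- list()
    for (s in universe) {
      members <- members_of[[s]]
      sup <- stats::setNames(rep(0, length(animals)), animals)
      for (a in animals) {
        ua <- unit_cands[[a]]
        keys <- names(ua)[sub("\r.*$", "", names(ua)) == tp]
        if (length(keys) == 0) next
        hit <- vapply(keys, function(k)
          any(vapply(ua[[k]], function(cm) all(members %in% cm),
                     logical(1))), logical(1))
        sup[a] <- mean(hit)
      }
      st[[s]] <- sup
    }
    sup_tab[[tp]] <- st
  }

  retained <- list()  # entries: muscles, key, support, animal_frac, movement
  for (tp in types_all) {
    for (s in universe) {
      sup <- sup_tab[[tp]][[s]]
      frac_animals <- mean(sup >= within_animal_frac)
      if (frac_animals < across_animal_frac) next
      # dominance: a strict subset of a (near-)equally regular larger group
      # is the same underlying ensemble with occasional member dropout, not
      # a separate syllable - unless the subset also occurs *independently*
      # (co-active intervals without the superset's extra members) at the
      # same support thresholds, as genuinely nested ensembles do
      dominated <- FALSE
      for (s2 in universe) {
        if (s2 == s) next
        m2 <- members_of[[s2]]
        if (length(m2) > length(members_of[[s]]) &&
            all(members_of[[s]] %in% m2) &&
            mean(sup_tab[[tp]][[s2]]) >= 0.8 * mean(sup)) {
          extra <- setdiff(m2, members_of[[s]])
          indep <- stats::setNames(rep(0, length(animals)), animals)
          for (a in animals) {
            ua <- unit_cands[[a]]
            keys <- names(ua)[sub("\r.*$", "", names(ua)) == tp]
            if (length(keys) == 0) next
            hit <- vapply(keys, function(k)
              any(vapply(ua[[k]], function(cm)
                all(members_of[[s]] %in% cm) && !all(extra %in% cm),
                logical(1))), logical(1))
            indep[a] <- mean(hit)
          }
          if (mean(indep >= within_animal_frac) < across_animal_frac) {
            dominated <- TRUE
            break
          }
        }
      }
      if (dominated) next
      retained[[length(retained) + 1L]] <-
        list(muscles = members_of[[s]], key = s, support = sup,
             animal_frac = frac_animals, movement = tp)
    }
  }

  # one entry per muscle set: best-supported unit type
  best <- list()
  for (r in retained) {
    prev <- best[[r$key]]
    if (is.null(prev) || r$animal_frac > prev$animal_frac ||
        (r$animal_frac == prev$animal_frac &&
         mean(r$support) > mean(prev$support))) {
      best[[r$key]] <- r
    }
  }
  pmes <- unname(best)
  # stable ordering: strongest consensus first, then natural label order
  if (length(pmes) > 0) {
    ord <- order(-vapply(pmes, function(p) p$animal_frac, numeric(1)),
                 -vapply(pmes, function(p) mean(p$support), numeric(1)),
                 vapply(pmes, function(p) p$key, character(1)))
    pmes <- pmes[ord]
    for (i in seq_along(pmes)) pmes[[i]]$id <- paste0("dPME", i)
  }
  out <- list(pmes = pmes, singles = list(),
              criteria = list(min_overlap_frames = min_overlap_frames,
                              within_animal_frac = within_animal_frac,
                              across_animal_frac = across_animal_frac,
                              unit = unit))
  class(out) <- "syllable_catalog"
  out
}

#' Single-muscle syllables
#'
#' A muscle qualifies as a single-muscle syllable when it is
#' movement-associated at the same support thresholds used for PMEs (active
#' in at least `within_animal_frac` of units in at least
#' `across_animal_frac` of animals, with units as in the catalog's
#' criteria) but is not a member of any retained PME.
#'
#' @param events combined event table (see [discover_pmes()]).
#' @param catalog a `syllable_catalog` from [discover_pmes()].
#' @return the catalog with its `singles` entry filled (list of
#'   `list(muscle, support, animal_frac)`).
#' @export
single_muscle_syllables <- function(events, catalog) {
  stopifnot_data(inherits(catalog, "syllable_catalog"),
                 "catalog must come from discover_pmes()")
  cr <- catalog$criteria
  animals <- unique(events$animal_id)
  pme_members <- unique(unlist(lapply(catalog$pmes, function(p) p$muscles)))
  unit_key <- if (cr$unit == "bout") {
    as.character(events$bout_id)
  } else {
    paste(events$movement, events$bout_id, sep = "\r")
  }
  unit_type <- if (cr$unit == "bout") rep("bout", nrow(events))
               else events$movement

  muscles <- natural_sort(unique(events$muscle))
  singles <- list()
  for (m in setdiff(muscles, pme_members)) {
    best <- NULL
    for (tp in unique(unit_type)) {
      sup <- stats::setNames(rep(0, length(animals)), animals)
      for (a in animals) {
        in_a <- events$animal_id == a & unit_type == tp
        units <- unique(unit_key[in_a])
        if (length(units) == 0) next
        with_m <- unique(unit_key[in_a & events$muscle == m])
        sup[a] <- length(with_m) / length(units)
      }
      frac_animals <- mean(sup >= cr$within_animal_frac)
      if (frac_animals >= cr$across_animal_frac &&
          (is.null(best) || frac_animals > best$animal_frac ||
           (frac_animals == best$animal_frac &&
            mean(sup) > mean(best$support)))) {
        best <- list(muscle = m, support = sup,
                     animal_frac = frac_animals, movement = tp)
      }
    }
    if (!is.null(best)) singles[[length(singles) + 1L]] <- best
  }
  catalog$singles <- singles
  catalog
}

#' Annotate one bout's activations with syllables
#'
#' Locates occurrences of each catalog PME (all members co-active for at
#' least the catalog's co-activity window) and assigns each activation to at
#' most one syllable event. Assignment is earliest-matching: an activation
#' joins the earliest-onset syllable event whose member set contains its
#' muscle and whose co-active interval overlaps the activation's interval;
#' remaining activations of single-syllable muscles become single-muscle
#' syllable events. Everything else is off-syllable.
#'
#' @param events data.frame for one bout (`muscle`, `onset_frame`,
#'   `offset_frame`).
#' @param catalog a `syllable_catalog` (PMEs and optionally singles).
#' @return list: `syllable_events` (data.frame `syllable`, `onset_frame`,
#'   `coactive_start`, `coactive_end`; onset = earliest assigned member
#'   onset), `assignment` (character per activation, NA = off-syllable),
#'   `off_syllable_fraction`.
#' @export
annotate_syllables <- function(events, catalog) {
  stopifnot_data(inherits(catalog, "syllable_catalog"),
                 "catalog must come from discover_pmes()")
  stopifnot_config(length(catalog$pmes) + length(catalog$singles) > 0,
                   "catalog is empty")
  w <- catalog$criteria$min_overlap_frames
  n_ev <- nrow(events)
  assignment <- rep(NA_character_, n_ev)
  syl_events <- list()

  if (n_ev > 0 && length(catalog$pmes) > 0) {
    lo <- min(events$onset_frame)
    hi <- max(events$offset_frame)
    frames <- lo:(hi - 1L)
    muscles <- unique(events$muscle)
    act <- matrix(FALSE, nrow = length(muscles), ncol = length(frames),
                  dimnames = list(muscles, NULL))
    for (i in seq_len(n_ev)) {
      act[events$muscle[i],
          (events$onset_frame[i] - lo + 1L):(events$offset_frame[i] - lo)] <- TRUE
    }
    occ <- list()
    for (p in catalog$pmes) {
      if (!all(p$muscles %in% muscles)) next
      all_on <- colSums(act[p$muscles, , drop = FALSE]) == length(p$muscles)
      r <- rle(all_on)
      ends_rel <- cumsum(r$lengths)
      starts_rel <- ends_rel - r$lengths + 1L
      for (j in which(r$values & r$lengths >= w)) {
        occ[[length(occ) + 1L]] <- list(
          syllable = p$id, muscles = p$muscles,
          start = frames[starts_rel[j]], end = frames[ends_rel[j]] + 1L)
      }
    }
    if (length(occ) > 0) {
      ord <- order(vapply(occ, function(o) o$start, numeric(1)))
      occ <- occ[ord]
      occ_members <- integer(0)
      for (oi in seq_along(occ)) {
        o <- occ[[oi]]
        cand <- which(is.na(assignment) &
                        events$muscle %in% o$muscles &
                        events$onset_frame < o$end &
                        events$offset_frame > o$start)
        if (length(cand) > 0) {
          assignment[cand] <- o$syllable
          syl_events[[length(syl_events) + 1L]] <- data.frame(
            syllable = o$syllable,
            onset_frame = min(events$onset_frame[cand]),
            coactive_start = o$start, coactive_end = o$end,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  single_labels <- vapply(catalog$singles, function(s) s$muscle, character(1))
  if (n_ev > 0 && length(single_labels) > 0) {
    for (i in which(is.na(assignment) & events$muscle %in% single_labels)) {
      assignment[i] <- events$muscle[i]
      syl_events[[length(syl_events) + 1L]] <- data.frame(
        syllable = events$muscle[i],
        onset_frame = events$onset_frame[i],
        coactive_start = events$onset_frame[i],
        coactive_end = events$offset_frame[i],
        stringsAsFactors = FALSE)
    }
  }

  syl_df <- if (length(syl_events) > 0) {
    x <- do.call(rbind, syl_events)
    x <- x[order(x$onset_frame, x$syllable), , drop = FALSE]
    rownames(x) <- NULL
    x
  } else {
    data.frame(syllable = character(0), onset_frame = integer(0),
               coactive_start = integer(0), coactive_end = integer(0))
  }
  frac <- if (n_ev == 0) 0 else mean(is.na(assignment))
  list(syllable_events = syl_df, assignment = assignment,
       off_syllable_fraction = frac)
}

#' Share of co-active duration represented by the qualifying window
#'
#' For each PME syllable event, the ratio of the co-activity window to the
#' event's total co-active duration; returns the mean over events. Values
#' near 0.15 indicate the 3-frame window is ~15% of typical co-active
#' spans.
#'
#' @param syllable_events data.frame from [annotate_syllables()] (PME events
#'   only are used: rows whose co-active span can exceed the window).
#' @param min_overlap_frames the qualifying window (frames).
#' @return mean fraction in `(0, 1]`.
#' @export
coactive_duration_share <- function(syllable_events, min_overlap_frames = 3) {
  stopifnot_data(nrow(syllable_events) >= 1, "need at least one event")
  dur <- syllable_events$coactive_end - syllable_events$coactive_start
  mean(min_overlap_frames / dur)
}

#' Construct a syllable catalog from known ensembles
#'
#' Builds the `syllable_catalog` container directly from given PME
#' memberships and single-muscle syllables - e.g. a generator's planted
#' syllabary - so annotation and sequence building can run against a known
#' truth instead of a discovered catalog.
#'
#' @param pmes named list of muscle-label vectors (size >= 2 each).
#' @param singles character vector of single-syllable muscle labels.
#' @param min_overlap_frames,within_animal_frac,across_animal_frac,unit
#'   criteria recorded in the catalog (the co-activity window is used by
#'   [annotate_syllables()]).
#' @return a `syllable_catalog`.
#' @export
syllable_catalog <- function(pmes, singles = character(0),
                             min_overlap_frames = 3,
                             within_animal_frac = 0.8,
                             across_animal_frac = 0.8,
                             unit = "movement") {
  stopifnot_config(all(vapply(pmes, length, integer(1)) >= 2),
                   "every PME must have >= 2 members")
  pl <- lapply(seq_along(pmes), function(i)
    list(id = names(pmes)[i], muscles = pmes[[i]],
         support = NULL, animal_frac = NA_real_, movement = NA_character_))
  sl <- lapply(singles, function(m)
    list(muscle = m, support = NULL, animal_frac = NA_real_,
         movement = NA_character_))
  out <- list(pmes = pl, singles = sl,
              criteria = list(min_overlap_frames = min_overlap_frames,
                              within_animal_frac = within_animal_frac,
                              across_animal_frac = across_animal_frac,
                              unit = unit))
  class(out) <- "syllable_catalog"
  out
}
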