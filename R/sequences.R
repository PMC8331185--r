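#' Build an activation-order token sequence
#'
#' Orders events by onset frame, breaking ties by label in natural collation
#' (M2 before M12), and emits tokens at the requested level of description:
#' \describe{
#'   \item{muscle}{one token per activation (muscle label), repeats kept.}
#'   \item{syllable}{one token per syllable event; pass the
#'     `syllable_events` data.frame from [annotate_syllables()].}
#'   \item{compartment}{tokens are D-V x A-P compartment tags
#'     (`dorsal.anterior`, ...), one per compartment *onset*: member events
#'     of a compartment are merged into union activity intervals and each
#'     interval contributes a single token at its start, so activity inside
#'     an already-active compartment adds no token.}
#'   \item{movement}{one token per movement, ordered by first onset,
#'     consecutive duplicates collapsed.}
#' }
#'
#' @param events data.frame; needs `onset_frame` plus `muscle` (muscle
#'   level), `muscle` + `segment` (compartment), `syllable` (syllable), or
#'   `movement` + `offset_frame` as appropriate.
#' @param level one of `"muscle"`, `"syllable"`, `"compartment"`,
#'   `"movement"`.
#' @return character vector of tokens (possibly empty).
#' @export
activation_order <- function(events,
                             level = c("muscle", "syllable", "compartment",
                                       "movement")) {
  level <- match.arg(level)
  if (nrow(events) == 0) return(character(0))
  if (level == "muscle") {
    mnum <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", events$muscle)))
    ord <- order(events$onset_frame, mnum, events$muscle)
    return(events$muscle[ord])
  }
  if (level == "syllable") {
    stopifnot_data(!is.null(events$syllable),
                   "syllable level needs syllable events (annotate_syllables)")
    ord <- order(events$onset_frame, events$syllable)
    return(events$syllable[ord])
  }
  if (level == "compartment") {
    stopifnot_data(!is.null(events$segment),
                   "compartment level needs a segment column")
    roster <- muscle_roster()
    dv <- roster$dv[match(events$muscle, roster$muscle)]
    stopifnot_data(!any(is.na(dv)), "unknown muscle label: no compartment tag")
    seg_num <- as.integer(sub("^A", "", events$segment))
    ap <- ifelse(seg_num <= 4, "anterior", "posterior")
    tag <- paste(dv, ap, sep = ".")
    toks <- list()
    for (tg in unique(tag)) {
      iv <- merge_intervals(events$onset_frame[tag == tg],
                            events$offset_frame[tag == tg])
      toks[[tg]] <- data.frame(token = tg, onset = iv$start)
    }
    tk <- do.call(rbind, toks)
    tk <- tk[order(tk$onset, tk$token), ]
    return(tk$token)
  }
  # movement level
  stopifnot_data(!is.null(events$movement), "movement level needs movements")
  first_on <- tapply(events$onset_frame, events$movement, min)
  mv <- events$movement[order(events$onset_frame)]
  mv <- mv[c(TRUE, mv[-1] != mv[-length(mv)])]  # collapse consecutive runs
  mv
}

merge_intervals <- function(starts, ends) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  out_s <- starts[1]; out_e <- ends[1]
  res_s <- c(); res_e <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e) {
      out_e <- max(out_e, ends[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- starts[i]; out_e <- ends[i]
    }
  }
  list(start = c(res_s, out_s), end = c(res_e, out_e))
}

#' Gestalt (Ratcliff-Obershelp) sequence similarity
#'
#' The similarity score used throughout: `2M / T`, where `M` is the total
#' number of matched tokens found by recursively locating the longest common
#' contiguous block (ties broken by earliest start in `a`, then in `b`) and
#' recursing on both flanks, and `T` is the total length. 1 means identical
#' token order, 0 means no shared tokens. No junk heuristics are applied.
#'
#' @param a,b character (or atomic) token vectors; must be non-empty.
#' @return ratio in `[0, 1]`.
#' @examples
#' gestalt_similarity(c("A","B","C","D"), c("B","C","D","A"))  # 0.75
#' @export
gestalt_similarity <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    abort_ecdysim("similarity undefined for empty sequences",
                  "ecdysim_undefined_similarity")
  }
  lev <- unique(c(a, b))
  .gestalt_ratio_ints(match(a, lev), match(b, lev))
}

# Internal: similarity via the naive reference implementation (testing).
gestalt_similarity_bruteforce <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    abort_ecdysim("similarity undefined for empty sequences",
                  "ecdysim_undefined_similarity")
  }
  lev <- unique(c(a, b))
  .gestalt_ratio_brute_ints(match(a, lev), match(b, lev))
}

#' Pairwise sequence-similarity distribution
#'
#' Scores all unordered pairs of sequences, within groups when a grouping is
#' supplied (the convention: pairs are formed within animal and pooled; the
#' grand mean is the mean over all pairs).
#'
#' @param sequences list of non-empty token vectors.
#' @param group optional vector (length = number of sequences); pairs are
#'   formed only within a group.
#' @return list of class `ss_result`: `scores` (data.frame `i`, `j`,
#'   `group`, `score`), `mean`, `sd`, `cv_pct`, `n_pairs`.
#' @export
pairwise_ss <- function(sequences, group = NULL) {
  keep <- vapply(sequences, length, integer(1)) > 0
  sequences <- sequences[keep]
  if (is.null(group)) group <- rep(1L, length(sequences))
  else group <- group[keep]
  lev <- unique(unlist(sequences))
  ints <- lapply(sequences, function(s) match(s, lev))
  ia <- list(); ib <- list(); gi <- c(); ii <- c(); jj <- c()
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 2) next
    pr <- utils::combn(idx, 2)
    for (k in seq_len(ncol(pr))) {
      ia[[length(ia) + 1L]] <- ints[[pr[1, k]]]
      ib[[length(ib) + 1L]] <- ints[[pr[2, k]]]
    }
    gi <- c(gi, rep(g, ncol(pr)))
    ii <- c(ii, pr[1, ]); jj <- c(jj, pr[2, ])
  }
  if (length(ia) == 0) {
    abort_ecdysim("need at least 2 sequences in some group",
                  "ecdysim_insufficient_data")
  }
  scores <- .gestalt_many_ints(ia, ib)
  m <- mean(scores)
  s <- if (length(scores) >= 2) stats::sd(scores) else NA_real_
  out <- list(scores = data.frame(i = ii, j = jj, group = gi, score = scores),
              mean = m, sd = s,
              cv_pct = if (!is.na(s) && m != 0) 100 * s / m else NA_real_,
              n_pairs = length(scores))
  class(out) <- "ss_result"
  out
}

#' Shuffled-sequence permutation null for the mean similarity
#'
#' Each permutation replaces every sequence by a uniform random reordering
#' of its own tokens (length and token multiset preserved) and recomputes
#' the mean pairwise similarity under the same grouping. The p-value is
#' `(1 + #\{null means >= observed\}) / (n_perm + 1)`.
#'
#' @param sequences list of non-empty token vectors.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param group optional grouping as in [pairwise_ss()].
#' @return list: `observed_mean`, `null_means` (length `n_perm`),
#'   `null_mean`, `null_sd`, `p_value`.
#' @export
shuffled_null <- function(sequences, n_perm = 1000, seed = 1, group = NULL) {
  stopifnot_config(n_perm >= 1, "n_perm must be >= 1")
  keep <- vapply(sequences, length, integer(1)) > 0
  sequences <- sequences[keep]
  if (is.null(group)) group <- rep(1L, length(sequences))
  else group <- group[keep]
  lev <- unique(unlist(sequences))
  ints <- lapply(sequences, function(s) match(s, lev))
  pairs <- list()
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 2) next
    pr <- utils::combn(idx, 2)
    for (k in seq_len(ncol(pr))) {
      pairs[[length(pairs) + 1L]] <- c(pr[1, k], pr[2, k])
    }
  }
  stopifnot_data(length(pairs) >= 1, "need at least one scorable pair")
  pair_mean <- function(sq) {
    ia <- lapply(pairs, function(p) sq[[p[1]]])
    ib <- lapply(pairs, function(p) sq[[p[2]]])
    mean(.gestalt_many_ints(ia, ib))
  }
  observed <- pair_mean(ints)
  set.seed(seed)
  null_means <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    shuf <- lapply(ints, function(s) if (length(s) > 1) sample(s) else s)
    null_means[p] <- pair_mean(shuf)
  }
  list(observed_mean = observed, null_means = null_means,
       null_mean = mean(null_means), null_sd = stats::sd(null_means),
       p_value = (1 + sum(null_means >= observed)) / (n_perm + 1))
}

#' Token sequences per movement instance
#'
#' Splits a ground-truth event table (see [simulate_recording()]) into one
#' token sequence per movement instance and returns the sequences with
#' their movement-type grouping, ready for [pairwise_ss()] /
#' [shuffled_null()]. Levels:
#' \describe{
#'   \item{muscle}{all activations, including idiosyncratic ones.}
#'   \item{syllable}{syllable events from [annotate_syllables()] (requires
#'     `catalog`); off-syllable activity is excluded.}
#'   \item{compartment}{D-V x A-P compartment onsets of the
#'     syllable-assigned activations (requires `catalog`): compartments
#'     aggregate syllable activity, so off-syllable twitches do not create
#'     compartment tokens.}
#' }
#'
#' @param events event table with `bout_id`, `movement`,
#'   `movement_instance`, `muscle`, `segment`, `onset_frame`,
#'   `offset_frame` (and `animal_id`, optional).
#' @param level `"muscle"`, `"syllable"`, or `"compartment"`.
#' @param catalog a `syllable_catalog`; required for syllable and
#'   compartment levels.
#' @param exclude_rest drop twitch-only bouts (movement `Rest`).
#' @return list with `sequences` (list of token vectors) and `group`
#'   (movement type per sequence).
#' @export
movement_sequences <- function(events, level = "muscle", catalog = NULL,
                               exclude_rest = TRUE) {
  if (exclude_rest) events <- events[events$movement != "Rest", ]
  if (is.null(events$movement_instance)) events$movement_instance <- 1L
  aid <- if (is.null(events$animal_id)) "" else events$animal_id
  key <- paste(aid, events$bout_id, events$movement,
               events$movement_instance)
  chunks <- split(events, key)
  grp <- vapply(chunks, function(e) e$movement[1], character(1))
  seqs <- lapply(chunks, function(e) {
    if (level == "muscle") return(activation_order(e, "muscle"))
    stopifnot_config(!is.null(catalog),
                     "syllable/compartment levels need a catalog")
    ann <- annotate_syllables(e, catalog)
    if (level == "syllable") {
      activation_order(ann$syllable_events, "syllable")
    } else {
      activation_order(e[!is.na(ann$assignment), , drop = FALSE],
                       "compartment")
    }
  })
  keep <- vapply(seqs, length, integer(1)) > 0
  list(sequences = seqs[keep], group = unname(grp[keep]))
}
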