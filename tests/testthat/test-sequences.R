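test_that("activation order sorts by onset, then natural muscle label", {
  ev <- data.frame(muscle = c("M3", "M13", "M22"),
                   onset_frame = c(5, 5, 7),
                   offset_frame = c(9, 9, 11))
  expect_identical(activation_order(ev, "muscle"), c("M3", "M13", "M22"))
  # natural collation: M2 before M12 despite lexicographic order
  ev2 <- data.frame(muscle = c("M12", "M2"), onset_frame = c(3, 3),
                    offset_frame = c(5, 5))
  expect_identical(activation_order(ev2, "muscle"), c("M2", "M12"))
  expect_identical(activation_order(ev[1, ], "muscle"), "M3")
})

test_that("syllable level collapses an ensemble to one token", {
  catalog <- syllable_catalog(list(PME2 = c("M21", "M22", "M23")))
  ev <- data.frame(muscle = c("M21", "M22", "M23"),
                   onset_frame = c(10, 11, 12),
                   offset_frame = c(18, 18, 18))
  ann <- annotate_syllables(ev, catalog)
  expect_identical(activation_order(ann$syllable_events, "syllable"),
                   "PME2")
})

test_that("compartment tokens mark compartment onsets, not every event", {
  ev <- data.frame(muscle = c("M21", "M22", "M13"),
                   segment = c("A6", "A6", "A3"),
                   onset_frame = c(0, 2, 10),
                   offset_frame = c(6, 8, 14))
  # two lateral-posterior events merge into one interval -> one token
  expect_identical(activation_order(ev, "compartment"),
                   c("lateral.posterior", "ventral.anterior"))
})

test_that("gestalt ratio matches its recursive block definition", {
  expect_equal(gestalt_similarity(c("A", "B", "C"), c("A", "B", "C")), 1.0)
  expect_equal(gestalt_similarity(c("A", "B", "C", "D"),
                                  c("W", "X", "Y", "Z")), 0.0)
  expect_equal(gestalt_similarity(c("A", "B", "C", "D"),
                                  c("B", "C", "D", "A")), 0.75)
  expect_error(gestalt_similarity(character(0), "A"),
               class = "ecdysim_undefined_similarity")
})

test_that("ratio is a pure function of the ordered pair, within bounds", {
  # the gestalt ratio is order-dependent in rare block-tie cases (difflib
  # behaves identically), so the contract is purity per ordered pair plus
  # agreement with the independent brute-force recursion
  seqs <- enumerate_sequences(c("A", "B", "C"), 4)
  set.seed(1)
  idx <- cbind(sample(length(seqs), 400, TRUE),
               sample(length(seqs), 400, TRUE))
  for (k in seq_len(nrow(idx))) {
    a <- seqs[[idx[k, 1]]]; b <- seqs[[idx[k, 2]]]
    r_ab <- gestalt_similarity(a, b)
    expect_identical(r_ab, gestalt_similarity(a, b))  # deterministic
    expect_identical(r_ab, ecdysim:::gestalt_similarity_bruteforce(a, b))
    expect_true(r_ab >= 0 && r_ab <= 1)
    if (identical(a, b)) expect_equal(r_ab, 1)
    if (length(intersect(a, b)) == 0) expect_equal(r_ab, 0)
  }
  # the canonical asymmetric case, matching the reference implementation
  expect_equal(gestalt_similarity(c("B", "A"), c("A", "B", "C", "A")), 2 / 3)
  expect_equal(gestalt_similarity(c("A", "B", "C", "A"), c("B", "A")), 1 / 3)
})

test_that("ratio agrees with the reference difflib implementation", {
  # python's difflib.SequenceMatcher (no junk heuristics) is the canonical
  # reference; compare on the exhaustive <=4-token suite
  py <- Sys.which("python")
  expect_true(nzchar(py))
  script <- '
import itertools
from difflib import SequenceMatcher
seqs = []
for L in range(1, 5):
    seqs += ["".join(p) for p in itertools.product("ABC", repeat=L)]
for a in seqs:
    for b in seqs:
        print(a, b, repr(SequenceMatcher(None, a, b, autojunk=False).ratio()))
'
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- system2(py, f, stdout = TRUE)
  parts <- strsplit(out, " ")
  mism <- 0
  for (p in parts) {
    a <- strsplit(p[1], "")[[1]]
    b <- strsplit(p[2], "")[[1]]
    if (!isTRUE(all.equal(gestalt_similarity(a, b), as.numeric(p[3]),
                          tolerance = 1e-12))) mism <- mism + 1
  }
  expect_equal(mism, 0)
  expect_equal(length(parts), 120^2)
})

test_that("pairwise SS counts unordered pairs within groups", {
  seqs <- rep(list(c("A", "B", "C")), 4)
  res <- pairwise_ss(seqs)
  expect_equal(res$n_pairs, 6L)
  expect_equal(res$mean, 1.0)
  expect_equal(res$sd, 0)
  # n(n-1)/2 pair count
  set.seed(2)
  seqs2 <- lapply(1:7, function(i) sample(LETTERS[1:4], 5, TRUE))
  expect_equal(pairwise_ss(seqs2)$n_pairs, 21L)
  # grouping restricts pairs
  expect_equal(pairwise_ss(seqs2, group = c(1, 1, 1, 2, 2, 2, 2))$n_pairs,
               3L + 6L)
  expect_error(pairwise_ss(list(c("A"))),
               class = "ecdysim_insufficient_data")
})

test_that("shuffled null has the stated degenerate and extreme behavior", {
  # all singleton sequences: shuffling is the identity, p = 1
  ones <- list("A", "B", "A", "C")
  nl <- shuffled_null(ones, n_perm = 50, seed = 1)
  expect_true(all(nl$null_means == nl$observed_mean))
  expect_equal(nl$p_value, 1)
  # observed exceeding every null mean gives the add-one bound
  idseqs <- rep(list(c("A", "B", "C", "D", "E")), 5)
  nl2 <- shuffled_null(idseqs, n_perm = 199, seed = 2)
  expect_equal(nl2$observed_mean, 1)
  expect_equal(nl2$p_value, 1 / 200)
})

test_that("Monte-Carlo null mean matches exhaustive enumeration", {
  # 4 copies of ABCD: under the null each sequence is an independent
  # uniform permutation, so the expected pair score is the mean ratio over
  # all ordered permutation pairs (computable exactly: 24 x 24)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  pp <- perms(c("A", "B", "C", "D"))
  scores <- outer(seq_along(pp), seq_along(pp),
                  Vectorize(function(i, j)
                    gestalt_similarity(pp[[i]], pp[[j]])))
  exact_mean <- mean(scores)
  nl <- shuffled_null(rep(list(c("A", "B", "C", "D")), 4),
                      n_perm = 2000, seed = 3)
  se <- nl$null_sd / sqrt(2000)
  expect_lt(abs(nl$null_mean - exact_mean), 3 * se)
})
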