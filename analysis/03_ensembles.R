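#!/usr/bin/env Rscript
# Discover pupal muscle ensembles (co-active >= 3 consecutive frames, in
# >= 80% of a movement's instances, in >= 80% of animals) plus
# single-muscle syllables, and quantify off-syllable activity.

suppressPackageStartupMessages(library(ecdysim))

seed <- 1L
map <- make_muscle_map(7)
recs <- simulate_cohort(sim_config(seed = seed), map, 8)
events <- cohort_events(recs, truth = TRUE)

catalog <- discover_pmes(events)
catalog <- single_muscle_syllables(events, catalog)

cat(sprintf("discovered %d ensembles and %d single-muscle syllables\n",
            length(catalog$pmes), length(catalog$singles)))
for (p in catalog$pmes) {
  cat(sprintf("  %-6s {%s}  via %-9s support %.2f in %.0f%% of animals\n",
              p$id, paste(p$muscles, collapse = ","), p$movement,
              mean(p$support), 100 * p$animal_frac))
}
for (s in catalog$singles) {
  cat(sprintf("  single %-4s via %-9s support %.2f\n",
              s$muscle, s$movement, mean(s$support)))
}

jsonlite::write_json(ecdysim:::catalog_to_list(catalog),
                     "results/catalog.json", auto_unbox = TRUE, digits = NA)

# off-syllable fraction against the planted truth catalog
syl <- default_syllabary()
truth_catalog <- syllable_catalog(
  syl$pmes,
  setdiff(unique(unlist(lapply(syl$movements, function(m) m$syllables))),
          names(syl$pmes)))
mv <- events[events$movement != "Rest", ]
key <- paste(mv$animal_id, mv$bout_id, mv$movement_instance)
tot <- 0; off <- 0; share <- c()
for (e in split(mv, key)) {
  a <- annotate_syllables(e, truth_catalog)
  tot <- tot + nrow(e); off <- off + sum(is.na(a$assignment))
  pe <- a$syllable_events
  pe <- pe[pe$coactive_end - pe$coactive_start > 2, ]
  if (nrow(pe) > 0) share <- c(share, coactive_duration_share(pe, 3))
}
cat(sprintf("off-syllable activation fraction: %.3f (n = %d)\n",
            off / tot, tot))
cat(sprintf("3-frame window / co-active duration: %.2f on average\n",
            mean(share)))
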