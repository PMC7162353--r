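#!/usr/bin/env Rscript

## Stage 1: state the synthetic world and draw the sequencing run.
##
## Five participants sampled in four respiratory compartments (lavage,
## throat, mouth, nose); a 200-species, five-phylum airway taxonomy; planted
## inside-out (lung-colonizing) and outside-in (passively transported)
## abundance gradients with the throat at the geometric midpoint; two
## participants with an infection-displaced lavage community; trace reagent
## contamination; nanopore-like per-read hit attributes.

library(respiromics)

seed <- 1L
depth <- 20000L          # reads per library (scaled down from a full run)
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- scenario_config(depth = depth, seed = seed)
truth <- build_scenario(cfg)
rr <- sample_reads(truth, cfg, seed = seed)

write_hit_table(rr$hits, file.path(out, "hits.tsv"))
write_lineage(rbind(cfg$taxonomy, cfg$reagent_taxonomy),
              file.path(out, "lineage.tsv"))
write_metadata(rr$metadata, file.path(out, "metadata.tsv"))
utils::write.table(truth$species, file.path(out, "truth_species.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_json_file(list(seed = seed, depth = depth,
                     effect_size = cfg$effect_size,
                     concentration = cfg$concentration,
                     contamination_rate = cfg$contamination_rate,
                     off_window_fraction = cfg$off_window_fraction,
                     infection_participants = cfg$infection_participants,
                     infection_genera = cfg$infection_genera),
                file.path(out, "scenario.json"))

cat(sprintf("simulated %d reads across %d libraries (%d participants)\n",
            nrow(rr$hits), nrow(rr$metadata),
            nrow(truth$participants)))
cat(sprintf("planted gradients: %s\n",
            paste(sprintf("%s=%d", names(table(truth$species$gradient_class)),
                          table(truth$species$gradient_class)),
                  collapse = ", ")))
cat(sprintf("infection-displaced lavages: %s\n",
            paste(cfg$infection_participants, collapse = ", ")))
cat(sprintf("wrote hit table, lineage, metadata and truth under %s\n", out))
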