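#!/usr/bin/env Rscript

## Stage 4: the core computation. Per participant, compartment counts are
## total-sum scaled to the participant's median depth, lavage counts are
## differenced against mouth and nose, species exceeding a 150-read
## difference in both comparisons are called lung-enriched, and each
## species' gradient along the tract is classified using the throat as the
## intermediate compartment. Recovery is scored against the planted truth.

library(respiromics)

dat <- file.path("results", "data")
out <- file.path("results", "enrichment")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
threshold <- 150

species_tab <- read_count_table(
  file.path("results", "profile", "counts_species.tsv"), rank = "species")
metadata <- read_metadata(file.path(dat, "metadata.tsv"))
truth <- utils::read.table(file.path(dat, "truth_species.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)

results <- list(); gradients <- list()
for (pid in unique(metadata$participant_id)) {
  prof <- normalize_counts(participant_profile(species_tab, metadata, pid))
  results[[pid]] <- classify_enriched(compartment_differences(prof),
                                      threshold)
  gradients[[pid]] <- gradient_classify(prof)
  cat(sprintf("%s: %d lung-enriched species (normalized to %.0f reads)\n",
              pid, sum(results[[pid]]$enriched), prof$target_depth))
}

long <- do.call(rbind, lapply(names(results), function(pid)
  cbind(participant_id = pid, results[[pid]],
        gradient_class = unname(gradients[[pid]][results[[pid]]$species]))))
utils::write.table(long, file.path(out, "enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

hm <- heatmap_matrix(results)
utils::write.table(data.frame(species = rownames(hm), hm,
                              check.names = FALSE),
                   file.path(out, "heatmap_matrix.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

enriched_union <- sort(unique(unlist(
  lapply(results, function(r) r$species[r$enriched]))))
detected <- sum(rowSums(species_tab$counts) > 0)
cat(sprintf("union across participants: %d species (%.1f%% of %d detected)\n",
            length(enriched_union),
            enriched_fraction(enriched_union, detected), detected))

## recovery vs the planted truth (species named in the hit tables)
planted <- truth$species[truth$is_lung_enriched]
tp <- length(intersect(enriched_union, planted))
cat(sprintf("vs planted truth: %d/%d planted colonizers recovered (recall %.2f)\n",
            tp, length(planted), tp / length(planted)))

## calls beyond the planted colonizers: in this world those should be the
## infection genera displacing the lavage community of the infected
## participants, which are genuinely lung-enriched without being planted
## inside-out colonizers
scen <- jsonlite::read_json(file.path(dat, "scenario.json"),
                            simplifyVector = TRUE)
lineage <- read_lineage(file.path(dat, "lineage.tsv"))
extra <- setdiff(enriched_union, planted)
extra_inf <- lineage$genus[match(extra, lineage$species)] %in%
  scen$infection_genera
cat(sprintf("additional calls: %d, of which %d are infection-displacement genera (%s)\n",
            length(extra), sum(extra_inf),
            paste(scen$infection_genera, collapse = ", ")))
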