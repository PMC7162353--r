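#!/usr/bin/env Rscript

## Stage 3: multi-rank taxonomic profiling of the QC-passing top hits:
## count tables at species/genus/phylum rank, relative abundances, dominant
## phyla, per-genus species richness, and the top genera within each
## dominant phylum.

library(respiromics)

dat <- file.path("results", "data")
out <- file.path("results", "profile")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tophits <- read_hit_table(file.path("results", "qc", "tophits_qc.tsv"))
lineage <- read_lineage(file.path(dat, "lineage.tsv"))

tables <- lapply(stats::setNames(c("species", "genus", "phylum"),
                                 c("species", "genus", "phylum")),
                 function(rk) aggregate_counts(tophits, lineage, rk))
for (rk in names(tables)) {
  write_count_table(tables[[rk]], file.path(out, sprintf("counts_%s.tsv", rk)))
  write_long_csv(tables[[rk]], file.path(out, sprintf("counts_%s_long.csv", rk)))
  write_count_table(relative_abundance(tables[[rk]]),
                    file.path(out, sprintf("relabund_%s.tsv", rk)))
}

dom <- dominant_phyla(tables$phylum, k = 5)
cat(sprintf("species detected: %d\n",
            sum(rowSums(tables$species$counts) > 0)))
cat(sprintf("dominant phyla: %s (%.1f%% of reads)\n",
            paste(dom$phyla, collapse = ", "), 100 * dom$coverage))

rich <- species_richness(tables$species, lineage)
utils::write.table(
  data.frame(genus = names(rich$genus), n_species = rich$genus),
  file.path(out, "richness_genus.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

for (ph in dom$phyla) {
  tg <- top_genera(tables$genus, lineage, ph, n = 15)
  utils::write.table(tg, file.path(out, sprintf("top_genera_%s.tsv", ph)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: leading genera %s\n", ph,
              paste(utils::head(tg$genus, 3), collapse = ", ")))
}
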