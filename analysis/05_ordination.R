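#!/usr/bin/env Rscript

## Stage 5: community similarity. Bray-Curtis dissimilarities between all
## samples (on proportions), the lavage-vs-throat per-participant summary,
## and two ordinations: PCA of log counts and PCoA of the Bray-Curtis
## matrix.

library(respiromics)

out <- file.path("results", "ordination")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

species_tab <- read_count_table(
  file.path("results", "profile", "counts_species.tsv"), rank = "species")
metadata <- read_metadata(file.path("results", "data", "metadata.tsv"))

d <- bray_curtis_matrix(species_tab)
utils::write.table(data.frame(sample = rownames(d), d, check.names = FALSE),
                   file.path(out, "bray_curtis.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

profiles <- lapply(unique(metadata$participant_id), function(pid)
  participant_profile(species_tab, metadata, pid))
bc <- compartment_dissimilarity_summary(profiles, pair = c("LAV", "throat"))
cat(sprintf("Bray-Curtis LAV vs throat: %.2f +/- %.2f over %d participants\n",
            bc$mean, bc$sd, bc$n))

for (method in c("pca_logcounts", "pcoa_braycurtis")) {
  ord <- ordinate(species_tab, method)
  utils::write.table(
    data.frame(sample = rownames(ord$scores), ord$scores, check.names = FALSE),
    file.path(out, sprintf("scores_%s.tsv", method)), sep = "\t",
    quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(axis = colnames(ord$scores),
               variance_pct = ord$variance_explained),
    file.path(out, sprintf("variance_%s.tsv", method)), sep = "\t",
    quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: axis 1 %.0f%%, axis 2 %.0f%%\n", method,
              ord$variance_explained[1], ord$variance_explained[2]))
}
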