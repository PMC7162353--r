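#!/usr/bin/env Rscript

## Stage 2: QA/QC of the hit table, top-hit selection, and the kitome.
##
## Size selection keeps reads of 3,700-5,700 bp; database hits are kept at
## 70-95% identity with alignments >1,200 bp; one top hit per read by bit
## score. A paired PCR-negative/PCR-positive run estimates reagent
## contamination.

library(respiromics)

dat <- file.path("results", "data")
out <- file.path("results", "qc")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hits <- read_hit_table(file.path(dat, "hits.tsv"))
qc <- qc_config()

after_len <- filter_read_lengths(hits, qc)
after_hit <- filter_hits(after_len, qc)
tophits <- select_top_hit(after_hit)

summ <- qc_summary(hits, after_len, after_hit, tophits)
write_hit_table(tophits, file.path(out, "tophits_qc.tsv"))
utils::write.table(summ, file.path(out, "qc_summary.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_json_file(summ, file.path(out, "qc_summary.json"))

cat(sprintf("reads in: %d; after size selection: %d; after hit QA/QC: %d\n",
            nrow(hits), nrow(after_len), nrow(after_hit)))

## kitome: simulate a paired PCR-negative / PCR-positive run at the same
## depth and compute the implied contamination
scen <- jsonlite::read_json(file.path(dat, "scenario.json"))
cfg <- scenario_config(depth = scen$depth, seed = scen$seed)
kp <- kitome_pair(cfg, neg_rate = 0.0003, seed = scen$seed + 1L)
kneg <- nrow(filter_hits(filter_read_lengths(kp$negative, qc), qc))
kpos <- nrow(filter_hits(filter_read_lengths(kp$positive, qc), qc))
kit <- kitome_contamination(kneg, kpos)
write_json_file(kit, file.path(out, "kitome.json"))
cat(sprintf("kitome: %d negative vs %d positive QC reads -> %.2f%% contamination",
            kit$neg_count, kit$pos_count, kit$percent),
    if (!is.na(kit$fold)) sprintf(" (%.0f-fold difference)\n", kit$fold)
    else "\n")
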