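test_that("aggregation is additive over lineages and conserves reads", {
  lin <- toy_lineage()
  hits <- toy_hits(c("t1", "t1", "t1", "t2", "t2"))
  gen <- aggregate_counts(hits, lin, "genus")
  expect_identical(unname(gen$counts["Genus1", "s1"]), 5L)
  sp <- aggregate_counts(hits, lin, "species")
  expect_identical(unname(sp$counts["Genus1 spA", "s1"]), 3L)
  expect_identical(sum(sp$counts), nrow(hits))
  ## empty input -> empty table
  empty <- aggregate_counts(toy_hits(character()), lin, "species")
  expect_identical(dim(empty), c(0L, 0L))
})

test_that("unknown taxa are bucketed as unclassified (strict mode errors)", {
  lin <- toy_lineage()
  hits <- toy_hits(c("t1", "nope", "t2"))
  expect_warning(tab <- aggregate_counts(hits, lin, "genus"), "unclassified")
  expect_identical(unname(tab$counts["unclassified", "s1"]), 1L)
  expect_identical(sum(tab$counts), 3L)          # conservation holds
  expect_error(aggregate_counts(hits, lin, "genus", strict = TRUE),
               "missing from the lineage")
})

test_that("rank aggregation is path independent", {
  cfg <- small_scenario(depth = 400, seed = 55)
  truth <- build_scenario(cfg)
  rr <- sample_reads(truth, cfg)
  lin <- rbind(cfg$taxonomy, cfg$reagent_taxonomy)
  sp <- aggregate_counts(rr$hits, lin, "species")
  for (rk in c("genus", "family", "phylum")) {
    direct <- aggregate_counts(rr$hits, lin, rk)
    rolled <- rollup_table(sp, lin, rk)
    expect_equal(rolled$counts[rownames(direct$counts), ], direct$counts)
    expect_identical(sum(direct$counts), nrow(rr$hits))
  }
})

test_that("species-level column sums equal per-sample read counts", {
  cfg <- small_scenario(depth = 300, seed = 14)
  truth <- build_scenario(cfg)
  rr <- sample_reads(truth, cfg)
  lin <- rbind(cfg$taxonomy, cfg$reagent_taxonomy)
  sp <- aggregate_counts(rr$hits, lin, "species")
  recount <- table(rr$hits$sample_id)
  expect_identical(colSums(sp$counts)[names(recount)],
                   stats::setNames(as.numeric(recount), names(recount)))
})

test_that("relative abundance normalizes columns to the simplex, idempotently", {
  mat <- matrix(c(2, 2, 1, 0), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  tab <- count_table(mat, "species")
  rel <- relative_abundance(tab)
  expect_equal(unname(rel$counts[, "s1"]), c(0.5, 0.5))
  expect_equal(unname(rel$counts[, "s2"]), c(1, 0))
  expect_equal(relative_abundance(rel)$counts, rel$counts)
  ## random fixture: columns sum to 1 within 1e-9
  big <- count_table(matrix(withr::with_seed(8, rpois(600, 40)), 30, 20,
                            dimnames = list(sprintf("t%02d", 1:30),
                                            sprintf("s%02d", 1:20))),
                     "species")
  expect_true(all(abs(colSums(relative_abundance(big)$counts) - 1) < 1e-9))
  ## zero-total samples are excluded with a warning
  mat0 <- cbind(mat, s3 = c(0, 0))
  expect_warning(rel0 <- relative_abundance(count_table(mat0, "species")),
                 "zero-total")
  expect_identical(colnames(rel0$counts), c("s1", "s2"))
})

test_that("dominant phyla ranking, coverage and tie-breaks are exact", {
  mk <- function(counts) count_table(
    matrix(counts, ncol = 1, dimnames = list(names(counts), "s1")), "phylum")
  single <- mk(c(OnlyPhylum = 10))
  expect_equal(dominant_phyla(single)$coverage, 1)
  pooled <- c(A = 50, B = 30, C = 10, D = 5, E = 4, F = 1)
  res <- dominant_phyla(mk(pooled), k = 5)
  expect_identical(res$phyla, c("A", "B", "C", "D", "E"))
  expect_equal(res$coverage, 0.99)
  tied <- c(Zeta = 10, Alpha = 10, Beta = 10, C1 = 10, C2 = 10, C3 = 1)
  expect_identical(dominant_phyla(mk(tied), k = 5)$phyla,
                   c("Alpha", "Beta", "C1", "C2", "Zeta"))
})

test_that("dominant phyla recover a planted >=98% five-phylum community", {
  cfg <- scenario_config(depth = 100000, n_participants = 1, seed = 19,
                         contamination_rate = 0.0003,
                         infection_participants = character())
  truth <- build_scenario(cfg)
  sc <- sample_counts(truth, cfg)
  lin <- rbind(cfg$taxonomy, cfg$reagent_taxonomy)
  sp_names <- stats::setNames(lin$species, lin$taxon_id)
  mat <- sc$counts$counts
  rownames(mat) <- sp_names[rownames(mat)]
  phy <- rollup_table(count_table(mat, "species"), lin, "phylum")
  res <- dominant_phyla(phy, k = 5)
  expect_setequal(res$phyla, unique(cfg$taxonomy$phylum))
  expect_gte(res$coverage, 0.98)
})

test_that("species richness counts distinct detected species per group", {
  lin <- toy_lineage()
  mat <- matrix(c(3, 1, 0, 2), 4, 1,
                dimnames = list(lin$species, "s1"))
  rich <- species_richness(count_table(mat, "species"), lin)
  expect_identical(rich$genus[["Genus1"]], 2L)
  expect_false("Genus2" %in% names(rich$genus))   # all-zero species excluded
  expect_identical(rich$phylum[["Phy1"]], 2L)
  expect_identical(rich$phylum[["Phy2"]], 1L)
  ## seeded fixture equals a set-size recount
  cfg <- small_scenario(depth = 200, seed = 23)
  truth <- build_scenario(cfg)
  rr <- sample_reads(truth, cfg)
  lin2 <- rbind(cfg$taxonomy, cfg$reagent_taxonomy)
  sp <- aggregate_counts(rr$hits, lin2, "species")
  rich2 <- species_richness(sp, lin2)
  detected <- rownames(sp$counts)[rowSums(sp$counts) > 0]
  oracle <- table(lin2$genus[match(detected, lin2$species)])
  expect_identical(rich2$genus[names(oracle)],
                   stats::setNames(as.integer(oracle), names(oracle)))
})

test_that("top genera are ranked, tie-broken and truncated with an other bucket", {
  lin <- data.frame(taxon_id = sprintf("t%d", 1:4),
                    species = sprintf("G%d s", 1:4),
                    genus = c("Ga", "Gb", "Gc", "Gd"),
                    family = "F", phylum = c("P", "P", "P", "Q"),
                    stringsAsFactors = FALSE)
  mat <- matrix(c(5, 5, 2, 9), 4, 1,
                dimnames = list(c("Ga", "Gb", "Gc", "Gd"), "s1"))
  tab <- count_table(mat, "genus")
  res <- top_genera(tab, lin, "P", n = 2)
  expect_identical(res$genus, c("Ga", "Gb", "other"))     # tie: Ga before Gb
  expect_equal(res$rel_abundance, c(5, 5, 2) / 12)
  one <- top_genera(tab, lin, "Q", n = 5)
  expect_identical(one$genus, "Gd")
  expect_equal(one$rel_abundance, 1)
  expect_warning(none <- top_genera(tab, lin, "Nope"), "no genera")
  expect_identical(nrow(none), 0L)
  ## fixture vs exhaustive sort oracle
  cfg <- small_scenario(depth = 500, seed = 29)
  truth <- build_scenario(cfg)
  rr <- sample_reads(truth, cfg)
  lin2 <- rbind(cfg$taxonomy, cfg$reagent_taxonomy)
  gen <- aggregate_counts(rr$hits, lin2, "genus")
  res2 <- top_genera(gen, lin2, "Firmicutes", n = 3)
  pooled <- rowSums(gen$counts)
  members <- intersect(names(pooled),
                       unique(lin2$genus[lin2$phylum == "Firmicutes"]))
  oracle <- sort(pooled[members], decreasing = TRUE)
  expect_identical(res2$genus[1:3], names(oracle)[1:3])
  expect_equal(res2$count[1:3], unname(oracle[1:3]))
})
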