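## Shared fixtures: everything is generated in code under fixed seeds.

## A small, fast scenario: minimal taxonomy, shallow depth.
small_scenario <- function(depth = 2000, seed = 101, ...) {
  scenario_config(
    n_participants = 2,
    taxonomy = default_taxonomy(44),
    n_inside_out = 4, n_outside_in = 8,
    depth = depth,
    infection_participants = character(),
    seed = seed,
    ...
  )
}

## Random hit table with controlled in/off-window structure; independent of
## the package's generator so filter tests have an external fixture.
random_hits <- function(n = 500, seed = 7, frac_bad_id = 0.06,
                        frac_bad_aln = 0.06, frac_bad_len = 0.06) {
  withr::with_seed(seed, {
    df <- data.frame(
      read_id = sprintf("r%05d", seq_len(n)),
      taxon_id = sprintf("T%04d", sample(50, n, replace = TRUE)),
      pct_identity = runif(n, 70, 95),
      aln_length = sample(1201:1600, n, replace = TRUE),
      bit_score = round(runif(n, 500, 2500), 1),
      read_length = sample(3700:5700, n, replace = TRUE),
      sample_id = sample(c("A_LAV", "A_mouth"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    bad_id <- sample(n, round(frac_bad_id * n))
    df$pct_identity[bad_id] <- sample(c(runif(length(bad_id), 40, 69.9),
                                        runif(length(bad_id), 95.1, 100)),
                                      length(bad_id))
    bad_aln <- sample(setdiff(seq_len(n), bad_id), round(frac_bad_aln * n))
    df$aln_length[bad_aln] <- sample(600:1200, length(bad_aln), replace = TRUE)
    bad_len <- sample(setdiff(seq_len(n), c(bad_id, bad_aln)),
                      round(frac_bad_len * n))
    df$read_length[bad_len] <- sample(c(2000:3699, 5701:7000),
                                      length(bad_len), replace = TRUE)
    df
  })
}

## Tiny lineage table for aggregation tests.
toy_lineage <- function() {
  data.frame(
    taxon_id = c("t1", "t2", "t3", "t4"),
    species = c("Genus1 spA", "Genus1 spB", "Genus2 spC", "Genus3 spD"),
    genus = c("Genus1", "Genus1", "Genus2", "Genus3"),
    family = c("Fam1", "Fam1", "Fam2", "Fam3"),
    phylum = c("Phy1", "Phy1", "Phy1", "Phy2"),
    stringsAsFactors = FALSE
  )
}

toy_hits <- function(taxa, sample_id = "s1") {
  n <- length(taxa)
  data.frame(read_id = sprintf("%s_r%03d", rep(sample_id, n), seq_len(n)),
             taxon_id = taxa,
             pct_identity = rep(85, n), aln_length = rep(1400L, n),
             bit_score = rep(2000, n), sample_id = rep(sample_id, n),
             stringsAsFactors = FALSE)
}

## Build a participant_profile directly from a species x compartment matrix.
make_profile <- function(mat, participant_id = "P1", normalized = FALSE,
                         target_depth = NA_real_) {
  structure(list(participant_id = participant_id, counts = mat,
                 normalized = normalized, target_depth = target_depth),
            class = "participant_profile")
}

compartment_matrix <- function(species, ...) {
  cols <- list(...)
  mat <- do.call(cbind, cols)
  rownames(mat) <- species
  mat
}

## Eigenvector signs are arbitrary; align each column of `a` with `ref`
## before comparing score matrices.
align_signs <- function(a, ref) {
  for (j in seq_len(ncol(a))) {
    if (sum(a[, j] * ref[, j]) < 0) a[, j] <- -a[, j]
  }
  a
}

## Independent double-centering PCoA oracle (dense eigensolver route).
pcoa_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-12
  scores <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  for (jx in seq_len(ncol(scores))) {
    if (scores[which.max(abs(scores[, jx])), jx] < 0)
      scores[, jx] <- -scores[, jx]
  }
  list(scores = scores,
       var_pct = 100 * e$values[keep] / sum(e$values[keep]))
}
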