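## Synthetic multi-compartment respiratory community generator.
##
## The generator states a small world with the structure the downstream
## analysis assumes: a 5-phylum oral/respiratory taxonomy, per-species
## abundance gradients along nose/mouth -> throat -> lavage (inside-out,
## outside-in or flat), optional infection displacement of the lavage
## community, Dirichlet-multinomial read-count noise, nanopore-like
## identity/length/alignment marginals, and trace reagent ("kitome")
## contamination. Every stochastic step flows from one integer seed.

#' Default respiratory-tract taxonomy
#'
#' Builds a species-level lineage table spanning the five phyla that dominate
#' respiratory samples (Firmicutes, Proteobacteria, Actinobacteria,
#' Bacteroidetes, Fusobacteria), with the genera most prominent in airway
#' communities (Streptococcus, Veillonella, Prevotella, Neisseria,
#' Actinomyces, ...). A handful of well-known airway species keep their real
#' epithets; the remainder are synthetic placeholder species distributed
#' round-robin so every genus holds at least two species.
#'
#' @param n_species total number of species (>= 42 so each genus gets two).
#' @return data.frame with columns `taxon_id`, `species`, `genus`, `family`,
#'   `phylum` — one row per species.
#' @export
default_taxonomy <- function(n_species = 200) {
  genera <- data.frame(
    genus = c("Streptococcus", "Veillonella", "Megasphaera", "Gemella",
              "Neisseria", "Campylobacter", "Haemophilus", "Pseudomonas",
              "Pantoea", "Tatumella", "Citrobacter",
              "Actinomyces", "Rothia", "Corynebacterium", "Propionibacterium",
              "Prevotella", "Porphyromonas", "Capnocytophaga",
              "Fusobacterium", "Leptotrichia"),
    family = c("Streptococcaceae", "Veillonellaceae", "Veillonellaceae",
               "Gemellaceae",
               "Neisseriaceae", "Campylobacteraceae", "Pasteurellaceae",
               "Pseudomonadaceae", "Erwiniaceae", "Erwiniaceae",
               "Enterobacteriaceae",
               "Actinomycetaceae", "Micrococcaceae", "Corynebacteriaceae",
               "Propionibacteriaceae",
               "Prevotellaceae", "Porphyromonadaceae", "Flavobacteriaceae",
               "Fusobacteriaceae", "Leptotrichiaceae"),
    phylum = c(rep("Firmicutes", 4), rep("Proteobacteria", 7),
               rep("Actinobacteria", 4), rep("Bacteroidetes", 3),
               rep("Fusobacteria", 2)),
    stringsAsFactors = FALSE
  )
  named <- list(
    Streptococcus = c("infantis", "mitis", "parasanguinis", "oralis"),
    Veillonella = c("dispar", "atypica", "tobetsuensis", "rogosae"),
    Megasphaera = "micronuciformis",
    Pseudomonas = "aeruginosa",
    Pantoea = "agglomerans",
    Tatumella = "ptyseos",
    Citrobacter = "youngae"
  )
  if (n_species < 2L * nrow(genera) + 2L)
    stopf("n_species must be at least %d (two species per genus)",
          2L * nrow(genera) + 2L)
  ## round-robin over genera until n_species rows exist
  rows <- vector("list", n_species)
  counter <- integer(nrow(genera))
  gi <- 0L
  for (i in seq_len(n_species)) {
    gi <- gi %% nrow(genera) + 1L
    counter[gi] <- counter[gi] + 1L
    g <- genera$genus[gi]
    epithets <- named[[g]]
    epi <- if (!is.null(epithets) && counter[gi] <= length(epithets))
      epithets[counter[gi]] else sprintf("sp%03d", counter[gi])
    rows[[i]] <- data.frame(
      taxon_id = sprintf("T%04d", i),
      species = paste(g, epi),
      genus = g, family = genera$family[gi], phylum = genera$phylum[gi],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Reagent ("kitome") taxa
#'
#' Lineage entries for the water/kit contaminant genera routinely reported in
#' low-biomass amplicon studies. These never carry community abundance; reads
#' assigned to them arise only through the configured contamination rate or a
#' PCR-negative library.
#' @return data.frame with the same columns as [default_taxonomy()].
#' @export
default_reagent_taxa <- function() {
  data.frame(
    taxon_id = sprintf("R%03d", 1:4),
    species = c("Ralstonia pickettii", "Sphingomonas paucimobilis",
                "Bradyrhizobium japonicum", "Methylobacterium extorquens"),
    genus = c("Ralstonia", "Sphingomonas", "Bradyrhizobium",
              "Methylobacterium"),
    family = c("Burkholderiaceae", "Sphingomonadaceae",
               "Bradyrhizobiaceae", "Methylobacteriaceae"),
    phylum = rep("Proteobacteria", 4),
    stringsAsFactors = FALSE
  )
}

#' Calibrate the Dirichlet-multinomial concentration to a replicate CV
#'
#' For Dirichlet-multinomial counts with total concentration c at depth n,
#' a taxon observed at `count` reads has
#' `CV^2 = (1 - p) (n + c) / (n p (1 + c))` with `p = count / n`. Long-read
#' rRNA operon profiling shows replicate counts above 100 reads reproducible
#' to a coefficient of variation of about 12% — barely above the pure
#' multinomial floor (`1/sqrt(count)` = 10%). Solving for c gives the
#' concentration that reproduces that technical reproducibility at the given
#' depth; `Inf` (pure multinomial) is returned when the requested CV is at
#' or below the multinomial floor.
#'
#' @param depth reads per library.
#' @param cv target coefficient of variation at `count` reads.
#' @param count read count at which the CV is pinned.
#' @return total Dirichlet concentration (possibly `Inf`).
#' @export
calibrate_concentration <- function(depth, cv = 0.12, count = 100) {
  if (depth <= count) stopf("depth must exceed the calibration count")
  p <- count / depth
  a <- cv^2 * count / (1 - p)
  if (a <= 1) return(Inf)
  (depth - a) / (a - 1)
}

#' Scenario configuration for the community simulator
#'
#' Collects every knob of the synthetic world. Defaults state the study
#' design the pipeline targets: 5 participants sampled in 4 respiratory
#' compartments, two of them with an infection-displaced lavage community, a
#' 200-species 5-phylum taxonomy, a heavy-tailed (log-normal) species
#' abundance distribution, planted inside-out and outside-in gradients,
#' Dirichlet-multinomial count noise, and nanopore-like hit marginals inside
#' the QC windows (identity 70--95%, alignment > 1,200 bp, read length
#' 3,700--5,700 bp) apart from a stated off-window fraction.
#'
#' @param n_participants number of participants; ids are taken from
#'   `participant_ids`.
#' @param taxonomy species-level lineage table (see [default_taxonomy()]).
#' @param base_abundance per-species relative abundance in the outer
#'   (mouth/nose) pool; must sum to 1. `NULL` draws a log-normal species
#'   abundance distribution (`sdlog` 1.5) from the seed.
#' @param gradient_class optional character vector (one of `"inside_out"`,
#'   `"outside_in"`, `"flat"` per species, aligned with `taxonomy`). `NULL`
#'   plants `n_inside_out` and `n_outside_in` labels at seeded random among
#'   species with above-median base abundance; the rest are flat.
#' @param n_inside_out,n_outside_in planted label counts used when
#'   `gradient_class` is `NULL`.
#' @param effect_size total fold-change across the tract for non-flat
#'   species (> 1); the throat sits at the geometric midpoint.
#' @param depth reads per sample (scalar, recycled over samples).
#' @param concentration Dirichlet-multinomial total concentration; larger is
#'   closer to multinomial sampling, `Inf` is exactly multinomial. `NULL`
#'   (the default) calibrates it with [calibrate_concentration()] so that a
#'   100-read count reproduces with the platform's ~12% replicate CV at the
#'   configured depth.
#' @param infection_participants participant ids whose lavage community is
#'   displaced by the infection genera.
#' @param infection_genera genera receiving the displaced lavage mass.
#' @param infection_mass fraction of the lavage community reallocated to the
#'   infection genera for infected participants.
#' @param contamination_rate fraction of reads per library drawn from the
#'   reagent pool, in `[0, 1)`.
#' @param reagent_taxonomy lineage table for reagent taxa.
#' @param identity_model,length_model,aln_model `c(mean =, sd =)` of percent
#'   identity (0--100), read length (bp) and alignment length (bp).
#' @param off_window_fraction fraction of reads forced outside at least one
#'   QC window.
#' @param qc QC window configuration ([qc_config()]) the in/off-window
#'   generation refers to.
#' @param participant_ids labels used for participants.
#' @param seed master integer seed; every downstream draw derives from it.
#' @return object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(n_participants = 5,
                            taxonomy = default_taxonomy(),
                            base_abundance = NULL,
                            gradient_class = NULL,
                            n_inside_out = 10,
                            n_outside_in = 50,
                            effect_size = 4,
                            depth = 50000,
                            concentration = NULL,
                            infection_participants = c("S07", "S08"),
                            infection_genera = c("Pseudomonas", "Pantoea",
                                                 "Tatumella"),
                            infection_mass = 0.6,
                            contamination_rate = 0.0003,
                            reagent_taxonomy = default_reagent_taxa(),
                            identity_model = c(mean = 87, sd = 4),
                            length_model = c(mean = 4400, sd = 300),
                            aln_model = c(mean = 1400, sd = 80),
                            off_window_fraction = 0.05,
                            qc = qc_config(),
                            participant_ids = NULL,
                            seed = 1) {
  if (is.null(participant_ids)) {
    pool <- c("S06", "S07", "S08", "S12", "S15",
              sprintf("S%02d", 16:99))
    participant_ids <- pool[seq_len(n_participants)]
  }
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    participant_ids = participant_ids,
    taxonomy = taxonomy,
    base_abundance = base_abundance,
    gradient_class = gradient_class,
    n_inside_out = as.integer(n_inside_out),
    n_outside_in = as.integer(n_outside_in),
    effect_size = effect_size,
    depth = depth,
    concentration = concentration %||%
      (if (stats::median(depth) > 100)
        calibrate_concentration(stats::median(depth)) else Inf),
    infection_participants = intersect(infection_participants,
                                       participant_ids),
    infection_genera = infection_genera,
    infection_mass = infection_mass,
    contamination_rate = contamination_rate,
    reagent_taxonomy = reagent_taxonomy,
    identity_model = identity_model,
    length_model = length_model,
    aln_model = aln_model,
    off_window_fraction = off_window_fraction,
    qc = qc,
    seed = check_seed(seed)
  ), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_taxonomy <- function(tax) {
  need <- c("taxon_id", "species", "genus", "family", "phylum")
  if (!all(need %in% names(tax)))
    stopf("taxonomy must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(tax$taxon_id))
    stopf("taxonomy has duplicated taxon_id values")
  ## a species name must map to exactly one genus, a genus to one
  ## family/phylum (no polyphyletic entries)
  for (pair in list(c("species", "genus"), c("genus", "family"),
                    c("genus", "phylum"))) {
    tab <- unique(tax[, pair])
    dup <- tab[[1]][duplicated(tab[[1]])]
    if (length(dup))
      stopf("inconsistent taxonomy: %s '%s' listed under two %s entries",
            pair[1], dup[1], pair[2])
  }
  invisible(tax)
}

validate_scenario_config <- function(cfg) {
  validate_taxonomy(cfg$taxonomy)
  validate_taxonomy(cfg$reagent_taxonomy)
  k <- nrow(cfg$taxonomy)
  if (!is.null(cfg$base_abundance)) {
    if (length(cfg$base_abundance) != k)
      stopf("base_abundance must have one entry per species")
    if (abs(sum(cfg$base_abundance) - 1) > 1e-9)
      stopf("base_abundance must sum to 1 (off by %.3g)",
            abs(sum(cfg$base_abundance) - 1))
    if (any(cfg$base_abundance < 0)) stopf("base_abundance must be >= 0")
  }
  if (!is.null(cfg$gradient_class)) {
    if (length(cfg$gradient_class) != k)
      stopf("gradient_class must have one entry per species")
    bad <- setdiff(unique(cfg$gradient_class), GRADIENT_CLASSES[1:3])
    if (length(bad))
      stopf("unknown gradient_class value '%s'", bad[1])
  }
  if (cfg$effect_size <= 1) stopf("effect_size must be > 1")
  if (any(cfg$depth < 0)) stopf("depths must be >= 0")
  if (cfg$concentration <= 0) stopf("concentration must be > 0")
  if (cfg$contamination_rate < 0 || cfg$contamination_rate >= 1)
    stopf("contamination_rate must be in [0, 1)")
  if (cfg$off_window_fraction < 0 || cfg$off_window_fraction >= 1)
    stopf("off_window_fraction must be in [0, 1)")
  if (cfg$contamination_rate + cfg$off_window_fraction >= 1)
    stopf("contamination_rate + off_window_fraction must be < 1")
  if (cfg$infection_mass < 0 || cfg$infection_mass >= 1)
    stopf("infection_mass must be in [0, 1)")
  invisible(cfg)
}

GRADIENT_CLASSES <- c("inside_out", "outside_in", "flat", "discordant")

#' Build the ground-truth expectation table for a scenario
#'
#' Turns a [scenario_config()] into per-participant expected compartment
#' proportions plus planted per-species labels. For a non-flat species with
#' outer-pool abundance p and total fold-change e, the pre-normalization
#' compartment weights are p, p*sqrt(e), p*e (outer, throat, lavage) for the
#' inside-out pattern and p, p/sqrt(e), p/e for the outside-in pattern —
#' the throat is the geometric midpoint of the two end members. Each
#' compartment vector is then renormalized to the simplex. Mouth and nose
#' share the outer pool. For infected participants the lavage vector
#' reallocates `infection_mass` of its total to the infection genera
#' (proportionally within the set) and rescales the remaining species.
#'
#' @param config a [scenario_config()].
#' @return object of class `truth_table`: list with `species` (lineage +
#'   `base_abundance`, `gradient_class`, `is_lung_enriched`), `expected`
#'   (per participant, a species x compartment matrix of proportions),
#'   `participants` (data.frame with `participant_id`, `infected`) and the
#'   originating `config`.
#' @export
build_scenario <- function(config) {
  validate_scenario_config(config)
  tax <- config$taxonomy
  k <- nrow(tax)
  seeds <- derive_seeds(config$seed, 2L)

  p <- config$base_abundance
  if (is.null(p)) {
    p <- withr::with_seed(seeds[1], stats::rlnorm(k, meanlog = 0, sdlog = 1.5))
    p <- p / sum(p)
  }

  cls <- config$gradient_class
  if (is.null(cls)) {
    if (config$n_inside_out + config$n_outside_in > k)
      stopf("planted label counts exceed the number of species")
    ## plant gradients among the more abundant half: shallow gradients on
    ## rare species are unobservable at realistic depths
    pool <- which(p >= stats::median(p))
    if (length(pool) < config$n_inside_out + config$n_outside_in)
      pool <- order(p, decreasing = TRUE)[
        seq_len(config$n_inside_out + config$n_outside_in)]
    picks <- withr::with_seed(
      seeds[2],
      sample(pool, config$n_inside_out + config$n_outside_in))
    cls <- rep("flat", k)
    cls[picks[seq_len(config$n_inside_out)]] <- "inside_out"
    if (config$n_outside_in > 0)
      cls[picks[config$n_inside_out + seq_len(config$n_outside_in)]] <-
        "outside_in"
  }

  e <- config$effect_size
  mult <- cbind(
    LAV = ifelse(cls == "inside_out", e, ifelse(cls == "outside_in", 1 / e, 1)),
    throat = ifelse(cls == "inside_out", sqrt(e),
                    ifelse(cls == "outside_in", 1 / sqrt(e), 1)),
    mouth = 1, nose = 1
  )[, COMPARTMENTS]
  base <- p * mult                      # species x compartment weights
  expected_base <- sweep(base, 2, colSums(base), "/")
  rownames(expected_base) <- tax$taxon_id

  inf_set <- tax$genus %in% config$infection_genera
  participants <- data.frame(
    participant_id = config$participant_ids,
    infected = config$participant_ids %in% config$infection_participants,
    stringsAsFactors = FALSE
  )
  expected <- lapply(seq_len(nrow(participants)), function(i) {
    m <- expected_base
    if (participants$infected[i]) {
      v <- m[, "LAV"]
      w <- if (sum(v[inf_set]) > 0) v[inf_set] / sum(v[inf_set])
           else rep(1 / sum(inf_set), sum(inf_set))
      v2 <- v
      v2[inf_set] <- config$infection_mass * w
      v2[!inf_set] <- v[!inf_set] *
        (1 - config$infection_mass) / sum(v[!inf_set])
      m[, "LAV"] <- v2
    }
    m
  })
  names(expected) <- participants$participant_id

  species <- cbind(tax, data.frame(
    base_abundance = p,
    gradient_class = cls,
    is_lung_enriched = cls == "inside_out",
    stringsAsFactors = FALSE
  ))
  structure(list(species = species, expected = expected,
                 participants = participants, config = config),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf(
    "truth_table: %d species, %d participants (%d infected)\n",
    nrow(x$species), nrow(x$participants), sum(x$participants$infected)))
  cat(sprintf("  gradient classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$species$gradient_class)),
                            table(x$species$gradient_class)),
                    collapse = ", ")))
  invisible(x)
}

## One Dirichlet-multinomial library draw around expected proportions,
## with a binomial number of reads diverted to the reagent pool.
sample_library_counts <- function(expected, depth, concentration,
                                  contamination_rate, n_reagent) {
  n_contam <- if (contamination_rate > 0)
    stats::rbinom(1, depth, contamination_rate) else 0L
  n_comm <- depth - n_contam
  comm <- if (n_comm > 0) {
    pr <- if (is.finite(concentration)) rdirichlet1(concentration * expected)
          else expected                      # Inf concentration: multinomial
    drop(stats::rmultinom(1, n_comm, pr))
  } else rep(0L, length(expected))
  reag <- if (n_contam > 0)
    drop(stats::rmultinom(1, n_contam, rep(1 / n_reagent, n_reagent)))
  else rep(0L, n_reagent)
  list(community = comm, reagent = reag)
}

#' Draw per-sample species counts for a scenario
#'
#' Samples one library per participant x compartment: read counts are
#' Dirichlet-multinomial around the truth-table expected proportions (total
#' concentration `config$concentration`), with a binomial
#' `contamination_rate` share of each library diverted to the reagent taxa.
#' Mouth and nose draw independently from the shared outer pool.
#'
#' @param truth a [build_scenario()] result.
#' @param config the scenario configuration (defaults to the one stored in
#'   `truth`).
#' @param seed integer seed (defaults to the config seed). Identical
#'   `(config, seed)` give identical output.
#' @return list with `counts` (a raw species-rank [count_table()] including
#'   reagent taxa rows) and `metadata` (`sample_id`, `participant_id`,
#'   `compartment`, `library_type`, `depth`).
#' @export
sample_counts <- function(truth, config = truth$config, seed = config$seed) {
  seed <- check_seed(seed)
  participants <- truth$participants$participant_id
  samples <- expand.grid(compartment = COMPARTMENTS,
                         participant_id = participants,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("participant_id", "compartment")]
  samples$sample_id <- paste(samples$participant_id, samples$compartment,
                             sep = "_")
  depth <- rep_len(config$depth, nrow(samples))
  seeds <- derive_seeds(seed, nrow(samples))

  n_reagent <- nrow(config$reagent_taxonomy)
  mat <- matrix(0L, nrow = nrow(truth$species) + n_reagent,
                ncol = nrow(samples),
                dimnames = list(c(truth$species$taxon_id,
                                  config$reagent_taxonomy$taxon_id),
                                samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    exp_i <- truth$expected[[samples$participant_id[i]]][,
                                                samples$compartment[i]]
    draw <- withr::with_seed(
      seeds[i],
      sample_library_counts(exp_i, depth[i], config$concentration,
                            config$contamination_rate, n_reagent))
    mat[, i] <- c(draw$community, draw$reagent)
  }
  metadata <- data.frame(sample_id = samples$sample_id,
                         participant_id = samples$participant_id,
                         compartment = samples$compartment,
                         library_type = "sample",
                         depth = depth,
                         stringsAsFactors = FALSE)
  list(counts = count_table(mat, rank = "species"), metadata = metadata)
}

## Expand one library's species counts to per-read hit records.
## In-window reads draw identity/length/alignment inside the QC windows
## (truncated normals); a round(off_window_fraction * n) subset is forced
## outside exactly one window each, so the post-QC survivor count is exact.
expand_library <- function(taxa, counts, sample_id, config) {
  n <- sum(counts)
  if (n == 0L) return(empty_hits())
  qc <- config$qc
  taxon_id <- rep(taxa, counts)
  ## shuffle so contaminant/community reads interleave like a real run
  ord <- sample.int(n)
  taxon_id <- taxon_id[ord]
  im <- config$identity_model; lm <- config$length_model
  am <- config$aln_model
  pct <- rtruncnorm(n, im["mean"], im["sd"], qc$id_min, qc$id_max)
  len <- round(rtruncnorm(n, lm["mean"], lm["sd"], qc$len_min, qc$len_max))
  aln <- round(rtruncnorm(n, am["mean"], am["sd"], qc$aln_min + 1, Inf))

  n_off <- round(config$off_window_fraction * n)
  if (n_off > 0) {
    off <- sample.int(n, n_off)
    mode <- sample(c("id_low", "id_high", "aln_low", "len_low", "len_high"),
                   n_off, replace = TRUE)
    pct[off][mode == "id_low"] <-
      stats::runif(sum(mode == "id_low"), max(1, qc$id_min - 25),
                   qc$id_min - 0.01)
    pct[off][mode == "id_high"] <-
      stats::runif(sum(mode == "id_high"), min(100, qc$id_max + 0.01), 100)
    aln[off][mode == "aln_low"] <-
      round(stats::runif(sum(mode == "aln_low"), qc$aln_min / 2, qc$aln_min))
    len[off][mode == "len_low"] <-
      round(stats::runif(sum(mode == "len_low"), qc$len_min / 2,
                         qc$len_min - 1))
    len[off][mode == "len_high"] <-
      round(stats::runif(sum(mode == "len_high"), qc$len_max + 1,
                         qc$len_max * 1.4))
  }
  bit <- pmax(0, round(1.8 * aln * pct / 100 + stats::rnorm(n, 0, 25), 1))
  data.frame(
    read_id = sprintf("%s_r%06d", sample_id, seq_len(n)),
    taxon_id = taxon_id,
    pct_identity = round(pct, 2),
    aln_length = as.integer(aln),
    bit_score = bit,
    read_length = as.integer(len),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

empty_hits <- function() {
  data.frame(read_id = character(), taxon_id = character(),
             pct_identity = numeric(), aln_length = integer(),
             bit_score = numeric(), read_length = integer(),
             sample_id = character(), stringsAsFactors = FALSE)
}

#' Simulate per-read hit records for a scenario
#'
#' Draws library counts with [sample_counts()] and expands them into one
#' BLAST-style top-hit record per read: percent identity, read length and
#' alignment length are truncated normals inside the QC windows, except for
#' `off_window_fraction` of reads per library which are forced outside
#' exactly one window (low/high identity, short alignment, or off-size read
#' length). Bit scores scale with alignment length and identity.
#'
#' @inheritParams sample_counts
#' @return list with `hits` (data.frame of HitRecords: `read_id`,
#'   `taxon_id`, `pct_identity`, `aln_length`, `bit_score`, `read_length`,
#'   `sample_id`), `counts`, `metadata` and `n_off_window` (per-sample count
#'   of planted off-window reads).
#' @export
sample_reads <- function(truth, config = truth$config, seed = config$seed) {
  seed <- check_seed(seed)
  seeds <- derive_seeds(seed, 2L)
  drawn <- sample_counts(truth, config, seed = seeds[1])
  mat <- drawn$counts$counts
  lib_seeds <- derive_seeds(seeds[2], ncol(mat))
  hits <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    hits[[j]] <- withr::with_seed(
      lib_seeds[j],
      expand_library(rownames(mat), mat[, j], colnames(mat)[j], config))
  }
  hits <- do.call(rbind, hits)
  rownames(hits) <- NULL
  n_off <- vapply(seq_len(ncol(mat)),
                  function(j) round(config$off_window_fraction * sum(mat[, j])),
                  numeric(1))
  names(n_off) <- colnames(mat)
  list(hits = hits, counts = drawn$counts, metadata = drawn$metadata,
       n_off_window = n_off)
}

#' Simulate a paired PCR-negative / PCR-positive kitome run
#'
#' The positive library is an ordinary sample drawn from the outer-pool
#' community of the first participant at the configured depth; the negative
#' library contains only reagent-taxon reads, with a Poisson total of
#' `neg_rate` times the positive depth. Both are generated in-window so they
#' survive QC, mirroring a contamination estimate on QC-passing reads.
#'
#' @param config a [scenario_config()].
#' @param neg_rate expected negative:positive read ratio, in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `negative` and `positive` HitRecord data.frames and a
#'   `metadata` data.frame (`library_type` `pcr_negative` / `pcr_positive`).
#' @export
kitome_pair <- function(config, neg_rate = 0.0003, seed = config$seed) {
  if (neg_rate < 0 || neg_rate >= 1) stopf("neg_rate must be in [0, 1)")
  seed <- check_seed(seed)
  validate_scenario_config(config)
  seeds <- derive_seeds(seed, 3L)
  truth <- build_scenario(config)
  depth <- rep_len(config$depth, 1L)

  pos_counts <- withr::with_seed(
    seeds[1],
    sample_library_counts(truth$expected[[1]][, "mouth"], depth,
                          config$concentration, config$contamination_rate,
                          nrow(config$reagent_taxonomy)))
  pos <- withr::with_seed(
    seeds[2],
    expand_library(c(truth$species$taxon_id, config$reagent_taxonomy$taxon_id),
                   c(pos_counts$community, pos_counts$reagent),
                   "kitome_pos", config))

  neg <- withr::with_seed(seeds[3], {
    n_neg <- stats::rpois(1, neg_rate * depth)
    reag <- if (n_neg > 0)
      drop(stats::rmultinom(1, n_neg,
                            rep(1 / nrow(config$reagent_taxonomy),
                                nrow(config$reagent_taxonomy))))
    else rep(0L, nrow(config$reagent_taxonomy))
    expand_library(config$reagent_taxonomy$taxon_id, reag, "kitome_neg",
                   config)
  })
  metadata <- data.frame(
    sample_id = c("kitome_neg", "kitome_pos"),
    participant_id = truth$participants$participant_id[1],
    compartment = "mouth",
    library_type = c("pcr_negative", "pcr_positive"),
    depth = c(nrow(neg), nrow(pos)),
    stringsAsFactors = FALSE
  )
  list(negative = neg, positive = pos, metadata = metadata)
}
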