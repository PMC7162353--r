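## End-to-end orchestration: synthetic or file-based input, QC, profiling,
## enrichment, diversity/ordination, kitome, manifest and report.

#' Run configuration
#'
#' @param mode `"synthetic"` (simulate from `scenario`) or `"files"` (read
#'   hit/lineage/metadata tables from `paths`).
#' @param scenario a [scenario_config()] (synthetic mode).
#' @param paths named list with `hits`, `lineage`, `metadata` (files mode);
#'   optionally `negative_hits`/`positive_hits` for a kitome pair.
#' @param qc a [qc_config()].
#' @param threshold enrichment read-difference threshold (> 0).
#' @param target_depth normalization target depth; `NULL` = per-participant
#'   median compartment depth.
#' @param epsilon gradient-ordering tolerance.
#' @param kitome_neg_rate expected negative:positive ratio for the
#'   simulated kitome pair (synthetic mode); `NULL` skips it.
#' @param ranks ranks to tabulate and export.
#' @param out_dir output directory for TSV/JSON artifacts; `NULL` keeps
#'   everything in memory.
#' @param seed master seed for all stochastic stages (synthetic mode
#'   defaults to the scenario's own seed).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       scenario = scenario_config(),
                       paths = list(),
                       qc = scenario$qc %||% qc_config(),
                       threshold = 150,
                       target_depth = NULL,
                       epsilon = 0,
                       kitome_neg_rate = 0.0003,
                       ranks = c("species", "genus", "phylum"),
                       out_dir = NULL,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (threshold <= 0) stopf("threshold must be > 0")
  if (mode == "files") {
    need <- c("hits", "lineage", "metadata")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stopf("files mode needs paths$%s", paste(miss, collapse = ", paths$"))
    for (p in unlist(paths[need]))
      if (!file.exists(p)) stopf("input path does not exist: %s", p)
  }
  seed <- check_seed(seed %||% (if (mode == "synthetic") scenario$seed else 1L))
  structure(list(mode = mode, scenario = scenario, paths = paths, qc = qc,
                 threshold = threshold, target_depth = target_depth,
                 epsilon = epsilon, kitome_neg_rate = kitome_neg_rate,
                 ranks = ranks, out_dir = out_dir, seed = seed),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage %s: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Sequences simulation/ingestion, hit QA/QC, multi-rank taxonomic
#' profiling, per-participant lung-enrichment calling with gradient
#' classification, Bray-Curtis/ordination summaries and (when available) the
#' kitome contamination estimate, then assembles a manifest of per-stage
#' record counts and headline summaries. Identical `(config, seed)` produce
#' identical manifests. When `config$out_dir` is set, all tables are written
#' as TSV/CSV plus a JSON manifest and QC summary.
#'
#' @param config a [run_config()].
#' @return object of class `run_result`: list with `manifest`
#'   (deterministic summary list) and `data` (in-memory stage outputs:
#'   tables, profiles, enrichment results, ordinations).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  kitome <- NULL

  ingest <- run_stage("ingest", {
    if (config$mode == "synthetic") {
      truth <- build_scenario(config$scenario)
      rr <- sample_reads(truth, config$scenario, seed = config$seed)
      lineage <- rbind(config$scenario$taxonomy,
                       config$scenario$reagent_taxonomy)
      if (!is.null(config$kitome_neg_rate)) {
        kp <- kitome_pair(config$scenario, config$kitome_neg_rate,
                          seed = config$seed + 1L)
        kitome <- kitome_contamination(
          nrow(filter_hits(filter_read_lengths(kp$negative, config$qc),
                           config$qc)),
          nrow(filter_hits(filter_read_lengths(kp$positive, config$qc),
                           config$qc)))
      }
      list(hits = rr$hits, lineage = lineage, metadata = rr$metadata,
           truth = truth)
    } else {
      md <- read_metadata(config$paths$metadata)
      kitome <- NULL
      if (!is.null(config$paths$negative_hits) &&
          !is.null(config$paths$positive_hits)) {
        neg <- read_hit_table(config$paths$negative_hits)
        pos <- read_hit_table(config$paths$positive_hits)
        kitome <- kitome_contamination(
          nrow(filter_hits(neg, config$qc)),
          nrow(filter_hits(pos, config$qc)))
      }
      list(hits = read_hit_table(config$paths$hits),
           lineage = read_lineage(config$paths$lineage),
           metadata = md, truth = NULL)
    }
  })
  hits <- ingest$hits

  qcres <- run_stage("hit_qc", {
    if (nrow(hits) == 0L) stopf("empty hit table")
    after_len <- if ("read_length" %in% names(hits))
      filter_read_lengths(hits, config$qc) else hits
    after_hits <- filter_hits(after_len, config$qc)
    tophits <- select_top_hit(after_hits)
    list(after_len = after_len, after_hits = after_hits, tophits = tophits,
         summary = qc_summary(hits, after_len, after_hits, tophits))
  })

  profile <- run_stage("taxonomy_profile", {
    tables <- lapply(stats::setNames(config$ranks, config$ranks), function(rk)
      aggregate_counts(qcres$tophits, ingest$lineage, rank = rk))
    species_tab <- tables[["species"]] %||%
      aggregate_counts(qcres$tophits, ingest$lineage, rank = "species")
    phylum_tab <- tables[["phylum"]] %||%
      aggregate_counts(qcres$tophits, ingest$lineage, rank = "phylum")
    dom <- dominant_phyla(phylum_tab, k = 5)
    list(tables = tables, species = species_tab, phylum = phylum_tab,
         dominant = dom,
         richness = species_richness(species_tab, ingest$lineage),
         rel = lapply(tables, relative_abundance))
  })

  enrich <- run_stage("enrichment", {
    md <- ingest$metadata[ingest$metadata$library_type == "sample", ,
                          drop = FALSE]
    pids <- unique(md$participant_id)
    profiles <- lapply(stats::setNames(pids, pids), function(pid)
      participant_profile(profile$species, md, pid))
    results <- list(); gradients <- list(); excluded <- character()
    for (pid in pids) {
      prof <- normalize_counts(profiles[[pid]], config$target_depth)
      if (!all(c("LAV", "mouth", "nose") %in% colnames(prof$counts))) {
        excluded <- c(excluded, pid)
      } else {
        results[[pid]] <- classify_enriched(compartment_differences(prof),
                                            config$threshold)
      }
      if (all(c("LAV", "throat") %in% colnames(prof$counts)) &&
          any(c("mouth", "nose") %in% colnames(prof$counts)))
        gradients[[pid]] <- gradient_classify(prof, config$epsilon)
    }
    enriched_union <- sort(unique(unlist(
      lapply(results, function(r) r$species[r$enriched]))))
    detected <- sum(rowSums(profile$species$counts) > 0)
    heat <- if (length(results) && length(enriched_union))
      heatmap_matrix(results) else NULL
    list(profiles = profiles, results = results, gradients = gradients,
         excluded = excluded, enriched_union = enriched_union,
         detected = detected,
         fraction = if (detected > 0)
           enriched_fraction(enriched_union, detected) else NA_real_,
         heatmap = heat)
  })

  divers <- run_stage("diversity_ordination", {
    bc <- tryCatch(
      compartment_dissimilarity_summary(enrich$profiles,
                                        pair = c("LAV", "throat")),
      error = function(e) NULL)
    nsamp <- ncol(profile$species$counts)
    list(
      bc_lav_throat = bc,
      pca = if (nsamp >= 3) ordinate(profile$species, "pca_logcounts"),
      pcoa = if (nsamp >= 3) ordinate(profile$species, "pcoa_braycurtis"),
      distances = bray_curtis_matrix(profile$species)
    )
  })

  manifest <- list(
    config_hash = fnv1a32(config[setdiff(names(config), "out_dir")]),
    mode = config$mode,
    seed = config$seed,
    reads_in = nrow(hits),
    reads_after_length_filter = nrow(qcres$after_len),
    reads_after_hit_filter = nrow(qcres$after_hits),
    reads_after_top_hit = nrow(qcres$tophits),
    n_samples = ncol(profile$species$counts),
    species_detected = enrich$detected,
    dominant_phyla = profile$dominant$phyla,
    dominant_coverage = profile$dominant$coverage,
    participants_excluded = enrich$excluded,
    enriched_per_participant = vapply(enrich$results,
                                      function(r) sum(r$enriched),
                                      numeric(1)),
    enriched_species_union = length(enrich$enriched_union),
    enriched_fraction_pct = enrich$fraction,
    threshold = config$threshold,
    bc_lav_throat_mean = divers$bc_lav_throat$mean %||% NA_real_,
    bc_lav_throat_sd = divers$bc_lav_throat$sd %||% NA_real_,
    pca_var_pct = if (!is.null(divers$pca))
      round(utils::head(divers$pca$variance_explained, 2), 4),
    kitome_percent = if (!is.null(kitome)) kitome$percent,
    kitome_counts = if (!is.null(kitome))
      c(negative = kitome$neg_count, positive = kitome$pos_count)
  )

  out <- structure(list(
    manifest = manifest,
    data = list(ingest = ingest, qc = qcres, profile = profile,
                enrichment = enrich, diversity = divers, kitome = kitome)
  ), class = "run_result")

  if (!is.null(config$out_dir)) write_run_outputs(out, config)
  out
}

write_run_outputs <- function(run, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  d <- run$data
  write_hit_table(d$qc$tophits, p("tophits_qc.tsv"))
  utils::write.table(d$qc$summary, p("qc_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_json_file(d$qc$summary, p("qc_summary.json"))
  for (rk in names(d$profile$tables)) {
    write_count_table(d$profile$tables[[rk]], p(sprintf("counts_%s.tsv", rk)))
    write_long_csv(d$profile$tables[[rk]], p(sprintf("counts_%s_long.csv", rk)))
  }
  if (length(d$enrichment$results)) {
    enr <- do.call(rbind, lapply(names(d$enrichment$results), function(pid) {
      r <- d$enrichment$results[[pid]]
      cbind(participant_id = pid, r,
            gradient_class = unname(
              d$enrichment$gradients[[pid]][r$species] %||%
                rep(NA_character_, nrow(r))))
    }))
    utils::write.table(enr, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(d$enrichment$heatmap))
    utils::write.table(
      data.frame(species = rownames(d$enrichment$heatmap),
                 d$enrichment$heatmap, check.names = FALSE),
      p("heatmap_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = rownames(d$diversity$distances),
               d$diversity$distances, check.names = FALSE),
    p("bray_curtis.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_file(run$manifest, p("manifest.json"))
  invisible(config$out_dir)
}

#' Human-readable run report
#'
#' Formats the run manifest as the study-style summary skeleton: reads in
#' and passing each QC step, species detected, dominant-phyla coverage,
#' per-participant and pooled lung-enriched species, the enriched fraction,
#' the lavage-throat Bray-Curtis summary, leading ordination axes, and the
#' kitome contamination percentage (two decimals).
#'
#' @param run a `run_result` (or its `manifest`).
#' @return the report lines, invisibly; printed to the console.
#' @export
summary_report <- function(run) {
  m <- if (inherits(run, "run_result")) run$manifest else run
  fmt_enr <- if (length(m$enriched_per_participant))
    paste(sprintf("%s=%d", names(m$enriched_per_participant),
                  as.integer(m$enriched_per_participant)), collapse = ", ")
  else "none computed"
  lines <- c(
    sprintf("respiromics run %s (mode %s, seed %d)", m$config_hash, m$mode,
            m$seed),
    sprintf("reads: %d in; %d after size selection; %d after hit QA/QC; %d top hits",
            m$reads_in, m$reads_after_length_filter,
            m$reads_after_hit_filter, m$reads_after_top_hit),
    sprintf("species detected: %d across %d samples", m$species_detected,
            m$n_samples),
    sprintf("dominant phyla (%s): %.1f%% of reads",
            paste(m$dominant_phyla, collapse = ", "),
            100 * m$dominant_coverage),
    sprintf("lung-enriched species (threshold %g reads): %s; union %d (%.1f%% of detected)",
            m$threshold, fmt_enr, m$enriched_species_union,
            m$enriched_fraction_pct),
    if (length(m$participants_excluded))
      sprintf("participants excluded from enrichment: %s",
              paste(m$participants_excluded, collapse = ", ")),
    if (!is.na(m$bc_lav_throat_mean))
      sprintf("Bray-Curtis LAV vs throat: %.2f +/- %.2f",
              m$bc_lav_throat_mean, m$bc_lav_throat_sd),
    if (!is.null(m$pca_var_pct))
      sprintf("PCA of log counts: PC1 %.0f%%, PC2 %.0f%%",
              m$pca_var_pct[1], m$pca_var_pct[2]),
    if (!is.null(m$kitome_percent))
      sprintf("kitome contamination: %.2f%% (%d negative vs %d positive reads)",
              m$kitome_percent, m$kitome_counts[["negative"]],
              m$kitome_counts[["positive"]])
  )
  lines <- lines[!vapply(lines, is.null, logical(1))]
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.run_result <- function(x, ...) {
  summary_report(x)
  invisible(x)
}
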