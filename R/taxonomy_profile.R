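## Multi-rank taxonomic count tables and community summaries.

RANKS <- c("species", "genus", "family", "phylum")

#' Taxa-by-sample count table
#'
#' Lightweight container for a taxa x samples matrix at one taxonomic rank.
#' Raw tables are integer read counts; normalized/proportional tables are
#' real-valued and flagged.
#'
#' @param counts numeric matrix, taxa in rows (rownames = taxon labels at
#'   `rank`), samples in columns.
#' @param rank one of `"species"`, `"genus"`, `"family"`, `"phylum"`.
#' @param normalized logical; `TRUE` for scaled/proportional values.
#' @return object of class `count_table`: list with `counts`, `rank`,
#'   `normalized`.
#' @export
count_table <- function(counts, rank, normalized = FALSE) {
  rank <- match.arg(rank, RANKS)
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stopf("count matrix needs taxon rownames and sample colnames")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (!normalized && any(counts != round(counts)))
    stopf("raw count tables must be integer-valued")
  structure(list(counts = counts, rank = rank, normalized = normalized),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s%s]: %d taxa x %d samples, %s reads\n",
              x$rank, if (x$normalized) ", normalized" else "",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

lineage_map <- function(lineage, rank) {
  rank <- match.arg(rank, RANKS)
  stats::setNames(lineage[[rank]], lineage$taxon_id)
}

#' Aggregate per-read assignments into a count table
#'
#' Counts assigned reads per taxon at the requested rank for each sample.
#' Reads whose `taxon_id` has no lineage entry are bucketed under
#' `"unclassified"` (with a warning) so that the grand total always equals
#' the number of assignments; `strict = TRUE` errors instead.
#'
#' @param hits data.frame of per-read assignments (`taxon_id`, `sample_id`).
#' @param lineage lineage table (`taxon_id`, `species`, `genus`, `family`,
#'   `phylum`).
#' @param rank target rank.
#' @param strict error on unknown taxon ids.
#' @return a raw [count_table()] at `rank`.
#' @export
aggregate_counts <- function(hits, lineage, rank = "species",
                             strict = FALSE) {
  check_hits(hits, c("taxon_id", "sample_id"))
  rank <- match.arg(rank, RANKS)
  map <- lineage_map(lineage, rank)
  label <- unname(map[hits$taxon_id])
  unknown <- is.na(label)
  if (any(unknown)) {
    if (strict)
      stopf("%d read(s) carry taxon ids missing from the lineage table",
            sum(unknown))
    warning(sprintf("%d read(s) with unknown taxon id bucketed as unclassified",
                    sum(unknown)), call. = FALSE)
    label[unknown] <- "unclassified"
  }
  if (nrow(hits) == 0L) {
    mat <- matrix(integer(0), nrow = 0, ncol = 0,
                  dimnames = list(character(0), character(0)))
    return(count_table(mat, rank = rank))
  }
  tab <- table(factor(label), factor(hits$sample_id,
                                     levels = unique(hits$sample_id)))
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  count_table(mat, rank = rank)
}

#' Roll a species table up to a coarser rank
#'
#' Sums species rows sharing the same genus/family/phylum. The
#' `"unclassified"` bucket, if present, is carried through unchanged, so
#' totals are conserved across ranks.
#'
#' @param table a species-rank [count_table()].
#' @param lineage lineage table mapping species names to coarser ranks.
#' @param rank target rank (coarser than species).
#' @return a [count_table()] at `rank`.
#' @export
rollup_table <- function(table, lineage, rank) {
  rank <- match.arg(rank, RANKS[-1])
  if (table$rank != "species") stopf("rollup_table expects a species table")
  map <- stats::setNames(lineage[[rank]], lineage$species)
  group <- unname(map[rownames(table$counts)])
  group[is.na(group)] <- "unclassified"
  mat <- rowsum(table$counts, group)
  count_table(mat[order(rownames(mat)), , drop = FALSE], rank = rank,
              normalized = table$normalized)
}

#' Per-sample relative abundances
#'
#' Scales every sample column to proportions. Samples with a zero total are
#' excluded with a warning (a proportion is undefined for them); remaining
#' columns sum to 1 to within 1e-9. Idempotent on proportion tables.
#'
#' @param table a [count_table()].
#' @return a normalized [count_table()] of proportions.
#' @export
relative_abundance <- function(table) {
  totals <- colSums(table$counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("excluding %d zero-total sample(s): %s", sum(zero),
                    paste(colnames(table$counts)[zero], collapse = ", ")),
            call. = FALSE)
  }
  mat <- sweep(table$counts[, !zero, drop = FALSE], 2, totals[!zero], "/")
  count_table(mat, rank = table$rank, normalized = TRUE)
}

#' Dominant phyla and their pooled coverage
#'
#' The k phyla with the largest read counts pooled over all samples (ties
#' broken lexicographically) together with the fraction of all reads they
#' account for. In healthy respiratory communities five phyla (Firmicutes,
#' Proteobacteria, Actinobacteria, Bacteroidetes, Fusobacteria) typically
#' cover > 98% of QC-passing reads.
#'
#' @param table a phylum-rank [count_table()] (raw counts).
#' @param k number of phyla to report.
#' @return list with `phyla` (character, ranked) and `coverage` (pooled
#'   proportion of all reads).
#' @export
dominant_phyla <- function(table, k = 5) {
  if (table$rank != "phylum") stopf("dominant_phyla expects a phylum table")
  pooled <- rowSums(table$counts)
  if (length(pooled) <= k)
    return(list(phyla = names(sort(pooled, decreasing = TRUE)),
                coverage = 1))
  ord <- order_desc_then_name(pooled, names(pooled))
  top <- names(pooled)[ord][seq_len(k)]
  list(phyla = top, coverage = sum(pooled[top]) / sum(pooled))
}

#' Distinct detected species per genus and phylum
#'
#' A species counts as detected when its pooled read count across samples is
#' positive. Species absent from the lineage table (e.g. the
#' `"unclassified"` bucket) are grouped under `"unclassified"`.
#'
#' @param table a species-rank [count_table()].
#' @param lineage lineage table.
#' @return list of named integer vectors `genus` and `phylum`.
#' @export
species_richness <- function(table, lineage) {
  if (table$rank != "species") stopf("species_richness expects a species table")
  detected <- rownames(table$counts)[rowSums(table$counts) > 0]
  out <- lapply(c(genus = "genus", phylum = "phylum"), function(rk) {
    map <- stats::setNames(lineage[[rk]], lineage$species)
    grp <- unname(map[detected])
    grp[is.na(grp)] <- "unclassified"
    tab <- table(grp)
    stats::setNames(as.integer(tab), names(tab))
  })
  out
}

#' Top genera within a phylum
#'
#' Genera of one phylum ranked by pooled read count (descending, ties
#' lexicographic), truncated to `n`, with the remainder pooled as
#' `"other"`. Relative abundances are fractions of the phylum's reads.
#'
#' @param table a genus-rank [count_table()].
#' @param lineage lineage table (maps genus to phylum).
#' @param phylum phylum name.
#' @param n number of genera to report.
#' @return data.frame with `genus`, `count`, `rel_abundance`; zero rows
#'   (with a warning) for an unknown phylum.
#' @export
top_genera <- function(table, lineage, phylum, n = 15) {
  if (table$rank != "genus") stopf("top_genera expects a genus table")
  map <- unique(lineage[, c("genus", "phylum")])
  members <- map$genus[map$phylum == phylum]
  pooled <- rowSums(table$counts)
  pooled <- pooled[names(pooled) %in% members]
  if (length(pooled) == 0L) {
    warning(sprintf("no genera found for phylum '%s'", phylum),
            call. = FALSE)
    return(data.frame(genus = character(), count = numeric(),
                      rel_abundance = numeric(), stringsAsFactors = FALSE))
  }
  ord <- order_desc_then_name(pooled, names(pooled))
  pooled <- pooled[ord]
  head_n <- utils::head(pooled, n)
  rest <- sum(pooled) - sum(head_n)
  out <- data.frame(genus = names(head_n), count = unname(head_n),
                    stringsAsFactors = FALSE)
  if (length(pooled) > n)
    out <- rbind(out, data.frame(genus = "other", count = rest,
                                 stringsAsFactors = FALSE))
  out$rel_abundance <- out$count / sum(pooled)
  rownames(out) <- NULL
  out
}
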