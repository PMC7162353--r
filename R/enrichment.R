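## Lung-enrichment calling: per-participant normalization of compartment
## counts, paired lavage-minus-mouth / lavage-minus-nose differencing, a
## conservative read-difference threshold, and gradient classification along
## the respiratory tract with the throat as the intermediate compartment.

#' Per-participant compartment profile
#'
#' Extracts one participant's sample columns from a species count table and
#' relabels them by compartment (`LAV`, `throat`, `mouth`, `nose`; any
#' subset may be present).
#'
#' @param table a species-rank [count_table()].
#' @param metadata sample metadata (`sample_id`, `participant_id`,
#'   `compartment`, `library_type`); only `library_type == "sample"` rows
#'   are used.
#' @param participant_id which participant.
#' @return object of class `participant_profile`: list with
#'   `participant_id`, `counts` (species x compartments), `normalized`,
#'   `target_depth`.
#' @export
participant_profile <- function(table, metadata, participant_id) {
  md <- metadata[metadata$participant_id == participant_id &
                   metadata$library_type == "sample", , drop = FALSE]
  md <- md[md$sample_id %in% colnames(table$counts), , drop = FALSE]
  if (nrow(md) == 0L)
    stopf("no samples found for participant '%s'", participant_id)
  if (anyDuplicated(md$compartment))
    stopf("participant '%s' has several samples in one compartment",
          participant_id)
  mat <- table$counts[, md$sample_id, drop = FALSE]
  colnames(mat) <- md$compartment
  mat <- mat[, intersect(COMPARTMENTS, colnames(mat)), drop = FALSE]
  structure(list(participant_id = participant_id, counts = mat,
                 normalized = table$normalized, target_depth = NA_real_),
            class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf("participant_profile %s: %d species x {%s}%s\n",
              x$participant_id, nrow(x$counts),
              paste(colnames(x$counts), collapse = ", "),
              if (x$normalized)
                sprintf(", normalized to %.0f reads", x$target_depth)
              else ""))
  invisible(x)
}

#' Normalize compartment counts to a common depth
#'
#' Total-sum scales each compartment column so all totals equal
#' `target_depth`. The default target is the participant's median raw
#' compartment depth, which keeps values on a read-count-like scale so a
#' read-difference threshold (150 reads) retains its meaning. Values stay
#' real; nothing is rounded. Empty (zero-total) compartments are dropped
#' with a warning.
#'
#' @param profile a [participant_profile()] of raw counts.
#' @param target_depth common total; `NULL` uses the median compartment
#'   depth.
#' @return the normalized profile (`normalized = TRUE`).
#' @export
normalize_counts <- function(profile, target_depth = NULL) {
  totals <- colSums(profile$counts)
  empty <- totals == 0
  if (any(empty)) {
    warning(sprintf("participant %s: dropping empty compartment(s) %s",
                    profile$participant_id,
                    paste(names(totals)[empty], collapse = ", ")),
            call. = FALSE)
    profile$counts <- profile$counts[, !empty, drop = FALSE]
    totals <- totals[!empty]
  }
  if (ncol(profile$counts) == 0L)
    stopf("participant %s has no non-empty compartments",
          profile$participant_id)
  target <- target_depth %||% stats::median(totals)
  if (target <= 0) stopf("target_depth must be > 0")
  profile$counts <- sweep(profile$counts, 2, target / totals, "*")
  profile$normalized <- TRUE
  profile$target_depth <- target
  profile
}

#' Lavage-minus-outer read-count differences
#'
#' For each species, subtracts the normalized mouth and nose counts from the
#' normalized lavage count: `d_mouth = LAV - mouth`, `d_nose = LAV - nose`.
#' Participants lacking any of LAV/mouth/nose cannot be characterized for
#' lung enrichment and raise an error (callers exclude them and keep the
#' participant in community-level summaries).
#'
#' @param profile a normalized [participant_profile()] containing LAV,
#'   mouth and nose.
#' @return data.frame with `species`, `d_mouth`, `d_nose` and the
#'   participant id as attribute `participant_id`.
#' @export
compartment_differences <- function(profile) {
  if (!profile$normalized)
    stopf("compartment_differences expects a normalized profile")
  need <- c("LAV", "mouth", "nose")
  miss <- setdiff(need, colnames(profile$counts))
  if (length(miss))
    stopf("participant %s lacks compartment(s) %s; excluded from enrichment",
          profile$participant_id, paste(miss, collapse = ", "))
  out <- data.frame(
    species = rownames(profile$counts),
    d_mouth = profile$counts[, "LAV"] - profile$counts[, "mouth"],
    d_nose = profile$counts[, "LAV"] - profile$counts[, "nose"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "participant_id") <- profile$participant_id
  out
}

#' Call lung-enriched species by read-difference threshold
#'
#' A species is lung-enriched when both its lavage-minus-mouth and
#' lavage-minus-nose normalized read differences strictly exceed the
#' threshold (default 150 reads — conservative relative to the < 50-read
#' replicate variation of the platform). The conjunction over both outer
#' compartments is the conservative reading of paired differencing.
#'
#' @param diffs a [compartment_differences()] data.frame.
#' @param threshold read-difference threshold (> 0).
#' @return the input data.frame with added `margin`
#'   (`min(d_mouth, d_nose) - threshold`) and logical `enriched`;
#'   attribute `threshold` records the cutoff.
#' @export
classify_enriched <- function(diffs, threshold = 150) {
  if (threshold <= 0) stopf("threshold must be > 0")
  if (any(!is.finite(diffs$d_mouth)) || any(!is.finite(diffs$d_nose)))
    stopf("differences must be finite")
  out <- diffs
  out$margin <- pmin(out$d_mouth, out$d_nose) - threshold
  out$enriched <- out$d_mouth > threshold & out$d_nose > threshold
  attr(out, "threshold") <- threshold
  attr(out, "participant_id") <- attr(diffs, "participant_id")
  out
}

#' Classify a species' abundance gradient along the tract
#'
#' Uses the throat as the intermediate compartment between the lavage and
#' the outer pool (mean of the present mouth/nose columns):
#' `inside_out` when LAV > throat + eps and throat > outer + eps (abundance
#' rising toward the lung, the colonization pattern); `outside_in` when the
#' ordering is reversed (passive transport and clearance); `flat` when all
#' pairwise differences are within eps; anything else is `discordant`.
#'
#' @param profile a normalized [participant_profile()] with LAV, throat and
#'   at least one of mouth/nose.
#' @param epsilon ordering tolerance on the normalized read-count scale
#'   (default 0: strict ordering).
#' @return character vector of classes named by species; all `NA` (with a
#'   warning) when the throat sample is missing.
#' @export
gradient_classify <- function(profile, epsilon = 0) {
  if (!profile$normalized)
    stopf("gradient_classify expects a normalized profile")
  cn <- colnames(profile$counts)
  species <- rownames(profile$counts)
  if (!all(c("LAV", "throat") %in% cn) ||
      !any(c("mouth", "nose") %in% cn)) {
    warning(sprintf(
      "participant %s: throat/LAV/outer compartment missing; gradient undetermined",
      profile$participant_id), call. = FALSE)
    return(stats::setNames(rep(NA_character_, length(species)), species))
  }
  lav <- profile$counts[, "LAV"]
  throat <- profile$counts[, "throat"]
  outer <- rowMeans(profile$counts[, intersect(c("mouth", "nose"), cn),
                                   drop = FALSE])
  cls <- rep("discordant", length(species))
  cls[lav > throat + epsilon & throat > outer + epsilon] <- "inside_out"
  cls[outer > throat + epsilon & throat > lav + epsilon] <- "outside_in"
  flat <- abs(lav - throat) <= epsilon & abs(throat - outer) <= epsilon &
    abs(lav - outer) <= epsilon
  cls[flat] <- "flat"
  stats::setNames(cls, species)
}

#' Fraction of detected species that are lung-enriched
#'
#' @param enriched character vector of enriched species (or their count).
#' @param detected number of detected species (> 0).
#' @return percent, `100 * |enriched| / detected`.
#' @export
enriched_fraction <- function(enriched, detected) {
  n <- if (is.numeric(enriched) && length(enriched) == 1L) enriched
       else length(enriched)
  if (detected <= 0) stopf("detected species count must be > 0")
  100 * n / detected
}

#' Heat-map matrix of lung-enriched species
#'
#' Assembles the species x (participant x difference-type) matrix behind the
#' enrichment heat map: rows are species whose differences exceed the
#' threshold in at least one participant; columns are each participant's
#' `d_mouth` and `d_nose`; values are normalized read differences (`NA`
#' where a participant lacks the species entry). Rows are ordered by
#' descending maximum difference, then name.
#'
#' @param results list of [classify_enriched()] data.frames, named by
#'   participant id (or carrying a `participant_id` attribute).
#' @return numeric matrix; zero rows (with a warning) when no species pass.
#' @export
heatmap_matrix <- function(results) {
  if (length(results) == 0L) stopf("need at least one participant result")
  ids <- names(results)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(results, function(r) attr(r, "participant_id") %||% "",
                  character(1))
  if (any(!nzchar(ids))) stopf("participant ids missing on results")
  names(results) <- ids
  keep <- sort(unique(unlist(
    lapply(results, function(r) r$species[r$enriched]))))
  cols <- as.vector(t(outer(ids, c("d_mouth", "d_nose"), paste, sep = ".")))
  if (length(keep) == 0L) {
    warning("no species exceed the enrichment threshold in any participant",
            call. = FALSE)
    return(matrix(numeric(0), nrow = 0, ncol = length(cols),
                  dimnames = list(character(0), cols)))
  }
  mat <- matrix(NA_real_, nrow = length(keep), ncol = length(cols),
                dimnames = list(keep, cols))
  for (pid in ids) {
    r <- results[[pid]]
    idx <- match(keep, r$species)
    mat[, paste0(pid, ".d_mouth")] <- r$d_mouth[idx]
    mat[, paste0(pid, ".d_nose")] <- r$d_nose[idx]
  }
  rowmax <- apply(mat, 1, max, na.rm = TRUE)
  mat[order_desc_then_name(rowmax, rownames(mat)), , drop = FALSE]
}
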