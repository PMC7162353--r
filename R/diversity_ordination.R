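## Bray-Curtis dissimilarity, log-count transformation and ordination
## (PCA of log counts; PCoA / classical MDS of Bray-Curtis distances).

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`: 0 for identical vectors, 1 for disjoint
#' supports. Note the index is scale-dependent on raw counts; compute it on
#' per-sample proportions (the package default elsewhere) for a
#' composition-only comparison.
#'
#' @param x,y non-negative numeric vectors on a shared taxa index.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must share one taxa index")
  if (!is_count_vector(x) || !is_count_vector(y))
    stopf("x and y must be finite and non-negative")
  s <- sum(x + y)
  if (s == 0) stopf("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(x - y)) / s
}

#' Bray-Curtis distance matrix over samples
#'
#' Pairwise Bray-Curtis dissimilarities between the sample columns of a
#' count table, computed with [vegan::vegdist()]. By default each sample is
#' first converted to proportions so the index reflects composition only.
#'
#' @param table a [count_table()].
#' @param proportions convert columns to proportions first (default).
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames and attribute `metric = "bray_curtis"`.
#' @export
bray_curtis_matrix <- function(table, proportions = TRUE) {
  tab <- if (proportions) relative_abundance(table) else table
  d <- vegan::vegdist(t(tab$counts), method = "bray")
  m <- as.matrix(d)
  attr(m, "metric") <- "bray_curtis"
  m
}

#' Log-transform a count table
#'
#' Element-wise `log(count + pseudocount)`; with the default pseudocount of
#' 1, zero counts map to 0 and the transform is monotone in the counts.
#'
#' @param table a [count_table()].
#' @param pseudocount non-negative offset added before the log.
#' @return a normalized-flagged [count_table()] of log counts.
#' @export
log_counts <- function(table, pseudocount = 1) {
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  if (pseudocount == 0 && any(table$counts == 0))
    stopf("pseudocount 0 with zero counts gives -Inf")
  count_table(log(table$counts + pseudocount), rank = table$rank,
              normalized = TRUE)
}

#' Ordinate samples by PCA of log counts or PCoA of Bray-Curtis distances
#'
#' `pca_logcounts` is principal component analysis (covariance
#' eigendecomposition) of the log-transformed counts with samples as
#' observations. `pcoa_braycurtis` is classical multidimensional scaling
#' ([stats::cmdscale()]) of the Bray-Curtis distance matrix (computed on
#' proportions when a count table is supplied). Axes are ordered by
#' explained variance; axes explaining (numerically) zero variance are
#' dropped; each axis' sign is fixed so its largest-magnitude loading
#' (PCA) or score (PCoA) is positive.
#'
#' @param x a [count_table()], or for `pcoa_braycurtis` optionally a
#'   precomputed square dissimilarity matrix.
#' @param method `"pca_logcounts"` or `"pcoa_braycurtis"`.
#' @param pseudocount passed to [log_counts()] for the PCA pathway.
#' @return object of class `ordination_result`: list with `scores` (samples
#'   x axes), `variance_explained` (percent per axis, non-increasing),
#'   `method`, and `loadings` (PCA only).
#' @export
ordinate <- function(x, method = c("pca_logcounts", "pcoa_braycurtis"),
                     pseudocount = 1) {
  method <- match.arg(method)
  if (method == "pca_logcounts") {
    if (!inherits(x, "count_table"))
      stopf("pca_logcounts needs a count_table")
    if (ncol(x$counts) < 3) stopf("ordination needs at least 3 samples")
    lm <- t(log_counts(x, pseudocount)$counts)   # samples x taxa
    pc <- stats::prcomp(lm, center = TRUE, scale. = FALSE)
    var <- pc$sdev^2
    keep <- var > max(var) * 1e-12
    scores <- pc$x[, keep, drop = FALSE]
    load <- pc$rotation[, keep, drop = FALSE]
    for (j in seq_len(ncol(scores))) {
      if (load[which.max(abs(load[, j])), j] < 0) {
        load[, j] <- -load[, j]
        scores[, j] <- -scores[, j]
      }
    }
    res <- list(scores = scores,
                variance_explained = 100 * var[keep] / sum(var),
                method = method, loadings = load)
  } else {
    m <- if (inherits(x, "count_table")) bray_curtis_matrix(x) else as.matrix(x)
    if (nrow(m) < 3) stopf("ordination needs at least 3 samples")
    if (max(abs(m - t(m))) > 1e-12 || any(diag(m) != 0))
      stopf("dissimilarity matrix must be symmetric with zero diagonal")
    k <- nrow(m) - 1L
    mds <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k,
                                            eig = TRUE))
    eig <- mds$eig
    pos <- which(eig > max(eig, 0) * 1e-12)
    scores <- if (length(pos) == 0L)
      matrix(numeric(0), nrow = nrow(m), ncol = 0,
             dimnames = list(rownames(m), NULL))
    else mds$points[, seq_along(pos), drop = FALSE]
    if (ncol(scores) > 0)
      colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
    for (j in seq_len(ncol(scores))) {
      if (scores[which.max(abs(scores[, j])), j] < 0)
        scores[, j] <- -scores[, j]
    }
    res <- list(scores = scores,
                variance_explained = 100 * eig[pos] / sum(eig[pos]),
                method = method, loadings = NULL)
  }
  structure(res, class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("ordination_result [%s]: %d samples, %d axes (%s)\n",
              x$method, nrow(x$scores), ncol(x$scores),
              paste(sprintf("%s %.0f%%", colnames(x$scores)[seq_len(min(2, length(ve)))],
                            ve[seq_len(min(2, length(ve)))]), collapse = "; ")))
  invisible(x)
}

#' Mean Bray-Curtis dissimilarity between two compartments
#'
#' For every participant carrying both compartments, computes the
#' Bray-Curtis dissimilarity between the pair (on proportions), then
#' reports the across-participant mean and sample (n-1) standard deviation.
#' The lavage-vs-throat pair summarizes how similar the lung community is
#' to its nearest upstream compartment.
#'
#' @param profiles list of [participant_profile()]s (raw or normalized).
#' @param pair two compartment names, default `c("LAV", "throat")`.
#' @return list with `mean`, `sd` (`NA` and flagged when < 2 participants),
#'   `n`, and `per_participant` (named dissimilarities).
#' @export
compartment_dissimilarity_summary <- function(profiles,
                                              pair = c("LAV", "throat")) {
  if (length(pair) != 2L) stopf("pair must name two compartments")
  vals <- c()
  for (pr in profiles) {
    if (!all(pair %in% colnames(pr$counts))) next
    a <- pr$counts[, pair[1]]
    b <- pr$counts[, pair[2]]
    if (sum(a) == 0 || sum(b) == 0) next
    vals[pr$participant_id] <- bray_curtis(a / sum(a), b / sum(b))
  }
  if (length(vals) == 0L)
    stopf("no participant carries both compartments %s",
          paste(pair, collapse = " and "))
  list(mean = mean(vals),
       sd = if (length(vals) >= 2) stats::sd(vals) else NA_real_,
       n = length(vals), per_participant = vals)
}
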