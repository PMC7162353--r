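## Plain-text interchange: hit tables and lineages as TSV, count tables as
## TSV/long CSV, configs and QC summaries as JSON, optional FASTQ export.

HIT_COLUMNS <- c("read_id", "taxon_id", "pct_identity", "aln_length",
                 "bit_score", "read_length", "sample_id")

#' Write / read a hit table as TSV
#'
#' Columns `read_id`, `taxon_id`, `pct_identity`, `aln_length`,
#' `bit_score`, optional `read_length`, `sample_id` — the outfmt-6 core
#' columns plus a sample id, with a header row.
#'
#' @param hits data.frame of hit records.
#' @param path file path.
#' @return `write_hit_table` returns `path` invisibly; `read_hit_table`
#'   returns the data.frame.
#' @export
write_hit_table <- function(hits, path) {
  cols <- intersect(HIT_COLUMNS, names(hits))
  utils::write.table(hits[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  hits <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c(read_id = "character",
                                           taxon_id = "character",
                                           sample_id = "character"))
  check_hits(hits, c("read_id", "taxon_id", "pct_identity", "aln_length",
                     "bit_score", "sample_id"))
  hits
}

#' Read a headerless BLAST outfmt-6 tabular file
#'
#' Standard 12-column outfmt 6 (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`); the mapping of
#' outfmt-6 names onto hit-record fields is configurable for exports with
#' reordered or truncated columns.
#'
#' @param path file path.
#' @param sample_id sample id attached to every record.
#' @param col_names names of the file's columns, in order.
#' @param mapping named character vector: hit-record field ->
#'   outfmt-6 column name.
#' @return hit-record data.frame.
#' @export
read_blast6 <- function(path, sample_id,
                        col_names = c("qseqid", "sseqid", "pident", "length",
                                      "mismatch", "gapopen", "qstart", "qend",
                                      "sstart", "send", "evalue", "bitscore"),
                        mapping = c(read_id = "qseqid", taxon_id = "sseqid",
                                    pct_identity = "pident",
                                    aln_length = "length",
                                    bit_score = "bitscore")) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) != length(col_names))
    stopf("expected %d columns, found %d", length(col_names), ncol(raw))
  names(raw) <- col_names
  miss <- setdiff(mapping, col_names)
  if (length(miss))
    stopf("mapping refers to absent column(s): %s",
          paste(miss, collapse = ", "))
  out <- stats::setNames(raw[, mapping, drop = FALSE], names(mapping))
  out$read_id <- as.character(out$read_id)
  out$taxon_id <- as.character(out$taxon_id)
  out$sample_id <- sample_id
  out
}

#' Write / read a lineage table as TSV
#'
#' @param lineage lineage data.frame (`taxon_id`, `species`, `genus`,
#'   `family`, `phylum`).
#' @param path file path.
#' @export
write_lineage <- function(lineage, path) {
  utils::write.table(lineage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lineage
#' @export
read_lineage <- function(path) {
  lin <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_taxonomy(lin)
  lin
}

#' Write / read sample metadata as TSV
#'
#' @param metadata data.frame (`sample_id`, `participant_id`,
#'   `compartment`, `library_type`).
#' @param path file path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "participant_id", "compartment", "library_type")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stopf("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  md
}

#' Write / read a count table as TSV (taxa rows x sample columns)
#'
#' @param table a [count_table()].
#' @param path file path.
#' @param rank,normalized rank and normalization flag to attach on read.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(taxon = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path, rank, normalized = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$taxon
  count_table(mat, rank = rank, normalized = normalized)
}

#' Export a count table in long format (taxon, sample, count)
#'
#' The spreadsheet-pivot-friendly layout: one row per taxon x sample cell.
#'
#' @param table a [count_table()].
#' @param path CSV path.
#' @export
write_long_csv <- function(table, path) {
  long <- data.frame(
    taxon = rep(rownames(table$counts), times = ncol(table$counts)),
    sample = rep(colnames(table$counts), each = nrow(table$counts)),
    count = as.vector(table$counts),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write hit records as a FASTQ of placeholder sequences
#'
#' Emits a standard 4-line FASTQ per record whose sequence length equals
#' the record's `read_length` (placeholder `A` bases, constant quality):
#' enough to exercise any length-based consumer without simulating
#' nucleotide content.
#'
#' @param hits hit records with `read_id` and `read_length`.
#' @param path FASTQ path.
#' @export
write_fastq <- function(hits, path) {
  check_hits(hits, c("read_id", "read_length"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(hits))) {
    n <- hits$read_length[i]
    writeLines(c(paste0("@", hits$read_id[i]),
                 strrep("A", n), "+", strrep("I", n)), con)
  }
  invisible(path)
}

#' Serialize an object to JSON on disk
#'
#' @param x list-like object.
#' @param path JSON path.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
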