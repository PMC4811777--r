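#' Read an expression matrix from TSV
#'
#' First column is the gene identifier, header row holds sample identifiers.
#'
#' @param path TSV file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  as_expr_matrix(m)
}

#' Write an expression matrix (or any gene-keyed matrix) to TSV
#'
#' @param x matrix with gene rownames.
#' @param path output path.
#' @param id_col name of the identifier column (default `"gene"`).
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene") {
  d <- data.frame(rownames(x), x, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1L] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation TSV (sample_id, condition, replicate_group)
#' @param path TSV file path.
#' @return data frame.
#' @export
read_annotation_tsv <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Read a centroid TSV (gene, one column per subtype)
#' @param path TSV file path.
#' @return numeric matrix, signature genes x subtypes.
#' @export
read_centroids_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  check_centroids(m)
}

#' Read a gene-symbol map TSV (source, target)
#' @param path TSV file path.
#' @return data frame.
#' @export
read_gene_map_tsv <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Read a SNP-marker track TSV
#'
#' Expected columns: `marker_id`, `chrom`, `pos`, `lrr`, and optionally
#' `baf`, `gc`, `is_allelic`.
#'
#' @param path TSV file path.
#' @param drop_non_allelic drop markers with `is_allelic == FALSE`
#'   (default `TRUE`), mirroring the removal of probes that do not measure
#'   allelic balance.
#' @return marker track data frame sorted by (chrom, pos).
#' @export
read_marker_tsv <- function(path, drop_non_allelic = TRUE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (drop_non_allelic && "is_allelic" %in% names(d))
    d <- d[as.logical(d$is_allelic), , drop = FALSE]
  d <- d[order(match(d$chrom, unique(d$chrom)), d$pos), , drop = FALSE]
  rownames(d) <- NULL
  check_markers(d, need_gc = FALSE)
}

#' Write a data frame to TSV
#' @param d data frame.
#' @param path output path.
#' @export
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called segments as BED
#'
#' BED uses 0-based half-open coordinates; internal segment coordinates are
#' 1-based inclusive, so `start` is shifted down by one. The name field
#' carries the copy-number state.
#'
#' @param segments called segment data frame.
#' @param path output path.
#' @export
write_bed <- function(segments, path) {
  if (nrow(segments) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = segments$chrom,
                    start = format(segments$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(segments$end, scientific = FALSE, trim = TRUE),
                    name = paste0("state", segments$state),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cohort TSV (sample_id, zscore, mutation_status, subtype, platform)
#' @param path TSV file path.
#' @return data frame.
#' @export
read_cohort_tsv <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)
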