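# Shared fixture builders; everything generated in code, nothing on disk.

# small collapsed expression matrix with explicit values
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, ncol = length(values) / ifelse(is.null(genes), 3,
                                                     length(genes)))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

toy_annotation <- function(sample_ids, conditions, groups = sample_ids) {
  data.frame(sample_id = sample_ids, condition = conditions,
             replicate_group = groups, stringsAsFactors = FALSE)
}

# marker track with explicit lrr/gc vectors on one chromosome
toy_track <- function(lrr, gc = rep(0.5, length(lrr)), chrom = "chr1",
                      spacing = 50000) {
  data.frame(marker_id = sprintf("m%04d", seq_along(lrr)),
             chrom = chrom, pos = seq_along(lrr) * spacing,
             lrr = lrr, baf = 0.5, gc = gc, is_allelic = TRUE,
             stringsAsFactors = FALSE)
}

# expected reported marker positions for a truth segment at a given spacing
expected_seg_bounds <- function(truth, spacing) {
  list(start = ceiling(truth$start / spacing) * spacing,
       end = floor(truth$end / spacing) * spacing)
}
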