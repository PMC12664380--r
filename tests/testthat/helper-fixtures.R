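# Small in-code fixtures shared across test files.

# A minimal annotation built directly from a gene table.
make_annotation <- function(chrom, start, end,
                            gene_id = sprintf("g%03d", seq_along(start)),
                            strand = rep("+", length(start))) {
  annotation_set(data.frame(
    gene_id = gene_id,
    transcript_id = paste0(gene_id, ".t1"),
    chrom = chrom, start = start, end = end, strand = strand,
    exon_count = 1L, cds_length = 0L, transcript_length = end - start,
    stringsAsFactors = FALSE))
}

# Random genes and peaks on a toy genome for interval oracles.
random_intervals <- function(n, chrom_pool = c("chr1", "chr2"),
                             max_pos = 200000L, min_w = 50L, max_w = 5000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  data.frame(chrom = sample(chrom_pool, n, replace = TRUE),
             start = start, end = start + w, stringsAsFactors = FALSE)
}

# 0-based half-open overlap test used by the quadratic interval oracles.
overlaps0 <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 < e2 & s2 < e1
}

# Category counts with a planted composition, for tabulation tests.
counts_from_categories <- function(categories) {
  tab <- table(factor(categories, levels = all_signal_categories()))
  stats::setNames(as.integer(tab), all_signal_categories())
}
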