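# Internal helpers shared across modules.

# All interval arithmetic in this package is done on 0-based half-open
# coordinates (BED convention). GRanges is 1-based closed, so conversion
# happens exactly here and nowhere else.
.as_granges <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    ...
  )
}

.granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_cell_types <- function(have, need) {
  missing <- setdiff(need, have)
  if (length(missing) > 0L)
    .stopf("missing cell type(s): %s", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' @keywords internal
"_PACKAGE"
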