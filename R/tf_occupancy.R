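# TF ChIP-seq peak assignment to gene neighborhoods and per-category
# occupancy enrichment against the non-differential background.

#' Assign TF peaks to gene neighborhoods
#'
#' The neighborhood of a gene is its span extended by `flank` base pairs on
#' both ends (from 10 kb upstream of the TSS to 10 kb past the polyA site;
#' for a whole-gene interval the extension is strand-symmetric), clamped at
#' coordinate 0. A peak is assigned to a gene on any (>= 1 bp) overlap with
#' the neighborhood; one peak can hit several genes and one gene several
#' peaks. Peaks on chromosomes absent from the annotation are skipped and
#' counted in the `skipped_peaks` attribute.
#'
#' @param annotation an `annotation_set`.
#' @param peaks a `peak_set`.
#' @param flank neighborhood extension in bp (default 10000).
#' @return A `neighborhood_occupancy` data.frame: `gene_id`, `tf_name`,
#'   `cell_type`, `peak_count`, `occupied`.
#' @export
assign_peaks <- function(annotation, peaks, flank = 10000L) {
  stopifnot(inherits(annotation, "annotation_set"), inherits(peaks, "peak_set"))
  g <- annotation$genes
  iv <- peaks$intervals
  known <- iv$chrom %in% unique(g$chrom)
  n_skipped <- sum(!known)
  if (n_skipped > 0L)
    .warnf("%d peak(s) on chromosomes absent from the annotation; skipped",
           n_skipped)
  iv <- iv[known, , drop = FALSE]
  counts <- integer(nrow(g))
  if (nrow(iv) > 0L && nrow(g) > 0L) {
    nb <- .as_granges(g$chrom, pmax(g$start - flank, 0L), g$end + flank)
    pk <- .as_granges(iv$chrom, iv$start, iv$end)
    hits <- GenomicRanges::countOverlaps(nb, pk)
    counts <- as.integer(hits)
  }
  out <- data.frame(gene_id = g$gene_id, tf_name = peaks$tf_name,
                    cell_type = peaks$cell_type, peak_count = counts,
                    occupied = counts >= 1L, stringsAsFactors = FALSE)
  attr(out, "flank") <- flank
  attr(out, "skipped_peaks") <- n_skipped
  class(out) <- c("neighborhood_occupancy", "data.frame")
  out
}

#' Occupancy enrichment of DE categories over a background gene set
#'
#' For each composite DE category, computes the percentage of genes whose
#' neighborhood is occupied by the TF and divides it by the percentage in the
#' background set (the non-differentially expressed genes), reporting the
#' log2 of the ratio: positive values are enrichment, negative depletion. A
#' Haldane-style pseudocount (default 0.5 occupied gene, added symmetrically
#' to numerator and denominator of each percentage) keeps the score finite
#' for categories with zero occupancy.
#'
#' @param occupancy a `neighborhood_occupancy` (or a data.frame with
#'   `gene_id` and `occupied`), for one TF/cell-type track.
#' @param categories a `de_categories` object.
#' @param background_genes character vector of background gene ids.
#' @param pseudocount genes added to each occupied count (default 0.5).
#' @return data.frame with one row per category: `category`, `tf_name`,
#'   `cell_type`, `n_genes`, `pct_category`, `pct_background`, `score`.
#'   Empty categories are omitted with a warning.
#' @export
occupancy_enrichment <- function(occupancy, categories, background_genes,
                                 pseudocount = 0.5) {
  stopifnot(is.data.frame(occupancy),
            all(c("gene_id", "occupied") %in% names(occupancy)),
            inherits(categories, "de_categories"))
  if (length(background_genes) == 0L) .stopf("background set is empty")
  occ_of <- function(genes) {
    hit <- occupancy$occupied[match(genes, occupancy$gene_id)]
    hit[is.na(hit)] <- FALSE
    hit
  }
  pct <- function(genes) {
    h <- occ_of(genes)
    100 * (sum(h) + pseudocount) / (length(h) + 2 * pseudocount)
  }
  pct_bg <- pct(background_genes)
  tf <- if (!is.null(occupancy$tf_name)) occupancy$tf_name[1L] else NA_character_
  ct <- if (!is.null(occupancy$cell_type)) occupancy$cell_type[1L] else NA_character_
  cats <- intersect(.DE_LABELS, unique(categories$label))
  rows <- lapply(cats, function(cat) {
    genes <- categories$gene_id[categories$label == cat]
    if (length(genes) == 0L) return(NULL)
    p <- pct(genes)
    data.frame(category = cat, tf_name = tf, cell_type = ct,
               n_genes = length(genes), pct_category = p,
               pct_background = pct_bg, score = log2(p / pct_bg),
               stringsAsFactors = FALSE)
  })
  expected <- .DE_LABELS
  if (identical(categories$source[1L], "consensus"))
    expected <- setdiff(expected, "NN")   # structurally absent from a consensus
  empty <- setdiff(expected, cats)
  if (length(empty) > 0L && length(empty) < length(.DE_LABELS))
    .warnf("empty categor%s omitted: %s",
           if (length(empty) > 1L) "ies" else "y",
           paste(empty, collapse = ", "))
  do.call(rbind, rows)
}

#' Co-bound track from several TF peak sets
#'
#' Builds a pseudo-TF track from the bases covered by at least `min_cobound`
#' of the input tracks (default: all of them, as for the heptad of
#' hematopoietic TFs mapped in the HPC7 progenitor model). Counting is at
#' base resolution: each input track contributes at most 1 per base
#' (overlapping peaks within a track are merged first).
#'
#' @param peaksets list of `peak_set` objects from the same cell type.
#' @param min_cobound minimum number of co-bound tracks per base (default
#'   `length(peaksets)`).
#' @param tf_name name for the resulting pseudo-TF (default
#'   `"cobound<min_cobound>"`).
#' @return A `peak_set` of merged co-bound intervals.
#' @export
heptad_track <- function(peaksets, min_cobound = length(peaksets),
                         tf_name = paste0("cobound", min_cobound)) {
  stopifnot(length(peaksets) >= 1L,
            all(vapply(peaksets, inherits, TRUE, "peak_set")))
  cts <- unique(vapply(peaksets, function(p) p$cell_type, ""))
  if (length(cts) != 1L)
    .stopf("all peak sets must come from the same cell type (got: %s)",
           paste(cts, collapse = ", "))
  if (length(peaksets) < min_cobound)
    .stopf("need at least %d tracks, got %d", min_cobound, length(peaksets))
  grs <- lapply(peaksets, function(p) {
    iv <- p$intervals
    GenomicRanges::reduce(.as_granges(iv$chrom, iv$start, iv$end))
  })
  lens <- .common_seqlens(grs)
  grs <- lapply(grs, function(gr) {
    GenomeInfoDb::seqlevels(gr) <- names(lens)
    GenomeInfoDb::seqlengths(gr) <- lens
    gr
  })
  cov <- Reduce(`+`, lapply(grs, GenomicRanges::coverage))
  hit <- IRanges::slice(cov, lower = min_cobound, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(hit)
  peak_set(tf_name, cts, .granges_to_df(gr))
}

# Common seqlengths so coverage RleLists align across tracks.
.common_seqlens <- function(grs) {
  ends <- lapply(grs, function(gr) {
    if (length(gr) == 0L) return(stats::setNames(integer(), character()))
    tapply(GenomicRanges::end(gr),
           as.character(GenomicRanges::seqnames(gr)), max)
  })
  all_chrom <- sort(unique(unlist(lapply(ends, names))))
  vapply(all_chrom, function(ch) {
    max(vapply(ends, function(e) {
      v <- e[[ch]]
      if (is.null(v) || is.na(v)) 0L else as.integer(v)
    }, 0L))
  }, 0L)
}
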