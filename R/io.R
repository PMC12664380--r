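# Reading and writing the external file formats consumed by the pipeline,
# and construction of the canonical one-transcript-per-gene annotation.

#' Select the canonical transcript for one gene
#'
#' Reduces a set of transcript models sharing a `gene_id` to a single
#' representative. When a curated lookup (e.g. a "knownCanonical"-style table)
#' names a transcript for the gene, that transcript is returned. Otherwise the
#' representative is chosen by three ordered keys: longest transcript, longest
#' coding sequence, and greatest exon count; any remaining tie is broken
#' lexicographically by `transcript_id` so the choice is deterministic.
#'
#' @param transcripts data.frame of transcript models for a single gene, with
#'   columns `gene_id`, `transcript_id`, `chrom`, `start`, `end`, `strand`,
#'   `exon_count`, `cds_length`, `transcript_length`.
#' @param canonical_lookup optional named character vector mapping
#'   `gene_id` to a `transcript_id`.
#' @return A single-row data.frame (the chosen transcript).
#' @export
select_canonical_transcript <- function(transcripts, canonical_lookup = NULL) {
  if (!is.data.frame(transcripts) || nrow(transcripts) == 0L)
    .stopf("'transcripts' must be a non-empty data.frame")
  gid <- unique(transcripts$gene_id)
  if (length(gid) != 1L)
    .stopf("all transcripts must share one gene_id (got: %s)",
           paste(gid, collapse = ", "))
  if (!is.null(canonical_lookup) && gid %in% names(canonical_lookup)) {
    want <- canonical_lookup[[gid]]
    hit <- which(transcripts$transcript_id == want)
    if (length(hit) == 0L)
      .stopf("canonical lookup names transcript '%s' absent from gene '%s'",
             want, gid)
    return(transcripts[hit[1L], , drop = FALSE])
  }
  ord <- order(-transcripts$transcript_length,
               -transcripts$cds_length,
               -transcripts$exon_count,
               transcripts$transcript_id)
  transcripts[ord[1L], , drop = FALSE]
}

#' Construct an annotation set from a gene table
#'
#' @param genes data.frame with one row per gene: `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `exon_count`,
#'   `cds_length`, `transcript_length`.
#' @param excluded optional data.frame (`gene_id`, `reason`) logging filtered
#'   genes.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(genes, excluded = NULL) {
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand",
            "exon_count", "cds_length", "transcript_length")
  stopifnot(is.data.frame(genes), all(need %in% names(genes)))
  if (any(genes$start >= genes$end)) .stopf("gene spans need start < end")
  if (any(genes$exon_count < 1L)) .stopf("exon_count must be >= 1")
  if (any(genes$transcript_length < genes$cds_length))
    .stopf("transcript_length must be >= cds_length")
  if (anyDuplicated(genes$gene_id))
    .stopf("duplicate gene_id: %s",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                 collapse = ", "))
  if (is.null(excluded)) excluded <- .empty_excluded_df()
  .new_annotation_set(genes[, need], excluded)
}

.new_annotation_set <- function(genes, excluded) {
  rownames(genes) <- NULL
  stopifnot(!anyDuplicated(genes$gene_id))
  structure(list(genes = genes, excluded = excluded),
            class = "annotation_set")
}

.empty_gene_df <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), exon_count = integer(),
             cds_length = integer(), transcript_length = integer(),
             stringsAsFactors = FALSE)
}

.empty_excluded_df <- function() {
  data.frame(gene_id = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Load gene models and build a canonical one-transcript-per-gene annotation
#'
#' Reads transcript models from GTF (1-based closed; converted on load) or
#' BED12 (0-based half-open), applies the contig and snoRNA exclusion filters,
#' and collapses each gene to one canonical transcript with
#' [select_canonical_transcript()]. All coordinates are stored 0-based
#' half-open. Exclusion filtering happens before the canonical lookup is
#' consulted.
#'
#' For BED12 input the `name` field is interpreted as
#' `"gene_id|transcript_id"`; a name without `"|"` is used as both ids.
#'
#' @param path file to read.
#' @param format `"gtf"` or `"bed12"`.
#' @param canonical_lookup optional named character vector, see
#'   [select_canonical_transcript()].
#' @param random_contig_pattern regex on the chromosome name; matching genes
#'   are excluded (default drops `*_random` contigs).
#' @param snorna_pattern regex on the gene id; matching genes are excluded
#'   (default drops ids starting with `Snora`).
#' @return An `annotation_set`: list with `genes` (one row per gene) and
#'   `excluded` (`gene_id`, `reason`).
#' @export
load_gene_models <- function(path, format = c("gtf", "bed12"),
                             canonical_lookup = NULL,
                             random_contig_pattern = "_random$",
                             snorna_pattern = "^Snora") {
  format <- match.arg(format)
  tx <- if (format == "gtf") .parse_gtf_transcripts(path)
        else .parse_bed12_transcripts(path)
  if (nrow(tx) == 0L)
    return(.new_annotation_set(.empty_gene_df(), .empty_excluded_df()))

  dup <- duplicated(tx[, c("gene_id", "transcript_id")])
  if (any(dup))
    .stopf("duplicate transcript record(s): %s",
           paste(unique(paste0(tx$gene_id[dup], "/", tx$transcript_id[dup])),
                 collapse = ", "))

  # Exclusion filters run before the canonical lookup (filter-first policy).
  excl <- .empty_excluded_df()
  bad_contig <- grepl(random_contig_pattern, tx$chrom)
  bad_sno <- grepl(snorna_pattern, tx$gene_id)
  for (gid in unique(tx$gene_id[bad_contig]))
    excl <- rbind(excl, data.frame(gene_id = gid, reason = "random contig"))
  for (gid in setdiff(unique(tx$gene_id[bad_sno]), excl$gene_id))
    excl <- rbind(excl, data.frame(gene_id = gid, reason = "snoRNA"))
  tx <- tx[!(tx$gene_id %in% excl$gene_id), , drop = FALSE]

  if (nrow(tx) == 0L)
    return(.new_annotation_set(.empty_gene_df(), excl))

  pieces <- split(tx, tx$gene_id)
  genes <- do.call(rbind, lapply(pieces, select_canonical_transcript,
                                 canonical_lookup = canonical_lookup))
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  .new_annotation_set(genes, excl)
}

.parse_gtf_transcripts <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) .stopf("malformed GTF '%s': %s",
                                            path, conditionMessage(e)))
  if (length(gr) == 0L) return(.empty_gene_df())
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id))
    .stopf("GTF '%s' lacks gene_id/transcript_id attributes", path)
  type <- as.character(md$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]; type <- type[keep]
  if (length(gr) == 0L) return(.empty_gene_df())
  key <- paste(md$gene_id, md$transcript_id, sep = "\r")
  is_exon <- type == "exon"
  w <- GenomicRanges::width(gr)
  first <- !duplicated(key)
  tx_len <- rowsum(w * is_exon, key)[, 1L]
  cds_len <- rowsum(w * !is_exon, key)[, 1L]
  n_exon <- rowsum(as.integer(is_exon), key)[, 1L]
  start0 <- tapply(GenomicRanges::start(gr) - 1L, key, min)
  end0 <- tapply(GenomicRanges::end(gr), key, max)
  ord <- names(tx_len)
  firsts <- match(ord, key)
  out <- data.frame(
    gene_id = as.character(md$gene_id)[firsts],
    transcript_id = as.character(md$transcript_id)[firsts],
    chrom = as.character(GenomicRanges::seqnames(gr))[firsts],
    start = as.integer(start0[ord]),
    end = as.integer(end0[ord]),
    strand = as.character(GenomicRanges::strand(gr))[firsts],
    exon_count = as.integer(pmax(n_exon[ord], 1L)),
    cds_length = as.integer(cds_len[ord]),
    transcript_length = as.integer(tx_len[ord]),
    stringsAsFactors = FALSE
  )
  bad <- out$transcript_length < out$cds_length | out$start >= out$end
  if (any(bad))
    .stopf("inconsistent transcript model(s): %s",
           paste(out$transcript_id[bad], collapse = ", "))
  rownames(out) <- NULL
  out
}

.parse_bed12_transcripts <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_gene_df())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    .stopf("malformed BED12 record at line %d of '%s' (%d fields)",
           which(nf < 12L)[1L], path, nf[which(nf < 12L)[1L]])
  rec <- function(i) {
    f <- fields[[i]]
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end) || start >= end)
      .stopf("invalid interval at line %d of '%s'", i, path)
    name <- f[4L]
    ids <- strsplit(name, "|", fixed = TRUE)[[1L]]
    gene_id <- ids[1L]
    transcript_id <- if (length(ids) > 1L) ids[2L] else ids[1L]
    block_count <- as.integer(f[10L])
    sizes <- as.integer(strsplit(sub(",$", "", f[11L]), ",")[[1L]])
    offsets <- as.integer(strsplit(sub(",$", "", f[12L]), ",")[[1L]])
    if (length(sizes) != block_count || length(offsets) != block_count)
      .stopf("block count mismatch at line %d of '%s'", i, path)
    thick_start <- as.integer(f[7L]); thick_end <- as.integer(f[8L])
    bs <- start + offsets
    be <- bs + sizes
    cds <- sum(pmax(0L, pmin(be, thick_end) - pmax(bs, thick_start)))
    data.frame(gene_id = gene_id, transcript_id = transcript_id,
               chrom = f[1L], start = start, end = end, strand = f[6L],
               exon_count = block_count, cds_length = cds,
               transcript_length = sum(sizes), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(fields), rec))
  rownames(out) <- NULL
  out
}

#' Write an annotation set as BED12
#'
#' Each canonical transcript is written as a single-block BED12 record with
#' name `"gene_id|transcript_id"`. Exon structure beyond the block count is
#' not retained by `annotation_set`, so re-reading recovers the gene span,
#' strand and ids but a single exon block.
#' @param annotation an `annotation_set`.
#' @param path output file.
#' @export
write_gene_models <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  g <- annotation$genes
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                   g$chrom, g$start, g$end, g$gene_id, g$transcript_id,
                   g$strand, g$start, g$end, g$end - g$start)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes (%d excluded)\n",
              nrow(x$genes), nrow(x$excluded)))
  if (nrow(x$excluded) > 0L) {
    tab <- table(x$excluded$reason)
    cat("  exclusions:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- expression matrix ------------------------------------------------------

#' Construct an expression matrix
#'
#' Wraps a gene-by-sample grid of FPKM values together with sample metadata,
#' the additive noise constant used before log2 transformation, and the
#' expressed/silent threshold on the log2 scale.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids); all values must be non-negative.
#' @param samples data.frame with columns `sample_id`, `cell_type`,
#'   `replicate`; if `NULL`, parsed from column names of the form
#'   `"<cell_type>_<replicate>"`.
#' @param noise_constant additive constant applied before log2 (default 1.1).
#' @param expressed_threshold log2-scale threshold; a gene is called expressed
#'   in a cell type only when its level is strictly above this (default 3).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples = NULL, noise_constant = 1.1,
                              expressed_threshold = 3) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("'values' needs gene rownames and sample colnames")
  if (any(values < 0))
    .stopf("negative FPKM values are not allowed")
  if (noise_constant <= 0) .stopf("noise_constant must be > 0")
  if (is.null(samples)) {
    ids <- colnames(values)
    ct <- sub("_[^_]*$", "", ids)
    rep_tag <- ifelse(grepl("_", ids), sub("^.*_", "", ids), "r1")
    samples <- data.frame(sample_id = ids, cell_type = ct,
                          replicate = rep_tag, stringsAsFactors = FALSE)
  }
  stopifnot(identical(samples$sample_id, colnames(values)))
  structure(list(values = values, samples = samples,
                 noise_constant = noise_constant,
                 expressed_threshold = expressed_threshold),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d genes x %d samples (%d cell types); eps=%g, tau=%g\n",
    nrow(x$values), ncol(x$values), length(unique(x$samples$cell_type)),
    x$noise_constant, x$expressed_threshold))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids with `gene_id` as the first column.
#' Fails on ragged rows and on negative values (naming the gene and sample).
#'
#' @inheritParams expression_matrix
#' @param path TSV file.
#' @param annotation optional `annotation_set`; genes absent from it are
#'   reported via the `"unannotated"` attribute.
#' @return An `expression_matrix`.
#' @export
load_expression_matrix <- function(path, annotation = NULL, samples = NULL,
                                   noise_constant = 1.1,
                                   expressed_threshold = 3) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    .stopf("ragged TSV '%s': line %d has %d fields, expected %d",
           path, which(nf != nf[1L])[1L], nf[which(nf != nf[1L])[1L]], nf[1L])
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id")
    .stopf("first column of '%s' must be 'gene_id'", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) .stopf("non-numeric expression values in '%s'", path)
  rownames(vals) <- df$gene_id
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1L, ]
    .stopf("negative FPKM for gene '%s' in sample '%s'",
           rownames(vals)[idx[1L]], colnames(vals)[idx[2L]])
  }
  m <- expression_matrix(vals, samples = samples,
                         noise_constant = noise_constant,
                         expressed_threshold = expressed_threshold)
  if (!is.null(annotation)) {
    missing <- setdiff(rownames(vals), annotation$genes$gene_id)
    attr(m, "unannotated") <- missing
  }
  m
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip is bit-identical.
#' @param m an `expression_matrix`.
#' @param path output file.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  txt <- apply(m$values, 2L, function(col) formatC(col, digits = 17,
                                                   format = "g"))
  txt <- matrix(trimws(txt), nrow = nrow(m$values))
  out <- cbind(gene_id = rownames(m$values), txt)
  colnames(out) <- c("gene_id", colnames(m$values))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- peaks and cCREs --------------------------------------------------------

#' Load ChIP-seq peak calls from BED
#'
#' @param path BED3+ file (0-based half-open intervals).
#' @param tf_name transcription factor name.
#' @param cell_type cell type the peaks were called in.
#' @return A `peak_set`: list with `tf_name`, `cell_type` and an `intervals`
#'   data.frame (`chrom`, `start`, `end`).
#' @export
load_peaks <- function(path, tf_name, cell_type) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(peak_set(tf_name, cell_type,
                    data.frame(chrom = character(), start = integer(),
                               end = integer(), stringsAsFactors = FALSE)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    .stopf("malformed BED record at line %d of '%s'", which(nf < 3L)[1L], path)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad))
    .stopf("invalid interval at line %d of '%s'", which(bad)[1L], path)
  peak_set(tf_name, cell_type,
           data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE))
}

#' Construct a peak set
#' @param tf_name,cell_type character scalars.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); intervals may overlap.
#' @export
peak_set <- function(tf_name, cell_type, intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    .stopf("peak intervals must satisfy start < end")
  structure(list(tf_name = tf_name, cell_type = cell_type,
                 intervals = intervals[, c("chrom", "start", "end")]),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %s in %s, %d intervals\n",
              x$tf_name, x$cell_type, nrow(x$intervals)))
  invisible(x)
}

#' Write a peak set as BED3
#' @param peaks a `peak_set`.
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  iv <- peaks$intervals
  writeLines(sprintf("%s\t%d\t%d", iv$chrom, iv$start, iv$end), path)
  invisible(path)
}

#' Load a cCRE table with per-cell-type ATAC signals
#'
#' The file is TSV with a header; columns `ccre_id`, `chrom`, `start`, `end`
#' plus one signal column per cell type (column order is free — columns are
#' matched by name). Signals are mean normalized ATAC-seq values on the
#' `-log10 p` scale and must be non-negative.
#'
#' @param path TSV file.
#' @param cell_types character vector of required cell-type columns; `NULL`
#'   takes every column after the coordinates.
#' @return A `ccre_table` data.frame with attribute `cell_types`.
#' @export
load_ccres <- function(path, cell_types = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("ccre_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    .stopf("cCRE table '%s' must have columns %s", path,
           paste(need, collapse = ", "))
  if (is.null(cell_types)) cell_types <- setdiff(names(df), need)
  .check_cell_types(names(df), cell_types)
  df <- df[, c(need, cell_types), drop = FALSE]
  ccre_table(df, cell_types)
}

#' Construct a cCRE table
#' @param df data.frame with `ccre_id`, `chrom`, `start`, `end` and one
#'   numeric signal column per cell type.
#' @param cell_types character vector naming the signal columns.
#' @export
ccre_table <- function(df, cell_types) {
  .check_cell_types(names(df), cell_types)
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1L]
    .stopf("invalid cCRE interval at row %d (start >= end)", bad)
  }
  for (ct in cell_types) {
    if (!is.numeric(df[[ct]]) || any(df[[ct]] < 0))
      .stopf("cCRE signals must be non-negative numbers ('%s')", ct)
    df[[ct]] <- as.numeric(df[[ct]])
  }
  structure(df, cell_types = cell_types,
            class = c("ccre_table", "data.frame"))
}

#' Write a cCRE table to TSV
#' @param ccres a `ccre_table`.
#' @param path output file.
#' @export
write_ccres <- function(ccres, path) {
  stopifnot(inherits(ccres, "ccre_table"))
  utils::write.table(as.data.frame(ccres), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
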