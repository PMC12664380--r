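# FPKM transformation, expressed/silent calls, lineage-sharing partition,
# globin extrapolation, pseudoreplicates, and replicate concordance.

#' Log2-transform FPKM values with an additive noise constant
#'
#' Computes `log2(FPKM + eps)` elementwise, where `eps` is the matrix's noise
#' constant (default 1.1). This maps an FPKM of 0 to a floor level of
#' `log2(1.1) = 0.1375` and avoids log-of-zero and divide-by-zero issues
#' downstream.
#'
#' @param m an [expression_matrix()].
#' @return Numeric matrix of log2 levels with the same dimnames as
#'   `m$values`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  log2(m$values + m$noise_constant)
}

#' Call genes expressed or silent per cell type
#'
#' Pools replicate FPKMs per cell type (arithmetic mean, a stand-in for
#' pooled-abundance estimates from an upstream quantifier), log2-transforms
#' with the noise constant, and calls a gene expressed in a cell type only
#' when its pooled level is strictly above the threshold `tau` (default 3 on
#' the log2 scale). A level of exactly `tau` is silent.
#'
#' @param m an [expression_matrix()].
#' @param pooling `"pooled"` (mean FPKM across replicates, then transform) or
#'   `"per_replicate"` (transform each replicate; a gene must exceed `tau` in
#'   every replicate of the cell type).
#' @param pooled_fpkm optional genes x cell-types matrix of pooled-abundance
#'   FPKMs from an upstream quantifier; when supplied (in `"pooled"` mode) it
#'   replaces the replicate-mean fallback for the cell types it covers.
#' @return An `expression_calls` object: list with matrices `log2_level` and
#'   `expressed` (genes x cell types) and the threshold used.
#' @export
call_expressed <- function(m, pooling = c("pooled", "per_replicate"),
                           pooled_fpkm = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  pooling <- match.arg(pooling)
  if (!is.null(pooled_fpkm))
    stopifnot(is.matrix(pooled_fpkm),
              identical(rownames(pooled_fpkm), rownames(m$values)))
  cts <- unique(m$samples$cell_type)
  tau <- m$expressed_threshold
  lev <- matrix(NA_real_, nrow(m$values), length(cts),
                dimnames = list(rownames(m$values), cts))
  expr <- matrix(NA, nrow(m$values), length(cts),
                 dimnames = list(rownames(m$values), cts))
  for (ct in cts) {
    cols <- which(m$samples$cell_type == ct)
    if (length(cols) == 0L) .stopf("unknown cell type '%s'", ct)
    if (pooling == "pooled") {
      pooled <- if (!is.null(pooled_fpkm) && ct %in% colnames(pooled_fpkm))
        pooled_fpkm[, ct]
      else rowMeans(m$values[, cols, drop = FALSE])
      if (any(pooled < 0)) .stopf("pooled FPKMs must be non-negative")
      lev[, ct] <- log2(pooled + m$noise_constant)
      expr[, ct] <- lev[, ct] > tau
    } else {
      ll <- log2(m$values[, cols, drop = FALSE] + m$noise_constant)
      lev[, ct] <- rowMeans(ll)
      expr[, ct] <- apply(ll > tau, 1L, all)
    }
  }
  structure(list(log2_level = lev, expressed = expr, threshold = tau,
                 pooling = pooling),
            class = "expression_calls")
}

#' @export
print.expression_calls <- function(x, ...) {
  n_expr <- colSums(x$expressed)
  cat(sprintf("expression_calls: %d genes, threshold log2 > %g (%s)\n",
              nrow(x$expressed), x$threshold, x$pooling))
  for (ct in colnames(x$expressed))
    cat(sprintf("  %s: %d expressed\n", ct, n_expr[[ct]]))
  invisible(x)
}

#' Partition genes by the set of lineages expressing them
#'
#' Assigns every gene to exactly one of the 8 subsets of the cell-type trio
#' (including the empty subset = silent everywhere) and reports the aggregate
#' counts: expressed in any lineage, in exactly one, in each pair, and in all
#' three.
#'
#' @param calls an `expression_calls` object covering the three cell types.
#' @param cell_types ordered trio of cell-type names
#'   (default `c("MEP", "MEG", "ERY")`).
#' @return A `sharing_partition`: list with `membership` (named character
#'   vector per gene, e.g. `"MEP+MEG"`, `"none"`), `counts` (per class) and
#'   `summary` (aggregates).
#' @export
partition_sharing <- function(calls, cell_types = c("MEP", "MEG", "ERY")) {
  stopifnot(inherits(calls, "expression_calls"))
  .check_cell_types(colnames(calls$expressed), cell_types)
  ex <- calls$expressed[, cell_types, drop = FALSE]
  label_of <- function(row) {
    on <- cell_types[row]
    if (length(on) == 0L) "none" else paste(on, collapse = "+")
  }
  membership <- apply(ex, 1L, label_of)
  all_classes <- c("none", unlist(lapply(seq_along(cell_types), function(k)
    utils::combn(cell_types, k, paste, collapse = "+"))))
  counts <- table(factor(membership, levels = all_classes))
  n_on <- rowSums(ex)
  pair_classes <- utils::combn(cell_types, 2L, paste, collapse = "+")
  summary <- list(
    total = nrow(ex),
    expressed_any = sum(n_on > 0L),
    exactly_one = sum(n_on == 1L),
    exactly_two = as.list(counts[pair_classes]),
    all_three = unname(counts[paste(cell_types, collapse = "+")])
  )
  structure(list(membership = membership, counts = counts, summary = summary,
                 cell_types = cell_types),
            class = "sharing_partition")
}

#' @export
print.sharing_partition <- function(x, ...) {
  s <- x$summary
  cat(sprintf("sharing_partition: %d genes, %d expressed in >=1 lineage\n",
              s$total, s$expressed_any))
  cat(sprintf("  one lineage only: %d; all three: %d\n",
              s$exactly_one, s$all_three))
  for (p in names(s$exactly_two))
    cat(sprintf("  %s only: %d\n", p, s$exactly_two[[p]]))
  invisible(x)
}

#' Extrapolate FPKM for masked genes from read counts
#'
#' Genes masked during upstream quantification (the globin loci, whose read
#' depth in erythroid cells makes direct estimation impractical) are assigned
#' FPKMs by scaling their read counts with the ratio of read counts to FPKMs
#' observed in the most highly expressed unmasked genes. The ratio is computed
#' on sums over the top `n_top` reference genes by count, which is robust to
#' low-FPKM outliers.
#'
#' @param masked_gene_counts named numeric vector of read counts for the
#'   masked genes.
#' @param reference_top_genes data.frame with columns `count` and `fpkm` for
#'   unmasked reference genes.
#' @param n_top number of top reference genes (by count) to use (default 20).
#' @return Named numeric vector of estimated FPKMs.
#' @export
estimate_globin_fpkm <- function(masked_gene_counts, reference_top_genes,
                                 n_top = 20L) {
  stopifnot(is.numeric(masked_gene_counts),
            is.data.frame(reference_top_genes),
            all(c("count", "fpkm") %in% names(reference_top_genes)))
  if (n_top > nrow(reference_top_genes))
    .stopf("n_top (%d) exceeds available reference genes (%d)",
           n_top, nrow(reference_top_genes))
  top <- reference_top_genes[order(-reference_top_genes$count), , drop = FALSE]
  top <- top[seq_len(n_top), , drop = FALSE]
  if (sum(top$fpkm) <= 0) .stopf("reference FPKM total must be positive")
  ratio <- sum(top$count) / sum(top$fpkm)
  masked_gene_counts / ratio
}

#' Split pooled alignment units into two pseudoreplicates
#'
#' Randomly partitions a pool of alignment units (opaque ids) into two halves
#' of equal size (within one unit when the pool is odd). Used to stabilize a
#' weak replicate by pooling both replicates and re-splitting. The split is a
#' deterministic function of the seed.
#'
#' @param alignment_units vector of opaque unit identifiers.
#' @param seed integer RNG seed.
#' @return List with elements `A` and `B`; together they contain every input
#'   unit exactly once (as a multiset).
#' @export
make_pseudoreplicates <- function(alignment_units, seed) {
  n <- length(alignment_units)
  if (n == 0L) .stopf("'alignment_units' must be non-empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n)
  n_a <- ceiling(n / 2)
  list(A = alignment_units[sort(idx[seq_len(n_a)])],
       B = alignment_units[sort(idx[-seq_len(n_a)])])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Replicate concordance by Spearman rank correlation
#'
#' Restricts to genes with FPKM strictly positive in both replicates of the
#' cell type (excluding the additive-constant floor artifact at silent genes)
#' and computes the Spearman rank correlation of the log2 levels with
#' average-rank tie handling.
#'
#' @param m an [expression_matrix()] with exactly two replicates for
#'   `cell_type`.
#' @param cell_type cell type to assess.
#' @return Spearman correlation coefficient in `[-1, 1]`.
#' @export
replicate_concordance <- function(m, cell_type) {
  stopifnot(inherits(m, "expression_matrix"))
  cols <- which(m$samples$cell_type == cell_type)
  if (length(cols) != 2L)
    .stopf("cell type '%s' must have exactly two replicates (found %d)",
           cell_type, length(cols))
  x <- m$values[, cols[1L]]
  y <- m$values[, cols[2L]]
  keep <- x > 0 & y > 0
  if (sum(keep) < 3L)
    .stopf("fewer than 3 genes with positive FPKM in both replicates")
  stats::cor(log2(x[keep] + m$noise_constant),
             log2(y[keep] + m$noise_constant), method = "spearman")
}
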