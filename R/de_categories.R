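# Nine-category differential-expression classification: pairwise-test route,
# k-means pattern-clustering route, and their consensus.

.DE_LABELS <- c("UU", "UN", "UD", "NU", "NN", "ND", "DU", "DN", "DD")

.new_de_categories <- function(gene_id, label, source) {
  stopifnot(all(label %in% .DE_LABELS))
  structure(data.frame(gene_id = gene_id, label = label,
                       source = source, stringsAsFactors = FALSE),
            class = c("de_categories", "data.frame"))
}

#' @export
print.de_categories <- function(x, ...) {
  cat(sprintf("de_categories (%s): %d genes\n", x$source[1L], nrow(x)))
  print(table(factor(x$label, levels = .DE_LABELS)))
  invisible(x)
}

#' Categorize genes from pairwise differential-expression tests
#'
#' Per comparison (daughter vs progenitor) a gene is labelled `U` (up) when
#' its q-value passes the FDR threshold, the fold change is positive, and it
#' is expressed in at least one of the two cell types compared; `D` (down)
#' analogously for negative fold change; otherwise `N` (no significant
#' change). The composite label concatenates the first (MEG vs MEP) and
#' second (ERY vs MEP) comparison outcomes, e.g. `"UN"`.
#'
#' @param de data.frame with columns `gene_id`, `comparison`, `log2fc`,
#'   `q_value`, `expressed_either`. Every gene must appear once per
#'   comparison.
#' @param comparisons character pair naming the two comparisons in composite
#'   order (default `c("MEG_vs_MEP", "ERY_vs_MEP")`).
#' @param alpha FDR threshold(s): a scalar, or a vector named by comparison.
#'   The original analysis used 0.05 but tightened the MEG-vs-MEP comparison
#'   to 0.02 because MEG pseudoreplicates understate the replicate variance.
#' @return A `de_categories` object with `source = "pairwise"`.
#' @export
pairwise_categorize <- function(de,
                                comparisons = c("MEG_vs_MEP", "ERY_vs_MEP"),
                                alpha = 0.05) {
  need <- c("gene_id", "comparison", "log2fc", "q_value", "expressed_either")
  stopifnot(is.data.frame(de), all(need %in% names(de)))
  if (any(de$q_value < 0 | de$q_value > 1))
    .stopf("q_value must lie in [0, 1]")
  if (length(alpha) == 1L && is.null(names(alpha)))
    alpha <- stats::setNames(rep(alpha, 2L), comparisons)
  if (!all(comparisons %in% names(alpha)))
    .stopf("alpha must be named by comparison when not scalar")
  if (any(alpha <= 0 | alpha >= 1)) .stopf("alpha must lie in (0, 1)")

  genes <- unique(de$gene_id)
  per_comp <- function(comp) {
    sub <- de[de$comparison == comp, , drop = FALSE]
    miss <- setdiff(genes, sub$gene_id)
    if (length(miss) > 0L)
      .stopf("comparison '%s' missing for gene(s): %s", comp,
             paste(utils::head(miss, 5L), collapse = ", "))
    sub <- sub[match(genes, sub$gene_id), , drop = FALSE]
    sig <- sub$q_value <= alpha[[comp]] & sub$expressed_either
    ifelse(sig & sub$log2fc > 0, "U", ifelse(sig & sub$log2fc < 0, "D", "N"))
  }
  lab <- paste0(per_comp(comparisons[1L]), per_comp(comparisons[2L]))
  .new_de_categories(genes, lab, "pairwise")
}

# Row standardization with an sd floor for (near-)constant rows.
.standardize_rows <- function(x, sd_floor = 1e-6) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  sdv <- pmax(sdv, sd_floor)
  (x - mu) / sdv
}

# Seeded farthest-point ("maximin") initialization: the first center is a
# seeded random point, each next center the point farthest from the chosen
# ones. Deterministic given the first point.
.farthest_point_init <- function(x, k, first) {
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[first, ]
  if (k == 1L) return(centers)
  d2 <- colSums((t(x) - centers[1L, ])^2)
  for (j in 2:k) {
    pick <- which.max(d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

.lloyd_once <- function(x, k, first) {
  init <- .farthest_point_init(x, k, first)
  init <- init[!duplicated(round(init, 12L)), , drop = FALSE]
  fit <- suppressWarnings(
    stats::kmeans(x, centers = init, iter.max = 300L, algorithm = "Lloyd"))
  fit
}

#' K-means clustering of expression patterns
#'
#' Clusters row-standardized log2 expression patterns across the cell-type
#' trio with Lloyd's algorithm, using seeded farthest-point initialization
#' restarted `nstart` times (best within-cluster sum of squares kept). When
#' `k_fixed` is `NULL`, k is scanned over `k_range` and chosen by the elbow
#' criterion: the k with the largest discrete second difference of the WSS
#' curve. The WSS curve is non-increasing in k, so an interior minimum cannot
#' exist; the elbow is the standard reading of "tightest clustering at k".
#'
#' @param levels numeric matrix of log2 levels, genes x cell types.
#' @param k_range integer vector of k values to scan (default `1:25`).
#' @param k_fixed optional fixed k (the replication default for the study
#'   data is 12); skips the scan.
#' @param seed integer seed controlling initialization.
#' @param nstart number of seeded restarts per k (default 10).
#' @param sd_floor floor on the row standard deviation before standardization
#'   (default 1e-6), so constant rows do not divide by zero.
#' @return An `expr_kmeans` object: list with `k`, `assignments` (named
#'   integer vector), `centers` (standardized space), `wss`, `wss_curve`,
#'   `seed`.
#' @export
kmeans_cluster <- function(levels, k_range = 1:25, k_fixed = NULL, seed = 1L,
                           nstart = 10L, sd_floor = 1e-6) {
  stopifnot(is.matrix(levels), is.numeric(levels))
  if (is.null(rownames(levels)))
    rownames(levels) <- paste0("g", seq_len(nrow(levels)))
  x <- .standardize_rows(levels, sd_floor)
  n <- nrow(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  fit_k <- function(k) {
    if (k > n) .stopf("k = %d exceeds the number of genes (%d)", k, n)
    firsts <- sample.int(n, min(nstart, n))
    best <- NULL
    for (f in firsts) {
      fit <- .lloyd_once(x, k, f)
      if (is.null(best) || sum(fit$withinss) < sum(best$withinss)) best <- fit
    }
    best
  }

  if (is.null(k_fixed)) {
    k_range <- sort(unique(as.integer(k_range)))
    k_range <- k_range[k_range <= n]
    fits <- lapply(k_range, fit_k)
    wss_curve <- vapply(fits, function(f) sum(f$withinss), 0)
    names(wss_curve) <- k_range
    if (length(k_range) >= 3L) {
      d2 <- diff(diff(wss_curve))        # aligned with interior k values
      k_best <- k_range[which.max(d2) + 1L]
    } else {
      k_best <- k_range[length(k_range)]
    }
    fit <- fits[[match(k_best, k_range)]]
  } else {
    k_best <- as.integer(k_fixed)
    fit <- fit_k(k_best)
    wss_curve <- stats::setNames(sum(fit$withinss), k_best)
  }

  structure(list(k = k_best,
                 assignments = stats::setNames(fit$cluster, rownames(levels)),
                 centers = fit$centers,
                 wss = sum(fit$withinss),
                 wss_curve = wss_curve,
                 seed = seed),
            class = "expr_kmeans")
}

#' @export
print.expr_kmeans <- function(x, ...) {
  cat(sprintf("expr_kmeans: k = %d, %d genes, WSS = %.4g (seed %d)\n",
              x$k, length(x$assignments), x$wss, x$seed))
  print(table(x$assignments))
  invisible(x)
}

#' Map expression clusters to composite DE categories
#'
#' Each cluster is labelled from its centroid on the raw (unstandardized)
#' log2 scale: per daughter lineage, `U` when the centroid daughter-minus-
#' progenitor difference is at least `delta`, `D` when at most `-delta`,
#' otherwise `N`. Every member gene inherits its cluster's composite label.
#' `delta = 1` (a 2-fold margin) separates the archetypal patterns.
#'
#' @param model an `expr_kmeans` object.
#' @param raw_levels matrix of raw log2 levels (genes x cell types) covering
#'   every clustered gene.
#' @param delta margin in log2 units (default 1).
#' @param cell_types trio naming the progenitor then the two daughters in
#'   composite order (default `c("MEP", "MEG", "ERY")`).
#' @return A `de_categories` object with `source = "kmeans"`.
#' @export
clusters_to_categories <- function(model, raw_levels, delta = 1,
                                   cell_types = c("MEP", "MEG", "ERY")) {
  stopifnot(inherits(model, "expr_kmeans"))
  .check_cell_types(colnames(raw_levels), cell_types)
  genes <- names(model$assignments)
  if (!all(genes %in% rownames(raw_levels)))
    .stopf("raw_levels must cover every clustered gene")
  lv <- raw_levels[genes, cell_types, drop = FALSE]
  lab1 <- character(model$k)
  for (cl in seq_len(model$k)) {
    members <- model$assignments == cl
    cent <- colMeans(lv[members, , drop = FALSE])
    call_one <- function(daughter) {
      diffv <- cent[[daughter]] - cent[[cell_types[1L]]]
      if (diffv >= delta) "U" else if (diffv <= -delta) "D" else "N"
    }
    lab1[cl] <- paste0(call_one(cell_types[2L]), call_one(cell_types[3L]))
  }
  .new_de_categories(genes, lab1[model$assignments], "kmeans")
}

#' Consensus of two category assignments
#'
#' Retains a gene only when both assignments agree on its composite label and
#' that label is not `NN`; all other genes are dropped. The result is
#' idempotent and symmetric in its arguments.
#'
#' @param a,b `de_categories` objects over the same gene universe.
#' @return A `de_categories` object with `source = "consensus"`.
#' @export
consensus_categories <- function(a, b) {
  stopifnot(inherits(a, "de_categories"), inherits(b, "de_categories"))
  if (!setequal(a$gene_id, b$gene_id))
    .stopf("assignments cover different gene universes")
  bl <- b$label[match(a$gene_id, b$gene_id)]
  keep <- a$label == bl & a$label != "NN"
  .new_de_categories(a$gene_id[keep], a$label[keep], "consensus")
}

#' Genes not differentially expressed by either route
#'
#' The background set for occupancy enrichment: genes labelled `NN` by both
#' the pairwise and the clustering route.
#'
#' @param a,b `de_categories` objects over the same gene universe. Genes in
#'   the universe absent from an assignment (e.g. never clustered because
#'   they were not candidate DE genes) count as `NN` for that route.
#' @param universe optional character vector of all gene ids; defaults to the
#'   union of the two assignments.
#' @return Character vector of background gene ids.
#' @export
nondifferential_background <- function(a, b, universe = NULL) {
  stopifnot(inherits(a, "de_categories"), inherits(b, "de_categories"))
  if (is.null(universe)) universe <- union(a$gene_id, b$gene_id)
  la <- a$label[match(universe, a$gene_id)]
  lb <- b$label[match(universe, b$gene_id)]
  la[is.na(la)] <- "NN"
  lb[is.na(lb)] <- "NN"
  universe[la == "NN" & lb == "NN"]
}
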