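# cCRE-gene pairing, H/M/L signal-state discretization, 27-category
# tabulation, and odds-ratio tests of the two discordance hypotheses.

.STATE_LEVELS <- c(L = 1L, M = 2L, H = 3L)

#' The 27 signal-state categories
#'
#' All 3-letter combinations of the H/M/L accessibility states across the
#' cell-type trio (ordered progenitor, daughter 1, daughter 2), in a fixed
#' canonical order (H, M, L nested per position).
#' @return Character vector of length 27.
#' @export
all_signal_categories <- function() {
  st <- c("H", "M", "L")
  as.vector(vapply(st, function(a)
    vapply(st, function(b) paste0(a, b, st), character(3L)), character(9L)))
}

#' Signal-state discretization policy
#'
#' Thresholds on the normalized ATAC-seq signal (`-log10 p` of deviation from
#' the negative-binomial background). A signal strictly below `low_threshold`
#' is low (L); at or above `high_threshold` is high (H); otherwise medium
#' (M). The defaults are 1.3 (the peak-calling cutoff) and 8.6 (the mean
#' signal over all cCRE-gene pairs and analysis cell types in the study
#' data); in `data_mean` mode the high threshold is recomputed from the data
#' at hand.
#'
#' @param low_threshold signal below which the state is L (default 1.3).
#' @param high_threshold signal at or above which the state is H
#'   (default 8.6).
#' @return A `signal_state_policy` list.
#' @export
signal_state_policy <- function(low_threshold = 1.3, high_threshold = 8.6) {
  if (!(0 < low_threshold && low_threshold < high_threshold))
    .stopf("need 0 < low_threshold < high_threshold (got %g, %g)",
           low_threshold, high_threshold)
  structure(list(low_threshold = low_threshold,
                 high_threshold = high_threshold),
            class = "signal_state_policy")
}

#' Pair cCREs with genes by extended gene-body overlap
#'
#' A cCRE is paired with a gene when it overlaps (>= 1 bp, or is fully
#' contained in when `containment = TRUE`) the interval from `flank` bp
#' upstream of the TSS to `flank` bp downstream of the polyA site, i.e. the
#' gene span extended symmetrically and clamped at 0. Close or overlapping
#' genes can claim the same cCRE, producing one pair per gene.
#'
#' @param annotation an `annotation_set`.
#' @param ccres a `ccre_table`.
#' @param flank extension in bp (default 10000).
#' @param containment require the cCRE to lie entirely within the extended
#'   span instead of any overlap (default `FALSE`).
#' @return A `ccre_pairs` data.frame: `ccre_id`, `gene_id` and one signal
#'   column per cell type (states unset until [discretize_states()]).
#' @export
pair_ccres <- function(annotation, ccres, flank = 10000L,
                       containment = FALSE) {
  stopifnot(inherits(annotation, "annotation_set"),
            inherits(ccres, "ccre_table"))
  g <- annotation$genes
  cts <- attr(ccres, "cell_types")
  cc <- as.data.frame(ccres)
  nb <- .as_granges(g$chrom, pmax(g$start - flank, 0L), g$end + flank)
  cr <- .as_granges(cc$chrom, cc$start, cc$end)
  hits <- GenomicRanges::findOverlaps(
    cr, nb, type = if (containment) "within" else "any")
  ci <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- data.frame(ccre_id = cc$ccre_id[ci], gene_id = g$gene_id[gi],
                    stringsAsFactors = FALSE)
  for (ct in cts) out[[ct]] <- cc[[ct]][ci]
  attr(out, "cell_types") <- cts
  class(out) <- c("ccre_pairs", "data.frame")
  out
}

#' Discretize ATAC signals into H/M/L states and assign categories
#'
#' Applies a [signal_state_policy()] to each analysis cell type of a pair
#' table: state L when the signal is strictly below the low threshold, H when
#' at or above the high threshold, M in between. The 3-letter category string
#' concatenates the states in `cell_types` order (progenitor, then the two
#' daughters).
#'
#' @param pairs a `ccre_pairs` data.frame.
#' @param policy a [signal_state_policy()].
#' @param threshold_mode `"fixed"` uses the policy's high threshold;
#'   `"data_mean"` replaces it with the mean signal over all pairs and
#'   analysis cell types of `pairs` (the convention used to derive 8.6).
#' @param cell_types ordered trio of analysis cell types
#'   (default `c("MEP", "MEG", "ERY")`).
#' @return `pairs` with added `state_<cell type>` columns and `category`.
#' @export
discretize_states <- function(pairs, policy = signal_state_policy(),
                              threshold_mode = c("fixed", "data_mean"),
                              cell_types = c("MEP", "MEG", "ERY")) {
  stopifnot(inherits(pairs, "ccre_pairs"),
            inherits(policy, "signal_state_policy"))
  threshold_mode <- match.arg(threshold_mode)
  .check_cell_types(names(pairs), cell_types)
  hi <- policy$high_threshold
  if (threshold_mode == "data_mean") {
    hi <- mean(as.matrix(pairs[, cell_types, drop = FALSE]))
    if (!is.finite(hi) || hi <= policy$low_threshold)
      .stopf(paste0("data-mean high threshold (%g) is not above the low ",
                    "threshold (%g); signals are too weak to discretize"),
             hi, policy$low_threshold)
  }
  lo <- policy$low_threshold
  states <- lapply(cell_types, function(ct) {
    s <- pairs[[ct]]
    ifelse(s < lo, "L", ifelse(s >= hi, "H", "M"))
  })
  for (i in seq_along(cell_types))
    pairs[[paste0("state_", cell_types[i])]] <- states[[i]]
  pairs$category <- do.call(paste0, states)
  attr(pairs, "policy") <- signal_state_policy(lo, hi)
  attr(pairs, "analysis_cell_types") <- cell_types
  pairs
}

#' Tabulate cCRE-gene pairs over the 27 signal-state categories
#'
#' @param pairs a `ccre_pairs` table with states set.
#' @param gene_set optional character vector; restrict to pairs whose gene is
#'   in the set.
#' @return Named integer vector over exactly the 27 categories (zero-filled).
#' @export
tabulate_categories <- function(pairs, gene_set = NULL) {
  stopifnot(inherits(pairs, "ccre_pairs"))
  if (is.null(pairs$category)) .stopf("states unset; run discretize_states()")
  if (!is.null(gene_set))
    pairs <- pairs[pairs$gene_id %in% gene_set, , drop = FALSE]
  cats <- all_signal_categories()
  tab <- table(factor(pairs$category, levels = cats))
  stats::setNames(as.integer(tab), cats)
}

#' Informative category subsets for the two discordance hypotheses
#'
#' H1 (precocious actuation): categories whose accessibility state is
#' strictly higher in both the progenitor (MEP) and ERY than in MEG --
#' chromatin open in the progenitor for genes expressed only later in ERY.
#' H2 (RNA retention): categories with a low state in MEP but medium or high
#' in MEG -- stable RNA persisting in MEP after accessibility is lost.
#' States are ordered L < M < H; categories are `MEP,MEG,ERY` strings.
#'
#' @param hypothesis `"H1_precocious"` or `"H2_rna_retention"`.
#' @return Character vector of category strings.
#' @export
informative_subset <- function(hypothesis = c("H1_precocious",
                                              "H2_rna_retention")) {
  hypothesis <- match.arg(hypothesis)
  cats <- all_signal_categories()
  st <- function(i) .STATE_LEVELS[substr(cats, i, i)]
  keep <- switch(hypothesis,
    H1_precocious = st(1L) > st(2L) & st(3L) > st(2L),
    H2_rna_retention = st(1L) == .STATE_LEVELS[["L"]] &
      st(2L) >= .STATE_LEVELS[["M"]])
  cats[keep]
}

# Two-sided Fisher exact p for a 2x2 table, by summation of hypergeometric
# point probabilities not exceeding the observed one (with the conventional
# relative tolerance for ties).
.fisher_p_2x2 <- function(a, b, c, d, tol = 1e-7) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + tol)])
}

#' Odds-ratio enrichment test of an informative category subset
#'
#' Arranges pair counts in a 2x2 contingency table -- cluster pairs in/not in
#' the subset versus all-expressed-gene pairs in/not in the subset -- and
#' reports the sample (cross-product) odds ratio `ad/(bc)`, the Woolf
#' log-normal confidence interval
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, the exact two-sided
#' Fisher p-value, and the two percentages. By default the all-genes column
#' retains the cluster's pairs (the convention under which the study tables
#' reproduce); `cluster_excluded = TRUE` subtracts them for a
#' disjoint-column comparison.
#'
#' @param counts_cluster named counts over categories for the cluster's
#'   pairs (as from [tabulate_categories()]).
#' @param counts_all named counts over categories for all expressed genes'
#'   pairs.
#' @param subset character vector of informative categories.
#' @param conf_level confidence level for the Woolf interval (default 0.95).
#' @param cluster_excluded subtract the cluster's pairs from the comparison
#'   column (default `FALSE`).
#' @param or_method `"sample"` (cross-product estimate with Woolf CI, the
#'   default under which the study tables reproduce) or `"cmle"` (conditional
#'   maximum-likelihood estimate with the exact CI from [stats::fisher.test()]).
#' @return A `ccre_enrichment` object (printed like an htest): counts
#'   `a, b, c, d`, `odds_ratio`, `conf_int`, `p_value`, `percent_cluster`,
#'   `percent_all`.
#' @export
enrichment_test <- function(counts_cluster, counts_all, subset,
                            conf_level = 0.95, cluster_excluded = FALSE,
                            or_method = c("sample", "cmle")) {
  or_method <- match.arg(or_method)
  stopifnot(!is.null(names(counts_cluster)), !is.null(names(counts_all)))
  unknown <- setdiff(subset, names(counts_all))
  if (length(unknown) > 0L)
    .stopf("unknown categor%s: %s",
           if (length(unknown) > 1L) "ies" else "y",
           paste(unknown, collapse = ", "))
  a <- sum(counts_cluster[subset])
  b <- sum(counts_cluster) - a
  c_ <- sum(counts_all[subset])
  d <- sum(counts_all) - c_
  if (cluster_excluded) {
    c_ <- c_ - a
    d <- d - b
    if (c_ < 0 || d < 0)
      .stopf("cluster counts exceed the all-genes counts; not a subset")
  }
  flagged <- (a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0
  if (or_method == "cmle" && !flagged) {
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                             conf.level = conf_level)
    or <- unname(ft$estimate)
    ci <- as.numeric(ft$conf.int)
  } else {
    or <- (a * d) / (b * c_)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    if (a > 0 && b > 0 && c_ > 0 && d > 0) {
      se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
      ci <- exp(log(or) + c(-z, z) * se)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
  }
  p <- if (flagged) NA_real_ else .fisher_p_2x2(a, b, c_, d)
  structure(list(a = a, b = b, c = c_, d = d,
                 odds_ratio = or, conf_int = ci, conf_level = conf_level,
                 p_value = p,
                 percent_cluster = 100 * a / (a + b),
                 percent_all = 100 * c_ / (c_ + d),
                 degenerate = flagged,
                 cluster_excluded = cluster_excluded,
                 or_method = or_method),
            class = "ccre_enrichment")
}

#' @export
print.ccre_enrichment <- function(x, digits = 3L, ...) {
  cat("cCRE-gene pair enrichment (Fisher's exact test)\n")
  cat(sprintf("  2x2 counts: a=%d b=%d c=%d d=%d%s\n", x$a, x$b, x$c, x$d,
              if (x$cluster_excluded) " (cluster excluded from comparison)"
              else ""))
  cat(sprintf("  %% in subset: cluster %.1f vs all %.1f\n",
              x$percent_cluster, x$percent_all))
  if (x$degenerate) {
    cat("  odds ratio undefined (zero margin)\n")
  } else {
    cat(sprintf("  odds ratio %.*g, %d%% CI [%.*g, %.*g], p = %.3g\n",
                digits, x$odds_ratio, round(100 * x$conf_level),
                digits, x$conf_int[1L], digits, x$conf_int[2L], x$p_value))
  }
  invisible(x)
}

#' Run the full cCRE-gene discordance analysis
#'
#' Pairs cCREs with the expressed genes, discretizes signals into H/M/L
#' states, tabulates the 27 categories for all expressed genes and for each
#' candidate cluster, and tests both discordance hypotheses against each
#' cluster: precocious actuation (H1) for the ERY-only-like cluster and RNA
#' retention (H2) for the MEP-and-MEG-like cluster, plus the reciprocal
#' tests.
#'
#' @param annotation an `annotation_set`.
#' @param ccres a `ccre_table`.
#' @param clusters named list of gene-id vectors (e.g.
#'   `list(cluster10 = ..., cluster3 = ...)`); each must be a subset of
#'   `expressed_genes`.
#' @param expressed_genes character vector of genes expressed in at least one
#'   analysis cell type.
#' @param policy a [signal_state_policy()].
#' @param flank extension in bp for pairing (default 10000).
#' @param threshold_mode,cell_types passed to [discretize_states()].
#' @param cluster_excluded passed to [enrichment_test()].
#' @return A `discordance_analysis`: list with `pairs`, `category_counts`
#'   (all genes and per cluster), and `results` -- one `ccre_enrichment` per
#'   hypothesis x cluster.
#' @export
run_discordance <- function(annotation, ccres, clusters, expressed_genes,
                            policy = signal_state_policy(), flank = 10000L,
                            threshold_mode = "fixed",
                            cell_types = c("MEP", "MEG", "ERY"),
                            cluster_excluded = FALSE) {
  stopifnot(is.list(clusters), !is.null(names(clusters)))
  for (nm in names(clusters)) {
    extra <- setdiff(clusters[[nm]], expressed_genes)
    if (length(extra) > 0L)
      .stopf("cluster '%s' contains %d gene(s) outside the expressed set",
             nm, length(extra))
  }
  pairs <- pair_ccres(annotation, ccres, flank = flank)
  pairs <- discretize_states(pairs, policy, threshold_mode = threshold_mode,
                             cell_types = cell_types)
  counts <- list(all = tabulate_categories(pairs, expressed_genes))
  for (nm in names(clusters))
    counts[[nm]] <- tabulate_categories(pairs, clusters[[nm]])
  hyps <- c("H1_precocious", "H2_rna_retention")
  results <- list()
  for (h in hyps) {
    sub <- informative_subset(h)
    for (nm in names(clusters))
      results[[paste(h, nm, sep = ".")]] <-
        enrichment_test(counts[[nm]], counts$all, sub,
                        cluster_excluded = cluster_excluded)
  }
  structure(list(pairs = pairs, category_counts = counts, results = results,
                 policy = attr(pairs, "policy"), clusters = clusters),
            class = "discordance_analysis")
}

#' @export
print.discordance_analysis <- function(x, ...) {
  cat(sprintf(
    "discordance_analysis: %d cCRE-gene pairs; thresholds L < %g <= M < %g <= H\n",
    sum(x$category_counts$all), x$policy$low_threshold,
    x$policy$high_threshold))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-28s OR %.2f [%.2f, %.2f] p=%.3g\n", nm, r$odds_ratio,
                r$conf_int[1L], r$conf_int[2L], r$p_value))
  }
  invisible(x)
}

#' Replicate the packaged study contingency tables
#'
#' Recomputes the four hypothesis-by-cluster enrichment results from the
#' per-category pair counts packaged with this package (transcribed from the
#' study's printed tables), without touching sequencing data. The per-cluster
#' totals over all 27 categories are part of the packaged input because the
#' per-category fixture covers only the informative categories.
#'
#' @param counts_file,totals_file optional overrides for the packaged TSVs.
#' @return List of four `ccre_enrichment` objects named
#'   `<hypothesis>.<cluster>`, plus the `table1` 27-category counts.
#' @export
replicate_tables <- function(counts_file = NULL, totals_file = NULL) {
  if (is.null(counts_file))
    counts_file <- system.file("extdata", "table2_counts.tsv",
                               package = "mepdiverge", mustWork = TRUE)
  if (is.null(totals_file))
    totals_file <- system.file("extdata", "table2_totals.tsv",
                               package = "mepdiverge", mustWork = TRUE)
  t2 <- utils::read.delim(counts_file, stringsAsFactors = FALSE)
  tot <- utils::read.delim(totals_file, stringsAsFactors = FALSE)
  totals <- stats::setNames(tot$total_pairs, tot$gene_set)
  t1_file <- system.file("extdata", "table1_counts.tsv",
                         package = "mepdiverge", mustWork = TRUE)
  t1 <- utils::read.delim(t1_file, stringsAsFactors = FALSE)
  table1 <- stats::setNames(t1$count, t1$category)

  # Build full-length category count vectors: informative categories from the
  # fixture, the remainder lumped into one catch-all bin so that totals match.
  mk_counts <- function(col, total, subset_rows) {
    v <- stats::setNames(subset_rows[[col]], subset_rows$category)
    rest <- total - sum(v)
    c(v, OTHER = rest)
  }
  hyp_map <- c(H1 = "H1_precocious", H2 = "H2_rna_retention")
  out <- list(table1 = table1)
  for (h in names(hyp_map)) {
    rows <- t2[t2$hypothesis == h, , drop = FALSE]
    subset <- rows$category
    all_counts <- mk_counts("all_genes", totals[["all_genes"]], rows)
    for (cl in c("cluster10", "cluster3")) {
      cl_counts <- mk_counts(cl, totals[[cl]], rows)
      out[[paste(hyp_map[[h]], cl, sep = ".")]] <-
        enrichment_test(cl_counts, all_counts, subset)
    }
  }
  out
}
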