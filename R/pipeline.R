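# End-to-end orchestration: expression calls -> DE consensus -> TF occupancy
# enrichment -> cCRE discordance, assembled into a JSON-serializable report.

#' Run the full divergence analysis
#'
#' Executes the stages in order on a coherent set of inputs (most simply the
#' components of a [simulate_dataset()] result): expressed/silent calls and
#' the lineage-sharing partition; the pairwise and k-means DE category
#' routes and their consensus; TF-occupancy enrichment against the
#' non-differential background; and the cCRE signal-state discordance tests,
#' with the ERY-only-like (`NU`) and MEP-and-MEG-like (`ND`) consensus
#' categories as the candidate clusters.
#'
#' @param annotation an `annotation_set`.
#' @param expression an `expression_matrix` (>= 1 replicate per cell type of
#'   the trio).
#' @param de pairwise DE table (see [pairwise_categorize()]).
#' @param ccres a `ccre_table`, or `NULL` to skip the discordance stage.
#' @param peaks list of `peak_set` objects, or `NULL` to skip the occupancy
#'   stage.
#' @param cell_types ordered trio, progenitor first.
#' @param alpha FDR threshold(s) for the pairwise route.
#' @param k k-means cluster count (default 12); `NULL` scans 1..25 and picks
#'   the elbow.
#' @param delta cluster-to-category margin in log2 units.
#' @param policy [signal_state_policy()] for the discordance stage.
#' @param threshold_mode `"fixed"` or `"data_mean"` (default; the high
#'   threshold is a property of the dataset at hand).
#' @param flank neighborhood extension in bp.
#' @param seed seed for the clustering initialization.
#' @return A `divergence_report` list with sections `params`, `expression`,
#'   `de`, `tf`, `discordance`, and the underlying objects in `$objects`.
#' @export
run_pipeline <- function(annotation, expression, de, ccres = NULL,
                         peaks = NULL, cell_types = c("MEP", "MEG", "ERY"),
                         alpha = 0.05, k = 12L, delta = 1,
                         policy = signal_state_policy(),
                         threshold_mode = "data_mean", flank = 10000L,
                         seed = 1L) {
  comparisons <- paste0(cell_types[2:3], "_vs_", cell_types[1L])

  calls <- call_expressed(expression)
  sharing <- partition_sharing(calls, cell_types)
  expressed_genes <- rownames(calls$expressed)[
    rowSums(calls$expressed[, cell_types, drop = FALSE]) > 0L]

  pw <- pairwise_categorize(de, comparisons = comparisons, alpha = alpha)
  de_genes <- pw$gene_id[pw$label != "NN"]
  levels_mat <- calls$log2_level[, cell_types, drop = FALSE]
  km_model <- kmeans_cluster(levels_mat[de_genes, , drop = FALSE],
                             k_fixed = k, seed = seed)
  km <- clusters_to_categories(km_model, levels_mat, delta = delta,
                               cell_types = cell_types)
  km_full <- .new_de_categories(
    pw$gene_id,
    ifelse(pw$gene_id %in% km$gene_id,
           km$label[match(pw$gene_id, km$gene_id)], "NN"),
    "kmeans")
  cons <- consensus_categories(pw, km_full)
  background <- nondifferential_background(pw, km_full)

  tf_section <- NULL
  enr <- NULL
  if (!is.null(peaks) && length(peaks) > 0L) {
    enr <- do.call(rbind, lapply(peaks, function(p) {
      occ <- assign_peaks(annotation, p, flank = flank)
      occupancy_enrichment(occ, cons, background)
    }))
    rownames(enr) <- NULL
    tf_section <- enr
  }

  disc <- NULL
  if (!is.null(ccres)) {
    clusters <- list(
      cluster10 = intersect(cons$gene_id[cons$label == "NU"],
                            expressed_genes),
      cluster3 = intersect(cons$gene_id[cons$label == "ND"],
                           expressed_genes))
    disc <- run_discordance(annotation, ccres, clusters, expressed_genes,
                            policy = policy, flank = flank,
                            threshold_mode = threshold_mode,
                            cell_types = cell_types)
  }

  count_labels <- function(x)
    as.list(table(factor(x$label, levels = .DE_LABELS)))
  report <- list(
    params = list(cell_types = cell_types, alpha = alpha, k = k,
                  delta = delta, flank = flank,
                  low_threshold = policy$low_threshold,
                  high_threshold = if (!is.null(disc))
                    disc$policy$high_threshold else policy$high_threshold,
                  threshold_mode = threshold_mode, seed = seed,
                  noise_constant = expression$noise_constant,
                  expressed_threshold = expression$expressed_threshold),
    expression = list(
      expressed_per_cell_type = as.list(colSums(
        calls$expressed[, cell_types, drop = FALSE])),
      sharing = sharing$summary,
      sharing_counts = as.list(sharing$counts)),
    de = list(pairwise = count_labels(pw),
              kmeans = count_labels(km_full),
              consensus = count_labels(cons),
              n_background = length(background)),
    tf = tf_section,
    discordance = if (!is.null(disc)) list(
      category_counts = lapply(disc$category_counts, as.list),
      tests = lapply(disc$results, function(r)
        list(a = r$a, b = r$b, c = r$c, d = r$d,
             odds_ratio = r$odds_ratio,
             ci_low = r$conf_int[1L], ci_high = r$conf_int[2L],
             p_value = r$p_value,
             percent_cluster = r$percent_cluster,
             percent_all = r$percent_all))) else NULL,
    objects = list(calls = calls, sharing = sharing, pairwise = pw,
                   kmeans_model = km_model, kmeans = km_full,
                   consensus = cons, background = background,
                   enrichment = enr, discordance = disc))
  class(report) <- "divergence_report"
  report
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("divergence_report\n")
  cat("  expressed per cell type:",
      paste(sprintf("%s=%d", names(x$expression$expressed_per_cell_type),
                    unlist(x$expression$expressed_per_cell_type)),
            collapse = ", "), "\n")
  cat(sprintf("  DE genes: pairwise %d, consensus %d, background %d\n",
              sum(unlist(x$de$pairwise)) - x$de$pairwise$NN,
              sum(unlist(x$de$consensus)), x$de$n_background))
  if (!is.null(x$discordance)) {
    cat("  discordance tests:\n")
    for (nm in names(x$discordance$tests)) {
      t <- x$discordance$tests[[nm]]
      cat(sprintf("    %-28s OR %.2f [%.2f, %.2f]\n", nm, t$odds_ratio,
                  t$ci_low, t$ci_high))
    }
  }
  invisible(x)
}

#' Write a report bundle as JSON
#'
#' Serializes every section of a `divergence_report` except the heavyweight
#' `$objects` slot.
#' @param report a `divergence_report`.
#' @param path output JSON file.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "divergence_report"))
  out <- report[setdiff(names(report), "objects")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
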