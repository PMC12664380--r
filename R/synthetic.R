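# Seeded trilineage simulator: gene models, replicated FPKM matrix, upstream
# differential-expression table, cCREs with expression-coupled ATAC signals
# (plus injectable discordance), and archetype-dependent TF peaks, all with a
# ground-truth ledger.

#' Default expression archetypes
#'
#' Twelve archetypal expression patterns across the trio (progenitor MEP and
#' daughters MEG, ERY), transcribed qualitatively from the cluster shapes of
#' the study data: target log2 levels per cell type, mixture weight, and the
#' implied composite DE label. The silent baseline is 1.5 and the expressed
#' baseline 6 on the log2(FPKM + 1.1) scale (the expressed threshold is 3),
#' with differential archetypes shifted by 3 log2 units. `ery_only` /
#' `cluster10_strong` emulate the ERY-specific cluster used to probe
#' precocious actuation; `meg_retained` / `cluster3_strong` the MEP-and-MEG
#' cluster used to probe RNA retention.
#'
#' @param effect log2 shift of differential archetypes (default 3).
#' @return data.frame with columns `name`, `MEP`, `MEG`, `ERY`, `weight`,
#'   `label`.
#' @export
default_archetypes <- function(effect = 3) {
  base <- 6; silent <- 1.5; mid <- base - effect
  a <- rbind(
    data.frame(name = "silent",           MEP = silent, MEG = silent, ERY = silent, label = "NN"),
    data.frame(name = "constitutive",     MEP = base,   MEG = base,   ERY = base,   label = "NN"),
    data.frame(name = "meg_retained",     MEP = base,   MEG = base,   ERY = mid,    label = "ND"),
    data.frame(name = "ery_only",         MEP = mid,    MEG = mid,    ERY = base,   label = "NU"),
    data.frame(name = "meg_only",         MEP = mid,    MEG = base,   ERY = mid,    label = "UN"),
    data.frame(name = "mep_retained_ery", MEP = base,   MEG = mid,    ERY = base,   label = "DN"),
    data.frame(name = "both_down",        MEP = base + 1, MEG = mid + 1, ERY = mid + 1, label = "DD"),
    data.frame(name = "both_up",          MEP = mid,    MEG = base,   ERY = base,   label = "UU"),
    data.frame(name = "up_meg_down_ery",  MEP = 5,      MEG = 5 + effect, ERY = 5 - effect, label = "UD"),
    data.frame(name = "down_meg_up_ery",  MEP = 5,      MEG = 5 - effect, ERY = 5 + effect, label = "DU"),
    data.frame(name = "cluster3_strong",  MEP = base + 0.5, MEG = base + 0.5, ERY = silent, label = "ND"),
    data.frame(name = "cluster10_strong", MEP = silent, MEG = silent, ERY = base + 0.5, label = "NU")
  )
  a$weight <- ifelse(a$name == "silent", 0.30,
                     ifelse(a$name == "constitutive", 0.14, 0.056))
  a
}

#' Simulation configuration
#'
#' Bundles every knob of the trilineage simulator. Defaults emulate the study
#' conditions at desk scale: 2000 genes, replicate noise of 0.5 log2 units,
#' differential effects of 3 log2 units, a Poisson mean of 6.4 cCREs per gene
#' (the study's pairs-per-expressed-gene ratio), and ATAC signals drawn per
#' state from truncated normals on the `-log10 p` scale (L mean 0.4, M mean
#' 4, H mean 12, sd 1.5, floored at 0).
#'
#' @param n_genes number of genes.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param archetypes archetype table as from [default_archetypes()]; weights
#'   must sum to 1.
#' @param fpkm_noise_sd replicate noise sd on the log2 scale.
#' @param ccre_rate Poisson mean of cCREs per gene.
#' @param signal_params list with `mean` (named `L`, `M`, `H`) and `sd`.
#' @param f_precocious fraction of ERY-only genes whose MEP cCRE signals are
#'   drawn from the high-state distribution (hypothesis-1 injection).
#' @param f_retention fraction of MEP-and-MEG genes whose MEP cCRE signals
#'   are drawn from the low-state distribution (hypothesis-2 injection).
#' @param tf_occ_probs named list per TF: list with `cell_type`, `baseline`
#'   occupancy probability, and optional named `per_archetype` overrides.
#'   The default plants one progenitor-cell TF at 0.2 baseline with 0.8 in
#'   the `meg_only` archetype (a 4-fold occupancy enrichment).
#' @param noise_constant,expressed_threshold passed to the expression matrix.
#' @param flank neighborhood extension used to place cCREs and peaks.
#' @param gene_length_range min/max simulated gene length (bp).
#' @param min_spacing minimum gap between adjacent genes (bp; keeps flanked
#'   neighborhoods unambiguous at the default flank).
#' @param seed integer seed; the simulation is a pure function of the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L,
                              chrom_sizes = c(chr1 = 25e6, chr2 = 25e6,
                                              chr3 = 25e6, chr4 = 25e6),
                              archetypes = default_archetypes(),
                              fpkm_noise_sd = 0.5,
                              ccre_rate = 6.4,
                              signal_params = list(
                                mean = c(L = 0.4, M = 4, H = 12), sd = 1.5),
                              f_precocious = 0,
                              f_retention = 0,
                              tf_occ_probs = list(
                                TF1 = list(cell_type = "prog", baseline = 0.2,
                                           per_archetype = c(meg_only = 0.8))),
                              noise_constant = 1.1,
                              expressed_threshold = 3,
                              flank = 10000L,
                              gene_length_range = c(2000L, 10000L),
                              min_spacing = 25000L,
                              seed = 1L) {
  stopifnot(abs(sum(archetypes$weight) - 1) < 1e-8,
            f_precocious >= 0, f_precocious <= 1,
            f_retention >= 0, f_retention <= 1,
            ccre_rate > 0)
  structure(list(n_genes = as.integer(n_genes), chrom_sizes = chrom_sizes,
                 archetypes = archetypes, fpkm_noise_sd = fpkm_noise_sd,
                 ccre_rate = ccre_rate, signal_params = signal_params,
                 f_precocious = f_precocious, f_retention = f_retention,
                 tf_occ_probs = tf_occ_probs,
                 noise_constant = noise_constant,
                 expressed_threshold = expressed_threshold,
                 flank = as.integer(flank),
                 gene_length_range = as.integer(gene_length_range),
                 min_spacing = as.integer(min_spacing),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.place_genes <- function(cfg) {
  n <- cfg$n_genes
  lens <- sample(seq(cfg$gene_length_range[1L], cfg$gene_length_range[2L]),
                 n, replace = TRUE)
  chrom <- character(n); start <- integer(n)
  ci <- 1L; cur <- 5000L
  sizes <- cfg$chrom_sizes
  for (i in seq_len(n)) {
    while (cur + lens[i] + cfg$min_spacing > sizes[[ci]]) {
      ci <- ci + 1L
      if (ci > length(sizes))
        .stopf("chromosomes too small for %d genes at %d bp spacing",
               n, cfg$min_spacing)
      cur <- 5000L
    }
    chrom[i] <- names(sizes)[ci]
    start[i] <- cur
    cur <- cur + lens[i] + cfg$min_spacing
  }
  data.frame(chrom = chrom, start = start, end = start + lens,
             stringsAsFactors = FALSE)
}

#' Simulate a trilineage multi-omic dataset with ground truth
#'
#' Draws an archetype per gene, places non-overlapping gene models, generates
#' a replicated FPKM matrix (`FPKM = 2^(level + noise) - eps`, floored at 0),
#' an upstream-style differential-expression table (known-variance z-test on
#' the replicate means, BH-adjusted), cCREs whose per-cell-type signals
#' follow the gene's expressed/silent truth (high-state vs low-state
#' distributions) with the two discordance injections overriding MEP signals
#' for flagged gene fractions, and TF peak sets placed in gene neighborhoods
#' with archetype-dependent occupancy probabilities. Byte-identical outputs
#' under an identical config (including its seed).
#'
#' @param cfg a [simulation_config()].
#' @return A `sim_dataset`: list with `annotation` (annotation_set),
#'   `expression` (expression_matrix, 2 replicates x 3 cell types), `de`
#'   (pairwise DE table), `ccres` (ccre_table), `peaks` (list of peak_set),
#'   `truth` (per-gene and per-cCRE ledger plus the config echo).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  cts <- c("MEP", "MEG", "ERY")
  arch <- cfg$archetypes
  n <- cfg$n_genes

  gene_arch <- sample(arch$name, n, replace = TRUE, prob = arch$weight)
  ai <- match(gene_arch, arch$name)
  levels_true <- as.matrix(arch[ai, cts])
  dimnames(levels_true) <- list(NULL, cts)

  loc <- .place_genes(cfg)
  gene_id <- sprintf("g%05d", seq_len(n))
  genes <- data.frame(
    gene_id = gene_id,
    transcript_id = paste0(gene_id, ".t1"),
    chrom = loc$chrom, start = loc$start, end = loc$end,
    strand = rep_len(c("+", "-"), n),
    exon_count = sample(1:10, n, replace = TRUE),
    cds_length = as.integer(round(0.5 * (loc$end - loc$start))),
    transcript_length = loc$end - loc$start,
    stringsAsFactors = FALSE)
  annotation <- .new_annotation_set(genes, .empty_excluded_df())

  # Expression: two independent replicate draws per cell type.
  eps <- cfg$noise_constant
  samples <- expand.grid(replicate = c("r1", "r2"), cell_type = cts,
                         stringsAsFactors = FALSE)[, 2:1]
  sample_id <- paste(samples$cell_type, samples$replicate, sep = "_")
  vals <- matrix(0, n, nrow(samples), dimnames = list(gene_id, sample_id))
  for (j in seq_len(nrow(samples))) {
    lev <- levels_true[, samples$cell_type[j]] +
      stats::rnorm(n, 0, cfg$fpkm_noise_sd)
    vals[, j] <- pmax(2^lev - eps, 0)
  }
  expr <- expression_matrix(vals,
                            samples = data.frame(sample_id = sample_id,
                                                 cell_type = samples$cell_type,
                                                 replicate = samples$replicate,
                                                 stringsAsFactors = FALSE),
                            noise_constant = eps,
                            expressed_threshold = cfg$expressed_threshold)

  # Upstream-style DE table: z-test with the known replicate noise sd.
  calls <- call_expressed(expr)
  ll <- log_transform(expr)
  mean_ct <- vapply(cts, function(ct)
    rowMeans(ll[, sample_id[samples$cell_type == ct], drop = FALSE]),
    numeric(n))
  de <- do.call(rbind, lapply(c(MEG = "MEG", ERY = "ERY"), function(d) {
    diffv <- mean_ct[, d] - mean_ct[, "MEP"]
    z <- diffv / cfg$fpkm_noise_sd          # se of a 2-vs-2 mean difference
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(gene_id = gene_id,
               comparison = paste0(d, "_vs_MEP"),
               log2fc = diffv,
               q_value = stats::p.adjust(p, "BH"),
               expressed_either = calls$expressed[, d] |
                 calls$expressed[, "MEP"],
               stringsAsFactors = FALSE)
  }))
  rownames(de) <- NULL

  # Discordance injections.
  expr_true <- levels_true > cfg$expressed_threshold
  elig_prec <- which(!expr_true[, "MEP"] & !expr_true[, "MEG"] &
                       expr_true[, "ERY"])
  elig_ret <- which(expr_true[, "MEP"] & expr_true[, "MEG"] &
                      !expr_true[, "ERY"])
  flag_prec <- logical(n)
  flag_ret <- logical(n)
  if (length(elig_prec) > 0L && cfg$f_precocious > 0) {
    take <- sample.int(length(elig_prec),
                       round(cfg$f_precocious * length(elig_prec)))
    flag_prec[elig_prec[take]] <- TRUE
  }
  if (length(elig_ret) > 0L && cfg$f_retention > 0) {
    take <- sample.int(length(elig_ret),
                       round(cfg$f_retention * length(elig_ret)))
    flag_ret[elig_ret[take]] <- TRUE
  }

  # cCREs: Poisson count per gene, uniform positions in the flanked span.
  n_cc <- stats::rpois(n, cfg$ccre_rate)
  owner <- rep.int(seq_len(n), n_cc)
  total_cc <- length(owner)
  cc_width <- 200L
  lo <- pmax(genes$start[owner] - cfg$flank, 0L)
  hi <- genes$end[owner] + cfg$flank - cc_width
  cc_start <- lo + floor(stats::runif(total_cc) * pmax(hi - lo, 1L))
  sp <- cfg$signal_params
  state_truth <- matrix("", total_cc, 3L, dimnames = list(NULL, cts))
  sig <- matrix(0, total_cc, 3L, dimnames = list(NULL, cts))
  for (ct in cts) {
    st <- ifelse(expr_true[owner, ct], "H", "L")
    if (ct == "MEP") {
      st[flag_prec[owner]] <- "H"
      st[flag_ret[owner]] <- "L"
    }
    state_truth[, ct] <- st
    sig[, ct] <- pmax(stats::rnorm(total_cc, sp$mean[st], sp$sd), 0)
  }
  cc_df <- data.frame(
    ccre_id = sprintf("cc%06d", seq_len(total_cc)),
    chrom = genes$chrom[owner],
    start = as.integer(cc_start),
    end = as.integer(cc_start + cc_width),
    stringsAsFactors = FALSE)
  for (ct in cts) cc_df[[ct]] <- sig[, ct]
  ccres <- ccre_table(cc_df, cts)

  # TF peaks with archetype-dependent occupancy probabilities.
  peaks <- list()
  occ_truth <- list()
  for (tf in names(cfg$tf_occ_probs)) {
    spec <- cfg$tf_occ_probs[[tf]]
    prob <- rep(spec$baseline, n)
    if (!is.null(spec$per_archetype)) {
      ov <- spec$per_archetype
      hit <- gene_arch %in% names(ov)
      prob[hit] <- ov[gene_arch[hit]]
    }
    occupied <- stats::runif(n) < prob
    idx <- which(occupied)
    pk_w <- 300L
    plo <- pmax(genes$start[idx] - cfg$flank, 0L)
    phi <- genes$end[idx] + cfg$flank - pk_w
    pstart <- plo + floor(stats::runif(length(idx)) * pmax(phi - plo, 1L))
    peaks[[tf]] <- peak_set(tf, spec$cell_type,
                            data.frame(chrom = genes$chrom[idx],
                                       start = as.integer(pstart),
                                       end = as.integer(pstart + pk_w),
                                       stringsAsFactors = FALSE))
    occ_truth[[tf]] <- occupied
  }

  truth <- list(
    genes = data.frame(gene_id = gene_id, archetype = gene_arch,
                       label = arch$label[ai],
                       expressed_MEP = expr_true[, "MEP"],
                       expressed_MEG = expr_true[, "MEG"],
                       expressed_ERY = expr_true[, "ERY"],
                       precocious = flag_prec, retention = flag_ret,
                       stringsAsFactors = FALSE),
    ccres = data.frame(ccre_id = cc_df$ccre_id, gene_id = gene_id[owner],
                       state_MEP = state_truth[, "MEP"],
                       state_MEG = state_truth[, "MEG"],
                       state_ERY = state_truth[, "ERY"],
                       stringsAsFactors = FALSE),
    occupancy = occ_truth,
    config = cfg)

  structure(list(annotation = annotation, expression = expr, de = de,
                 ccres = ccres, peaks = peaks, truth = truth, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: %d genes, %d cCREs, %d TF track(s) (seed %d)\n",
    nrow(x$truth$genes), nrow(x$truth$ccres), length(x$peaks),
    x$config$seed))
  invisible(x)
}

#' Evaluate pipeline outputs against simulation truth
#'
#' Compares recovered quantities with the generator's ledger: a composite
#' DE-label confusion matrix and accuracy (genes without a recovered label
#' count as `NN`), the error of TF-occupancy enrichment scores against the
#' planted log2 effects, and the hypothesis odds ratios alongside the
#' injected discordance fractions.
#'
#' @param truth the `truth` component of a `sim_dataset`.
#' @param categories optional `de_categories` (any source).
#' @param enrichment optional enrichment data.frame from
#'   [occupancy_enrichment()] for one TF track.
#' @param discordance optional `discordance_analysis`.
#' @return List with `confusion`, `accuracy`, `enrichment` (observed score,
#'   planted log2 effect, error per category), and `or_panel`.
#' @export
truth_evaluate <- function(truth, categories = NULL, enrichment = NULL,
                           discordance = NULL) {
  out <- list()
  if (!is.null(categories)) {
    stopifnot(inherits(categories, "de_categories"))
    extra <- setdiff(categories$gene_id, truth$genes$gene_id)
    if (length(extra) > 0L)
      .stopf("categories contain %d gene(s) unknown to the truth ledger",
             length(extra))
    pred <- categories$label[match(truth$genes$gene_id, categories$gene_id)]
    pred[is.na(pred)] <- "NN"
    confusion <- table(truth = factor(truth$genes$label, .DE_LABELS),
                       predicted = factor(pred, .DE_LABELS))
    out$confusion <- confusion
    out$accuracy <- sum(diag(confusion)) / sum(confusion)
  }
  if (!is.null(enrichment)) {
    tf <- enrichment$tf_name[1L]
    spec <- truth$config$tf_occ_probs[[tf]]
    if (is.null(spec)) .stopf("TF '%s' unknown to the truth ledger", tf)
    arch <- truth$config$archetypes
    prob_of_arch <- rep(spec$baseline, nrow(arch))
    names(prob_of_arch) <- arch$name
    if (!is.null(spec$per_archetype))
      prob_of_arch[names(spec$per_archetype)] <- spec$per_archetype
    # planted effect per DE label: mean occupancy prob of its archetypes
    # (weight-averaged) over the baseline
    planted <- vapply(enrichment$category, function(lab) {
      rows <- arch$label == lab
      p <- sum(prob_of_arch[arch$name[rows]] * arch$weight[rows]) /
        sum(arch$weight[rows])
      log2(p / spec$baseline)
    }, 0)
    out$enrichment <- data.frame(category = enrichment$category,
                                 observed = enrichment$score,
                                 planted = unname(planted),
                                 error = enrichment$score - unname(planted))
  }
  if (!is.null(discordance)) {
    out$or_panel <- data.frame(
      test = names(discordance$results),
      odds_ratio = vapply(discordance$results, `[[`, 0, "odds_ratio"),
      p_value = vapply(discordance$results, `[[`, 0, "p_value"),
      f_precocious = truth$config$f_precocious,
      f_retention = truth$config$f_retention,
      row.names = NULL)
  }
  out
}
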