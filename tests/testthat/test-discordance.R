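# cCRE-gene pairing, signal-state discretization, 27-category tabulation,
# informative subsets, and the odds-ratio enrichment test.

mk_ccres <- function(chrom, start, end, mep, meg, ery,
                     id = sprintf("cc%03d", seq_along(start))) {
  df <- data.frame(ccre_id = id, chrom = chrom, start = start, end = end,
                   MEP = mep, MEG = meg, ERY = ery, stringsAsFactors = FALSE)
  ccre_table(df, c("MEP", "MEG", "ERY"))
}

test_that("cCREs pair with genes through the 10 kb flank, possibly multiply", {
  ann <- make_annotation(c("chr1", "chr1"), c(50000L, 62000L),
                         c(60000L, 63000L))
  cc <- mk_ccres("chr1", 41000L, 41200L, 1, 1, 1)
  pr <- pair_ccres(ann, cc)
  expect_equal(pr$gene_id, "g001")      # within 10 kb upstream

  # one cCRE between two genes, within the flank of both -> two pairs
  cc2 <- mk_ccres("chr1", 61000L, 61200L, 1, 1, 1)
  pr2 <- pair_ccres(ann, cc2)
  expect_setequal(pr2$gene_id, c("g001", "g002"))
  expect_equal(nrow(pr2), 2L)

  # containment mode requires the cCRE fully inside the extended span
  cc3 <- mk_ccres("chr1", 39900L, 40100L, 1, 1, 1)   # straddles the boundary
  expect_equal(nrow(pair_ccres(ann, cc3)), 1L)
  expect_equal(nrow(pair_ccres(ann, cc3, containment = TRUE)), 0L)
})

test_that("pairing equals the quadratic all-pairs interval oracle", {
  set.seed(29)
  g <- random_intervals(40)
  ann <- make_annotation(g$chrom, g$start, g$end)
  cc_iv <- random_intervals(150, min_w = 100L, max_w = 400L)
  cc <- mk_ccres(cc_iv$chrom, cc_iv$start, cc_iv$end,
                 runif(150) * 15, runif(150) * 15, runif(150) * 15,
                 id = sprintf("cc%04d", 1:150))
  pr <- pair_ccres(ann, cc, flank = 10000L)
  ag <- ann$genes
  want <- 0L
  for (i in seq_len(nrow(ag))) {
    hits <- overlaps0(ag$chrom[i], max(ag$start[i] - 10000L, 0L),
                      ag$end[i] + 10000L, cc_iv$chrom, cc_iv$start, cc_iv$end)
    want <- want + sum(hits)
    expect_setequal(pr$ccre_id[pr$gene_id == ag$gene_id[i]],
                    cc$ccre_id[hits])
  }
  expect_equal(nrow(pr), want)
})

test_that("signal discretization honors the boundary conventions", {
  ann <- make_annotation("chr1", 50000L, 60000L)
  cc <- mk_ccres(rep("chr1", 4), rep(55000L, 4), rep(55200L, 4),
                 mep = c(0.5, 8.6, 1.3, 1.29),
                 meg = c(9.0, 8.6, 1.3, 1.29),
                 ery = c(2.0, 8.6, 1.3, 1.29))
  pr <- discretize_states(pair_ccres(ann, cc), signal_state_policy(1.3, 8.6))
  expect_equal(pr$category[pr$ccre_id == "cc001"], "LHM")
  expect_equal(pr$category[pr$ccre_id == "cc002"], "HHH")  # 8.6 is H
  expect_equal(pr$category[pr$ccre_id == "cc003"], "MMM")  # 1.3 is M
  expect_equal(pr$category[pr$ccre_id == "cc004"], "LLL")  # 1.29 is L

  # 1000 random signals equal the one-line comparison oracle
  set.seed(31)
  s <- matrix(runif(3000) * 12, 1000, 3)
  cc2 <- mk_ccres(rep("chr1", 1000), rep(55000L, 1000), rep(55200L, 1000),
                  s[, 1], s[, 2], s[, 3], id = sprintf("cc%04d", 1:1000))
  pr2 <- discretize_states(pair_ccres(ann, cc2), signal_state_policy(1.3, 8.6))
  pr2 <- pr2[match(cc2$ccre_id, pr2$ccre_id), ]
  oracle <- apply(s, 2, function(x)
    ifelse(x < 1.3, "L", ifelse(x >= 8.6, "H", "M")))
  expect_equal(pr2$category, paste0(oracle[, 1], oracle[, 2], oracle[, 3]))

  # data_mean mode recomputes the high threshold from the pairs themselves
  pr3 <- discretize_states(pair_ccres(ann, cc2), threshold_mode = "data_mean")
  expect_equal(attr(pr3, "policy")$high_threshold, mean(s))
  expect_error(signal_state_policy(8.6, 1.3), "low_threshold")
})

test_that("category tabulation covers exactly 27 zero-filled keys and conserves pairs", {
  ann <- make_annotation("chr1", 50000L, 60000L)
  cc0 <- mk_ccres(character(), integer(), integer(),
                  numeric(), numeric(), numeric(), id = character())
  pr0 <- discretize_states(pair_ccres(ann, cc0))
  t0 <- tabulate_categories(pr0)
  expect_length(t0, 27L)
  expect_named(t0, all_signal_categories())
  expect_true(all(t0 == 0L))

  set.seed(41)
  planted <- sample(all_signal_categories(), 500, replace = TRUE,
                    prob = runif(27))
  sig_of <- function(st) c(L = 0.5, M = 5, H = 10)[st]
  cc <- mk_ccres(rep("chr1", 500), rep(55000L, 500), rep(55200L, 500),
                 sig_of(substr(planted, 1, 1)),
                 sig_of(substr(planted, 2, 2)),
                 sig_of(substr(planted, 3, 3)),
                 id = sprintf("cc%04d", 1:500))
  pr <- discretize_states(pair_ccres(ann, cc), signal_state_policy(1.3, 8.6))
  tab <- tabulate_categories(pr)
  expect_equal(tab, counts_from_categories(planted))
  expect_equal(sum(tab), 500L)
  # gene_set restriction: the only gene vs a disjoint set
  expect_equal(sum(tabulate_categories(pr, "g001")), 500L)
  expect_equal(sum(tabulate_categories(pr, "nope")), 0L)
})

test_that("informative subsets match the printed blocks and the brute-force predicate", {
  h1 <- informative_subset("H1_precocious")
  h2 <- informative_subset("H2_rna_retention")
  expect_setequal(h1, c("HLH", "HLM", "HMH", "MLH", "MLM"))
  expect_setequal(h2, c("LHH", "LHL", "LHM", "LMH", "LML", "LMM"))
  expect_length(intersect(h1, h2), 0L)   # disjoint by construction

  # exhaustive predicate over all 27 categories
  rank <- c(L = 1, M = 2, H = 3)
  cats <- all_signal_categories()
  st <- function(i) rank[substr(cats, i, i)]
  expect_setequal(h1, cats[st(1) > st(2) & st(3) > st(2)])
  expect_setequal(h2, cats[st(1) == 1 & st(2) >= 2])
  expect_error(informative_subset("H3"), "arg")
})

test_that("the enrichment test reproduces the odds ratio, Woolf CI and percents", {
  # counts from the H1 / ERY-only-cluster contingency table of the study
  cats <- all_signal_categories()
  sub <- informative_subset("H1_precocious")
  mk_counts <- function(inside, total) {
    v <- setNames(rep(0, 27), cats)
    v[sub[1]] <- inside
    v["MMM"] <- total - inside
    v
  }
  r <- enrichment_test(mk_counts(1050, 5223), mk_counts(4976, 48701), sub)
  expect_equal(c(r$a, r$b, r$c, r$d), c(1050, 4173, 4976, 43725))
  expect_equal(round(r$odds_ratio, 2), 2.21)
  expect_equal(round(r$conf_int, 2), c(2.05, 2.38))
  expect_equal(round(r$percent_cluster, 1), 20.1)
  expect_equal(round(r$percent_all, 1), 10.2)
  expect_lt(r$p_value, 1e-10)

  # equal proportions give OR exactly 1 with a CI containing 1
  r1 <- enrichment_test(mk_counts(100, 1000), mk_counts(400, 4000), sub)
  expect_equal(r1$odds_ratio, 1.0)
  expect_lt(r1$conf_int[1], 1)
  expect_gt(r1$conf_int[2], 1)

  # degenerate margin flagged
  r0 <- enrichment_test(mk_counts(0, 0), mk_counts(10, 100), sub)
  expect_true(r0$degenerate)

  # cluster-excluded variant subtracts the cluster from the comparison
  rx <- enrichment_test(mk_counts(100, 1000), mk_counts(400, 4000), sub,
                        cluster_excluded = TRUE)
  expect_equal(c(rx$c, rx$d), c(300, 2700))

  # conditional-MLE variant agrees with fisher.test on estimate and CI
  rc <- enrichment_test(mk_counts(30, 100), mk_counts(90, 600), sub,
                        or_method = "cmle")
  ft <- stats::fisher.test(matrix(c(30, 70, 90, 510), 2, byrow = TRUE))
  expect_equal(rc$odds_ratio, unname(ft$estimate))
  expect_equal(rc$conf_int, as.numeric(ft$conf.int))
  expect_equal(rc$p_value, ft$p.value, tolerance = 1e-9)
})

test_that("the Fisher p-value equals hypergeometric enumeration and fisher.test", {
  # spot enumeration for the (3,7,5,5) example
  p_impl <- mepdiverge:::.fisher_p_2x2(3, 7, 5, 5)
  enum <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c
    x <- max(0, k - r2):min(k, r1)
    pr <- choose(r1, x) * choose(r2, k - x) / choose(r1 + r2, k)
    sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
  }
  expect_equal(p_impl, enum(3, 7, 5, 5), tolerance = 1e-12)

  set.seed(53)
  for (i in 1:50) {
    t <- rmultinom(1, sample(8:60, 1), runif(4))[, 1]
    expect_equal(mepdiverge:::.fisher_p_2x2(t[1], t[2], t[3], t[4]),
                 enum(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
    expect_equal(mepdiverge:::.fisher_p_2x2(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(matrix(t, 2))$p.value, tolerance = 1e-9)
  }
})

test_that("run_discordance wires the stages and self-comparison gives OR 1", {
  sim <- simulate_dataset(simulation_config(n_genes = 400L, seed = 61L))
  calls <- call_expressed(sim$expression)
  expressed <- rownames(calls$expressed)[rowSums(calls$expressed) > 0]
  d <- run_discordance(sim$annotation, sim$ccres,
                       list(all = expressed), expressed,
                       threshold_mode = "data_mean")
  for (r in d$results) expect_equal(r$odds_ratio, 1.0)
  # conservation: the 27 counts sum to the number of pairs for every set
  expect_equal(sum(d$category_counts$all),
               sum(d$pairs$gene_id %in% expressed))
  expect_error(
    run_discordance(sim$annotation, sim$ccres,
                    list(bad = c(expressed[1], "ghost")), expressed),
    "outside")
})

test_that("injected precocious actuation raises the H1 odds ratio of the ERY-only cluster", {
  or_at <- function(f) {
    sim <- simulate_dataset(simulation_config(n_genes = 800L,
                                              f_precocious = f, seed = 71L))
    tg <- sim$truth$genes
    calls <- call_expressed(sim$expression)
    expressed <- rownames(calls$expressed)[rowSums(calls$expressed) > 0]
    cl <- intersect(tg$gene_id[!tg$expressed_MEP & !tg$expressed_MEG &
                                 tg$expressed_ERY], expressed)
    d <- run_discordance(sim$annotation, sim$ccres, list(c10 = cl),
                         expressed, threshold_mode = "data_mean")
    d$results$H1_precocious.c10
  }
  r0 <- or_at(0)
  r5 <- or_at(0.5)
  expect_gt(r5$odds_ratio, r0$odds_ratio)
  expect_gt(r5$odds_ratio, 1)
  expect_lt(r5$p_value, 0.001)
})
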