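# Log transformation, expressed/silent calls, sharing partition, globin
# extrapolation, pseudoreplicates, and replicate concordance.

mat_from <- function(vals, n_genes, samples) {
  matrix(vals, n_genes, length(samples),
         dimnames = list(paste0("g", seq_len(n_genes)), samples),
         byrow = TRUE)
}

test_that("log transform applies the noise constant and inverts algebraically", {
  m <- expression_matrix(
    mat_from(c(0, 6.9, 100, 3), 2, c("MEP_r1", "MEP_r2")))
  ll <- log_transform(m)
  # FPKM 0 maps to the documented floor level
  expect_equal(round(ll[1, 1], 4), 0.1375)
  # FPKM 6.9 with eps = 1.1 is exactly log2(8) = 3
  expect_identical(ll[1, 2], 3)

  set.seed(42)
  vals <- matrix(rexp(60) * 20, 10, 6,
                 dimnames = list(paste0("g", 1:10),
                                 paste0(rep(c("MEP", "MEG", "ERY"),
                                            each = 2), "_r", 1:2)))
  m2 <- expression_matrix(vals)
  back <- 2^log_transform(m2) - m2$noise_constant
  expect_true(max(abs(back - vals)) < 1e-9)
  # strict monotonicity in FPKM
  x <- sort(runif(50) * 100)
  mx <- expression_matrix(matrix(x, ncol = 1,
                                 dimnames = list(paste0("g", 1:50), "A_r1")))
  expect_true(all(diff(log_transform(mx)[, 1]) > 0))
})

test_that("expressed calls use a strict threshold on the pooled level", {
  # pooled FPKMs chosen so pooled log2 levels are exactly 3, just above, below
  f_at <- 2^3 - 1.1      # level exactly tau
  f_up <- 2^3.01 - 1.1
  f_dn <- 2^2.9 - 1.1
  vals <- mat_from(c(f_at, f_at, f_up, f_up, f_dn, f_dn), 3,
                   c("MEP_r1", "MEP_r2"))
  calls <- call_expressed(expression_matrix(vals))
  expect_identical(unname(calls$expressed[, "MEP"]), c(FALSE, TRUE, FALSE))
  expect_equal(unname(calls$log2_level[1, "MEP"]), 3)

  # calls equal the elementwise comparison oracle on a random matrix
  set.seed(11)
  vals2 <- matrix(rexp(30) * 30, 10, 3,
                  dimnames = list(paste0("g", 1:10),
                                  c("MEP_r1", "MEG_r1", "ERY_r1")))
  m2 <- expression_matrix(vals2)
  calls2 <- call_expressed(m2)
  oracle <- log2(vals2 + 1.1) > 3
  colnames(oracle) <- c("MEP", "MEG", "ERY")
  expect_identical(calls2$expressed, oracle)
})

test_that("an upstream pooled-FPKM table overrides the replicate mean", {
  vals <- mat_from(c(100, 100, 1, 1), 2, c("MEP_r1", "MEP_r2"))
  pooled <- matrix(c(1, 100), 2, 1,
                   dimnames = list(rownames(vals), "MEP"))
  calls <- call_expressed(expression_matrix(vals), pooled_fpkm = pooled)
  expect_identical(unname(calls$expressed[, "MEP"]), c(FALSE, TRUE))
  expect_equal(unname(calls$log2_level[, "MEP"]), log2(c(1, 100) + 1.1))
})

test_that("per-replicate pooling requires every replicate above threshold", {
  vals <- mat_from(c(100, 1, 100, 100), 2, c("MEP_r1", "MEP_r2"))
  m <- expression_matrix(vals)
  calls <- call_expressed(m, pooling = "per_replicate")
  expect_identical(unname(calls$expressed[, "MEP"]), c(FALSE, TRUE))
})

test_that("sharing partition is exhaustive, disjoint, and matches construction", {
  set.seed(3)
  cts <- c("MEP", "MEG", "ERY")
  # plant known classes for 100 genes
  classes <- sample(0:7, 100, replace = TRUE)  # bitmask over the trio
  planted <- t(vapply(classes, function(k)
    as.logical(bitwAnd(k, c(1L, 2L, 4L))), logical(3)))
  colnames(planted) <- cts
  # FPKM high where expressed, 0 where silent
  fpkm <- ifelse(planted, 200, 0)
  colnames(fpkm) <- paste0(cts, "_r1")
  rownames(fpkm) <- sprintf("g%03d", 1:100)
  calls <- call_expressed(expression_matrix(fpkm))
  part <- partition_sharing(calls, cts)

  expect_equal(sum(part$counts), 100)                 # exhaustive
  expect_equal(length(part$membership), 100)          # one class per gene
  expect_equal(part$summary$expressed_any, sum(classes != 0))
  expect_equal(part$summary$exactly_one,
               sum(rowSums(planted) == 1))
  expect_equal(part$summary$all_three, sum(classes == 7))
  expect_equal(part$counts[["MEP+MEG"]],
               sum(planted[, 1] & planted[, 2] & !planted[, 3]))
  expect_equal(part$summary$expressed_any,
               100 - part$counts[["none"]])
  # all genes silent -> expressed-in-any is zero
  silent <- expression_matrix(mat_from(rep(0, 3), 1,
                                       paste0(cts, "_r1")))
  p0 <- partition_sharing(call_expressed(silent), cts)
  expect_equal(p0$summary$expressed_any, 0)
})

test_that("globin extrapolation follows the count/FPKM ratio and is scale-consistent", {
  # ratio 4000/2000 = 2 -> globin count 500 becomes FPKM 250
  ref <- data.frame(count = rep(200, 20), fpkm = rep(100, 20))
  est <- estimate_globin_fpkm(c(Hba = 500), ref, n_top = 20)
  expect_equal(unname(est), 250)
  # single reference gene; zero-count globin stays zero
  est0 <- estimate_globin_fpkm(c(Hbb = 0),
                               data.frame(count = 10, fpkm = 5), n_top = 1)
  expect_equal(unname(est0), 0)
  # independent two-line computation on random references
  set.seed(5)
  ref2 <- data.frame(count = rpois(40, 5000), fpkm = rexp(40) * 300)
  counts <- c(a = 1234, b = 77)
  r <- sum(sort(ref2$count, decreasing = TRUE)[1:20]) /
    sum(ref2$fpkm[order(-ref2$count)][1:20])
  expect_equal(estimate_globin_fpkm(counts, ref2), counts / r)
  # scale consistency: multiplying every count by c leaves estimates unchanged
  ref3 <- ref2; ref3$count <- ref3$count * 7
  expect_equal(estimate_globin_fpkm(counts * 7, ref3),
               estimate_globin_fpkm(counts, ref2))
  expect_error(estimate_globin_fpkm(counts, data.frame(count = 1, fpkm = 0),
                                    n_top = 1), "positive")
})

test_that("pseudoreplicates conserve the pool, balance sizes, and are seed-deterministic", {
  u10 <- paste0("r", 1:10)
  s <- make_pseudoreplicates(u10, seed = 1)
  expect_equal(length(s$A), 5)
  expect_equal(length(s$B), 5)
  expect_setequal(c(s$A, s$B), u10)
  expect_length(intersect(s$A, s$B), 0)

  u11 <- paste0("r", 1:11)
  s11 <- make_pseudoreplicates(u11, seed = 2)
  expect_true(abs(length(s11$A) - length(s11$B)) <= 1)
  expect_setequal(c(s11$A, s11$B), u11)

  big <- paste0("u", 1:1000)
  expect_identical(make_pseudoreplicates(big, seed = 9),
                   make_pseudoreplicates(big, seed = 9))
  expect_false(identical(make_pseudoreplicates(big, seed = 9),
                         make_pseudoreplicates(big, seed = 10)))
})

test_that("replicate concordance is Spearman on positive-FPKM genes", {
  genes <- paste0("g", 1:8)
  base <- c(5, 9, 1, 14, 3, 22, 7, 11)
  m <- expression_matrix(
    matrix(c(base, base), 8, 2, dimnames = list(genes, c("MEP_r1", "MEP_r2"))))
  expect_equal(replicate_concordance(m, "MEP"), 1.0)

  rev <- expression_matrix(
    matrix(c(base, max(base) + 1 - base), 8, 2,
           dimnames = list(genes, c("MEP_r1", "MEP_r2"))))
  expect_equal(replicate_concordance(rev, "MEP"), -1.0)

  # matches the exhaustive rank computation (average ranks, ties included)
  set.seed(8)
  a <- c(rpois(8, 20), 0)           # one zero: excluded from the computation
  b <- c(rpois(8, 20), 12)
  m2 <- expression_matrix(
    matrix(c(a, b), 9, 2, dimnames = list(paste0("g", 1:9),
                                          c("ERY_r1", "ERY_r2"))))
  keep <- a > 0 & b > 0
  ra <- rank(log2(a[keep] + 1.1)); rb <- rank(log2(b[keep] + 1.1))
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(replicate_concordance(m2, "ERY"), oracle)

  expect_error(replicate_concordance(m2, "MEG"), "two replicates")
})
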