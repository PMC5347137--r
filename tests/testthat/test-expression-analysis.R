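# Expression filtering, DE classes, chi-squared fraction tests,
# rank-sum tests, restoration logic, and gene-set statistics.

make_expr <- function(n = 10, log2fc = 0, p = 1, status = "OK",
                      contrast = "daf2_vs_WT") {
  df <- data.frame(
    transcript_id = sprintf("t%03d", seq_len(n)),
    gene_id = sprintf("g%03d", seq_len(n)),
    status = status,
    fpkm_WT = 10, fpkm_daf2 = 10,
    stringsAsFactors = FALSE)
  df[[paste0("log2fc_", contrast)]] <- log2fc
  df[[paste0("p_", contrast)]] <- p
  df
}

test_that("compute_fpkm is the unit definition and scale-invariant", {
  expect_equal(compute_fpkm(100, 1000, 1e6), 100)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(200, 1000, 2e6), compute_fpkm(100, 1000, 1e6))
  expect_error(compute_fpkm(10, 0, 1e6), "length")
  expect_error(compute_fpkm(10, 1000, 0), "total")
})

test_that("filter_expression drops failing status and zero FPKM", {
  e <- make_expr(6)
  e$status[2] <- "NOTEST"; e$status[3] <- "HIDATA"; e$status[4] <- "FAIL"
  e$fpkm_daf2[5] <- 0
  out <- filter_expression(e)
  expect_equal(out$transcript_id, c("t001", "t006"))
  removed <- attr(out, "removed")
  expect_equal(unname(removed["zero_fpkm"]), 1)
  expect_equal(sum(removed), 4)
  # all-OK nonzero table is identity
  ok <- make_expr(4)
  expect_equal(nrow(filter_expression(ok)), 4)
})

test_that("classify_de boundaries are inclusive and thresholds configurable", {
  e <- make_expr(4, log2fc = c(-1.0, -0.5, -0.5, 1.0),
                 p = c(0.10, 0.01, 0.01, 0.05))
  de <- classify_de(e, "daf2_vs_WT")
  expect_equal(de$class, c("down", "unchanged", "unchanged", "up"))
  de2 <- classify_de(e, "daf2_vs_WT", fc_threshold = 0.4)
  expect_equal(de2$class[2], "down")
  expect_error(classify_de(e, "nope"), "contrast")
  # relaxing the threshold never shrinks the down set
  set.seed(3)
  e3 <- make_expr(200, log2fc = rnorm(200), p = runif(200))
  d1 <- classify_de(e3, "daf2_vs_WT", fc_threshold = 1)
  d04 <- classify_de(e3, "daf2_vs_WT", fc_threshold = 0.4)
  expect_true(all(d1$transcript_id[d1$class == "down"] %in%
                  d04$transcript_id[d04$class == "down"]))
})

test_that("feature_fraction_test reproduces the hand-computed Pearson chi2", {
  # planted 2x2 table [[30,70],[10,190]]: 100 feature+ (30 down),
  # 200 feature- (10 down)
  n <- 300
  ids <- sprintf("t%03d", 1:n)
  has <- c(rep(TRUE, 100), rep(FALSE, 200))
  down <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 190))
  de <- data.frame(contrast = "c", transcript_id = ids,
                   class = ifelse(down, "down", "unchanged"))
  feats <- data.frame(transcript_id = ids, has_ptc = has)
  r <- feature_fraction_test(de, feats, "ptc")
  expect_equal(as.vector(r$table), c(30, 10, 70, 190))
  expect_equal(sum(r$table), n)
  # independent oracle: N (ad - bc)^2 / (r1 r2 c1 c2)
  chi_hand <- 300 * (30 * 190 - 70 * 10)^2 / (100 * 200 * 40 * 260)
  expect_equal(r$chi2, chi_hand, tolerance = 1e-12)
  expect_equal(r$p, pchisq(chi_hand, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(unname(r$fractions), c(30 / 40, 70 / 260))
})

test_that("equal fractions give chi2 = 0 and zero margins are untestable", {
  ids <- sprintf("t%03d", 1:40)
  de <- data.frame(contrast = "c", transcript_id = ids,
                   class = rep(c("down", "unchanged"), each = 20))
  feats <- data.frame(transcript_id = ids,
                      has_ptc = rep(c(TRUE, FALSE, TRUE, FALSE), 10))
  r <- feature_fraction_test(de, feats, "ptc")
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  feats2 <- data.frame(transcript_id = ids, has_ptc = FALSE)
  r2 <- feature_fraction_test(de, feats2, "ptc")
  expect_true(r2$untestable)
  expect_true(is.na(r2$p))
})

test_that("ranksum normal approximation tracks wilcox.test and the exact path", {
  set.seed(21)
  x <- rnorm(30); y <- rnorm(40, 0.5)
  r <- ranksum_test(x, y, method = "normal")
  w <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$statistic, unname(w$statistic))
  expect_equal(r$p.value, w$p.value, tolerance = 1e-12)
  # ties handled
  xt <- c(1, 1, 2, 3); yt <- c(1, 2, 2, 4, 4)
  rt <- ranksum_test(xt, yt, method = "normal")
  wt <- wilcox.test(xt, yt, exact = FALSE, correct = TRUE)
  expect_equal(rt$p.value, wt$p.value, tolerance = 1e-12)
  # identical samples: p ~= 1
  z <- rnorm(20)
  expect_gt(ranksum_test(z, z, method = "normal")$p.value, 0.95)
})

test_that("small-sample normal approximation is within 0.05 of exact permutation", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(4, sample(c(0, 1), 1))
    pn <- ranksum_test(x, y, method = "normal")$p.value
    pe <- ranksum_test(x, y, method = "exact")$p.value
    expect_lt(abs(pn - pe), 0.05)
  }
})

test_that("utr3_foldchange_test reports medians and pairwise tests", {
  set.seed(4)
  n <- 90
  ids <- sprintf("t%03d", 1:n)
  cat3 <- rep(c("short", "medium", "long"), each = 30)
  fc <- rnorm(n, ifelse(cat3 == "long", -0.8, 0), 0.3)
  e <- data.frame(transcript_id = ids, gene_id = ids, status = "OK",
                  fpkm_WT = 1, log2fc_daf2_vs_WT = fc, p_daf2_vs_WT = 0.5)
  feats <- data.frame(transcript_id = ids, utr3_category = cat3)
  r <- utr3_foldchange_test(e, feats, "daf2_vs_WT")
  expect_equal(unname(r$n), c(30L, 30L, 30L))
  expect_lt(r$medians[["long"]], r$medians[["short"]])
  expect_lt(r$tests$p[r$tests$comparison == "long_vs_short"], 0.01)
  # category with < 2 members is skipped with a warning
  feats2 <- feats; feats2$utr3_category[feats2$utr3_category == "long"] <- "medium"
  feats2$utr3_category[1] <- "long"
  e2 <- e; feats2 <- feats2
  expect_warning(r2 <- utr3_foldchange_test(e2, feats2, "daf2_vs_WT"),
                 "skipping")
  expect_true("long_vs_short" %in% r2$skipped)
})

test_that("restoration logic flags downs that rise in the double mutant", {
  e <- make_expr(4, log2fc = c(-2, -2, -2, 0.5), p = 0.01)
  e$log2fc_smg2daf2_vs_daf2 <- c(0.8, -0.2, 0, 1)
  e$p_smg2daf2_vs_daf2 <- 0.5
  r <- restoration_analysis(e, "daf2_vs_WT", "smg2daf2_vs_daf2")
  expect_equal(r$down_in_mutA_vs_WT, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$restored_in_double_vs_mutA, c(TRUE, FALSE, TRUE, NA))
  s <- attr(r, "summary")
  expect_equal(s$n_down, 3)
  expect_equal(s$n_restored, 2)
  # threshold variant
  r2 <- restoration_analysis(e, "daf2_vs_WT", "smg2daf2_vs_daf2",
                             restore_threshold = 0.4)
  expect_equal(r2$restored_in_double_vs_mutA, c(TRUE, FALSE, FALSE, NA))
})

test_that("overrepresentation matches exact hypergeometric summation and EASE >= Fisher", {
  # N=100, term 10, target 10, overlap 5
  universe <- sprintf("g%03d", 1:100)
  term_genes <- universe[1:10]
  target <- c(universe[1:5], universe[50:54])
  tm <- data.frame(term_id = "T1", term_name = "term one",
                   gene_id = term_genes)
  r <- overrepresentation_test(target, tm, universe)
  # independent oracle: explicit tail summation over choose()
  tail_sum <- function(k, K, n, N)
    sum(vapply(k:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
  # exact tail P(X >= 5) = 6.72e-4 (hypergeometric N=100, K=10, n=10)
  expect_equal(r$p_fisher, tail_sum(5, 10, 10, 100), tolerance = 1e-12)
  expect_equal(signif(r$p_fisher, 3), 6.72e-4)
  expect_equal(r$p_ease, tail_sum(4, 10, 10, 100), tolerance = 1e-12)
  expect_gte(r$p_ease, r$p_fisher)

  # overlap 1 => EASE tail starts at 0 => p_ease = 1
  tm2 <- data.frame(term_id = "T2", term_name = "t2", gene_id = universe[1])
  r2 <- overrepresentation_test(universe[1], tm2, universe)
  expect_equal(r2$p_ease, 1)

  # disjoint term is skipped
  tm3 <- data.frame(term_id = "T3", term_name = "t3", gene_id = universe[90:99])
  r3 <- overrepresentation_test(universe[1:5], tm3, universe)
  expect_equal(nrow(r3), 0)

  expect_error(overrepresentation_test(target, tm, character(0)), "universe")
})

test_that("set_overlap_test: identical, independent, and disjoint sets", {
  universe <- sprintf("g%04d", 1:1000)
  A <- universe[1:20]
  r <- set_overlap_test(A, A, universe)
  expect_equal(r$overlap, 20)
  expect_lt(r$p, 1e-30)

  r2 <- set_overlap_test(universe[1:10], universe[500:509], universe)
  expect_equal(r2$overlap, 0)
  expect_equal(r2$p, 1)

  r3 <- set_overlap_test(character(0), A, universe)
  expect_true(is.na(r3$fold))
  expect_equal(r3$p, 1)

  # independent random sets: mean fold ~= 1 over simulations
  set.seed(99)
  folds <- replicate(500, {
    a <- sample(universe, 50); b <- sample(universe, 50)
    set_overlap_test(a, b, universe)$fold
  })
  expect_lt(abs(mean(folds) - 1), 0.1)
})
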