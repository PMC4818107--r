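test_that("spearman_matrix: exact rank correlations and invariance", {
  f <- data.frame(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
  p <- data.frame(theta = c(1, 2, 3, 4))
  m <- spearman_matrix(f, p)
  expect_equal(m["a", "theta"], 1)
  expect_equal(m["b", "theta"], -1)
  expect_equal(m["c", "theta"], 0.8)  # hand rank formula: 1 - 6*2/(4*15)
  # invariant under strictly monotone transforms of either side
  withr::with_seed(6, {
    x <- rnorm(20); y <- x + rnorm(20)
    m1 <- spearman_matrix(cbind(x = x), cbind(y = y))
    m2 <- spearman_matrix(cbind(x = exp(3 * x)), cbind(y = y^3 + 5 * y))
    expect_equal(m1, m2)
  })
  # constant column -> NA, not an error
  expect_true(is.na(suppressWarnings(
    spearman_matrix(cbind(k = rep(1, 5)), cbind(y = 1:5))[1, 1])))
  expect_error(spearman_matrix(cbind(1:2), cbind(1:2)), ">= 3")
})

test_that("hier_cluster: duplicates merge at zero, blocks split, order-stable", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  hc <- hier_cluster(m)
  expect_equal(min(hc$row_hclust$height), 0, tolerance = 1e-12)
  # anti-correlated blocks separate at the top split
  blocks <- rbind(p1 = c(1, 2, 3), p2 = c(1.1, 2, 2.9),
                  n1 = c(3, 2, 1), n2 = c(2.9, 2, 1.1))
  g <- cutree(hier_cluster(blocks)$row_hclust, k = 2)
  expect_identical(g[["p1"]], g[["p2"]])
  expect_identical(g[["n1"]], g[["n2"]])
  expect_false(g[["p1"]] == g[["n1"]])
  # permuting row order preserves memberships
  perm <- blocks[c(3, 1, 4, 2), ]
  g2 <- cutree(hier_cluster(perm)$row_hclust, k = 2)
  expect_identical(g2[["p1"]] == g2[["p2"]], TRUE)
  expect_false(g2[["p1"]] == g2[["n1"]])
  expect_error(hier_cluster(rbind(c(1, NA))), "non-finite")
})

test_that("percentile_threshold and median_stratify conventions", {
  v <- 1:100
  memb <- percentile_threshold(v, 80)
  expect_identical(sum(memb), 20L)
  expect_true(all(which(memb) > 80))
  expect_false(any(percentile_threshold(rep(5, 10), 50)))
  expect_error(percentile_threshold(numeric(0), 50), "empty")
  expect_error(percentile_threshold(1:5, 100), "pct")

  s <- median_stratify(c(a = 1, b = 2, c = 3, d = 4))
  expect_identical(names(which(s$hi)), c("c", "d"))
  expect_identical(names(which(s$lo)), c("a", "b"))
  # ties at the median are dropped from both strata
  s2 <- median_stratify(c(1, 2, 2, 3))
  expect_identical(which(s2$hi), 4L)
  expect_identical(which(s2$lo), 1L)
  # invariant under monotone transforms
  v2 <- c(0.3, 2.2, 5, 9, 11)
  expect_identical(median_stratify(v2)$hi, median_stratify(exp(v2))$hi)
  expect_error(median_stratify(rep(3, 4)), "all values equal")
  # pct = 50 matches the median split on odd-length distinct data
  v3 <- c(2, 9, 4, 7, 1)
  expect_identical(percentile_threshold(v3, 50), median_stratify(v3)$hi)
})

test_that("ranksum_test: exact p agrees with the enumeration oracle", {
  rt <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p, 0.1)
  expect_identical(rt$direction, "lo-sensitive")
  # identical groups
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 0.01)
  withr::with_seed(8, {
    for (rep in 1:15) {
      na <- sample(3:5, 1); nb <- sample(3:5, 1)
      v <- sample(1:50, na + nb)  # distinct -> tie-free
      a <- v[1:na]; b <- v[-(1:na)]
      expect_equal(ranksum_test(a, b)$p, oracle_ranksum_p(a, b),
                   tolerance = 1e-10)
      # swap symmetry
      r1 <- ranksum_test(a, b); r2 <- ranksum_test(b, a)
      expect_equal(r1$p, r2$p)
      if (r1$direction != "none") expect_false(r1$direction == r2$direction)
    }
  })
  expect_error(ranksum_test(c(1, 2), c(3, 4, 5)), ">= 3")
})

test_that("signed_p conventions", {
  expect_equal(signed_p(0.01, "hi-sensitive"), 2)
  expect_equal(signed_p(1, "lo-sensitive"), 0)
  expect_equal(signed_p(0.1, "lo-sensitive"), -1)
  expect_equal(signed_p(0.05, "hi"), -signed_p(0.05, "lo"))
  expect_error(signed_p(0, "hi"), "p in")
})

test_that("hypergeometric_tail: exact mass sums and the subset oracle", {
  expect_equal(hypergeometric_tail(10, 4, 3, 2), 1 / 3)  # (36 + 4)/120
  expect_equal(hypergeometric_tail(100, 10, 5, 0), 1)
  withr::with_seed(9, {
    for (rep in 1:12) {
      N <- sample(6:12, 1); n <- sample(1:N, 1); K <- sample(1:5, 1)
      r <- sample(0:K, 1)
      expect_equal(hypergeometric_tail(N, n, K, r),
                   oracle_hyper_tail(N, n, K, r), tolerance = 1e-12)
    }
  })
  # monotone decreasing in r
  tails <- sapply(0:5, function(r) hypergeometric_tail(50, 20, 5, r))
  expect_true(all(diff(tails) < 0))
  expect_error(hypergeometric_tail(10, 4, 11, 2), "<= N")
})

test_that("differential screen: hit logic, filters, monotonicity in alpha", {
  scr <- simulate_screen(n_cols = 200, n_planted = 20, effect_size = 3,
                         seed = 14)
  res <- differential_sensitivity_screen(scr$matrix, scr$strat, alpha = 0.05)
  expect_identical(res$n_hits, length(res$hits))
  expect_gte(length(intersect(res$hits, scr$planted)), 18)
  # alpha = 1 with no effect filter: every testable column is a hit
  res_all <- differential_sensitivity_screen(scr$matrix, scr$strat, alpha = 1)
  expect_identical(res_all$n_hits, res_all$n_total)
  # hits monotone non-decreasing in alpha
  hits_at <- sapply(c(0.01, 0.05, 0.2, 1), function(a)
    differential_sensitivity_screen(scr$matrix, scr$strat, alpha = a)$n_hits)
  expect_true(all(diff(hits_at) >= 0))
  # effect filter prunes
  res_f <- differential_sensitivity_screen(scr$matrix, scr$strat,
                                           alpha = 0.05, effect_filter = 10)
  expect_identical(res_f$n_hits, 0L)
  # sparse columns are untestable and excluded from n_total
  m2 <- scr$matrix
  m2[, 1] <- NA
  m2[cbind(3:20, 2)] <- NA
  res2 <- differential_sensitivity_screen(m2, scr$strat)
  expect_identical(res2$n_total, ncol(m2) - 2L)
  expect_setequal(res2$untestable, colnames(m2)[1:2])
  expect_error(differential_sensitivity_screen(
    scr$matrix, list(hi = scr$strat$hi, lo = scr$strat$hi)), "overlap")
})

test_that("canonical_enrichment wires screen counts into the tail", {
  scr <- simulate_screen(n_cols = 100, n_planted = 10, effect_size = 3,
                         seed = 15)
  res <- differential_sensitivity_screen(scr$matrix, scr$strat)
  e <- canonical_enrichment(res, head(scr$planted, 5))
  expect_identical(e$N, res$n_total)
  expect_identical(e$n, res$n_hits)
  expect_identical(e$K, 5L)
  expect_lte(e$r, min(e$n, e$K))
  expect_equal(e$p, hypergeometric_tail(e$N, e$n, e$K, e$r))
  # untested canonical ids drop from K with a warning
  expect_warning(e2 <- canonical_enrichment(res, c(head(scr$planted, 3),
                                                   "NOT_A_GENE")),
                 "untested")
  expect_identical(e2$K, 3L)
  # empty hit list: r = 0, tail = 1
  null_scr <- structure(list(stats = res$stats, hits = character(0),
                             n_total = res$n_total, n_hits = 0L),
                        class = "screen_result")
  e3 <- canonical_enrichment(null_scr, head(scr$planted, 5))
  expect_identical(e3$r, 0L)
  expect_equal(e3$p, 1)
})
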