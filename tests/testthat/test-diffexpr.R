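test_that("one-way ANOVA handles degenerate inputs and matches base R", {
  expect_equal(one_way_anova(rep(5, 9), rep(1:3, 3)),
               list(statistic = 0, df = c(2L, 6L), p.value = 1, mse = 0),
               ignore_attr = TRUE)
  # identical group contents -> identical means -> F = 0
  r <- one_way_anova(c(1, 2, 3, 1, 2, 3, 1, 2, 3), rep(1:3, each = 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # perfect separation
  r2 <- one_way_anova(c(0, 0, 1, 1, 2, 2), rep(1:3, each = 2))
  expect_identical(r2$statistic, Inf)
  expect_identical(r2$p.value, 0)
  # agreement with stats::oneway.test on random data
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    n <- sample(3:6, k, replace = TRUE)
    g <- rep(seq_len(k), n)
    x <- rnorm(sum(n), mean = g / 2)
    ours <- one_way_anova(x, g)
    ref <- stats::oneway.test(x ~ factor(g), var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-10)
  }
  expect_error(one_way_anova(1:3, c(1, 2, 2)), "at least 2 observations")
})

test_that("strong separation is confirmed by an exhaustive permutation oracle", {
  x <- c(0, 0, 1, 1, 2, 2)
  g <- rep(1:3, each = 2)
  # between-group SS = 4, within-group SS = 0
  gm <- tapply(x, g, mean)
  expect_equal(sum(2 * (gm - mean(x))^2), 4)
  expect_equal(sum((x - gm[g])^2), 0)
  # the permutation null puts mass only on the most extreme labelings
  p_perm <- anova_perm_oracle(x, g)
  expect_lte(p_perm, 90 / 720 + 1e-12)
  expect_identical(one_way_anova(x, g)$p.value, 0)
  # a clearly separated configuration: the permutation p attains the
  # exhaustive minimum (48/720: only relabelings reproducing the grouping
  # reach the observed F), and the parametric p is far smaller
  x2 <- c(1.0, 1.2, 2.9, 3.3, 5.0, 5.4)
  expect_lt(one_way_anova(x2, g)$p.value, 0.01)
  expect_equal(anova_perm_oracle(x2, g), 48 / 720, tolerance = 1e-12)
})

test_that("pooled t-test matches base R and its permutation oracle", {
  expect_equal(two_group_ttest(c(5, 5), c(5, 5)),
               list(statistic = 0, df = 2, p.value = 1, degenerate = FALSE),
               ignore_attr = TRUE)
  # swapping the groups flips t, keeps p
  a <- c(1.2, 3.4, 2.2)
  b <- c(4.1, 5.0, 6.3)
  r1 <- two_group_ttest(a, b)
  r2 <- two_group_ttest(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p.value, r2$p.value)
  # zero pooled variance with unequal means: degenerate, p = 0
  rd <- two_group_ttest(c(1, 1), c(2, 2))
  expect_true(rd$degenerate)
  expect_identical(rd$p.value, 0)
  # agreement with stats::t.test(var.equal = TRUE)
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1), 0.8)
    ours <- two_group_ttest(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-10)
  }
  # {1,2,3,4} vs {2,3,4,5}: exhaustive 70-relabeling oracle brackets the
  # parametric p (both are clearly nonsignificant and of the same order)
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  p_par <- two_group_ttest(x, y)$p.value
  p_perm <- ttest_perm_oracle(x, y)
  expect_equal(p_par, 0.3153336, tolerance = 1e-6)
  expect_equal(p_perm, 32 / 70, tolerance = 1e-12)
  expect_false(p_par <= 0.05 || p_perm <= 0.05)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
  set.seed(31)
  for (i in 1:200) {
    m <- sample(1:80, 1)
    p <- switch(sample(3, 1), runif(m), round(runif(m), 2),
                rbeta(m, 0.3, 1))
    adj <- bh_adjust(p)
    expect_identical(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("de_table applies the expression, significance and fold gates", {
  # 4 + 4 samples, two subcaste groups; rows engineered around the gates
  v <- rbind(
    pass  = c(300, 310, 290, 300, 100, 105, 95, 100),   # ratio 3, clean
    fold  = c(150, 155, 145, 150, 90, 92, 88, 90),      # ratio 1.67 < 2
    dim   = c(90, 91, 89, 90, 50, 52, 48, 50),          # below intensity gate
    flat  = c(500, 500, 500, 500, 500, 500, 500, 500))  # no signal
  grp <- rep(c("g1", "g2"), each = 4)
  ct <- linear_table(v, grp)
  de <- de_table(ct, thresholds = de_thresholds())
  rec <- function(id) de[de$contig_id == id, ]
  expect_true(rec("pass")$expressed)
  expect_true(rec("pass")$relevant)
  expect_true(rec("fold")$expressed)
  expect_false(rec("fold")$relevant)
  expect_gte(rec("fold")$mean_g1, 100)
  expect_false(rec("dim")$expressed)
  expect_true(is.na(rec("dim")$p))
  expect_false(rec("dim")$relevant)
  expect_equal(rec("pass")$max_ratio, 3, tolerance = 0.01)
  # adjusted p never below raw p, never above 1
  ok <- !is.na(de$p)
  expect_true(all(de$p_adj[ok] >= de$p[ok] - 1e-15))
  expect_true(all(de$p_adj[ok] <= 1))
})

test_that("de_table is invariant to contig and sample order", {
  set.seed(41)
  cfg <- tiny_config(seed = 8)
  sim <- simulate_intensities(design_probes(cfg), cfg)
  ag <- aggregate_probes(quantile_normalize(sim$intensities, 2), sim$probes)
  de1 <- de_table(ag)
  # permute contigs
  ag2 <- ag
  perm <- sample(nrow(ag$values))
  ag2$values <- ag$values[perm, , drop = FALSE]
  de2 <- de_table(ag2)
  de2 <- de2[match(de1$contig_id, de2$contig_id), ]
  rownames(de2) <- NULL
  expect_equal(as.data.frame(de2), as.data.frame(de1))
  # permute samples
  ag3 <- subset_samples(ag, sample(ncol(ag$values)))
  de3 <- de_table(ag3)
  de3 <- de3[match(de1$contig_id, de3$contig_id), ]
  expect_equal(de3$p, de1$p)
  expect_equal(de3$relevant, de1$relevant)
})

test_that("three-group de_table attaches SNK letters to significant contigs", {
  set.seed(55)
  n <- 4
  v <- rbind(
    up_in_one = 2^c(rnorm(n, 10, 0.1), rnorm(n, 10, 0.1), rnorm(n, 12, 0.1)),
    flat = 2^c(rnorm(3 * n, 9, 0.1)))
  grp <- rep(c("queens", "males", "workers"), each = n)
  ct <- linear_table(v, grp)
  de <- de_table(ct)
  expect_identical(attr(de, "test"), "anova")
  rec <- de[de$contig_id == "up_in_one", ]
  expect_true(rec$relevant)
  letters3 <- strsplit(rec$snk, "/")[[1]]
  names(letters3) <- attr(de, "groups")
  # workers separated from queens+males, which share a letter
  expect_identical(letters3[["queens"]], letters3[["males"]])
  expect_false(letters3[["workers"]] == letters3[["queens"]])
  expect_identical(de[de$contig_id == "flat", "snk"], "")
})

test_that("a spiked contig is recovered as relevant (single-seed sanity)", {
  cfg <- config_de_spike(seed = 4L)
  sim <- simulate_intensities(design_probes(cfg), cfg)
  ag <- aggregate_probes(quantile_normalize(sim$intensities, 2), sim$probes)
  de <- de_table(ag)
  expect_true(de[de$contig_id == cfg$spikes$contig_id, "relevant"])
})

test_that("heatmap_matrix masks exactly the non-relevant contigs", {
  v <- rbind(
    pass = c(300, 310, 290, 300, 100, 105, 95, 100),
    dim  = c(90, 91, 89, 90, 50, 52, 48, 50))
  ct <- linear_table(v, rep(c("g1", "g2"), each = 4))
  de <- de_table(ct)
  hm <- heatmap_matrix(de)
  expect_identical(dim(hm), c(2L, 2L))
  expect_false(anyNA(hm["pass", ]))
  expect_true(all(is.na(hm["dim", ])))
  expect_equal(hm["pass", "g1"], log2(mean(c(300, 310, 290, 300)) + 1))
  expect_identical(sum(!complete.cases(hm)), nrow(de) - sum(de$relevant))
})
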