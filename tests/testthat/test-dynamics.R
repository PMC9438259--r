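test_that("LAD mean scores average full bins only", {
  genome <- genome_spec("chr1", 1e5)
  tr <- binned_track(list(chr1 = c(9, 1, 3, 5, 9, 9, 9, 9, 9, 9)),
                     1e4, genome, "zscore")
  lads <- lad_set("chr1", 1e4, 4e4, genome)
  expect_equal(lad_mean_scores(tr, lads), 3) # full bins 2-4: mean(1, 3, 5)

  # partial edge bins are excluded
  lads2 <- lad_set("chr1", 1.5e4, 4.5e4, genome)
  expect_equal(lad_mean_scores(tr, lads2), 4) # full bins 3,4 only

  const <- binned_track(list(chr1 = rep(2, 10)), 1e4, genome, "zscore")
  expect_equal(lad_mean_scores(const, lads), 2)

  # no full bin -> NA
  tiny <- lad_set("chr1", 1.2e4, 1.8e4, genome)
  expect_true(is.na(lad_mean_scores(tr, tiny)))
})

test_that("null thresholds are type-7 quantiles at 0.1% and 99.9%", {
  set.seed(31)
  d <- rnorm(10000)
  thr <- null_thresholds(d)
  # sorted-array type-7 oracle
  q7 <- function(p) {
    s <- sort(d)
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  expect_equal(unname(thr), c(q7(0.001), q7(0.999)))
  expect_lt(abs(thr[["high"]] - 3.09), 0.25)
  expect_lt(abs(thr[["low"]] + thr[["high"]]), 0.2) # symmetric null

  expect_warning(null_thresholds(rnorm(100)), "noisy")
})

test_that("change classification counts exceedances of the null", {
  thr <- c(low = -1, high = 1)
  all_stable <- classify_changes(c(-0.5, 0, 0.9), thr)
  expect_true(all(all_stable$class == "stable"))
  expect_equal(all_stable$fraction_changed, 0)

  one_up <- classify_changes(c(rep(0, 9), 2), thr)
  expect_equal(one_up$fraction_changed, 0.1)
  expect_equal(sum(one_up$class == "up"), 1)

  suppressMessages(
    with_na <- classify_changes(c(0, NA, 2, -2), thr))
  expect_equal(with_na$n, 3)
  expect_equal(with_na$fraction_changed, 2 / 3)
})

test_that("LAD features match their definitions", {
  genome <- genome_spec("chr1", 8e7)
  consensus <- lad_set("chr1", c(9.5e6, 4e7), c(10.5e6, 4.1e7), genome)
  ann <- site_annotation(
    ctcf = data.frame(chrom = "chr1",
                      pos = c(9.6e6, 9.7e6, 9.8e6, 10e6, 10.2e6, 2e7),
                      strand = "+"),
    genes = data.frame(chrom = "chr1", start = c(9.6e6, 4.05e7),
                       end = c(9.61e6, 4.06e7), strand = "+",
                       fpkm = c(10, 0.1)),
    genome = genome)
  ft <- compute_lad_features(consensus, ann, genome = genome)
  expect_equal(ft$size_log2_bp, c(log2(1e6), log2(1e6)))
  expect_equal(ft$ctcf_density, c(5, 0))       # 5 sites in a 1-Mb LAD
  expect_equal(ft$active_gene_density, c(1, 0)) # FPKM > 1 only
  expect_equal(ft$dist_to_chrom_ends[1], 10)   # midpoint at 10 Mb
  expect_equal(ft$chrom_size, c(80, 80))

  # genome entirely LAD -> local density 1
  g2 <- genome_spec("chr1", 2e7)
  full <- lad_set("chr1", 0, 2e7, g2)
  ft2 <- compute_lad_features(full, site_annotation(genome = g2),
                              genome = g2)
  expect_equal(ft2$local_lad_density, 1)

  # histone means come from the track
  h <- binned_track(list(chr1 = rep(0.7, 8000)), 1e4, genome, "other")
  ft3 <- compute_lad_features(consensus, ann, histone_tracks = list(k9 = h),
                              genome = genome)
  expect_equal(ft3$k9_mean, c(0.7, 0.7))
})

test_that("feature correlations match a brute-force rank oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    feats <- data.frame(f = x)
    res <- correlate_features(matrix(y, ncol = 1,
                                     dimnames = list(NULL, "c1")), feats)
    oracle <- cor(rank(x), rank(y)) # Pearson on ranks
    expect_equal(unname(res$rho["f", "c1"]), oracle, tolerance = 1e-12)
  }

  # self- and monotone-transform correlation is exactly 1
  d <- matrix(rexp(20), ncol = 1, dimnames = list(NULL, "c"))
  expect_equal(unname(correlate_features(d, data.frame(f = d[, 1]))$rho["f", "c"]),
               1)
  expect_equal(unname(correlate_features(d, data.frame(f = log(d[, 1])))$rho["f", "c"]),
               1)

  # constant feature -> undefined rho, masked
  resc <- correlate_features(d, data.frame(f = rep(1, 20)))
  expect_true(is.na(resc$rho["f", "c"]))
  expect_false(resc$significant["f", "c"])
})

test_that("condition correlations behave under duplication and sign flips", {
  set.seed(51)
  a <- rnorm(300)
  b <- rnorm(300)
  m <- cbind(c1 = a, c2 = a, c3 = b, c4 = -b)
  cc <- correlate_conditions(m)
  expect_equal(diag(cc), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cc["c1", "c2"], 1)
  expect_equal(cc["c3", "c4"], -1)
  expect_lt(abs(cc["c1", "c3"]), 3 / sqrt(300)) # independent conditions
  expect_error(correlate_conditions(m[1:2, ]), "at least 3")
})

test_that("DE-content grouping excludes mixed LADs and finds the effect", {
  genome <- genome_spec("chr1", 1e7)
  consensus <- lad_set("chr1", seq(0, 9e6, 1e6) + 1e5,
                       seq(0, 9e6, 1e6) + 9e5, genome)
  gene_in <- function(i) { # a gene inside LAD i
    data.frame(chrom = "chr1", start = (i - 1) * 1e6 + 4e5,
               end = (i - 1) * 1e6 + 4.1e5)
  }
  de <- list(up = rbind(gene_in(1), gene_in(2), gene_in(3)),
             down = rbind(gene_in(3), gene_in(4), gene_in(5)))
  set.seed(61)
  deltas <- rnorm(10, 0, 0.01)
  deltas[4:5] <- deltas[4:5] + 0.3 # down-only LADs gain
  suppressMessages(res <- diffs_by_de_content(deltas, consensus, de))
  expect_equal(res$group[3], "excluded") # has both up and down
  expect_equal(sum(res$group == "up"), 2)
  expect_equal(sum(res$group == "down"), 2)
  expect_lt(abs((res$medians[["down"]] - res$medians[["neither"]]) - 0.3),
            0.05)
  expect_true(all(c("p_value", "p_adjusted") %in% names(res$tests)))

  # no DE genes -> single 'neither' group
  suppressMessages(
    res2 <- diffs_by_de_content(deltas, consensus,
                                list(up = NULL, down = NULL)))
  expect_equal(names(res2$groups), "neither")
  expect_equal(length(res2$groups$neither), 10)
})

test_that("expression matching picks nearest log-expression twins", {
  # identical pools match exactly
  idx <- match_expression_controls(c(2, 5, 9), c(2, 5, 9))
  expect_equal(idx, 1:3)

  # LAD genes at FPKM 2 against {1.9, 2.1, 50}: 50 is never taken
  idx2 <- match_expression_controls(c(2, 2), c(1.9, 2.1, 50))
  expect_setequal(idx2, c(1, 2))

  expect_equal(match_expression_controls(numeric(0), c(1, 2)), integer(0))
  expect_error(match_expression_controls(c(1), numeric(0)), "empty")
  expect_error(match_expression_controls(c(0, 1), c(1, 2)), "filter")

  # matched distributions pass a rank test on simulated data
  set.seed(71)
  lad_g <- rlnorm(100, 1, 0.8)
  pool <- rlnorm(2000, 1.4, 1)
  m <- match_expression_controls(lad_g, pool)
  expect_equal(length(m), 100)
  expect_equal(anyDuplicated(m), 0)
  expect_gt(suppressWarnings(wilcox.test(log(lad_g), log(pool[m]))$p.value),
            0.05)
})
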