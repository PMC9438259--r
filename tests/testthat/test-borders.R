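make_border <- function(pos = 1e6, side = "left", chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, side = side, lad_id = 1L,
             stringsAsFactors = FALSE)
}

test_that("CTCF border classification applies the outside-window rule", {
  genome <- genome_spec("chr1", 5e6)
  # left border at 1 Mb: iLAD is leftward, so 'outside' is below 1 Mb
  b <- make_border(1e6, "left")

  ann <- site_annotation(ctcf = data.frame(chrom = "chr1", pos = 1e6 - 15e3,
                                           strand = "+"),
                         genome = genome)
  cls <- classify_borders(b, ann)
  expect_true(cls$has_ctcf)
  expect_equal(cls$n_ctcf, 1L)

  # 25 kb outside and 5 kb inside both fail the (0, 20 kb] outside rule
  ann2 <- site_annotation(ctcf = data.frame(chrom = "chr1",
                                            pos = c(1e6 - 25e3, 1e6 + 5e3),
                                            strand = c("+", "+")),
                          genome = genome)
  cls2 <- classify_borders(b, ann2)
  expect_false(cls2$has_ctcf)
  expect_equal(cls2$n_ctcf, 0L)
  expect_equal(cls2$orientation_class, "none")

  # empty annotation
  cls3 <- classify_borders(b, site_annotation(genome = genome))
  expect_false(cls3$has_ctcf)
  expect_false(cls3$near_active_gene)
  expect_false(cls3$at_loop_anchor)

  # active gene within 10 kb of the border (edge distance), and loop anchor
  ann4 <- site_annotation(
    genes = data.frame(chrom = "chr1", start = 1e6 + 8e3, end = 1e6 + 30e3,
                       strand = "+", fpkm = 5),
    loops = data.frame(chrom1 = "chr1", start1 = 1e6 - 18e3, end1 = 1e6 - 12e3,
                       chrom2 = "chr1", start2 = 3e6, end2 = 3.01e6),
    genome = genome)
  cls4 <- classify_borders(b, ann4)
  expect_true(cls4$near_active_gene)
  expect_true(cls4$at_loop_anchor)
  # silent gene at the same place does not flag
  ann5 <- ann4
  ann5$genes$fpkm <- 0.5
  expect_false(classify_borders(b, ann5)$near_active_gene)

  expect_error(classify_borders(data.frame(chrom = "chr1", pos = 1e6),
                                ann), "side")
})

test_that("motif orientation classes follow the single/mixed/unknown rules", {
  # left border: LAD rightward, '+' motifs point into the LAD
  expect_equal(assign_orientation("+", "left"), "inward")
  expect_equal(assign_orientation("-", "left"), "outward")
  expect_equal(assign_orientation("-", "right"), "inward")
  expect_equal(assign_orientation(c("+", "+"), "left"), "inward")
  expect_equal(assign_orientation(c("+", "-"), "left"), "ambiguous")
  expect_equal(assign_orientation("*", "left"), "ambiguous")
  expect_equal(assign_orientation(character(0), "left"), "none")
})

test_that("meta-profiles orient windows LAD-inward with valid CIs", {
  genome <- genome_spec("chr1", 1e6)
  const <- binned_track(list(chr1 = rep(2.5, 100)), 1e4, genome, "zscore")
  borders <- rbind(make_border(3e5, "left"), make_border(7e5, "right"))
  mp <- metaprofile(const, borders, flank = 5e4)
  expect_true(all(mp$mean == 2.5))
  expect_true(all(mp$ci_half_width == 0))
  expect_true(all(mp$n == 2))

  # two borders with values 0 and 2 at the same offset -> mean 1
  v <- rep(0, 100); v[31] <- 0 # border A inward first bin
  w <- rep(2, 100)
  tr <- binned_track(list(chr1 = v), 1e4, genome, "zscore")
  tr$values$chr1[36] <- 2 # give border B's window a different value
  mpx <- metaprofile(tr, rbind(make_border(3e5, "left"),
                               make_border(3.5e5, "left")), flank = 1e4)
  expect_equal(mpx$mean[2], 1) # offsets: -5e3, +5e3; inward bin means (0+2)/2

  # mirrored LAD: left and right borders give identical oriented windows
  lad <- c(rep(-1, 40), rep(1, 20), rep(-1, 40))
  sym <- binned_track(list(chr1 = lad), 1e4, genome, "zscore")
  bl <- metaprofile(sym, make_border(4e5, "left"), flank = 1e5)
  br <- metaprofile(sym, make_border(6e5, "right"), flank = 1e5)
  expect_equal(bl$mean, br$mean)
})

test_that("outside-border change detects a constructed CTCF-specific gain", {
  genome <- genome_spec("chr1", 2e6)
  base <- binned_track(list(chr1 = rep(0, 200)), 1e4, genome, "zscore")
  borders <- rbind(make_border(5e5, "left"), make_border(1.5e6, "left"))

  expect_equal(border_outside_change(base, base, borders), c(0, 0))

  # +0.3 only in the 20-kb outside window of the first border
  shifted <- base
  shifted$values$chr1[c(49, 50)] <- 0.3
  d <- border_outside_change(shifted, base, borders, outside_window = 2e4)
  expect_equal(d, c(0.3, 0))

  res <- compare_border_groups(list(t6 = c(rep(0.3, 10), rep(0, 10))),
                               has_ctcf = rep(c(TRUE, FALSE), each = 10))
  expect_equal(res$median_ctcf, 0.3)
  expect_equal(res$median_no_ctcf, 0)
  expect_equal(res$p_adjusted, res$p_value) # single timepoint
})

test_that("border shifts are signed toward the iLAD and censored", {
  ref <- rbind(make_border(1e6, "left"), make_border(2e6, "right"))

  same <- border_shift_cdf(ref, ref)
  expect_true(all(same$shifts$ref_distance == 0))
  expect_equal(same$n_censored, 0)
  expect_equal(same$cdf(0), 1) # step at 0

  # both borders moved 20 kb into the iLAD:
  # left border (iLAD leftward) moves to smaller coordinates
  cond <- rbind(make_border(1e6 - 2e4, "left"), make_border(2e6 + 2e4, "right"))
  sh <- border_shift_cdf(cond, ref)
  expect_equal(sh$shifts$ref_distance, c(2e4, 2e4))

  # censoring beyond the cutoff
  far <- make_border(1e6 + 5e5, "left")
  expect_equal(border_shift_cdf(far, ref, cutoff = 1e5)$n_censored, 1)
  expect_equal(border_shift_cdf(far, ref, cutoff = Inf)$n_censored, 0)

  # chromosome absent from the reference -> censored
  other <- make_border(1e6, "left", chrom = "chr2")
  expect_equal(border_shift_cdf(other, ref)$n_censored, 1)

  # antisymmetry under swapping condition and reference
  sh_fwd <- border_shift_cdf(cond, ref)
  sh_rev <- border_shift_cdf(ref, cond)
  expect_equal(sh_fwd$shifts$ref_distance, -sh_rev$shifts$ref_distance)
})

test_that("CTCF-count strata expose a constructed dose effect", {
  anns <- data.frame(n_ctcf = rep(c(0L, 1L, 2L, 4L), each = 25))
  set.seed(9)
  deltas <- 0.1 * anns$n_ctcf + rnorm(100, 0, 0.05)
  s <- stratify_by_ctcf_count(anns, deltas)
  expect_named(s$groups, c("0", "1", "2", ">=3"))
  expect_true(all(diff(s$medians) > 0))
  expect_gt(s$trend_rho, 0.8)
  expect_lt(s$trend_p, 1e-6)

  # degenerate: single stratum, configurable breaks
  one <- data.frame(n_ctcf = rep(0L, 10))
  expect_message(s2 <- stratify_by_ctcf_count(one, rnorm(10)), "empty strata")
  expect_equal(lengths(s2$groups)[["0"]], 10L)
  s3 <- stratify_by_ctcf_count(anns, deltas, breaks = c(0, 2))
  expect_named(s3$groups, c("0", ">=2"))
})
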