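test_that("threshold quartiles, fence and minimum match hand computation", {
  # unique counts {2,4,6,8,10,100}: type-7 Q1 = 4.5, Q3 = 9.5, fence = 17
  m <- fit_threshold(c(2, 4, 6, 8, 10, 100), alpha = 0.05)
  expect_equal(m$q1, 4.5)
  expect_equal(m$q3, 9.5)
  expect_equal(m$outlier_fence, 17)
  expect_equal(m$n_outliers, 1L)  # the 100 is removed
  # minimum = ceiling of the empirical 5% quantile of {2,4,6,8,10}
  expect_equal(m$min_reads, ceiling(unname(quantile(c(2, 4, 6, 8, 10), 0.05, type = 1))))
  expect_equal(m$min_reads, 2)
  expect_error(fit_threshold(c(5, 5, 5, 7, 7, 9)), "4 distinct")
})

test_that("threshold deduplicates counts and degenerates sanely", {
  # duplication of values must not move the quartiles
  base <- c(2, 4, 6, 8, 10, 100)
  m1 <- fit_threshold(base)
  m2 <- fit_threshold(rep(base, times = c(50, 1, 1, 1, 1, 3)))
  expect_equal(m1$q1, m2$q1)
  expect_equal(m1$q3, m2$q3)
  expect_equal(m1$outlier_fence, m2$outlier_fence)
  # near-degenerate: quartiles come from the unique values but the minimum
  # comes from the full empirical distribution, dominated by the mode
  x <- c(rep(7, 100), 5, 6, 8)
  m3 <- fit_threshold(x)
  expect_equal(m3$min_reads, ceiling(unname(quantile(x, 0.05, type = 1))))
  expect_equal(m3$min_reads, 7)
  expect_equal(m3$n_outliers, 0L)
})

test_that("threshold recovers the tail of an NB distribution with a planted outlier", {
  set.seed(99)
  x <- c(rnbinom(1e4, mu = 50, size = 10), 1e6)
  m <- fit_threshold(x)
  expect_equal(m$n_outliers, 1L)  # only the planted outlier is extreme
  expect_lte(m$min_reads, m$q1)
  expect_gte(m$min_reads, 1)
  # direct empirical-quantile oracle on the outlier-free draws
  kept <- x[x <= m$outlier_fence]
  expect_equal(m$min_reads, ceiling(unname(quantile(kept, 0.05, type = 1))))
})

test_that("filtering keeps the closed interval [min_reads, fence]", {
  m <- fit_threshold(c(2, 4, 6, 8, 10, 100))
  e <- mk_exons("t", c(0, 100, 200, 300), c(50, 150, 250, 350),
                counts = c(m$min_reads, m$min_reads - 1, 17, 18))
  f <- filter_significant(e, m)
  expect_equal(f$kept$count, c(m$min_reads, 17))
  expect_equal(f$removed_low$count, m$min_reads - 1)
  expect_equal(f$removed_outlier$count, 18)
  tf <- mk_tfset("s1", "A", list(e))
  m$sample_id <- "s2"
  expect_error(filter_significant(tf, m), "sample")
})

test_that("significance filter keeps expressed exons at roughly 1 - alpha", {
  set.seed(7)
  ref_counts <- rnbinom(2000, mu = 50, size = 5)
  m <- fit_threshold(ref_counts, alpha = 0.05)
  expressed <- mk_exons("e", seq(0, by = 1000, length.out = 100),
                        seq(100, by = 1000, length.out = 100),
                        counts = rnbinom(100, mu = 50, size = 5))
  weak <- mk_exons("w", seq(1e6, by = 1000, length.out = 50),
                   seq(1e6 + 100, by = 1000, length.out = 50),
                   counts = rpois(50, 0.3))
  f <- filter_significant(rbind(expressed, weak), m)
  kept_expr <- sum(f$kept$transcript_id == "e")
  expect_gte(kept_expr, 88)   # >= 95% expected minus binomial slack
  expect_lte(sum(f$kept$transcript_id == "w"), 5)
})

test_that("the five exon labels follow the stated precedence and definitions", {
  ref <- tiny_annotation()
  lab <- function(s, e, chrom = "chr1", strand = "+")
    classify_exon(genomic_interval(chrom, s, e, strand), ref)$label
  expect_identical(lab(100, 200), "Exact")
  expect_identical(lab(120, 180), "Within")
  expect_identical(lab(150, 250), "Overlap")
  expect_identical(lab(250, 290), "Novel-T")   # intronic, inside gA span
  expect_identical(lab(5000, 5100), "Novel-U") # outside every span
  # strict superset of a reference exon is Overlap, not Within
  expect_identical(lab(90, 210), "Overlap")
  # strand compatibility: gB is on '-'; a '+' exon there reads as novel
  expect_identical(lab(2000, 2200, strand = "-"), "Exact")
  expect_identical(lab(2000, 2200, strand = "+"), "Novel-U")
  expect_identical(lab(2000, 2200, strand = "*"), "Exact")
})

test_that("classifier agrees with the linear-scan oracle on randomized intervals", {
  ref <- generate_annotation(n_genes = 30, seed = 13)$annotation
  set.seed(14)
  n <- 2000
  lo <- sample.int(6e5, n)
  qs <- data.table::data.table(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = lo, end = lo + sample.int(800, n, replace = TRUE),
    strand = sample(c("+", "-", "*"), n, TRUE))
  got <- classify_exons(qs, ref)$label
  want <- vapply(seq_len(n), function(i)
    oracle_classify_exon(qs$chrom[i], qs$start[i], qs$end[i], qs$strand[i], ref),
    character(1))
  expect_identical(got, want)
  expect_true(all(got %in% c("Exact", "Within", "Overlap", "Novel-T", "Novel-U")))
})

test_that("treatment partition splits exons into unique and common additively", {
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  ex <- function(s) data.table::data.table(chrom = "chr1", start = s,
                                           end = s + 100, strand = "+",
                                           label = "Exact")
  classified <- list(
    a1 = rbind(ex(0), ex(1000)),          # 0 shared by a1, a2, b1
    a2 = rbind(ex(0), ex(2000)),
    b1 = rbind(ex(0), ex(3000)),
    b2 = ex(4000))
  p <- partition_by_treatment(classified, grp)
  s <- p$summary
  expect_equal(s$common, 1L)
  expect_equal(s$unique_A, 2L)
  expect_equal(s$unique_B, 2L)
  expect_equal(s$common + s$unique_A + s$unique_B, nrow(p$exons))
  # requiring 2 supporting samples per group demotes the shared exon (only
  # one B replicate carries it) to unique in the group that does support it
  p2 <- partition_by_treatment(classified, grp, min_support_per_group = 2L)
  expect_equal(p2$summary$common, 0L)
  expect_equal(p2$summary$unique_A, 3L)
  expect_error(partition_by_treatment(classified, c(a1 = "A")), "unknown sample")
})

test_that("planted unique/common Novel-U exons are recovered and order-invariant", {
  grp <- c(A_1 = "A", A_2 = "A", B_1 = "B", B_2 = "B")
  mk <- function(starts) data.table::data.table(
    chrom = "chr9", start = starts, end = starts + 50, strand = "+",
    label = "Novel-U")
  common_starts <- seq(0, by = 1e4, length.out = 10)
  a_starts <- seq(1e6, by = 1e4, length.out = 5)
  b_starts <- seq(2e6, by = 1e4, length.out = 5)
  classified <- list(A_1 = mk(c(common_starts, a_starts)),
                     A_2 = mk(common_starts),
                     B_1 = mk(c(common_starts, b_starts)),
                     B_2 = mk(common_starts))
  p <- partition_by_treatment(classified, grp)
  expect_equal(p$summary$unique_A, 5L)
  expect_equal(p$summary$unique_B, 5L)
  expect_equal(p$summary$common, 10L)
  p_rev <- partition_by_treatment(rev(classified), grp)
  expect_equal(as.data.frame(p$exons), as.data.frame(p_rev$exons))
})
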