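grp8 <- setNames(rep(c("CTRL", "TREATED"), each = 4),
                 c(paste0("CTRL_", 1:4), paste0("TREATED_", 1:4)))

mk_ft <- function(m, grp = grp8) {
  colnames(m) <- names(grp)[seq_len(ncol(m))]
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%03d", seq_len(nrow(m)))
  feature_table(m, group_labels = grp)
}

test_that("RPM normalization is counts per million mapped reads", {
  ft <- mk_ft(matrix(c(500, 0, 250, 1000), nrow = 2), grp8[1:2])
  totals <- c(CTRL_1 = 1e7, CTRL_2 = 5e6)
  r <- rpm_normalize(ft, totals)
  expect_equal(r$values[1, 1], 50)
  expect_equal(r$values[2, 1], 0)
  expect_equal(r$values[2, 2], 200)
  # column sums scale exactly by 1e6 / total
  expect_equal(colSums(r$values),
               1e6 * colSums(ft$values) / totals, ignore_attr = TRUE)
  expect_error(rpm_normalize(ft, c(CTRL_1 = 1e7)), "totals")
})

test_that("quantile normalization equalizes column distributions", {
  # 3-value hand computation: post-log columns get per-rank means
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3)
  ft <- mk_ft(m, grp8[1:2])
  q <- log2_quantile_normalize(ft, pseudocount = 0)
  want <- rowMeans(log2(m))
  expect_equal(unname(q$values[, 1]), want)
  expect_equal(unname(q$values[, 2]), want)
  # identical columns are a fixed point (up to the log)
  m2 <- matrix(rep(c(3, 9, 27), 2), nrow = 3)
  q2 <- log2_quantile_normalize(mk_ft(m2, grp8[1:2]), pseudocount = 0)
  expect_equal(unname(q2$values[, 1]), log2(c(3, 9, 27)))
  # defining property on random data: sorted columns identical; idempotent
  set.seed(1)
  m3 <- matrix(rexp(400, 0.1), nrow = 50)
  q3 <- log2_quantile_normalize(mk_ft(m3), pseudocount = 1)
  sorted <- apply(q3$values, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1, 1, 1, 1)], ignore_attr = TRUE)
  q4 <- feature_table(2^(q3$values), group_labels = q3$group_labels)
  q5 <- log2_quantile_normalize(q4, pseudocount = 0)
  expect_equal(q5$values, q3$values, tolerance = 1e-12)
})

test_that("median polish decomposes additive matrices exactly", {
  x <- matrix(c(1, 3, 2, 4), nrow = 2)  # perfectly additive
  colnames(x) <- c("s1", "s2")
  mp <- median_polish_summarize(x)
  expect_equal(max(abs(mp$residuals)), 0)
  expect_equal(unname(mp$summary), c(2, 3))
  # single probe passes through
  one <- matrix(c(5, 7, 6, 9), nrow = 1, dimnames = list("p1", paste0("s", 1:4)))
  expect_equal(unname(median_polish_summarize(one)$summary), c(5, 7, 6, 9))
  expect_error(median_polish_summarize(matrix(c(1, NA), 1)), "finite")
})

test_that("median polish agrees with the base-R sweep oracle on random matrices", {
  set.seed(21)
  for (i in 1:20) {
    x <- matrix(rnorm(5 * 4, mean = 8), nrow = 5)
    colnames(x) <- paste0("s", 1:4)
    mp <- median_polish_summarize(x, max_iter = 100, tol = 1e-9)
    expect_equal(unname(mp$summary), unname(oracle_median_polish_summary(x)),
                 tolerance = 1e-6)
  }
  # row permutation invariance; column-shift equivariance
  x <- matrix(rnorm(24, 10), nrow = 6, dimnames = list(NULL, paste0("s", 1:4)))
  s1 <- median_polish_summarize(x, max_iter = 100, tol = 1e-9)$summary
  s2 <- median_polish_summarize(x[sample(6), ], max_iter = 100, tol = 1e-9)$summary
  expect_equal(s1, s2, tolerance = 1e-9)
  x3 <- x; x3[, 2] <- x3[, 2] + 1.5
  s3 <- median_polish_summarize(x3, max_iter = 100, tol = 1e-9)$summary
  expect_equal(unname(s3 - s1), c(0, 1.5, 0, 0), tolerance = 1e-7)
})

test_that("signed fold change is the symmetric ratio convention", {
  expect_equal(signed_fold_change(8, 2), 4)
  expect_equal(signed_fold_change(2, 4), -2)
  expect_equal(signed_fold_change(3, 3), 1)
  expect_equal(signed_fold_change(c(8, 2), c(2, 4)), c(4, -2))
  # antisymmetry away from r = 1
  expect_equal(signed_fold_change(5, 2), -signed_fold_change(2, 5))
  expect_error(signed_fold_change(0, 1), "positive")
})

test_that("exact permutation p enumerates all distinct partitions", {
  # (1,2) vs (3,4): 2 of 6 subsets reach |t| of the observed split
  r <- permutation_t_test(c(1, 2, 3, 4), c("A", "A", "B", "B"), mode = "exact")
  expect_equal(r$p_value, 2 / 6)
  expect_equal(r$n_used, 6L)
  expect_equal(r$p_value, oracle_exact_perm_p(c(1, 2, 3, 4), c("A", "A", "B", "B")))
  # 4v4 enumerates choose(8,4) = 70 and matches brute force
  set.seed(3)
  for (i in 1:10) {
    v <- rnorm(8)
    r <- permutation_t_test(v, grp8, mode = "exact")
    expect_equal(r$n_used, 70L)
    expect_equal(r$p_value, oracle_exact_perm_p(v, unname(grp8)))
  }
  expect_error(permutation_t_test(1:3, c("A", "A", "B")), "at least 2")
})

test_that("constant features return p = 1 with a zero-variance flag", {
  r <- permutation_t_test(rep(5, 8), grp8, mode = "exact")
  expect_equal(r$p_value, 1)
  expect_true(r$zero_variance)
})

test_that("random-mode p agrees with exact mode within Monte-Carlo tolerance", {
  set.seed(11)
  for (i in 1:5) {
    v <- rnorm(8) + rep(c(0, 1.2), each = 4)
    pe <- permutation_t_test(v, grp8, mode = "exact")$p_value
    pr <- permutation_t_test(v, grp8, mode = "random", n_perm = 10000,
                             seed = 100 + i)$p_value
    tol <- 3 * sqrt(pe * (1 - pe) / 10000) + 2 / 10000
    expect_lt(abs(pr - pe), max(tol, 0.01))
  }
})

test_that("exact permutation p-values are super-uniform under the null", {
  set.seed(31)
  p <- vapply(1:500, function(i)
    permutation_t_test(rnorm(8), grp8, mode = "exact")$p_value, numeric(1))
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lte(frac, 0.05 + 3 * se)
  expect_gte(min(p), 1 / 70)
})

test_that("call_degs applies the uncorrected FC and p cutoffs", {
  set.seed(5)
  n_eff <- 50
  effects <- setNames(c(rep(4, n_eff), rep(1, 950)), sprintf("f%04d", 1:1000))
  ft <- generate_counts(effects, grp8, base_mean = 200, dispersion = 0.02,
                        seed = 17)
  deg <- call_degs(ft, n_perm = 2000, seed = 1)
  called <- deg$feature_id[deg$is_deg]
  planted <- names(effects)[effects > 1]
  expect_gte(length(intersect(called, planted)), 45)
  expect_lte(length(setdiff(called, planted)), ceiling(0.005 * 950) + 3)
  # DEG record invariant: is_deg <=> |fc| > cut & p < cut
  expect_equal(deg$is_deg,
               abs(deg$signed_fc) > 2 & deg$p_value < 0.005 & !deg$zero_variance)
  expect_true(all(abs(deg$signed_fc) >= 1))
})

test_that("per-feature null mode cannot undercut its granularity floor", {
  set.seed(6)
  effects <- setNames(rep(1, 20), sprintf("f%02d", 1:20))
  ft <- generate_counts(effects, grp8, base_mean = 100, dispersion = 0.1, seed = 2)
  deg <- call_degs(ft, mode = "exact", null_dist = "per_feature")
  expect_gte(min(deg$p_value), 1 / 70)
  expect_false(any(deg$is_deg))
})

test_that("quartile Spearman rho rises with expression under signal-dependent noise", {
  pp <- generate_platform_pair(n_features = 400, noise = "signal_dependent",
                               seed = 5)
  qs <- quartile_spearman(pp$a, pp$b)
  rho_q <- vapply(1:4, function(q) mean(qs$rho[qs$quartile == q]), numeric(1))
  expect_true(all(diff(rho_q) > 0))
  expect_gt(rho_q[4], 0.8)
  # exchangeable noise: statistically flat profile
  pp2 <- generate_platform_pair(n_features = 400, noise = "exchangeable", seed = 6)
  qs2 <- quartile_spearman(pp2$a, pp2$b)
  rho_q2 <- vapply(1:4, function(q) mean(qs2$rho[qs2$quartile == q]), numeric(1))
  expect_lt(max(rho_q2) - min(rho_q2), 0.15)
  # p-value is the t-approximation
  one <- qs[1]
  tt <- one$rho * sqrt((one$n - 2) / (1 - one$rho^2))
  expect_equal(one$p_value, 2 * pt(-abs(tt), one$n - 2))
})

test_that("perfectly monotone platforms give rho 1 in every quartile", {
  set.seed(8)
  m <- matrix(runif(400, 1, 100), nrow = 50)
  a <- mk_ft(m)
  b <- mk_ft(m * 3 + 1)
  qs <- quartile_spearman(a, b)
  expect_true(all(qs$rho == 1))
  expect_true(all(qs$p_value == 0))
})

test_that("exon-specific fold change separates defining from shared exons", {
  # two isoforms share exons 2-3; exon 1 of each isoform is defining
  fam <- rbind(
    mk_exons("iso1", c(0, 1000, 2000), c(100, 1100, 2100), gene = "fam"),
    mk_exons("iso2", c(500, 1000, 2000), c(600, 1100, 2100), gene = "fam"))
  grp <- c(c1 = "CTRL", c2 = "CTRL", t1 = "TREATED", t2 = "TREATED")
  base <- c(iso1 = 100, iso2 = 100)
  ec <- data.table::rbindlist(lapply(names(grp), function(s) {
    k <- if (grp[s] == "TREATED") 6 else 1  # defining exon of iso1 induced
    data.table::data.table(
      transcript_id = rep(c("iso1", "iso2"), each = 3),
      exon_index = rep(1:3, 2),
      sample_id = s,
      count = c(100 * k, 100, 100, 50, 100, 100))
  }))
  r <- exon_specific_fc(annotation_set(fam), ec, grp)
  pe <- r$per_exon
  expect_equal(pe$role, c("defining", "defining", "shared", "shared"))
  expect_equal(pe$fc[pe$start == 0], 6)          # planted induction, exact
  expect_equal(pe$fc[pe$start == 500], 1)        # iso2 defining unchanged
  expect_true(all(pe$fc[pe$role == "shared"] == 1))
  ptx <- r$per_transcript
  fc1 <- ptx$fc[ptx$transcript_id == "iso1"]
  expect_gt(fc1, 1); expect_lt(fc1, 6)           # count-weighted compromise
  expect_equal(fc1, (600 + 200) / (100 + 200))   # closed form from count sums
  # whole-transcript FC lies between the per-exon extremes
  expect_gte(fc1, min(pe$fc[1:3])); expect_lte(fc1, max(pe$fc[1:3]))
})

test_that("exon FC degenerates are flagged rather than computed", {
  fam <- mk_exons("solo", c(0, 1000), c(100, 1100), gene = "g")
  grp <- c(c1 = "CTRL", t1 = "TREATED", c2 = "CTRL", t2 = "TREATED")
  ec <- data.table::CJ(transcript_id = "solo", exon_index = 1:2,
                       sample_id = names(grp))
  ec[, count := ifelse(exon_index == 1, 30, 0)]
  expect_warning(r <- exon_specific_fc(fam, ec, grp), "family of one")
  expect_true(all(r$per_exon$role == "defining"))
  expect_identical(r$per_exon$flag[r$per_exon$start == 1000], "undefined")
  expect_true(is.na(r$per_exon$fc[r$per_exon$start == 1000]))
})

test_that("platform overlap computes exact Venn regions", {
  v <- platform_overlap(list(x = c("a", "b", "c"), y = c("b", "c", "d")))
  r <- setNames(v$regions$n, v$regions$region)
  expect_equal(unname(r[c("x", "x&y", "y")]), c(1L, 2L, 1L))
  expect_equal(sum(v$regions$n), 4L)
  expect_equal(v$pairwise$shared, 2L)
  # identical sets collapse to one region
  v2 <- platform_overlap(list(x = c("a", "b"), y = c("a", "b")))
  expect_equal(v2$regions$region, "x&y")
  # three random sets: regions partition the union (brute-force set algebra)
  set.seed(9)
  uni <- sprintf("u%04d", 1:1000)
  sets <- lapply(1:3, function(i) sample(uni, 100))
  names(sets) <- c("s1", "s2", "s3")
  v3 <- platform_overlap(sets)
  expect_equal(sum(v3$regions$n), length(unique(unlist(sets))))
  expect_error(platform_overlap(list(a = "x")), "2 or 3")
})
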