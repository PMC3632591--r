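test_that("interval constructor rejects degenerate input", {
  expect_error(genomic_interval("chr1", 10, 10), "empty interval")
  expect_error(genomic_interval("chr1", 20, 10), "empty interval")
  expect_error(genomic_interval("chr1", -1, 10), "non-negative")
  expect_error(genomic_interval("chr1", 1.5, 10), "non-negative integers")
  expect_error(genomic_interval("chr1", 1, 10, strand = "x"), "strand")
})

test_that("overlap_relation matches the stated examples", {
  gi <- function(s, e, st = "+") genomic_interval("chr1", s, e, st)
  expect_identical(overlap_relation(gi(100, 200), gi(100, 200)), "exact")
  expect_identical(overlap_relation(gi(120, 180), gi(100, 200)), "a_within_b")
  expect_identical(overlap_relation(gi(150, 250), gi(100, 200)), "partial")
  expect_identical(overlap_relation(gi(100, 200), gi(120, 180)), "b_within_a")
  # strand semantics: opposite known strands are disjoint unless ignored
  expect_identical(overlap_relation(gi(100, 200), gi(100, 200, "-")), "disjoint")
  expect_identical(overlap_relation(gi(100, 200), gi(100, 200, "-"), "ignore"), "exact")
  expect_identical(overlap_relation(gi(100, 200), gi(100, 200, "*")), "exact")
  expect_identical(
    overlap_relation(gi(100, 200), genomic_interval("chr2", 100, 200)), "disjoint")
})

test_that("overlap_relation agrees with the position-set brute force exhaustively", {
  # all ordered pairs of integer intervals within [0, 12)
  bounds <- t(combn(0:12, 2))
  ivs <- lapply(seq_len(nrow(bounds)), function(i)
    genomic_interval("chr1", bounds[i, 1], bounds[i, 2], "+"))
  pairs <- expand.grid(i = seq_along(ivs), j = seq_along(ivs))
  for (mode in c("require_same", "ignore")) {
    got <- mapply(function(i, j) overlap_relation(ivs[[i]], ivs[[j]], mode),
                  pairs$i, pairs$j)
    want <- mapply(function(i, j) oracle_overlap_relation(ivs[[i]], ivs[[j]], mode),
                   pairs$i, pairs$j)
    expect_identical(got, want)
    # symmetry up to swapping containment roles
    swap <- c(disjoint = "disjoint", exact = "exact", partial = "partial",
              a_within_b = "b_within_a", b_within_a = "a_within_b")
    back <- mapply(function(i, j) overlap_relation(ivs[[j]], ivs[[i]], mode),
                   pairs$i, pairs$j)
    expect_identical(back, unname(swap[got]))
  }
})

test_that("intron_chain returns consecutive junction pairs", {
  e <- mk_exons("t", c(0, 20, 40), c(10, 30, 50))
  expect_equal(intron_chain(e), cbind(donor = c(10, 30), acceptor = c(20, 40)))
  expect_equal(nrow(intron_chain(mk_exons("t", 0, 10))), 0L)
  # chain equality is invariant to terminal-exon end perturbation ...
  e2 <- mk_exons("t", c(3, 20, 40), c(10, 30, 47))
  expect_equal(intron_chain(e2), intron_chain(e))
  # ... and sensitive to any internal splice-site shift of +/-1
  for (row in 1:3) for (d in c(-1L, 1L)) {
    e3 <- copy(e)
    if (row < 3) e3[row, "end"] <- e3[row, ]$end + d
    else e3[2, "start"] <- e3[2, ]$start + d
    expect_false(isTRUE(all.equal(intron_chain(e3), intron_chain(e))))
  }
  bad <- mk_exons("t", c(0, 5), c(10, 30))  # overlapping exons
  expect_error(intron_chain(bad), "overlapping")
})

test_that("merge_union collapses identical chains and keeps presence", {
  e1 <- mk_exons("x1", c(0, 100, 200), c(50, 150, 250), counts = c(10, 10, 10))
  e2 <- mk_exons("y1", c(10, 100, 200), c(50, 150, 260), counts = c(5, 5, 5))
  s1 <- mk_tfset("s1", "A", list(e1))
  s2 <- mk_tfset("s2", "B", list(e2))
  u <- merge_union(list(s1, s2))
  expect_equal(nrow(u$transcripts), 1L)
  expect_identical(u$presence[[1L]], c("s1", "s2"))
  expect_equal(c(u$transcripts$start, u$transcripts$end), c(0, 260))  # widest
  expect_equal(unname(u$counts[1, ]), c(30, 15))
  # one junction difference keeps records apart
  e3 <- mk_exons("z1", c(0, 101, 200), c(50, 150, 250), counts = c(1, 1, 1))
  u2 <- merge_union(list(s1, mk_tfset("s3", "B", list(e3))))
  expect_equal(nrow(u2$transcripts), 2L)
})

test_that("single-exon transfrags merge by same-strand single-linkage", {
  a <- mk_exons("a", 100, 200, counts = 1)
  b <- mk_exons("b", 180, 300, counts = 1)          # overlaps a
  c_ <- mk_exons("c", 290, 400, counts = 1)         # overlaps b, not a
  d <- mk_exons("d", 100, 200, strand = "-", counts = 1)  # opposite strand
  u <- merge_union(list(mk_tfset("s1", "A", list(a)), mk_tfset("s2", "A", list(b)),
                        mk_tfset("s3", "B", list(c_)), mk_tfset("s4", "B", list(d))))
  expect_equal(nrow(u$transcripts), 2L)  # {a,b,c} chained; d apart
  chained <- u$transcripts[u$transcripts$strand == "+", ]
  expect_equal(c(chained$start, chained$end), c(100, 400))
})

test_that("merge_union is idempotent and order-invariant", {
  set.seed(42)
  sets <- lapply(1:4, function(i) {
    exons <- rbind(
      mk_exons("shared", c(0, 100), c(50, 150), counts = c(2, 2)),
      mk_exons(paste0("uniq", i), c(1000 * i, 1000 * i + 200),
               c(1000 * i + 100, 1000 * i + 300), counts = c(3, 3)))
    transfrag_set(exons, sample_id = paste0("s", i),
                  group_label = if (i <= 2) "A" else "B")
  })
  u <- merge_union(sets)
  expect_equal(nrow(u$transcripts), 5L)  # 1 shared + 4 unique
  # order invariance
  u_rev <- merge_union(rev(sets))
  cols <- c("chrom", "strand", "start", "end", "n_exons", "chain")
  expect_equal(as.data.frame(u$transcripts)[cols], as.data.frame(u_rev$transcripts)[cols])
  expect_identical(u$presence, u_rev$presence[names(u$presence)])
  # idempotence: restating the union as one sample reproduces the records
  ue <- copy(u$exons)
  setnames(ue, "union_id", "transcript_id")
  ue[, `:=`(gene_id = transcript_id, count = 1)]
  u2 <- merge_union(list(transfrag_set(ue, sample_id = "u", group_label = "A")))
  expect_equal(as.data.frame(u2$transcripts)[cols], as.data.frame(u$transcripts)[cols])
  expect_error(merge_union(list()), "at least one")
})

test_that("union size recovers the planted distinct-chain count", {
  # 8 samples, planted: 3 chains shared by all, plus one unique chain each
  sets <- lapply(1:8, function(i) {
    shared <- rbindlist(lapply(1:3, function(k)
      mk_exons(paste0("sh", k), c(k * 10000, k * 10000 + 500),
               c(k * 10000 + 100, k * 10000 + 700), counts = c(1, 1))))
    uniq <- mk_exons(paste0("un", i), c(i * 100000, i * 100000 + 400),
                     c(i * 100000 + 150, i * 100000 + 600), counts = c(1, 1))
    transfrag_set(rbind(shared, uniq), sample_id = paste0("s", i),
                  group_label = if (i <= 4) "A" else "B")
  })
  u <- merge_union(sets)
  # exhaustive pairwise chain-equality oracle on the planted models
  all_models <- rbindlist(lapply(sets, function(s) {
    t <- s$transcripts; t$sample <- s$sample_id; t
  }))
  planted_distinct <- nrow(unique(all_models[, c("chrom", "chain")]))
  expect_equal(nrow(u$transcripts), planted_distinct)
  expect_equal(nrow(u$transcripts), 11L)
  shared_rec <- u$transcripts[vapply(u$presence[u$transcripts$union_id],
                                     length, integer(1L)) == 8L, ]
  expect_equal(nrow(shared_rec), 3L)
})
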