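# Independent oracles and fixture builders used across the suite. Every
# oracle is a deliberately naive implementation (position sets, linear scans,
# exhaustive enumeration, base-R reference routines) kept free of the
# package's interval-index code paths.

library(data.table)

.compat <- function(s1, s2) s1 == "*" | s2 == "*" | s1 == s2

# position-set brute force for interval relations
oracle_overlap_relation <- function(a, b, strand_mode = "require_same") {
  if (a$chrom != b$chrom) return("disjoint")
  if (strand_mode == "require_same" && !.compat(a$strand, b$strand)) return("disjoint")
  pa <- seq(a$start, a$end - 1L); pb <- seq(b$start, b$end - 1L)
  common <- intersect(pa, pb)
  if (!length(common)) return("disjoint")
  if (setequal(pa, pb)) return("exact")
  if (all(pa %in% pb)) return("a_within_b")
  if (all(pb %in% pa)) return("b_within_a")
  "partial"
}

# linear scan over all reference exons / transcript spans, restating the
# five-class definitions verbatim: Exact (identical boundaries) > Within
# (contained in a reference exon) > Overlap (partial overlap); otherwise
# Novel-T when between the transcription start and end site of a gene,
# else Novel-U.
oracle_classify_exon <- function(chrom, start, end, strand, ref) {
  re <- ref$exons; rt <- ref$transcripts
  hit <- re$chrom == chrom & .compat(strand, re$strand) &
    start < re$end & re$start < end
  if (any(hit)) {
    exact <- hit & re$start == start & re$end == end
    if (any(exact)) return("Exact")
    within <- hit & start >= re$start & end <= re$end
    if (any(within)) return("Within")
    return("Overlap")
  }
  span <- rt$chrom == chrom & .compat(strand, rt$strand) &
    start >= rt$start & end <= rt$end
  if (any(span)) "Novel-T" else "Novel-U"
}

# junction chain as a plain matrix, by sorting exon rows
oracle_chain <- function(e) {
  e <- e[order(e$start), ]
  n <- nrow(e)
  if (n == 1L) return(NULL)
  cbind(e$end[-n], e$start[-1L])
}

# linear-scan transcript classifier: complete / partial / novel
oracle_classify_transcript <- function(exons, ref) {
  exons <- as.data.table(exons)[order(start)]
  chrom <- exons$chrom[1L]; strand <- exons$strand[1L]
  ch <- oracle_chain(exons)
  for (tid in ref$transcripts$transcript_id) {
    rt <- ref$transcripts[ref$transcripts$transcript_id == tid, ]
    if (rt$chrom != chrom || !.compat(strand, rt$strand)) next
    re <- ref$exons[ref$exons$transcript_id == tid, ]
    rch <- oracle_chain(as.data.table(re))
    if (is.null(ch) && is.null(rch)) {
      if (exons$start[1L] >= re$start[1L] && exons$end[1L] <= re$end[1L]) {
        return("complete")
      }
    } else if (!is.null(ch) && !is.null(rch) && identical(ch, rch)) {
      return("complete")
    }
  }
  span_lo <- min(exons$start); span_hi <- max(exons$end)
  touches <- any(ref$transcripts$chrom == chrom &
                   span_lo < ref$transcripts$end &
                   ref$transcripts$start < span_hi)
  if (touches) "partial" else "novel"
}

# base-R reference for the median-polish summaries
oracle_median_polish_summary <- function(x, eps = 1e-9) {
  mp <- stats::medpolish(x, eps = eps, maxiter = 5000L, trace.iter = FALSE)
  mp$overall + mp$col
}

# exhaustive two-sample pooled-t permutation p (all C(n, n1) group-A subsets)
oracle_exact_perm_p <- function(values, group_labels) {
  glev <- sort(unique(group_labels))
  ia <- which(group_labels == glev[1L])
  n <- length(values); n1 <- length(ia)
  tstat <- function(sel) {
    x <- values[sel]; y <- values[-sel]
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n - 2)
    d <- mean(x) - mean(y)
    den <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    if (den == 0) { if (d == 0) 0 else sign(d) * Inf } else d / den
  }
  t_obs <- tstat(ia)
  subsets <- combn(n, n1, simplify = FALSE)
  mean(vapply(subsets, function(s) abs(tstat(s)) >= abs(t_obs), logical(1L)))
}

# fixture builders ------------------------------------------------------

mk_exons <- function(tid, starts, ends, chrom = "chr1", strand = "+",
                     gene = tid, counts = NULL) {
  d <- data.table(transcript_id = tid, gene_id = gene, chrom = chrom,
                  start = starts, end = ends, strand = strand)
  if (!is.null(counts)) d$count <- counts
  d
}

# a small hand-built annotation: two multi-exon genes, one single-exon gene,
# on two chromosomes and both strands
tiny_annotation <- function() {
  annotation_set(rbind(
    mk_exons("gA.t1", c(100, 300, 600), c(200, 400, 700), gene = "gA"),
    mk_exons("gB.t1", c(2000, 2500), c(2200, 2700), strand = "-", gene = "gB"),
    mk_exons("gC.t1", 500, 900, chrom = "chr2", gene = "gC")
  ))
}

mk_tfset <- function(sample_id, group, exon_list) {
  transfrag_set(rbindlist(exon_list), sample_id = sample_id,
                group_label = group)
}
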