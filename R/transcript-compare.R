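# Classification of assembled transcript models against reference annotation:
# 'complete' (identical intron chain), 'partial' (overlaps annotation without a
# full chain match) and 'novel' (intergenic: no span overlap with any reference
# transcript), plus probe-coverage accounting.

# normalize annotation_set / transfrag_union to (transcripts, exons) with a
# transcript_id column
.models_of <- function(x) {
  if (inherits(x, "transfrag_union")) {
    tx <- copy(x$transcripts); setnames(tx, "union_id", "transcript_id")
    ex <- copy(x$exons); setnames(ex, "union_id", "transcript_id")
    list(transcripts = tx, exons = ex)
  } else if (inherits(x, "annotation_set")) {
    list(transcripts = copy(x$transcripts), exons = copy(x$exons))
  } else stop("expected an annotation_set or transfrag_union")
}

# vectorized classifier core; returns data.table(transcript_id, class, match_id)
.classify_models <- function(q, ref) {
  qt <- q$transcripts; qe <- q$exons
  rt <- ref$transcripts; re <- ref$exons
  out <- data.table(transcript_id = qt$transcript_id,
                    class = "novel", match_id = NA_character_)
  if (!nrow(rt)) return(out)

  q_width <- qt$end - qt$start
  setkey(out, transcript_id)

  ## complete: multi-exon chain identity (strand-compatible)
  multi <- qt[n_exons > 1L]
  if (nrow(multi)) {
    rmulti <- rt[n_exons > 1L]
    if (nrow(rmulti)) {
      cand <- merge(multi[, .(transcript_id, chrom, chain, strand,
                              width = end - start)],
                    rmulti[, .(ref_id = transcript_id, chrom, chain,
                               ref_strand = strand, ref_width = end - start)],
                    by = c("chrom", "chain"), allow.cartesian = TRUE)
      cand <- cand[.strand_compatible(strand, ref_strand)]
      if (nrow(cand)) {
        cand[, dspan := abs(width - ref_width)]
        setorder(cand, transcript_id, dspan, ref_id)
        best <- cand[, .SD[1L], by = transcript_id]
        out[best$transcript_id, `:=`(class = "complete", match_id = best$ref_id)]
      }
    }
  }
  ## complete: single-exon containment in a single-exon reference exon
  single <- qt[n_exons == 1L]
  if (nrow(single)) {
    rsingle_ids <- rt[n_exons == 1L, transcript_id]
    if (length(rsingle_ids)) {
      rse <- re[transcript_id %in% rsingle_ids]
      qgr <- GenomicRanges::GRanges(single$chrom,
                                    IRanges::IRanges(single$start + 1L, single$end),
                                    strand = single$strand)
      rgr <- GenomicRanges::GRanges(rse$chrom,
                                    IRanges::IRanges(rse$start + 1L, rse$end),
                                    strand = rse$strand)
      hits <- .fo(qgr, rgr, type = "within")
      if (length(hits)) {
        h <- data.table(transcript_id = single$transcript_id[S4Vectors::queryHits(hits)],
                        ref_id = rse$transcript_id[S4Vectors::subjectHits(hits)],
                        width = single$end[S4Vectors::queryHits(hits)] -
                          single$start[S4Vectors::queryHits(hits)],
                        ref_width = rse$end[S4Vectors::subjectHits(hits)] -
                          rse$start[S4Vectors::subjectHits(hits)])
        h[, dspan := abs(width - ref_width)]
        setorder(h, transcript_id, dspan, ref_id)
        best <- h[, .SD[1L], by = transcript_id]
        out[best$transcript_id, `:=`(class = "complete", match_id = best$ref_id)]
      }
    }
  }

  ## remaining: partial iff the span intersects any reference transcript span
  ## (any strand: 'intergenic' means annotation-free on either strand)
  rest <- out[class == "novel", transcript_id]
  if (length(rest)) {
    qs <- qt[transcript_id %in% rest]
    qspan <- GenomicRanges::GRanges(qs$chrom, IRanges::IRanges(qs$start + 1L, qs$end))
    rspan <- GenomicRanges::GRanges(rt$chrom, IRanges::IRanges(rt$start + 1L, rt$end))
    sp_hits <- .fo(qspan, rspan, ignore.strand = TRUE)
    touched <- unique(S4Vectors::queryHits(sp_hits))
    if (length(touched)) {
      out[qs$transcript_id[touched], class := "partial"]
      # best match for partials: reference transcript with most exon-exon
      # overlap on a compatible strand, ties by transcript_id
      pe <- qe[transcript_id %in% qs$transcript_id[touched]]
      pgr <- GenomicRanges::GRanges(pe$chrom, IRanges::IRanges(pe$start + 1L, pe$end),
                                    strand = pe$strand)
      rgr <- .exon_gr(re)
      eh <- .fo(pgr, rgr)
      if (length(eh)) {
        qi <- S4Vectors::queryHits(eh); si <- S4Vectors::subjectHits(eh)
        ov <- pmin(pe$end[qi], re$end[si]) - pmax(pe$start[qi], re$start[si])
        hdt <- data.table(transcript_id = pe$transcript_id[qi],
                          ref_id = re$transcript_id[si], ov = ov)
        agg <- hdt[, .(ov = sum(ov)), by = .(transcript_id, ref_id)]
        setorder(agg, transcript_id, -ov, ref_id)
        best <- agg[, .SD[1L], by = transcript_id]
        out[best$transcript_id, match_id := best$ref_id]
      }
    }
  }
  out[qt$transcript_id]
}

#' Classify one transcript model against reference annotation
#'
#' A model is `complete` when a strand-compatible reference transcript has an
#' identical intron chain (single-exon case: the exon is contained in a
#' single-exon reference transcript's exon), `partial` when it is not complete
#' but its span intersects annotated transcripts, and `novel` when its span
#' intersects no reference transcript (intergenic).
#'
#' @param exons exon table for a single transcript model.
#' @param ref an [annotation_set()].
#' @return list with `class` and `match_id` (best-matching reference
#'   transcript, or `NA`).
#' @export
classify_transcript <- function(exons, ref) {
  stopifnot(inherits(ref, "annotation_set"))
  exons <- .validate_exon_df(
    if (!"gene_id" %in% names(as.data.frame(exons)))
      cbind(as.data.frame(exons), gene_id = "g") else exons)
  q <- list(transcripts = .transcript_table(exons), exons = exons)
  res <- .classify_models(q, .models_of(ref))
  list(class = res$class[1L], match_id = res$match_id[1L])
}

#' Classify every union record against reference annotation
#'
#' @param union a [merge_union()] result (or a second `annotation_set`).
#' @param ref an [annotation_set()].
#' @return list with `table` (per-record class and best match) and `summary`
#'   (named counts `total`, `complete`, `partial`, `novel`; the three classes
#'   partition the total).
#' @export
classify_all <- function(union, ref) {
  stopifnot(inherits(ref, "annotation_set"))
  q <- .models_of(union)
  tab <- .classify_models(q, .models_of(ref))
  tab <- merge(tab, q$transcripts[, .(transcript_id, chrom, strand, start, end, n_exons)],
               by = "transcript_id", sort = FALSE)
  summary <- c(total = nrow(tab),
               complete = sum(tab$class == "complete"),
               partial = sum(tab$class == "partial"),
               novel = sum(tab$class == "novel"))
  list(table = tab[], summary = summary)
}

#' Probe coverage of transcript models
#'
#' A probe covers a transcript when any of its placements intersects any exon
#' of the transcript; strand is ignored (probes interrogate transcripts
#' regardless of the recorded placement strand).
#'
#' @param x an `annotation_set` or `transfrag_union`.
#' @param probes probe placement table ([read_probe_bed()]).
#' @return list with `pairs` (transcript_id, probe_id), `covered_ids`,
#'   `n_covered`, and `probes_used` (probes hitting at least one transcript).
#' @export
probe_coverage <- function(x, probes) {
  m <- .models_of(x)
  probes <- as.data.table(probes)
  pgr <- GenomicRanges::GRanges(probes$chrom,
                                IRanges::IRanges(probes$start + 1L, probes$end))
  egr <- GenomicRanges::GRanges(m$exons$chrom,
                                IRanges::IRanges(m$exons$start + 1L, m$exons$end))
  hits <- .fo(pgr, egr, ignore.strand = TRUE)
  pairs <- unique(data.table(
    transcript_id = m$exons$transcript_id[S4Vectors::subjectHits(hits)],
    probe_id = probes$probe_id[S4Vectors::queryHits(hits)]))
  setorder(pairs, transcript_id, probe_id)
  covered <- sort(unique(pairs$transcript_id))
  list(pairs = pairs[], covered_ids = covered, n_covered = length(covered),
       probes_used = sort(unique(pairs$probe_id)))
}
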