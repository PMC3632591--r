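#' @import data.table
#' @importFrom stats quantile median rnbinom runif rnorm setNames cor pt
#' @importFrom utils combn head tail packageVersion
NULL

# Canonical exon table columns shared by all containers. Coordinates are
# 0-based half-open internally; GTF I/O converts to/from 1-based inclusive.
.EXON_COLS <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")

.valid_strand <- function(s) s %in% c("+", "-", "*")

#' Construct a genomic interval
#'
#' The atom of all overlap logic: a chromosome, a 0-based half-open
#' `[start, end)` coordinate span, and a strand (`"*"` = unknown).
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (non-negative integer).
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start != floor(start) ||
      end != floor(end) || start < 0) {
    stop("genomic_interval: coordinates must be non-negative integers")
  }
  if (start >= end) stop("genomic_interval: empty interval rejected (start >= end)")
  if (!.valid_strand(strand)) stop("genomic_interval: strand must be +, - or *")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

.strand_compatible <- function(a, b) a == "*" | b == "*" | a == b

#' Relation between two genomic intervals
#'
#' Classifies the positional relation of interval `a` against interval `b`.
#' Under `strand_mode = "require_same"` intervals on opposite known strands
#' are reported `disjoint` (an unknown strand matches either).
#'
#' @param a,b `genomic_interval` objects.
#' @param strand_mode `"require_same"` (default) or `"ignore"`.
#' @return One of `"disjoint"`, `"exact"`, `"a_within_b"`, `"b_within_a"`,
#'   `"partial"`.
#' @export
overlap_relation <- function(a, b, strand_mode = c("require_same", "ignore")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  if (a$chrom != b$chrom) return("disjoint")
  if (strand_mode == "require_same" && !.strand_compatible(a$strand, b$strand)) {
    return("disjoint")
  }
  if (a$start >= b$end || b$start >= a$end) return("disjoint")
  if (a$start == b$start && a$end == b$end) return("exact")
  if (a$start >= b$start && a$end <= b$end) return("a_within_b")
  if (b$start >= a$start && b$end <= a$end) return("b_within_a")
  "partial"
}

.validate_exon_df <- function(exons, counts_required = FALSE) {
  exons <- as.data.table(exons)
  need <- .EXON_COLS
  if (counts_required) need <- c(need, "count")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("exon table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(exons) == 0L) stop("exon table is empty")
  if (any(!is.finite(exons$start)) || any(!is.finite(exons$end)) ||
      any(exons$start != floor(exons$start)) || any(exons$end != floor(exons$end)) ||
      any(exons$start < 0)) {
    stop("exon coordinates must be non-negative integers")
  }
  if (any(exons$start >= exons$end)) stop("exon with start >= end rejected")
  if (!all(.valid_strand(exons$strand))) stop("strand must be +, - or *")
  if (counts_required) {
    if (any(!is.finite(exons$count)) || any(exons$count < 0) ||
        any(exons$count != floor(exons$count))) {
      stop("exon counts must be non-negative integers")
    }
  }
  setorder(exons, transcript_id, start)
  exons[, exon_index := seq_len(.N), by = transcript_id]
  # within a transcript: one chrom/strand, non-overlapping sorted exons
  bad <- exons[, .(ok = uniqueN(chrom) == 1L && uniqueN(strand) == 1L &&
                     (.N == 1L || all(head(end, -1L) <= tail(start, -1L)))),
               by = transcript_id][!(ok)]
  if (nrow(bad)) {
    stop("transcript(s) with overlapping exons or mixed chrom/strand: ",
         paste(head(bad$transcript_id, 5L), collapse = ", "))
  }
  exons[]
}

.chain_string <- function(starts, ends) {
  # junction chain key; NA for single-exon models
  n <- length(starts)
  if (n == 1L) return(NA_character_)
  paste(ends[-n], starts[-1L], sep = "-", collapse = "|")
}

.transcript_table <- function(exons) {
  exons[, .(
    gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
    start = min(start), end = max(end), n_exons = .N,
    chain = .chain_string(start, end)
  ), by = transcript_id]
}

#' Build an annotation set from an exon table
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (one row per exon; internal 0-based half-open
#'   coordinates).
#' @return An `annotation_set`: validated exon table plus a per-transcript
#'   summary table carrying span and intron-chain keys.
#' @export
annotation_set <- function(exons) {
  exons <- .validate_exon_df(exons)
  tx <- .transcript_table(exons)
  if (anyDuplicated(tx$transcript_id)) stop("duplicate transcript_id in annotation")
  structure(list(exons = exons, transcripts = tx), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d transcripts, %d exons, %d chromosome(s)\n",
              nrow(x$transcripts), nrow(x$exons), uniqueN(x$exons$chrom)))
  invisible(x)
}

#' Build one sample's transfrag set
#'
#' A transfrag set holds one sample's assembled transcript models together
#' with raw read counts per exon and per transcript.
#'
#' @param exons exon table as in [annotation_set()] plus a `count` column of
#'   raw per-exon read counts.
#' @param sample_id,group_label sample identifier and treatment group.
#' @param transcript_counts named numeric vector of raw per-transcript counts;
#'   defaults to the per-transcript sum of exon counts.
#' @param total_mapped_reads positive integer library size.
#' @return A `transfrag_set` (inherits from `annotation_set`).
#' @export
transfrag_set <- function(exons, sample_id, group_label,
                          transcript_counts = NULL,
                          total_mapped_reads = NULL) {
  exons <- .validate_exon_df(exons, counts_required = TRUE)
  tx <- .transcript_table(exons)
  if (anyDuplicated(tx$transcript_id)) stop("duplicate transcript_id in transfrag set")
  if (is.null(transcript_counts)) {
    tc <- exons[, .(count = sum(count)), by = transcript_id]
    transcript_counts <- setNames(tc$count, tc$transcript_id)
  }
  if (!all(tx$transcript_id %in% names(transcript_counts))) {
    stop("transcript_counts missing entries for some transcripts")
  }
  if (is.null(total_mapped_reads)) total_mapped_reads <- sum(exons$count)
  total_mapped_reads <- as.numeric(total_mapped_reads)
  if (!is.finite(total_mapped_reads) || total_mapped_reads <= 0) {
    stop("total_mapped_reads must be positive")
  }
  structure(list(exons = exons, transcripts = tx, sample_id = sample_id,
                 group_label = group_label,
                 transcript_counts = transcript_counts[tx$transcript_id],
                 total_mapped_reads = total_mapped_reads),
            class = c("transfrag_set", "annotation_set"))
}

#' @export
print.transfrag_set <- function(x, ...) {
  cat(sprintf("<transfrag_set> sample %s (%s): %d transfrags, %d exons, %g mapped reads\n",
              x$sample_id, x$group_label, nrow(x$transcripts), nrow(x$exons),
              x$total_mapped_reads))
  invisible(x)
}

#' Intron chain of a transcript model
#'
#' @param exons exon table for a single transcript (sorted, non-overlapping),
#'   or an `annotation_set` together with `transcript_id`.
#' @param transcript_id optional transcript to extract when `exons` is an
#'   `annotation_set`.
#' @return Integer matrix with columns `donor`, `acceptor`; zero rows for a
#'   single-exon model.
#' @export
intron_chain <- function(exons, transcript_id = NULL) {
  if (inherits(exons, "annotation_set")) {
    stopifnot(!is.null(transcript_id))
    exons <- exons$exons[exons$exons$transcript_id == transcript_id, ]
    if (nrow(exons) == 0L) stop("unknown transcript_id: ", transcript_id)
  }
  exons <- .validate_exon_df(
    if (!"gene_id" %in% names(exons)) cbind(as.data.frame(exons), gene_id = "g") else exons
  )
  if (uniqueN(exons$transcript_id) != 1L) stop("intron_chain expects a single transcript")
  n <- nrow(exons)
  m <- cbind(donor = exons$end[-n], acceptor = exons$start[-1L])
  if (n == 1L) m <- m[0L, , drop = FALSE]
  m
}

# union-find over n nodes with edge list (2-column matrix); returns component root ids
.uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { j <- parent[i]; parent[i] <<- r; i <- j }
    r
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

# strand consensus for a compatibility cluster: the unique known strand, or "*"
.strand_consensus <- function(s) {
  known <- unique(s[s != "*"])
  if (length(known) == 1L) known else "*"
}

#' Merge per-sample transfrag sets into a union
#'
#' Multi-exon transfrags collapse when chromosome and intron chain are
#' identical and strands are compatible (an unknown strand matches either);
#' the union record spans the widest contributing terminal exons. Single-exon
#' transfrags collapse by same-strand single-linkage overlap. Each union
#' record keeps the set of contributing samples and the per-sample raw
#' transcript counts.
#'
#' @param sets list of `transfrag_set` objects (unique sample ids).
#' @return A `transfrag_union`: `transcripts` and `exons` tables keyed by
#'   `union_id`, `members` (union_id, sample_id, transcript_id), `presence`
#'   (named list of sample-id vectors), and a `counts` matrix
#'   (union records x samples) of summed raw transcript counts.
#' @export
merge_union <- function(sets) {
  if (!length(sets)) stop("merge_union: need at least one transfrag set")
  stopifnot(all(vapply(sets, inherits, logical(1L), "transfrag_set")))
  sample_ids <- vapply(sets, `[[`, character(1L), "sample_id")
  if (anyDuplicated(sample_ids)) stop("merge_union: duplicate sample ids")
  groups <- setNames(vapply(sets, `[[`, character(1L), "group_label"), sample_ids)

  tx <- rbindlist(lapply(sets, function(s) {
    t <- copy(s$transcripts)
    t[, sample_id := s$sample_id]
    t[, count := as.numeric(s$transcript_counts[transcript_id])]
    t
  }))
  ex <- rbindlist(lapply(sets, function(s) {
    e <- copy(s$exons)
    e[, sample_id := s$sample_id]
    e
  }), fill = TRUE)

  tx[, cluster := NA_integer_]
  next_cluster <- 0L

  # multi-exon: group by chrom+chain, then split by strand compatibility
  multi <- which(tx$n_exons > 1L)
  if (length(multi)) {
    key <- paste(tx$chrom[multi], tx$chain[multi])
    for (idx in split(multi, key)) {
      s <- tx$strand[idx]
      edges <- which(outer(seq_along(idx), seq_along(idx), function(i, j) i < j &
                             .strand_compatible(s[i], s[j])), arr.ind = TRUE)
      comp <- .uf_components(length(idx), edges)
      for (cc in split(idx, comp)) {
        next_cluster <- next_cluster + 1L
        tx$cluster[cc] <- next_cluster
      }
    }
  }
  # single-exon: single-linkage overlap within chrom, strand-compatible
  single <- which(tx$n_exons == 1L)
  if (length(single)) {
    for (idx in split(single, tx$chrom[single])) {
      ir <- IRanges::IRanges(start = tx$start[idx] + 1L, end = tx$end[idx])
      hits <- IRanges::findOverlaps(ir, ir)
      q <- S4Vectors::queryHits(hits); s2 <- S4Vectors::subjectHits(hits)
      keep <- q < s2 & .strand_compatible(tx$strand[idx][q], tx$strand[idx][s2])
      edges <- cbind(q[keep], s2[keep])
      comp <- .uf_components(length(idx), edges)
      for (cc in split(idx, comp)) {
        next_cluster <- next_cluster + 1L
        tx$cluster[cc] <- next_cluster
      }
    }
  }

  # one record per cluster: widest span, consensus strand
  rec <- tx[, .(
    chrom = chrom[1L], strand = .strand_consensus(strand),
    start = min(start), end = max(end),
    n_exons = n_exons[1L], chain = chain[1L]
  ), by = cluster]
  setorder(rec, chrom, start, end, n_exons, strand, chain, na.last = TRUE)
  rec[, union_id := sprintf("UN%05d", .I)]
  id_of <- setNames(rec$union_id, rec$cluster)
  tx[, union_id := id_of[as.character(cluster)]]

  # representative exon chains
  uex <- rbindlist(lapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i]
    if (r$n_exons == 1L) {
      data.table(union_id = r$union_id, exon_index = 1L, chrom = r$chrom,
                 start = r$start, end = r$end, strand = r$strand)
    } else {
      j <- matrix(as.numeric(unlist(strsplit(unlist(strsplit(r$chain, "|", fixed = TRUE)), "-"))),
                  ncol = 2L, byrow = TRUE)
      starts <- c(r$start, j[, 2L]); ends <- c(j[, 1L], r$end)
      data.table(union_id = r$union_id, exon_index = seq_along(starts),
                 chrom = r$chrom, start = starts, end = ends, strand = r$strand)
    }
  }))

  members <- tx[, .(union_id, sample_id, transcript_id, count)]
  setorder(members, union_id, sample_id, transcript_id)
  presence <- lapply(split(members$sample_id, members$union_id), function(s) sort(unique(s)))
  presence <- presence[rec$union_id]

  counts <- matrix(0, nrow = nrow(rec), ncol = length(sample_ids),
                   dimnames = list(rec$union_id, sample_ids))
  agg <- members[, .(count = sum(count)), by = .(union_id, sample_id)]
  counts[cbind(agg$union_id, agg$sample_id)] <- agg$count

  rec[, cluster := NULL]
  setcolorder(rec, c("union_id", "chrom", "strand", "start", "end", "n_exons", "chain"))
  structure(list(transcripts = rec[], exons = uex, members = members[],
                 presence = presence, counts = counts,
                 sample_ids = sample_ids, group_labels = groups),
            class = "transfrag_union")
}

#' @export
print.transfrag_union <- function(x, ...) {
  cat(sprintf("<transfrag_union> %d union records from %d samples\n",
              nrow(x$transcripts), length(x$sample_ids)))
  invisible(x)
}

# subset a union by union_id, keeping all slots aligned
.subset_union <- function(u, ids) {
  keep <- u$transcripts$union_id %in% ids
  structure(list(
    transcripts = u$transcripts[keep],
    exons = u$exons[u$exons$union_id %in% ids],
    members = u$members[u$members$union_id %in% ids],
    presence = u$presence[u$transcripts$union_id[keep]],
    counts = u$counts[u$transcripts$union_id[keep], , drop = FALSE],
    sample_ids = u$sample_ids, group_labels = u$group_labels
  ), class = "transfrag_union")
}

# findOverlaps without the "no sequence levels in common" warning: disjoint
# chromosome sets are a valid query here (e.g. an empty or foreign reference)
.fo <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
}

# GRanges helpers (1-based inclusive for IRanges)
.exon_gr <- function(x) {
  e <- if (inherits(x, "annotation_set")) x$exons else as.data.table(x)
  GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start + 1L, e$end),
                         strand = e$strand,
                         transcript_id = e$transcript_id,
                         exon_index = e$exon_index)
}

.span_gr <- function(x) {
  t <- x$transcripts
  GenomicRanges::GRanges(t$chrom, IRanges::IRanges(t$start + 1L, t$end),
                         strand = t$strand, transcript_id = t$transcript_id)
}
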