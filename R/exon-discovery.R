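# Empirical exon-significance threshold and five-way exon classification
# (Exact / Overlap / Within / Novel-T / Novel-U), plus the treatment
# unique/common partition of classified exons.

EXON_LABELS <- c("Exact", "Within", "Overlap", "Novel-T", "Novel-U")

#' Fit a per-sample exon significance threshold
#'
#' Quartiles are computed over the deduplicated ("all unique") reference-exon
#' read counts with type-7 interpolation; the outlier fence is Tukey's
#' `Q3 + 1.5 (Q3 - Q1)`. Counts above the fence are removed as outliers and
#' the minimum read count is the lower-tail `alpha` quantile of the empirical
#' relative frequency distribution of the remaining counts, rounded up to the
#' next integer.
#'
#' @param ref_exon_counts numeric vector of raw read counts over reference
#'   exons for one sample.
#' @param alpha tail probability for the minimum-reads quantile (default 0.05).
#' @param sample_id sample the threshold belongs to.
#' @param tail `"lower"` (expression floor, default) or `"upper"`.
#' @return A `threshold_model` with `q1`, `q3`, `outlier_fence`, `min_reads`,
#'   `alpha`, `n_outliers`.
#' @export
fit_threshold <- function(ref_exon_counts, alpha = 0.05, sample_id = NA_character_,
                          tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  x <- ref_exon_counts
  if (any(!is.finite(x)) || any(x < 0)) stop("counts must be finite and non-negative")
  u <- unique(x)
  if (length(u) < 4L) stop("need at least 4 distinct count values to fit quartiles")
  q <- unname(quantile(u, c(0.25, 0.75), type = 7))
  fence <- q[2L] + 1.5 * (q[2L] - q[1L])
  keep <- x[x <= fence]
  prob <- if (tail == "lower") alpha else 1 - alpha
  min_reads <- ceiling(unname(quantile(keep, prob, type = 1)))
  structure(list(sample_id = sample_id, q1 = q[1L], q3 = q[2L],
                 outlier_fence = fence, min_reads = min_reads, alpha = alpha,
                 tail = tail, n_outliers = sum(x > fence)),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> sample %s: Q1=%.3g Q3=%.3g fence=%.3g min_reads=%d (alpha=%g)\n",
              x$sample_id, x$q1, x$q3, x$outlier_fence, x$min_reads, x$alpha))
  invisible(x)
}

#' Filter exons by the significance threshold
#'
#' Keeps exons whose raw count lies in `[min_reads, outlier_fence]`
#' (boundaries inclusive); exons below and above are reported separately.
#'
#' @param x a [transfrag_set()] or an exon table with a `count` column.
#' @param model a [fit_threshold()] result for the same sample.
#' @return list of exon tables: `kept`, `removed_low`, `removed_outlier`.
#' @export
filter_significant <- function(x, model) {
  stopifnot(inherits(model, "threshold_model"))
  if (inherits(x, "transfrag_set")) {
    if (!is.na(model$sample_id) && model$sample_id != x$sample_id) {
      stop("threshold fitted for sample ", model$sample_id,
           " applied to sample ", x$sample_id)
    }
    e <- x$exons
  } else {
    e <- as.data.table(x)
    if (!"count" %in% names(e)) stop("exon table needs a count column")
  }
  list(kept = e[count >= model$min_reads & count <= model$outlier_fence],
       removed_low = e[count < model$min_reads],
       removed_outlier = e[count > model$outlier_fence])
}

#' Classify exons against reference annotation
#'
#' Five exclusive labels, evaluated over strand-compatible reference exons
#' with precedence Exact > Within > Overlap: `Exact` (start and end positions
#' identical), `Within` (completely contained in a reference exon), `Overlap`
#' (partial overlap). An exon touching no reference exon is `Novel-T` when it
#' lies between the transcription start and end site of some reference
#' transcript (fully inside the span), otherwise `Novel-U`.
#'
#' @param exons exon table (`chrom`, `start`, `end`, `strand`; extra columns
#'   pass through).
#' @param ref an [annotation_set()].
#' @return the input table with `label`, `match_exon` (`transcript:index`) and
#'   `match_transcript` columns.
#' @export
classify_exons <- function(exons, ref) {
  stopifnot(inherits(ref, "annotation_set"))
  e <- as.data.table(exons)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(e)))
  re <- ref$exons
  out <- copy(e)
  out[, `:=`(label = "Novel-U", match_exon = NA_character_,
             match_transcript = NA_character_)]
  if (!nrow(e)) return(out[])

  qgr <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start + 1L, e$end),
                                strand = e$strand)
  rgr <- .exon_gr(ref)
  hits <- .fo(qgr, rgr)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    exact <- e$start[qi] == re$start[si] & e$end[qi] == re$end[si]
    within <- !exact & e$start[qi] >= re$start[si] & e$end[qi] <= re$end[si]
    h <- data.table(qi = qi,
                    rank = ifelse(exact, 1L, ifelse(within, 2L, 3L)),
                    ref_tx = re$transcript_id[si], ref_idx = re$exon_index[si])
    setorder(h, qi, rank, ref_tx, ref_idx)
    best <- h[, .SD[1L], by = qi]
    out[best$qi, `:=`(label = c("Exact", "Within", "Overlap")[best$rank],
                      match_exon = paste0(best$ref_tx, ":", best$ref_idx),
                      match_transcript = best$ref_tx)]
  }
  # no exon hit: Novel-T iff contained in some transcript span (strand-compatible)
  restless <- which(out$label == "Novel-U")
  if (length(restless)) {
    sgr <- .span_gr(ref)
    sh <- .fo(qgr[restless], sgr, type = "within")
    if (length(sh)) {
      qi <- S4Vectors::queryHits(sh); si <- S4Vectors::subjectHits(sh)
      h <- data.table(qi = restless[qi], ref_tx = ref$transcripts$transcript_id[si])
      setorder(h, qi, ref_tx)
      best <- h[, .SD[1L], by = qi]
      out[best$qi, `:=`(label = "Novel-T", match_transcript = best$ref_tx)]
    }
  }
  out[]
}

#' Classify a single exon
#' @param e a [genomic_interval()].
#' @param ref an [annotation_set()].
#' @return list with `label`, `match_exon`, `match_transcript`.
#' @export
classify_exon <- function(e, ref) {
  stopifnot(inherits(e, "genomic_interval"))
  r <- classify_exons(data.table(chrom = e$chrom, start = e$start, end = e$end,
                                 strand = e$strand), ref)
  list(label = r$label[1L], match_exon = r$match_exon[1L],
       match_transcript = r$match_transcript[1L])
}

#' Partition classified exons by treatment group
#'
#' Exons are merged across samples by exact coordinates and strand. An exon is
#' `common` when present (post-filter) in at least `min_support_per_group`
#' samples of each group, otherwise unique to the group containing it.
#'
#' @param classified named list (sample_id -> classified, filtered exon table
#'   with a `label` column).
#' @param group_labels named character vector sample_id -> group (two groups).
#' @param min_support_per_group minimum samples per group for `common`.
#' @return list with `exons` (distinct exons with `status`) and `summary`
#'   (label x status count table; statuses are `unique_<A>`, `unique_<B>`,
#'   `common` and are additive).
#' @export
partition_by_treatment <- function(classified, group_labels, min_support_per_group = 1L) {
  stopifnot(length(classified) >= 1L, !is.null(names(classified)))
  if (!all(names(classified) %in% names(group_labels))) {
    stop("unknown sample id(s): ",
         paste(setdiff(names(classified), names(group_labels)), collapse = ", "))
  }
  grp <- group_labels[names(classified)]
  glev <- sort(unique(unname(grp)))
  if (length(glev) != 2L) stop("partition_by_treatment needs exactly two groups, got: ",
                               paste(glev, collapse = ", "))
  all_e <- rbindlist(lapply(names(classified), function(s) {
    e <- as.data.table(classified[[s]])
    stopifnot(all(c("chrom", "start", "end", "strand", "label") %in% names(e)))
    e[, .(chrom, start, end, strand, label, sample_id = s)]
  }))
  key_cols <- c("chrom", "start", "end", "strand", "label")
  dist <- all_e[, .(
    n_a = uniqueN(sample_id[grp[sample_id] == glev[1L]]),
    n_b = uniqueN(sample_id[grp[sample_id] == glev[2L]])
  ), by = key_cols]
  dist[, status := ifelse(n_a >= min_support_per_group & n_b >= min_support_per_group,
                          "common",
                          ifelse(n_a > 0L, paste0("unique_", glev[1L]),
                                 paste0("unique_", glev[2L])))]
  statuses <- c(paste0("unique_", glev[1L]), paste0("unique_", glev[2L]), "common")
  summary <- dcast(dist[, .N, by = .(label, status)], label ~ status,
                   value.var = "N", fill = 0L)
  for (s in setdiff(statuses, names(summary))) summary[, (s) := 0L]
  setcolorder(summary, c("label", statuses))
  setorder(dist, chrom, start, end, strand)
  list(exons = dist[], summary = summary[])
}
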