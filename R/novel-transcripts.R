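# Replicate-supported discovery of intergenic novel transcripts: span-level
# novelty against the reference, replicate-presence filtering with treatment
# categories, secondary-annotation flagging and DEG intersection.

#' Extract novel (intergenic) union records
#'
#' @param union a [merge_union()] result.
#' @param ref an [annotation_set()].
#' @return A `transfrag_union` restricted to records classified `novel`
#'   (per-sample presence maps kept).
#' @export
find_novel <- function(union, ref) {
  stopifnot(inherits(union, "transfrag_union"))
  cls <- classify_all(union, ref)
  .subset_union(union, cls$table$transcript_id[cls$table$class == "novel"])
}

#' Filter novel records by replicate support
#'
#' @param novel a `transfrag_union` (e.g. from [find_novel()]).
#' @param min_replicates minimum number of samples a record must appear in.
#' @return list with `kept` (filtered union), `histogram` (records at each
#'   support value and surviving counts at thresholds `1..n`), and
#'   `categories` (per-record support and treatment category: group A only,
#'   group B only, or both).
#' @export
filter_by_support <- function(novel, min_replicates = 2L) {
  stopifnot(inherits(novel, "transfrag_union"))
  if (min_replicates < 1L) stop("min_replicates must be >= 1")
  support <- vapply(novel$presence, length, integer(1L))
  grp <- novel$group_labels
  glev <- sort(unique(unname(grp)))
  category <- vapply(novel$presence, function(s) {
    g <- unique(unname(grp[s]))
    if (length(g) > 1L) "both" else g
  }, character(1L))
  n <- length(novel$sample_ids)
  histogram <- data.table(
    support = seq_len(n),
    n_records = vapply(seq_len(n), function(k) sum(support == k), integer(1L)),
    n_surviving = vapply(seq_len(n), function(k) sum(support >= k), integer(1L)))
  categories <- data.table(union_id = novel$transcripts$union_id,
                           support = support, category = category)
  kept_ids <- categories$union_id[categories$support >= min_replicates]
  list(kept = .subset_union(novel, kept_ids),
       histogram = histogram[], categories = categories[],
       min_replicates = as.integer(min_replicates))
}

#' Flag novel records against a secondary annotation
#'
#' A record is `annotated_secondary` when any of its exons intersects a
#' secondary-annotation exon on a compatible strand.
#'
#' @param novel a `transfrag_union`.
#' @param secondary an [annotation_set()] or `NULL` (all records unannotated).
#' @return data.table (`union_id`, `flag`).
#' @export
cross_annotate <- function(novel, secondary = NULL) {
  stopifnot(inherits(novel, "transfrag_union"))
  ids <- novel$transcripts$union_id
  flag <- rep("unannotated", length(ids))
  if (!is.null(secondary) && nrow(secondary$transcripts)) {
    e <- novel$exons
    qgr <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start + 1L, e$end),
                                  strand = e$strand)
    hits <- .fo(qgr, .exon_gr(secondary))
    hit_ids <- unique(e$union_id[S4Vectors::queryHits(hits)])
    flag[ids %in% hit_ids] <- "annotated_secondary"
  }
  data.table(union_id = ids, flag = flag)
}

#' Intersect novel records with a differential-expression table
#'
#' Keeps records with `|signed FC| > fc_cut` and `p < p_cut`. Records absent
#' from the DEG table are retained with an `untested` flag, never dropped.
#'
#' @param novel a `transfrag_union`.
#' @param deg_table data.frame with `feature_id`, `signed_fc`, `p_value`
#'   (any engine; see [call_degs()]).
#' @param fc_cut,p_cut cutoffs (defaults: absolute fold change > 2,
#'   p < 0.005).
#' @return list with `table` (per-record genomic location, FC, p, support,
#'   status `deg`/`not_deg`/`untested`) and `kept` (union of the `deg` rows).
#' @export
intersect_deg <- function(novel, deg_table, fc_cut = 2, p_cut = 0.005) {
  stopifnot(inherits(novel, "transfrag_union"))
  deg_table <- as.data.table(deg_table)
  stopifnot(all(c("feature_id", "signed_fc", "p_value") %in% names(deg_table)))
  tab <- copy(novel$transcripts)
  m <- match(tab$union_id, deg_table$feature_id)
  tab[, `:=`(signed_fc = deg_table$signed_fc[m], p_value = deg_table$p_value[m])]
  tab[, support := vapply(novel$presence[union_id], length, integer(1L))]
  tab[, status := ifelse(is.na(signed_fc) | is.na(p_value), "untested",
                         ifelse(abs(signed_fc) > fc_cut & p_value < p_cut,
                                "deg", "not_deg"))]
  list(table = tab[], kept = .subset_union(novel, tab$union_id[tab$status == "deg"]))
}

#' Full novel-transcript report
#'
#' Chains [find_novel()], [filter_by_support()], [cross_annotate()] and
#' [intersect_deg()] into the replicate-supported novel-DEG report. The DEG
#' table defaults to [call_degs()] on the union's summed per-record raw
#' transcript counts.
#'
#' @param union a [merge_union()] result.
#' @param ref primary [annotation_set()].
#' @param secondary optional secondary annotation.
#' @param deg_table optional externally computed DEG table; when `NULL` every
#'   union record's summed raw counts are tested with [call_degs()] (the full
#'   union, not only the novel records, so the permutation null is anchored
#'   by the expressed background).
#' @param min_replicates replicate-support threshold (default 2).
#' @param fc_cut,p_cut DEG cutoffs.
#' @param ... passed to [call_degs()] (e.g. `n_perm`, `seed`).
#' @return list with `report` (one row per supported novel record: location,
#'   exon count, support, category, annotation flag, FC, p, status),
#'   `histogram`, and the intermediate objects.
#' @export
novel_transcript_report <- function(union, ref, secondary = NULL, deg_table = NULL,
                                    min_replicates = 2L, fc_cut = 2, p_cut = 0.005,
                                    ...) {
  novel <- find_novel(union, ref)
  sup <- filter_by_support(novel, min_replicates)
  kept <- sup$kept
  ann <- cross_annotate(kept, secondary)
  if (is.null(deg_table) && nrow(kept$transcripts)) {
    ft <- feature_table(union$counts, group_labels = union$group_labels)
    deg_table <- call_degs(ft, fc_cut = fc_cut, p_cut = p_cut, ...)
  }
  dg <- if (nrow(kept$transcripts)) intersect_deg(kept, deg_table, fc_cut, p_cut)
        else list(table = data.table(), kept = kept)
  report <- if (nrow(kept$transcripts)) {
    r <- merge(dg$table, sup$categories[, .(union_id, category)], by = "union_id")
    r <- merge(r, ann, by = "union_id")
    setorder(r, chrom, start, end)
    r[]
  } else data.table()
  list(report = report, histogram = sup$histogram, novel = novel,
       supported = kept, deg = dg)
}
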