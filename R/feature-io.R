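# Readers/writers for GTF (annotation, transfrags), BED (probes) and TSV
# feature tables. Parsing of the standard formats is delegated to rtracklayer;
# this file adds the package's validation and coordinate conventions
# (internal 0-based half-open <-> GTF 1-based inclusive).

#' Read a GTF file as an annotation or transfrag set
#'
#' Exon rows are grouped by `transcript_id` into transcript models. GTF's
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. In `transfrags` mode per-exon raw read counts are
#' taken from a sidecar TSV (`transcript_id`, `exon_index`, `count`) or, if
#' none is given, from a `read_count` attribute on the exon rows.
#'
#' @param path GTF file path.
#' @param mode `"annotation"` or `"transfrags"`.
#' @param exon_counts path to the sidecar count TSV (transfrags mode).
#' @param sample_id,group_label,total_mapped_reads transfrag-set metadata.
#' @return An [annotation_set()] or [transfrag_set()].
#' @export
read_gtf <- function(path, mode = c("annotation", "transfrags"),
                     exon_counts = NULL, sample_id = NULL, group_label = NULL,
                     total_mapped_reads = NULL) {
  mode <- match.arg(mode)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF '", path, "': ",
                                          conditionMessage(e)))
  df <- as.data.table(as.data.frame(gr))
  if (!nrow(df)) stop("GTF '", path, "' contains no records")
  df <- df[df$type == "exon"]
  if (!nrow(df)) stop("GTF '", path, "' contains no exon records")
  gid <- if ("gene_id" %in% names(df)) df$gene_id else rep(NA_character_, nrow(df))
  tid <- if ("transcript_id" %in% names(df)) df$transcript_id else rep(NA_character_, nrow(df))
  bad <- which(is.na(gid) | is.na(tid))
  if (length(bad)) {
    lines <- .gtf_exon_lines(path)
    stop("GTF '", path, "' exon record(s) missing gene_id/transcript_id at line(s): ",
         paste(head(lines[bad], 5L), collapse = ", "))
  }
  exons <- data.table(
    transcript_id = tid, gene_id = gid,
    chrom = as.character(df$seqnames),
    start = df$start - 1L, end = df$end,
    strand = as.character(df$strand)
  )
  if (mode == "annotation") return(annotation_set(exons))

  if (is.null(sample_id)) sample_id <- sub("\\.gtf$", "", basename(path))
  if (is.null(group_label)) group_label <- "NA"
  exons <- exons[order(transcript_id, start)]
  exons[, exon_index := seq_len(.N), by = transcript_id]
  if (!is.null(exon_counts)) {
    ct <- fread(exon_counts, sep = "\t")
    need <- c("transcript_id", "exon_index", "count")
    if (!all(need %in% names(ct))) {
      stop("exon count sidecar '", exon_counts, "' must have columns: ",
           paste(need, collapse = ", "))
    }
    exons <- merge(exons, ct[, need, with = FALSE],
                   by = c("transcript_id", "exon_index"), all.x = TRUE)
    if (anyNA(exons$count)) stop("exon count sidecar missing counts for some exons")
  } else if ("read_count" %in% names(df)) {
    exons[, count := as.numeric(df$read_count[order(df$transcript_id, df$start)])]
  } else {
    stop("transfrags mode needs an exon_counts sidecar or read_count GTF attribute")
  }
  transfrag_set(exons, sample_id = sample_id, group_label = group_label,
                total_mapped_reads = total_mapped_reads)
}

# file line numbers of exon records (non-comment GTF lines with feature 'exon')
.gtf_exon_lines <- function(path) {
  ln <- readLines(path)
  idx <- which(!startsWith(ln, "#"))
  feat <- vapply(strsplit(ln[idx], "\t", fixed = TRUE),
                 function(f) if (length(f) >= 3L) f[3L] else "", character(1L))
  idx[feat == "exon"]
}

.gtf_attr <- function(...) {
  kv <- list(...)
  paste(vapply(names(kv), function(k) sprintf('%s "%s";', k, kv[[k]]), character(1L)),
        collapse = " ")
}

#' Write an annotation or transfrag set as GTF
#'
#' Emits transcript and exon rows with the common `key "value";` attribute
#' dialect; converts internal coordinates back to 1-based inclusive. For a
#' transfrag set, per-exon raw counts are written both as a `read_count`
#' attribute and (optionally) to a sidecar TSV.
#'
#' @param x an `annotation_set` or `transfrag_set`.
#' @param path output GTF path.
#' @param exon_counts optional sidecar TSV path for per-exon counts.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path, exon_counts = NULL, source = "txclass") {
  stopifnot(inherits(x, "annotation_set"))
  e <- x$exons
  tx <- x$transcripts
  is_tf <- inherits(x, "transfrag_set")
  tx_lines <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      tx$chrom, source, tx$start + 1L, tx$end, tx$strand,
                      mapply(function(g, t) .gtf_attr(gene_id = g, transcript_id = t),
                             tx$gene_id, tx$transcript_id))
  ex_attr <- if (is_tf) {
    mapply(function(g, t, i, ct) .gtf_attr(gene_id = g, transcript_id = t,
                                           exon_number = i, read_count = ct),
           e$gene_id, e$transcript_id, e$exon_index, e$count)
  } else {
    mapply(function(g, t, i) .gtf_attr(gene_id = g, transcript_id = t, exon_number = i),
           e$gene_id, e$transcript_id, e$exon_index)
  }
  ex_lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                      e$chrom, source, e$start + 1L, e$end, e$strand, ex_attr)
  # interleave deterministically: transcripts in table order, each with its exons
  ord <- order(match(e$transcript_id, tx$transcript_id), e$exon_index)
  out <- unlist(mapply(function(i, tid) c(tx_lines[i], ex_lines[ord][e$transcript_id[ord] == tid]),
                       seq_len(nrow(tx)), tx$transcript_id, SIMPLIFY = FALSE))
  writeLines(out, path)
  if (is_tf && !is.null(exon_counts)) {
    fwrite(e[, .(transcript_id, exon_index, count)], exon_counts, sep = "\t")
  }
  invisible(path)
}

#' Read microarray probe placements from BED
#'
#' BED coordinates (0-based half-open) are kept verbatim. BED12 blocks become
#' multiple placements of the same probe.
#'
#' @param path BED6 or BED12 file.
#' @return data.table with columns `probe_id`, `chrom`, `start`, `end`,
#'   `strand` (one row per placement).
#' @export
read_probe_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("failed to parse BED '", path, "': ",
                                          conditionMessage(e)))
  if (!length(gr)) stop("BED '", path, "' contains no records")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) stop("BED '", path, "': every probe needs a name")
  if (anyDuplicated(nm)) {
    stop("BED '", path, "': duplicate probe_id: ",
         paste(head(unique(nm[duplicated(nm)]), 5L), collapse = ", "))
  }
  if (!is.null(gr$blocks)) {
    bl <- gr$blocks
    placements <- GenomicRanges::GRanges(
      rep(GenomicRanges::seqnames(gr), S4Vectors::elementNROWS(bl)),
      IRanges::shift(unlist(bl), rep(GenomicRanges::start(gr) - 1L,
                                     S4Vectors::elementNROWS(bl))),
      strand = rep(GenomicRanges::strand(gr), S4Vectors::elementNROWS(bl)))
    probe_id <- rep(nm, S4Vectors::elementNROWS(bl))
  } else {
    placements <- gr
    probe_id <- nm
  }
  data.table(probe_id = probe_id,
             chrom = as.character(GenomicRanges::seqnames(placements)),
             start = GenomicRanges::start(placements) - 1L,
             end = GenomicRanges::end(placements),
             strand = as.character(GenomicRanges::strand(placements)))
}

#' Write probe placements as BED6
#' @param probes probe placement table as returned by [read_probe_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(probes, path) {
  probes <- as.data.table(probes)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", probes$chrom,
                     as.integer(probes$start), as.integer(probes$end),
                     probes$probe_id,
                     ifelse(probes$strand == "*", ".", probes$strand)), path)
  invisible(path)
}

#' Construct a feature table
#'
#' Features x samples numeric matrix with per-sample group labels; the
#' substrate of all statistics in the package.
#'
#' @param values numeric matrix with feature row names and sample column names.
#' @param group_labels named character vector (names = sample ids).
#' @param integer_counts require non-negative integer values.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, group_labels = NULL, integer_counts = FALSE) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("feature_table: values needs feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("feature_table: values must be finite")
  if (integer_counts && (any(values < 0) || any(values != floor(values)))) {
    stop("feature_table: counts must be non-negative integers")
  }
  if (!is.null(group_labels)) {
    if (!all(colnames(values) %in% names(group_labels))) {
      stop("group_labels missing for some samples")
    }
    group_labels <- group_labels[colnames(values)]
  }
  structure(list(values = values, group_labels = group_labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$group_labels))
                paste0(" (groups: ", paste(unique(x$group_labels), collapse = "/"), ")")
              else ""))
  invisible(x)
}

#' Read a feature table from TSV
#'
#' First column `feature_id`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @param group_labels optional named character vector of sample groups.
#' @param integer_counts require integer counts (rejects e.g. 3.5).
#' @return A [feature_table()].
#' @export
read_table <- function(path, group_labels = NULL, integer_counts = FALSE) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1L] != "feature_id") stop("TSV '", path, "': first column must be feature_id")
  vals <- as.matrix(dt[, -1L])
  if (!is.numeric(vals)) stop("TSV '", path, "': non-numeric cells")
  rownames(vals) <- dt$feature_id
  feature_table(vals, group_labels = group_labels, integer_counts = integer_counts)
}

#' Write a feature table as TSV
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  dt <- data.table(feature_id = rownames(table$values))
  dt <- cbind(dt, as.data.table(table$values))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
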