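# Orchestration: run the full analysis from a YAML config into an output
# directory with TSV reports and a JSON manifest; identical config + seed
# reproduce identical outputs.

.stage_msg <- function(log, stage, text) {
  line <- sprintf("[%s] %s", stage, text)
  message(line)
  cat(line, "\n", file = log, append = TRUE, sep = "")
  invisible(NULL)
}

#' Run the full pipeline from a config
#'
#' Executes simulate (optional) -> I/O round trip -> transcript classification
#' -> exon significance filtering and classification -> treatment partition ->
#' novel-transcript discovery -> differential expression on both platforms ->
#' platform overlap and quartile correlation -> isoform exon fold changes.
#' Every stage writes a TSV report; a JSON manifest records the config hash,
#' seed, per-stage row counts and output file checksums.
#'
#' @param config path to a YAML config, or an equivalent named list. The
#'   bundled demo config (`system.file("extdata", "demo-config.yaml",
#'   package = "txclass")`) documents the schema: a `simulate` block
#'   (generator arguments), a `thresholds` block (`alpha`, `fc_cut`, `p_cut`,
#'   `min_replicates`, `n_perm`) and a `seed`.
#' @param outdir output directory (created; default a temp directory).
#' @param seed optional override of the config seed.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir = tempfile("txclass_run_"), seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  th <- cfg$thresholds
  defaults <- list(alpha = 0.05, fc_cut = 2, p_cut = 0.005, min_replicates = 2L,
                   n_perm = 10000L)
  for (k in names(defaults)) if (is.null(th[[k]])) th[[k]] <- defaults[[k]]

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(outdir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)
  log <- file.path(outdir, "run.log")
  cat(sprintf("txclass %s | seed %d | %s\n", packageVersion("txclass"),
              cfg$seed, format(Sys.time(), "%Y-%m-%d")), file = log)

  if (is.null(cfg$simulate)) stop("config needs a 'simulate' block (or input paths)")
  sim_args <- cfg$simulate
  sim <- do.call(simulate_study, c(list(seed = cfg$seed), sim_args))
  n_samples <- length(sim$samples)
  if (th$min_replicates > n_samples) {
    stop("config error: min_replicates (", th$min_replicates,
         ") exceeds the number of replicates (", n_samples, ")")
  }
  .stage_msg(log, "simulate", sprintf("%d samples, %d transfrag templates",
                                      n_samples, nrow(sim$truth$transcripts)))

  ## write inputs and read them back through feature_io (round-trip exercised)
  write_gtf(sim$annotation, file.path(in_dir, "annotation.gtf"))
  write_gtf(sim$secondary, file.path(in_dir, "secondary.gtf"))
  for (s in names(sim$samples)) {
    write_gtf(sim$samples[[s]], file.path(in_dir, paste0(s, ".gtf")),
              exon_counts = file.path(in_dir, paste0(s, ".exon_counts.tsv")))
  }
  write_table(sim$ref_exon_counts, file.path(in_dir, "ref_exon_counts.tsv"))
  write_probe_bed(sim$probes, file.path(in_dir, "probes.bed"))
  write_table(sim$probe_signal, file.path(in_dir, "probe_signal.tsv"))

  annotation <- read_gtf(file.path(in_dir, "annotation.gtf"), "annotation")
  secondary <- read_gtf(file.path(in_dir, "secondary.gtf"), "annotation")
  grp <- sim$group_labels
  samples <- lapply(names(sim$samples), function(s)
    read_gtf(file.path(in_dir, paste0(s, ".gtf")), "transfrags",
             exon_counts = file.path(in_dir, paste0(s, ".exon_counts.tsv")),
             sample_id = s, group_label = unname(grp[s]),
             total_mapped_reads = sim$samples[[s]]$total_mapped_reads))
  names(samples) <- names(sim$samples)
  ref_exon_counts <- read_table(file.path(in_dir, "ref_exon_counts.tsv"),
                                group_labels = grp, integer_counts = TRUE)
  probes <- read_probe_bed(file.path(in_dir, "probes.bed"))
  probe_signal <- read_table(file.path(in_dir, "probe_signal.tsv"),
                             group_labels = grp)
  .stage_msg(log, "io", "inputs written and re-read")

  ## union + transcript classification
  union <- merge_union(samples)
  cls <- classify_all(union, annotation)
  fwrite(cls$table, file.path(outdir, "transcript_classes.tsv"), sep = "\t")
  fwrite(data.table(class = names(cls$summary), n = as.integer(cls$summary)),
         file.path(outdir, "transcript_summary.tsv"), sep = "\t")
  cov <- probe_coverage(union, probes)
  .stage_msg(log, "classify", sprintf(
    "%d union records: %d complete / %d partial / %d novel; %d probe-covered",
    cls$summary["total"], cls$summary["complete"], cls$summary["partial"],
    cls$summary["novel"], cov$n_covered))

  ## exon thresholds, filtering, classification, treatment partition
  thresholds <- lapply(names(samples), function(s)
    fit_threshold(ref_exon_counts$values[, s], alpha = th$alpha, sample_id = s))
  names(thresholds) <- names(samples)
  fwrite(rbindlist(lapply(thresholds, function(m) data.table(
    sample_id = m$sample_id, q1 = m$q1, q3 = m$q3, outlier_fence = m$outlier_fence,
    min_reads = m$min_reads, n_outliers = m$n_outliers))),
    file.path(outdir, "thresholds.tsv"), sep = "\t")
  classified <- lapply(names(samples), function(s) {
    kept <- filter_significant(samples[[s]], thresholds[[s]])$kept
    classify_exons(kept, annotation)
  })
  names(classified) <- names(samples)
  part <- partition_by_treatment(classified, grp,
                                 min_support_per_group = 1L)
  fwrite(part$exons, file.path(outdir, "exon_classes.tsv"), sep = "\t")
  fwrite(part$summary, file.path(outdir, "exon_partition.tsv"), sep = "\t")
  .stage_msg(log, "exons", sprintf("%d distinct significant exons",
                                   nrow(part$exons)))

  ## RNA-Seq differential expression: union records and annotation
  ## transcripts tested jointly so the permutation null is anchored by the
  ## expressed background (as when testing a full annotation table)
  tx_of <- sub(":[0-9]+$", "", rownames(ref_exon_counts$values))
  rna_tx <- rowsum(ref_exon_counts$values, tx_of)
  rna_counts <- rbind(union$counts,
                      `rownames<-`(rna_tx, paste0("ref:", rownames(rna_tx))))
  deg_rna <- call_degs(feature_table(rna_counts, group_labels = grp),
                       fc_cut = th$fc_cut, p_cut = th$p_cut,
                       n_perm = th$n_perm, seed = cfg$seed, platform = "rnaseq")
  fwrite(deg_rna, file.path(outdir, "deg_rnaseq.tsv"), sep = "\t")

  ## novel transcripts
  nv <- novel_transcript_report(union, annotation, secondary = secondary,
                                deg_table = deg_rna,
                                min_replicates = th$min_replicates,
                                fc_cut = th$fc_cut, p_cut = th$p_cut)
  if (nrow(nv$report)) {
    fwrite(nv$report, file.path(outdir, "novel_report.tsv"), sep = "\t")
  }
  fwrite(nv$histogram, file.path(outdir, "novel_support_histogram.tsv"), sep = "\t")
  .stage_msg(log, "novel", sprintf(
    "%d novel, %d with >=%d replicates, %d DEG",
    nrow(nv$novel$transcripts), nrow(nv$supported$transcripts),
    th$min_replicates, if (nrow(nv$report)) sum(nv$report$status == "deg") else 0L))

  ## microarray: median-polish probe summaries per annotation transcript
  acov <- probe_coverage(annotation, probes)
  tx_signal <- do.call(rbind, lapply(split(acov$pairs$probe_id,
                                           acov$pairs$transcript_id),
    function(pids) median_polish_summarize(
      probe_signal$values[pids, , drop = FALSE])$summary))
  ma_ft <- feature_table(tx_signal, group_labels = grp)
  deg_ma <- call_degs(ma_ft, fc_cut = th$fc_cut, p_cut = th$p_cut,
                      n_perm = th$n_perm, seed = cfg$seed, log2_input = TRUE,
                      pseudocount = 0, platform = "microarray")
  fwrite(deg_ma, file.path(outdir, "deg_microarray.tsv"), sep = "\t")
  # platform Venn on the shared annotation-transcript namespace
  venn <- platform_overlap(list(
    rnaseq = sub("^ref:", "", grep("^ref:", deg_rna$feature_id[deg_rna$is_deg],
                                   value = TRUE)),
    microarray = deg_ma$feature_id[deg_ma$is_deg]))
  fwrite(venn$regions, file.path(outdir, "platform_venn.tsv"), sep = "\t")
  .stage_msg(log, "diffexp", sprintf("%d RNA-Seq DEG, %d microarray DEG",
                                     sum(deg_rna$is_deg), sum(deg_ma$is_deg)))

  ## cross-platform quartile correlation: annotation-transcript RNA-Seq signal
  ## (reference-exon counts summed per transcript, RPM + log2 + quantile
  ## normalized) against the median-polish microarray summaries
  rna_ft <- log2_quantile_normalize(
    rpm_normalize(feature_table(rna_tx, group_labels = grp),
                  setNames(rep(2e6, n_samples), colnames(rna_tx))))
  qs <- quartile_spearman(ma_ft, rna_ft)
  fwrite(qs, file.path(outdir, "quartile_correlation.tsv"), sep = "\t")

  ## isoform exon-level fold change on the family templates
  fam_templates <- sim$truth$transcripts[grepl("^tmpl_fam_", template_id), template_id]
  fam_ec <- sim$exon_counts[template_id %in% fam_templates,
                            .(transcript_id = template_id, exon_index, sample_id,
                              count)]
  fam_def <- unique(sim$exon_counts[template_id %in% fam_templates,
                                    .(transcript_id = template_id, exon_index,
                                      chrom, start, end, strand)])
  fam_def[, gene_id := "FAM"]
  iso <- exon_specific_fc(annotation_set(fam_def), fam_ec, grp)
  fwrite(iso$per_exon, file.path(outdir, "isoform_exon_fc.tsv"), sep = "\t")
  fwrite(iso$per_transcript, file.path(outdir, "isoform_transcript_fc.tsv"),
         sep = "\t")
  .stage_msg(log, "isoform", sprintf("%d family exons (%d defining)",
                                     nrow(iso$per_exon),
                                     sum(iso$per_exon$role == "defining")))

  ## manifest
  outs <- sort(list.files(outdir, pattern = "\\.tsv$", full.names = TRUE))
  manifest <- list(
    package = "txclass", version = as.character(packageVersion("txclass")),
    seed = cfg$seed, thresholds = th,
    config_hash = unname(tools::md5sum(.write_config_echo(cfg, outdir))),
    rows = list(union = nrow(union$transcripts),
                significant_exons = nrow(part$exons),
                novel = nrow(nv$novel$transcripts),
                novel_supported = nrow(nv$supported$transcripts),
                deg_rnaseq = sum(deg_rna$is_deg),
                deg_microarray = sum(deg_ma$is_deg)),
    files = as.list(tools::md5sum(outs)))
  names(manifest$files) <- basename(outs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(outdir = outdir, manifest = manifest, sim = sim, union = union,
                 classes = cls, thresholds = thresholds, partition = part,
                 novel = nv, deg_rnaseq = deg_rna, deg_microarray = deg_ma,
                 venn = venn, quartile = qs, isoform = iso))
}

.write_config_echo <- function(cfg, outdir) {
  p <- file.path(outdir, "config_echo.yaml")
  yaml::write_yaml(cfg, p)
  p
}
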