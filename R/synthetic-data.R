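# Deterministic synthetic-data generator with planted ground truth: a
# multi-gene annotation including a shared-exon isoform family, per-replicate
# transfrag sets realizing planted transcript/exon classes and novel-locus
# replicate-presence patterns, negative-binomial read counts with planted
# treatment effects, and microarray probe placements/signals.
#
# One global seed fans out to fixed per-operation substreams so each stage can
# be regenerated independently and (config, seed) -> byte-identical outputs.

.nb_draw <- function(mu, dispersion) {
  if (dispersion == 0) round(mu) else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

.logunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Generate a synthetic reference annotation
#'
#' Non-overlapping genes on two chromosomes and both strands, including one
#' shared-exon isoform family (k isoforms sharing the last `m_shared` exons,
#' each with one unique 5' exon) and a secondary ("Ensembl-like") annotation
#' equal to the primary plus extra transcripts placed in reserved intergenic
#' slots. The remaining slots are kept free for novel-transcript placement by
#' [generate_transfrags()].
#'
#' @param n_genes number of ordinary genes (>= 10).
#' @param seed RNG seed.
#' @param chroms chromosome names (two used round-robin).
#' @param exon_len_range,intron_len_range,gap_range integer ranges (bp).
#' @param p_single_exon fraction of single-exon genes.
#' @param family list `k` (isoforms), `m_shared` (shared exons).
#' @param secondary_extra number of secondary-only transcripts.
#' @return list with `annotation`, `secondary` ([annotation_set()]s), `slots`
#'   (reserved intergenic windows; the first `secondary_extra` hold the
#'   secondary-only transcripts), `family_ids`, and the config echo.
#' @export
generate_annotation <- function(n_genes = 60L, seed = 1L,
                                chroms = c("chr1", "chr2"),
                                exon_len_range = c(80L, 400L),
                                intron_len_range = c(200L, 2000L),
                                gap_range = c(9000L, 16000L),
                                p_single_exon = 0.15,
                                family = list(k = 6L, m_shared = 4L),
                                secondary_extra = 5L) {
  stopifnot(n_genes >= 10L, length(chroms) >= 2L)
  set.seed(seed + 101L)
  cur <- setNames(rep(10000L, length(chroms)), chroms)
  exons <- list(); slots <- list()
  for (g in seq_len(n_genes)) {
    chrom <- chroms[(g - 1L) %% length(chroms) + 1L]
    gap <- round(runif(1L, gap_range[1L], gap_range[2L]))
    # reserve a slot window centered in the gap, clear of both gene ends
    slot_start <- cur[chrom] + round((gap - 2000L) / 2)
    slots[[length(slots) + 1L]] <- data.table(
      chrom = chrom, start = slot_start, end = slot_start + 2000L)
    pos <- cur[chrom] + gap
    n_ex <- if (runif(1L) < p_single_exon) 1L else sample(2:8, 1L)
    strand <- sample(c("+", "-"), 1L)
    lens <- round(runif(n_ex, exon_len_range[1L], exon_len_range[2L]))
    introns <- if (n_ex > 1L) round(runif(n_ex - 1L, intron_len_range[1L], intron_len_range[2L])) else integer()
    starts <- pos + c(0L, cumsum(lens[-n_ex] + introns))
    tid <- sprintf("G%03d.t1", g)
    exons[[g]] <- data.table(transcript_id = tid, gene_id = sprintf("G%03d", g),
                             chrom = chrom, start = starts, end = starts + lens,
                             strand = strand)
    cur[chrom] <- max(starts + lens)
  }
  # shared-exon isoform family on chroms[1]: k isoforms, unique 5' exon each,
  # shared 3' block of m_shared exons
  k <- family$k; m <- family$m_shared
  fam_anchor <- cur[chroms[1L]] + 12000L
  shared_starts <- fam_anchor + (seq_len(m) - 1L) * 450L
  shared <- data.table(chrom = chroms[1L], start = shared_starts,
                       end = shared_starts + 150L, strand = "+")
  fam <- rbindlist(lapply(seq_len(k), function(j) {
    uniq_start <- fam_anchor - j * 800L
    rbind(
      data.table(transcript_id = sprintf("FAM.t%d", j), gene_id = "FAM",
                 chrom = chroms[1L], start = uniq_start, end = uniq_start + 100L,
                 strand = "+"),
      data.table(transcript_id = sprintf("FAM.t%d", j), gene_id = "FAM",
                 chrom = shared$chrom, start = shared$start, end = shared$end,
                 strand = shared$strand))
  }))
  cur[chroms[1L]] <- max(fam$end)
  # tail slots after the last gene on each chrom
  for (chrom in chroms) {
    for (i in 1:4) {
      s <- cur[chrom] + 8000L + (i - 1L) * 4000L
      slots[[length(slots) + 1L]] <- data.table(chrom = chrom, start = s, end = s + 2000L)
    }
  }
  slots <- rbindlist(slots)
  slots[, slot_id := sprintf("S%03d", .I)]

  exon_dt <- rbind(rbindlist(exons), fam)
  annotation <- annotation_set(exon_dt)

  # secondary = primary + extras in the first secondary_extra slots
  sec_extra <- rbindlist(lapply(seq_len(secondary_extra), function(i) {
    s <- slots[i]
    data.table(transcript_id = sprintf("ENS%03d", i), gene_id = sprintf("ENSG%03d", i),
               chrom = s$chrom,
               start = c(s$start + 100L, s$start + 1300L),
               end = c(s$start + 500L, s$start + 1700L),
               strand = "+")
  }))
  secondary <- annotation_set(rbind(exon_dt, sec_extra))
  list(annotation = annotation, secondary = secondary, slots = slots[],
       family_ids = sprintf("FAM.t%d", seq_len(k)),
       config = list(n_genes = n_genes, seed = seed, chroms = chroms,
                     exon_len_range = exon_len_range,
                     intron_len_range = intron_len_range, gap_range = gap_range,
                     p_single_exon = p_single_exon, family = family,
                     secondary_extra = secondary_extra))
}

# default replicate-presence roster for planted novel loci. Patterns are
# expressed against sample names <A>_1..n and <B>_1..n; 'effect' is the
# planted treated/control fold change of fully-present loci (group-unique
# loci express presence, not a count ratio).
.default_novel_patterns <- function() {
  list(
    list(name = "nv_deg_up_a",  presence = "all",          effect = 21.5, secondary = TRUE,  deg = TRUE),
    list(name = "nv_deg_up_b",  presence = "all",          effect = 21.5, secondary = FALSE, deg = TRUE),
    list(name = "nv_deg_up_c",  presence = "all",          effect = 8.5,  secondary = TRUE,  deg = TRUE),
    list(name = "nv_null_a",    presence = "all",          effect = 1,    secondary = FALSE, deg = FALSE),
    list(name = "nv_null_b",    presence = "all",          effect = 1,    secondary = TRUE,  deg = FALSE),
    list(name = "nv_trt4_a",    presence = "treated",      effect = 1,    secondary = TRUE,  deg = TRUE),
    list(name = "nv_trt4_b",    presence = "treated",      effect = 1,    secondary = FALSE, deg = TRUE),
    list(name = "nv_ctrl4",     presence = "control",      effect = 1,    secondary = FALSE, deg = TRUE),
    list(name = "nv_both2",     presence = c(1L, 5L),      effect = 1,    secondary = FALSE, deg = FALSE),
    list(name = "nv_both2b",    presence = c(2L, 6L),      effect = 1,    secondary = TRUE,  deg = FALSE),
    list(name = "nv_both3",     presence = c(1L, 2L, 5L),  effect = 1,    secondary = FALSE, deg = FALSE),
    list(name = "nv_both3b",    presence = c(3L, 4L, 7L),  effect = 1,    secondary = FALSE, deg = FALSE),
    list(name = "nv_s1_trt",    presence = 5L,             effect = 1,    secondary = FALSE, deg = FALSE),
    list(name = "nv_s1_ctrl",   presence = 1L,             effect = 1,    secondary = FALSE, deg = FALSE)
  )
}

#' Generate per-replicate transfrag templates with planted truth
#'
#' Builds locus templates realizing a planted class budget: `complete`
#' transfrags restate annotation transcripts (optionally with inward terminal
#' trims, whose terminal exons become `Within`); `partial` variants are made
#' by boundary extension (`Overlap` exon), sub-chain trimming (`Within`
#' exons) or intron exon insertion (`Novel-T` exon); `novel` loci are
#' intergenic multi-exon models placed in reserved slots with controlled
#' replicate-presence patterns (all exons `Novel-U`). Counts are added later
#' by [simulate_study()] (or any caller) via [generate_counts()]-style draws.
#'
#' @param ann result of [generate_annotation()].
#' @param n_per_group replicates per group (default 4).
#' @param groups two group labels, control first.
#' @param budget list with `complete`, `complete_single`, `partial_overlap`,
#'   `partial_within`, `partial_novelT` counts.
#' @param novel_patterns roster of planted novel loci (see source for the
#'   default; sample indices are 1..n control then n+1..2n treated).
#' @param seed RNG seed.
#' @return list with `templates` (per-template exon tables with per-exon
#'   planted labels, presence, class truth) and `truth` tables
#'   (`transcripts`, `exons`, `novel`).
#' @export
generate_transfrags <- function(ann, n_per_group = 4L,
                                groups = c("CTRL", "TREATED"),
                                budget = list(complete = 6L, complete_single = 2L,
                                              partial_overlap = 3L,
                                              partial_within = 2L,
                                              partial_novelT = 3L),
                                novel_patterns = .default_novel_patterns(),
                                seed = 1L) {
  set.seed(seed + 202L)
  anno <- ann$annotation
  tx <- anno$transcripts
  sample_ids <- c(paste0(groups[1L], "_", seq_len(n_per_group)),
                  paste0(groups[2L], "_", seq_len(n_per_group)))
  presence_of <- function(spec) {
    if (identical(spec, "all")) sample_ids
    else if (identical(spec, "control")) sample_ids[seq_len(n_per_group)]
    else if (identical(spec, "treated")) sample_ids[n_per_group + seq_len(n_per_group)]
    else sample_ids[spec]
  }

  fam_ids <- ann$family_ids
  multi <- tx[n_exons >= 4L & !(transcript_id %in% fam_ids)][order(transcript_id)]
  single <- tx[n_exons == 1L][order(transcript_id)]
  need_multi <- budget$complete + budget$partial_overlap +
    budget$partial_within + budget$partial_novelT
  if (nrow(multi) < need_multi) stop("annotation too small for the class budget")
  if (nrow(single) < budget$complete_single) stop("not enough single-exon genes")
  picks <- multi$transcript_id[seq_len(need_multi)]
  i <- 0L
  take <- function(n) { r <- picks[i + seq_len(n)]; i <<- i + n; r }

  templates <- list()
  add_template <- function(id, exons, labels, class, source_ref, presence,
                           effect = 1, exon_effects = NULL, pattern = NA_character_,
                           secondary = FALSE, deg = FALSE) {
    exons <- as.data.table(exons)
    exons[, `:=`(transcript_id = id, gene_id = id)]
    setorder(exons, start)
    exons[, exon_index := seq_len(.N)]
    exons[, label := labels]
    if (is.null(exon_effects)) exon_effects <- rep(1, nrow(exons))
    exons[, exon_effect := exon_effects]
    templates[[id]] <<- list(template_id = id, exons = exons[], class = class,
                             source_ref = source_ref, presence = presence,
                             effect = effect, pattern = pattern,
                             secondary = secondary, deg = deg)
  }
  ref_exons <- function(tid) anno$exons[transcript_id == tid,
                                        .(chrom, start, end, strand)]

  ## complete (multi-exon): half untrimmed (all Exact), half inward-trimmed
  for (j in seq_len(budget$complete)) {
    rid <- take(1L)
    e <- ref_exons(rid)
    labels <- rep("Exact", nrow(e))
    if (j > budget$complete / 2) {
      trim <- 20L
      e$start[1L] <- e$start[1L] + trim
      e$end[nrow(e)] <- e$end[nrow(e)] - trim
      labels[c(1L, nrow(e))] <- "Within"
    }
    add_template(sprintf("tmpl_complete_%02d", j), e, labels, "complete", rid,
                 presence_of("all"))
  }
  ## complete (single-exon): contained restatement
  for (j in seq_len(budget$complete_single)) {
    rid <- single$transcript_id[j]
    e <- ref_exons(rid)
    e$start <- e$start + 15L; e$end <- e$end - 15L
    add_template(sprintf("tmpl_csingle_%02d", j), e, "Within", "complete", rid,
                 presence_of("all"))
  }
  ## family isoforms restated exactly; defining exon of isoform 1 induced
  fam_effect <- 6
  for (j in seq_along(fam_ids)) {
    e <- ref_exons(fam_ids[j])
    shared <- ann$annotation$exons[gene_id == "FAM",
                                   .(n = uniqueN(transcript_id)),
                                   by = .(chrom, start, end, strand)][n >= 2L]
    is_shared <- paste(e$start, e$end) %in% paste(shared$start, shared$end)
    eff <- rep(1, nrow(e))
    if (j == 1L) eff[!is_shared] <- fam_effect
    add_template(sprintf("tmpl_fam_%02d", j), e, rep("Exact", nrow(e)),
                 "complete", fam_ids[j], presence_of("all"),
                 exon_effects = eff)
  }
  ## partial: boundary extension into the intron -> Overlap exon
  ov_presence <- list("all", "treated", "control")
  for (j in seq_len(budget$partial_overlap)) {
    rid <- take(1L)
    e <- ref_exons(rid)
    mid <- 2L
    e$end[mid] <- e$end[mid] + 12L
    labels <- rep("Exact", nrow(e)); labels[mid] <- "Overlap"
    add_template(sprintf("tmpl_overlap_%02d", j), e, labels, "partial", rid,
                 presence_of(ov_presence[[(j - 1L) %% 3L + 1L]]))
  }
  ## partial: trimmed sub-chain -> Within terminal exons
  wi_presence <- list("all", "treated")
  for (j in seq_len(budget$partial_within)) {
    rid <- take(1L)
    e <- ref_exons(rid)
    e <- e[2:(nrow(e) - 1L)]
    e$start[1L] <- e$start[1L] + 10L
    e$end[nrow(e)] <- e$end[nrow(e)] - 10L
    labels <- rep("Exact", nrow(e)); labels[c(1L, nrow(e))] <- "Within"
    add_template(sprintf("tmpl_within_%02d", j), e, labels, "partial", rid,
                 presence_of(wi_presence[[(j - 1L) %% 2L + 1L]]))
  }
  ## partial: exon inserted mid-intron -> Novel-T
  nt_presence <- list("all", "treated", "control")
  for (j in seq_len(budget$partial_novelT)) {
    rid <- take(1L)
    e <- ref_exons(rid)
    gap_i <- which.max(e$start[-1L] - e$end[-nrow(e)])
    ins_start <- e$end[gap_i] + round((e$start[gap_i + 1L] - e$end[gap_i] - 100L) / 2)
    ins <- data.table(chrom = e$chrom[1L], start = ins_start,
                      end = ins_start + 100L, strand = e$strand[1L])
    e2 <- rbind(e, ins)[order(start)]
    labels <- rep("Exact", nrow(e2))
    labels[e2$start == ins_start] <- "Novel-T"
    add_template(sprintf("tmpl_novelT_%02d", j), e2, labels, "partial", rid,
                 presence_of(nt_presence[[(j - 1L) %% 3L + 1L]]))
  }
  ## novel intergenic loci in reserved slots; overlap-designated loci share
  ## the secondary-only slots (1..secondary_extra), others use free slots
  slots <- ann$slots
  n_sec <- ann$config$secondary_extra
  sec_slot <- 0L; free_slot <- n_sec
  for (p in novel_patterns) {
    if (isTRUE(p$secondary)) {
      sec_slot <- sec_slot + 1L
      if (sec_slot > n_sec) stop("not enough secondary slots for overlap patterns")
      s <- slots[sec_slot]
      starts <- s$start + c(150L, 700L, 1200L)   # exon 1 overlaps ENS exon 1
    } else {
      free_slot <- free_slot + 1L
      if (free_slot > nrow(slots)) stop("not enough free slots for novel loci")
      s <- slots[free_slot]
      starts <- s$start + c(100L, 700L, 1300L)
    }
    e <- data.table(chrom = s$chrom, start = starts, end = starts + 140L,
                    strand = "+")
    add_template(paste0("tmpl_", p$name), e, rep("Novel-U", nrow(e)), "novel",
                 NA_character_, presence_of(p$presence), effect = p$effect,
                 pattern = p$name, secondary = isTRUE(p$secondary),
                 deg = isTRUE(p$deg))
  }

  ## truth tables
  grp <- setNames(rep(groups, each = n_per_group), sample_ids)
  truth_tx <- rbindlist(lapply(templates, function(t) data.table(
    template_id = t$template_id, class = t$class, source_ref = t$source_ref,
    n_exons = nrow(t$exons), support = length(t$presence),
    effect = t$effect, is_deg = t$deg)))
  status_of <- function(presence) {
    g <- unique(unname(grp[presence]))
    if (length(g) > 1L) "common" else paste0("unique_", g)
  }
  truth_ex <- rbindlist(lapply(templates, function(t) {
    data.table(chrom = t$exons$chrom, start = t$exons$start, end = t$exons$end,
               strand = t$exons$strand, label = t$exons$label,
               status = status_of(t$presence), template_id = t$template_id)
  }))
  truth_novel <- rbindlist(lapply(Filter(function(t) t$class == "novel", templates),
    function(t) data.table(
      template_id = t$template_id, pattern = t$pattern,
      support = length(t$presence),
      category = {
        g <- unique(unname(grp[t$presence]))
        if (length(g) > 1L) "both" else g
      },
      effect = t$effect, secondary_overlap = t$secondary, is_deg = t$deg)))

  list(templates = templates, sample_ids = sample_ids, group_labels = grp,
       truth = list(transcripts = truth_tx[], exons = truth_ex[],
                    novel = truth_novel[]))
}

#' Generate a negative-binomial count table with planted effects
#'
#' Counts are `NB(mean = base * libsize * effect(group), size = 1/dispersion)`
#' with a shared dispersion; `dispersion = 0` degenerates to the rounded mean
#' (Poisson limit's zero-noise analogue used for exact truth recovery).
#'
#' @param effects named numeric vector of signed fold changes per feature
#'   (magnitude convention: `-2` means halved in the treated group).
#' @param group_labels named character vector sample_id -> group (two groups).
#' @param base_mean scalar, or named vector per feature; by default drawn
#'   log-uniformly from `[50, 500]`.
#' @param dispersion NB dispersion (>= 0).
#' @param library_sizes scalar or named per-sample relative library sizes.
#' @param seed RNG seed.
#' @param treated treated group label (default as in [call_degs()]).
#' @return A [feature_table()] of integer counts.
#' @export
generate_counts <- function(effects, group_labels, base_mean = NULL,
                            dispersion = 0.05, library_sizes = 1, seed = 1L,
                            treated = NULL) {
  stopifnot(dispersion >= 0, !is.null(names(effects)))
  set.seed(seed + 303L)
  glev <- sort(unique(unname(group_labels)))
  treated <- .pick_treated(glev, treated)
  samples <- names(group_labels)
  if (length(library_sizes) == 1L) {
    library_sizes <- setNames(rep(library_sizes, length(samples)), samples)
  }
  if (is.null(base_mean)) {
    base_mean <- setNames(.logunif(length(effects), 50, 500), names(effects))
  } else if (length(base_mean) == 1L) {
    base_mean <- setNames(rep(base_mean, length(effects)), names(effects))
  }
  mult <- ifelse(effects >= 1, effects, -1 / effects)  # signed FC -> ratio
  counts <- matrix(0, nrow = length(effects), ncol = length(samples),
                   dimnames = list(names(effects), samples))
  for (s in samples) {
    eff_s <- if (unname(group_labels[s]) == treated) mult else 1
    mu <- base_mean[names(effects)] * library_sizes[s] * eff_s
    counts[, s] <- .nb_draw(mu, dispersion)
  }
  feature_table(counts, group_labels = group_labels, integer_counts = TRUE)
}

#' Generate probe placements and signals
#'
#' Realizes the probe-placement scenarios relevant to cross-platform
#' comparison: a 3'-terminal-exon probe for most ordinary transcripts, probes
#' on the isoform-defining and shared exons of the family, and an `absent`
#' class with no probe at all. The log2 probe signal is
#' `a + b * log2(1 + true probed-exon abundance)` plus Gaussian noise.
#'
#' @param ann result of [generate_annotation()].
#' @param exon_mu per-sample true exon abundance: data.table
#'   `transcript_id`, `exon_index`, `sample_id`, `mu`.
#' @param p_absent fraction of ordinary transcripts with no probe.
#' @param a,b affine response parameters.
#' @param signal_sd Gaussian noise SD on the log2 scale (0 = noise-free).
#' @param seed RNG seed.
#' @return list with `probes` (placement table as in [read_probe_bed()]),
#'   `signal` ([feature_table()] probes x samples), and `probe_truth`
#'   (probe_id, transcript_id, exon_index, scenario).
#' @export
generate_probes <- function(ann, exon_mu, p_absent = 0.2, a = 4, b = 1,
                            signal_sd = 0.25, seed = 1L) {
  set.seed(seed + 404L)
  anno <- ann$annotation
  fam_ids <- ann$family_ids
  ord <- anno$transcripts[!(transcript_id %in% fam_ids)][order(transcript_id)]
  absent <- ord$transcript_id[runif(nrow(ord)) < p_absent]
  placements <- list(); truth <- list()
  add_probe <- function(pid, tid, idx, scenario) {
    e <- anno$exons[transcript_id == tid & exon_index == idx]
    p_start <- e$start + min(10L, e$end - e$start - 50L)
    placements[[pid]] <<- data.table(probe_id = pid, chrom = e$chrom,
                                     start = p_start, end = p_start + 50L,
                                     strand = e$strand)
    truth[[pid]] <<- data.table(probe_id = pid, transcript_id = tid,
                                exon_index = idx, scenario = scenario)
  }
  for (tid in setdiff(ord$transcript_id, absent)) {
    n_ex <- ord[transcript_id == tid, n_exons]
    # 3'-most exon depends on strand
    idx <- if (ord[transcript_id == tid, strand] == "+") n_ex else 1L
    add_probe(paste0("P_", tid), tid, idx, "three_prime")
  }
  fam_ex <- anno$exons[gene_id == "FAM"]
  shared_keys <- fam_ex[, .(n = uniqueN(transcript_id)), by = .(start, end)][n >= 2L]
  for (tid in fam_ids) {
    e <- fam_ex[transcript_id == tid]
    def_idx <- e$exon_index[!(paste(e$start, e$end) %in%
                                paste(shared_keys$start, shared_keys$end))][1L]
    add_probe(paste0("P_def_", tid), tid, def_idx, "defining")
  }
  # one probe on the first shared exon (attached to isoform 1's coordinates)
  sh_idx <- fam_ex[transcript_id == fam_ids[1L]][
    paste(start, end) %in% paste(shared_keys$start, shared_keys$end), exon_index][1L]
  add_probe("P_shared_FAM", fam_ids[1L], sh_idx, "shared")

  probes <- rbindlist(placements)
  truth <- rbindlist(truth)
  if (length(absent)) {
    truth <- rbind(truth, data.table(probe_id = NA_character_,
                                     transcript_id = absent,
                                     exon_index = NA_integer_,
                                     scenario = "absent"))
  }
  exon_mu <- as.data.table(exon_mu)
  samples <- sort(unique(exon_mu$sample_id))
  sig <- merge(truth[!is.na(probe_id)], exon_mu,
               by = c("transcript_id", "exon_index"), allow.cartesian = TRUE)
  # complete the probe x sample grid; a probed exon absent from a sample's
  # assembly reads as zero abundance (array background)
  grid <- CJ(probe_id = truth[!is.na(probe_id), probe_id], sample_id = samples)
  sig <- merge(grid, sig[, .(probe_id, sample_id, mu)],
               by = c("probe_id", "sample_id"), all.x = TRUE)
  sig[is.na(mu), mu := 0]
  sig[, value := a + b * log2(1 + mu) +
        (if (signal_sd > 0) rnorm(.N, 0, signal_sd) else 0)]
  m <- dcast(sig, probe_id ~ sample_id, value.var = "value")
  vals <- as.matrix(m[, -1L]); rownames(vals) <- m$probe_id
  list(probes = probes[], signal = feature_table(vals), probe_truth = truth[])
}

#' Simulate the full study with planted ground truth
#'
#' Wires the generator stages into the complete study layout: annotation with
#' isoform family and secondary annotation; 2 x `n_per_group` replicate
#' transfrag sets realizing the planted transcript/exon classes and
#' novel-locus presence patterns; per-exon and per-transcript NB counts
#' (planted treatment effects; `dispersion = 0` gives exact zero-noise truth
#' recovery); reference-exon counts for threshold fitting; probe placements
#' and signals.
#'
#' @param seed global seed; fixed offsets derive each stage's substream.
#' @param n_per_group replicates per group.
#' @param groups group labels, control first.
#' @param dispersion NB dispersion for all counts (0 = noise-free).
#' @param base_range log-uniform range of transfrag template expression.
#' @param ref_base_range log-uniform range of reference gene expression.
#' @param signal_sd microarray probe noise SD (log2 scale).
#' @param annotation_args passed to [generate_annotation()].
#' @param ... passed to [generate_transfrags()].
#' @return list with `annotation`, `secondary`, `slots`, `samples` (list of
#'   [transfrag_set()]), `ref_exon_counts`, `probes`, `probe_signal`,
#'   `probe_truth`, `exon_counts` (long per-sample true assignments),
#'   `group_labels`, `truth`, `params`.
#' @export
simulate_study <- function(seed = 1L, n_per_group = 4L,
                           groups = c("CTRL", "TREATED"),
                           dispersion = 0.05,
                           base_range = c(300, 800),
                           ref_base_range = c(10, 3000),
                           signal_sd = 0.25,
                           annotation_args = list(), ...) {
  ann <- do.call(generate_annotation, c(list(seed = seed), annotation_args))
  tf <- generate_transfrags(ann, n_per_group = n_per_group, groups = groups,
                            seed = seed, ...)
  templates <- tf$templates
  sample_ids <- tf$sample_ids
  grp <- tf$group_labels
  treated <- groups[2L]

  ## per-template base expression (shared across samples)
  set.seed(seed + 505L)
  bases <- setNames(.logunif(length(templates), base_range[1L], base_range[2L]),
                    names(templates))
  # strong planted effects ride on a fixed moderate base so that induced exon
  # counts stay inside the outlier fence of the significance filter; the
  # family gets a fixed base for the same reason (its defining exon is
  # induced several-fold)
  for (id in names(templates)) {
    if (templates[[id]]$class == "novel" && abs(templates[[id]]$effect) > 2) {
      bases[id] <- 100
    }
    if (grepl("^tmpl_fam_", id)) bases[id] <- 250
  }

  ## per-exon true means and NB draws, per sample
  set.seed(seed + 606L)
  exon_rows <- rbindlist(lapply(templates, function(t) {
    e <- copy(t$exons)
    # per-length read rate (reads per 300 bp at unit base) keeps every exon's
    # expected count well inside the significance filter's working range
    e[, lenfac := (end - start) / 300]
    e[, template_id := t$template_id]
    e[, effect := ifelse(t$effect >= 1, t$effect, -1 / t$effect)]
    e
  }))
  long <- rbindlist(lapply(sample_ids, function(s) {
    pres <- vapply(templates, function(t) s %in% t$presence, logical(1L))
    e <- exon_rows[template_id %in% names(templates)[pres]]
    is_trt <- unname(grp[s]) == treated
    e[, mu := bases[template_id] * lenfac *
        (if (is_trt) effect * exon_effect else 1)]
    e[, `:=`(sample_id = s, count = .nb_draw(mu, dispersion))]
    e
  }))

  samples <- lapply(sample_ids, function(s) {
    e <- long[sample_id == s,
              .(transcript_id, gene_id, chrom, start, end, strand, count)]
    transfrag_set(e, sample_id = s, group_label = unname(grp[s]),
                  total_mapped_reads = 2e6)
  })
  names(samples) <- sample_ids

  ## reference-exon counts for threshold fitting; genes restated by a
  ## transfrag template inherit that template's base so both platforms (and
  ## the reference-count track) measure one latent expression per gene
  set.seed(seed + 707L)
  ref_ex <- copy(ann$annotation$exons)
  gene_base <- setNames(.logunif(uniqueN(ref_ex$gene_id),
                                 ref_base_range[1L], ref_base_range[2L]),
                        unique(ref_ex$gene_id))
  src_gene <- ann$annotation$transcripts[, setNames(gene_id, transcript_id)]
  for (t in templates) {
    if (!is.na(t$source_ref)) gene_base[src_gene[t$source_ref]] <- bases[t$template_id]
  }
  ref_ex[, mu := gene_base[gene_id] * (end - start) / 300]
  ref_counts <- vapply(sample_ids, function(s) .nb_draw(ref_ex$mu, dispersion),
                       numeric(nrow(ref_ex)))
  rownames(ref_counts) <- paste0(ref_ex$transcript_id, ":", ref_ex$exon_index)
  ref_exon_counts <- feature_table(ref_counts, group_labels = grp,
                                   integer_counts = TRUE)

  ## probe signals from the true per-exon means of annotation-derived
  ## templates; template exons are mapped back to annotation exons by
  ## overlap (trims/extensions keep a 1:1 overlap, dropped exons map to
  ## nothing and read as absent)
  sourced <- Filter(function(t) !is.na(t$source_ref), templates)
  probe_mu <- rbindlist(lapply(sourced, function(t) {
    ae <- ann$annotation$exons[transcript_id == t$source_ref,
                               .(exon_index, a_start = start, a_end = end)]
    te <- long[template_id == t$template_id, .(sample_id, start, end, mu)]
    out <- rbindlist(lapply(seq_len(nrow(ae)), function(i) {
      sub <- te[start < ae$a_end[i] & end > ae$a_start[i]]
      if (nrow(sub)) data.table(exon_index = ae$exon_index[i],
                                sample_id = sub$sample_id, mu = sub$mu)
    }))
    if (nrow(out)) out[, transcript_id := t$source_ref]
    out
  }), fill = TRUE)
  # transcripts without a transfrag template: constant abundance equal to
  # their gene's latent expression (same quantity the reference counts track)
  missing_tx <- setdiff(ann$annotation$transcripts$transcript_id,
                        unique(probe_mu$transcript_id))
  if (length(missing_tx)) {
    flat <- merge(CJ(transcript_id = missing_tx, sample_id = sample_ids),
                  ref_ex[, .(transcript_id, exon_index, mu)],
                  by = "transcript_id", allow.cartesian = TRUE)
    probe_mu <- rbind(probe_mu, flat[, .(transcript_id, exon_index, sample_id, mu)])
  }
  pr <- generate_probes(ann, probe_mu, signal_sd = signal_sd, seed = seed)

  list(annotation = ann$annotation, secondary = ann$secondary, slots = ann$slots,
       family_ids = ann$family_ids,
       samples = samples, ref_exon_counts = ref_exon_counts,
       probes = pr$probes, probe_signal = pr$signal, probe_truth = pr$probe_truth,
       exon_counts = long[, .(template_id, transcript_id, exon_index, sample_id,
                              chrom, start, end, strand, mu, count)],
       group_labels = grp, truth = tf$truth,
       params = list(seed = seed, n_per_group = n_per_group, groups = groups,
                     dispersion = dispersion, base_range = base_range,
                     ref_base_range = ref_base_range, signal_sd = signal_sd))
}

#' Generate a paired two-platform expression dataset
#'
#' Convenience generator for correlation studies: a shared true log2
#' abundance per feature observed by two platforms, with either
#' signal-dependent noise (SD proportional to 1/signal, the regime where
#' cross-platform concordance improves with expression) or exchangeable noise
#' (constant SD).
#'
#' @param n_features,n_per_group sizes.
#' @param noise `"signal_dependent"` or `"exchangeable"`.
#' @param seed RNG seed.
#' @param groups group labels, control first.
#' @return list of two [feature_table()]s `a` and `b` with shared ids.
#' @export
generate_platform_pair <- function(n_features = 400L, n_per_group = 4L,
                                   noise = c("signal_dependent", "exchangeable"),
                                   seed = 1L, groups = c("CTRL", "TREATED")) {
  noise <- match.arg(noise)
  set.seed(seed + 808L)
  samples <- c(paste0(groups[1L], "_", seq_len(n_per_group)),
               paste0(groups[2L], "_", seq_len(n_per_group)))
  grp <- setNames(rep(groups, each = n_per_group), samples)
  ids <- sprintf("F%04d", seq_len(n_features))
  true <- runif(n_features, 2, 12)   # log2 abundance
  sd_of <- if (noise == "signal_dependent") 15 / true^2 else rep(1.2, n_features)
  make <- function() {
    m <- vapply(samples, function(s) true + rnorm(n_features, 0, sd_of),
                numeric(n_features))
    rownames(m) <- ids
    feature_table(m, group_labels = grp)
  }
  list(a = make(), b = make())
}
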