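# Cross-platform expression statistics: RPM and log2-quantile normalization,
# median-polish probe summarization, signed fold changes, permutation t-test
# DEG calling (uncorrected, per the study design), quartile-stratified
# Spearman correlation, exon-specific isoform fold changes and platform
# Venn overlaps.

#' Reads-per-million normalization
#'
#' @param table a [feature_table()] of raw counts.
#' @param totals named numeric vector of per-sample total mapped reads.
#' @return A `feature_table` with `value / (total / 1e6)` per sample.
#' @export
rpm_normalize <- function(table, totals) {
  stopifnot(inherits(table, "feature_table"))
  if (!all(colnames(table$values) %in% names(totals))) {
    stop("totals missing for some samples")
  }
  totals <- totals[colnames(table$values)]
  if (any(!is.finite(totals)) || any(totals <= 0)) stop("totals must be positive")
  feature_table(sweep(table$values, 2L, totals / 1e6, "/"),
                group_labels = table$group_labels)
}

#' Log2 transform and quantile normalize
#'
#' `log2(x + pseudocount)` followed by classic quantile normalization (rank
#' substitution by per-rank means, ties averaged); afterwards every column
#' shares an identical sorted value multiset.
#'
#' @param table a [feature_table()] with non-negative values.
#' @param pseudocount added before the log (default 1).
#' @return A normalized `feature_table`.
#' @export
log2_quantile_normalize <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$values < 0)) stop("values must be non-negative")
  lg <- log2(table$values + pseudocount)
  if (ncol(lg) < 2L) {
    warning("single sample: returning log2 values without quantile normalization")
    return(feature_table(lg, group_labels = table$group_labels))
  }
  qn <- limma::normalizeQuantiles(lg, ties = TRUE)
  dimnames(qn) <- dimnames(lg)
  feature_table(qn, group_labels = table$group_labels)
}

#' Summarize probe signals by median polish
#'
#' Tukey's alternating row/column median sweeps decompose a probes x samples
#' log2 matrix into overall + probe + sample effects + residuals; the
#' summarized per-sample signal is overall + sample effect. Sweeps stop when
#' the largest absolute median removed in a full sweep drops below `tol`.
#'
#' @param probe_signals numeric matrix (probes x samples), log2 scale.
#' @param max_iter,tol sweep controls.
#' @return list with `summary` (named per-sample signal), `overall`, `row`,
#'   `col`, `residuals`, `converged`, `iterations`.
#' @export
median_polish_summarize <- function(probe_signals, max_iter = 20L, tol = 1e-6) {
  x <- as.matrix(probe_signals)
  if (any(!is.finite(x))) stop("probe signals must be finite")
  if (nrow(x) == 1L) {
    v <- x[1L, ]
    ov <- median(v)
    return(list(summary = v, overall = ov, row = 0,
                col = v - ov, residuals = x * 0, converged = TRUE, iterations = 0L))
  }
  overall <- 0
  row_eff <- rep(0, nrow(x)); col_eff <- rep(0, ncol(x))
  r <- x
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    rdelta <- apply(r, 1L, median)
    r <- r - rdelta
    row_eff <- row_eff + rdelta
    d <- median(col_eff); col_eff <- col_eff - d; overall <- overall + d
    cdelta <- apply(r, 2L, median)
    r <- sweep(r, 2L, cdelta)
    col_eff <- col_eff + cdelta
    d <- median(row_eff); row_eff <- row_eff - d; overall <- overall + d
    if (max(abs(rdelta), abs(cdelta)) < tol) { converged <- TRUE; break }
  }
  summary <- overall + col_eff
  names(summary) <- colnames(x)
  list(summary = summary, overall = overall, row = row_eff, col = col_eff,
       residuals = r, converged = converged, iterations = it)
}

#' Signed fold change
#'
#' Ratio convention in which down-regulation `r < 1` is reported as `-1/r`,
#' so magnitudes are symmetric about +/-1 (e.g. a halving is -2).
#'
#' @param mean_treated,mean_control positive linear-scale group means
#'   (apply a pseudocount upstream for counts).
#' @return signed fold change(s); `+1` for no change.
#' @export
signed_fold_change <- function(mean_treated, mean_control) {
  if (any(mean_treated <= 0) || any(mean_control <= 0)) {
    stop("group means must be positive (apply a pseudocount upstream)")
  }
  r <- mean_treated / mean_control
  ifelse(r >= 1, r, -1 / r)
}

# pooled-variance two-sample t for each feature (rows of X) under each
# grouping; P is an n x B 0/1 matrix whose columns pick group A (size n1).
# Returns features x B matrix; zero pooled variance gives 0 (no mean
# difference) or +/-Inf.
.perm_t_matrix <- function(X, P, n1, n2) {
  Tot <- rowSums(X); TS <- rowSums(X^2)
  SA <- X %*% P; SSA <- X^2 %*% P
  mA <- SA / n1
  mB <- (Tot - SA) / n2
  ssA <- pmax(SSA - SA^2 / n1, 0)
  ssB <- pmax((TS - SSA) - (Tot - SA)^2 / n2, 0)
  sp2 <- (ssA + ssB) / (n1 + n2 - 2)
  num <- mA - mB
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- num / denom
  zero <- denom == 0
  if (any(zero)) t[zero] <- ifelse(num[zero] == 0, 0, sign(num[zero]) * Inf)
  t
}

# group-A index subsets as an n x B indicator matrix
.perm_indicator <- function(n, idx_list) {
  P <- matrix(0, nrow = n, ncol = length(idx_list))
  for (j in seq_along(idx_list)) P[idx_list[[j]], j] <- 1
  P
}

.group_split <- function(group_labels) {
  glev <- sort(unique(unname(group_labels)))
  if (length(glev) != 2L) stop("need exactly two groups, got: ",
                               paste(glev, collapse = ", "))
  a <- which(group_labels == glev[1L]); b <- which(group_labels == glev[2L])
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 samples")
  list(levels = glev, a = a, b = b)
}

#' Two-sample permutation t-test for one feature
#'
#' Two-sided p-value from the empirical distribution of the pooled-variance
#' Student t-statistic under sample-label permutation. `exact` mode
#' enumerates all distinct group-A subsets (e.g. choose(8,4) = 70 for 4v4)
#' and reports the raw proportion with `|t*| >= |t_obs|`; `random` mode draws
#' `n_perm` label permutations and reports the add-one estimator
#' `(1 + count) / (1 + n_perm)`. A zero-variance feature returns p = 1 with a
#' `zero_variance` flag.
#'
#' @param values numeric vector, one feature across samples.
#' @param group_labels character vector (or named vector) of two group labels.
#' @param n_perm number of random permutations (random mode).
#' @param mode `"random"` or `"exact"`.
#' @param seed RNG seed for random mode.
#' @return list with `p_value`, `t_obs`, `n_used`, `mode`, `zero_variance`.
#' @export
permutation_t_test <- function(values, group_labels, n_perm = 10000L,
                               mode = c("random", "exact"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(values) == length(group_labels))
  gs <- .group_split(group_labels)
  n <- length(values); n1 <- length(gs$a); n2 <- length(gs$b)
  X <- matrix(values, nrow = 1L)
  t_obs <- .perm_t_matrix(X, .perm_indicator(n, list(gs$a)), n1, n2)[1L, 1L]
  if (is.nan(t_obs)) t_obs <- 0
  zero_var <- t_obs == 0 && all(values == values[1L])
  if (zero_var) {
    return(list(p_value = 1, t_obs = 0, n_used = 0L, mode = mode,
                zero_variance = TRUE))
  }
  # a permutation and its complement compute the same |t| through different
  # floating-point paths; compare with a relative tolerance so exact ties count
  thr <- if (is.finite(t_obs)) abs(t_obs) - 1e-8 * (abs(t_obs) + 1) else abs(t_obs)
  if (mode == "exact") {
    subs <- combn(n, n1, simplify = FALSE)
    tstar <- .perm_t_matrix(X, .perm_indicator(n, subs), n1, n2)[1L, ]
    p <- mean(abs(tstar) >= thr)
    n_used <- length(subs)
  } else {
    set.seed(seed)
    subs <- lapply(seq_len(n_perm), function(i) sample.int(n, n1))
    tstar <- .perm_t_matrix(X, .perm_indicator(n, subs), n1, n2)[1L, ]
    p <- (1 + sum(abs(tstar) >= thr)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(p_value = p, t_obs = t_obs, n_used = n_used, mode = mode,
       zero_variance = FALSE)
}

.control_synonyms <- c("ctrl", "cntl", "control", "untreated", "vehicle")

.pick_treated <- function(glev, treated = NULL) {
  if (!is.null(treated)) {
    if (!treated %in% glev) stop("treated group '", treated, "' not among labels")
    return(treated)
  }
  is_ctrl <- tolower(glev) %in% .control_synonyms
  if (sum(is_ctrl) == 1L) glev[!is_ctrl] else glev[2L]
}

#' Call differentially expressed features
#'
#' Per-feature signed fold change on linear-scale group means (pseudocount
#' applied) and a permutation t-test p-value; a feature is a DEG when
#' `|signed FC| > fc_cut` and `p < p_cut`, with no multiple-testing
#' correction. The default null distribution pools permutation t-statistics
#' across all features (Storey-style empirical null), which with few samples
#' per group resolves p-values far below the granularity any single feature's
#' own permutations can reach; `null_dist = "per_feature"` gives the
#' classical per-feature permutation p instead.
#'
#' @param table a normalized [feature_table()] with group labels.
#' @param fc_cut,p_cut DEG cutoffs (defaults 2 and 0.005).
#' @param n_perm permutations (random mode).
#' @param mode `"random"` or `"exact"` label permutations.
#' @param null_dist `"pooled"` (default) or `"per_feature"`.
#' @param seed RNG seed.
#' @param log2_input are values log2 scale? (fold changes are computed on the
#'   linearized values; the t-test uses the values as given).
#' @param pseudocount added to linear group means before the ratio.
#' @param treated treated group label; by default the non-control-sounding
#'   label (else the second sorted level).
#' @param platform annotation string carried into the output.
#' @return data.table: `feature_id`, `mean_control`, `mean_treated`,
#'   `signed_fc`, `t_stat`, `p_value`, `is_deg`, `zero_variance`, `platform`.
#' @export
call_degs <- function(table, fc_cut = 2, p_cut = 0.005, n_perm = 10000L,
                      mode = c("random", "exact"),
                      null_dist = c("pooled", "per_feature"), seed = 1L,
                      log2_input = FALSE, pseudocount = 1, treated = NULL,
                      platform = "rnaseq") {
  mode <- match.arg(mode); null_dist <- match.arg(null_dist)
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$group_labels)) stop("call_degs needs group labels")
  gl <- table$group_labels
  gs <- .group_split(gl)
  treated <- .pick_treated(gs$levels, treated)
  control <- setdiff(gs$levels, treated)
  X <- table$values
  n <- ncol(X)
  idx_t <- which(unname(gl) == treated); idx_c <- which(unname(gl) == control)
  n1 <- length(idx_t); n2 <- length(idx_c)

  lin <- if (log2_input) 2^X else X
  m_t <- rowMeans(lin[, idx_t, drop = FALSE]) + pseudocount
  m_c <- rowMeans(lin[, idx_c, drop = FALSE]) + pseudocount
  fc <- signed_fold_change(m_t, m_c)

  t_obs <- .perm_t_matrix(X, .perm_indicator(n, list(idx_t)), n1, n2)[, 1L]
  t_obs[is.nan(t_obs)] <- 0
  zero_var <- apply(X, 1L, function(v) all(v == v[1L]))

  if (mode == "exact") {
    subs <- combn(n, n1, simplify = FALSE)
  } else {
    set.seed(seed)
    subs <- lapply(seq_len(n_perm), function(i) sample.int(n, n1))
  }
  tstar <- abs(.perm_t_matrix(X, .perm_indicator(n, subs), n1, n2))
  B <- length(subs)
  # relative tolerance so a permutation equal to the observed grouping counts
  # as a tie despite floating-point path differences
  thr <- ifelse(is.finite(t_obs), abs(t_obs) - 1e-8 * (abs(t_obs) + 1),
                abs(t_obs))
  if (null_dist == "per_feature") {
    cnt <- rowSums(tstar >= thr)
    p <- if (mode == "exact") cnt / B else (1 + cnt) / (1 + B)
  } else {
    pool <- sort(as.numeric(tstar))
    # count pooled |t*| >= |t_obs| per feature
    cnt <- length(pool) - findInterval(thr, pool, left.open = TRUE)
    p <- (1 + cnt) / (1 + length(pool))
  }
  p[zero_var] <- 1

  data.table(feature_id = rownames(X), mean_control = unname(m_c - pseudocount),
             mean_treated = unname(m_t - pseudocount),
             signed_fc = unname(fc), t_stat = unname(t_obs),
             p_value = unname(p),
             is_deg = unname(abs(fc) > fc_cut & p < p_cut & !zero_var),
             zero_variance = unname(zero_var), platform = platform)
}

#' Quartile-stratified Spearman correlation between platforms
#'
#' Shared features are binned into `n_bins` equal-size bins ranked on the
#' average control signal of platform `a` across replicates (ties broken by
#' feature id); within each bin, for each shared sample, Spearman's rho
#' between the two platforms is computed with the asymptotic t-approximation
#' p-value `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param a ranking platform [feature_table()] (e.g. microarray), with group
#'   labels.
#' @param b second platform `feature_table` (e.g. normalized RNA-Seq).
#' @param control control group label of `a`; by default the
#'   control-sounding label.
#' @param n_bins number of bins (default 4 quartiles).
#' @return data.table: `quartile`, `sample_id`, `n`, `rho`, `p_value`.
#' @export
quartile_spearman <- function(a, b, control = NULL, n_bins = 4L) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  feats <- intersect(rownames(a$values), rownames(b$values))
  samples <- intersect(colnames(a$values), colnames(b$values))
  if (length(feats) < n_bins * 3L) stop("too few shared features")
  if (!length(samples)) stop("no shared samples")
  if (is.null(a$group_labels)) stop("platform a needs group labels")
  glev <- sort(unique(unname(a$group_labels)))
  if (is.null(control)) {
    is_ctrl <- tolower(glev) %in% .control_synonyms
    control <- if (sum(is_ctrl) == 1L) glev[is_ctrl] else glev[1L]
  }
  ctrl_cols <- names(a$group_labels)[unname(a$group_labels) == control]
  ctrl_cols <- intersect(ctrl_cols, colnames(a$values))
  if (!length(ctrl_cols)) stop("no control samples in platform a")
  basis <- rowMeans(a$values[feats, ctrl_cols, drop = FALSE])
  ord <- order(basis, feats)
  bin <- ceiling(seq_along(ord) * n_bins / length(ord))
  res <- rbindlist(lapply(seq_len(n_bins), function(q) {
    f <- feats[ord[bin == q]]
    rbindlist(lapply(samples, function(s) {
      x <- a$values[f, s]; y <- b$values[f, s]
      rho <- suppressWarnings(cor(x, y, method = "spearman"))
      nq <- length(f)
      p <- if (is.na(rho)) NA_real_
           else if (abs(rho) >= 1) 0
           else 2 * pt(-abs(rho * sqrt((nq - 2) / (1 - rho^2))), df = nq - 2)
      data.table(quartile = q, sample_id = s, n = nq, rho = rho, p_value = p)
    }))
  }))
  res[]
}

#' Exon-specific isoform fold change
#'
#' For a family of transcript models sharing exons, exons present (by exact
#' coordinates and strand) in two or more family members are `shared`;
#' single-member exons are isoform-`defining`. The per-exon fold change uses
#' that exon's counts alone; the per-transcript fold change uses all of a
#' model's exon counts summed, and is therefore a count-weighted compromise
#' between its exons' ratios.
#'
#' @param family an [annotation_set()] (or exon table) of the family members.
#' @param exon_counts data.frame `transcript_id`, `exon_index`, `sample_id`,
#'   `count` of raw per-exon counts per sample.
#' @param group_labels named character vector sample_id -> group.
#' @param treated treated group label (default as in [call_degs()]).
#' @param pseudocount added to group means before the ratio when any mean is
#'   zero alongside a nonzero partner (default 0; zero/zero exons are
#'   flagged `undefined`).
#' @return list with `per_exon` (coordinates, `role`, `n_members`, `fc`,
#'   `flag`) and `per_transcript` (`transcript_id`, `fc`).
#' @export
exon_specific_fc <- function(family, exon_counts, group_labels, treated = NULL,
                             pseudocount = 0) {
  m <- if (inherits(family, "annotation_set")) .models_of(family)
       else list(exons = .validate_exon_df(family))
  fe <- m$exons
  if (uniqueN(fe$transcript_id) == 1L) {
    warning("family of one transcript: all exons are defining")
  }
  ec <- as.data.table(exon_counts)
  stopifnot(all(c("transcript_id", "exon_index", "sample_id", "count") %in% names(ec)))
  glev <- sort(unique(unname(group_labels)))
  treated <- .pick_treated(glev, treated)
  control <- setdiff(glev, treated)

  ec <- merge(ec, fe[, .(transcript_id, exon_index, chrom, start, end, strand)],
              by = c("transcript_id", "exon_index"))
  ec[, group := unname(group_labels[sample_id])]

  membership <- fe[, .(n_members = uniqueN(transcript_id)),
                   by = .(chrom, start, end, strand)]
  membership[, role := ifelse(n_members >= 2L, "shared", "defining")]

  .fc_of <- function(mt, mc) {
    if (is.na(mt) || is.na(mc)) return(list(fc = NA_real_, flag = "undefined"))
    if (mt == 0 && mc == 0) return(list(fc = NA_real_, flag = "undefined"))
    if (pseudocount == 0 && (mt == 0 || mc == 0)) {
      return(list(fc = NA_real_, flag = "unbounded"))
    }
    list(fc = signed_fold_change(mt + pseudocount, mc + pseudocount), flag = "ok")
  }

  per_exon <- ec[, {
    # a shared exon's reads are counted once per exon coordinate: average the
    # per-member counts rather than summing duplicated assignments
    per_member <- .SD[, .(count = mean(count)), by = .(sample_id, group)]
    mt <- per_member[group == treated, mean(count)]
    mc <- per_member[group == control, mean(count)]
    r <- .fc_of(ifelse(length(mt), mt, NA_real_), ifelse(length(mc), mc, NA_real_))
    .(fc = r$fc, flag = r$flag)
  }, by = .(chrom, start, end, strand)]
  per_exon <- merge(per_exon, membership, by = c("chrom", "start", "end", "strand"))
  setorder(per_exon, chrom, start, end)

  per_tx <- ec[, {
    per_sample <- .SD[, .(count = sum(count)), by = .(sample_id, group)]
    mt <- per_sample[group == treated, mean(count)]
    mc <- per_sample[group == control, mean(count)]
    r <- .fc_of(ifelse(length(mt), mt, NA_real_), ifelse(length(mc), mc, NA_real_))
    .(fc = r$fc, flag = r$flag)
  }, by = transcript_id]

  list(per_exon = per_exon[], per_transcript = per_tx[])
}

#' Venn region counts for 2 or 3 feature-id sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return list with `regions` (membership pattern and count; regions sum to
#'   the union size) and `pairwise` (shared counts and shared fractions).
#' @export
platform_overlap <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || !length(sets) %in% c(2L, 3L)) {
    stop("platform_overlap needs a named list of 2 or 3 sets")
  }
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- as.data.table(table(pattern))
  setnames(regions, c("region", "n"))
  regions[, n := as.integer(n)]
  pairs <- combn(names(sets), 2L, simplify = FALSE)
  pairwise <- rbindlist(lapply(pairs, function(p) {
    shared <- length(intersect(sets[[p[1L]]], sets[[p[2L]]]))
    data.table(set_a = p[1L], set_b = p[2L], shared = shared,
               frac_a = if (length(sets[[p[1L]]])) shared / length(sets[[p[1L]]]) else NA_real_,
               frac_b = if (length(sets[[p[2L]]])) shared / length(sets[[p[2L]]]) else NA_real_)
  }))
  list(regions = regions[], pairwise = pairwise[])
}
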