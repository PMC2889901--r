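# Two-color splice analysis: filtering/normalization, spot calibration,
# self-to-self variance calibration, expression-vs-splicing hypothesis
# testing, form-change ranking, replicate analysis and positional-bias QC.

#' Preprocess raw two-channel intensities
#'
#' Three stages. (1) Detection: the per-array, per-channel signal cutoff is
#' the mean + `k` SD of the negative-control spots; a spot is `detected` when
#' both channels exceed their cutoffs. (2) Spot calibration: within each
#' replicated control-probe family, spots whose log-ratio deviates from the
#' family median by more than 3 MAD are flagged and excluded downstream (the
#' MAD of the within-family deviations is pooled across families, which
#' keeps the false-flag rate at the nominal Gaussian level).
#' (3) Normalization: the per-array log2(Cy5/Cy3) ratios are median-centered
#' over detected gene probes (optionally with intensity-dependent
#' local-regression centering).
#'
#' @param intensities An `intensity_matrix` (see [simulate_cohort()] /
#'   [read_intensities()]).
#' @param design The matching `array_design`.
#' @param k Threshold multiplier used for the detection cutoff.
#' @param normalize `"median"` (default) or `"loess"` for additional
#'   intensity-dependent centering.
#' @return An object of class `splice_prep`: list with the normalized
#'   log-ratio matrix `ratio` (spots x arrays), `detected` and `spot_flag`
#'   logical matrices, the spot table, array metadata and the detection
#'   cutoffs.
#' @export
preprocess <- function(intensities, design, k = 3, normalize = c("median", "loess")) {
  normalize <- match.arg(normalize)
  spots <- design$spots
  stopifnot(all(rownames(intensities$cy3) == spots$spot_id))
  neg <- spots$kind == "negative"
  if (!any(neg)) {
    .stopf("no_negative_controls",
           "detection cutoff undefined: design has no negative controls")
  }
  cy3 <- intensities$cy3; cy5 <- intensities$cy5
  cut3 <- colMeans(cy3[neg, , drop = FALSE]) +
    k * apply(cy3[neg, , drop = FALSE], 2, stats::sd)
  cut5 <- colMeans(cy5[neg, , drop = FALSE]) +
    k * apply(cy5[neg, , drop = FALSE], 2, stats::sd)
  detected <- sweep(cy3, 2, cut3, ">=") & sweep(cy5, 2, cut5, ">=")
  ratio <- log2(cy5 / cy3)
  # spot calibration within replicated probe families: deviations are taken
  # from the family median, but the MAD that scales the 3-MAD rule is pooled
  # across families (a per-family MAD over ~12 replicates is too noisy and
  # would flag a few percent of clean spots)
  spot_flag <- matrix(FALSE, nrow(ratio), ncol(ratio), dimnames = dimnames(ratio))
  fam <- split(seq_len(nrow(spots)), spots$probe_id)
  fam <- fam[vapply(fam, length, 0L) >= 4L]
  if (length(fam)) {
    fam_idx <- unlist(fam, use.names = FALSE)
    for (a in seq_len(ncol(ratio))) {
      devs <- ratio[, a]
      for (idx in fam) devs[idx] <- devs[idx] - stats::median(devs[idx])
      scale <- stats::mad(devs[fam_idx])
      if (scale > 0) spot_flag[fam_idx[abs(devs[fam_idx]) > 3 * scale], a] <- TRUE
    }
  }
  gene_spot <- spots$kind %in% c("exon", "junction")
  for (a in seq_len(ncol(ratio))) {
    use <- gene_spot & detected[, a] & !spot_flag[, a]
    ratio[, a] <- ratio[, a] - stats::median(ratio[use, a])
    if (normalize == "loess") {
      A <- 0.5 * (log2(cy3[, a]) + log2(cy5[, a]))
      fit <- stats::lowess(A[use], ratio[use, a], f = 0.4)
      ratio[, a] <- ratio[, a] - stats::approx(fit, xout = A, rule = 2)$y
    }
  }
  structure(list(ratio = ratio, detected = detected, spot_flag = spot_flag,
                 spots = spots, arrays = intensities$arrays,
                 cutoffs = data.frame(array_id = intensities$arrays$array_id,
                                      cy3 = cut3, cy5 = cut5)),
            class = "splice_prep")
}

#' Estimate experimental variability from self-to-self arrays
#'
#' On each self-to-self array the spread of the gene-probe log-ratios
#' (`sigma_g`) and of the control-probe log-ratios (`sigma_c`) is measured;
#' the calibration factor `CF` is the mean of their ratio. Spread is
#' estimated with the Gaussian-consistent robust scale (1.4826 MAD): spot
#' calibration removes the extreme tail of the replicated control families,
#' which would bias a plain sample SD downward. For every array
#' the no-change SD is then estimated from its own control spread as
#' `sigma_star = CF * sigma_c`, with robust-change threshold
#' `TH = +/- k * sigma_star`. Gene-probe spread runs slightly above
#' control-probe spread, so `CF` is typically a little above 1.
#'
#' @param prep A [preprocess()] result containing at least one self-to-self
#'   array.
#' @param k Threshold multiplier.
#' @return Object of class `variability`: list with `per_array` (data frame
#'   of `array_id`, `sigma_c`, `sigma_g`, `sigma_star`, `th`), `CF` and `k`.
#' @export
estimate_variability <- function(prep, k = 3) {
  arrays <- prep$arrays
  if (!any(arrays$is_self_self)) {
    .stopf("no_self_self_arrays", "calibration impossible: no self-to-self arrays")
  }
  gene_spot <- prep$spots$kind %in% c("exon", "junction")
  ctl_spot <- prep$spots$kind %in%
    c("control_full", "control_half_5", "control_half_3")
  sigma_c <- sigma_g <- rep(NA_real_, nrow(arrays))
  for (a in seq_len(nrow(arrays))) {
    use_c <- ctl_spot & prep$detected[, a] & !prep$spot_flag[, a]
    sigma_c[a] <- stats::mad(prep$ratio[use_c, a])
    use_g <- gene_spot & prep$detected[, a] & !prep$spot_flag[, a]
    sigma_g[a] <- stats::mad(prep$ratio[use_g, a])
  }
  if (any(!is.finite(sigma_c)) || any(sigma_c == 0)) {
    .stopf("degenerate_sigma_c",
           "control-probe log-ratio SD is zero or undefined on some array")
  }
  self <- arrays$is_self_self
  CF <- mean(sigma_g[self] / sigma_c[self])
  sigma_star <- CF * sigma_c
  per_array <- data.frame(array_id = arrays$array_id,
                          is_self_self = arrays$is_self_self,
                          sigma_c = sigma_c,
                          sigma_g = ifelse(self, sigma_g, NA_real_),
                          sigma_star = sigma_star, th = k * sigma_star,
                          stringsAsFactors = FALSE)
  structure(list(per_array = per_array, CF = CF, k = k), class = "variability")
}

# exact optimal two-group split of a 1-D sample: minimum total within-group
# sum of squares over every split of the sorted values
.two_group_sse <- function(r) {
  n <- length(r)
  if (n < 2L) return(0)
  x <- sort(r)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  j <- seq_len(n - 1L)
  sse_left <- cs2[j] - cs[j]^2 / j
  sse_right <- (cs2[n] - cs2[j]) - (cs[n] - cs[j])^2 / (n - j)
  min(sse_left + sse_right)
}

#' Classify one gene: expression change versus splice-form change
#'
#' Given the detected probe log-ratios of a gene and the calibrated
#' no-change SD, computes the gene mean `mu_G`, per-probe deviations, the
#' error of the single-shift (whole-gene expression) hypothesis
#' `E_expr = sum((r_p - mu_G)^2)` and of the isoform-mixture hypothesis
#' `E_iso` (exact optimal two-group split of the sorted ratios), and the
#' form change `sum(max(0, |r_p - mu_G| - k sigma*)) / sigma*`. A gene is a
#' splice candidate when at least one probe falls outside
#' `mu_G +/- k sigma*` and the mixture hypothesis explains the profile
#' substantially better (`E_iso <= alpha E_expr`); otherwise it is an
#' expression change when `|mu_G - center|` exceeds the threshold, else no
#' change.
#'
#' @param ratios Numeric vector of the gene's detected probe log-ratios.
#' @param sigma_star Calibrated no-change SD for the array.
#' @param k Threshold multiplier.
#' @param alpha Margin by which the mixture hypothesis must beat the
#'   expression hypothesis.
#' @param min_probes Minimum detected probes for a gene to be analyzable.
#' @param center Fold-change reference for the expression call (0 for single
#'   pairs; the array-wide mean in replicate analysis).
#' @return List with `mu`, `n_probes`, `n_outside`, `e_expr`, `e_iso`,
#'   `classification` and `form_change`.
#' @export
analyze_gene <- function(ratios, sigma_star, k = 3, alpha = 0.5,
                         min_probes = 4L, center = 0) {
  if (is.null(sigma_star) || is.na(sigma_star) || sigma_star <= 0) {
    .stopf("missing_sigma_star", "sigma_star must be a positive number")
  }
  ratios <- ratios[is.finite(ratios)]
  n <- length(ratios)
  if (n < min_probes) {
    return(list(mu = NA_real_, n_probes = n, n_outside = NA_integer_,
                e_expr = NA_real_, e_iso = NA_real_,
                classification = "not_detected", form_change = NA_real_))
  }
  mu <- mean(ratios)
  dev <- ratios - mu
  th <- k * sigma_star
  n_outside <- sum(abs(dev) > th)
  e_expr <- sum(dev^2)
  e_iso <- .two_group_sse(ratios)
  form_change <- sum(pmax(0, abs(dev) - th)) / sigma_star
  classification <- if (n_outside >= 1L && e_iso <= alpha * e_expr) {
    "splice_candidate"
  } else if (abs(mu - center) > th) {
    "expression_change"
  } else "no_change"
  list(mu = mu, n_probes = n, n_outside = n_outside,
       e_expr = e_expr, e_iso = e_iso,
       classification = classification, form_change = form_change)
}

# gene-level analysis of one array (or of a precomputed ratio profile)
.analyze_profile <- function(ratio_vec, keep, spots, sigma_star, k, alpha,
                             min_probes, center = 0) {
  gene_spot <- spots$kind %in% c("exon", "junction") & keep
  genes <- unique(spots$gene_id[spots$kind %in% c("exon", "junction")])
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    idx <- which(gene_spot & spots$gene_id == genes[i])
    res <- analyze_gene(ratio_vec[idx], sigma_star, k = k, alpha = alpha,
                        min_probes = min_probes, center = center)
    rows[[i]] <- data.frame(gene_id = genes[i], n_probes = res$n_probes,
                            mu = res$mu, n_outside = res$n_outside,
                            e_expr = res$e_expr, e_iso = res$e_iso,
                            classification = res$classification,
                            form_change = res$form_change,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Analyze every gene of one tumor/normal pair
#'
#' @param prep A [preprocess()] result.
#' @param varest An [estimate_variability()] result.
#' @param array_id Array to analyze.
#' @inheritParams analyze_gene
#' @return `data.frame` with one row per gene (see [analyze_gene()]).
#' @export
analyze_pair <- function(prep, varest, array_id, alpha = 0.5, min_probes = 4L) {
  a <- match(array_id, prep$arrays$array_id)
  if (is.na(a)) .stopf("unknown_array", "array %s not found", array_id)
  sstar <- varest$per_array$sigma_star[match(array_id, varest$per_array$array_id)]
  keep <- prep$detected[, a] & !prep$spot_flag[, a]
  .analyze_profile(prep$ratio[, a], keep, prep$spots, sstar,
                   k = varest$k, alpha = alpha, min_probes = min_probes)
}

#' Biological-replicate analysis and form-change ranking
#'
#' Averages each probe's log-ratio across all tumor/normal pairs with no
#' sample exclusion (a probe enters the mean profile only if detected in
#' every pair, so that prevalence is not distorted), re-runs the gene
#' analysis on the mean profile with a pooled `sigma_star` (mean over pair
#' arrays) and the fold-change reference set to the array-wide mean ratio,
#' and ranks splice candidates by form change with per-gene prevalence
#' (fraction of pairs in which the gene was individually called a splice
#' candidate) attached.
#'
#' @inheritParams analyze_pair
#' @return Object of class `candidate_table`: list with `candidates` (ranked
#'   data frame), `gene_results` (all genes, mean profile), `per_pair`
#'   (per-array gene results), `sigma_star_pooled` and `center`.
#' @export
replicate_analysis <- function(prep, varest, alpha = 0.5, min_probes = 4L) {
  pair_ids <- prep$arrays$array_id[!prep$arrays$is_self_self]
  if (length(pair_ids) < 2L) {
    .stopf("too_few_pairs", "replicate analysis needs >= 2 pairs (got %d)",
           length(pair_ids))
  }
  pa <- match(pair_ids, prep$arrays$array_id)
  keep <- prep$detected[, pa, drop = FALSE] & !prep$spot_flag[, pa, drop = FALSE]
  all_pairs <- rowSums(keep) == length(pa)        # no outlier elimination
  mean_ratio <- rowMeans(prep$ratio[, pa, drop = FALSE])
  sstar <- mean(varest$per_array$sigma_star[match(pair_ids,
                                                  varest$per_array$array_id)])
  gene_spot <- prep$spots$kind %in% c("exon", "junction")
  center <- mean(mean_ratio[gene_spot & all_pairs])
  gene_results <- .analyze_profile(mean_ratio, all_pairs, prep$spots, sstar,
                                   k = varest$k, alpha = alpha,
                                   min_probes = min_probes, center = center)
  per_pair <- lapply(pair_ids, function(id) {
    analyze_pair(prep, varest, id, alpha = alpha, min_probes = min_probes)
  })
  names(per_pair) <- pair_ids
  prevalence <- rowMeans(vapply(per_pair, function(df) {
    df$classification[match(gene_results$gene_id, df$gene_id)] == "splice_candidate"
  }, logical(nrow(gene_results))), na.rm = TRUE)
  direction <- vapply(seq_len(nrow(gene_results)), function(i) {
    if (gene_results$classification[i] != "splice_candidate") return(NA_character_)
    idx <- which(gene_spot & all_pairs &
                   prep$spots$gene_id == gene_results$gene_id[i])
    dev <- mean_ratio[idx] - gene_results$mu[i]
    out <- dev[abs(dev) > varest$k * sstar]
    if (all(out > 0)) "up" else if (all(out < 0)) "down" else "mixed"
  }, "")
  gene_results$prevalence <- prevalence
  gene_results$direction <- direction
  cand <- gene_results[gene_results$classification == "splice_candidate", ,
                       drop = FALSE]
  cand <- cand[order(-cand$form_change), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, gene_results = gene_results,
                 per_pair = per_pair, sigma_star_pooled = sstar,
                 center = center),
            class = "candidate_table")
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("<candidate table: %d splice candidates of %d genes; pooled sigma* = %.4f>\n",
              nrow(x$candidates), nrow(x$gene_results), x$sigma_star_pooled))
  if (nrow(x$candidates)) {
    print(utils::head(x$candidates[, c("gene_id", "form_change", "prevalence",
                                       "direction")], 10))
  }
  invisible(x)
}

#' Positional-bias QC from control probes
#'
#' Regresses the log2 control-probe signal (mean of both channels, averaged
#' over arrays) on probe position, expressed as distance from the transcript
#' 3' end, for each control transcript. 3'-biased labeling produces a
#' negative slope. A transcript is flagged when the slope differs from zero
#' at `p < p_cut`.
#'
#' @param prep A [preprocess()] result (the design must contain
#'   `control_full` probes with recorded positions).
#' @param intensities The matching `intensity_matrix` (raw channel
#'   intensities are used, not ratios).
#' @param p_cut Significance level for the bias flag.
#' @return `data.frame` with one row per control transcript: `control_id`,
#'   `n_positions`, `slope_per_kb` (log2 units), `p_value`, `biased`.
#' @export
assess_positional_bias <- function(prep, intensities, p_cut = 0.01) {
  sp <- prep$spots
  ctl <- which(sp$kind == "control_full" & !is.na(sp$control_pos))
  if (!length(ctl)) .stopf("no_control_probes", "design has no positioned controls")
  y_all <- 0.5 * (log2(intensities$cy3) + log2(intensities$cy5))
  rows <- list()
  for (cid in unique(sp$control_id[ctl])) {
    idx <- ctl[sp$control_id[ctl] == cid]
    # one point per probe: replicate spots share a probe affinity, so
    # treating them as independent would inflate the slope test
    spot_mean <- rowMeans(y_all[idx, , drop = FALSE])
    agg <- tapply(spot_mean, sp$probe_id[idx], mean)
    pos <- sp$control_pos[idx][match(names(agg), sp$probe_id[idx])]
    if (length(unique(pos)) < 5L) {
      .stopf("too_few_positions",
             "control %s has < 5 distinct probe positions", cid)
    }
    ctl_len <- max(pos) + sp$length[idx][which.max(sp$control_pos[idx])]
    dist3_kb <- (ctl_len - pos) / 1000
    y <- as.numeric(agg)
    fit <- stats::lm(y ~ dist3_kb)
    sm <- summary(fit)$coefficients
    rows[[length(rows) + 1L]] <- data.frame(
      control_id = cid, n_positions = length(unique(pos)),
      slope_per_kb = unname(sm["dist3_kb", "Estimate"]),
      p_value = unname(sm["dist3_kb", "Pr(>|t|)"]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$biased <- out$p_value < p_cut
  out
}
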