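# Hybridization simulator: synthetic transcriptomes with known splice events
# and two-channel probe intensities under a mixture/partial-match binding
# model with spike-in controls and multiplicative lognormal noise.

#' Hybridization simulation parameters
#'
#' @param residual_fraction Signal fraction a junction probe retains when
#'   exactly one of its arms matches an isoform (half-matched binding; on the
#'   physical platform half-oligonucleotide signals drop sharply but not to
#'   zero).
#' @param noise_sd_log2 Per-spot, per-channel multiplicative lognormal noise
#'   SD in log2 units. `NULL` means "calibrate so that a self-to-self array
#'   has fold-change SD equal to `target_fc_sd`".
#' @param target_fc_sd Self-to-self log2 fold-change SD the noise is
#'   calibrated to when `noise_sd_log2` is `NULL`; the platform's measured
#'   value is 0.093.
#' @param background_mean,background_sd Additive background intensity drawn
#'   per spot from a truncated normal (shared by both channels).
#' @param positional_bias_rate Per-kb decay of labeling efficiency with
#'   distance from the transcript 3' end (0 = unbiased labeling).
#' @param affinity_sd_log2 Per-probe sequence-affinity spread (log2 SD);
#'   affinities multiply both channels and cancel in ratios.
#' @param gene_noise_mult Multiplier on the noise SD for gene probes relative
#'   to control probes (gene-probe spread runs slightly above control-probe
#'   spread on the physical platform).
#' @param conc_meanlog2,conc_sdlog2 Log2-normal distribution of per-gene
#'   transcript concentration (arbitrary units).
#' @param spike_tiers Concentrations of the three balanced spike-in control
#'   tiers.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(residual_fraction = 0.15,
                       noise_sd_log2 = NULL,
                       target_fc_sd = 0.093,
                       background_mean = 100,
                       background_sd = 10,
                       positional_bias_rate = 0,
                       affinity_sd_log2 = 0.3,
                       gene_noise_mult = 1.1,
                       conc_meanlog2 = 11,
                       conc_sdlog2 = 1,
                       spike_tiers = c(1000, 8000, 64000)) {
  stopifnot(residual_fraction >= 0, residual_fraction < 1,
            background_mean >= 0, background_sd >= 0,
            positional_bias_rate >= 0)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate random gene models
#'
#' Each gene gets a random exon chain (gene-level GC content drawn uniformly
#' from `gc_range`) and two isoforms: the full inclusion isoform and a
#' skip isoform missing one random internal exon.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param n_exons_range,exon_len_range,gc_range Ranges for exon count, exon
#'   length (bp) and gene GC fraction.
#' @return List of [gene_model()] objects.
#' @export
simulate_gene_models <- function(n_genes, seed = 1L,
                                 n_exons_range = c(4L, 12L),
                                 exon_len_range = c(30L, 300L),
                                 gc_range = c(0.2, 0.8)) {
  withr::with_seed(seed, {
    rows <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("G%04d", g)
      gc <- stats::runif(1, gc_range[1], gc_range[2])
      nex <- sample(seq.int(n_exons_range[1], n_exons_range[2]), 1L)
      lens <- sample(seq.int(exon_len_range[1], exon_len_range[2]), nex,
                     replace = TRUE)
      exons <- vapply(lens, .random_dna, "", gc = gc)
      skip <- sample(seq.int(2L, nex - 1L), 1L)
      tx1 <- sprintf("%s.1", gid); tx2 <- sprintf("%s.2", gid)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tx1, exon_index = seq_len(nex),
        sequence = exons, stringsAsFactors = FALSE)
      keep <- setdiff(seq_len(nex), skip)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tx2, exon_index = seq_along(keep),
        sequence = exons[keep], stringsAsFactors = FALSE)
    }
    .models_from_fragments(do.call(rbind, rows))
  })
}

#' Simulate spike-in control transcripts
#'
#' Three single-isoform control transcripts at the kilobase lengths of the
#' platform's yeast controls (7.1, 4.9 and 4.6 kb).
#'
#' @param seed Integer seed.
#' @param lengths Transcript lengths in bp.
#' @return List of [isoform()] objects.
#' @export
simulate_control_isoforms <- function(seed = 1L,
                                      lengths = c(7100L, 4900L, 4600L)) {
  withr::with_seed(seed, {
    lapply(seq_along(lengths), function(i) {
      tx <- sprintf("CTL%d", i)
      sq <- .random_dna(lengths[i], gc = 0.4)
      isoform(tx, tx,
              data.frame(chrom = tx, start = 0L, end = lengths[i],
                         strand = "+", stringsAsFactors = FALSE),
              sq)
    })
  })
}

## ----------------------------------------------------------- match model --

# Match weight of one probe against one isoform sequence:
#   1                  full-length perfect match
#   residual_fraction  exactly one junction arm (or half-oligo half) matches
#   0                  otherwise
# Also returns the 1-based position of the matched block for positional bias.
.match_weight <- function(probe, iso_seq, residual_fraction) {
  pos <- regexpr(probe$sequence, iso_seq, fixed = TRUE)
  if (pos > 0L) return(c(w = 1, pos = pos, len = nchar(probe$sequence)))
  al <- probe$arm_left; ar <- probe$arm_right
  if (is.na(al) && is.na(ar)) return(c(w = 0, pos = NA, len = NA))
  al <- if (is.na(al)) 0L else al
  ar <- if (is.na(ar)) 0L else ar
  n <- nchar(probe$sequence)
  lpos <- if (al > 0L) regexpr(substr(probe$sequence, 1L, al), iso_seq,
                               fixed = TRUE) else -1L
  rpos <- if (ar > 0L) regexpr(substr(probe$sequence, n - ar + 1L, n), iso_seq,
                               fixed = TRUE) else -1L
  if (xor(lpos > 0L, rpos > 0L)) {
    if (lpos > 0L) c(w = residual_fraction, pos = lpos, len = al)
    else c(w = residual_fraction, pos = rpos, len = ar)
  } else {
    c(w = 0, pos = NA, len = NA)
  }
}

# sparse weight matrix: design spots x isoforms; entries already include the
# positional-bias attenuation for the matched block
.weight_matrix <- function(design, isoforms, params) {
  iso_ids <- vapply(isoforms, function(x) x$transcript_id, "")
  iso_gene <- vapply(isoforms, function(x) x$gene_id, "")
  iso_len <- vapply(isoforms, function(x) nchar(x$sequence), 0L)
  probes <- design$probes
  trip_i <- integer(); trip_j <- integer(); trip_x <- numeric()
  for (p in seq_len(nrow(probes))) {
    pr <- probes[p, ]
    own <- if (pr$kind %in% c("control_full", "control_half_5", "control_half_3")) {
      which(iso_ids == pr$control_id)
    } else if (!is.na(pr$gene_id)) {
      which(iso_gene == pr$gene_id)
    } else integer()
    for (j in own) {
      mw <- .match_weight(pr, isoforms[[j]]$sequence, params$residual_fraction)
      if (mw["w"] > 0) {
        w <- mw["w"]
        if (params$positional_bias_rate > 0) {
          dist3_kb <- (iso_len[j] - (mw["pos"] + mw["len"] - 1)) / 1000
          w <- w * exp(-params$positional_bias_rate * dist3_kb)
        }
        trip_i <- c(trip_i, p); trip_j <- c(trip_j, j); trip_x <- c(trip_x, w)
      }
    }
  }
  W <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nrow(probes), length(isoforms)),
                            dimnames = list(probes$probe_id, iso_ids))
  # expand probe rows to spot rows
  W[match(design$spots$probe_id, probes$probe_id), , drop = FALSE]
}

#' Simulated signal of a single probe against an isoform mixture
#'
#' Expected signal is the concentration-weighted sum over isoforms of the
#' probe's match weight (1 for a full match, `residual_fraction` when exactly
#' one junction arm matches, 0 otherwise), optionally attenuated by 3'
#' positional bias, plus additive background; multiplicative lognormal noise
#' is applied per call. Uses the current RNG state.
#'
#' @param probe One-row probe `data.frame` (as in an `array_design`).
#' @param isoforms List of [isoform()] objects of the probe's gene.
#' @param conc Named numeric vector of isoform concentrations (one entry per
#'   isoform, matched by `transcript_id`).
#' @param params A [sim_params()] record (`noise_sd_log2` must be set).
#' @return Named vector with elements `cy3` and `cy5` (both channels see the
#'   same concentrations; supply different `conc` per channel for test
#'   arrays).
#' @export
probe_signal <- function(probe, isoforms, conc, params = sim_params(noise_sd_log2 = 0)) {
  s <- params$noise_sd_log2 %||% 0
  expected <- 0
  for (iso in isoforms) {
    ci <- if (iso$transcript_id %in% names(conc)) conc[[iso$transcript_id]] else 0
    if (ci <= 0) next
    mw <- .match_weight(probe, iso$sequence, params$residual_fraction)
    w <- mw[["w"]]
    if (w > 0 && params$positional_bias_rate > 0) {
      dist3_kb <- (nchar(iso$sequence) - (mw[["pos"]] + mw[["len"]] - 1)) / 1000
      w <- w * exp(-params$positional_bias_rate * dist3_kb)
    }
    expected <- expected + ci * w
  }
  bg <- max(0, stats::rnorm(1, params$background_mean, params$background_sd))
  c(cy3 = (expected + bg) * 2^stats::rnorm(1, 0, s),
    cy5 = (expected + bg) * 2^stats::rnorm(1, 0, s))
}

#' Expected spike-in control behavior of a design
#'
#' Assigns the three control transcripts to the three concentration tiers
#' (channel-balanced) and returns the per-spot expected intensities of all
#' control and negative spots, before noise.
#'
#' @param design An `array_design` containing control probes.
#' @param params A [sim_params()] record.
#' @param controls List of control [isoform()] objects.
#' @return `data.frame` with `spot_id`, `kind`, `control_id`, `tier`,
#'   `expected_cy3`, `expected_cy5`.
#' @export
spike_in_controls <- function(design, params, controls) {
  ctl_ids <- vapply(controls, function(x) x$transcript_id, "")
  tiers <- params$spike_tiers[((seq_along(ctl_ids) - 1L) %% 3L) + 1L]
  names(tiers) <- ctl_ids
  sp <- design$spots[design$spots$kind %in%
                       c("control_full", "control_half_5", "control_half_3",
                         "negative"), , drop = FALSE]
  W <- .weight_matrix(design, controls, params)
  conc <- tiers[colnames(W)]
  conc[is.na(conc)] <- 0
  expected <- as.numeric(W %*% conc)[match(sp$spot_id, design$spots$spot_id)] +
    params$background_mean
  data.frame(spot_id = sp$spot_id, kind = sp$kind, control_id = sp$control_id,
             tier = ifelse(is.na(sp$control_id), NA, tiers[sp$control_id]),
             expected_cy3 = expected, expected_cy5 = expected,
             stringsAsFactors = FALSE)
}

#' Calibrate the simulation noise to a target self-to-self fold-change SD
#'
#' Finds, by monotone 1-D root search, the per-channel log2 noise SD for
#' which the SD of the log2 fold change across a simulated self-to-self
#' array's probes equals the requested value (default 0.093, the platform's
#' measured self-to-self fold-change SD).
#'
#' @param target_fc_sd Requested self-to-self log2 fold-change SD.
#' @param params A [sim_params()] record (all other parameters held fixed).
#' @param n_probes Probes simulated per evaluation.
#' @param seed Seed for the common random numbers used by the search.
#' @return The calibrated `noise_sd_log2` value.
#' @export
calibrate_noise <- function(target_fc_sd = 0.093, params = sim_params(),
                            n_probes = 10000L, seed = 1L) {
  if (target_fc_sd < 0) .stopf("noise_target_unreachable", "negative target SD")
  if (target_fc_sd == 0) return(0)
  draws <- withr::with_seed(seed, list(
    conc = 2^stats::rnorm(n_probes, params$conc_meanlog2, params$conc_sdlog2),
    aff = 2^stats::rnorm(n_probes, 0, params$affinity_sd_log2),
    z3 = stats::rnorm(n_probes), z5 = stats::rnorm(n_probes),
    bg = pmax(0, stats::rnorm(n_probes, params$background_mean,
                              params$background_sd))
  ))
  fc_sd <- function(s) {
    base <- draws$conc * draws$aff + draws$bg
    m <- params$gene_noise_mult
    stats::sd(log2((base * 2^(m * s * draws$z5)) / (base * 2^(m * s * draws$z3))))
  }
  if (fc_sd(2) < target_fc_sd) {
    .stopf("noise_target_unreachable", "target SD %.3f not reachable", target_fc_sd)
  }
  stats::uniroot(function(s) fc_sd(s) - target_fc_sd, c(1e-9, 2),
                 tol = 1e-7)$root
}

## ---------------------------------------------------------------- cohort --

#' Simulate a full two-color splice-array cohort
#'
#' Generates seeded random gene models, designs the array, assigns splice
#' and expression events to genes, draws per-pair concentrations and emits
#' two-channel intensities for `n_pairs` tumor/normal-style arrays plus
#' `n_self` self-to-self arrays. Fully reproducible by seed.
#'
#' Events: `exon_skip_switch` moves `switch_fraction` of the gene's
#' concentration from the inclusion isoform to the skip isoform in the Cy5
#' channel; `expression_change` multiplies the Cy5 concentration of all
#' isoforms by `expression_fold`.
#'
#' @param n_genes,n_splice_genes,n_expression_genes Gene counts.
#' @param n_pairs Number of paired (tumor vs normal) arrays.
#' @param n_self Number of self-to-self arrays.
#' @param params A [sim_params()] record; a `NULL` `noise_sd_log2` is
#'   calibrated to `params$target_fc_sd` first.
#' @param switch_fraction Fraction of concentration switched to the skip
#'   isoform in splice-event genes.
#' @param expression_fold Fold change of expression-event genes.
#' @param config A [design_config()].
#' @param seed Integer seed (required; governs every random draw).
#' @return An object of class `splice_cohort`: list with `models`, `design`,
#'   `intensities` (an intensity matrix object), `truth` (gene_id, event,
#'   effect) and `params`.
#' @export
simulate_cohort <- function(n_genes, n_splice_genes, n_expression_genes,
                            n_pairs, n_self = 3L, params = sim_params(),
                            switch_fraction = 0.5, expression_fold = 2,
                            config = design_config(), seed = 1L) {
  if (n_splice_genes + n_expression_genes > n_genes) {
    .stopf("infeasible_counts", "event genes exceed n_genes")
  }
  if (n_pairs < 1L) .stopf("infeasible_counts", "n_pairs must be >= 1")
  if (is.null(params$noise_sd_log2)) {
    params$noise_sd_log2 <- calibrate_noise(params$target_fc_sd, params,
                                            seed = seed)
  }
  models <- simulate_gene_models(n_genes, seed = seed)
  controls <- simulate_control_isoforms(seed = seed + 1L)
  design <- build_design(models, controls, config, seed = seed + 2L)

  withr::with_seed(seed + 3L, {
    gene_ids <- vapply(models, function(m) m$gene_id, "")
    ev <- sample(gene_ids, n_splice_genes + n_expression_genes)
    truth <- data.frame(gene_id = gene_ids, event = "none", effect = 1,
                        stringsAsFactors = FALSE)
    truth$event[gene_ids %in% ev[seq_len(n_splice_genes)]] <- "exon_skip_switch"
    truth$effect[truth$event == "exon_skip_switch"] <- switch_fraction
    if (n_expression_genes > 0L) {
      truth$event[gene_ids %in% ev[n_splice_genes + seq_len(n_expression_genes)]] <-
        "expression_change"
      truth$effect[truth$event == "expression_change"] <- expression_fold
    }
    conc_gene <- 2^stats::rnorm(n_genes, params$conc_meanlog2, params$conc_sdlog2)

    isoforms <- c(unlist(lapply(models, function(m) m$isoforms),
                         recursive = FALSE), controls)
    iso_ids <- vapply(isoforms, function(x) x$transcript_id, "")
    n_iso <- length(isoforms)
    ctl_ids <- vapply(controls, function(x) x$transcript_id, "")
    tiers <- params$spike_tiers[((seq_along(ctl_ids) - 1L) %% 3L) + 1L]

    # per-channel isoform concentration profiles (normal = A, tumor = B)
    conc_A <- conc_B <- stats::setNames(numeric(n_iso), iso_ids)
    for (g in seq_len(n_genes)) {
      inc <- sprintf("%s.1", gene_ids[g]); skp <- sprintf("%s.2", gene_ids[g])
      conc_A[inc] <- conc_gene[g]
      switch (truth$event[g],
        none = { conc_B[inc] <- conc_gene[g] },
        expression_change = { conc_B[inc] <- conc_gene[g] * expression_fold },
        exon_skip_switch = {
          conc_B[inc] <- conc_gene[g] * (1 - switch_fraction)
          conc_B[skp] <- conc_gene[g] * switch_fraction
        })
    }
    conc_A[ctl_ids] <- conc_B[ctl_ids] <- tiers

    W <- .weight_matrix(design, isoforms, params)
    n_spots <- nrow(design$spots)
    arrays <- data.frame(
      array_id = c(sprintf("P%02d", seq_len(n_pairs)),
                   sprintf("S%02d", seq_len(n_self))),
      is_self_self = c(rep(FALSE, n_pairs), rep(TRUE, n_self)),
      stringsAsFactors = FALSE)
    aff <- 2^stats::rnorm(nrow(design$probes), 0, params$affinity_sd_log2)
    aff <- aff[match(design$spots$probe_id, design$probes$probe_id)]
    is_gene_spot <- design$spots$kind %in% c("exon", "junction")
    noise_sd <- params$noise_sd_log2 *
      ifelse(is_gene_spot, params$gene_noise_mult, 1)
    eA <- as.numeric(W %*% conc_A) * aff
    eB <- as.numeric(W %*% conc_B) * aff
    cy3 <- cy5 <- matrix(0, n_spots, nrow(arrays),
                         dimnames = list(design$spots$spot_id, arrays$array_id))
    for (a in seq_len(nrow(arrays))) {
      bg <- pmax(0, stats::rnorm(n_spots, params$background_mean,
                                 params$background_sd))
      e5 <- if (arrays$is_self_self[a]) eA else eB
      cy3[, a] <- (eA + bg) * 2^stats::rnorm(n_spots, 0, noise_sd)
      cy5[, a] <- (e5 + bg) * 2^stats::rnorm(n_spots, 0, noise_sd)
    }
    intensities <- structure(list(cy3 = cy3, cy5 = cy5, arrays = arrays),
                             class = "intensity_matrix")
    structure(list(models = models, design = design, intensities = intensities,
                   truth = truth, params = params, seed = seed),
              class = "splice_cohort")
  })
}

#' Simulate calibration-only null arrays without probe design
#'
#' Lightweight generator of self-to-self and null test arrays over a stub
#' design (gene probes, replicated control probes, negative probes) with no
#' expression or splicing events. Used for variance-calibration studies
#' where sequence-level probe design is irrelevant.
#'
#' @param n_gene_probes,n_control_probes,n_negative Spot counts (control
#'   spots are grouped into replicate families of 12).
#' @param params A [sim_params()] record with `noise_sd_log2` set.
#' @param n_self,n_test Numbers of self-to-self and (null) test arrays.
#' @param seed Integer seed.
#' @return List with `design` (stub `array_design`) and `intensities`.
#' @export
simulate_null_arrays <- function(n_gene_probes, n_control_probes = 1200L,
                                 n_negative = 200L, params = sim_params(noise_sd_log2 = 0.066),
                                 n_self = 1L, n_test = 0L, seed = 1L) {
  withr::with_seed(seed, {
    n_fam <- max(1L, n_control_probes %/% 12L)
    ctl_pid <- sprintf("CTL_P%04d", rep(seq_len(n_fam), each = 12L))
    spots <- data.frame(
      probe_id = c(sprintf("GP%05d", seq_len(n_gene_probes)), ctl_pid,
                   sprintf("NEG%04d", rep(seq_len(max(1L, n_negative %/% 12L)),
                                          each = 12L))),
      kind = c(rep("exon", n_gene_probes), rep("control_full", length(ctl_pid)),
               rep("negative", 12L * max(1L, n_negative %/% 12L))),
      stringsAsFactors = FALSE)
    spots$gene_id <- ifelse(spots$kind == "exon", spots$probe_id, NA)
    spots$spot_id <- make.unique(spots$probe_id, sep = ".")
    spots$control_id <- NA; spots$control_pos <- NA
    probes <- spots[!duplicated(spots$probe_id), , drop = FALSE]
    design <- structure(list(probes = probes, spots = spots, targets = NULL,
                             failures = NULL, config = design_config()),
                        class = "array_design")
    n_spots <- nrow(spots)
    conc <- numeric(n_spots)
    isg <- spots$kind == "exon"
    conc[isg] <- 2^stats::rnorm(sum(isg), params$conc_meanlog2, params$conc_sdlog2)
    conc[spots$kind == "control_full"] <-
      rep(params$spike_tiers[((seq_len(n_fam) - 1L) %% 3L) + 1L],
          each = 12L)[seq_len(sum(spots$kind == "control_full"))]
    aff <- 2^stats::rnorm(nrow(probes), 0, params$affinity_sd_log2)
    aff <- aff[match(spots$probe_id, probes$probe_id)]
    expected <- conc * aff
    noise_sd <- params$noise_sd_log2 * ifelse(isg, params$gene_noise_mult, 1)
    arrays <- data.frame(
      array_id = c(sprintf("S%02d", seq_len(n_self)),
                   if (n_test > 0L) sprintf("P%02d", seq_len(n_test))),
      is_self_self = c(rep(TRUE, n_self), rep(FALSE, n_test)),
      stringsAsFactors = FALSE)
    cy3 <- cy5 <- matrix(0, n_spots, nrow(arrays),
                         dimnames = list(spots$spot_id, arrays$array_id))
    for (a in seq_len(nrow(arrays))) {
      bg <- pmax(0, stats::rnorm(n_spots, params$background_mean,
                                 params$background_sd))
      cy3[, a] <- (expected + bg) * 2^stats::rnorm(n_spots, 0, noise_sd)
      cy5[, a] <- (expected + bg) * 2^stats::rnorm(n_spots, 0, noise_sd)
    }
    list(design = design,
         intensities = structure(list(cy3 = cy3, cy5 = cy5, arrays = arrays),
                                 class = "intensity_matrix"))
  })
}

#' @export
print.splice_cohort <- function(x, ...) {
  cat(sprintf("<splice cohort: %d genes (%d splice, %d expression events), %d arrays, seed %d>\n",
              length(x$models),
              sum(x$truth$event == "exon_skip_switch"),
              sum(x$truth$event == "expression_change"),
              nrow(x$intensities$arrays), x$seed))
  invisible(x)
}

## -------------------------------------------------------------- file I/O --

#' Write / read two-channel intensity tables
#'
#' Long-format TSV (`spot_id`, `array_id`, `cy3`, `cy5`) plus a samples TSV
#' (`array_id`, `is_self_self`) marking the self-to-self arrays.
#'
#' @param x An `intensity_matrix` object.
#' @param path Intensity TSV path (samples TSV written next to it as
#'   `<path>.samples.tsv`).
#' @return `path`, invisibly.
#' @export
write_intensities <- function(x, path) {
  long <- data.frame(
    spot_id = rep(rownames(x$cy3), ncol(x$cy3)),
    array_id = rep(colnames(x$cy3), each = nrow(x$cy3)),
    cy3 = as.numeric(x$cy3), cy5 = as.numeric(x$cy5),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$arrays, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  arrays <- utils::read.delim(paste0(path, ".samples.tsv"),
                              stringsAsFactors = FALSE)
  spot_ids <- unique(long$spot_id)
  cy3 <- matrix(NA_real_, length(spot_ids), nrow(arrays),
                dimnames = list(spot_ids, arrays$array_id))
  cy5 <- cy3
  idx <- cbind(match(long$spot_id, spot_ids), match(long$array_id, arrays$array_id))
  cy3[idx] <- long$cy3
  cy5[idx] <- long$cy5
  structure(list(cy3 = cy3, cy5 = cy5, arrays = arrays),
            class = "intensity_matrix")
}
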