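# Probe design: target extraction from gene models, exon/junction probe
# selection under nearest-neighbor Tm constraints with suboptimal tagging,
# and control/half-oligo/negative probe generation.

#' Probe design configuration
#'
#' All thresholds of the designer in one record. The defaults are the
#' published design constraints of the platform: 36-bp exon targets, 25 bp on
#' each side of a junction (50 bp total), exon probes of 30--36 bp, junction
#' probes of 25--42 bp, a 75 °C Tm target with a 70--80 °C acceptance window,
#' and a 60 °C cross-hybridization limit.
#'
#' @param exon_target_len Exon target length in bp.
#' @param junction_flank Bases contributed by each side of a junction target.
#' @param exon_probe_len Length range (bp) for exon probes.
#' @param junction_probe_len Total length range (bp) for junction probes.
#' @param tm_target,tm_range Target duplex Tm and acceptance window, °C.
#' @param cross_tm_max Cross-hybridization Tm limit, °C.
#' @param fold_tm_max Secondary-structure folding Tm limit, °C.
#' @param min_arm Minimum junction arm length, bp; below ~10 bp an arm adds
#'   no junction specificity.
#' @param balance_tol Tolerance band (°C) around the best arm-Tm balance
#'   within which total-Tm optimization is allowed to choose.
#' @param cross_seed_len Seed length of the cross-hybridization search.
#' @param n_control_positions Full-length control probes per control
#'   transcript.
#' @param n_negative_probes Number of distinct negative (shuffled) probes.
#' @param negative_cross_max Cross-Tm ceiling (°C) a negative probe must
#'   satisfy against every target.
#' @param n_replicates Spots per control/negative probe in the manifest
#'   (replicated to measure intra-array variability).
#' @param conditions A [hyb_conditions()] record.
#' @return A list of class `design_config`.
#' @export
design_config <- function(exon_target_len = 36L,
                          junction_flank = 25L,
                          exon_probe_len = c(30L, 36L),
                          junction_probe_len = c(25L, 42L),
                          tm_target = 75,
                          tm_range = c(70, 80),
                          cross_tm_max = 60,
                          fold_tm_max = 60,
                          min_arm = 10L,
                          balance_tol = 1.0,
                          cross_seed_len = 10L,
                          n_control_positions = 12L,
                          n_negative_probes = 10L,
                          negative_cross_max = 40,
                          n_replicates = 12L,
                          conditions = hyb_conditions()) {
  structure(as.list(environment()), class = "design_config")
}

## ---------------------------------------------------------------- targets --

#' Extract exon target sequences from a gene model
#'
#' One target per (isoform, exon), deduplicated by sequence within the gene.
#' Exons of at least the target length yield a window of that length centered
#' on the exon midpoint; shorter exons are padded from flanking exons with an
#' even split (odd remainder to the 5' side), terminal exons padding only
#' inward. A transcript shorter than the target length yields a single
#' whole-transcript target marked `short_target`.
#'
#' @param gene A [gene_model()].
#' @param config A [design_config()].
#' @return `data.frame` with one row per target: `target_id`, `gene_id`,
#'   `transcript_id`, `kind`, `index`, `sequence`, `left_flank_len`,
#'   `right_flank_len`, `short_target`.
#' @export
extract_exon_targets <- function(gene, config = design_config()) {
  tl <- config$exon_target_len
  rows <- list()
  for (iso in gene$isoforms) {
    lay <- .spliced_layout(iso)
    if (lay$total < tl) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id, transcript_id = iso$transcript_id,
        kind = "exon", index = 1L, sequence = iso$sequence,
        left_flank_len = NA_integer_, right_flank_len = NA_integer_,
        short_target = TRUE, stringsAsFactors = FALSE)
      next
    }
    for (i in seq_along(lay$len)) {
      s <- lay$start[i]; L <- lay$len[i]
      if (L >= tl) {
        ws <- s + floor((L - tl) / 2)
      } else {
        pad <- tl - L
        pl <- ceiling(pad / 2)                 # odd remainder goes 5'
        pr <- pad - pl
        avail_l <- s
        avail_r <- lay$total - (s + L)
        if (pl > avail_l) { pr <- pr + (pl - avail_l); pl <- avail_l }
        if (pr > avail_r) { pl <- min(avail_l, pl + (pr - avail_r)); pr <- avail_r }
        ws <- s - pl
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id, transcript_id = iso$transcript_id,
        kind = "exon", index = i,
        sequence = substr(iso$sequence, ws + 1L, ws + tl),
        left_flank_len = NA_integer_, right_flank_len = NA_integer_,
        short_target = FALSE, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df$sequence), , drop = FALSE]
  df$target_id <- sprintf("%s:E%02d", df$gene_id, seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("target_id", "gene_id", "transcript_id", "kind", "index", "sequence",
         "left_flank_len", "right_flank_len", "short_target")]
}

#' Extract junction target sequences from a gene model
#'
#' One target per (isoform, exon-exon junction), deduplicated by sequence
#' within the gene. Each side contributes up to `junction_flank` bases of
#' spliced sequence, recruited across multiple small exons where necessary
#' and truncated (recorded in the flank lengths) at transcript ends.
#'
#' @inheritParams extract_exon_targets
#' @return `data.frame` in the same layout as [extract_exon_targets()], with
#'   `left_flank_len`/`right_flank_len` filled in.
#' @export
extract_junction_targets <- function(gene, config = design_config()) {
  fl <- config$junction_flank
  rows <- list()
  for (iso in gene$isoforms) {
    lay <- .spliced_layout(iso)
    if (length(lay$len) < 2L) next
    for (j in seq_len(length(lay$len) - 1L)) {
      p <- lay$start[j] + lay$len[j]          # junction position (bases before)
      lf <- min(fl, p)
      rf <- min(fl, lay$total - p)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id, transcript_id = iso$transcript_id,
        kind = "junction", index = j,
        sequence = substr(iso$sequence, p - lf + 1L, p + rf),
        left_flank_len = lf, right_flank_len = rf,
        short_target = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(target_id = character(), gene_id = character(),
                      transcript_id = character(), kind = character(),
                      index = integer(), sequence = character(),
                      left_flank_len = integer(), right_flank_len = integer(),
                      short_target = logical()))
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df$sequence), , drop = FALSE]
  df$target_id <- sprintf("%s:J%02d", df$gene_id, seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("target_id", "gene_id", "transcript_id", "kind", "index", "sequence",
         "left_flank_len", "right_flank_len", "short_target")]
}

## --------------------------------------------------- cross-hyb bookkeeping --

# Find, for every target, the maximal exact matches (>= seed length) it shares
# with targets of OTHER genes. Only duplicated k-mers across the whole design
# are examined, which keeps the screen near-linear on random sequence.
# Returns a list (per target index) of matrices with columns qs, qe.
.cross_regions <- function(sequences, gene_ids, k = 10L) {
  n <- length(sequences)
  regions <- vector("list", n)
  lens <- nchar(sequences)
  km <- lapply(seq_len(n), function(i) {
    if (lens[i] < k) return(NULL)
    s <- seq_len(lens[i] - k + 1L)
    data.frame(kmer = substring(sequences[i], s, s + k - 1L),
               idx = i, pos = s, stringsAsFactors = FALSE)
  })
  km <- do.call(rbind, km)
  if (is.null(km) || !nrow(km)) return(regions)
  dup <- unique(km$kmer[duplicated(km$kmer)])
  km <- km[km$kmer %in% dup, , drop = FALSE]
  if (!nrow(km)) return(regions)
  chars <- strsplit(sequences, "", fixed = TRUE)
  add <- function(i, qs, qe) {
    regions[[i]] <<- rbind(regions[[i]], c(qs, qe))
  }
  for (grp in split(seq_len(nrow(km)), km$kmer)) {
    if (length(grp) < 2L) next
    for (a in seq_len(length(grp) - 1L)) {
      for (b in seq.int(a + 1L, length(grp))) {
        ia <- km$idx[grp[a]]; ib <- km$idx[grp[b]]
        if (gene_ids[ia] == gene_ids[ib]) next
        pa <- km$pos[grp[a]]; pb <- km$pos[grp[b]]
        # left-maximal anchors only, so each match region is found once
        if (pa > 1L && pb > 1L && chars[[ia]][pa - 1L] == chars[[ib]][pb - 1L]) next
        len <- k
        while (pa + len <= lens[ia] && pb + len <= lens[ib] &&
               chars[[ia]][pa + len] == chars[[ib]][pb + len]) {
          len <- len + 1L
        }
        add(ia, pa, pa + len - 1L)
        add(ib, pb, pb + len - 1L)
      }
    }
  }
  lapply(regions, function(r) if (is.null(r)) r else unique(r))
}

# cross Tm of window [i, j] of a target given its precomputed NN sums and its
# match regions; 0 when no region overlaps the window by >= 10 bp
.window_cross_tm <- function(pre, regions, i, j) {
  if (is.null(regions) || !nrow(regions)) return(0)
  best <- 0
  for (r in seq_len(nrow(regions))) {
    qs <- max(regions[r, 1L], i)
    qe <- min(regions[r, 2L], j)
    if (qe - qs + 1L >= 10L) {
      tm <- .best_subwindow_tm(pre, qs, qe)
      if (tm > best) best <- tm
    }
  }
  min(best, .window_tm(pre, i, j))
}

## ------------------------------------------------------------ probe picks --

.probe_flags <- function(tm, cross, fold, config, short_target = FALSE) {
  f <- character()
  if (is.na(tm) || tm < config$tm_range[1] || tm > config$tm_range[2]) f <- c(f, "tm_out_of_range")
  if (cross > config$cross_tm_max) f <- c(f, "cross_hyb_high")
  if (fold > config$fold_tm_max) f <- c(f, "fold_high")
  if (short_target) f <- c(f, "short_target")
  .join_flags(f)
}

# core exon-window selection given precomputed sums and cross regions
.design_exon_core <- function(target_seq, pre, regions, config) {
  L <- nchar(target_seq)
  lmin <- config$exon_probe_len[1]; lmax <- config$exon_probe_len[2]
  cond <- config$conditions
  if (L < lmin) {
    tm <- if (L >= 10L) .window_tm(pre, 1L, L) else NA_real_
    cross <- if (L >= 10L) .window_cross_tm(pre, regions, 1L, L) else 0
    fold <- if (L >= 10L) compute_fold_tm(target_seq, cond) else 0
    return(list(i = 1L, j = L, tm = tm, cross = cross, fold = fold,
                flags = .probe_flags(tm %||% NA, cross, fold, config,
                                     short_target = TRUE)))
  }
  wins <- expand.grid(i = seq_len(L - lmin + 1L), len = lmin:lmax)
  wins$j <- wins$i + wins$len - 1L
  wins <- wins[wins$j <= L, , drop = FALSE]
  wins$tm <- .window_tm(pre, wins$i, wins$j)
  wins$cross <- vapply(seq_len(nrow(wins)), function(r) {
    .window_cross_tm(pre, regions, wins$i[r], wins$j[r])
  }, 0)
  qual <- wins$tm >= config$tm_range[1] & wins$tm <= config$tm_range[2] &
    wins$cross <= config$cross_tm_max
  fold_of <- function(r) {
    compute_fold_tm(substr(target_seq, wins$i[r], wins$j[r]), cond)
  }
  if (any(qual)) {
    d <- abs(wins$tm - config$tm_target)
    m <- min(d[qual])
    tie <- which(qual & d <= m + 1e-6)
    if (length(tie) > 1L) {
      folds <- vapply(tie, fold_of, 0)
      tie <- tie[order(round(folds, 6), wins$len[tie], wins$i[tie])]
    }
    pick <- tie[1L]
    fold <- fold_of(pick)
  } else {
    folds <- vapply(seq_len(nrow(wins)), fold_of, 0)
    # scores are rounded to 1e-6 degC so that windows with identical
    # nearest-neighbor content tie exactly and fall through to the
    # deterministic (length, position) tie-break
    ord <- order(round(wins$cross, 6), round(folds, 6),
                 round(abs(wins$tm - config$tm_target), 6),
                 wins$len, wins$i)
    pick <- ord[1L]
    fold <- folds[pick]
  }
  list(i = wins$i[pick], j = wins$j[pick], tm = wins$tm[pick],
       cross = wins$cross[pick], fold = fold,
       flags = .probe_flags(wins$tm[pick], wins$cross[pick], fold, config))
}

#' Design an exon probe for a target sequence
#'
#' Enumerates every window of the allowed length range within the target.
#' Among windows whose duplex Tm lies in the acceptance range and whose
#' cross-hybridization Tm is below the limit, the window with Tm nearest the
#' target temperature wins (ties: smaller fold Tm, then shorter, then
#' leftmost). When no window qualifies, the best possible oligonucleotide is
#' still returned -- the window minimizing (cross Tm, fold Tm, |Tm - target|)
#' lexicographically -- with the violated constraints recorded in `flags`.
#'
#' @param target One row of [extract_exon_targets()] output (or an
#'   equivalent list with `sequence`, `target_id`, `gene_id`).
#' @param background Character vector of target sequences from other genes
#'   used for the cross-hybridization screen (may be empty).
#' @param config A [design_config()].
#' @return One-row `data.frame` describing the probe (sequence, offset,
#'   length, Tm triple, flags).
#' @export
design_exon_probe <- function(target, background = character(),
                              config = design_config()) {
  seq <- target$sequence
  pre <- .tm_precompute(.encode_dna(seq), config$conditions)
  regions <- NULL
  if (length(background)) {
    mm <- lapply(background, function(bg) {
      .maximal_matches(seq, bg, k = config$cross_seed_len)
    })
    mm <- do.call(rbind, mm)
    if (!is.null(mm) && nrow(mm)) regions <- mm
  }
  sel <- .design_exon_core(seq, pre, regions, config)
  short <- isTRUE(target$short_target) || nchar(seq) < config$exon_probe_len[1]
  data.frame(
    probe_id = paste0(target$target_id, "_p"),
    gene_id = target$gene_id, target_id = target$target_id, kind = "exon",
    sequence = substr(seq, sel$i, sel$j),
    offset_in_target = sel$i - 1L, length = sel$j - sel$i + 1L,
    arm_left = NA_integer_, arm_right = NA_integer_,
    tm = sel$tm, tm_left = NA_real_, tm_right = NA_real_,
    tm_fold = sel$fold, tm_cross = sel$cross,
    flags = if (short && !.has_flag(sel$flags, "short_target")) {
      .join_flags(c(strsplit(sel$flags, ",")[[1]][nzchar(strsplit(sel$flags, ",")[[1]])],
                    "short_target"))
    } else sel$flags,
    stringsAsFactors = FALSE)
}

# core junction arm-pair selection; lf = junction position within the target
.design_junction_core <- function(target_seq, lf, rf, pre, regions, config) {
  amin <- config$min_arm
  tmin <- config$junction_probe_len[1]; tmax <- config$junction_probe_len[2]
  if (lf < amin || rf < amin || lf + rf < tmin) return(NULL)
  cand <- expand.grid(a = amin:lf, b = amin:rf)
  cand <- cand[cand$a + cand$b >= tmin & cand$a + cand$b <= tmax, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand$tm_l <- .window_tm(pre, lf - cand$a + 1L, lf)
  cand$tm_r <- .window_tm(pre, lf + 1L, lf + cand$b)
  cand$d <- abs(cand$tm_l - cand$tm_r)
  dmin <- min(cand$d)
  near <- cand$d <= dmin + config$balance_tol
  cand$tm <- .window_tm(pre, lf - cand$a + 1L, lf + cand$b)
  score <- abs(cand$tm - config$tm_target)
  m <- min(score[near])
  tie <- which(near & score <= m + 1e-6)
  tie <- tie[order(round(cand$d[tie], 6), cand$a[tie] + cand$b[tie],
                   cand$a[tie])]
  pick <- tie[1L]
  i <- lf - cand$a[pick] + 1L; j <- lf + cand$b[pick]
  cross <- .window_cross_tm(pre, regions, i, j)
  fold <- compute_fold_tm(substr(target_seq, i, j), config$conditions)
  list(a = cand$a[pick], b = cand$b[pick], i = i, j = j,
       tm = cand$tm[pick], tm_l = cand$tm_l[pick], tm_r = cand$tm_r[pick],
       cross = cross, fold = fold,
       flags = .probe_flags(cand$tm[pick], cross, fold, config))
}

#' Design a thermodynamically balanced junction probe
#'
#' Enumerates every admissible arm pair anchored at the junction (each arm at
#' least `min_arm` bp and at most its flank length; total length within the
#' allowed range). The primary criterion is the balance of the two arm Tms;
#' among near-balanced candidates (within `balance_tol` of the best balance)
#' the pair whose total Tm is nearest the target temperature is selected.
#' Constraint violations of the chosen probe are recorded in `flags`.
#'
#' @param target One row of [extract_junction_targets()] output.
#' @inheritParams design_exon_probe
#' @return One-row `data.frame` describing the probe, or `NULL` when both
#'   flanks are shorter than `min_arm` (a design failure for that junction).
#' @export
design_junction_probe <- function(target, background = character(),
                                  config = design_config()) {
  seq <- target$sequence
  pre <- .tm_precompute(.encode_dna(seq), config$conditions)
  regions <- NULL
  if (length(background)) {
    mm <- do.call(rbind, lapply(background, function(bg) {
      .maximal_matches(seq, bg, k = config$cross_seed_len)
    }))
    if (!is.null(mm) && nrow(mm)) regions <- mm
  }
  sel <- .design_junction_core(seq, target$left_flank_len,
                               target$right_flank_len, pre, regions, config)
  if (is.null(sel)) return(NULL)
  data.frame(
    probe_id = paste0(target$target_id, "_p"),
    gene_id = target$gene_id, target_id = target$target_id, kind = "junction",
    sequence = substr(seq, sel$i, sel$j),
    offset_in_target = sel$i - 1L, length = sel$j - sel$i + 1L,
    arm_left = sel$a, arm_right = sel$b,
    tm = sel$tm, tm_left = sel$tm_l, tm_right = sel$tm_r,
    tm_fold = sel$fold, tm_cross = sel$cross, flags = sel$flags,
    stringsAsFactors = FALSE)
}

## --------------------------------------------------------------- controls --

# thermodynamically balanced split point of a probe sequence: the internal
# split minimizing the |dTm| of the two halves (each half >= 10 bp)
.balanced_split <- function(seq, conditions) {
  n <- nchar(seq)
  pre <- .tm_precompute(.encode_dna(seq), conditions)
  s <- 10L:(n - 10L)
  d <- abs(.window_tm(pre, 1L, s) - .window_tm(pre, s + 1L, n))
  s[which.min(d)]
}

#' Generate control and half-oligonucleotide probes
#'
#' For each control transcript, `n_positions` full-length optimum probes are
#' designed at evenly spaced positions (to assess labeling bias along the
#' transcript), and each full probe is split into two thermodynamically
#' equivalent halves, complemented with AT stretches back to the parent
#' length (the 5' half is padded at its 3' end and vice versa). Half
#' oligonucleotides emulate a splice event in which one side of a junction is
#' fully joined to foreign sequence.
#'
#' @param control_transcripts List of [isoform()] objects (control
#'   transcripts; kilobase-scale sequences are expected).
#' @param n_positions Number of probe positions per control transcript.
#' @param config A [design_config()].
#' @return `data.frame` of probes (kinds `control_full`, `control_half_5`,
#'   `control_half_3`) with `control_id` and `control_pos` (probe start,
#'   0-based, within the control transcript).
#' @export
make_control_probes <- function(control_transcripts,
                                n_positions = NULL,
                                config = design_config()) {
  n_positions <- n_positions %||% config$n_control_positions
  tl <- config$exon_target_len
  rows <- list()
  for (ctl in control_transcripts) {
    L <- nchar(ctl$sequence)
    npos <- n_positions
    if (L < tl * n_positions) {
      npos <- max(1L, L %/% tl)
      warning(sprintf("control %s is short; using %d positions",
                      ctl$transcript_id, npos), call. = FALSE)
    }
    starts <- unique(round(seq(1L, L - tl + 1L, length.out = npos)))
    for (ix in seq_along(starts)) {
      tgt <- list(target_id = sprintf("%s:C%02d", ctl$transcript_id, ix),
                  gene_id = ctl$gene_id,
                  sequence = substr(ctl$sequence, starts[ix], starts[ix] + tl - 1L),
                  short_target = FALSE)
      full <- design_exon_probe(tgt, character(), config)
      full$kind <- "control_full"
      full$control_id <- ctl$transcript_id
      full$control_pos <- starts[ix] - 1L + full$offset_in_target
      n <- full$length
      s <- .balanced_split(full$sequence, config$conditions)
      h5seq <- paste0(substr(full$sequence, 1L, s), .at_pad(n - s))
      h3seq <- paste0(.at_pad(s), substr(full$sequence, s + 1L, n))
      mk_half <- function(suffix, kind, seqh, al, ar) {
        h <- full
        h$probe_id <- paste0(full$probe_id, suffix)
        h$kind <- kind
        h$sequence <- seqh
        h$arm_left <- al; h$arm_right <- ar
        h$tm <- compute_tm(seqh, config$conditions)
        h$tm_left <- if (al > 0) compute_tm(substr(seqh, 1L, al), config$conditions) else NA_real_
        h$tm_right <- if (ar > 0) compute_tm(substr(seqh, n - ar + 1L, n), config$conditions) else NA_real_
        h$tm_fold <- compute_fold_tm(seqh, config$conditions)
        h$tm_cross <- 0
        h$flags <- ""
        h
      }
      rows[[length(rows) + 1L]] <- full
      rows[[length(rows) + 1L]] <- mk_half("_h5", "control_half_5", h5seq, s, 0L)
      rows[[length(rows) + 1L]] <- mk_half("_h3", "control_half_3", h3seq, 0L, n - s)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

# negative probes: shuffled-composition sequences screened against all targets
.make_negative_probes <- function(target_seqs, config) {
  comp <- table(factor(strsplit(paste(substr(target_seqs, 1, 50), collapse = ""),
                                "")[[1]], levels = c("A", "C", "G", "T")))
  prob <- as.numeric(comp) / sum(comp)
  bg_kmers <- unique(unlist(lapply(target_seqs, function(s) {
    n <- nchar(s); k <- config$cross_seed_len
    if (n < k) return(character())
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  })))
  out <- character(config$n_negative_probes)
  made <- 0L
  tries <- 0L
  while (made < config$n_negative_probes && tries < 200L) {
    tries <- tries + 1L
    cand <- paste(sample(c("A", "C", "G", "T"), config$exon_target_len,
                         replace = TRUE, prob = prob), collapse = "")
    n <- nchar(cand); k <- config$cross_seed_len
    ck <- substring(cand, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    cross <- 0
    if (any(ck %in% bg_kmers)) {
      cross <- compute_cross_tm(cand, target_seqs, config$conditions,
                                seed_len = config$cross_seed_len)
    }
    if (cross <= config$negative_cross_max) {
      made <- made + 1L
      out[made] <- cand
    }
  }
  if (made < config$n_negative_probes) {
    .stopf("negative_design_failed",
           "could not generate %d negative probes", config$n_negative_probes)
  }
  data.frame(
    probe_id = sprintf("NEG%02d", seq_len(made)),
    gene_id = NA_character_, target_id = NA_character_, kind = "negative",
    sequence = out, offset_in_target = 0L,
    length = nchar(out), arm_left = NA_integer_, arm_right = NA_integer_,
    tm = vapply(out, compute_tm, 0, conditions = config$conditions,
                USE.NAMES = FALSE),
    tm_left = NA_real_, tm_right = NA_real_,
    tm_fold = vapply(out, compute_fold_tm, 0, conditions = config$conditions,
                     USE.NAMES = FALSE),
    tm_cross = 0, flags = "", stringsAsFactors = FALSE)
}

## ----------------------------------------------------------- build_design --

#' Build a complete array design from gene models
#'
#' Runs target extraction and probe design for every gene, adds control,
#' half-oligo and negative probes, and assembles the spot-level manifest.
#' Control and negative probes are replicated `n_replicates` times so that
#' intra-array variability can be measured. Deterministic for a given seed.
#'
#' @param genes List of [gene_model()] objects.
#' @param controls Optional list of [isoform()] control transcripts.
#' @param config A [design_config()].
#' @param seed Integer seed governing negative-probe generation.
#' @return An object of class `array_design`: a list with `probes` (unique
#'   probes), `spots` (spot-level manifest rows), `targets`, `failures`
#'   (junctions for which no admissible probe exists) and `config`.
#' @export
build_design <- function(genes, controls = NULL, config = design_config(),
                         seed = 1L) {
  targets <- do.call(rbind, c(
    lapply(genes, extract_exon_targets, config = config),
    lapply(genes, extract_junction_targets, config = config)))
  rownames(targets) <- NULL
  regions <- .cross_regions(targets$sequence, targets$gene_id,
                            k = config$cross_seed_len)
  probes <- vector("list", nrow(targets))
  failures <- list()
  for (t in seq_len(nrow(targets))) {
    tgt <- targets[t, ]
    pre <- .tm_precompute(.encode_dna(tgt$sequence), config$conditions)
    if (tgt$kind == "exon") {
      sel <- .design_exon_core(tgt$sequence, pre, regions[[t]], config)
      short <- tgt$short_target || nchar(tgt$sequence) < config$exon_probe_len[1]
      flags <- sel$flags
      if (short && !.has_flag(flags, "short_target")) {
        parts <- strsplit(flags, ",")[[1]]
        flags <- .join_flags(c(parts[nzchar(parts)], "short_target"))
      }
      probes[[t]] <- data.frame(
        probe_id = paste0(tgt$target_id, "_p"), gene_id = tgt$gene_id,
        target_id = tgt$target_id, kind = "exon",
        sequence = substr(tgt$sequence, sel$i, sel$j),
        offset_in_target = sel$i - 1L, length = sel$j - sel$i + 1L,
        arm_left = NA_integer_, arm_right = NA_integer_,
        tm = sel$tm, tm_left = NA_real_, tm_right = NA_real_,
        tm_fold = sel$fold, tm_cross = sel$cross, flags = flags,
        stringsAsFactors = FALSE)
    } else {
      sel <- .design_junction_core(tgt$sequence, tgt$left_flank_len,
                                   tgt$right_flank_len, pre, regions[[t]],
                                   config)
      if (is.null(sel)) {
        failures[[length(failures) + 1L]] <- data.frame(
          target_id = tgt$target_id, gene_id = tgt$gene_id,
          transcript_id = tgt$transcript_id, index = tgt$index,
          reason = "no_admissible_arm_pair", stringsAsFactors = FALSE)
        next
      }
      probes[[t]] <- data.frame(
        probe_id = paste0(tgt$target_id, "_p"), gene_id = tgt$gene_id,
        target_id = tgt$target_id, kind = "junction",
        sequence = substr(tgt$sequence, sel$i, sel$j),
        offset_in_target = sel$i - 1L, length = sel$j - sel$i + 1L,
        arm_left = sel$a, arm_right = sel$b,
        tm = sel$tm, tm_left = sel$tm_l, tm_right = sel$tm_r,
        tm_fold = sel$fold, tm_cross = sel$cross, flags = sel$flags,
        stringsAsFactors = FALSE)
    }
  }
  probes <- do.call(rbind, probes[!vapply(probes, is.null, TRUE)])
  probes$control_id <- NA_character_
  probes$control_pos <- NA_integer_
  if (!is.null(controls) && length(controls)) {
    probes <- rbind(probes, make_control_probes(controls, config = config))
  }
  neg <- withr::with_seed(seed, .make_negative_probes(targets$sequence, config))
  neg$control_id <- NA_character_
  neg$control_pos <- NA_integer_
  probes <- rbind(probes, neg)
  if (anyDuplicated(probes$probe_id)) {
    .stopf("duplicate_probe_id", "duplicate probe_id in design: %s",
           probes$probe_id[duplicated(probes$probe_id)][1])
  }
  rownames(probes) <- NULL
  reps <- ifelse(probes$kind %in% c("exon", "junction"), 1L, config$n_replicates)
  spots <- probes[rep(seq_len(nrow(probes)), reps), , drop = FALSE]
  ri <- unlist(lapply(reps, seq_len))
  spots$spot_id <- ifelse(rep(reps, reps) == 1L, spots$probe_id,
                          sprintf("%s.%02d", spots$probe_id, ri))
  rownames(spots) <- NULL
  structure(list(probes = probes, spots = spots, targets = targets,
                 failures = if (length(failures)) do.call(rbind, failures) else NULL,
                 config = config),
            class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf("<array design: %d probes (%s), %d spots, %d design failures>\n",
              nrow(x$probes),
              paste(sprintf("%s=%d", names(table(x$probes$kind)),
                            as.integer(table(x$probes$kind))), collapse = ", "),
              nrow(x$spots),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  invisible(x)
}

#' Write / read a probe manifest
#'
#' The manifest is the spot-level TSV consumed by the analysis engine (one
#' row per physical spot), accompanied by a probe FASTA.
#'
#' @param design An `array_design` object.
#' @param path Output TSV path (the FASTA is written next to it with
#'   extension `.fasta`).
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design$spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fa <- Biostrings::DNAStringSet(design$probes$sequence)
  names(fa) <- design$probes$probe_id
  Biostrings::writeXStringSet(fa, sub("\\.tsv$", ".fasta", path))
  invisible(path)
}

#' @rdname write_design
#' @param config Optional [design_config()] attached to the re-read design.
#' @export
read_design <- function(path, config = design_config()) {
  spots <- utils::read.delim(path, stringsAsFactors = FALSE)
  spots$flags[is.na(spots$flags)] <- ""
  probes <- spots[!duplicated(spots$probe_id), setdiff(names(spots), "spot_id"),
                  drop = FALSE]
  rownames(probes) <- NULL
  structure(list(probes = probes, spots = spots, targets = NULL,
                 failures = NULL, config = config),
            class = "array_design")
}
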