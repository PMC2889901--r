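# Thermodynamic primitives: nearest-neighbor duplex Tm, a hairpin-stem folding
# screen, and a seed-and-extend cross-hybridization screen. These are the
# currency of all probe selection in the package.

.TM_R <- 1.9872          # gas constant, cal / (mol K)
.FOLD_LOOP_DS <- -15     # entropic penalty of the hairpin loop, cal / (mol K)

# Unified nearest-neighbor parameters (SantaLucia 1998), indexed by
# (first base - 1) * 4 + second base with A=1, C=2, G=3, T=4.
# dH in kcal/mol, dS in cal/(mol K).
.NN_DH <- c(
  -7.9, -8.4, -7.8, -7.2,   # AA AC AG AT
  -8.5, -8.0, -10.6, -7.8,  # CA CC CG CT
  -8.2, -9.8, -8.0, -8.4,   # GA GC GG GT
  -7.2, -8.2, -8.5, -7.9    # TA TC TG TT
)
.NN_DS <- c(
  -22.2, -22.4, -21.0, -20.4,
  -22.7, -19.9, -27.2, -21.0,
  -22.2, -24.4, -19.9, -22.4,
  -21.3, -22.2, -22.7, -22.2
)
# duplex initiation terms per terminal base (A/T vs G/C)
.INIT_DH <- c(2.3, 0.1, 0.1, 2.3)
.INIT_DS <- c(4.1, -2.8, -2.8, 4.1)

.BASE_CODE <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x[utf8ToInt("a")] <- 1L; x[utf8ToInt("c")] <- 2L
  x[utf8ToInt("g")] <- 3L; x[utf8ToInt("t")] <- 4L
  x
})

#' Hybridization conditions for melting-temperature calculations
#'
#' Conditions record consumed by [compute_tm()] and the probe designer:
#' monovalent-salt molarity (logarithmic entropy correction) and total strand
#' concentration.
#'
#' The defaults (0.1 M Na+, 1 µM strand) place a mid-GC 30--36-mer close to
#' the 75 °C design target, which keeps the standard probe constraint set
#' (Tm in 70--80 °C, cross-hybridization limit 60 °C) self-consistent under
#' the unified nearest-neighbor parameter set.
#'
#' @param na_molar Monovalent cation concentration in mol/L.
#' @param strand_conc Total strand concentration in mol/L.
#' @return An object of class `hyb_conditions`.
#' @examples
#' compute_tm(strrep("ACGT", 9), hyb_conditions(na_molar = 0.05))
#' @export
hyb_conditions <- function(na_molar = 0.1, strand_conc = 1e-6) {
  if (!is.numeric(na_molar) || na_molar <= 0 ||
      !is.numeric(strand_conc) || strand_conc <= 0) {
    .stopf("invalid_conditions", "na_molar and strand_conc must be positive")
  }
  structure(list(na_molar = na_molar, strand_conc = strand_conc),
            class = "hyb_conditions")
}

# encode a DNA string as integer codes 1..4; error on anything else
.encode_dna <- function(seq) {
  v <- utf8ToInt(seq)
  if (any(v > 256L)) .stopf("ambiguous_base", "non-DNA character in sequence")
  codes <- .BASE_CODE[v]
  if (anyNA(codes)) {
    .stopf("ambiguous_base", "ambiguous or non-ACGT base in sequence '%s'",
           substr(seq, 1, 40))
  }
  codes
}

# Precompute cumulative NN sums so that the Tm of any window of the sequence
# is an O(1) lookup. Used heavily by the window-enumeration design code.
.tm_precompute <- function(codes, conditions) {
  L <- length(codes)
  if (L >= 2L) {
    nn <- (codes[-L] - 1L) * 4L + codes[-1L]
    csH <- c(0, cumsum(.NN_DH[nn]))
    csS <- c(0, cumsum(.NN_DS[nn]))
  } else {
    csH <- csS <- 0
  }
  list(codes = codes, csH = csH, csS = csS,
       saltS = 0.368 * log(conditions$na_molar),
       rlnc = .TM_R * log(conditions$strand_conc / 4))
}

# Tm (deg C) of windows [i, j] (1-based inclusive) of a precomputed sequence.
# Vectorized over i and j.
.window_tm <- function(pre, i, j) {
  dH <- (pre$csH[j] - pre$csH[i]) + .INIT_DH[pre$codes[i]] + .INIT_DH[pre$codes[j]]
  dS <- (pre$csS[j] - pre$csS[i]) + .INIT_DS[pre$codes[i]] + .INIT_DS[pre$codes[j]] +
    pre$saltS * (j - i) + pre$rlnc
  1000 * dH / dS - 273.15
}

#' Duplex melting temperature of an oligonucleotide
#'
#' Nearest-neighbor melting temperature of the perfect probe/target duplex
#' under the unified DNA parameter set, with a logarithmic monovalent-salt
#' entropy correction and a strand-concentration term for a
#' non-self-complementary duplex.
#'
#' @param seq DNA string (A/C/G/T only), at least 10 bp.
#' @param conditions A [hyb_conditions()] record.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' compute_tm(strrep("GC", 15)) > compute_tm(strrep("AT", 15))
#' @export
compute_tm <- function(seq, conditions = hyb_conditions()) {
  if (!is.character(seq) || length(seq) != 1L) {
    .stopf("invalid_sequence", "seq must be a single string")
  }
  L <- nchar(seq)
  if (L < 10L) .stopf("sequence_too_short", "Tm undefined for < 10 bp (got %d)", L)
  pre <- .tm_precompute(.encode_dna(seq), conditions)
  .window_tm(pre, 1L, L)
}

#' Secondary-structure folding temperature (hairpin screen)
#'
#' Deterministic hairpin scan: every candidate stem of at least 4 perfectly
#' Watson-Crick paired bases enclosing a loop of at least 3 nt is enumerated,
#' and the melting temperature of the most stable stem is returned.
#' Stem stability is the nearest-neighbor enthalpy/entropy of the stem duplex
#' plus a fixed loop entropy penalty; the result is floored at 0 °C when no
#' stem exists. This is a screening heuristic, not a partition-function fold.
#'
#' @inheritParams compute_tm
#' @return Folding temperature in degrees Celsius (0 when unstructured).
#' @examples
#' compute_fold_tm("ACGTACGTACGTACGTACGT")  # palindrome folds
#' @export
compute_fold_tm <- function(seq, conditions = hyb_conditions()) {
  if (!is.character(seq) || length(seq) != 1L) {
    .stopf("invalid_sequence", "seq must be a single string")
  }
  L <- nchar(seq)
  if (L < 10L) .stopf("sequence_too_short", "fold Tm undefined for < 10 bp (got %d)", L)
  codes <- .encode_dna(seq)
  comp <- 5L - codes
  salt <- 0.368 * log(conditions$na_molar)
  best <- 0
  # stem start pair (i, j): need >= 4 pairs and >= 3 loop nt between them
  for (i in seq_len(L - 10L)) {
    for (j in seq.int(i + 10L, L)) {
      if (codes[i] != comp[j]) next
      len <- 1L
      while (i + len <= L && j - len >= 1L &&
             (j - len) - (i + len) - 1L >= 3L &&
             codes[i + len] == comp[j - len]) {
        len <- len + 1L
      }
      if (len < 4L) next
      # evaluate every inner-truncated sub-stem of the run anchored at (i, j)
      # (outer truncations are reached from later anchors); a GC-rich
      # sub-stem can be more stable than the full run
      stem <- codes[i:(i + len - 1L)]
      nn <- (stem[-len] - 1L) * 4L + stem[-1L]
      csH <- cumsum(.NN_DH[nn]); csS <- cumsum(.NN_DS[nn])
      for (l in 4:len) {
        dH <- csH[l - 1L]
        dS <- csS[l - 1L] + salt * (l - 1L) + .FOLD_LOOP_DS
        tm <- 1000 * dH / dS - 273.15
        if (tm > best) best <- tm
      }
    }
  }
  max(best, 0)
}

# maximal exact matches (>= k) between two strings; returns matrix with
# columns qs, qe (positions in `a`)
.maximal_matches <- function(a, b, k = 10L) {
  na <- nchar(a); nb <- nchar(b)
  k <- min(k, na, nb)
  if (k < 1L) return(matrix(integer(0), ncol = 2L))
  ak <- substring(a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
  bk <- substring(b, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
  pos_by_kmer <- split(seq_along(bk), bk)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  out <- list()
  for (i in seq_along(ak)) {
    hits <- pos_by_kmer[[ak[i]]]
    if (is.null(hits)) next
    for (p in hits) {
      # only extend from left-maximal anchors so each match is reported once
      if (i > 1L && p > 1L && av[i - 1L] == bv[p - 1L]) next
      len <- k
      while (i + len <= na && p + len <= nb && av[i + len] == bv[p + len]) {
        len <- len + 1L
      }
      out[[length(out) + 1L]] <- c(i, i + len - 1L)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2L))
  unique(do.call(rbind, out))
}

# best Tm over all sub-windows >= 10 bp of region [qs, qe] of a precomputed seq
.best_subwindow_tm <- function(pre, qs, qe) {
  if (qe - qs + 1L < 10L) return(-Inf)
  idx <- expand.grid(i = qs:(qe - 9L), j = qs:qe)
  idx <- idx[idx$j - idx$i + 1L >= 10L, , drop = FALSE]
  max(.window_tm(pre, idx$i, idx$j))
}

#' Maximum cross-hybridization temperature against a background
#'
#' Seed-and-extend search for the best local duplex a probe can form with any
#' background target sequence: exact seed matches are extended to maximal
#' perfectly matched regions and the nearest-neighbor Tm of the best matched
#' sub-region (at least 10 bp) is reported, capped at the probe's own perfect
#' duplex Tm. Matches shorter than the seed length are ignored; they cannot
#' approach the 60 °C screening limit used in probe design.
#'
#' @inheritParams compute_tm
#' @param background Character vector of target sequences. Must not contain
#'   the probe's own target.
#' @param seed_len Exact-match seed length used to anchor local alignments.
#' @return Maximum cross-hybridization Tm in degrees Celsius (0 when there is
#'   no match; an empty background returns 0 with a warning).
#' @export
compute_cross_tm <- function(seq, background, conditions = hyb_conditions(),
                             seed_len = 10L) {
  if (length(background) == 0L) {
    warning("empty cross-hybridization background; returning 0",
            call. = FALSE)
    return(0)
  }
  L <- nchar(seq)
  if (L < 10L) .stopf("sequence_too_short", "cross Tm undefined for < 10 bp")
  pre <- .tm_precompute(.encode_dna(seq), conditions)
  best <- 0
  for (bg in background) {
    mm <- .maximal_matches(seq, bg, k = seed_len)
    if (!nrow(mm)) next
    for (r in seq_len(nrow(mm))) {
      tm <- .best_subwindow_tm(pre, mm[r, 1L], mm[r, 2L])
      if (tm > best) best <- tm
    }
  }
  min(best, .window_tm(pre, 1L, L))
}

#' @describeIn compute_tm Thermodynamic profile (duplex, fold and cross Tm)
#'   of a probe sequence as a named list.
#' @param background Character vector of background target sequences for the
#'   cross-hybridization screen (empty vector for none).
#' @export
thermo_profile <- function(seq, background = character(),
                           conditions = hyb_conditions()) {
  list(
    tm_duplex = compute_tm(seq, conditions),
    tm_fold = compute_fold_tm(seq, conditions),
    tm_cross_max = if (length(background)) {
      compute_cross_tm(seq, background, conditions)
    } else 0
  )
}
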