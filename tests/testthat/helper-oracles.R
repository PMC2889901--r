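# Independent oracle implementations used to verify the package's
# thermodynamic and selection code. These are written as direct, brute-force
# formulations (string-keyed tables, exhaustive enumeration, dynamic
# programming) and deliberately share no code with R/.

ORC_DH <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
            CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
            GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
            TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
ORC_DS <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
            CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
            GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
            TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)

orc_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# nearest-neighbor duplex Tm by direct dinucleotide summation
orc_tm <- function(seq, na = 0.1, ct = 1e-6) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dh <- 0; ds <- 0
  for (i in seq_len(n - 1)) {
    dn <- paste0(ch[i], ch[i + 1])
    dh <- dh + ORC_DH[[dn]]
    ds <- ds + ORC_DS[[dn]]
  }
  for (b in ch[c(1, n)]) {
    if (b %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na) + 1.9872 * log(ct / 4)
  1000 * dh / ds - 273.15
}

# exhaustive hairpin-stem enumeration: every (block1 start, stem length,
# block2 start) triple with perfect reverse-complement pairing, stem >= 4 bp
# and loop >= 3 nt
orc_fold_tm <- function(seq, na = 0.1, loop_ds = -15) {
  n <- nchar(seq)
  best <- 0
  for (L in 4:max(4, floor((n - 3) / 2))) {
    if (2 * L + 3 > n) break
    for (i in seq_len(n - 2 * L - 3 + 1)) {
      stem <- substr(seq, i, i + L - 1)
      rc <- orc_revcomp(stem)
      for (q in seq.int(i + L + 3, n - L + 1)) {
        if (substr(seq, q, q + L - 1) != rc) next
        ch <- strsplit(stem, "")[[1]]
        dh <- 0; ds <- 0
        for (t in seq_len(L - 1)) {
          dn <- paste0(ch[t], ch[t + 1])
          dh <- dh + ORC_DH[[dn]]; ds <- ds + ORC_DS[[dn]]
        }
        ds <- ds + 0.368 * (L - 1) * log(na) + loop_ds
        tm <- 1000 * dh / ds - 273.15
        if (tm > best) best <- tm
      }
    }
  }
  max(best, 0)
}

# all common substrings (>= min_len) of `seq` against one background string,
# by longest-common-suffix dynamic programming; returns intervals in seq
# coordinates as a data.frame(start, end)
orc_common_substrings <- function(seq, bg, min_len = 10) {
  a <- strsplit(seq, "")[[1]]; b <- strsplit(bg, "")[[1]]
  n <- length(a); m <- length(b)
  Lmat <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    eq <- a[i] == b
    Lmat[i + 1, 2:(m + 1)] <- ifelse(eq, Lmat[i, 1:m] + 1L, 0L)
  }
  ends <- which(Lmat >= min_len, arr.ind = TRUE)
  if (!nrow(ends)) return(data.frame(start = integer(), end = integer()))
  unique(data.frame(start = ends[, 1] - Lmat[ends] ,  # (i+1) - L = start index
                    end = ends[, 1] - 1L))
}

# exhaustive cross-hybridization Tm: max Tm over every common substring
# >= 10 bp with any background sequence, capped at the perfect-duplex Tm
orc_cross_tm <- function(seq, bgs, na = 0.1, ct = 1e-6) {
  best <- 0
  for (bg in bgs) {
    cs <- orc_common_substrings(seq, bg)
    if (!nrow(cs)) next
    for (r in seq_len(nrow(cs))) {
      for (s in cs$start[r]:(cs$end[r] - 9L)) {
        for (e in (s + 9L):cs$end[r]) {
          tm <- orc_tm(substr(seq, s, e), na, ct)
          if (tm > best) best <- tm
        }
      }
    }
  }
  min(best, orc_tm(seq, na, ct))
}

# cross Tm restricted to a window [i, j] of the target, given precomputed
# common-substring intervals for the whole target
orc_window_cross <- function(seq, cs, i, j, na = 0.1, ct = 1e-6) {
  best <- 0
  if (nrow(cs)) {
    for (r in seq_len(nrow(cs))) {
      s0 <- max(cs$start[r], i); e0 <- min(cs$end[r], j)
      if (e0 - s0 + 1 >= 10) {
        for (s in s0:(e0 - 9L)) {
          for (e in (s + 9L):e0) {
            tm <- orc_tm(substr(seq, s, e), na, ct)
            if (tm > best) best <- tm
          }
        }
      }
    }
  }
  min(best, orc_tm(substr(seq, i, j), na, ct))
}

# exhaustive exon-window selection under the published rule; returns
# c(start, end) of the winning window (1-based in the target)
orc_exon_pick <- function(target, bgs, lmin = 30, lmax = 36,
                          tm_lo = 70, tm_hi = 80, tm_target = 75,
                          cross_max = 60) {
  n <- nchar(target)
  cs <- do.call(rbind, lapply(bgs, function(b) orc_common_substrings(target, b)))
  if (is.null(cs)) cs <- data.frame(start = integer(), end = integer())
  wins <- expand.grid(i = seq_len(n), len = lmin:lmax)
  wins$j <- wins$i + wins$len - 1
  wins <- wins[wins$j <= n, ]
  wins$tm <- mapply(function(i, j) orc_tm(substr(target, i, j)), wins$i, wins$j)
  wins$cross <- mapply(function(i, j) orc_window_cross(target, cs, i, j),
                       wins$i, wins$j)
  qual <- wins$tm >= tm_lo & wins$tm <= tm_hi & wins$cross <= cross_max
  if (any(qual)) {
    d <- abs(wins$tm - tm_target)
    m <- min(d[qual])
    tie <- which(qual & d <= m + 1e-6)
    if (length(tie) > 1) {
      folds <- vapply(tie, function(r) orc_fold_tm(substr(target, wins$i[r], wins$j[r])), 0)
      tie <- tie[order(round(folds, 6), wins$len[tie], wins$i[tie])]
    }
    pick <- tie[1]
  } else {
    folds <- vapply(seq_len(nrow(wins)),
                    function(r) orc_fold_tm(substr(target, wins$i[r], wins$j[r])), 0)
    pick <- order(round(wins$cross, 6), round(folds, 6),
                  round(abs(wins$tm - tm_target), 6),
                  wins$len, wins$i)[1]
  }
  c(wins$i[pick], wins$j[pick])
}

# exhaustive junction arm-pair selection; returns c(arm_left, arm_right)
orc_junction_pick <- function(target, lf, rf, amin = 10, tmin = 25, tmax = 42,
                              tm_target = 75, balance_tol = 1.0) {
  cand <- expand.grid(a = amin:lf, b = amin:rf)
  cand <- cand[cand$a + cand$b >= tmin & cand$a + cand$b <= tmax, ]
  if (!nrow(cand)) return(NULL)
  cand$tm_l <- mapply(function(a) orc_tm(substr(target, lf - a + 1, lf)), cand$a)
  cand$tm_r <- mapply(function(b) orc_tm(substr(target, lf + 1, lf + b)), cand$b)
  cand$d <- abs(cand$tm_l - cand$tm_r)
  near <- cand$d <= min(cand$d) + balance_tol
  cand$tm <- mapply(function(a, b) orc_tm(substr(target, lf - a + 1, lf + b)),
                    cand$a, cand$b)
  score <- abs(cand$tm - tm_target)
  m <- min(score[near])
  tie <- which(near & score <= m + 1e-6)
  tie <- tie[order(round(cand$d[tie], 6), cand$a[tie] + cand$b[tie],
                   cand$a[tie])]
  c(cand$a[tie[1]], cand$b[tie[1]])
}

# brute-force optimal two-group partition: minimum within-group SSE over all
# 2^(n-1) bipartitions (not just sorted splits)
orc_two_group_sse <- function(r) {
  n <- length(r)
  if (n < 2) return(0)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sse <- sum((r[g] - mean(r[g]))^2) + sum((r[!g] - mean(r[!g]))^2)
    if (sse < best) best <- sse
  }
  best
}

# random DNA helper for fixtures (independent of the package internal)
orc_random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
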