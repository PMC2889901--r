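# Target extraction geometry, probe selection, controls and design assembly.

test_that("exon targets follow the published geometry", {
  set.seed(201)
  e1 <- orc_random_dna(100); e2 <- orc_random_dna(100); e3 <- orc_random_dna(100)
  g <- fix_gene("gA", list(c(e1, e2, e3)))
  tg <- extract_exon_targets(g)
  expect_true(all(nchar(tg$sequence) == 36))
  # centered 36-bp window of the middle 100-bp exon
  mid <- tg[tg$index == 2, ]
  expect_equal(mid$sequence, substr(paste0(e1, e2, e3), 133, 168))

  # 20-bp internal exon padded 8 bp from each neighbor
  s1 <- orc_random_dna(100); s2 <- orc_random_dna(20); s3 <- orc_random_dna(100)
  gs <- fix_gene("gB", list(c(s1, s2, s3)))
  tgs <- extract_exon_targets(gs)
  short <- tgs[tgs$index == 2, ]
  expect_equal(short$sequence,
               paste0(substr(s1, 93, 100), s2, substr(s3, 1, 8)))

  # odd remainder goes to the 5' side
  o2 <- orc_random_dna(21)
  go <- fix_gene("gC", list(c(s1, o2, s3)))
  tgo <- extract_exon_targets(go)[2, ]
  expect_equal(tgo$sequence, paste0(substr(s1, 93, 100), o2, substr(s3, 1, 7)))

  # terminal short exon pads only inward
  gt <- fix_gene("gD", list(c(orc_random_dna(20), s3)))
  tgt <- extract_exon_targets(gt)[1, ]
  expect_equal(substr(tgt$sequence, 1, 20), gt$isoforms[[1]]$sequence |> substr(1, 20))

  # whole transcript shorter than 36 bp -> single short_target
  gw <- fix_gene("gE", list(orc_random_dna(30)))
  tgw <- extract_exon_targets(gw)
  expect_equal(nrow(tgw), 1)
  expect_true(tgw$short_target)
  expect_equal(nchar(tgw$sequence), 30)
})

test_that("junction targets recruit across small exons and truncate at ends", {
  set.seed(202)
  e1 <- orc_random_dna(100); e2 <- orc_random_dna(100)
  g <- fix_gene("gJ", list(c(e1, e2)))
  tg <- extract_junction_targets(g)
  expect_equal(nchar(tg$sequence), 50)
  expect_equal(tg$left_flank_len, 25)
  expect_equal(tg$right_flank_len, 25)
  expect_equal(tg$sequence, paste0(substr(e1, 76, 100), substr(e2, 1, 25)))

  # 10-bp exon: left side = 15 bp of the earlier exon + the 10-bp exon
  s2 <- orc_random_dna(10); s3 <- orc_random_dna(100)
  gs <- fix_gene("gK", list(c(e1, s2, s3)))
  tgs <- extract_junction_targets(gs)
  j2 <- tgs[tgs$index == 2, ]
  expect_equal(substr(j2$sequence, 1, 25), paste0(substr(e1, 86, 100), s2))

  # first exon of 12 bp: left flank truncated to 12, total 37
  gf <- fix_gene("gL", list(c(orc_random_dna(12), s3)))
  tgf <- extract_junction_targets(gf)
  expect_equal(tgf$left_flank_len, 12)
  expect_equal(nchar(tgf$sequence), 37)
})

test_that("exon probe selection obeys constraints and flags failures", {
  set.seed(203)
  # a compliant mid-GC target yields an unflagged probe in range
  tgt <- list(target_id = "t1", gene_id = "g", sequence = orc_random_dna(36, 0.5),
              short_target = FALSE)
  p <- design_exon_probe(tgt)
  expect_true(p$length >= 30 && p$length <= 36)
  if (p$flags == "") {
    expect_true(p$tm >= 70 && p$tm <= 80)
  }
  # poly-AT target cannot reach 70 C -> flagged tm_out_of_range
  tat <- list(target_id = "t2", gene_id = "g", sequence = strrep("AT", 18),
              short_target = FALSE)
  pat <- design_exon_probe(tat)
  expect_match(pat$flags, "tm_out_of_range")
  # target shorter than the minimum probe length -> whole target, short flag
  tsh <- list(target_id = "t3", gene_id = "g", sequence = orc_random_dna(24, 0.5),
              short_target = TRUE)
  psh <- design_exon_probe(tsh)
  expect_equal(psh$sequence, tsh$sequence)
  expect_match(psh$flags, "short_target")
})

test_that("exon and junction picks match exhaustive-enumeration oracles", {
  set.seed(204)
  for (i in 1:8) {
    target <- orc_random_dna(sample(40:60, 1), runif(1, 0.35, 0.6))
    bgs <- replicate(3, orc_random_dna(120, 0.5))
    if (i %% 3 == 0) {
      bgs[1] <- paste0(orc_random_dna(25, 0.5), substr(target, 10, 30),
                       orc_random_dna(25, 0.5))
    }
    p <- design_exon_probe(list(target_id = "t", gene_id = "g",
                                sequence = target, short_target = FALSE), bgs)
    expect_equal(c(p$offset_in_target + 1L, p$offset_in_target + p$length),
                 orc_exon_pick(target, bgs))
  }
  for (i in 1:8) {
    lf <- sample(12:25, 1); rf <- sample(12:25, 1)
    target <- orc_random_dna(lf + rf, runif(1, 0.35, 0.6))
    p <- design_junction_probe(list(target_id = "t", gene_id = "g",
                                    sequence = target, left_flank_len = lf,
                                    right_flank_len = rf))
    expect_equal(c(p$arm_left, p$arm_right), orc_junction_pick(target, lf, rf))
  }
})

test_that("junction probes balance arm Tm and asymmetry compensates GC skew", {
  set.seed(205)
  # AT-rich left side, GC-rich right side -> longer left arm
  target <- paste0(orc_random_dna(25, 0.15), orc_random_dna(25, 0.85))
  p <- design_junction_probe(list(target_id = "t", gene_id = "g",
                                  sequence = target, left_flank_len = 25,
                                  right_flank_len = 25))
  expect_gt(p$arm_left, p$arm_right)
  expect_true(p$length >= 25 && p$length <= 42)
  expect_equal(p$arm_left + p$arm_right, p$length)
  # balance equals the brute-force minimum over admissible arm pairs
  orc <- orc_junction_pick(target, 25, 25)
  expect_equal(c(p$arm_left, p$arm_right), orc)
})

test_that("control probes split into balanced AT-padded halves, replicated", {
  set.seed(206)
  ctl <- simulate_control_isoforms(seed = 7, lengths = 4900L)[[1]]
  probes <- make_control_probes(list(ctl), n_positions = 12)
  full <- probes[probes$kind == "control_full", ]
  h5 <- probes[probes$kind == "control_half_5", ]
  h3 <- probes[probes$kind == "control_half_3", ]
  expect_equal(nrow(full), 12)
  expect_equal(nrow(h5), 12)
  expect_equal(nrow(h3), 12)
  # halves have the parent's length; real half + AT pad
  expect_equal(h5$length, full$length)
  expect_equal(h3$length, full$length)
  for (r in 1:12) {
    n <- full$length[r]
    s <- h5$arm_left[r]
    expect_equal(substr(h5$sequence[r], 1, s), substr(full$sequence[r], 1, s))
    expect_match(substr(h5$sequence[r], s + 1, n), "^(AT)*A?$")
    # split point equals the brute-force |dTm| argmin over internal splits
    d <- vapply(10:(n - 10), function(sp) {
      abs(orc_tm(substr(full$sequence[r], 1, sp)) -
            orc_tm(substr(full$sequence[r], sp + 1, n)))
    }, 0)
    expect_equal(s, (10:(n - 10))[which.min(d)])
  }
  # replicated >= 10x in the spot manifest
  d <- build_design(simulate_gene_models(3, seed = 9), list(ctl), seed = 2)
  reps <- table(d$spots$probe_id[d$spots$kind == "control_full"])
  expect_true(all(reps >= 10))
})

test_that("build_design is deterministic, deduplicated and accounted for", {
  models <- simulate_gene_models(10, seed = 31)
  ctl <- simulate_control_isoforms(seed = 8, lengths = c(4600L, 4900L))
  d1 <- build_design(models, ctl, seed = 5)
  d2 <- build_design(models, ctl, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_design(d1, f1); write_design(d2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # accounting: one probe per target except junction design failures
  n_fail <- if (is.null(d1$failures)) 0L else nrow(d1$failures)
  expect_equal(sum(d1$probes$kind %in% c("exon", "junction")) + n_fail,
               nrow(d1$targets))
  # identical target sequences across isoforms appear exactly once
  expect_equal(anyDuplicated(d1$targets$sequence), 0)
  expect_equal(anyDuplicated(d1$probes$probe_id), 0)

  # every junction of every isoform has a probe or a logged failure
  for (m in models) {
    for (iso in m$isoforms) {
      lens <- iso$exons$end - iso$exons$start
      total <- sum(lens)
      pos <- cumsum(lens)
      for (p in pos[-length(pos)]) {
        lf <- min(25, p); rf <- min(25, total - p)
        jseq <- substr(iso$sequence, p - lf + 1, p + rf)
        ti <- match(jseq, d1$targets$sequence)
        expect_false(is.na(ti))
        tid <- d1$targets$target_id[ti]
        covered <- tid %in% d1$probes$target_id ||
          (!is.null(d1$failures) && tid %in% d1$failures$target_id)
        expect_true(covered)
      }
    }
  }
})

test_that("designed probe sets satisfy the constraint suite", {
  models <- simulate_gene_models(15, seed = 77)
  d <- build_design(models, seed = 6)
  jp <- d$probes[d$probes$kind == "junction", ]
  ep <- d$probes[d$probes$kind == "exon", ]
  expect_true(all(jp$length >= 25 & jp$length <= 42))
  expect_true(all(ep$length[!grepl("short_target", ep$flags)] >= 30))
  expect_true(all(ep$length <= 36))
  ok <- d$probes$flags == "" & d$probes$kind %in% c("exon", "junction")
  expect_true(all(d$probes$tm[ok] >= 70 & d$probes$tm[ok] <= 80))
  expect_true(all(d$probes$tm_cross[ok] <= 60))
  # every probe is a substring of its target
  ti <- match(d$probes$target_id[ok], d$targets$target_id)
  expect_true(all(mapply(grepl, d$probes$sequence[ok],
                         d$targets$sequence[ti], MoreArgs = list(fixed = TRUE))))
  # negative probes pass the cross-hybridization ceiling against all targets
  neg <- d$probes[d$probes$kind == "negative", ]
  expect_equal(nrow(neg), 10)
  for (s in neg$sequence[1:3]) {
    expect_lte(compute_cross_tm(s, d$targets$sequence), 40)
  }
})
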