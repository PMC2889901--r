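# Preprocessing, variance calibration, gene classification, replicate
# ranking and positional-bias QC.

test_that("detection cutoff is mean + k SD of negative controls", {
  # negatives at 90/100/110 -> mean 100, SD 10, cutoff 130
  kinds <- c(rep("exon", 4), rep("negative", 3))
  d <- fix_stub_design(kinds, gene_id = c(rep("g1", 4), rep(NA, 3)))
  neg_vals <- c(90, 100, 110)
  cy3 <- matrix(c(200, 120, 500, 1000, neg_vals), ncol = 1,
                dimnames = list(d$spots$spot_id, "A1"))
  cy5 <- cy3
  prep <- preprocess(fix_intensities(cy3, cy5, FALSE), d, k = 3)
  expect_equal(unname(prep$cutoffs$cy3), 130)
  expect_false(prep$detected["p0002", 1])   # 120 in both channels
  expect_true(prep$detected["p0001", 1])
  expect_error(
    preprocess(fix_intensities(cy3, cy5, FALSE),
               fix_stub_design(rep("exon", 7), gene_id = "g1"), k = 3),
    class = "no_negative_controls")
})

test_that("spot calibration flags replicate outliers by the 3-MAD rule", {
  set.seed(501)
  kinds <- c(rep("control_full", 12), rep("exon", 4), rep("negative", 4))
  d <- fix_stub_design(kinds,
                       probe_id = c(rep("CTLP1", 12), sprintf("g%d", 1:4),
                                    sprintf("n%d", 1:4)),
                       gene_id = c(rep(NA, 12), rep("g1", 4), rep(NA, 4)))
  cy3 <- matrix(c(rep(5000, 12), rep(4000, 4), rep(100, 4) + rnorm(4)),
                ncol = 1, dimnames = list(d$spots$spot_id, "A1"))
  cy5 <- cy3 * 2^rnorm(20, 0, 0.02)
  cy5[1] <- cy3[1] * 10                     # one spot at 10x its siblings
  prep <- preprocess(fix_intensities(cy3, cy5, FALSE), d, k = 3)
  expect_true(prep$spot_flag[1, 1])
  expect_false(any(prep$spot_flag[2:12, 1]))
})

test_that("self-to-self balanced input normalizes to median log-ratio 0", {
  set.seed(502)
  kinds <- c(rep("exon", 50), rep("negative", 5))
  d <- fix_stub_design(kinds, gene_id = c(rep("g1", 50), rep(NA, 5)))
  cy3 <- matrix(c(2^rnorm(50, 11, 1), rnorm(5, 100, 10)), ncol = 1,
                dimnames = list(d$spots$spot_id, "A1"))
  prep <- preprocess(fix_intensities(cy3, cy3 * 1.7, TRUE), d, k = 3)
  use <- d$spots$kind == "exon" & prep$detected[, 1]
  expect_equal(median(prep$ratio[use, 1]), 0)
})

test_that("variability calibration recovers CF and sigma*", {
  p1 <- sim_params(noise_sd_log2 = 0.066, gene_noise_mult = 1)
  sim <- simulate_null_arrays(6000, n_control_probes = 4800, params = p1,
                              n_self = 2, seed = 21)
  prep <- preprocess(sim$intensities, sim$design, k = 3)
  v <- estimate_variability(prep, k = 3)
  expect_lt(abs(v$CF - 1), 0.05)           # equal gene and control noise
  expect_equal(v$per_array$th, 3 * v$per_array$sigma_star)
  expect_equal(v$per_array$sigma_star, v$CF * v$per_array$sigma_c)

  p2 <- sim_params(noise_sd_log2 = 0.066, gene_noise_mult = 1.2)
  sim2 <- simulate_null_arrays(6000, n_control_probes = 4800, params = p2,
                               n_self = 2, seed = 22)
  v2 <- estimate_variability(preprocess(sim2$intensities, sim2$design), k = 3)
  expect_gt(v2$CF, 1)
  expect_lt(abs(v2$CF - 1.2) / 1.2, 0.05)  # CF tracks the noise ratio
  # degenerate noise-free input is refused
  p0 <- sim_params(noise_sd_log2 = 0)
  sim0 <- simulate_null_arrays(500, params = p0, n_self = 1, seed = 23)
  expect_error(estimate_variability(preprocess(sim0$intensities, sim0$design)),
               class = "degenerate_sigma_c")
})

test_that("gene classification separates expression shifts from splicing", {
  # uniform +1 shift: every probe over the change threshold, none deviates
  r <- analyze_gene(rep(1, 8), sigma_star = 0.1)
  expect_equal(r$n_outside, 0)
  expect_equal(r$classification, "expression_change")
  expect_equal(r$form_change, 0)
  # bimodal profile: mixture hypothesis wins with zero error
  r2 <- analyze_gene(c(0, 0, 0, 0, 1, 1), sigma_star = 0.1)
  expect_gte(r2$n_outside, 1)
  expect_equal(r2$e_iso, 0)
  expect_lt(r2$e_iso, 0.5 * r2$e_expr)
  expect_equal(r2$classification, "splice_candidate")
  expect_gt(r2$form_change, 0)
  # all-zero profile
  r3 <- analyze_gene(rep(0, 6), sigma_star = 0.1)
  expect_equal(r3$mu, 0)
  expect_equal(r3$classification, "no_change")
  expect_equal(r3$form_change, 0)
  # too few probes
  expect_equal(analyze_gene(c(0, 1), sigma_star = 0.1)$classification,
               "not_detected")
  expect_error(analyze_gene(rep(0, 8), sigma_star = NA),
               class = "missing_sigma_star")
})

test_that("two-group error is exact and nested within the expression error", {
  set.seed(503)
  for (i in 1:25) {
    r <- rnorm(sample(4:10, 1), sd = runif(1, 0.1, 2)) +
      sample(c(0, 2), 1) * rbinom(1, 1, 0.5)
    res <- analyze_gene(r, sigma_star = 0.1)
    expect_lte(res$e_iso, res$e_expr + 1e-12)
    # exhaustive bipartition oracle (optimal split must be an interval of
    # the sorted values, but the oracle does not assume that)
    expect_equal(res$e_iso, orc_two_group_sse(r), tolerance = 1e-9)
  }
})

test_that("form change grows monotonically with switch magnitude", {
  base <- rep(0, 10)
  fc <- vapply(seq(0, 2, by = 0.25), function(delta) {
    analyze_gene(c(base, -delta, -delta), sigma_star = 0.1)$form_change
  }, 0)
  expect_true(all(diff(fc) >= 0))
  expect_equal(fc[1], 0)
  expect_gt(fc[length(fc)], 0)
})

test_that("pure expression changes rarely leak into splice candidates", {
  set.seed(504)
  leaks <- vapply(1:1000, function(i) {
    fold <- runif(1, 1, 3)                 # uniform 2x to 8x in log2
    ratios <- fold + rnorm(8, 0, 0.15)
    analyze_gene(ratios, sigma_star = 0.15)$classification == "splice_candidate"
  }, TRUE)
  expect_lte(mean(leaks), 0.05)
})

# build a minimal splice_prep + variability pair directly (the analysis
# contract is plain lists, so tests can construct profiles exactly)
fix_prep <- function(ratio, spots, is_self_self) {
  arrays <- data.frame(array_id = colnames(ratio), is_self_self = is_self_self,
                       stringsAsFactors = FALSE)
  structure(list(ratio = ratio,
                 detected = matrix(TRUE, nrow(ratio), ncol(ratio),
                                   dimnames = dimnames(ratio)),
                 spot_flag = matrix(FALSE, nrow(ratio), ncol(ratio),
                                    dimnames = dimnames(ratio)),
                 spots = spots, arrays = arrays,
                 cutoffs = NULL),
            class = "splice_prep")
}

fix_varest <- function(array_ids, sigma_star, k = 3) {
  structure(list(per_array = data.frame(array_id = array_ids,
                                        sigma_star = sigma_star,
                                        th = k * sigma_star,
                                        stringsAsFactors = FALSE),
                 CF = 1, k = k), class = "variability")
}

test_that("replicate analysis ranks prevalent events above sporadic ones", {
  set.seed(505)
  n_pairs <- 20
  spots <- fix_stub_design(c(rep("exon", 24), rep("negative", 2)),
                           probe_id = sprintf("p%03d", 1:26),
                           gene_id = c(rep(c("g_prev", "g_rare", "g_null"),
                                           each = 8), NA, NA))$spots
  ratio <- matrix(rnorm(26 * (n_pairs + 1), 0, 0.05), 26, n_pairs + 1,
                  dimnames = list(spots$spot_id,
                                  c(sprintf("P%02d", 1:n_pairs), "S01")))
  # identical-magnitude exon-skip signature: 3 deviating probes at -1
  dev_rows_prev <- 6:8        # probes of g_prev
  dev_rows_rare <- 14:16      # probes of g_rare
  ratio[dev_rows_prev, 1:15] <- ratio[dev_rows_prev, 1:15] - 1
  ratio[dev_rows_rare, 1:2] <- ratio[dev_rows_rare, 1:2] - 1
  prep <- fix_prep(ratio, spots, c(rep(FALSE, n_pairs), TRUE))
  varest <- fix_varest(colnames(ratio), rep(0.05, n_pairs + 1))
  res <- replicate_analysis(prep, varest)
  expect_true("g_prev" %in% res$candidates$gene_id)
  r_prev <- match("g_prev", res$candidates$gene_id)
  r_rare <- match("g_rare", res$candidates$gene_id)
  expect_true(is.na(r_rare) || r_prev < r_rare)
  # the 15/20 gene is individually called in most pairs
  prev <- res$gene_results$prevalence[res$gene_results$gene_id == "g_prev"]
  expect_gt(prev, 0.5)
  # null gene never appears among candidates
  expect_false("g_null" %in% res$candidates$gene_id)
  # ranking is sorted by form change, descending
  expect_true(all(diff(res$candidates$form_change) <= 0))
  # a single pair is refused
  expect_error(replicate_analysis(fix_prep(ratio[, c(1, 21), drop = FALSE],
                                           spots, c(FALSE, TRUE)), varest),
               class = "too_few_pairs")
})

test_that("positional-bias regression flags decay and ignores channel scale", {
  set.seed(506)
  n_pos <- 12
  pos <- round(seq(0, 4800, length.out = n_pos))
  spots <- fix_stub_design(c(rep("control_full", n_pos), rep("negative", 2)),
                           probe_id = c(sprintf("c%02d", 1:n_pos), "n1", "n2"),
                           control_id = c(rep("CTLX", n_pos), NA, NA),
                           control_pos = c(pos, NA, NA))$spots
  prep <- fix_prep(matrix(0, n_pos + 2, 2,
                          dimnames = list(spots$spot_id, c("A1", "A2"))),
                   spots, c(FALSE, FALSE))
  flat <- 5000 * 2^rnorm(n_pos + 2, 0, 0.15)
  mk_int <- function(cy3) fix_intensities(
    matrix(rep(cy3, 2), ncol = 2, dimnames = list(spots$spot_id, c("A1", "A2"))),
    matrix(rep(cy3, 2), ncol = 2, dimnames = list(spots$spot_id, c("A1", "A2"))),
    c(FALSE, FALSE))
  bias_flat <- assess_positional_bias(prep, mk_int(flat))
  expect_false(bias_flat$biased)
  # simulated 3' decay: signal falls with distance from the 3' end
  decay <- flat * c(exp(-0.5 * (max(pos) + 36 - pos) / 1000), 1, 1)
  bias_decay <- assess_positional_bias(prep, mk_int(decay))
  expect_true(bias_decay$biased)
  expect_lt(bias_decay$slope_per_kb, 0)
  # constant-multiple channel imbalance leaves the slope unchanged
  int_bal <- mk_int(decay)
  int_imb <- int_bal
  int_imb$cy5 <- int_imb$cy5 * 4
  bias_imb <- assess_positional_bias(prep, int_imb)
  expect_equal(bias_imb$slope_per_kb, bias_decay$slope_per_kb, tolerance = 1e-9)
  # fewer than five positions is refused
  spots5 <- spots[c(1:4, 13:14), ]
  prep5 <- fix_prep(matrix(0, 6, 1, dimnames = list(spots5$spot_id, "A1")),
                    spots5, FALSE)
  int5 <- fix_intensities(
    matrix(flat[c(1:4, 13:14)], ncol = 1, dimnames = list(spots5$spot_id, "A1")),
    matrix(flat[c(1:4, 13:14)], ncol = 1, dimnames = list(spots5$spot_id, "A1")),
    FALSE)
  expect_error(assess_positional_bias(prep5, int5), class = "too_few_positions")
})
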