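# Genome-scan workflow: cofactor selection, scans, thresholds, peaks and
# model selection.

test_that("stepwise cofactor selection: cap, power, null behaviour", {
  expect_identical(select_cofactors_mps(small_data(seed = 1),
                                        max_cofactors = 0), integer(0))
  # a strong QTL's interval is selected in nearly all replicates
  hits <- 0
  for (s in 1:15) {
    d <- small_data(a = 4, seed = s)
    sel <- select_cofactors_mps(d, alpha_in = 0.01, max_cofactors = 3)
    if (any(sel %in% c(2L, 3L))) hits <- hits + 1 # QTL at 25 cM spans 20-30
  }
  expect_gte(hits, 13)
  # pure noise: mean selection count stays near the stepwise null rate
  cnt <- vapply(1:15, function(s)
    length(select_cofactors_mps(null_data(seed = 100 + s), alpha_in = 0.01,
                                max_cofactors = 10)), numeric(1))
  expect_lt(mean(cnt), 0.01 * 10 * 3) # alpha_in x #intervals, 3x slack
})

test_that("scan grids are consistent across step sizes", {
  d <- small_data(seed = 2)
  cof <- select_cofactors_mps(d, max_cofactors = 2)
  p1 <- scan_1d(d, cof, step_cM = 1)
  p10 <- scan_1d(d, cof, step_cM = 10)
  shared <- merge(p1, p10, by = c("chrom", "pos_cM"))
  expect_gt(nrow(shared), 0)
  expect_equal(shared$F.x, shared$F.y, tolerance = 1e-10)
})

test_that("permutation threshold: definition, monotonicity, reproducibility", {
  d <- small_data(seed = 3)
  thr <- permutation_threshold(d, "1D", n_perm = 100, alpha = 0.05, seed = 5,
                               step_cM = 10)
  expect_equal(thr$threshold, sort(thr$max_F)[95])
  thr2 <- permutation_threshold(d, "1D", n_perm = 100, alpha = 0.01, seed = 5,
                                step_cM = 10)
  expect_gte(thr2$threshold, thr$threshold)
  thr3 <- permutation_threshold(d, "1D", n_perm = 100, alpha = 0.05, seed = 5,
                                step_cM = 10)
  expect_identical(thr$max_F, thr3$max_F)
  expect_error(permutation_threshold(d, "1D", n_perm = 10, alpha = 0.05),
               "n_perm")
})

test_that("peak calling: local maxima, merging, tie-breaking", {
  prof <- data.frame(chrom = 1L, pos_cM = seq(0, 50, by = 5),
                     F = c(1, 2, 3, 3.5, 3, 2, 1, 0.5, 0.4, 0.3, 0.2))
  expect_equal(nrow(call_peaks(prof, threshold = 4)), 0)
  pk <- call_peaks(prof, threshold = 2)
  expect_equal(pk$pos_cM, 15)
  # two peaks 5 cM apart merge to the larger
  prof2 <- data.frame(chrom = 1L, pos_cM = seq(0, 30, by = 5),
                      F = c(0, 5, 1, 6, 0, 0, 0))
  pk2 <- call_peaks(prof2, threshold = 2, min_separation_cM = 20)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$pos_cM, 15)
  # distinct chromosomes are never merged
  prof3 <- rbind(prof2, transform(prof2, chrom = 2L))
  expect_equal(nrow(call_peaks(prof3, 2, 20)), 2)
})

test_that("pair peak suppression honours both orientations", {
  prof <- data.frame(chrom_i = c(1, 1, 2), pos_i = c(10, 15, 40),
                     chrom_j = c(2, 2, 1), pos_j = c(40, 44, 12),
                     F = c(9, 8, 7))
  pk <- call_pair_peaks(prof, threshold = 5, min_separation_cM = 20)
  expect_equal(nrow(pk), 1) # rows 2 and 3 are suppressed (3 is swapped)
  expect_equal(pk$F, 9)
})

test_that("excluded cofactor leaves the no-cofactor F untouched", {
  d <- small_data(seed = 4)
  f0 <- henderson_f(build_1d_design(d, 1, 25, integer(0)))$F
  f1 <- henderson_f(build_1d_design(d, 1, 25, cofactors = 3L))$F
  expect_equal(f0, f1) # interval 3 contains the tested position
})

test_that("backward elimination discards spurious candidates", {
  dropped_all <- 0
  for (s in 1:8) {
    d <- small_data(a = 3.5, seed = 40 + s, n1 = 80, n2 = 80)
    cand <- data.frame(chrom = c(1L, 1L, 2L), pos_cM = c(25, 48, 30))
    res <- select_final_model(d, cand, NULL, alpha = 0.05, method = "em")
    keep_true <- any(res$qtl$chrom == 1 & abs(res$qtl$pos_cM - 25) < 1)
    no_spur <- !any(res$qtl$chrom == 2) && !any(abs(res$qtl$pos_cM - 48) < 1)
    if (keep_true && no_spur) dropped_all <- dropped_all + 1
  }
  expect_gte(dropped_all, 6)
  # strong true candidates all survive
  d <- small_data(a = 4, seed = 60, n1 = 100, n2 = 100)
  res <- select_final_model(d, data.frame(chrom = 1L, pos_cM = 25), NULL,
                            method = "em")
  expect_equal(nrow(res$qtl), 1)
  # no candidates: population-mean-only result
  res0 <- select_final_model(d, NULL, NULL, method = "em")
  expect_equal(nrow(res0$qtl), 0)
  expect_equal(nrow(res0$estimates$qtl), 0)
})

test_that("map_qtls is deterministic given data and seed", {
  d <- small_data(a = 4, seed = 70, n1 = 80, n2 = 80)
  cfg <- dbx_config(n_perm = 100, gibbs_burn = 100, gibbs_keep = 300,
                    method = "em")
  r1 <- map_qtls(d, cfg, seed = 8)
  r2 <- map_qtls(d, cfg, seed = 8)
  expect_identical(r1$qtl, r2$qtl)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$thresholds, r2$thresholds)
  # the simulated QTL is mapped close to its true position
  expect_true(any(r1$qtl$chrom == 1 & abs(r1$qtl$pos_cM - 25) <= 10))
})

test_that("dbx_config validates inputs", {
  expect_error(dbx_config(alpha = 1.2))
  expect_error(dbx_config(step1_cM = 0))
  cfg <- dbx_config()
  expect_equal(cfg$step1_cM, 1)
  expect_equal(cfg$n_perm, 200)
})
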