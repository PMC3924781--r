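# Monte Carlo harness: matching rules, pairing, summary accounting.

test_that("main-QTL matching windows and false-positive rule", {
  truth_main <- data.frame(id = "Q1", chrom = 1L, pos_cM = 44)
  truth_all <- data.frame(chrom = c(1L, 4L), pos_cM = c(44, 24))
  m <- dbxqtl:::.match_mains(data.frame(chrom = 1L, pos_cM = 50),
                             truth_all, truth_main, 10, 20)
  expect_equal(m$detected, 1L)          # 6 cM away: detected
  expect_equal(m$n_false, 0L)
  m <- dbxqtl:::.match_mains(data.frame(chrom = 1L, pos_cM = 58),
                             truth_all, truth_main, 10, 20)
  expect_true(is.na(m$detected))        # outside the detection window
  expect_equal(m$n_false, 0L)           # but within the FP window
  m <- dbxqtl:::.match_mains(data.frame(chrom = c(1L, 4L), pos_cM = c(80, 30)),
                             truth_all, truth_main, 10, 20)
  expect_equal(m$n_false, 1L)           # chr1:80 far from everything
  # declared near a pure-epistatic QTL is not a false positive
  m <- dbxqtl:::.match_mains(data.frame(chrom = 4L, pos_cM = 23),
                             truth_all, truth_main, 10, 20)
  expect_equal(m$n_false, 0L)
})

test_that("pair matching requires both members within the window", {
  tp <- data.frame(id = "EQ1", chrom_i = 1L, pos_i = 44,
                   chrom_j = 4L, pos_j = 24)
  hit <- data.frame(chrom_i = 1L, pos_i = 40, chrom_j = 4L, pos_j = 30)
  m <- dbxqtl:::.match_pairs(hit, tp, 10)
  expect_equal(m$detected, 1L)
  expect_false(m$swapped[1])
  # swapped orientation also matches
  m <- dbxqtl:::.match_pairs(
    data.frame(chrom_i = 4L, pos_i = 20, chrom_j = 1L, pos_j = 47), tp, 10)
  expect_equal(m$detected, 1L)
  expect_true(m$swapped[1])
  # one member out of window: a false pair
  m <- dbxqtl:::.match_pairs(
    data.frame(chrom_i = 1L, pos_i = 40, chrom_j = 4L, pos_j = 40), tp, 10)
  expect_true(is.na(m$detected))
  expect_equal(m$n_false, 1L)
})

test_that("child seeds are deterministic and within integer range", {
  s1 <- dbxqtl:::.child_seed(42, 1)
  expect_identical(s1, dbxqtl:::.child_seed(42, 1))
  expect_false(s1 == dbxqtl:::.child_seed(42, 2))
  expect_true(all(vapply(1:1000, function(k)
    dbxqtl:::.child_seed(7, k), numeric(1)) < 2^31))
})

test_that("paired model variants consume identical datasets", {
  # tiny paired run on the small map via run_experiment's data_list hook
  sc <- small_scenario(a = 4)
  dl <- lapply(1:3, function(r) simulate_cross(sc, small_map(), 60, 60,
                                               seed = 1000 + r))
  cfg <- dbx_config(n_perm = 100, gibbs_burn = 100, gibbs_keep = 200,
                    method = "em", max_cofactors = 3)
  cfg2 <- cfg; cfg2$include_epistasis <- FALSE
  a <- run_experiment(sc, 60, 60, n_reps = 3, seed = 5, map = small_map(),
                      config = cfg, data_list = dl)
  b <- run_experiment(sc, 60, 60, n_reps = 3, seed = 5, map = small_map(),
                      config = cfg2, data_list = dl)
  # the 1D stage is identical, so main-QTL detection and power agree
  expect_identical(a$qtl$power, b$qtl$power)
  expect_true(all(a$qtl$power >= 0 & a$qtl$power <= 100))
  expect_equal(a$qtl$power, 100 * sum(!is.na(a$qtl_acc[, 1, 1])) / 3)
  expect_true(all(is.na(a$qtl$pos_sd) | a$qtl$pos_sd >= 0))
})

test_that("constitution study returns one summary and FDR per ratio", {
  cfg <- dbx_config(n_perm = 100, gibbs_burn = 100, gibbs_keep = 200,
                    method = "em")
  cs <- constitution_study(ratios = list(c(40, 40), c(20, 60)), n_reps = 1,
                           seed = 3, config = cfg)
  expect_named(cs$tables, c("40:40", "20:60"))
  expect_length(cs$fdr_pairs, 2)
  expect_s3_class(cs$tables[[1]], "summary_table")
  expect_equal(nrow(cs$tables[[1]]$qtl), 5) # five main-effect QTLs tracked
})

test_that("null scenario declares nothing almost always", {
  sc <- qtl_scenario(data.frame(id = "Q1", chrom = 1L, pos_cM = 25,
                                a = 0, d = 0), n_env = 2, h2 = 0.5)
  cfg <- dbx_config(n_perm = 100, gibbs_burn = 50, gibbs_keep = 100,
                    method = "em", max_cofactors = 3)
  declared <- 0
  for (r in 1:4) {
    d <- null_data(seed = 300 + r)
    res <- map_qtls(d, cfg, seed = r)
    declared <- declared + nrow(res$qtl) + nrow(res$pairs)
  }
  expect_lte(declared, 1) # genome-wide alpha = 0.05 per scan
})
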