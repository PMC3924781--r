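# Population and phenotype simulator.

test_that("default map and scenario match the stated simulation world", {
  map <- default_linkage_map()
  expect_equal(nrow(map), 55)
  expect_equal(length(unique(map$chrom)), 5)
  for (c_ in 1:5) {
    p <- map$pos_cM[map$chrom == c_]
    expect_equal(p, seq(0, 100, by = 10))
  }
  sc <- default_qtl_scenario()
  expect_equal(sc$qtl$a[sc$qtl$id == "Q1"], -2.78)
  expect_equal(sc$qtl$d[sc$qtl$id == "Q1"], -3.08)
  expect_equal(sc$qtl$pos_cM, c(44, 75, 50, 73, 15, 24, 79))
  expect_equal(sc$epistasis$aa, c(-3.09, 2.10, -2.60))
  expect_equal(sc$aae[3, ], c(0, 0, 0)) # pure epistatic pair, no QE
  expect_equal(sc$h2, 0.60)
  expect_equal(sc$n_env, 3L)
  sc0 <- default_qtl_scenario(epistasis = FALSE)
  expect_null(sc0$epistasis)
})

test_that("DH lines are homozygous with calibrated segregation and map", {
  set.seed(1)
  map <- default_linkage_map()
  ln <- simulate_lines(map, 10000, "DH")
  expect_true(all(ln$markers %in% c(0, 1)))
  # 1:1 segregation at every locus (chi-square not rejected at alpha=0.001)
  p_seg <- apply(ln$markers[, c(1, 20, 55)], 2, function(g)
    stats::chisq.test(table(factor(g, levels = 0:1)))$p.value)
  expect_true(all(p_seg > 0.001))
  f <- mean(ln$markers[, 1])
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 10000))
  # adjacent-marker recombinants at the Haldane fraction, map recovery
  rec <- mean(ln$markers[, 1] != ln$markers[, 2])
  expect_lt(abs(rec - haldane(10)), 3 * sqrt(haldane(10) * (1 - haldane(10)) / 10000))
  expect_lt(abs(haldane_inverse(rec) - 10), 0.7)
})

test_that("RI lines show map expansion 2r/(1+2r)", {
  set.seed(2)
  ln <- simulate_lines(default_linkage_map(), 10000, "RI")
  r <- haldane(10)
  R <- 2 * r / (1 + 2 * r)
  rec <- mean(ln$markers[, 3] != ln$markers[, 4])
  expect_lt(abs(rec - R), 3 * sqrt(R * (1 - R) / 10000))
})

test_that("double backcross arithmetic and pooled genotype frequencies", {
  set.seed(3)
  sc <- default_qtl_scenario()
  ln <- simulate_lines(default_linkage_map(), 10000, "DH",
                       qtl_positions = sc$qtl[, c("chrom", "pos_cM")])
  pr <- simulate_double_backcross(ln, 5000, 5000)
  expect_equal(sum(pr$origin == "BC_P1"), 5000)
  expect_true(all(pr$geno[pr$origin == "BC_P1", ] %in% c(1, 2)))
  expect_true(all(pr$geno[pr$origin == "BC_P2", ] %in% c(0, 1)))
  g <- pr$geno[, 17]
  se <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(g == 2) - 0.25), se)
  expect_lt(abs(mean(g == 1) - 0.50), 3 * sqrt(0.25 / 10000))
  # implied coefficient moments in the 1:1 mixture
  xA <- g - 1
  xD <- ifelse(g == 1, 0.5, -0.5)
  expect_lt(abs(mean(xA)), 3 * sqrt(0.5 / 10000))
  expect_lt(abs(var(xA) - 0.5), 0.02)
  expect_lt(abs(var(xD) - 0.25), 0.01)
  expect_error(simulate_double_backcross(ln, -1, 10), "non-negative")
})

test_that("phenotype model: degenerate case, additive contrast, calibration", {
  map <- small_map()
  sc0 <- qtl_scenario(data.frame(id = "Q1", chrom = 1L, pos_cM = 25,
                                 a = 0, d = 0), n_env = 2, h2 = 0.5, mu = 7)
  ln <- simulate_lines(map, 50, "DH", sc0$qtl[, c("chrom", "pos_cM")], seed = 1)
  pr <- simulate_double_backcross(ln, 25, 25, seed = 2)
  ph <- simulate_phenotypes(pr, sc0, seed = 3)$pheno
  expect_true(all(ph$value == 7)) # no effects, no residual
  # a single QTL with a = 1.9: homozygote contrast 2a
  sc1 <- qtl_scenario(data.frame(id = "Q1", chrom = 1L, pos_cM = 25,
                                 a = 1.9, d = 0), n_env = 1, h2 = 0.9)
  ln <- simulate_lines(map, 10000, "DH", sc1$qtl[, c("chrom", "pos_cM")],
                       seed = 4)
  pr <- simulate_double_backcross(ln, 5000, 5000, seed = 5)
  pr <- simulate_phenotypes(pr, sc1, seed = 6)
  y <- pr$pheno$value
  gq <- pr$qtl_geno[, 1]
  contrast <- mean(y[gq == 2]) - mean(y[gq == 0])
  expect_lt(abs(contrast - 3.8), 0.1)
  # calibration identities
  sc2 <- qtl_scenario(data.frame(id = "Q1", chrom = 1L, pos_cM = 25,
                                 a = 2, d = 0), n_env = 1, h2 = 0.5)
  s2 <- calibrate_residual_variance(sc2, pr)
  expect_lt(abs(s2 - 2), 0.1) # sigma2 = V_G = a^2 Var(x_A) = 4 * 1/2
  sc3 <- qtl_scenario(sc2$qtl, n_env = 1, h2 = 1)
  expect_equal(calibrate_residual_variance(sc3, pr), 0)
  expect_identical(calibrate_residual_variance(sc2, pr),
                   calibrate_residual_variance(sc2, pr)) # deterministic
})

test_that("seeded simulation is bit-reproducible", {
  a <- simulate_cross(default_qtl_scenario(), n1 = 30, n2 = 30, seed = 11)
  b <- simulate_cross(default_qtl_scenario(), n1 = 30, n2 = 30, seed = 11)
  expect_identical(a$geno, b$geno)
  expect_identical(a$pheno, b$pheno)
  c_ <- simulate_cross(default_qtl_scenario(), n1 = 30, n2 = 30, seed = 12)
  expect_false(identical(a$pheno, c_$pheno))
})

test_that("variance decomposition: realized heritability near target", {
  h2 <- vapply(1:10, function(s)
    attr(simulate_cross(default_qtl_scenario(), seed = s)$pheno,
         "h2_realized"), numeric(1))
  expect_lt(abs(mean(h2) - 0.6), 0.03)
})
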