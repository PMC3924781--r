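# Henderson III F-test and design-matrix assembly.

test_that("hand-computable extra-sum-of-squares example", {
  m <- list(y = c(1, 2, 3, 4), WB = matrix(1, 4, 1),
            WQ = matrix(c(0, 0, 1, 1), 4, 1))
  hf <- henderson_f(m)
  expect_equal(hf$F, 8)
  expect_equal(hf$df1, 1L)
  expect_equal(hf$df2, 2L)
  expect_equal(hf$SSR, 4)
  expect_equal(hf$SSE, 1)
})

test_that("aliased tested block reports inestimable, never F = 0", {
  m <- list(y = rnorm(10), WB = cbind(1, 1:10), WQ = cbind(2 * (1:10)))
  hf <- henderson_f(m)
  expect_identical(hf$status, "inestimable")
  expect_true(is.na(hf$F))
})

test_that("reduction identity and reparameterization invariance", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 40
    WB <- cbind(1, matrix(rnorm(n * 3), n))
    WQ <- matrix(rnorm(n * 2), n)
    y <- rnorm(n)
    hf <- henderson_f(list(y = y, WB = WB, WQ = WQ))
    # SSE(WB) = SSR(bQ|bB) + SSE(W)
    sse_b <- sum(qr.resid(qr(WB), y)^2)
    expect_equal(sse_b, hf$SSR + hf$SSE, tolerance = 1e-8)
    # invertible reparameterization of both blocks leaves F unchanged
    TB <- matrix(rnorm(16), 4); while (abs(det(TB)) < 0.1) TB <- matrix(rnorm(16), 4)
    TQ <- matrix(c(2, 0.5, -1, 3), 2)
    hf2 <- henderson_f(list(y = y, WB = WB %*% TB, WQ = WQ %*% TQ))
    expect_equal(hf$F, hf2$F, tolerance = 1e-6)
    expect_equal(hf$df1, hf2$df1)
  }
})

test_that("null calibration: rejection rate at nominal level", {
  set.seed(7)
  n <- 25
  hits <- 0
  nsim <- 4000
  for (i in seq_len(nsim)) {
    y <- rnorm(n)
    hf <- henderson_f(list(y = y, WB = matrix(1, n, 1),
                           WQ = matrix(rnorm(2 * n), n)))
    if (hf$p_value < 0.05) hits <- hits + 1
  }
  expect_lt(abs(hits / nsim - 0.05), 3 * sqrt(0.05 * 0.95 / nsim))
})

test_that("1D design layout follows the scan model", {
  d <- small_data(seed = 5)                       # 2 environments
  md <- build_1d_design(d, 1, 17, integer(0))
  expect_equal(ncol(md$WQ), 4)                    # a_h, d_h per environment
  expect_equal(ncol(md$WB), 2)                    # environment means only
  expect_equal(length(md$y), nrow(md$WQ))
  # at a marker the coefficients are the degenerate genotype codes
  md0 <- build_1d_design(d, 1, 10, integer(0))
  expect_true(all(md0$WQ %in% c(0, 1, -1, 0.5, -0.5)))
  # cofactors inside the exclusion window are dropped
  md1 <- build_1d_design(d, 1, 17, cofactors = c(2L), window = 10)
  expect_equal(ncol(md1$WB), 2)                   # interval 2 is adjacent
  md2 <- build_1d_design(d, 1, 17, cofactors = c(9L), window = 10)
  expect_equal(ncol(md2$WB), 2 + 8)               # other-chromosome cofactor
})

test_that("2D design layout and pair validity", {
  d <- small_data(seed = 6)
  md <- build_2d_design(d, 1, 17, 2, 33)
  expect_equal(ncol(md$WQ), 2)                    # one aa column per env
  expect_error(build_2d_design(d, 1, 12, 1, 17),  # same/adjacent interval
               "distinct")
  dec <- data.frame(chrom = 1L, pos_cM = 25)
  md2 <- build_2d_design(d, 1, 17, 2, 33, declared_qtls = dec)
  expect_equal(ncol(md2$WB), 2 + 4)
})

test_that("scan engines agree with direct Henderson fits", {
  d <- small_data(seed = 7)
  cof <- c(3L, 8L)
  prof <- scan_1d(d, cof, step_cM = 5)
  for (i in c(2, 5, 9)) {
    hf <- henderson_f(build_1d_design(d, prof$chrom[i], prof$pos_cM[i], cof))
    expect_equal(prof$F[i], hf$F, tolerance = 1e-8)
  }
  dec <- data.frame(chrom = 1L, pos_cM = 25)
  prof2 <- scan_2d(d, dec, step_cM = 25)
  for (i in seq_len(min(4, nrow(prof2)))) {
    hf <- henderson_f(build_2d_design(d, prof2$chrom_i[i], prof2$pos_i[i],
                                      prof2$chrom_j[i], prof2$pos_j[i],
                                      declared_qtls = dec))
    expect_equal(prof2$F[i], hf$F, tolerance = 1e-8)
  }
})
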