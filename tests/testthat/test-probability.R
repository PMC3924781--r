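# Probability kernel: recombination arithmetic, Table-style conditional
# probabilities, and the effect-coefficient rules.

test_that("Haldane map function and its inverse", {
  expect_identical(haldane(0), 0)
  expect_equal(haldane(10), 0.090635, tolerance = 1e-5)
  expect_equal(haldane(1000), 0.5, tolerance = 1e-8)
  expect_true(all(diff(haldane(seq(0, 200, by = 5))) > 0))
  expect_error(haldane(-1), "non-negative")
  expect_equal(haldane_inverse(haldane(17.3)), 17.3, tolerance = 1e-10)
})

test_that("split_interval composes sub-distances under no interference", {
  g <- split_interval(0, 10)
  expect_equal(g$r1, 0)
  expect_equal(g$r2, 0.090635, tolerance = 1e-5)
  expect_equal(g$r, g$r2)
  g <- split_interval(5, 5)
  expect_equal(g$r1, g$r2)
  expect_equal(g$r1, 0.047581, tolerance = 1e-5)
  expect_equal(g$r, 0.090635, tolerance = 1e-5)          # Haldane additivity
  expect_equal(g$r, g$r1 + g$r2 - 2 * g$r1 * g$r2)
  expect_equal(split_interval(10, 10)$r, 0.164840, tolerance = 1e-5)
  expect_equal(g$s, 1 - g$r)
})

test_that("conditional probabilities reproduce the closed-form cells", {
  g <- geom_from_r(0.1, 0.1)
  expect_equal(unname(conditional_probs("hom", "hom", "P1", "DH", g)),
               c(0.987805, 0.012195, 0), tolerance = 1e-6)
  expect_equal(unname(conditional_probs("hom", "het", "P1", "DH", g)),
               c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(unname(conditional_probs("hom", "hom", "P1", "RI", g)),
               c(0.961538, 0.038462, 0), tolerance = 1e-6)
  # P2 progeny carry no P1/P1 QTL genotype
  p <- conditional_probs("het", "het", "P2", "DH", g)
  expect_equal(unname(p[1]), 0)
  expect_equal(unname(p[2]), 0.987805, tolerance = 1e-6)
})

test_that("QTL at a marker collapses to a point mass; zero-r conflicts error", {
  g <- geom_from_r(0, 0.2)
  for (right in c("hom", "het")) {
    p <- conditional_probs("hom", right, "P1", "DH", g)
    expect_equal(unname(p[1]), 1) # left marker determines the QTL state
  }
  expect_error(conditional_probs("hom", "het", "P1", "DH", geom_from_r(0, 0)),
               "inconsistent")
})

test_that("DH cells match brute-force gamete enumeration on a grid", {
  rs <- seq(0.01, 0.49, length.out = 5)
  worst <- 0
  for (r1 in rs) for (r2 in rs) {
    g <- geom_from_r(r1, r2)
    for (left in c("hom", "het")) for (right in c("hom", "het")) {
      p <- conditional_probs(left, right, "P1", "DH", g)
      q1 <- dh_gamete_oracle(as.numeric(left == "hom"),
                             as.numeric(right == "hom"), r1, r2)
      worst <- max(worst, abs(p[1] - q1))
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("RI cells match the Markov RI-chain oracle exactly", {
  # The RI column treats the fixed-line genome as a Markov chain with
  # effective recombination R = 2r/(1+2r) per interval; check the cell
  # formulas against the chain conditional computed independently.
  for (r in list(c(0.05, 0.2), c(0.1, 0.1), c(0.3, 0.45))) {
    R1 <- 2 * r[1] / (1 + 2 * r[1])
    R2 <- 2 * r[2] / (1 + 2 * r[2])
    g <- geom_from_r(r[1], r[2])
    for (left in 0:1) for (right in 0:1) {
      p <- conditional_probs(c("het", "hom")[left + 1],
                             c("het", "hom")[right + 1], "P1", "RI", g)
      t1 <- if (left == 1) c(1 - R1, R1) else c(R1, 1 - R1)  # P(mid|left)
      t2 <- function(mid) if (mid == right) 1 - R2 else R2
      q1 <- t1[1] * t2(1) / (t1[1] * t2(1) + t1[2] * t2(0))
      expect_equal(unname(p[1]), q1, tolerance = 1e-12)
    }
  }
})

test_that("the RI cells approximate exact three-locus selfing closely", {
  # Exact selfing-to-fixation enumeration shows the fixed selfed-RI
  # genome is not exactly Markov at three loci; the cell formulas are the
  # Markov approximation.  Document the approximation magnitude.
  or <- ri_selfing_oracle(0.1, 0.1)
  g <- geom_from_r(0.1, 0.1)
  worst <- 0
  for (left in 0:1) for (right in 0:1) {
    p <- conditional_probs(c("het", "hom")[left + 1],
                           c("het", "hom")[right + 1], "P1", "RI", g)
    worst <- max(worst, abs(p[1] - or$q1(left, right)))
  }
  expect_gt(worst, 1e-4)  # genuinely not exact
  expect_lt(worst, 0.02)  # but close
})

test_that("P1/P2 mirror symmetry maps (p1,p2,p3) to (p3,p2,p1)", {
  rs <- c(0.02, 0.15, 0.4)
  for (r1 in rs) for (r2 in rs) {
    g <- geom_from_r(r1, r2)
    for (lt in c("DH", "RI")) {
      for (left in c("hom", "het")) for (right in c("hom", "het")) {
        a <- conditional_probs(left, right, "P1", lt, g)
        b <- conditional_probs(left, right, "P2", lt, g)
        expect_equal(unname(a), unname(rev(b)), tolerance = 1e-12)
      }
    }
  }
})

test_that("effect coefficients follow the stated coding", {
  expect_equal(effect_coefficients(c(1, 0, 0)), list(x_A = 1, x_D = -0.5))
  expect_equal(effect_coefficients(c(0, 1, 0)), list(x_A = 0, x_D = 0.5))
  expect_equal(effect_coefficients(c(0, 0, 1)), list(x_A = -1, x_D = -0.5))
  co <- effect_coefficients(c(0.987805, 0.012195, 0))
  expect_equal(co$x_A, 0.987805)
  expect_equal(co$x_D, -0.487805)
  expect_error(effect_coefficients(c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("epistasis coefficient is the bounded product", {
  expect_identical(epistasis_coefficient(1, -1), -1)
  expect_identical(epistasis_coefficient(0, 0.7), 0)
  expect_equal(epistasis_coefficient(0.987805, 0.987805), 0.975759,
               tolerance = 1e-6)
  expect_error(epistasis_coefficient(1.2, 0), "\\[-1, 1\\]")
})

test_that("marker cofactor coefficients", {
  expect_equal(marker_cofactor_coefficients("MM"), list(xi = 1, zeta = -0.5))
  expect_equal(marker_cofactor_coefficients("Mm"), list(xi = 0, zeta = 0.5))
  expect_equal(marker_cofactor_coefficients("mm"), list(xi = -1, zeta = -0.5))
  expect_equal(marker_cofactor_coefficients(c(2, 1, 0)),
               list(xi = c(1, 0, -1), zeta = c(-0.5, 0.5, -0.5)))
  expect_error(marker_cofactor_coefficients("M"), "MM")
})

test_that("probability_table exports a normalized audit grid", {
  tab <- probability_table(c(0.1, 0.2), c(0.1, 0.3), "DH")
  expect_equal(nrow(tab), 2 * 2 * 2 * 4)
  expect_true(all(abs(tab$p1 + tab$p2 + tab$p3 - 1) < 1e-12))
  expect_true(all(tab$p3[tab$side == "P1"] == 0))
  expect_true(all(tab$p1[tab$side == "P2"] == 0))
})
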