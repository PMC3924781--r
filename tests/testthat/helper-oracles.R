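# Independent oracles for the conditional-probability kernel.

# DH lines: brute-force enumeration of the 8 three-locus F1 gamete classes
# under no interference.  Returns P(QTL allele = P1 | flanking gamete
# alleles gl, gr), with r1, r2 the marker-QTL recombination fractions.
dh_gamete_oracle <- function(gl, gr, r1, r2) {
  num <- 0; den <- 0
  for (gq in c(0, 1)) {
    f <- 0.5 * (if (gl != gq) r1 else 1 - r1) * (if (gq != gr) r2 else 1 - r2)
    den <- den + f
    if (gq == 1) num <- num + f
  }
  num / den
}

# Selfed RI lines: iterate the three-locus selfing process from the F1
# diplotype to fixation, tracking the distribution over unordered
# haplotype pairs; the fixed-line haplotype distribution then gives the
# conditional probability of the middle locus given the flanks.
ri_selfing_oracle <- function(r1, r2, max_gen = 5000, tol = 1e-14) {
  haps <- as.matrix(expand.grid(l1 = 0:1, l2 = 0:1, l3 = 0:1))
  nh <- nrow(haps)
  # gamete distribution from a diplotype (ordered haplotype indices i, j)
  gamete_dist <- function(i, j) {
    g <- numeric(nh)
    for (s1 in 0:1) for (s2 in 0:1) for (s3 in 0:1) {
      pp <- 0.5 * (if (s1 != s2) r1 else 1 - r1) *
        (if (s2 != s3) r2 else 1 - r2)
      gam <- c(if (s1 == 0) haps[i, 1] else haps[j, 1],
               if (s2 == 0) haps[i, 2] else haps[j, 2],
               if (s3 == 0) haps[i, 3] else haps[j, 3])
      k <- which(haps[, 1] == gam[1] & haps[, 2] == gam[2] &
                   haps[, 3] == gam[3])
      g[k] <- g[k] + pp
    }
    g
  }
  # states: ordered pairs collapsed by symmetry is unnecessary at this size
  dist <- matrix(0, nh, nh)
  i_p1 <- which(haps[, 1] == 1 & haps[, 2] == 1 & haps[, 3] == 1)
  i_p2 <- which(haps[, 1] == 0 & haps[, 2] == 0 & haps[, 3] == 0)
  dist[i_p1, i_p2] <- 1
  gd <- lapply(seq_len(nh), function(i)
    lapply(seq_len(nh), function(j) gamete_dist(i, j)))
  for (gen in seq_len(max_gen)) {
    newd <- matrix(0, nh, nh)
    het_mass <- 0
    for (i in seq_len(nh)) for (j in seq_len(nh)) {
      w <- dist[i, j]
      if (w == 0) next
      if (i == j) { newd[i, j] <- newd[i, j] + w; next }
      het_mass <- het_mass + w
      g <- gd[[i]][[j]]
      newd <- newd + w * outer(g, g)
    }
    dist <- newd
    if (het_mass < tol) break
  }
  pi_h <- diag(dist) / sum(diag(dist))
  list(haps = haps, pi = pi_h,
       q1 = function(gl, gr) {
         sel <- haps[, 1] == gl & haps[, 3] == gr
         sum(pi_h[sel & haps[, 2] == 1]) / sum(pi_h[sel])
       })
}

# Geometry helper used across tests.
geom_from_r <- function(r1, r2) {
  structure(list(r1 = r1, r2 = r2, r = r1 + r2 - 2 * r1 * r2,
                 s = 1 - (r1 + r2 - 2 * r1 * r2), s1 = 1 - r1, s2 = 1 - r2),
            class = "interval_geometry")
}
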