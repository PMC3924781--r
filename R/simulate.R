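# Gamete-level simulation of DH/RI lines, the two backcross progeny sets,
# and multi-environment phenotypes with heritability calibration.

# Deterministic child seed from a master seed and a counter, kept below
# 2^31 so it is a valid R integer seed.
.child_seed <- function(master, k) {
  as.integer((as.numeric(master) + 48271 * as.numeric(k)) %% 2147483629)
}

#' Simulate DH or selfed RI line genotypes
#'
#' Each DH line is a single F1 gamete doubled: allele origins along a
#' chromosome follow a Markov chain over the ordered loci with transition
#' probabilities equal to the pairwise Haldane recombination fractions.
#' Selfed RI lines use the map-expanded effective recombination
#' R = 2r/(1 + 2r); the multilocus selfed-RI genome is likewise Markov
#' under no interference.
#'
#' @param map A `linkage_map`.
#' @param n Number of lines.
#' @param line_type `"DH"` or `"RI"`.
#' @param qtl_positions Optional data.frame with columns `chrom`, `pos_cM`:
#'   extra (unobserved) loci simulated jointly with the markers, e.g. the
#'   true QTLs of a scenario.
#' @param seed Optional integer seed.
#' @return A list of class `line_panel`: `markers` (n x n_markers 0/1
#'   matrix, 1 = P1 allele), `qtl` (n x n_qtl matrix or NULL), `map`,
#'   `line_type`.
#' @export
simulate_lines <- function(map, n, line_type = c("DH", "RI"),
                           qtl_positions = NULL, seed = NULL) {
  line_type <- match.arg(line_type)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  loci <- data.frame(chrom = map$chrom, pos_cM = map$pos_cM,
                     is_marker = TRUE, idx = seq_len(nrow(map)))
  if (!is.null(qtl_positions) && nrow(qtl_positions) > 0) {
    loci <- rbind(loci, data.frame(chrom = qtl_positions$chrom,
                                   pos_cM = qtl_positions$pos_cM,
                                   is_marker = FALSE,
                                   idx = seq_len(nrow(qtl_positions))))
  }
  loci <- loci[order(loci$chrom, loci$pos_cM, -loci$is_marker), ]
  markers <- matrix(NA_real_, n, nrow(map))
  qtl <- if (!is.null(qtl_positions) && nrow(qtl_positions) > 0)
    matrix(NA_real_, n, nrow(qtl_positions)) else NULL
  for (c_ in unique(loci$chrom)) {
    lc <- loci[loci$chrom == c_, , drop = FALSE]
    r <- haldane(diff(lc$pos_cM))
    if (line_type == "RI") r <- 2 * r / (1 + 2 * r)
    g <- matrix(0, n, nrow(lc))
    g[, 1] <- stats::rbinom(n, 1, 0.5)
    for (k in seq_along(r)) {
      # duplicated positions (QTL exactly at a marker) have r = 0
      flip <- stats::rbinom(n, 1, r[k])
      g[, k + 1] <- (g[, k] + flip) %% 2
    }
    for (k in seq_len(nrow(lc))) {
      if (lc$is_marker[k]) markers[, lc$idx[k]] <- g[, k]
      else qtl[, lc$idx[k]] <- g[, k]
    }
  }
  colnames(markers) <- map$marker
  structure(list(markers = markers, qtl = qtl, map = map,
                 line_type = line_type), class = "line_panel")
}

#' Cross a line panel to both parents
#'
#' Produces the double backcross progeny set: `n1` progeny from crossing
#' lines to parent P1 and `n2` from crossing to parent P2.  A DH/RI line
#' contributes its (homozygous) haplotype as the gamete; the parent
#' contributes its fixed gamete.  One progeny per sampled line; lines are
#' sampled with replacement if the panel is smaller than n1 + n2.
#'
#' @param lines A `line_panel` from [simulate_lines()].
#' @param n1,n2 Progeny counts for the P1-side and P2-side backcrosses.
#' @param seed Optional integer seed.
#' @return A list of class `progeny_data` with fields `map`, `geno`
#'   (progeny x markers, coded as the count of P1 alleles: 2/1/0), `origin`
#'   (`"BC_P1"`/`"BC_P2"`), `line_type`, `qtl_geno` (true QTL genotypes, if
#'   the panel carried QTL loci), `pheno` (NULL until phenotypes are
#'   simulated or read).
#' @export
simulate_double_backcross <- function(lines, n1, n2, seed = NULL) {
  stopifnot(inherits(lines, "line_panel"))
  if (n1 < 0 || n2 < 0) stop("n1 and n2 must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  nl <- nrow(lines$markers)
  idx <- if (nl >= n) sample.int(nl, n) else sample.int(nl, n, replace = TRUE)
  gam <- lines$markers[idx, , drop = FALSE]
  parent <- rep(c(1, 0), c(n1, n2)) # P1 gamete carries the P1 allele
  geno <- gam + parent
  qtl_geno <- NULL
  if (!is.null(lines$qtl)) qtl_geno <- lines$qtl[idx, , drop = FALSE] + parent
  structure(list(map = lines$map,
                 geno = geno,
                 origin = rep(c("BC_P1", "BC_P2"), c(n1, n2)),
                 line_type = lines$line_type,
                 qtl_geno = qtl_geno,
                 pheno = NULL),
            class = "progeny_data")
}

# True coefficient matrices (known-genotype coding) for scenario QTLs.
.true_coefficients <- function(progeny, scenario) {
  g <- progeny$qtl_geno
  if (is.null(g))
    stop("progeny carry no true QTL genotypes; simulate with qtl_positions",
         call. = FALSE)
  if (ncol(g) != nrow(scenario$qtl))
    stop("QTL genotype matrix does not match the scenario", call. = FALSE)
  xA <- g - 1
  xD <- ifelse(g == 1, 0.5, -0.5)
  epi <- scenario$epistasis
  xAA <- NULL
  if (!is.null(epi) && nrow(epi) > 0) {
    ii <- match(epi$qtl_i, scenario$qtl$id)
    jj <- match(epi$qtl_j, scenario$qtl$id)
    xAA <- xA[, ii, drop = FALSE] * xA[, jj, drop = FALSE]
  }
  list(xA = xA, xD = xD, xAA = xAA)
}

# Per-individual-by-environment matrix of summed genetic contributions.
.genetic_values <- function(progeny, scenario) {
  co <- .true_coefficients(progeny, scenario)
  p <- scenario$n_env
  G <- matrix(0, nrow(progeny$geno), p)
  for (h in seq_len(p)) {
    G[, h] <- co$xA %*% (scenario$qtl$a + scenario$ae[, h]) +
      co$xD %*% (scenario$qtl$d + scenario$de[, h])
    if (!is.null(co$xAA))
      G[, h] <- G[, h] + co$xAA %*% (scenario$epistasis$aa + scenario$aae[, h])
  }
  G
}

#' Residual variance implied by the scenario heritability
#'
#' Computes the empirical genetic variance V_G of the summed genetic terms
#' (main + epistatic + environment-interaction contributions) over all
#' individuals and environments of the realized design, and returns
#' `sigma2_eps = V_G (1 - h2) / h2`.  Deterministic given the genotypes.
#'
#' @param scenario A `qtl_scenario`.
#' @param progeny A `progeny_data` carrying true QTL genotypes.
#' @return The residual variance `sigma2_eps`.
#' @export
calibrate_residual_variance <- function(scenario, progeny) {
  if (scenario$h2 <= 0) stop("h2 must be positive", call. = FALSE)
  G <- .genetic_values(progeny, scenario)
  vg <- stats::var(as.vector(G))
  if (vg == 0 && scenario$h2 < 1)
    stop("genetic variance is zero but h2 < 1: residual variance undefined",
         call. = FALSE)
  vg * (1 - scenario$h2) / scenario$h2
}

#' Simulate multi-environment phenotypes
#'
#' Generates `y = mu + sum(a x_A) + sum(d x_D) + sum(aa x_AA) + e_h +
#' sum(ae_h x_A) + sum(de_h x_D) + sum(aae_h x_AA) + eps` for every
#' individual and environment, using the true (known-genotype) QTL
#' coefficients of the simulated progeny.  The environment-interaction
#' deviations take the scenario's fixed per-environment values; `e_h` is
#' drawn once per environment from N(0, sigma2_env); the residual variance
#' is calibrated to the scenario heritability unless supplied.
#'
#' @param progeny A `progeny_data`.
#' @param scenario A `qtl_scenario`.
#' @param seed Optional integer seed.
#' @param sigma2_eps Optional residual variance override.
#' @return The `progeny_data` with a `pheno` data.frame (`env`, `id`,
#'   `value`) attached, plus attributes `sigma2_eps`, `V_G` and
#'   `h2_realized` on the pheno table.
#' @export
simulate_phenotypes <- function(progeny, scenario, seed = NULL,
                                sigma2_eps = NULL) {
  stopifnot(inherits(progeny, "progeny_data"), inherits(scenario, "qtl_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(progeny$geno)
  p <- scenario$n_env
  G <- .genetic_values(progeny, scenario)
  if (is.null(sigma2_eps)) {
    vg <- stats::var(as.vector(G))
    sigma2_eps <- if (vg == 0) 0 else vg * (1 - scenario$h2) / scenario$h2
  }
  e_env <- if (scenario$sigma2_env > 0)
    stats::rnorm(p, 0, sqrt(scenario$sigma2_env)) else rep(0, p)
  eps <- matrix(stats::rnorm(n * p, 0, sqrt(sigma2_eps)), n, p)
  Y <- scenario$mu + sweep(G + eps, 2, e_env, "+")
  pheno <- data.frame(env = rep(seq_len(p), each = n),
                      id = rep(seq_len(n), p),
                      value = as.vector(Y))
  vg <- stats::var(as.vector(G))
  attr(pheno, "sigma2_eps") <- sigma2_eps
  attr(pheno, "V_G") <- vg
  attr(pheno, "h2_realized") <-
    if (vg + stats::var(as.vector(eps)) > 0)
      vg / (vg + stats::var(as.vector(eps))) else NA_real_
  progeny$pheno <- pheno
  progeny$truth <- list(scenario = scenario)
  progeny
}

#' Simulate a complete double backcross experiment
#'
#' Convenience wrapper: simulates a line panel (with the scenario's QTL
#' loci), crosses it to both parents, and generates phenotypes.
#'
#' @param scenario A `qtl_scenario` (default [default_qtl_scenario()]).
#' @param map A `linkage_map` (default [default_linkage_map()]).
#' @param n1,n2 Backcross progeny counts (default 150:150).
#' @param line_type `"DH"` or `"RI"`.
#' @param seed Optional integer seed.
#' @return A `progeny_data` with phenotypes and simulation truth attached.
#' @export
simulate_cross <- function(scenario = default_qtl_scenario(),
                           map = default_linkage_map(),
                           n1 = 150, n2 = 150,
                           line_type = c("DH", "RI"), seed = NULL) {
  line_type <- match.arg(line_type)
  if (!is.null(seed)) set.seed(seed)
  lines <- simulate_lines(map, n1 + n2, line_type,
                          qtl_positions = scenario$qtl[, c("chrom", "pos_cM")])
  prog <- simulate_double_backcross(lines, n1, n2)
  simulate_phenotypes(prog, scenario)
}
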