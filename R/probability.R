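# Recombination arithmetic and conditional QTL-genotype probabilities for
# the two backcross sides of an immortal double backcross population.

# Numerical guard: recombination fractions below this are treated as exact
# zero so that r-denominators never produce 0/0.
.R_EPS <- 1e-8

#' Haldane map function
#'
#' Converts genetic map distance to a recombination fraction assuming no
#' crossover interference, \eqn{r = (1 - e^{-2d})/2} with \eqn{d} in Morgans.
#'
#' @param distance_cM Non-negative genetic distance(s) in centiMorgans.
#' @return Recombination fraction(s) in \[0, 0.5).
#' @examples
#' haldane(10)   # 0.0906
#' haldane(0)    # 0
#' @export
haldane <- function(distance_cM) {
  if (any(is.na(distance_cM)) || any(distance_cM < 0))
    stop("map distance must be non-negative", call. = FALSE)
  0.5 * (1 - exp(-2 * distance_cM / 100))
}

#' Inverse Haldane map function
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @return Map distance(s) in centiMorgans.
#' @export
haldane_inverse <- function(r) {
  if (any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)", call. = FALSE)
  -50 * log(1 - 2 * r)
}

#' Recombination geometry of a marker interval containing a putative QTL
#'
#' For a QTL splitting a marker interval into sub-distances `left_dist_cM`
#' and `right_dist_cM`, returns the recombination fractions r1 (left marker
#' to QTL), r2 (QTL to right marker) and r across the whole interval, with
#' their complements s = 1 - r, s1, s2.  Under no interference
#' r = r1 + r2 - 2 r1 r2, which is exactly the Haldane fraction of the
#' summed distance.
#'
#' @param left_dist_cM,right_dist_cM Non-negative distances in cM.
#' @return A list of class `interval_geometry` with fields `r1`, `r2`, `r`,
#'   `s`, `s1`, `s2`.
#' @export
split_interval <- function(left_dist_cM, right_dist_cM) {
  r1 <- haldane(left_dist_cM)
  r2 <- haldane(right_dist_cM)
  r <- r1 + r2 - 2 * r1 * r2
  structure(list(r1 = r1, r2 = r2, r = r,
                 s = 1 - r, s1 = 1 - r1, s2 = 1 - r2),
            class = "interval_geometry")
}

# Probability that the line gamete carries the P1 allele at the QTL, given
# the line-gamete alleles at the two flanking markers (1 = P1 allele,
# 0 = P2 allele).  This is the side-free core of the conditional probability
# table: both backcross sides reduce to it after relabelling genotypes.
.gamete_p1_prob <- function(gl, gr, r1, r2, line_type) {
  r <- r1 + r2 - 2 * r1 * r2
  if (r1 < .R_EPS && r2 < .R_EPS) {
    if (any(gl != gr))
      stop("inconsistent flanking genotypes: recombinant flank class with r = 0",
           call. = FALSE)
    return(as.numeric(gl))
  }
  if (r1 < .R_EPS) return(as.numeric(gl))
  if (r2 < .R_EPS) return(as.numeric(gr))
  if (line_type == "DH") {
    s <- 1 - r; s1 <- 1 - r1; s2 <- 1 - r2
    # flank classes (gl, gr): (1,1) (1,0) (0,1) (0,0)
    p11 <- s1 * s2 / s
    p10 <- s1 * r2 / r
    p01 <- r1 * s2 / r
    p00 <- r1 * r2 / s
  } else { # selfed RI: effective recombination expands to 2r/(1+2r)
    p11 <- 1 / (1 + 4 * r1 * r2)
    p10 <- r2 / (r1 + r2)
    p01 <- r1 / (r1 + r2)
    p00 <- 4 * r1 * r2 / (1 + 4 * r1 * r2)
  }
  ifelse(gl == 1,
         ifelse(gr == 1, p11, p10),
         ifelse(gr == 1, p01, p00))
}

#' Conditional QTL-genotype probabilities given flanking marker genotypes
#'
#' Probabilities of the three QTL genotypes (QQ, Qq, qq, with Q the allele
#' of parent P1) for one progeny individual of a DH (or selfed RI) line
#' backcross, given the genotype class of the two flanking markers.  In a
#' `side = "P1"` progeny the qq class has probability zero; in a
#' `side = "P2"` progeny the QQ class has probability zero.
#'
#' @param left,right Flanking marker states, `"hom"` (homozygous for the
#'   recurrent parent of the cross) or `"het"` (heterozygous).
#' @param side `"P1"` or `"P2"`: which parent the lines were crossed to.
#' @param line_type `"DH"` or `"RI"` (RI by selfing).
#' @param geom An `interval_geometry` from [split_interval()].
#' @return Numeric vector `c(p1, p2, p3)` summing to 1: probabilities of
#'   QQ, Qq and qq.
#' @export
conditional_probs <- function(left, right, side = c("P1", "P2"),
                              line_type = c("DH", "RI"), geom) {
  side <- match.arg(side)
  line_type <- match.arg(line_type)
  stopifnot(inherits(geom, "interval_geometry"))
  if (!left %in% c("hom", "het") || !right %in% c("hom", "het"))
    stop("flank states must be 'hom' or 'het'", call. = FALSE)
  # Line-gamete allele implied by each flank state.  On the P1 side a
  # homozygous marker means the line gamete carried the P1 allele; on the
  # P2 side a heterozygous marker does.
  to_gamete <- function(state) {
    if (side == "P1") as.numeric(state == "hom") else as.numeric(state == "het")
  }
  q1 <- .gamete_p1_prob(to_gamete(left), to_gamete(right),
                        geom$r1, geom$r2, line_type)
  if (side == "P1") c(p1 = q1, p2 = 1 - q1, p3 = 0)
  else              c(p1 = 0, p2 = q1, p3 = 1 - q1)
}

#' Additive and dominance coefficients from conditional probabilities
#'
#' `x_A = p1 - p3` and `x_D = (p2 - p1 - p3)/2`, so that a known QQ, Qq, qq
#' genotype yields (1, -0.5), (0, 0.5), (-1, -0.5) respectively.
#'
#' @param probs Numeric vector `c(p1, p2, p3)` of QTL-genotype probabilities.
#' @return List with components `x_A` and `x_D`.
#' @export
effect_coefficients <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-8 || any(probs < -1e-12))
    stop("probabilities must be non-negative and sum to 1", call. = FALSE)
  list(x_A = unname(probs[1] - probs[3]),
       x_D = unname((probs[2] - probs[1] - probs[3]) / 2))
}

#' Additive-additive epistasis coefficient
#'
#' The epistatic coefficient is the product of the two additive
#' coefficients, `x_AA = x_A(i) * x_A(j)`.
#'
#' @param xA_i,xA_j Additive coefficients in \[-1, 1\].
#' @return The product coefficient.
#' @export
epistasis_coefficient <- function(xA_i, xA_j) {
  if (any(abs(xA_i) > 1 + 1e-12) || any(abs(xA_j) > 1 + 1e-12))
    stop("additive coefficients must lie in [-1, 1]", call. = FALSE)
  xA_i * xA_j
}

#' Marker cofactor coefficients
#'
#' Coefficients of a cofactor marker in the composite interval scan model:
#' xi = 1, 0, -1 and zeta = -0.5, 0.5, -0.5 for genotypes MM, Mm, mm.
#' Genotypes may be given as `"MM"/"Mm"/"mm"` or as the numeric codes
#' 2/1/0 (count of P1 alleles).
#'
#' @param marker_genotype Character or numeric genotype code(s).
#' @return List with components `xi` and `zeta`.
#' @export
marker_cofactor_coefficients <- function(marker_genotype) {
  if (is.character(marker_genotype)) {
    code <- c(MM = 2, Mm = 1, mm = 0)[marker_genotype]
    if (any(is.na(code)))
      stop("marker genotype must be one of 'MM', 'Mm', 'mm'", call. = FALSE)
  } else {
    code <- marker_genotype
    if (any(!code %in% c(0, 1, 2) & !is.na(code)))
      stop("numeric marker codes must be 0, 1 or 2", call. = FALSE)
  }
  list(xi = unname(code - 1),
       zeta = unname(ifelse(is.na(code), NA_real_, ifelse(code == 1, 0.5, -0.5))))
}

#' Export a conditional probability table
#'
#' Tabulates the conditional QTL-genotype probabilities for all flank
#' classes of both backcross sides on a grid of (r1, r2) values, e.g. for
#' audit as CSV.
#'
#' @param r1,r2 Vectors of recombination fractions (crossed as a grid).
#' @param line_type `"DH"` or `"RI"`.
#' @return A data.frame with columns side, line_type, flank_class, r1, r2,
#'   p1, p2, p3.
#' @export
probability_table <- function(r1, r2, line_type = c("DH", "RI")) {
  line_type <- match.arg(line_type)
  grid <- expand.grid(r1 = r1, r2 = r2, side = c("P1", "P2"),
                      left = c("hom", "het"), right = c("hom", "het"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    geom <- structure(list(r1 = g$r1, r2 = g$r2,
                           r = g$r1 + g$r2 - 2 * g$r1 * g$r2),
                      class = "interval_geometry")
    p <- conditional_probs(g$left, g$right, g$side, line_type, geom)
    data.frame(side = g$side, line_type = line_type,
               flank_class = paste(g$left, g$right, sep = "/"),
               r1 = g$r1, r2 = g$r2, p1 = p[1], p2 = p[2], p3 = p[3])
  }))
  rownames(out) <- NULL
  out
}
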