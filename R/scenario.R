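# QTL scenario container: true positions and effects used by the simulator.

#' Construct a QTL scenario
#'
#' Describes the generative truth for the phenotype simulator: QTL
#' positions, fixed additive/dominance effects, additive-additive epistatic
#' pairs, and the per-environment interaction deviations (treated as fixed,
#' known constants by the generator).
#'
#' @param qtl data.frame with columns `id`, `chrom`, `pos_cM`, `a`, `d`.
#' @param ae,de Numeric matrices (nrow(qtl) x n_env) of additive- and
#'   dominance-by-environment deviations; default all zero.
#' @param epistasis data.frame with columns `id`, `qtl_i`, `qtl_j` (ids in
#'   `qtl$id`) and `aa`, or NULL.
#' @param aae Numeric matrix (nrow(epistasis) x n_env) of
#'   epistasis-by-environment deviations; default all zero.
#' @param n_env Number of environments.
#' @param h2 Total broad-sense heritability in (0, 1] used to calibrate the
#'   residual variance.
#' @param mu Population mean.
#' @param sigma2_env Variance of the random environment main effect
#'   (default 0).
#' @return A list of class `qtl_scenario`.
#' @export
qtl_scenario <- function(qtl, ae = NULL, de = NULL, epistasis = NULL,
                         aae = NULL, n_env = 1, h2 = 0.6, mu = 0,
                         sigma2_env = 0) {
  stopifnot(is.data.frame(qtl),
            all(c("id", "chrom", "pos_cM", "a", "d") %in% names(qtl)))
  nq <- nrow(qtl)
  if (is.null(ae)) ae <- matrix(0, nq, n_env)
  if (is.null(de)) de <- matrix(0, nq, n_env)
  ae <- as.matrix(ae); de <- as.matrix(de)
  if (!all(dim(ae) == c(nq, n_env)) || !all(dim(de) == c(nq, n_env)))
    stop("ae and de must be nrow(qtl) x n_env matrices", call. = FALSE)
  if (!is.null(epistasis)) {
    stopifnot(all(c("id", "qtl_i", "qtl_j", "aa") %in% names(epistasis)))
    if (!all(c(epistasis$qtl_i, epistasis$qtl_j) %in% qtl$id))
      stop("epistasis members must reference declared QTL ids", call. = FALSE)
    ne <- nrow(epistasis)
    if (is.null(aae)) aae <- matrix(0, ne, n_env)
    aae <- as.matrix(aae)
    if (!all(dim(aae) == c(ne, n_env)))
      stop("aae must be nrow(epistasis) x n_env", call. = FALSE)
  } else {
    aae <- matrix(0, 0, n_env)
  }
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]", call. = FALSE)
  structure(list(qtl = qtl, ae = ae, de = de, epistasis = epistasis,
                 aae = aae, n_env = as.integer(n_env), h2 = h2, mu = mu,
                 sigma2_env = sigma2_env),
            class = "qtl_scenario")
}

#' Default 7-QTL, 3-environment simulation scenario
#'
#' The built-in genetic architecture used for the package's power and bias
#' studies: five main-effect QTLs (Q1--Q5 on chromosomes 1--5), two pure
#' epistatic QTLs (Q6 on chromosome 4, Q7 on chromosome 5), three
#' additive-additive epistatic pairs EQ1 (Q1--Q6), EQ2 (Q3--Q5) and
#' EQ3 (Q6--Q7, epistasis only), environment-interaction deviations for
#' three environments, and a total heritability of 60\%.
#'
#' @param epistasis Logical: include the epistatic pairs (default TRUE).
#'   With FALSE the same main-effect architecture is kept but all aa and
#'   aae effects are removed (the "no epistasis" generative world).
#' @return A `qtl_scenario`.
#' @export
default_qtl_scenario <- function(epistasis = TRUE) {
  qtl <- data.frame(
    id = paste0("Q", 1:7),
    chrom = c(1L, 2L, 3L, 4L, 5L, 4L, 5L),
    pos_cM = c(44, 75, 50, 73, 15, 24, 79),
    a = c(-2.78, 0.00, 2.90, -3.30, 1.90, 0, 0),
    d = c(-3.08, 2.50, 3.50, -1.90, 0.00, 0, 0),
    stringsAsFactors = FALSE)
  ae <- matrix(0, 7, 3)
  ae[2, ] <- c(-2.00, -0.70, 2.70)
  ae[3, ] <- c(2.60, -1.30, -1.30)
  de <- matrix(0, 7, 3)
  de[4, ] <- c(-2.10, 2.50, -0.40)
  epi <- NULL; aae <- NULL
  if (epistasis) {
    epi <- data.frame(
      id = paste0("EQ", 1:3),
      qtl_i = c("Q1", "Q3", "Q6"),
      qtl_j = c("Q6", "Q5", "Q7"),
      aa = c(-3.09, 2.10, -2.60),
      stringsAsFactors = FALSE)
    aae <- rbind(c(2.52, -0.16, -2.36),
                 c(-2.10, 0.20, 1.90),
                 c(0, 0, 0))
  }
  qtl_scenario(qtl, ae = ae, de = de, epistasis = epi, aae = aae,
               n_env = 3, h2 = 0.60, mu = 0, sigma2_env = 0)
}
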