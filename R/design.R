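# Design-matrix assembly for the composite interval scan models and the
# Henderson III F-test for fixed QTL-effect blocks.

# Relative rank tolerance used throughout (QR pivot / eigenvalue cutoff).
.RANK_TOL <- 1e-10

# Row context of a dataset: one row per (environment, individual) phenotype.
.rows <- function(data) {
  stopifnot(inherits(data, "progeny_data"))
  if (is.null(data$pheno))
    stop("dataset has no phenotypes", call. = FALSE)
  ph <- data$pheno
  keep <- !is.na(ph$value)
  ph <- ph[keep, , drop = FALSE]
  p <- max(ph$env)
  list(ind = ph$id, env = ph$env, y = ph$value, n = nrow(ph), p = p,
       origin = data$origin[ph$id])
}

# Expand per-individual base columns into per-environment design columns:
# each base column becomes p columns, masked by environment indicator.
.env_expand <- function(base, rows) {
  base <- as.matrix(base)
  out <- matrix(0, rows$n, ncol(base) * rows$p)
  for (h in seq_len(rows$p)) {
    m <- rows$env == h
    cols <- (seq_len(ncol(base)) - 1) * rows$p + h
    out[m, cols] <- base[rows$ind[m], , drop = FALSE]
  }
  out
}

# Per-environment intercept columns.
.env_means <- function(rows) {
  out <- matrix(0, rows$n, rows$p)
  out[cbind(seq_len(rows$n), rows$env)] <- 1
  out
}

# xi/zeta coefficients of one marker for all individuals.
.marker_xi_zeta <- function(data, marker_idx) {
  g <- data$geno[, marker_idx]
  list(xi = g - 1, zeta = ifelse(is.na(g), NA_real_, ifelse(g == 1, 0.5, -0.5)))
}

# Cofactor block of a marker interval: xi and zeta of both flanking
# markers, environment-expanded (4 * p columns).
.interval_block <- function(data, intervals, interval, rows) {
  iv <- intervals[intervals$interval == interval, ]
  l <- .marker_xi_zeta(data, iv$left)
  r <- .marker_xi_zeta(data, iv$right)
  .env_expand(cbind(l$xi, l$zeta, r$xi, r$zeta), rows)
}

# Expected additive/dominance coefficients of a putative QTL at (chrom,
# pos) for every individual, from the conditional probabilities given the
# nearest informative flanking markers.
.position_xcoef <- function(data, chrom, pos,
                            intervals = .map_intervals(data$map)) {
  map <- data$map
  interval <- .find_interval(intervals, chrom, pos)
  iv <- intervals[intervals$interval == interval, ]
  n <- nrow(data$geno)
  side_p1 <- data$origin == "BC_P1"
  lt <- data$line_type
  chr_idx <- which(map$chrom == chrom)

  gl_code <- data$geno[, iv$left]
  gr_code <- data$geno[, iv$right]
  l_idx <- rep(iv$left, n)
  r_idx <- rep(iv$right, n)
  # enlarge the interval per individual past missing flanks
  if (anyNA(gl_code) || anyNA(gr_code)) {
    for (i in which(is.na(gl_code))) {
      cand <- chr_idx[chr_idx <= iv$left & !is.na(data$geno[i, chr_idx])]
      l_idx[i] <- if (length(cand)) max(cand) else NA_integer_
    }
    for (i in which(is.na(gr_code))) {
      cand <- chr_idx[chr_idx >= iv$right & !is.na(data$geno[i, chr_idx])]
      r_idx[i] <- if (length(cand)) min(cand) else NA_integer_
    }
  }

  xA <- rep(NA_real_, n)
  xD <- rep(NA_real_, n)
  if (!anyNA(gl_code) && !anyNA(gr_code)) { # complete-data fast path
    r1 <- haldane(pos - iv$lpos)
    r2 <- haldane(iv$rpos - pos)
    gl <- ifelse(side_p1, as.numeric(gl_code == 2), as.numeric(gl_code == 1))
    gr <- ifelse(side_p1, as.numeric(gr_code == 2), as.numeric(gr_code == 1))
    q1 <- .gamete_p1_prob(gl, gr, r1, r2, lt)
    xA <- ifelse(side_p1, q1, q1 - 1)
    xD <- ifelse(side_p1, (1 - 2 * q1) / 2, (2 * q1 - 1) / 2)
    return(list(xA = xA, xD = xD, interval = interval))
  }
  for (key in unique(paste(l_idx, r_idx))) {
    sel <- which(paste(l_idx, r_idx) == key)
    li <- l_idx[sel[1]]; ri <- r_idx[sel[1]]
    if (is.na(li) && is.na(ri)) next # no information: dropped (NA)
    # gamete allele implied by marker code on each side
    gam <- function(code, p1) ifelse(p1, as.numeric(code == 2),
                                     as.numeric(code == 1))
    if (is.na(li) || is.na(ri)) {
      # one-sided information
      mi <- if (is.na(li)) ri else li
      rr <- haldane(abs(pos - map$pos_cM[mi]))
      if (lt == "RI") rr <- 2 * rr / (1 + 2 * rr)
      g <- gam(data$geno[sel, mi], side_p1[sel])
      q1 <- g * (1 - rr) + (1 - g) * rr
    } else {
      r1 <- haldane(pos - map$pos_cM[li])
      r2 <- haldane(map$pos_cM[ri] - pos)
      gl <- gam(data$geno[sel, li], side_p1[sel])
      gr <- gam(data$geno[sel, ri], side_p1[sel])
      q1 <- .gamete_p1_prob(gl, gr, r1, r2, lt)
    }
    xA[sel] <- ifelse(side_p1[sel], q1, q1 - 1)
    xD[sel] <- ifelse(side_p1[sel], (1 - 2 * q1) / 2, (2 * q1 - 1) / 2)
  }
  list(xA = xA, xD = xD, interval = interval)
}

# Cofactor intervals to drop at a tested interval: those whose span lies
# within `window` cM of the tested interval on the same chromosome.
.excluded_cofactors <- function(intervals, cofactors, tested_interval, window) {
  if (length(cofactors) == 0) return(logical(0))
  vapply(cofactors, function(cf)
    .interval_gap(intervals, cf, tested_interval) <= window, logical(1))
}

#' Build the 1D composite interval scan model at a genome position
#'
#' Assembles the testable model for a putative QTL at `pos` on `chrom`:
#' the tested block `WQ` holds environment-specific additive and dominance
#' coefficient columns (expected coefficients from the conditional
#' probability kernel); the background block `WB` holds per-environment
#' means and the xi/zeta terms of the selected cofactor marker intervals,
#' excluding cofactors within `window` cM of the tested interval.
#'
#' @param data A `progeny_data` with phenotypes.
#' @param chrom,pos Tested genome position.
#' @param cofactors Integer vector of cofactor interval indices (as in the
#'   `interval` column of the package's interval table), possibly empty.
#' @param window Cofactor exclusion window in cM (default 10).
#' @return A list of class `testable_model` with fields `y`, `WQ`, `WB`,
#'   `dropped` (number of rows dropped for missing information).
#' @export
build_1d_design <- function(data, chrom, pos, cofactors = integer(0),
                            window = 10) {
  rows <- .rows(data)
  intervals <- .map_intervals(data$map)
  co <- .position_xcoef(data, chrom, pos)
  drop_cf <- .excluded_cofactors(intervals, cofactors, co$interval, window)
  keep_cf <- cofactors[!drop_cf]
  WQ <- .env_expand(cbind(co$xA, co$xD), rows)
  WB <- .env_means(rows)
  for (cf in keep_cf)
    WB <- cbind(WB, .interval_block(data, intervals, cf, rows))
  ok <- stats::complete.cases(WQ) & stats::complete.cases(WB)
  structure(list(y = rows$y[ok], WQ = WQ[ok, , drop = FALSE],
                 WB = WB[ok, , drop = FALSE], dropped = sum(!ok)),
            class = "testable_model")
}

#' Build the 2D epistasis scan model for a position pair
#'
#' The tested block holds the environment-specific additive-additive
#' product columns `x_A(i) * x_A(j)`; the background holds per-environment
#' means, the declared QTLs' additive/dominance terms and the selected
#' marker-interval-pair interaction terms (xi*xi products), excluding pair
#' cofactors within `window` cM of either tested interval.
#'
#' @param data A `progeny_data` with phenotypes.
#' @param chrom_i,pos_i,chrom_j,pos_j The tested position pair; the two
#'   positions must lie in distinct, non-adjacent intervals (or on
#'   different chromosomes).
#' @param declared_qtls data.frame with columns `chrom`, `pos_cM` of
#'   already-declared main-effect QTLs (may be empty/NULL).
#' @param cofactor_pairs Two-column matrix/data.frame of cofactor interval
#'   index pairs (may be empty/NULL).
#' @param window Cofactor exclusion window in cM (default 10).
#' @return A `testable_model`.
#' @export
build_2d_design <- function(data, chrom_i, pos_i, chrom_j, pos_j,
                            declared_qtls = NULL, cofactor_pairs = NULL,
                            window = 10) {
  rows <- .rows(data)
  intervals <- .map_intervals(data$map)
  ci <- .position_xcoef(data, chrom_i, pos_i)
  cj <- .position_xcoef(data, chrom_j, pos_j)
  if (!.valid_pair_intervals(intervals, ci$interval, cj$interval))
    stop("tested positions must lie in distinct non-adjacent intervals",
         call. = FALSE)
  WQ <- .env_expand(ci$xA * cj$xA, rows)
  WB <- .env_means(rows)
  if (!is.null(declared_qtls) && nrow(declared_qtls) > 0) {
    for (q in seq_len(nrow(declared_qtls))) {
      cq <- .position_xcoef(data, declared_qtls$chrom[q],
                            declared_qtls$pos_cM[q])
      WB <- cbind(WB, .env_expand(cbind(cq$xA, cq$xD), rows))
    }
  }
  if (!is.null(cofactor_pairs) && nrow(cofactor_pairs) > 0) {
    for (k in seq_len(nrow(cofactor_pairs))) {
      ia <- cofactor_pairs[k, 1]; ib <- cofactor_pairs[k, 2]
      near <- min(.interval_gap(intervals, ia, ci$interval),
                  .interval_gap(intervals, ia, cj$interval),
                  .interval_gap(intervals, ib, ci$interval),
                  .interval_gap(intervals, ib, cj$interval))
      if (near <= window) next
      WB <- cbind(WB, .pair_product_block(data, intervals, ia, ib, rows))
    }
  }
  ok <- stats::complete.cases(WQ) & stats::complete.cases(WB)
  structure(list(y = rows$y[ok], WQ = WQ[ok, , drop = FALSE],
                 WB = WB[ok, , drop = FALSE], dropped = sum(!ok)),
            class = "testable_model")
}

# A tested pair is valid if the two intervals are on different chromosomes
# or separated by at least one full interval.
.valid_pair_intervals <- function(intervals, int_i, int_j) {
  a <- intervals[intervals$interval == int_i, ]
  b <- intervals[intervals$interval == int_j, ]
  if (a$chrom != b$chrom) return(TRUE)
  abs(int_i - int_j) >= 2
}

# xi*xi interaction columns of an interval pair, environment-expanded.
.pair_product_block <- function(data, intervals, int_a, int_b, rows) {
  a <- intervals[intervals$interval == int_a, ]
  b <- intervals[intervals$interval == int_b, ]
  xa_l <- .marker_xi_zeta(data, a$left)$xi
  xa_r <- .marker_xi_zeta(data, a$right)$xi
  xb_l <- .marker_xi_zeta(data, b$left)$xi
  xb_r <- .marker_xi_zeta(data, b$right)$xi
  .env_expand(cbind(xa_l * xb_l, xa_r * xb_r), rows)
}

#' Henderson III F-test of a fixed QTL-effect block
#'
#' Tests H0: b_Q = 0 in the model `y = WQ bQ + WB bB + eps` by the
#' extra-sum-of-squares quadratic forms: `SSR(bQ | bB)` is the drop in
#' residual sum of squares when the tested block enters the model, and
#' `F = [SSR/(rW - rWB)] / [SSE/(n - rW)]` with ranks computed by a
#' tolerance-based pivoted QR.
#'
#' @param model A `testable_model` (or any list with fields `y`, `WQ`,
#'   `WB`).
#' @return A list with fields `F`, `df1`, `df2`, `p_value`, `SSR`, `SSE`,
#'   and `status` (`"ok"` or `"inestimable"` when the tested block adds no
#'   rank; `F` is NA then, never silently 0).
#' @export
henderson_f <- function(model) {
  y <- model$y
  WB <- as.matrix(model$WB)
  WQ <- as.matrix(model$WQ)
  n <- length(y)
  qb <- qr(WB, tol = .RANK_TOL)
  qw <- qr(cbind(WB, WQ), tol = .RANK_TOL)
  rB <- qb$rank
  rW <- qw$rank
  df1 <- rW - rB
  df2 <- n - rW
  if (df1 == 0L)
    return(list(F = NA_real_, df1 = 0L, df2 = df2, p_value = NA_real_,
                SSR = 0, SSE = sum(qr.resid(qw, y)^2), status = "inestimable"))
  if (df2 <= 0L)
    stop("model is saturated: n must exceed rank(W)", call. = FALSE)
  sse_b <- sum(qr.resid(qb, y)^2)
  sse <- sum(qr.resid(qw, y)^2)
  ssr <- max(sse_b - sse, 0)
  Fv <- (ssr / df1) / (sse / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p_value = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       SSR = ssr, SSE = sse, status = "ok")
}
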