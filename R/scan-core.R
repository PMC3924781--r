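# Vectorized engines behind the 1D and 2D genome scans.  The Henderson III
# quadratic forms are evaluated through shared orthonormal bases of the
# background block so that a scan over all positions (and over many
# permuted phenotype vectors at once) costs a handful of BLAS calls per
# tested-interval group instead of one regression per fit.

# Orthonormal basis of the column space of X (tolerance-based rank).
.ortho_basis <- function(X) {
  qx <- qr(X, tol = .RANK_TOL)
  r <- qx$rank
  list(Q = qr.Q(qx)[, seq_len(r), drop = FALSE], rank = r)
}

# SSR of a tested block Z given a background with orthonormal basis Q, for
# every column of Y simultaneously.  YB = crossprod(Q, Y) precomputed.
# Returns list(SSR = df1 x m matrix collapsed to vector of length m, df1).
.block_ssr <- function(Z, Q, Y, YB) {
  G <- crossprod(Q, Z)
  EE <- crossprod(Z) - crossprod(G)
  TT <- crossprod(Z, Y) - crossprod(G, YB)
  eg <- eigen(EE, symmetric = TRUE)
  tol <- max(eg$values[1], 0) * 1e-8
  keep <- eg$values > tol & eg$values > 0
  df1 <- sum(keep)
  if (df1 == 0L) return(list(SSR = rep(NA_real_, ncol(TT)), df1 = 0L))
  A <- crossprod(eg$vectors[, keep, drop = FALSE], TT)
  list(SSR = colSums(A^2 / eg$values[keep]), df1 = df1)
}

# 1D scan core: F statistics at every grid position for every column of Y.
# Background = per-environment means + cofactor interval blocks, with the
# exclusion-window rule applied per tested interval.
.scan_1d_core <- function(data, cofactors, step, Y, window = 10) {
  rows <- .rows(data)
  Y <- as.matrix(Y)
  m <- ncol(Y)
  intervals <- .map_intervals(data$map)
  grid <- .scan_grid(data$map, step)
  npos <- nrow(grid)
  Fmat <- matrix(NA_real_, npos, m)
  df1v <- integer(npos)
  df2v <- integer(npos)
  col_sq <- colSums(Y^2)

  # group tested intervals by which cofactors survive the exclusion window
  kept_by_interval <- lapply(unique(grid$interval), function(t_)
    cofactors[!.excluded_cofactors(intervals, cofactors, t_, window)])
  names(kept_by_interval) <- as.character(unique(grid$interval))
  sig <- vapply(as.character(grid$interval), function(k)
    paste(kept_by_interval[[k]], collapse = ","), character(1))

  for (s in unique(sig)) {
    pos_idx <- which(sig == s)
    kept <- kept_by_interval[[as.character(grid$interval[pos_idx[1]])]]
    WB <- .env_means(rows)
    for (cf in kept) WB <- cbind(WB, .interval_block(data, intervals, cf, rows))
    if (anyNA(WB)) return(.scan_1d_slow(data, cofactors, grid, Y, window))
    ob <- .ortho_basis(WB)
    YB <- crossprod(ob$Q, Y)
    sseB <- col_sq - colSums(YB^2)
    for (i in pos_idx) {
      co <- .position_xcoef(data, grid$chrom[i], grid$pos_cM[i], intervals)
      Z <- .env_expand(cbind(co$xA, co$xD), rows)
      if (anyNA(Z)) { # missing-information rows: slow per-position path
        Fmat[i, ] <- .scan_pos_slow(data, grid$chrom[i], grid$pos_cM[i],
                                    kept, Y, window)$F
        next
      }
      bs <- .block_ssr(Z, ob$Q, Y, YB)
      if (bs$df1 == 0L) next
      df1v[i] <- bs$df1
      df2v[i] <- rows$n - ob$rank - bs$df1
      sse <- pmax(sseB - bs$SSR, 0)
      Fmat[i, ] <- (bs$SSR / bs$df1) / (sse / df2v[i])
    }
  }
  list(grid = grid, F = Fmat, df1 = df1v, df2 = df2v)
}

# Fallback paths for datasets with missing marker information.  These fit
# the observed phenotype only (single-column Y); permutation scans require
# complete data.
.scan_pos_slow <- function(data, chrom, pos, cofactors, Y, window) {
  if (ncol(as.matrix(Y)) > 1L)
    stop("permutation scans require complete marker data", call. = FALSE)
  md <- build_1d_design(data, chrom, pos, cofactors, window)
  hf <- henderson_f(md)
  list(F = hf$F)
}

.scan_1d_slow <- function(data, cofactors, grid, Y, window) {
  m <- ncol(as.matrix(Y))
  if (m > 1L)
    stop("permutation scans require complete marker data", call. = FALSE)
  Fmat <- matrix(NA_real_, nrow(grid), m)
  df1v <- integer(nrow(grid)); df2v <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    md <- build_1d_design(data, grid$chrom[i], grid$pos_cM[i], cofactors, window)
    hf <- henderson_f(md)
    Fmat[i, 1] <- hf$F; df1v[i] <- hf$df1; df2v[i] <- hf$df2
  }
  list(grid = grid, F = Fmat, df1 = df1v, df2 = df2v)
}

# Expected additive coefficients at a set of grid positions, one column
# per position.
.xA_matrix <- function(data, grid, intervals = .map_intervals(data$map)) {
  out <- matrix(NA_real_, nrow(data$geno), nrow(grid))
  for (i in seq_len(nrow(grid)))
    out[, i] <- .position_xcoef(data, grid$chrom[i], grid$pos_cM[i],
                                intervals)$xA
  out
}

# All valid tested pairs over a position grid (vectorized validity:
# different chromosomes, or at least one full interval between).
.pair_index <- function(intervals, grid) {
  npos <- nrow(grid)
  ij <- which(upper.tri(matrix(0, npos, npos)), arr.ind = TRUE)
  ch <- intervals$chrom[match(grid$interval, intervals$interval)]
  i1 <- grid$interval[ij[, 1]]; i2 <- grid$interval[ij[, 2]]
  ok <- ch[ij[, 1]] != ch[ij[, 2]] | abs(i1 - i2) >= 2
  ij[ok, , drop = FALSE]
}

# Gap in cM between one interval and a vector of intervals (vectorized
# version of .interval_gap).
.interval_gap_vec <- function(intervals, one, many) {
  a <- intervals[intervals$interval == one, ]
  b <- intervals[match(many, intervals$interval), ]
  gap <- pmax(0, pmax(a$lpos, b$lpos) - pmin(a$rpos, b$rpos))
  gap[a$chrom != b$chrom] <- Inf
  gap
}

# 2D scan core: F statistics for additive-additive blocks of position
# pairs, for every column of Y.  `pairs` indexes rows of `grid`.
.scan_2d_core <- function(data, declared_qtls, cofactor_pairs, grid, pairs,
                          Y, window = 10) {
  rows <- .rows(data)
  Y <- as.matrix(Y)
  m <- ncol(Y)
  p <- rows$p
  intervals <- .map_intervals(data$map)
  XA <- .xA_matrix(data, grid, intervals)
  if (anyNA(XA))
    stop("2D scan requires complete marker information", call. = FALSE)
  npair <- nrow(pairs)
  Fmat <- matrix(NA_real_, npair, m)
  df1v <- integer(npair); df2v <- integer(npair)
  col_sq <- colSums(Y^2)

  # declared-QTL background columns (always present)
  WB0 <- .env_means(rows)
  if (!is.null(declared_qtls) && nrow(declared_qtls) > 0) {
    for (q in seq_len(nrow(declared_qtls))) {
      cq <- .position_xcoef(data, declared_qtls$chrom[q],
                            declared_qtls$pos_cM[q], intervals)
      WB0 <- cbind(WB0, .env_expand(cbind(cq$xA, cq$xD), rows))
    }
  }
  ncf <- if (is.null(cofactor_pairs)) 0L else nrow(cofactor_pairs)
  # which pair cofactors survive the window for each tested pair
  keep_mask <- matrix(TRUE, npair, max(ncf, 1L))
  if (ncf > 0) {
    for (k in seq_len(ncf)) {
      ia <- cofactor_pairs[k, 1]; ib <- cofactor_pairs[k, 2]
      gap_to <- function(pos_int) pmin(
        .interval_gap_vec(intervals, ia, pos_int),
        .interval_gap_vec(intervals, ib, pos_int))
      gi <- gap_to(grid$interval[pairs[, 1]])
      gj <- gap_to(grid$interval[pairs[, 2]])
      keep_mask[, k] <- pmin(gi, gj) > window
    }
  }
  sig <- apply(keep_mask, 1, function(z) paste(which(z), collapse = ","))

  env_rows <- lapply(seq_len(p), function(h) which(rows$env == h))
  for (s in unique(sig)) {
    pr_idx <- which(sig == s)
    kept <- if (ncf > 0) which(keep_mask[pr_idx[1], ]) else integer(0)
    WB <- WB0
    for (k in kept)
      WB <- cbind(WB, .pair_product_block(data, intervals,
                                          cofactor_pairs[k, 1],
                                          cofactor_pairs[k, 2], rows))
    ob <- .ortho_basis(WB)
    rb <- ob$rank
    YB <- crossprod(ob$Q, Y)
    sseB <- col_sq - colSums(YB^2)
    U <- XA[, pairs[pr_idx, 1], drop = FALSE] *
      XA[, pairs[pr_idx, 2], drop = FALSE]
    P <- length(pr_idx)
    G <- vector("list", p); TT <- vector("list", p); d <- vector("list", p)
    for (h in seq_len(p)) {
      rh <- env_rows[[h]]
      Uh <- U[rows$ind[rh], , drop = FALSE]
      G[[h]] <- crossprod(ob$Q[rh, , drop = FALSE], Uh)
      TT[[h]] <- crossprod(Uh, Y[rh, , drop = FALSE]) - crossprod(G[[h]], YB)
      d[[h]] <- colSums(Uh^2)
    }
    if (p == 3L) {
      # vectorized 3x3 inverse via the adjugate
      e11 <- d[[1]] - colSums(G[[1]]^2)
      e22 <- d[[2]] - colSums(G[[2]]^2)
      e33 <- d[[3]] - colSums(G[[3]]^2)
      e12 <- -colSums(G[[1]] * G[[2]])
      e13 <- -colSums(G[[1]] * G[[3]])
      e23 <- -colSums(G[[2]] * G[[3]])
      det <- e11 * (e22 * e33 - e23^2) - e12 * (e12 * e33 - e23 * e13) +
        e13 * (e12 * e23 - e22 * e13)
      scale <- pmax(e11, e22, e33, 0)
      ok <- det > (scale^3) * 1e-10 & scale > 0
      i11 <- (e22 * e33 - e23^2) / det
      i22 <- (e11 * e33 - e13^2) / det
      i33 <- (e11 * e22 - e12^2) / det
      i12 <- (e13 * e23 - e12 * e33) / det
      i13 <- (e12 * e23 - e13 * e22) / det
      i23 <- (e12 * e13 - e11 * e23) / det
      T1 <- TT[[1]]; T2 <- TT[[2]]; T3 <- TT[[3]]
      SSR <- i11 * T1^2 + i22 * T2^2 + i33 * T3^2 +
        2 * (i12 * T1 * T2 + i13 * T1 * T3 + i23 * T2 * T3)
      df1 <- 3L
      df2 <- rows$n - rb - df1
      sse <- pmax(sweep(-SSR, 2, sseB, "+"), 0)
      Fg <- (SSR / df1) / (sse / df2)
      Fg[!ok, ] <- NA_real_
      Fmat[pr_idx, ] <- Fg
      df1v[pr_idx] <- ifelse(ok, df1, 0L)
      df2v[pr_idx] <- df2
      # degenerate pairs: exact eigen treatment
      for (kk in which(!ok)) {
        Z <- .env_expand(U[, kk], rows)
        bs <- .block_ssr(Z, ob$Q, Y, YB)
        if (bs$df1 == 0L) next
        df1v[pr_idx[kk]] <- bs$df1
        df2v[pr_idx[kk]] <- rows$n - rb - bs$df1
        sse <- pmax(sseB - bs$SSR, 0)
        Fmat[pr_idx[kk], ] <- (bs$SSR / bs$df1) / (sse / df2v[pr_idx[kk]])
      }
    } else {
      for (kk in seq_len(P)) {
        Z <- .env_expand(U[, kk], rows)
        bs <- .block_ssr(Z, ob$Q, Y, YB)
        if (bs$df1 == 0L) next
        df1v[pr_idx[kk]] <- bs$df1
        df2v[pr_idx[kk]] <- rows$n - rb - bs$df1
        sse <- pmax(sseB - bs$SSR, 0)
        Fmat[pr_idx[kk], ] <- (bs$SSR / bs$df1) / (sse / df2v[pr_idx[kk]])
      }
    }
  }
  list(grid = grid, pairs = pairs, F = Fmat, df1 = df1v, df2 = df2v)
}

# Stratified permutation columns: phenotype values shuffled within each
# environment x backcross-origin cell, preserving the design structure.
.perm_Y <- function(rows, n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strata <- split(seq_len(rows$n), paste(rows$env, rows$origin))
  Y <- matrix(0, rows$n, n_perm)
  for (j in seq_len(n_perm)) {
    yp <- rows$y
    for (idx in strata) yp[idx] <- yp[idx][sample.int(length(idx))]
    Y[, j] <- yp
  }
  Y
}
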