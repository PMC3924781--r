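# The composite-interval mapping workflow: marker-pair cofactor
# pre-selection, 1D and 2D genome scans, permutation thresholds, peak
# calling and final model selection.

#' Tuning configuration for the mapping workflow
#'
#' Collects every tunable of the scan pipeline with its default.  Unknown
#' names are rejected.
#'
#' @param step1_cM 1D scan grid step (cM).
#' @param step2_cM 2D pair-grid step (cM); peaks are refined on a 1 cM
#'   grid around each called pair.
#' @param alpha Genome-wide type-I error for the permutation thresholds.
#' @param n_perm Number of permutations per threshold.
#' @param alpha_in Entry threshold for stepwise cofactor selection.
#' @param max_cofactors Maximum marker intervals selected as 1D cofactors.
#' @param max_pairs Maximum interval pairs selected as 2D cofactors.
#' @param window Cofactor exclusion window around the tested interval (cM).
#' @param min_separation_cM Peak merging distance.
#' @param alpha_model Significance level for backward elimination in final
#'   model selection.
#' @param include_epistasis Run the 2D stage (FALSE reproduces the
#'   "epistasis ignored" model variant).
#' @param method Effect-estimation method: `"gibbs"` (default) or the
#'   deterministic `"em"` fallback.
#' @param gibbs_burn,gibbs_keep Gibbs chain lengths for [map_qtls()].
#' @param match_window_cM Detection window: a declared QTL within this
#'   distance of a true QTL counts as that QTL (Monte Carlo matching).
#' @param fp_window_cM Declared QTLs with no true QTL within this distance
#'   count as false positives.
#' @param cache_thresholds Compute permutation thresholds once on a
#'   reference replicate and reuse across Monte Carlo replicates.
#' @return A list of class `dbx_config`.
#' @export
dbx_config <- function(step1_cM = 1, step2_cM = 5, alpha = 0.05,
                       n_perm = 200, alpha_in = 0.01, max_cofactors = 10,
                       max_pairs = 5, window = 10, min_separation_cM = 20,
                       alpha_model = 0.05, include_epistasis = TRUE,
                       method = c("gibbs", "em"),
                       gibbs_burn = 2000, gibbs_keep = 10000,
                       match_window_cM = 10, fp_window_cM = 20,
                       cache_thresholds = TRUE) {
  method <- match.arg(method)
  cfg <- list(step1_cM = step1_cM, step2_cM = step2_cM, alpha = alpha,
              n_perm = n_perm, alpha_in = alpha_in,
              max_cofactors = max_cofactors, max_pairs = max_pairs,
              window = window, min_separation_cM = min_separation_cM,
              alpha_model = alpha_model, include_epistasis = include_epistasis,
              method = method, gibbs_burn = gibbs_burn,
              gibbs_keep = gibbs_keep, match_window_cM = match_window_cM,
              fp_window_cM = fp_window_cM, cache_thresholds = cache_thresholds)
  stopifnot(cfg$step1_cM > 0, cfg$step2_cM > 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$alpha_in > 0, cfg$alpha_in < 1)
  class(cfg) <- "dbx_config"
  cfg
}

#' Stepwise marker-interval cofactor selection (MPS)
#'
#' Forward stepwise selection over marker intervals: at each step the
#' interval whose flanking-marker terms (xi and zeta of both markers, per
#' environment) give the largest significant Henderson F conditional on
#' the already-selected terms is added, stopping when no candidate reaches
#' `alpha_in` or when `max_cofactors` is hit.
#'
#' @param data A `progeny_data` with phenotypes.
#' @param alpha_in Entry p-value threshold.
#' @param max_cofactors Selection cap.
#' @return Integer vector of selected interval indices (possibly empty).
#' @export
select_cofactors_mps <- function(data, alpha_in = 0.01, max_cofactors = 10) {
  if (max_cofactors <= 0) return(integer(0))
  rows <- .rows(data)
  intervals <- .map_intervals(data$map)
  blocks <- lapply(intervals$interval, function(j)
    .interval_block(data, intervals, j, rows))
  .stepwise_select(rows, .env_means(rows), blocks, alpha_in, max_cofactors)
}

#' Stepwise interval-pair cofactor selection for the 2D stage
#'
#' Selects interval pairs whose xi*xi product terms are significant given
#' the declared QTLs, from the candidate set formed by pairing the
#' 1D-selected cofactor intervals and the intervals containing declared
#' QTLs.
#'
#' @param data A `progeny_data` with phenotypes.
#' @param declared_qtls data.frame (`chrom`, `pos_cM`) of declared QTLs.
#' @param candidate_intervals Interval indices to pair (typically the 1D
#'   cofactors plus the declared QTLs' intervals).
#' @param alpha_in Entry p-value threshold.
#' @param max_pairs Selection cap.
#' @return Two-column matrix of selected interval-index pairs.
#' @export
select_cofactor_pairs <- function(data, declared_qtls, candidate_intervals,
                                  alpha_in = 0.01, max_pairs = 5) {
  empty <- matrix(integer(0), 0, 2)
  if (max_pairs <= 0 || length(candidate_intervals) < 2) return(empty)
  rows <- .rows(data)
  intervals <- .map_intervals(data$map)
  cand <- t(utils::combn(sort(unique(candidate_intervals)), 2))
  ok <- vapply(seq_len(nrow(cand)), function(k)
    .valid_pair_intervals(intervals, cand[k, 1], cand[k, 2]), logical(1))
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  WB <- .env_means(rows)
  if (!is.null(declared_qtls) && nrow(declared_qtls) > 0) {
    for (q in seq_len(nrow(declared_qtls))) {
      cq <- .position_xcoef(data, declared_qtls$chrom[q],
                            declared_qtls$pos_cM[q])
      WB <- cbind(WB, .env_expand(cbind(cq$xA, cq$xD), rows))
    }
  }
  blocks <- lapply(seq_len(nrow(cand)), function(k)
    .pair_product_block(data, intervals, cand[k, 1], cand[k, 2], rows))
  sel <- .stepwise_select(rows, WB, blocks, alpha_in, max_pairs)
  cand[sel, , drop = FALSE]
}

# Shared forward-stepwise engine over candidate blocks.
.stepwise_select <- function(rows, WB, blocks, alpha_in, max_k) {
  y <- rows$y
  n <- rows$n
  selected <- integer(0)
  repeat {
    ob <- .ortho_basis(WB)
    yr <- y - ob$Q %*% crossprod(ob$Q, y)
    sse_cur <- sum(yr^2)
    best <- list(p = Inf, idx = NA_integer_)
    for (k in seq_along(blocks)) {
      if (k %in% selected) next
      Z <- blocks[[k]]
      E <- Z - ob$Q %*% crossprod(ob$Q, Z)
      qe <- qr(E, tol = 1e-8)
      re <- qe$rank
      if (re == 0L) next
      tvec <- crossprod(qr.Q(qe)[, seq_len(re), drop = FALSE], yr)
      ssr <- sum(tvec^2)
      df2 <- n - ob$rank - re
      if (df2 <= 0) next
      Fv <- (ssr / re) / ((sse_cur - ssr) / df2)
      pv <- stats::pf(Fv, re, df2, lower.tail = FALSE)
      if (pv < best$p) best <- list(p = pv, idx = k)
    }
    if (!is.finite(best$p) || best$p >= alpha_in) break
    selected <- c(selected, best$idx)
    WB <- cbind(WB, blocks[[best$idx]])
    if (length(selected) >= max_k) break
  }
  selected
}

#' 1D composite interval scan
#'
#' Tests H0: a_hi = d_hi = 0 for all environments h at every grid position,
#' with the selected cofactor intervals in the background (dropping those
#' within the exclusion window of the tested interval).
#'
#' @param data A `progeny_data` with phenotypes.
#' @param cofactors Integer vector of cofactor interval indices.
#' @param step_cM Grid step.
#' @param window Cofactor exclusion window (cM).
#' @return A data.frame of class `scan_profile`: `chrom`, `pos_cM`, `F`,
#'   `df1`, `df2`, `p_value`.
#' @export
scan_1d <- function(data, cofactors = integer(0), step_cM = 1, window = 10) {
  rows <- .rows(data)
  sc <- .scan_1d_core(data, cofactors, step_cM, rows$y, window)
  out <- data.frame(chrom = sc$grid$chrom, pos_cM = sc$grid$pos_cM,
                    F = sc$F[, 1], df1 = sc$df1, df2 = sc$df2)
  out$p_value <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  class(out) <- c("scan_profile", "data.frame")
  out
}

#' 2D epistasis scan
#'
#' Tests H0: aa_hij = 0 for all environments over a grid of position
#' pairs in distinct non-adjacent intervals, with the declared QTLs' main
#' terms and the selected pair cofactors in the background.
#'
#' @param data A `progeny_data` with phenotypes.
#' @param declared_qtls data.frame (`chrom`, `pos_cM`) of declared
#'   main-effect QTLs (may be empty).
#' @param cofactor_pairs Two-column matrix of cofactor interval pairs.
#' @param step_cM Pair-grid step.
#' @param window Cofactor exclusion window (cM).
#' @return A data.frame of class `scan_profile_2d`: `chrom_i`, `pos_i`,
#'   `chrom_j`, `pos_j`, `F`, `df1`, `df2`, `p_value`.
#' @export
scan_2d <- function(data, declared_qtls = NULL, cofactor_pairs = NULL,
                    step_cM = 5, window = 10) {
  rows <- .rows(data)
  intervals <- .map_intervals(data$map)
  grid <- .scan_grid(data$map, step_cM)
  pairs <- .pair_index(intervals, grid)
  sc <- .scan_2d_core(data, declared_qtls, cofactor_pairs, grid, pairs,
                      rows$y, window)
  .pair_profile(sc, 1L)
}

.pair_profile <- function(sc, col) {
  out <- data.frame(chrom_i = sc$grid$chrom[sc$pairs[, 1]],
                    pos_i = sc$grid$pos_cM[sc$pairs[, 1]],
                    chrom_j = sc$grid$chrom[sc$pairs[, 2]],
                    pos_j = sc$grid$pos_cM[sc$pairs[, 2]],
                    F = sc$F[, col], df1 = sc$df1, df2 = sc$df2)
  out$p_value <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  class(out) <- c("scan_profile_2d", "data.frame")
  out
}

#' Permutation-based genome-wide F threshold
#'
#' Phenotype values are permuted within each environment-by-origin cell;
#' the genome-wide maximum F of each permuted scan is recorded and the
#' empirical (1 - alpha) quantile (order statistic) returned.
#'
#' @param data A `progeny_data` with phenotypes.
#' @param scan_kind `"1D"` or `"2D"`.
#' @param n_perm Number of permutations (>= 100 recommended; must exceed
#'   1/alpha).
#' @param alpha Genome-wide type-I error.
#' @param seed Optional integer seed (threshold is bit-reproducible).
#' @param cofactors 1D cofactor intervals (for `scan_kind = "1D"`).
#' @param declared_qtls,cofactor_pairs Background structure (for `"2D"`).
#' @param step_cM Scan grid step.
#' @param window Exclusion window (cM).
#' @return List with `threshold` and the vector `max_F` of per-permutation
#'   genome-wide maxima.
#' @export
permutation_threshold <- function(data, scan_kind = c("1D", "2D"),
                                  n_perm = 200, alpha = 0.05, seed = NULL,
                                  cofactors = integer(0),
                                  declared_qtls = NULL, cofactor_pairs = NULL,
                                  step_cM = NULL, window = 10) {
  scan_kind <- match.arg(scan_kind)
  if (alpha < 1 / n_perm)
    stop("n_perm too small for requested alpha", call. = FALSE)
  rows <- .rows(data)
  Y <- .perm_Y(rows, n_perm, seed)
  if (scan_kind == "1D") {
    if (is.null(step_cM)) step_cM <- 1
    sc <- .scan_1d_core(data, cofactors, step_cM, Y, window)
  } else {
    if (is.null(step_cM)) step_cM <- 5
    intervals <- .map_intervals(data$map)
    grid <- .scan_grid(data$map, step_cM)
    pairs <- .pair_index(intervals, grid)
    sc <- .scan_2d_core(data, declared_qtls, cofactor_pairs, grid, pairs,
                        Y, window)
  }
  max_F <- apply(sc$F, 2, max, na.rm = TRUE)
  k <- ceiling((1 - alpha) * n_perm)
  list(threshold = sort(max_F)[k], max_F = max_F)
}

#' Call QTL peaks from a 1D scan profile
#'
#' Local maxima above the threshold; maxima closer than
#' `min_separation_cM` on the same chromosome are merged keeping the
#' larger F (ties broken by leftmost position).
#'
#' @param profile A `scan_profile` from [scan_1d()].
#' @param threshold F threshold.
#' @param min_separation_cM Merging distance.
#' @return data.frame (`chrom`, `pos_cM`, `F`), possibly empty.
#' @export
call_peaks <- function(profile, threshold, min_separation_cM = 20) {
  out <- data.frame(chrom = integer(0), pos_cM = numeric(0), F = numeric(0))
  for (c_ in unique(profile$chrom)) {
    pr <- profile[profile$chrom == c_, , drop = FALSE]
    pr <- pr[order(pr$pos_cM), , drop = FALSE]
    f <- pr$F
    f[is.na(f)] <- -Inf
    nloc <- length(f)
    is_max <- vapply(seq_len(nloc), function(i) {
      left <- if (i > 1) f[i - 1] else -Inf
      right <- if (i < nloc) f[i + 1] else -Inf
      f[i] > threshold && f[i] >= left && f[i] >= right
    }, logical(1))
    cand <- pr[is_max, , drop = FALSE]
    cand <- cand[order(-cand$F, cand$pos_cM), , drop = FALSE]
    kept <- cand[0, ]
    for (i in seq_len(nrow(cand))) {
      if (nrow(kept) == 0 ||
          all(abs(kept$pos_cM - cand$pos_cM[i]) >= min_separation_cM))
        kept <- rbind(kept, cand[i, ])
    }
    out <- rbind(out, kept)
  }
  out <- out[order(out$chrom, out$pos_cM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call epistatic pairs from a 2D scan profile
#'
#' Greedy selection by descending F among pairs above the threshold; a
#' candidate is suppressed if both of its members lie within
#' `min_separation_cM` of an already-kept pair on the same chromosome
#' pair.
#'
#' @param profile A `scan_profile_2d` from [scan_2d()].
#' @param threshold F threshold.
#' @param min_separation_cM Suppression distance.
#' @return data.frame (`chrom_i`, `pos_i`, `chrom_j`, `pos_j`, `F`).
#' @export
call_pair_peaks <- function(profile, threshold, min_separation_cM = 20) {
  cand <- profile[!is.na(profile$F) & profile$F > threshold, , drop = FALSE]
  cand <- cand[order(-cand$F, cand$pos_i, cand$pos_j), , drop = FALSE]
  kept <- cand[0, c("chrom_i", "pos_i", "chrom_j", "pos_j", "F")]
  for (i in seq_len(nrow(cand))) {
    close_to_kept <- FALSE
    for (k in seq_len(nrow(kept))) {
      same <- kept$chrom_i[k] == cand$chrom_i[i] &&
        kept$chrom_j[k] == cand$chrom_j[i] &&
        abs(kept$pos_i[k] - cand$pos_i[i]) < min_separation_cM &&
        abs(kept$pos_j[k] - cand$pos_j[i]) < min_separation_cM
      swap <- kept$chrom_i[k] == cand$chrom_j[i] &&
        kept$chrom_j[k] == cand$chrom_i[i] &&
        abs(kept$pos_i[k] - cand$pos_j[i]) < min_separation_cM &&
        abs(kept$pos_j[k] - cand$pos_i[i]) < min_separation_cM
      if (same || swap) { close_to_kept <- TRUE; break }
    }
    if (!close_to_kept)
      kept <- rbind(kept, cand[i, c("chrom_i", "pos_i", "chrom_j", "pos_j", "F")])
  }
  rownames(kept) <- NULL
  kept
}

# Refine a called pair on a 1 cM grid in a +/- box around both members.
.refine_pair <- function(data, declared_qtls, cofactor_pairs, pair_row,
                         window, half = 4) {
  map <- data$map
  intervals <- .map_intervals(map)
  mk_grid <- function(chrom, pos) {
    span <- range(map$pos_cM[map$chrom == chrom])
    g <- seq(max(span[1], pos - half), min(span[2], pos + half), by = 1)
    data.frame(chrom = chrom, pos_cM = g)
  }
  gi <- mk_grid(pair_row$chrom_i, pair_row$pos_i)
  gj <- mk_grid(pair_row$chrom_j, pair_row$pos_j)
  grid <- rbind(gi, gj)
  grid$interval <- vapply(seq_len(nrow(grid)), function(i)
    .find_interval(intervals, grid$chrom[i], grid$pos_cM[i]), integer(1))
  pairs <- as.matrix(expand.grid(seq_len(nrow(gi)),
                                 nrow(gi) + seq_len(nrow(gj))))
  ok <- vapply(seq_len(nrow(pairs)), function(k)
    .valid_pair_intervals(intervals, grid$interval[pairs[k, 1]],
                          grid$interval[pairs[k, 2]]), logical(1))
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) return(pair_row)
  rows <- .rows(data)
  sc <- .scan_2d_core(data, declared_qtls, cofactor_pairs, grid, pairs,
                      rows$y, window)
  best <- which.max(sc$F[, 1])
  if (length(best) == 0 || is.na(sc$F[best, 1])) return(pair_row)
  data.frame(chrom_i = grid$chrom[pairs[best, 1]],
             pos_i = grid$pos_cM[pairs[best, 1]],
             chrom_j = grid$chrom[pairs[best, 2]],
             pos_j = grid$pos_cM[pairs[best, 2]],
             F = sc$F[best, 1])
}
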