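# Final model selection and the end-to-end mapping workflow.

# Coefficient vectors (per individual) for a set of declared QTLs/pairs.
.candidate_coefs <- function(data, mains, pairs) {
  xa <- list(); xd <- list()
  if (!is.null(mains) && nrow(mains) > 0) {
    for (q in seq_len(nrow(mains))) {
      co <- .position_xcoef(data, mains$chrom[q], mains$pos_cM[q])
      xa[[q]] <- co$xA; xd[[q]] <- co$xD
    }
  }
  xaa <- list()
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ci <- .position_xcoef(data, pairs$chrom_i[k], pairs$pos_i[k])
      cj <- .position_xcoef(data, pairs$chrom_j[k], pairs$pos_j[k])
      xaa[[k]] <- ci$xA * cj$xA
    }
  }
  list(xa = xa, xd = xd, xaa = xaa)
}

#' Backward model selection over candidate QTLs and epistatic pairs
#'
#' Assembles the full model with all candidate main-effect QTLs (additive
#' and dominance terms per environment) and epistatic pairs (per-environment
#' additive-additive terms), then repeatedly drops the least significant
#' candidate block (Henderson F given all remaining terms) until every
#' surviving block has p <= alpha.  Genetic effects of the surviving
#' structure are then estimated with [estimate_effects()].
#'
#' @param data A `progeny_data` with phenotypes.
#' @param mains data.frame (`chrom`, `pos_cM`) of candidate main-effect
#'   QTLs (may be empty).
#' @param pairs data.frame (`chrom_i`, `pos_i`, `chrom_j`, `pos_j`) of
#'   candidate epistatic pairs (may be empty/NULL).
#' @param alpha Retention significance level.
#' @param method,gibbs_burn,gibbs_keep Passed to [estimate_effects()].
#' @param seed Optional seed for the Gibbs chain.
#' @return A list of class `mapping_result`: `qtl`, `pairs`, `estimates`,
#'   `posterior`, `audit` (elimination log).
#' @export
select_final_model <- function(data, mains, pairs = NULL, alpha = 0.05,
                               method = c("gibbs", "em"), gibbs_burn = 2000,
                               gibbs_keep = 10000, seed = NULL) {
  method <- match.arg(method)
  rows <- .rows(data)
  if (is.null(mains)) mains <- data.frame(chrom = integer(0), pos_cM = numeric(0))
  if (is.null(pairs))
    pairs <- data.frame(chrom_i = integer(0), pos_i = numeric(0),
                        chrom_j = integer(0), pos_j = numeric(0))
  audit <- character(0)
  repeat {
    nm <- nrow(mains); np <- nrow(pairs)
    if (nm + np == 0) break
    co <- .candidate_coefs(data, mains, pairs)
    blocks <- c(
      lapply(seq_len(nm), function(q)
        .env_expand(cbind(co$xa[[q]], co$xd[[q]]), rows)),
      lapply(seq_len(np), function(k) .env_expand(co$xaa[[k]], rows)))
    pvals <- vapply(seq_along(blocks), function(b) {
      WB <- do.call(cbind, c(list(.env_means(rows)), blocks[-b]))
      hf <- henderson_f(list(y = rows$y, WQ = blocks[[b]], WB = WB))
      if (hf$status != "ok") 1 else hf$p_value
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha) break
    if (worst <= nm) {
      audit <- c(audit, sprintf("dropped QTL chr%d@%.1f (p=%.3g)",
                                mains$chrom[worst], mains$pos_cM[worst],
                                pvals[worst]))
      mains <- mains[-worst, , drop = FALSE]
    } else {
      k <- worst - nm
      audit <- c(audit, sprintf("dropped pair chr%d@%.1f x chr%d@%.1f (p=%.3g)",
                                pairs$chrom_i[k], pairs$pos_i[k],
                                pairs$chrom_j[k], pairs$pos_j[k], pvals[k + nm]))
      pairs <- pairs[-k, , drop = FALSE]
    }
  }
  est <- estimate_effects(data, mains, pairs, method = method,
                          burn = gibbs_burn, keep = gibbs_keep, seed = seed)
  structure(list(qtl = mains, pairs = pairs, estimates = est$estimates,
                 posterior = est$posterior, audit = audit),
            class = "mapping_result")
}

#' Estimate genetic effects of a declared QTL structure
#'
#' Fits the full mixed model for the declared QTLs and pairs: fixed
#' population mean, additive, dominance and additive-additive effects;
#' random environment, additive-by-environment, dominance-by-environment
#' and epistasis-by-environment effect vectors with their variance
#' components; residual.  Coefficients are the expected values from the
#' conditional probability kernel at the declared positions.
#'
#' @param data A `progeny_data` with phenotypes.
#' @param mains data.frame (`chrom`, `pos_cM`); may be empty.
#' @param pairs data.frame (`chrom_i`, `pos_i`, `chrom_j`, `pos_j`); may
#'   be empty or NULL.
#' @param method `"gibbs"` or `"em"`.
#' @param burn,keep Gibbs chain lengths.
#' @param seed Optional seed.
#' @return List with `posterior` (an `effect_posterior`) and `estimates`
#'   (tidy per-QTL and per-pair data.frames of posterior means).
#' @export
estimate_effects <- function(data, mains, pairs = NULL,
                             method = c("gibbs", "em"), burn = 2000,
                             keep = 10000, seed = NULL) {
  method <- match.arg(method)
  rows <- .rows(data)
  p <- rows$p
  if (is.null(pairs))
    pairs <- data.frame(chrom_i = integer(0), pos_i = numeric(0),
                        chrom_j = integer(0), pos_j = numeric(0))
  nm <- nrow(mains); np <- nrow(pairs)
  co <- .candidate_coefs(data, mains, pairs)
  expand_const <- function(v) v[rows$ind]
  X <- matrix(1, rows$n, 1)
  cn <- "mu"
  for (q in seq_len(nm)) {
    X <- cbind(X, expand_const(co$xa[[q]]), expand_const(co$xd[[q]]))
    cn <- c(cn, sprintf("a_%d", q), sprintf("d_%d", q))
  }
  for (k in seq_len(np)) {
    X <- cbind(X, expand_const(co$xaa[[k]]))
    cn <- c(cn, sprintf("aa_%d", k))
  }
  colnames(X) <- cn
  # Environment-interaction random vectors are parameterized on the
  # orthonormal sum-to-zero subspace across environments: this separates
  # the fixed main effect (the environment mean of the QTL effect) from
  # its environment deviations, which would otherwise be confounded.
  Qc <- qr.Q(qr(cbind(1, diag(p))))[, 2:p, drop = FALSE]
  Z <- list(env = .env_means(rows) %*% Qc)
  for (q in seq_len(nm)) {
    Z[[sprintf("ae_%d", q)]] <- .env_expand(co$xa[[q]], rows) %*% Qc
    Z[[sprintf("de_%d", q)]] <- .env_expand(co$xd[[q]], rows) %*% Qc
  }
  for (k in seq_len(np))
    Z[[sprintf("aae_%d", k)]] <- .env_expand(co$xaa[[k]], rows) %*% Qc
  post <- mlm_gibbs(rows$y, X, Z, burn = burn, keep = keep, seed = seed,
                    method = method, return_draws = TRUE)
  # tidy extraction; per-environment QE values are Qc %*% f
  fmean <- stats::setNames(post$fixed$mean, cn)
  rget <- function(block) {
    iu <- post$index[[block]]
    if (post$method == "gibbs") {
      ed <- post$draws[, iu, drop = FALSE] %*% t(Qc)
      colMeans(ed)
    } else {
      drop(Qc %*% post$theta[iu])
    }
  }
  qtl_est <- NULL
  if (nm > 0) {
    qtl_est <- data.frame(chrom = mains$chrom, pos_cM = mains$pos_cM,
                          a = unname(fmean[sprintf("a_%d", seq_len(nm))]),
                          d = unname(fmean[sprintf("d_%d", seq_len(nm))]))
    for (h in seq_len(p)) {
      qtl_est[[sprintf("ae%d", h)]] <- vapply(seq_len(nm), function(q)
        unname(rget(sprintf("ae_%d", q))[h]), numeric(1))
      qtl_est[[sprintf("de%d", h)]] <- vapply(seq_len(nm), function(q)
        unname(rget(sprintf("de_%d", q))[h]), numeric(1))
    }
  } else {
    qtl_est <- data.frame(chrom = integer(0), pos_cM = numeric(0))
  }
  if (np > 0) {
    pair_est <- data.frame(chrom_i = pairs$chrom_i, pos_i = pairs$pos_i,
                           chrom_j = pairs$chrom_j, pos_j = pairs$pos_j,
                           aa = unname(fmean[sprintf("aa_%d", seq_len(np))]))
    for (h in seq_len(p))
      pair_est[[sprintf("aae%d", h)]] <- vapply(seq_len(np), function(k)
        unname(rget(sprintf("aae_%d", k))[h]), numeric(1))
  } else {
    pair_est <- data.frame(chrom_i = integer(0), pos_i = numeric(0),
                           chrom_j = integer(0), pos_j = numeric(0))
  }
  list(posterior = post, estimates = list(qtl = qtl_est, pairs = pair_est))
}

# Pipeline with optionally precomputed thresholds (Monte Carlo reuse).
.map_qtls_core <- function(data, cfg, thr1 = NULL, thr2 = NULL,
                           seed = NULL) {
  log <- character(0)
  intervals <- .map_intervals(data$map)
  cof <- select_cofactors_mps(data, cfg$alpha_in, cfg$max_cofactors)
  log <- c(log, sprintf("MPS selected %d cofactor interval(s)", length(cof)))
  if (is.null(thr1))
    thr1 <- permutation_threshold(data, "1D", cfg$n_perm, cfg$alpha,
                                  seed = seed, cofactors = cof,
                                  step_cM = cfg$step1_cM,
                                  window = cfg$window)$threshold
  prof1 <- scan_1d(data, cof, cfg$step1_cM, cfg$window)
  mains <- call_peaks(prof1, thr1, cfg$min_separation_cM)
  log <- c(log, sprintf("1D scan: %d candidate QTL(s) above F=%.2f",
                        nrow(mains), thr1))
  pairs <- NULL
  pair_cof <- NULL
  if (cfg$include_epistasis) {
    qtl_iv <- if (nrow(mains)) vapply(seq_len(nrow(mains)), function(q)
      .find_interval(intervals, mains$chrom[q], mains$pos_cM[q]),
      integer(1)) else integer(0)
    pair_cof <- select_cofactor_pairs(data, mains[, c("chrom", "pos_cM")],
                                      unique(c(cof, qtl_iv)),
                                      cfg$alpha_in, cfg$max_pairs)
    if (is.null(thr2))
      thr2 <- permutation_threshold(data, "2D", cfg$n_perm, cfg$alpha,
                                    seed = seed,
                                    declared_qtls = mains[, c("chrom", "pos_cM")],
                                    cofactor_pairs = pair_cof,
                                    step_cM = cfg$step2_cM,
                                    window = cfg$window)$threshold
    prof2 <- scan_2d(data, mains[, c("chrom", "pos_cM")], pair_cof,
                     cfg$step2_cM, cfg$window)
    pairs <- call_pair_peaks(prof2, thr2, cfg$min_separation_cM)
    log <- c(log, sprintf("2D scan: %d candidate pair(s) above F=%.2f",
                          nrow(pairs), thr2))
    if (nrow(pairs) > 0) {
      refined <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k)
        .refine_pair(data, mains[, c("chrom", "pos_cM")], pair_cof,
                     pairs[k, ], cfg$window)))
      # refinement can pull initially-separate peaks together: re-apply
      # the minimum-separation suppression on the refined positions
      pairs <- call_pair_peaks(refined, -Inf, cfg$min_separation_cM)
    }
  }
  res <- select_final_model(data, mains[, c("chrom", "pos_cM"), drop = FALSE],
                            if (is.null(pairs)) NULL else
                              pairs[, c("chrom_i", "pos_i", "chrom_j", "pos_j"),
                                    drop = FALSE],
                            alpha = cfg$alpha_model, method = cfg$method,
                            gibbs_burn = cfg$gibbs_burn,
                            gibbs_keep = cfg$gibbs_keep, seed = seed)
  res$thresholds <- list(f_1d = thr1, f_2d = thr2)
  res$cofactors <- cof
  res$cofactor_pairs <- pair_cof
  res$audit <- c(log, res$audit)
  res$config <- cfg
  res
}

#' Map QTLs in a double backcross dataset
#'
#' The full workflow: stepwise cofactor selection, 1D permutation
#' threshold, 1D composite interval scan, peak calling, pair-cofactor
#' selection, 2D permutation threshold, 2D epistasis scan, pair calling
#' with local refinement, backward model selection, and Gibbs estimation
#' of the surviving QTL structure.
#'
#' @param data A `progeny_data` with phenotypes.
#' @param config A [dbx_config()].
#' @param seed Optional integer seed controlling permutations and the
#'   Gibbs chain (the result is reproducible given data and seed).
#' @return A `mapping_result`: declared `qtl` and `pairs` with posterior
#'   effect estimates, thresholds, cofactors and an audit log.
#' @export
map_qtls <- function(data, config = dbx_config(), seed = NULL) {
  .map_qtls_core(data, config, seed = seed)
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("Mapping result:", nrow(x$qtl), "QTL(s),", nrow(x$pairs),
      "epistatic pair(s)\n")
  if (nrow(x$estimates$qtl)) {
    cat("\nMain-effect QTLs:\n")
    print(x$estimates$qtl, digits = 3)
  }
  if (nrow(x$estimates$pairs)) {
    cat("\nEpistatic pairs:\n")
    print(x$estimates$pairs, digits = 3)
  }
  invisible(x)
}
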