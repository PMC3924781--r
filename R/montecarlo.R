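# Replicate-level Monte Carlo harness: power, false discovery rate and
# mean(SD) of parameter estimates under the standard simulation designs.

# Match declared main-effect QTLs to the truth.  A true QTL is detected if
# a declared QTL lies within `window` cM on the same chromosome (nearest
# declared QTL supplies the estimates); a declared QTL with no true QTL
# (of any kind) within `fp_window` cM is a false positive.
.match_mains <- function(declared, truth_all, truth_main, window = 10,
                         fp_window = 20) {
  det <- rep(NA_integer_, nrow(truth_main))
  if (nrow(declared) > 0) {
    for (q in seq_len(nrow(truth_main))) {
      same <- which(declared$chrom == truth_main$chrom[q])
      if (!length(same)) next
      dd <- abs(declared$pos_cM[same] - truth_main$pos_cM[q])
      if (min(dd) <= window) det[q] <- same[which.min(dd)]
    }
  }
  fp <- 0L
  if (nrow(declared) > 0) {
    for (i in seq_len(nrow(declared))) {
      same <- which(truth_all$chrom == declared$chrom[i])
      if (!length(same) ||
          min(abs(truth_all$pos_cM[same] - declared$pos_cM[i])) > fp_window)
        fp <- fp + 1L
    }
  }
  list(detected = det, n_false = fp, n_declared = nrow(declared))
}

# Match declared pairs to true pairs: both members within `window` cM of
# the corresponding true members (either orientation).
.match_pairs <- function(declared, truth_pairs, window = 10) {
  det <- rep(NA_integer_, nrow(truth_pairs))
  matched_decl <- rep(FALSE, nrow(declared))
  orient <- rep(FALSE, nrow(truth_pairs)) # TRUE if matched swapped
  if (nrow(declared) > 0 && nrow(truth_pairs) > 0) {
    for (k in seq_len(nrow(truth_pairs))) {
      best <- NA_integer_; best_d <- Inf; best_swap <- FALSE
      for (i in seq_len(nrow(declared))) {
        straight <- declared$chrom_i[i] == truth_pairs$chrom_i[k] &&
          declared$chrom_j[i] == truth_pairs$chrom_j[k] &&
          abs(declared$pos_i[i] - truth_pairs$pos_i[k]) <= window &&
          abs(declared$pos_j[i] - truth_pairs$pos_j[k]) <= window
        swapped <- declared$chrom_i[i] == truth_pairs$chrom_j[k] &&
          declared$chrom_j[i] == truth_pairs$chrom_i[k] &&
          abs(declared$pos_i[i] - truth_pairs$pos_j[k]) <= window &&
          abs(declared$pos_j[i] - truth_pairs$pos_i[k]) <= window
        if (straight || swapped) {
          d <- if (straight)
            abs(declared$pos_i[i] - truth_pairs$pos_i[k]) +
              abs(declared$pos_j[i] - truth_pairs$pos_j[k])
          else
            abs(declared$pos_i[i] - truth_pairs$pos_j[k]) +
              abs(declared$pos_j[i] - truth_pairs$pos_i[k])
          if (d < best_d) { best <- i; best_d <- d; best_swap <- swapped && !straight }
        }
      }
      if (!is.na(best)) {
        det[k] <- best
        orient[k] <- best_swap
        matched_decl[best] <- TRUE
      }
    }
  }
  list(detected = det, swapped = orient,
       n_false = sum(!matched_decl), n_declared = nrow(declared))
}

#' Run a Monte Carlo mapping experiment
#'
#' Simulates `n_reps` double backcross datasets under a scenario, maps
#' each with the full workflow, matches declared QTLs/pairs to the truth,
#' and summarises detection power, estimate means/SDs (over detecting
#' replicates) and experiment-level false discovery rates.  Permutation
#' thresholds are computed once on a reference replicate and reused when
#' `config$cache_thresholds` is TRUE (the default).
#'
#' @param scenario A `qtl_scenario` (the generative truth).
#' @param n1,n2 Backcross progeny counts.
#' @param n_reps Number of replicates.
#' @param seed Master seed; per-replicate child seeds are derived
#'   deterministically.
#' @param map A `linkage_map`.
#' @param line_type `"DH"` or `"RI"`.
#' @param config A [dbx_config()]; set `include_epistasis = FALSE` for the
#'   "epistasis ignored" model variant.
#' @param data_list Optional pre-simulated list of `progeny_data` (used by
#'   [case_comparison()] to pair model variants on identical data).
#' @return A list of class `summary_table`: `qtl` and `pairs` summary
#'   data.frames, `fdr_mains`, `fdr_pairs`, counters and the per-replicate
#'   detection records.
#' @export
run_experiment <- function(scenario, n1 = 150, n2 = 150, n_reps = 50,
                           seed = 1, map = default_linkage_map(),
                           line_type = "DH", config = dbx_config(),
                           data_list = NULL) {
  truth_main <- scenario$qtl[rowSums(abs(cbind(scenario$qtl$a, scenario$qtl$d,
                                               scenario$ae, scenario$de))) > 0,
                             c("id", "chrom", "pos_cM"), drop = FALSE]
  truth_all <- scenario$qtl[, c("chrom", "pos_cM")]
  truth_pairs <- if (!is.null(scenario$epistasis)) {
    ii <- match(scenario$epistasis$qtl_i, scenario$qtl$id)
    jj <- match(scenario$epistasis$qtl_j, scenario$qtl$id)
    data.frame(id = scenario$epistasis$id,
               chrom_i = scenario$qtl$chrom[ii],
               pos_i = scenario$qtl$pos_cM[ii],
               chrom_j = scenario$qtl$chrom[jj],
               pos_j = scenario$qtl$pos_cM[jj])
  } else data.frame(id = character(0), chrom_i = integer(0), pos_i = numeric(0),
                    chrom_j = integer(0), pos_j = numeric(0))
  p <- scenario$n_env
  sim_one <- function(r)
    simulate_cross(scenario, map, n1, n2, line_type,
                   seed = .child_seed(seed, r))
  get_data <- function(r) if (is.null(data_list)) sim_one(r) else data_list[[r]]

  thr1 <- thr2 <- NULL
  if (isTRUE(config$cache_thresholds)) {
    ref <- get_data(1L)
    cof <- select_cofactors_mps(ref, config$alpha_in, config$max_cofactors)
    thr1 <- permutation_threshold(ref, "1D", config$n_perm, config$alpha,
                                  seed = .child_seed(seed, 900001L),
                                  cofactors = cof, step_cM = config$step1_cM,
                                  window = config$window)$threshold
    if (config$include_epistasis) {
      prof1 <- scan_1d(ref, cof, config$step1_cM, config$window)
      mains <- call_peaks(prof1, thr1, config$min_separation_cM)
      intervals <- .map_intervals(ref$map)
      qtl_iv <- if (nrow(mains)) vapply(seq_len(nrow(mains)), function(q)
        .find_interval(intervals, mains$chrom[q], mains$pos_cM[q]),
        integer(1)) else integer(0)
      pair_cof <- select_cofactor_pairs(ref, mains[, c("chrom", "pos_cM")],
                                        unique(c(cof, qtl_iv)),
                                        config$alpha_in, config$max_pairs)
      thr2 <- permutation_threshold(ref, "2D", config$n_perm, config$alpha,
                                    seed = .child_seed(seed, 900002L),
                                    declared_qtls = mains[, c("chrom", "pos_cM")],
                                    cofactor_pairs = pair_cof,
                                    step_cM = config$step2_cM,
                                    window = config$window)$threshold
    }
  }

  eff_names <- c("pos", "a", "d", sprintf("ae%d", seq_len(p)),
                 sprintf("de%d", seq_len(p)))
  qtl_acc <- array(NA_real_, c(n_reps, nrow(truth_main), length(eff_names)),
                   dimnames = list(NULL, truth_main$id, eff_names))
  pair_names <- c("pos_i", "pos_j", "aa", sprintf("aae%d", seq_len(p)))
  pair_acc <- array(NA_real_, c(n_reps, nrow(truth_pairs), length(pair_names)),
                    dimnames = list(NULL, truth_pairs$id, pair_names))
  fp_m <- 0L; n_decl_m <- 0L; fp_p <- 0L; n_decl_p <- 0L
  failures <- 0L
  for (r in seq_len(n_reps)) {
    data <- get_data(r)
    res <- tryCatch(
      .map_qtls_core(data, config, thr1 = thr1, thr2 = thr2,
                     seed = .child_seed(seed, 100000L + r)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      warning("replicate ", r, " failed: ", conditionMessage(res),
              call. = FALSE)
      next
    }
    mm <- .match_mains(res$qtl, truth_all, truth_main,
                       config$match_window_cM, config$fp_window_cM)
    fp_m <- fp_m + mm$n_false
    n_decl_m <- n_decl_m + mm$n_declared
    est <- res$estimates$qtl
    for (q in seq_len(nrow(truth_main))) {
      i <- mm$detected[q]
      if (is.na(i)) next
      vals <- c(est$pos_cM[i], est$a[i], est$d[i],
                unlist(est[i, sprintf("ae%d", seq_len(p))]),
                unlist(est[i, sprintf("de%d", seq_len(p))]))
      qtl_acc[r, q, ] <- vals
    }
    mp <- .match_pairs(res$pairs, truth_pairs, config$match_window_cM)
    fp_p <- fp_p + mp$n_false
    n_decl_p <- n_decl_p + mp$n_declared
    pest <- res$estimates$pairs
    for (k in seq_len(nrow(truth_pairs))) {
      i <- mp$detected[k]
      if (is.na(i)) next
      pi_ <- if (mp$swapped[k]) pest$pos_j[i] else pest$pos_i[i]
      pj_ <- if (mp$swapped[k]) pest$pos_i[i] else pest$pos_j[i]
      vals <- c(pi_, pj_, pest$aa[i],
                unlist(pest[i, sprintf("aae%d", seq_len(p))]))
      pair_acc[r, k, ] <- vals
    }
  }
  summarise <- function(acc, ids) {
    if (length(ids) == 0)
      return(data.frame(id = character(0)))
    out <- data.frame(id = ids)
    det <- apply(!is.na(acc[, , 1, drop = FALSE]), 2, sum)
    out$power <- 100 * det / n_reps
    for (j in seq_len(dim(acc)[3])) {
      nm <- dimnames(acc)[[3]][j]
      out[[paste0(nm, "_mean")]] <- apply(acc[, , j, drop = FALSE], 2, mean,
                                          na.rm = TRUE)
      out[[paste0(nm, "_sd")]] <- apply(acc[, , j, drop = FALSE], 2,
                                        stats::sd, na.rm = TRUE)
    }
    out
  }
  structure(list(
    qtl = summarise(qtl_acc, truth_main$id),
    pairs = summarise(pair_acc, truth_pairs$id),
    fdr_mains = if (n_decl_m > 0) fp_m / n_decl_m else NA_real_,
    fdr_pairs = if (n_decl_p > 0) fp_p / n_decl_p else NA_real_,
    n_false_mains = fp_m, n_declared_mains = n_decl_m,
    n_false_pairs = fp_p, n_declared_pairs = n_decl_p,
    n_reps = n_reps, failures = failures,
    thresholds = list(f_1d = thr1, f_2d = thr2),
    qtl_acc = qtl_acc, pair_acc = pair_acc),
    class = "summary_table")
}

#' Paired comparison of the four model/scenario cases
#'
#' Case I: epistasis exists and is modelled; Case II: epistasis exists but
#' the model ignores it; Case III: no epistasis, epistatic model; Case IV:
#' no epistasis, non-epistatic model.  Cases sharing a generative world
#' (I/II and III/IV) are run on identical per-replicate datasets so
#' model-misspecification contrasts are paired.
#'
#' @param n_reps Replicates per case.
#' @param seed Master seed.
#' @param n1,n2 Backcross sizes.
#' @param cases Subset of `c("I","II","III","IV")` to run.
#' @param config Base [dbx_config()]; `include_epistasis` is overridden
#'   per case.
#' @param map A `linkage_map`.
#' @return Named list of `summary_table`s.
#' @export
case_comparison <- function(n_reps = 50, seed = 1, n1 = 150, n2 = 150,
                            cases = c("I", "II", "III", "IV"),
                            config = dbx_config(),
                            map = default_linkage_map()) {
  cases <- match.arg(cases, several.ok = TRUE)
  out <- list()
  sc_epi <- default_qtl_scenario(epistasis = TRUE)
  sc_null <- default_qtl_scenario(epistasis = FALSE)
  make_data <- function(scenario)
    lapply(seq_len(n_reps), function(r)
      simulate_cross(scenario, map, n1, n2, "DH", seed = .child_seed(seed, r)))
  with_epi <- intersect(cases, c("I", "II"))
  if (length(with_epi)) {
    dl <- make_data(sc_epi)
    for (cs in with_epi) {
      cfg <- config
      cfg$include_epistasis <- (cs == "I")
      out[[cs]] <- run_experiment(sc_epi, n1, n2, n_reps, seed, map, "DH",
                                  cfg, data_list = dl)
    }
  }
  without_epi <- intersect(cases, c("III", "IV"))
  if (length(without_epi)) {
    dl <- make_data(sc_null)
    for (cs in without_epi) {
      cfg <- config
      cfg$include_epistasis <- (cs == "III")
      out[[cs]] <- run_experiment(sc_null, n1, n2, n_reps, seed, map, "DH",
                                  cfg, data_list = dl)
    }
  }
  out
}

#' Population-constitution study
#'
#' Runs the epistatic-model experiment for several constitutions of the
#' two backcrosses at fixed total size, summarising estimates and the
#' epistasis false discovery rate per constitution.
#'
#' @param ratios List of `c(n1, n2)` pairs.
#' @param n_reps Replicates per constitution.
#' @param seed Master seed.
#' @param config A [dbx_config()].
#' @param map A `linkage_map`.
#' @return List with `tables` (one `summary_table` per ratio) and
#'   `fdr_pairs` (named numeric vector).
#' @export
constitution_study <- function(ratios = list(c(150, 150), c(100, 200),
                                             c(50, 250)),
                               n_reps = 50, seed = 1, config = dbx_config(),
                               map = default_linkage_map()) {
  sc <- default_qtl_scenario(epistasis = TRUE)
  tables <- lapply(ratios, function(nn)
    run_experiment(sc, nn[1], nn[2], n_reps, seed, map, "DH", config))
  names(tables) <- vapply(ratios, function(nn)
    sprintf("%d:%d", nn[1], nn[2]), character(1))
  list(tables = tables,
       fdr_pairs = vapply(tables, function(t_) t_$fdr_pairs, numeric(1)))
}

#' @export
print.summary_table <- function(x, ...) {
  cat("Monte Carlo summary over", x$n_reps, "replicates\n")
  if (nrow(x$qtl)) {
    cat("\nMain-effect QTLs (means over detecting replicates):\n")
    print(x$qtl[, c("id", "power", "pos_mean", "pos_sd", "a_mean", "d_mean")],
          digits = 3)
  }
  if (nrow(x$pairs)) {
    cat("\nEpistatic pairs:\n")
    print(x$pairs[, c("id", "power", "pos_i_mean", "pos_j_mean", "aa_mean")],
          digits = 3)
  }
  cat("\nFDR (mains):", format(x$fdr_mains, digits = 3),
      " FDR (pairs):", format(x$fdr_pairs, digits = 3), "\n")
  invisible(x)
}
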