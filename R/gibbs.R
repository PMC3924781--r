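# Bayesian (Gibbs) and deterministic (EM) estimation of fixed genetic
# effects and variance components in the full mixed linear model
#   y = X b + sum_u Z_u e_u + eps,  e_u ~ N(0, sigma2_u I), eps ~ N(0, sigma2_eps I).
# All conditional updates run in coefficient space on precomputed
# crossproducts, so chain length, not n, dominates the cost.

# Effective sample size from the initial positive autocorrelation sum.
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (a in ac) {
    if (a <= 0) break
    s <- s + a
  }
  n / (1 + 2 * s)
}

#' Mixed linear model fit by Gibbs sampling (or EM fallback)
#'
#' Block Gibbs sampler with flat priors on the fixed effects and limiting
#' vague scaled-inverse-chi-square priors on the variance components
#' (positivity floor 1e-10).  Fixed effects are drawn from their joint
#' conditional normal; each random-effect vector from its conditional
#' normal; variance components from conditional scaled inverse
#' chi-squares.  `method = "em"` instead iterates an EM algorithm on the
#' mixed model equations and returns deterministic point estimates with
#' curvature-based standard deviations.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (including any intercept).
#' @param Z Named list of random-effect design matrices (may be empty).
#' @param burn,keep Burn-in and retained Gibbs iterations.
#' @param seed Optional integer seed (chain is reproducible).
#' @param method `"gibbs"` or `"em"`.
#' @param return_draws Keep the retained coefficient draws (Gibbs only);
#'   used by wrappers that need posterior summaries of linear transforms.
#' @return A list of class `effect_posterior`: `fixed` (data.frame term,
#'   mean, sd, ess), `random` (data.frame block, level, mean, sd),
#'   `sigma2` (data.frame component, mean, sd), and `flags`.  With
#'   `return_draws = TRUE` also `draws` and `index` (column index per
#'   block); the EM path always returns `theta` and `cov`.
#' @export
mlm_gibbs <- function(y, X, Z = list(), burn = 2000, keep = 10000,
                      seed = NULL, method = c("gibbs", "em"),
                      return_draws = FALSE) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- length(y)
  pX <- ncol(X)
  Z <- lapply(Z, as.matrix)
  qs <- vapply(Z, ncol, integer(1))
  M <- if (length(Z)) cbind(X, do.call(cbind, Z)) else X
  qtot <- ncol(M)
  C <- crossprod(M)
  cy <- drop(crossprod(M, y))
  yty <- sum(y^2)
  vary <- stats::var(y)
  fx <- seq_len(pX)
  rnd_blocks <- list()
  off <- pX
  for (u in seq_along(Z)) {
    rnd_blocks[[u]] <- off + seq_len(qs[u])
    off <- off + qs[u]
  }
  names(rnd_blocks) <- names(Z)
  XtX <- C[fx, fx, drop = FALSE]
  RX <- tryCatch(chol(XtX), error = function(e)
    chol(XtX + diag(1e-8 * max(diag(XtX)), pX)))
  if (method == "em")
    return(.mlm_em(C, cy, yty, n, fx, rnd_blocks, names(Z), vary))

  floor_v <- 1e-10
  theta <- numeric(qtot)
  theta[fx] <- backsolve(RX, backsolve(RX, cy[fx], transpose = TRUE))
  s2e <- max(vary, floor_v)
  s2u <- rep(s2e / 10, length(Z))
  n_draw <- burn + keep
  th_draws <- matrix(0, keep, qtot)
  s2_draws <- matrix(0, keep, length(Z) + 1)
  divergent <- FALSE
  for (it in seq_len(n_draw)) {
    # fixed effects | rest
    w <- cy[fx] - drop(crossprod(C[, fx, drop = FALSE], theta)) +
      XtX %*% theta[fx]
    mu_b <- backsolve(RX, backsolve(RX, w, transpose = TRUE))
    theta[fx] <- mu_b + backsolve(RX, stats::rnorm(pX)) * sqrt(s2e)
    # random-effect blocks | rest
    for (u in seq_along(rnd_blocks)) {
      iu <- rnd_blocks[[u]]
      qu <- length(iu)
      w <- cy[iu] - drop(crossprod(C[, iu, drop = FALSE], theta)) +
        C[iu, iu, drop = FALSE] %*% theta[iu]
      P <- C[iu, iu, drop = FALSE] / s2e
      P[seq(1, qu * qu, by = qu + 1)] <- diag(P) + 1 / s2u[u]
      RP <- chol(P)
      mu_u <- backsolve(RP, backsolve(RP, w / s2e, transpose = TRUE))
      theta[iu] <- mu_u + backsolve(RP, stats::rnorm(qu))
      # variance component | e_u (limiting vague: df = q_u - 2, min 1)
      ss <- sum(theta[iu]^2)
      dfu <- max(length(iu) - 2L, 1L)
      s2u[u] <- max(ss / stats::rchisq(1, dfu), floor_v)
      if (s2u[u] > 1e6 * vary) {
        divergent <- TRUE
        s2u[u] <- 1e6 * vary
      }
    }
    # residual variance
    sse <- max(yty - 2 * sum(theta * cy) +
                 drop(crossprod(theta, C %*% theta)), 0)
    s2e <- max(sse / stats::rchisq(1, max(n - 2, 1)), floor_v)
    if (it > burn) {
      th_draws[it - burn, ] <- theta
      s2_draws[it - burn, ] <- c(s2u, s2e)
    }
  }
  fixed <- data.frame(term = colnames(X) %||% paste0("b", fx),
                      mean = colMeans(th_draws[, fx, drop = FALSE]),
                      sd = apply(th_draws[, fx, drop = FALSE], 2, stats::sd),
                      ess = apply(th_draws[, fx, drop = FALSE], 2, .ess))
  random <- do.call(rbind, lapply(seq_along(rnd_blocks), function(u) {
    iu <- rnd_blocks[[u]]
    data.frame(block = names(rnd_blocks)[u] %||% paste0("u", u),
               level = seq_along(iu),
               mean = colMeans(th_draws[, iu, drop = FALSE]),
               sd = apply(th_draws[, iu, drop = FALSE], 2, stats::sd))
  }))
  sigma2 <- data.frame(
    component = c(names(rnd_blocks), "residual"),
    mean = colMeans(s2_draws),
    sd = apply(s2_draws, 2, stats::sd))
  out <- structure(list(fixed = fixed, random = random, sigma2 = sigma2,
                        flags = list(divergent = divergent),
                        method = "gibbs"),
                   class = "effect_posterior")
  if (return_draws) {
    out$draws <- th_draws
    out$index <- c(list(fixed = fx), rnd_blocks)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# EM on the mixed model equations: deterministic point estimates.
.mlm_em <- function(C, cy, yty, n, fx, rnd_blocks, znames, vary,
                    max_iter = 500, tol = 1e-9) {
  qtot <- length(cy)
  s2e <- max(vary, 1e-10)
  s2u <- rep(s2e / 10, length(rnd_blocks))
  theta <- numeric(qtot)
  for (it in seq_len(max_iter)) {
    D <- numeric(qtot)
    for (u in seq_along(rnd_blocks)) D[rnd_blocks[[u]]] <- 1 / s2u[u]
    A <- C / s2e + diag(D, qtot)
    S <- tryCatch(solve(A), error = function(e)
      solve(A + diag(1e-10 * max(diag(A)), qtot)))
    theta <- drop(S %*% (cy / s2e))
    s2u_new <- s2u
    for (u in seq_along(rnd_blocks)) {
      iu <- rnd_blocks[[u]]
      s2u_new[u] <- max((sum(theta[iu]^2) +
                           sum(diag(S[iu, iu, drop = FALSE]))) / length(iu),
                        1e-10)
    }
    sse <- max(yty - 2 * sum(theta * cy) +
                 drop(crossprod(theta, C %*% theta)), 0)
    s2e_new <- max((sse + sum(diag(S %*% C))) / n, 1e-10)
    delta <- max(abs(c(s2u_new - s2u, s2e_new - s2e)))
    s2u <- s2u_new
    s2e <- s2e_new
    if (delta < tol * vary) break
  }
  sds <- sqrt(pmax(diag(S), 0))
  fixed <- data.frame(term = paste0("b", fx), mean = theta[fx],
                      sd = sds[fx], ess = NA_real_)
  random <- do.call(rbind, lapply(seq_along(rnd_blocks), function(u) {
    iu <- rnd_blocks[[u]]
    data.frame(block = znames[u] %||% paste0("u", u), level = seq_along(iu),
               mean = theta[iu], sd = sds[iu])
  }))
  sigma2 <- data.frame(component = c(znames, "residual"),
                       mean = c(s2u, s2e), sd = NA_real_)
  structure(list(fixed = fixed, random = random, sigma2 = sigma2,
                 flags = list(divergent = FALSE), method = "em",
                 theta = theta, cov = S,
                 index = c(list(fixed = fx), rnd_blocks)),
            class = "effect_posterior")
}
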