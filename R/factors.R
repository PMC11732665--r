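# Exploratory factor reduction of the questionnaire battery: retention
# diagnostics (Horn's parallel analysis, Velicer's minimum average partial
# test), minimum-residual extraction, oblimin (quartimin) rotation by
# gradient projection, and regression-method factor scores.

cor_pairwise <- function(x) {
  stats::cor(x, use = "pairwise.complete.obs")
}

#' Horn's parallel analysis
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' chosen quantile of eigenvalues obtained from noise data of the same
#' dimensions. The suggested dimensionality is the number of leading
#' observed eigenvalues exceeding their noise counterpart (counted from the
#' first consecutive run, so a late spurious crossing is not counted).
#'
#' @param score_table numeric matrix/data.frame (participants x variables);
#'   missing entries are tolerated via pairwise-complete correlations.
#' @param n_resamples number of noise data sets (default 500).
#' @param quantile noise quantile used as the retention threshold
#'   (default 0.95).
#' @param mode `"simulation"` draws standard-normal noise; `"resampling"`
#'   permutes each observed column independently.
#' @param seed RNG seed for the noise draws.
#' @return list with `n_factors`, observed `eigenvalues` and the noise
#'   `threshold` eigenvalues.
#' @export
parallel_analysis <- function(score_table, n_resamples = 500,
                              quantile = 0.95,
                              mode = c("simulation", "resampling"),
                              seed = 1L) {
  mode <- match.arg(mode)
  x <- as.matrix(score_table)
  stop_if_not(ncol(x) >= 3, "need at least 3 variables")
  if (nrow(x) < ncol(x)) {
    warning("fewer observations than variables; proceeding on the ",
            "pairwise-complete correlation matrix")
  }
  obs <- eigen(cor_pairwise(x), symmetric = TRUE, only.values = TRUE)$values
  p <- ncol(x); n <- nrow(x)
  noise <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      xb <- if (mode == "simulation") {
        matrix(stats::rnorm(n * p), n)
      } else {
        apply(x, 2, function(col) sample(col))
      }
      eigen(cor_pairwise(xb), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  threshold <- apply(noise, 1, stats::quantile, probs = quantile,
                     na.rm = TRUE)
  exceeds <- obs > threshold
  n_factors <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  list(n_factors = as.integer(n_factors), eigenvalues = obs,
       threshold = threshold)
}

#' Velicer's minimum average partial (MAP) test
#'
#' After partialling out the first m principal components, the average
#' squared off-diagonal partial correlation is computed; the suggested
#' number of components minimises this curve. If no partialling improves on
#' the unreduced matrix, zero components are suggested.
#'
#' @param correlation_matrix a correlation matrix.
#' @param ridge ridge added to a computationally singular partial
#'   covariance (with a warning).
#' @return list with `n_factors` and the `map` curve (index m = 0 ... p-1).
#' @export
velicer_map <- function(correlation_matrix, ridge = 1e-8) {
  R <- as.matrix(correlation_matrix)
  p <- ncol(R)
  stop_if_not(isTRUE(all.equal(unname(diag(R)), rep(1, p), tolerance = 1e-6)),
              "not a correlation matrix (unit diagonal required)")
  eig <- eigen(R, symmetric = TRUE)
  map <- numeric(p)                        # map[m + 1] for m components
  off <- function(M) (sum(M^2) - sum(diag(M)^2)) / (p * (p - 1))
  map[1] <- off(R)
  for (m in seq_len(p - 1)) {
    L <- eig$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(eig$values[seq_len(m)], 0)), m)
    C <- R - L %*% t(L)
    d <- diag(C)
    if (any(d <= ridge)) {
      warning("near-singular partial covariance; applying ridge")
      d <- d + ridge
    }
    D <- diag(1 / sqrt(d), p)
    map[m + 1] <- off(D %*% C %*% D)
  }
  list(n_factors = as.integer(which.min(map) - 1L), map = map)
}

# Minimum-residual (minres/ULS) extraction: minimise the sum of squared
# off-diagonal residuals of R - Lambda Lambda' over the uniquenesses, with
# loadings obtained from the reduced correlation matrix's leading
# eigenstructure.
minres_extract <- function(R, k, max_iter = 1000) {
  p <- ncol(R)
  loadings_from_psi <- function(psi) {
    Rs <- R; diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    val <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(val), k)
  }
  objective <- function(psi) {
    L <- loadings_from_psi(psi)
    resid <- R - L %*% t(L)
    diag(resid) <- 0
    sum(resid^2) / 2
  }
  # start from 1 - squared multiple correlation
  start <- pmin(pmax(1 / diag(solve(R + diag(1e-8, p))), 0.05), 0.95)
  opt <- stats::nlminb(start, objective, lower = 0.005, upper = 0.995,
                       control = list(iter.max = max_iter))
  converged <- opt$convergence == 0 ||
    grepl("X-convergence|relative convergence", opt$message)
  if (!converged) {
    stop(sprintf("minres extraction failed to converge after %d iterations: %s",
                 opt$iterations, opt$message), call. = FALSE)
  }
  L <- loadings_from_psi(opt$par)
  list(loadings = L, uniquenesses = opt$par, objective = opt$objective,
       iterations = opt$iterations)
}

# Quartimin criterion and gradient for oblique gradient-projection rotation
# (oblimin with gamma = 0).
vgQ_quartimin <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, G = L * X)
}

# Oblique gradient-projection rotation (quartimin criterion).
gpf_oblq <- function(A, max_iter = 500, tol = 1e-6) {
  k <- ncol(A)
  Tm <- diag(k)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- vgQ_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% Ti)
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in 1:20) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vg <- vgQ_quartimin(L)
      if (vg$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt
    f <- vg$f
    G <- -t(t(L) %*% vg$G %*% Ti)
  }
  list(loadings = L, Phi = t(Tm) %*% Tm, f = f, iterations = iter)
}

# Flip factor signs so each factor's largest-magnitude loading is positive,
# and order factors by explained sum of squares (descending).
align_solution <- function(L, Phi) {
  signs <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  signs[signs == 0] <- 1
  L <- sweep(L, 2, signs, `*`)
  S <- diag(signs, length(signs))
  Phi <- S %*% Phi %*% S
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  list(loadings = L[, ord, drop = FALSE],
       Phi = Phi[ord, ord, drop = FALSE])
}

#' Fit an exploratory factor model
#'
#' Minimum-residual extraction on the (pairwise-complete) correlation
#' matrix, oblimin (quartimin) rotation allowing correlated factors, and
#' per-participant factor scores by the regression (Thurstone) method —
#' Bartlett scores are available behind a switch. Factors are sign-aligned
#' (largest loading positive) and ordered by explained sum of squares.
#'
#' @param score_table numeric matrix/data.frame (participants x variables).
#' @param k number of factors to extract.
#' @param rotate `"oblimin"` (default) or `"none"`.
#' @param scores `"regression"` (default) or `"bartlett"`.
#' @return object of class `factor_solution`: loadings (pattern matrix),
#'   factor correlations `Phi`, `factor_scores` (rows with any missing
#'   variable get `NA` scores), `uniquenesses`, retention diagnostics slot
#'   (filled by the caller), per-factor `variance_explained`, residual
#'   root-mean-square `rmsr` and `top_loading` variable names.
#' @export
fit_factors <- function(score_table, k, rotate = c("oblimin", "none"),
                        scores = c("regression", "bartlett")) {
  rotate <- match.arg(rotate)
  scores <- match.arg(scores)
  stop_if_not(k >= 1, "k must be >= 1")
  x <- as.matrix(score_table)
  R <- cor_pairwise(x)
  ext <- minres_extract(R, k)
  if (rotate == "oblimin" && k > 1) {
    rot <- gpf_oblq(ext$loadings)
    sol <- align_solution(rot$loadings, rot$Phi)
  } else {
    sol <- align_solution(ext$loadings, diag(k))
  }
  L <- sol$loadings
  Phi <- sol$Phi
  rownames(L) <- colnames(x)
  colnames(L) <- paste0("factor_", seq_len(k))
  dimnames(Phi) <- list(colnames(L), colnames(L))

  # model-implied correlation and residual fit
  implied <- L %*% Phi %*% t(L)
  resid <- R - implied
  diag(resid) <- 0
  rmsr <- sqrt(sum(resid^2) / (ncol(R) * (ncol(R) - 1)))

  # factor scores on standardized complete rows
  xz <- scale(x)
  W <- if (scores == "regression") {
    solve(R, L %*% Phi)                          # R^{-1} S, S = structure
  } else {
    U <- diag(1 / ext$uniquenesses)
    U %*% L %*% solve(t(L) %*% U %*% L)
  }
  fs <- matrix(NA_real_, nrow(x), k,
               dimnames = list(rownames(x), colnames(L)))
  complete <- stats::complete.cases(x)
  fs[complete, ] <- xz[complete, , drop = FALSE] %*% W

  structure(list(loadings = L, Phi = Phi, factor_scores = fs,
                 uniquenesses = stats::setNames(ext$uniquenesses,
                                                colnames(x)),
                 variance_explained = colSums(L^2) / ncol(R),
                 rmsr = rmsr, retention = NULL,
                 score_method = scores,
                 top_loading = apply(L, 2, function(col)
                   rownames(L)[which.max(abs(col))]),
                 n_complete = sum(complete)),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("Factor solution: %d factors, %d variables, RMSR %.4f\n",
              k, nrow(x$loadings), x$rmsr))
  cat("  top-loading variables:",
      paste(sprintf("%s=%s", colnames(x$loadings), x$top_loading),
            collapse = ", "), "\n")
  if (!is.null(x$retention)) {
    cat(sprintf("  retention: parallel analysis %d, MAP %d\n",
                x$retention$parallel_analysis_k, x$retention$velicer_map_k))
  }
  invisible(x)
}

#' Tucker congruence-based alignment of a solution with reference loadings
#'
#' Greedily matches each reference factor to the estimated factor with the
#' highest absolute Tucker congruence, flipping signs as needed. Used in
#' recovery checks where factor order and sign are arbitrary.
#'
#' @param est estimated loading matrix.
#' @param ref reference loading matrix (same dimensions).
#' @return list with the permuted/sign-aligned `loadings` and the vector of
#'   per-factor `congruence` values.
#' @export
align_to_reference <- function(est, ref) {
  stop_if_not(all(dim(est) == dim(ref)), "dimension mismatch")
  k <- ncol(ref)
  congr <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  C <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) congr(ref[, i], est[, j])))
  perm <- integer(k); used <- logical(k)
  for (i in order(-apply(abs(C), 1, max))) {
    j <- which.max(ifelse(used, -Inf, abs(C[i, ])))
    perm[i] <- j; used[j] <- TRUE
  }
  signs <- sign(C[cbind(seq_len(k), perm)])
  signs[signs == 0] <- 1
  aligned <- sweep(est[, perm, drop = FALSE], 2, signs, `*`)
  list(loadings = aligned,
       congruence = abs(C[cbind(seq_len(k), perm)]))
}
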