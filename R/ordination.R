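#' Impute missing cells by multivariate-normal EM
#'
#' Single imputation under a multivariate normal model: starting from
#' mean-imputed values, alternately replaces each row's missing entries by
#' their conditional expectation given the observed entries and the current
#' mean vector and covariance matrix, and re-estimates mean and covariance
#' (including the conditional-covariance correction) until the parameters
#' stabilize. The procedure is deterministic; the `seed` argument is recorded
#' for provenance and reserved for stochastic variants.
#'
#' @param x numeric matrix (or data.frame of numerics) with `NA` cells
#' @param seed integer, recorded in the result attributes
#' @param max_iter,tol EM iteration controls
#' @param ridge small diagonal inflation keeping the covariance invertible
#' @return completed numeric matrix (attributes: `imputed` index matrix,
#'   `iterations`, `seed`)
#' @export
impute_missing <- function(x, seed = 1L, max_iter = 1000L, tol = 1e-10,
                           ridge = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "imputed") <- which(miss, arr.ind = TRUE)
    attr(x, "iterations") <- 0L
    attr(x, "seed") <- seed
    return(x)
  }
  if (any(colSums(!miss) == 0L)) {
    stop("column(s) entirely missing: ",
         paste(colnames(x)[colSums(!miss) == 0L], collapse = ", "))
  }
  frac <- colMeans(miss)
  if (any(frac >= 0.2)) {
    stop("missingness >= 20% in column(s): ",
         paste(colnames(x)[frac >= 0.2], collapse = ", "))
  }

  n <- nrow(x)
  p <- ncol(x)
  xf <- x
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(p)) xf[miss[, j], j] <- mu[j]

  rows_miss <- which(rowSums(miss) > 0L)
  for (it in seq_len(max_iter)) {
    mu <- colMeans(xf)
    sig <- stats::cov(xf) * (n - 1) / n
    # conditional-covariance correction accumulated over incomplete rows
    corr <- matrix(0, p, p)
    xf_new <- xf
    for (i in rows_miss) {
      m <- miss[i, ]
      o <- !m
      s_oo <- sig[o, o, drop = FALSE] + diag(ridge, sum(o))
      s_mo <- sig[m, o, drop = FALSE]
      beta <- s_mo %*% solve(s_oo)
      xf_new[i, m] <- mu[m] + beta %*% (xf[i, o] - mu[o])
      cmm <- sig[m, m, drop = FALSE] - beta %*% t(s_mo)
      corr[m, m] <- corr[m, m] + cmm
    }
    delta <- max(abs(xf_new[miss] - xf[miss]))
    xf <- xf_new
    if (delta < tol) break
  }
  attr(xf, "imputed") <- which(miss, arr.ind = TRUE)
  attr(xf, "iterations") <- it
  attr(xf, "seed") <- seed
  xf
}

#' Principal component analysis of explanatory variables
#'
#' Eigen-decomposition (via SVD) of the centred and optionally scaled data
#' matrix. Axis signs are fixed by making each axis's largest-magnitude
#' loading positive.
#'
#' @param x numeric matrix or data.frame, rows = sites
#' @param center,scale logical; scaling corresponds to a correlation PCA
#' @return object of class `pca_fit`: `eigenvalues`, `pct_variance`,
#'   `loadings`, `scores`, `contributions` (percent, per variable and axis),
#'   `center`, `scale`
#' @export
fit_pca <- function(x, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3L || ncol(x) < 2L) stop("PCA needs >= 3 rows and >= 2 columns")
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance column(s) under scaling: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    }
  }
  xs <- base::scale(x, center = center, scale = scale)
  sv <- svd(xs)
  ev <- sv$d^2 / (nrow(x) - 1)
  v <- sv$v
  for (j in seq_len(ncol(v))) {
    if (v[which.max(abs(v[, j])), j] < 0) {
      v[, j] <- -v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  rownames(v) <- colnames(x)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- rownames(x)
  colnames(v) <- colnames(scores) <- paste0("PC", seq_along(ev))
  out <- list(
    eigenvalues = ev,
    pct_variance = 100 * ev / sum(ev),
    loadings = v,
    scores = scores,
    contributions = 100 * v^2,
    center = center, scale = scale
  )
  class(out) <- "pca_fit"
  out
}

#' @export
print.pca_fit <- function(x, ...) {
  cat("PCA:", length(x$eigenvalues), "axes;",
      paste(sprintf("%.1f%%", x$pct_variance[seq_len(min(3, length(x$pct_variance)))]),
            collapse = " + "), "...\n")
  invisible(x)
}

#' Redundancy analysis
#'
#' Regresses a (centred, optionally scaled) multivariate response on a set of
#' explanatory variables and decomposes the fitted values into constrained
#' axes. The coefficient of determination is the share of the response's
#' total variance captured by the fitted values; the adjusted R2 uses the
#' Ezekiel correction \eqn{1 - (1 - R^2)(n-1)/(n-m-1)} with m the number of
#' explanatory variables.
#'
#' @param y response matrix (rows = sites)
#' @param x explanatory matrix or data.frame (rows aligned with `y`)
#' @param scale_y,scale_x standardize columns before analysis
#' @return object of class `rda_fit`: `r2`, `adj_r2`, `total_variance`,
#'   `constrained_variance`, `residual_variance`, `eigenvalues` (constrained
#'   axes), `axes` (response-space eigenvectors), `site_scores`, `n`, `m`
#' @export
fit_rda <- function(y, x, scale_y = TRUE, scale_x = TRUE) {
  y <- as.matrix(y)
  x <- as.matrix(x)
  if (nrow(y) != nrow(x)) stop("y and x must have the same number of rows")
  n <- nrow(y)
  m <- ncol(x)
  ys <- base::scale(y, center = TRUE, scale = scale_y)
  xs <- base::scale(x, center = TRUE, scale = scale_x)
  if (any(!is.finite(ys))) stop("zero-variance response column under scaling")
  if (any(!is.finite(xs))) stop("zero-variance explanatory column under scaling")
  qx <- qr(xs)
  if (qx$rank < m) stop("explanatory columns are linearly dependent")
  if (n <= m + 1L) stop("adjusted R2 undefined: need n > m + 1")
  yhat <- qr.fitted(qx, ys)
  tot <- sum(ys^2) / (n - 1)
  con <- sum(yhat^2) / (n - 1)
  r2 <- con / tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  sv <- svd(yhat)
  keep <- sv$d > max(sv$d) * 1e-10
  out <- list(
    r2 = r2, adj_r2 = adj,
    total_variance = tot, constrained_variance = con,
    residual_variance = tot - con,
    eigenvalues = (sv$d[keep])^2 / (n - 1),
    axes = sv$v[, keep, drop = FALSE],
    site_scores = (sv$u %*% diag(sv$d, nrow = length(sv$d)))[, keep, drop = FALSE],
    n = n, m = m
  )
  class(out) <- "rda_fit"
  out
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA: R2 = %.4f, adjusted R2 = %.4f (n = %d, m = %d)\n",
              x$r2, x$adj_r2, x$n, x$m))
  cat(sprintf("  variance: constrained %.4g + residual %.4g = total %.4g\n",
              x$constrained_variance, x$residual_variance, x$total_variance))
  invisible(x)
}

# R2 of ys on the orthonormal basis q (both centred); permutes rows of ys
rda_r2_quick <- function(q, ys) {
  sum(crossprod(q, ys)^2) / sum(ys^2)
}

# Permutation test of Y ~ X: statistic R2, rows of Y freely permuted.
# Y and X must already be centred/scaled; returns observed R2 and p.
rda_perm_test <- function(ys, xs, nperm, seed) {
  if (sum(ys^2) < 1e-12 * length(ys)) {
    # nothing left to explain: any candidate is uninformative
    return(list(statistic = 0, p = 1))
  }
  q <- qr.Q(qr(xs))
  obs <- rda_r2_quick(q, ys)
  n <- nrow(ys)
  perm_ge <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(nperm)) {
      yp <- ys[sample.int(n), , drop = FALSE]
      yp <- base::scale(yp, center = TRUE, scale = FALSE)
      if (rda_r2_quick(q, yp) >= obs) count <- count + 1L
    }
    count
  })
  list(statistic = obs, p = (1 + perm_ge) / (1 + nperm))
}

#' Forward selection of explanatory variables for RDA
#'
#' Stepwise forward selection driven solely by the adjusted R2 and
#' permutation p-values, following the double-stopping-rule scheme: (i) a
#' global permutation test of the full candidate set must be significant
#' before any selection starts; then, at each step, the candidate giving the
#' highest cumulative adjusted R2 is added only if (ii) its marginal
#' permutation p-value (rows of the response residualized on the already
#' selected variables freely permuted) is below `alpha` and (iii) the
#' cumulative adjusted R2 does not exceed the adjusted R2 of the
#' all-candidates model. With `nperm` permutations the smallest attainable
#' p-value is `1/(nperm + 1)`.
#'
#' @param y response matrix (rows = sites)
#' @param candidates data.frame or matrix of candidate explanatory variables
#' @param alpha significance threshold for entry
#' @param nperm number of permutations
#' @param seed integer seed for the permutations
#' @param scale_y standardize response columns
#' @return object of class `forward_selection`: `selected` (names in entry
#'   order), `path` (per-step data.frame: variable, cumulative adj R2,
#'   marginal statistic and p), `global` (full-model adj R2 and p), and the
#'   final `model` ([fit_rda()] result) or NULL if nothing was selected
#' @export
forward_select <- function(y, candidates, alpha = 0.05, nperm = 199L,
                           seed = 1L, scale_y = TRUE) {
  y <- as.matrix(y)
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1L) stop("need at least one candidate")
  cand_names <- colnames(candidates)
  n <- nrow(y)

  ys <- base::scale(y, center = TRUE, scale = scale_y)
  xall <- base::scale(as.matrix(candidates), center = TRUE, scale = TRUE)

  global_fit <- fit_rda(y, candidates, scale_y = scale_y)
  gl_test <- rda_perm_test(ys, xall, nperm, seed)
  global <- list(adj_r2 = global_fit$adj_r2, r2 = global_fit$r2, p = gl_test$p)

  selected <- character(0)
  path <- data.frame(variable = character(0), adj_r2 = numeric(0),
                     statistic = numeric(0), p = numeric(0))
  if (gl_test$p >= alpha) {
    return(structure(list(selected = selected, path = path, global = global,
                          model = NULL, alpha = alpha, nperm = nperm),
                     class = "forward_selection"))
  }

  step_seed <- seed
  repeat {
    remaining <- setdiff(cand_names, selected)
    if (!length(remaining)) break
    adj <- vapply(remaining, function(v) {
      xs <- as.matrix(candidates[c(selected, v)])
      if (n <= ncol(xs) + 1L) return(-Inf)
      f <- try(fit_rda(y, xs, scale_y = scale_y), silent = TRUE)
      if (inherits(f, "try-error")) -Inf else f$adj_r2
    }, numeric(1))
    if (all(!is.finite(adj))) break
    # ties broken by candidate label order (the order of `candidates`)
    best <- remaining[which.max(adj)]
    if (adj[best] > global$adj_r2 + 1e-12) break
    # marginal permutation test, response and candidate residualized on the
    # already-selected variables
    if (length(selected)) {
      qs <- qr(base::scale(as.matrix(candidates[selected]), TRUE, TRUE))
      yres <- qr.resid(qs, ys)
      xres <- qr.resid(qs, base::scale(as.matrix(candidates[best]), TRUE, TRUE))
    } else {
      yres <- ys
      xres <- base::scale(as.matrix(candidates[best]), TRUE, TRUE)
    }
    step_seed <- step_seed + 1L
    tst <- rda_perm_test(yres, xres, nperm, step_seed)
    path <- rbind(path, data.frame(variable = best, adj_r2 = adj[best],
                                   statistic = tst$statistic, p = tst$p))
    if (tst$p >= alpha) break
    selected <- c(selected, best)
  }

  model <- if (length(selected)) {
    fit_rda(y, as.matrix(candidates[selected]), scale_y = scale_y)
  } else {
    NULL
  }
  structure(list(selected = selected, path = path, global = global,
                 model = model, alpha = alpha, nperm = nperm),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("Forward selection (alpha =", x$alpha, ",", x$nperm, "permutations)\n")
  cat(sprintf("  global model: adj R2 = %.4f, p = %.4g\n",
              x$global$adj_r2, x$global$p))
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = " + "), "\n")
    cat(sprintf("  final adj R2 = %.4f\n", x$model$adj_r2))
  } else {
    cat("  no variable selected\n")
  }
  invisible(x)
}
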