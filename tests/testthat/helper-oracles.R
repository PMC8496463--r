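# Independent brute-force oracles used to cross-check the package's
# multivariate routines against the literal definitions.

# RV coefficient computed entry-by-entry from the definition
oracle_rv <- function(x, y) {
  wx <- x %*% t(x)
  wy <- y %*% t(y)
  num <- 0
  dx <- 0
  dy <- 0
  for (i in seq_len(nrow(wx))) {
    for (j in seq_len(ncol(wx))) {
      num <- num + wx[i, j] * wy[i, j]
      dx <- dx + wx[i, j]^2
      dy <- dy + wy[i, j]^2
    }
  }
  num / sqrt(dx * dy)
}

# Full PTA computed step by step from the definitions, independent of the
# package's composition of the same quantities.
oracle_pta <- function(tables) {
  k <- length(tables)
  rv <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      rv[i, j] <- oracle_rv(tables[[i]], tables[[j]])
    }
  }
  eig <- eigen(rv, symmetric = TRUE)
  w <- eig$vectors[, 1]
  if (sum(w) < 0) w <- -w
  coords <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), nrow = k)
  cos2 <- coords[, 1]^2 / rowSums(coords^2)
  alpha <- w / sum(w)
  comp <- matrix(0, nrow(tables[[1]]), ncol(tables[[1]]))
  for (i in seq_len(k)) comp <- comp + alpha[i] * tables[[i]]
  ceig <- eigen(t(comp) %*% comp, symmetric = TRUE)
  ev <- pmax(ceig$values, 0)
  keep <- ev > max(ev) * 1e-12
  v <- ceig$vectors[, keep, drop = FALSE]
  ev <- ev[keep]
  for (j in seq_len(ncol(v))) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  u <- comp %*% v %*% diag(1 / sqrt(ev), nrow = length(ev))
  list(
    rv = rv,
    inter_eigenvalues = eig$values,
    weights = w,
    cos2 = cos2,
    compromise = comp,
    comp_eigenvalues = ev,
    comp_var_coords = v %*% diag(sqrt(ev), nrow = length(ev)),
    comp_row_coords = comp %*% v,
    intra_rows = lapply(tables, function(x) x %*% v),
    intra_vars = lapply(tables, function(x) t(x) %*% u)
  )
}

# long-format stack input from a list of matrices (already standardized
# values are passed through build_stack with scaling that leaves them be)
stack_from_matrices <- function(tables, wavelengths = NULL) {
  if (is.null(wavelengths)) wavelengths <- seq_along(tables)
  do.call(rbind, lapply(seq_along(tables), function(k) {
    x <- tables[[k]]
    expand.grid(station = seq_len(nrow(x)), parameter = paste0("p", seq_len(ncol(x))),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
      transform(wavelength = wavelengths[k],
                value = as.vector(x))
  }))
}
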