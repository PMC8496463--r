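#' Build a K-table stack of detrended parameters
#'
#' Arranges a long table of detrended photosynthetic parameters into one
#' matrix per wavelength (stations in rows, parameters in columns) sharing
#' identical row and column sets. Stations missing any wavelength-by-parameter
#' cell are dropped when `drop_incomplete` (and listed in the result). Each
#' parameter column is then standardized globally: by the mean and standard
#' deviation (or, optionally, the half-range) computed over the stacked rows
#' of all tables, so that the between-table differences the analysis targets
#' are preserved.
#'
#' @param data long data.frame with columns `wavelength`, `station`,
#'   `parameter`, `value`
#' @param drop_incomplete drop stations with missing cells (default TRUE)
#' @param scale `"sd"` (centre-and-reduce by the global SD) or `"range"`
#'   (divide by the global max - min)
#' @return object of class `ktable_stack`: `tables` (named list of matrices),
#'   `wavelengths`, `stations`, `parameters`, `scaling` (per-parameter centre
#'   and scale), `dropped_stations`
#' @export
build_stack <- function(data, drop_incomplete = TRUE, scale = c("sd", "range")) {
  scale <- match.arg(scale)
  stopifnot(all(c("wavelength", "station", "parameter", "value") %in% names(data)))
  wls <- sort(unique(data$wavelength))
  if (length(wls) < 2L) stop("need at least 2 wavelengths")
  pars <- unique(data$parameter)
  stations <- unique(data$station)

  full <- expand.grid(wavelength = wls, station = stations, parameter = pars,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- merge(full, data, all.x = TRUE, sort = FALSE)
  bad <- unique(m$station[!is.finite(m$value)])
  dropped <- character(0)
  if (length(bad)) {
    if (!drop_incomplete) stop("missing cells for station(s): ",
                               paste(bad, collapse = ", "))
    dropped <- as.character(bad)
    message("dropping incomplete station(s) from the K-table stack: ",
            paste(dropped, collapse = ", "))
    m <- m[!(m$station %in% bad), ]
    stations <- setdiff(stations, bad)
  }
  if (length(stations) < 2L || length(pars) < 2L) {
    stop("stack needs at least 2 complete stations and 2 parameters")
  }

  centre <- vapply(pars, function(p) mean(m$value[m$parameter == p]), numeric(1))
  scl <- vapply(pars, function(p) {
    v <- m$value[m$parameter == p]
    s <- if (scale == "sd") stats::sd(v) else (max(v) - min(v))
    s
  }, numeric(1))
  if (any(scl <= 0)) {
    stop("zero variance across the stack for parameter(s): ",
         paste(pars[scl <= 0], collapse = ", "))
  }

  tables <- lapply(wls, function(w) {
    sub <- m[m$wavelength == w, ]
    x <- matrix(NA_real_, nrow = length(stations), ncol = length(pars),
                dimnames = list(as.character(stations), pars))
    x[cbind(as.character(sub$station), sub$parameter)] <-
      (sub$value - centre[sub$parameter]) / scl[sub$parameter]
    x
  })
  names(tables) <- as.character(wls)

  out <- list(
    tables = tables, wavelengths = wls,
    stations = as.character(stations), parameters = pars,
    scaling = data.frame(parameter = pars, centre = unname(centre),
                         scale = unname(scl), method = scale),
    dropped_stations = dropped
  )
  class(out) <- "ktable_stack"
  out
}

#' Undo the stack standardization
#'
#' @param stack a [build_stack()] result
#' @return long data.frame (`wavelength`, `station`, `parameter`, `value`)
#'   on the original scale
#' @export
unscale_stack <- function(stack) {
  do.call(rbind, lapply(seq_along(stack$tables), function(k) {
    x <- stack$tables[[k]]
    long <- expand.grid(station = rownames(x), parameter = colnames(x),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sc <- stack$scaling
    i <- match(long$parameter, sc$parameter)
    long$value <- x[cbind(long$station, long$parameter)] * sc$scale[i] + sc$centre[i]
    cbind(wavelength = stack$wavelengths[k], long)
  }))
}

rv_coefficient <- function(x, y) {
  wx <- tcrossprod(x)
  wy <- tcrossprod(y)
  sum(wx * wy) / sqrt(sum(wx * wx) * sum(wy * wy))
}

#' PTA interstructure: similarity of the wavelength tables
#'
#' Computes the matrix of RV coefficients between all pairs of tables,
#' \deqn{RV(X_k, X_l) = \mathrm{tr}(X_k X_k' X_l X_l') /
#'   \sqrt{\mathrm{tr}((X_k X_k')^2)\,\mathrm{tr}((X_l X_l')^2)},}
#' its eigendecomposition, the table weights (components of the first
#' eigenvector, oriented positive, unit norm) and the representation quality
#' cos^2 of each table (share of its squared coordinates carried by axis 1).
#'
#' @param stack a [build_stack()] result
#' @return list: `rv` (K x K matrix), `eigenvalues`, `pct_inertia`,
#'   `weights`, `coords` (table coordinates on the interstructure axes),
#'   `cos2`
#' @export
interstructure <- function(stack) {
  tabs <- stack$tables
  k <- length(tabs)
  for (nm in names(tabs)) {
    if (all(abs(tabs[[nm]]) < 1e-300)) stop("degenerate (all-zero) table: ", nm)
  }
  rv <- matrix(1, k, k, dimnames = list(names(tabs), names(tabs)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j > i) rv[i, j] <- rv[j, i] <- rv_coefficient(tabs[[i]], tabs[[j]])
    }
  }
  eig <- eigen(rv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  w <- eig$vectors[, 1]
  if (sum(w) < 0) w <- -w # Perron eigenvector of a positive matrix: one sign
  coords <- eig$vectors %*% diag(sqrt(ev), nrow = k)
  rownames(coords) <- names(tabs)
  cos2 <- coords[, 1]^2 / rowSums(coords^2)
  list(
    rv = rv,
    eigenvalues = eig$values,
    pct_inertia = 100 * eig$values / sum(eig$values),
    weights = stats::setNames(w, names(tabs)),
    coords = coords,
    cos2 = cos2
  )
}

#' PTA compromise: consensus structure of the wavelength tables
#'
#' Forms the compromise matrix as the convex combination
#' \eqn{C = \sum_k \alpha_k X_k} with \eqn{\alpha_k = w_k / \sum w} (the
#' interstructure weights renormalized to sum to one; the axes' percentage of
#' inertia is invariant to that renormalization), and decomposes its
#' cross-product into principal axes. Axis signs are fixed by making the
#' largest-magnitude variable loading of each axis positive.
#'
#' @param stack a [build_stack()] result
#' @param weights positive table weights, typically from [interstructure()]
#' @return list: `compromise` (matrix), `eigenvalues`, `pct_inertia`,
#'   `variable_coords`, `row_coords`, `axes` (eigenvectors), `alpha`
#' @export
pta_compromise <- function(stack, weights) {
  tabs <- stack$tables
  if (length(weights) != length(tabs)) stop("one weight per table required")
  if (any(weights <= 0)) stop("weights must be positive")
  alpha <- weights / sum(weights)
  comp <- Reduce(`+`, Map(`*`, tabs, alpha))
  eig <- eigen(crossprod(comp), symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  keep <- ev > max(ev) * 1e-12
  v <- eig$vectors[, keep, drop = FALSE]
  ev <- ev[keep]
  # sign convention: dominant loading positive on each axis
  for (j in seq_len(ncol(v))) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  rownames(v) <- colnames(comp)
  var_coords <- v %*% diag(sqrt(ev), nrow = length(ev))
  row_coords <- comp %*% v
  colnames(var_coords) <- colnames(row_coords) <-
    paste0("axis", seq_along(ev))
  list(
    compromise = comp,
    eigenvalues = ev,
    pct_inertia = 100 * ev / sum(ev),
    variable_coords = var_coords,
    row_coords = row_coords,
    axes = v,
    alpha = alpha
  )
}

#' PTA intrastructure: per-table projections on the compromise axes
#'
#' Projects each wavelength table's rows (stations) and columns (parameters)
#' onto the principal axes of the compromise. The weighted average of the
#' per-table projections reproduces the compromise coordinates exactly. For
#' plotting and wavelength-dependence metrics, the per-station "polygon"
#' (its K positions on the first two axes, one per wavelength) and its area
#' are returned.
#'
#' @param stack a [build_stack()] result
#' @param comp a [pta_compromise()] result on the same stack
#' @param n_axes number of compromise axes to project on (at most the
#'   compromise rank)
#' @return list: `row_coords` and `variable_coords` (named lists of per-table
#'   matrices), `polygons` (per-station matrices of K vertices on axes 1-2),
#'   `polygon_areas`
#' @export
pta_intrastructure <- function(stack, comp, n_axes = 2L) {
  if (n_axes > length(comp$eigenvalues)) {
    stop("n_axes exceeds the compromise rank (", length(comp$eigenvalues), ")")
  }
  v <- comp$axes
  u <- comp$compromise %*% v %*% diag(1 / sqrt(comp$eigenvalues),
                                      nrow = length(comp$eigenvalues))
  row_coords <- lapply(stack$tables, function(x) {
    rc <- x %*% v
    colnames(rc) <- paste0("axis", seq_len(ncol(rc)))
    rc
  })
  variable_coords <- lapply(stack$tables, function(x) {
    vc <- crossprod(x, u)
    colnames(vc) <- paste0("axis", seq_len(ncol(vc)))
    vc
  })
  polygons <- lapply(stack$stations, function(s) {
    do.call(rbind, lapply(row_coords, function(rc) rc[s, seq_len(n_axes)]))
  })
  names(polygons) <- stack$stations
  areas <- vapply(polygons, function(p) polygon_area(p[, 1], p[, 2]), numeric(1))
  list(
    row_coords = row_coords,
    variable_coords = variable_coords,
    polygons = polygons,
    polygon_areas = areas
  )
}

# shoelace area of the (possibly self-intersecting) wavelength polygon
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Full partial triadic analysis
#'
#' Convenience wrapper running [interstructure()], [pta_compromise()] and
#' [pta_intrastructure()] on a stack.
#'
#' @inheritParams pta_intrastructure
#' @param stack a [build_stack()] result
#' @return list of class `pta_result` with elements `interstructure`,
#'   `compromise`, `intrastructure`
#' @export
pta <- function(stack, n_axes = 2L) {
  inter <- interstructure(stack)
  comp <- pta_compromise(stack, inter$weights)
  intra <- pta_intrastructure(stack, comp, n_axes = min(n_axes, length(comp$eigenvalues)))
  out <- list(interstructure = inter, compromise = comp, intrastructure = intra)
  class(out) <- "pta_result"
  out
}

#' @export
print.pta_result <- function(x, ...) {
  cat("Partial triadic analysis\n")
  cat("  interstructure axes 1-2:",
      sprintf("%.2f%%", sum(x$interstructure$pct_inertia[1:2])),
      "of total inertia\n")
  cat("  table weights:",
      paste(sprintf("%.3f", x$interstructure$weights), collapse = ", "), "\n")
  cat("  compromise axes 1-2:",
      sprintf("%.2f%%", sum(x$compromise$pct_inertia[seq_len(min(2, length(x$compromise$pct_inertia)))])),
      "of total inertia\n")
  invisible(x)
}
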