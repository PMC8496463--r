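#' Diffuse attenuation coefficient of PAR
#'
#' Estimates the downwelling diffuse attenuation coefficient Kd(PAR) from a
#' vertical PAR profile. With exactly two depths this is the classical
#' two-point form \eqn{K_d = [\ln(I_0) - \ln(I_z)]/Z}; with more depths it is
#' the negative least-squares slope of ln(PAR) on depth, which uses all
#' measurements and reduces to the two-point form when only two are present.
#'
#' @param depths depths (m, strictly increasing, >= 0)
#' @param par PAR at those depths (umol quanta m-2 s-1, all > 0)
#' @return Kd(PAR) in m-1. A value of 0 (uniform profile) is returned with a
#'   `degenerate` attribute set: the euphotic depth is undefined in that case.
#' @export
attenuation_coefficient <- function(depths, par) {
  keep <- is.finite(depths) & is.finite(par)
  depths <- depths[keep]
  par <- par[keep]
  if (length(depths) < 2L) stop("need at least 2 usable depths")
  if (any(par <= 0)) stop("all PAR values used for attenuation must be > 0")
  if (any(diff(order(depths)) <= 0)) {
    o <- order(depths)
    depths <- depths[o]
    par <- par[o]
  }
  if (length(depths) == 2L) {
    kd <- (log(par[1]) - log(par[2])) / (depths[2] - depths[1])
  } else {
    kd <- -unname(stats::coef(stats::lm(log(par) ~ depths))[2])
  }
  if (abs(kd) < 1e-12) {
    kd <- 0
    attr(kd, "degenerate") <- TRUE
  }
  kd
}

#' Euphotic-layer depth
#'
#' Depth at which downwelling PAR falls to 1% of its surface value,
#' \eqn{Z_{eu} = 4.6 / K_{d(PAR)}}.
#'
#' @param kd_par diffuse attenuation coefficient (m-1, > 0)
#' @return euphotic depth in m
#' @export
euphotic_depth <- function(kd_par) {
  if (any(kd_par <= 0)) stop("kd_par must be positive (uniform profiles have no euphotic depth)")
  4.6 / kd_par
}

#' Vertically averaged light intensity in the mixed layer
#'
#' \deqn{E_{avg} = I_0 (1 - e^{-K_d Z}) / (K_d Z)}
#' with the continuous limit \eqn{E_{avg} \to I_0} as \eqn{K_d Z \to 0}.
#'
#' @param i0 surface PAR (umol quanta m-2 s-1)
#' @param kd_par diffuse attenuation coefficient (m-1)
#' @param z_umixl upper-mixed-layer depth (m)
#' @return averaged PAR in umol quanta m-2 s-1
#' @export
averaged_light <- function(i0, kd_par, z_umixl) {
  if (any(i0 <= 0) || any(kd_par <= 0) || any(z_umixl <= 0)) {
    stop("i0, kd_par and z_umixl must all be positive")
  }
  x <- kd_par * z_umixl
  i0 * (-expm1(-x)) / x
}

#' Upper-mixed-layer depth and stratification flag
#'
#' A water column is considered stratified when the density difference
#' between the bottom of the profile and the mean density of the surface
#' layer (0-1.5 m) strictly exceeds 0.086 kg m-3 (the boundary value counts
#' as mixed). For mixed columns the upper-mixed-layer depth Z_umixl is the
#' bottom depth; for stratified columns it is the shallowest depth at which
#' the density excess over the surface mean first exceeds the threshold.
#'
#' @param depths depths (m, strictly increasing)
#' @param density seawater density at those depths (kg m-3)
#' @param surface_band depth interval defining the surface layer (m)
#' @param threshold stratification threshold (kg m-3)
#' @return list with `z_umixl` (m) and `stratified` (logical)
#' @export
mixed_layer <- function(depths, density, surface_band = c(0, 1.5),
                        threshold = 0.086) {
  stopifnot(length(depths) == length(density))
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  surf <- depths >= surface_band[1] & depths <= surface_band[2]
  if (!any(surf)) stop("no depths within the surface band")
  surf_mean <- mean(density[surf])
  excess <- density - surf_mean
  stratified <- excess[length(excess)] > threshold
  if (!stratified) {
    z <- depths[length(depths)]
  } else {
    z <- depths[which(excess > threshold)[1]]
  }
  list(z_umixl = z, stratified = stratified)
}

# Quantum integral of a spectrum over [lo, hi] nm by trapezoid with linear
# interpolation at the band edges (band limits need not fall on the grid).
integrate_band <- function(wavelength, value, lo, hi) {
  o <- order(wavelength)
  wl <- wavelength[o]
  v <- value[o]
  if (lo < min(wl) || hi > max(wl)) {
    stop(sprintf("spectral grid [%g, %g] does not cover band [%g, %g] nm",
                 min(wl), max(wl), lo, hi))
  }
  inside <- wl > lo & wl < hi
  xs <- c(lo, wl[inside], hi)
  ys <- c(stats::approx(wl, v, xout = lo)$y, v[inside],
          stats::approx(wl, v, xout = hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Spectral-band light-quality ratios
#'
#' Integrates hyperspectral downwelling quanta over the blue (410-490 nm),
#' green (480-580 nm) and red (600-700 nm) bands (the blue and green bands
#' overlap by construction) and forms the light-quality ratios R/B, G/B and
#' G/R. Ratios are computed per replicate profile, averaged over replicates
#' at each depth, then averaged over all depths down to `z_max`.
#'
#' @param spectral data.frame with columns `depth`, `wavelength`, `value`
#'   (quanta per nm) and optionally `replicate`
#' @param z_max maximum depth (m) entering the average
#' @param bands named list of band limits (nm)
#' @return named list `ratio_rb`, `ratio_gb`, `ratio_gr`
#' @export
band_ratios <- function(spectral, z_max = 2.5,
                        bands = list(B = c(410, 490), G = c(480, 580),
                                     R = c(600, 700))) {
  stopifnot(all(c("depth", "wavelength", "value") %in% names(spectral)))
  if (is.null(spectral$replicate)) spectral$replicate <- 1L
  spectral <- spectral[spectral$depth <= z_max, , drop = FALSE]
  if (nrow(spectral) == 0L) stop("no spectral measurements within z_max")

  cell <- interaction(spectral$depth, spectral$replicate, drop = TRUE)
  per_cell <- lapply(split(spectral, cell), function(d) {
    b <- integrate_band(d$wavelength, d$value, bands$B[1], bands$B[2])
    g <- integrate_band(d$wavelength, d$value, bands$G[1], bands$G[2])
    r <- integrate_band(d$wavelength, d$value, bands$R[1], bands$R[2])
    if (b <= 0) stop("blue-band integral is zero: R/B and G/B undefined")
    if (r <= 0) stop("red-band integral is zero: G/R undefined")
    data.frame(depth = d$depth[1], rb = r / b, gb = g / b, gr = g / r)
  })
  rat <- do.call(rbind, per_cell)
  by_depth <- stats::aggregate(rat[c("rb", "gb", "gr")],
                               by = list(depth = rat$depth), FUN = mean)
  list(
    ratio_rb = mean(by_depth$rb),
    ratio_gb = mean(by_depth$gb),
    ratio_gr = mean(by_depth$gr)
  )
}
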