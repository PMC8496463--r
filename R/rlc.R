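#' Default rapid-light-curve PAR ladder
#'
#' A 14-step, roughly geometric ladder from 0 to 2000 umol quanta m-2 s-1.
#' The initial dark step determines Fv/Fm; the top steps are supra-saturating
#' for typical coastal communities so that the photoinhibited branch of the
#' PE response is sampled.
#'
#' @export
default_par_steps <- function() {
  c(0, 10, 20, 40, 70, 110, 170, 260, 390, 580, 860, 1270, 1700, 2000)
}

#' Simulate a rapid light curve
#'
#' Constructs the fluorescence readings (F, Fm') of a 14-step rapid light
#' curve from a ground-truth Eilers-Peeters PE response, a dark-acclimated
#' maximum quantum yield and an NPQ light-response model:
#' \deqn{Fm'(E) = Fm / (1 + NPQ(E)), \quad
#'       Y(E) = r.ETR_{EP}(E) / (0.5 E) \; (E > 0), \quad Y(0) = F_v/F_m,}
#' \deqn{F = Fm' (1 - Y).}
#' Additive Gaussian noise truncated at zero can be applied to F and Fm'.
#'
#' @param ep Eilers-Peeters coefficients, numeric `c(a, b, c)` (all > 0)
#' @param fvfm dark-acclimated maximum quantum yield, in (0, 0.7]
#' @param npq_model list describing the NPQ light response: either
#'   `list(model = "michaelis_menten", npq_max =, k_half =)`,
#'   `list(model = "linear_origin", slope =)` or `list(model = "zero")`
#' @param par_steps PAR ladder; the first step must be 0 (dark) and steps must
#'   strictly increase
#' @param fm dark maximal fluorescence level (relative units)
#' @param noise_sd additive Gaussian noise SD on the fluorescence readings
#' @param seed integer seed for the noise
#' @return data.frame of class `rapid_light_curve` with columns `par`, `f`,
#'   `fm_prime`.
#' @export
simulate_rlc <- function(ep, fvfm, npq_model, par_steps = default_par_steps(),
                         fm = 1, noise_sd = 0, seed = 1L) {
  if (length(ep) != 3L || any(!is.finite(ep)) || any(ep <= 0)) {
    stop("ep: Eilers-Peeters coefficients (a, b, c) must all be positive")
  }
  if (!(fvfm > 0 && fvfm <= 0.7)) stop("fvfm must lie in (0, 0.7]")
  if (par_steps[1] != 0) stop("par_steps: first step must be 0 (dark, for Fv/Fm)")
  if (any(diff(par_steps) <= 0)) stop("par_steps must be strictly increasing")

  a <- ep[[1]]; b <- ep[[2]]; cc <- ep[[3]]
  e <- par_steps
  y <- ifelse(e > 0, ep_predict(e, a, b, cc) / (ETR_FACTOR * e), fvfm)
  if (any(y <= 0 | y >= 1)) {
    stop("inconsistent truth: implied Y(II) outside (0, 1) at PAR = ",
         paste(e[y <= 0 | y >= 1], collapse = ", "))
  }
  if (any(y[e > 0] > fvfm + 1e-12)) {
    stop("inconsistent truth: implied Y(II) exceeds fvfm at PAR = ",
         paste(e[e > 0][y[e > 0] > fvfm + 1e-12], collapse = ", "))
  }
  pars <- npq_model[setdiff(names(npq_model), "model")]
  npq <- npq_model_predict(npq_model$model, pars, e)
  if (any(npq < 0)) stop("npq_model produced negative NPQ")
  fm_prime <- fm / (1 + npq)
  f <- fm_prime * (1 - y)
  if (noise_sd > 0) {
    ns <- with_seed(seed, stats::rnorm(2L * length(e), sd = noise_sd))
    f <- pmax(f + ns[seq_along(e)], 1e-6)
    fm_prime <- pmax(fm_prime + ns[length(e) + seq_along(e)], 1e-6)
    fm_prime <- pmax(fm_prime, f + 1e-6) # keep 0 < F <= Fm'
  }
  out <- data.frame(par = e, f = f, fm_prime = fm_prime)
  class(out) <- c("rapid_light_curve", "data.frame")
  out
}

#' Derive per-step fluorescence quantities from a rapid light curve
#'
#' Computes, from the raw (PAR, F, Fm') steps of one rapid light curve and a
#' PSII functional absorption cross section, the dark-acclimated maximum
#' quantum yield and the per-step derived quantities:
#' \deqn{Y(II) = (Fm' - F)/Fm', \quad F_v/F_m = (F_m - F_0)/F_m,}
#' \deqn{r.ETR = Y(II) \times PAR \times 0.5, \quad
#'       PAR(II) = \sigma_{PSII} L \, PAR, \quad
#'       ETR(II) = PAR(II) \, Y(II)/(F_v/F_m), \quad
#'       NPQ = F_m/Fm' - 1,}
#' with Fm taken from the initial dark step and the factor 0.5 expressing
#' equal light partitioning between the photosystems.
#'
#' @param rlc data.frame with columns `par`, `f`, `fm_prime`; the first row
#'   must be the dark step (PAR = 0)
#' @param sigma functional absorption cross section of PSII (nm^2)
#' @return list: `fvfm` and `steps`, a data.frame with columns `par`, `y_ii`,
#'   `r_etr`, `par_ii`, `etr_ii`, `npq`.
#' @export
derive_steps <- function(rlc, sigma) {
  stopifnot(all(c("par", "f", "fm_prime") %in% names(rlc)))
  if (nrow(rlc) < 2L) stop("rapid light curve needs at least 2 steps")
  if (rlc$par[1] != 0) stop("first step must be dark (PAR = 0)")
  if (sigma <= 0) stop("sigma must be positive")
  if (any(rlc$fm_prime <= 0)) stop("fm_prime must be positive")
  if (any(rlc$f > rlc$fm_prime)) stop("F exceeds Fm' at PAR = ",
    paste(rlc$par[rlc$f > rlc$fm_prime], collapse = ", "))

  fm <- rlc$fm_prime[1]
  f0 <- rlc$f[1]
  fvfm <- (fm - f0) / fm

  y <- (rlc$fm_prime - rlc$f) / rlc$fm_prime
  r_etr <- y * rlc$par * ETR_FACTOR
  par_ii <- sigma * PARII_PER_NM2 * rlc$par
  etr_ii <- par_ii * (y / fvfm)
  npq <- fm / rlc$fm_prime - 1

  list(
    fvfm = fvfm,
    steps = data.frame(
      par = rlc$par, y_ii = y, r_etr = r_etr,
      par_ii = par_ii, etr_ii = etr_ii, npq = npq
    )
  )
}
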