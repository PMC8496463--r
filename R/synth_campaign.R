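#' Ground truth for a synthetic multi-wavelength campaign
#'
#' Defines the generative model behind a synthetic field campaign: population
#' lines (intercept at 440 nm and slope per nm of transposed wavelength) for
#' each base photosynthetic parameter, between-station random-effect standard
#' deviations, measurement-noise levels and the underwater light-field
#' settings. The defaults reproduce the conditions of a spring coastal-sea
#' campaign: 19 stations, five measuring wavelengths (440, 480, 540, 590,
#' 625 nm), Fv/Fm centred on 0.61 with a -0.00012 per-nm trend, Sigma(II)
#' falling from ~6 to ~2 nm2 across the spectrum, relative ETRmax rising from
#' ~41 to ~120, and NPQ saturation parameters that give NPQ300/NPQ1200 of
#' about 0.9/1.9 at 440 nm, fading towards the red.
#'
#' Absolute-unit parameters (alpha(II), ETRmax(II), Ek(II), Eop(II)) are not
#' specified independently: they follow physically from the relative
#' Eilers-Peeters triple, Sigma(II) and Fv/Fm, so a zero-noise campaign is
#' exactly self-consistent end to end.
#'
#' @param seed integer seed; a fixed seed yields a byte-identical campaign
#' @param population data.frame with columns `parameter`, `intercept`,
#'   `slope` for the six base parameters `fvfm`, `sigma`, `r_alpha`,
#'   `r_etrmax`, `r_eop`, `npq_max`
#' @param random_sds data.frame with columns `parameter`, `sd_intercept`,
#'   `sd_slope` (between-station SDs of intercept and slope deviations)
#' @param noise_sd named list: `fluorescence` (RLC readings), `induction`
#'   (O-I1 readings), both in relative fluorescence units
#' @param k_half Michaelis-Menten half-saturation PAR of the NPQ response
#'   (umol quanta m-2 s-1)
#' @param induction_par actinic PAR of the O-I1 protocol
#' @param par_steps rapid-light-curve PAR ladder
#' @param light list of light-field settings: `kd_range` (log-uniform range of
#'   Kd(PAR), m-1), `i0_range` (surface PAR), `bottom_range` (profile bottom
#'   depth, m), `p_stratified` (probability a station is stratified),
#'   `density_step_range` (kg m-3), `step_depth_range` (m)
#' @return object of class `synthetic_truth`
#' @export
synthetic_truth <- function(
    seed = 1L,
    population = data.frame(
      parameter = c("fvfm", "sigma", "r_alpha", "r_etrmax", "r_eop", "npq_max"),
      intercept = c(0.61, 6.08, 0.21, 41.19, 1998.9, 3.16),
      slope     = c(-0.00012, -0.0241, 0.00029, 0.44, -1.69, -0.014)
    ),
    random_sds = data.frame(
      parameter    = c("fvfm", "sigma", "r_alpha", "r_etrmax", "r_eop", "npq_max"),
      sd_intercept = c(0.02, 0.25, 0.015, 5.0, 120, 0.25),
      sd_slope     = c(0, 0, 0, 0.05, 0, 0)
    ),
    noise_sd = list(fluorescence = 0.01, induction = 0.005),
    k_half = 750,
    induction_par = 1500,
    par_steps = default_par_steps(),
    light = list(
      kd_range = c(0.07, 0.5), i0_range = c(500, 1500),
      bottom_range = c(20, 80), p_stratified = 0.33,
      density_step_range = c(0.12, 0.4), step_depth_range = c(5, 18)
    )) {
  stopifnot(
    all(c("parameter", "intercept", "slope") %in% names(population)),
    all(c("parameter", "sd_intercept", "sd_slope") %in% names(random_sds))
  )
  need <- c("fvfm", "sigma", "r_alpha", "r_etrmax", "r_eop", "npq_max")
  missing_pop <- setdiff(need, population$parameter)
  if (length(missing_pop)) {
    stop("population is missing parameters: ", paste(missing_pop, collapse = ", "))
  }
  if (k_half <= 0) stop("k_half must be positive")
  out <- list(
    seed = as.integer(seed), population = population, random_sds = random_sds,
    noise_sd = noise_sd, k_half = k_half, induction_par = induction_par,
    par_steps = par_steps, light = light
  )
  class(out) <- "synthetic_truth"
  out
}

CAMPAIGN_WAVELENGTHS <- c(440, 480, 540, 590, 625)

pop_value <- function(truth, parameter, wl_t) {
  row <- truth$population[truth$population$parameter == parameter, ]
  row$intercept + row$slope * wl_t
}

# Draw station deviations (intercept, slope) for every base parameter,
# rejecting draws whose implied physics is inconsistent at any wavelength
# (non-positive Eilers-Peeters coefficients, Fv/Fm outside (0, 0.7],
# effective yield exceeding Fv/Fm at the lowest actinic step).
draw_station_effects <- function(truth, wl_t_all, max_tries = 200L) {
  pars <- truth$population$parameter
  e1 <- min(truth$par_steps[truth$par_steps > 0])
  for (try_i in seq_len(max_tries)) {
    dev <- lapply(pars, function(p) {
      sds <- truth$random_sds[truth$random_sds$parameter == p, ]
      c(int = stats::rnorm(1, 0, sds$sd_intercept),
        slp = stats::rnorm(1, 0, sds$sd_slope))
    })
    names(dev) <- pars
    ok <- TRUE
    for (wt in wl_t_all) {
      v <- vapply(pars, function(p) {
        pop_value(truth, p, wt) + dev[[p]]["int"] + dev[[p]]["slp"] * wt
      }, numeric(1))
      names(v) <- pars
      fvfm <- v["fvfm"]; alpha <- v["r_alpha"]; etrmax <- v["r_etrmax"]
      eop <- v["r_eop"]; sig <- v["sigma"]; nmx <- v["npq_max"]
      if (!(fvfm > 0.05 && fvfm <= 0.7) || alpha <= 0 || etrmax <= 0 ||
          eop <= 0 || sig <= 0 || nmx < 0) { ok <- FALSE; break }
      ep <- try(ep_coefficients(alpha, etrmax, eop), silent = TRUE)
      if (inherits(ep, "try-error")) { ok <- FALSE; break }
      y1 <- ep_predict(e1, ep[1], ep[2], ep[3]) / (ETR_FACTOR * e1)
      if (y1 >= 0.98 * fvfm) { ok <- FALSE; break }
    }
    if (ok) return(dev)
  }
  stop("could not draw physically consistent station effects; ",
       "random-effect SDs are too large for the population lines")
}

#' Simulate a synthetic multi-wavelength field campaign
#'
#' Generates every raw data stream of a campaign with known ground truth:
#' triplicate rapid light curves and six O-I1 induction subsamples (three
#' consecutive repeats each) per station and wavelength, one PAR + one
#' hyperspectral light profile and one density profile per station, and a
#' station table of abiotic and biotic explanatory variables. The returned
#' bundle also echoes the realized truth (every per-station, per-wavelength
#' parameter value) so downstream recovery can be checked exactly.
#'
#' @param truth a [synthetic_truth()] object
#' @param n_stations number of stations (>= 2)
#' @param wavelengths measuring wavelengths, a subset of
#'   440, 480, 540, 590, 625 nm
#' @return list of class `campaign` with elements `stations`, `rlc`,
#'   `induction`, `par_profiles`, `spectral_profiles`, `density_profiles`,
#'   `params_true` and `truth`.
#' @export
simulate_campaign <- function(truth, n_stations = 19L,
                              wavelengths = CAMPAIGN_WAVELENGTHS) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_stations < 2L) stop("n_stations must be at least 2")
  bad_wl <- setdiff(wavelengths, CAMPAIGN_WAVELENGTHS)
  if (length(bad_wl)) {
    stop("wavelengths: unknown value(s) ", paste(bad_wl, collapse = ", "),
         " (supported: ", paste(CAMPAIGN_WAVELENGTHS, collapse = ", "), ")")
  }
  wavelengths <- sort(wavelengths)
  wl_t_all <- wavelengths - 440

  old <- local_rng(truth$seed)
  on.exit(restore_rng(old))

  stations <- seq_len(n_stations)
  lt <- truth$light

  # --- station-level light-field and abiotic truth -------------------------
  kd_par <- exp(stats::runif(n_stations, log(lt$kd_range[1]), log(lt$kd_range[2])))
  i0 <- stats::runif(n_stations, lt$i0_range[1], lt$i0_range[2])
  bottom <- stats::runif(n_stations, lt$bottom_range[1], lt$bottom_range[2])
  strat <- stats::runif(n_stations) < lt$p_stratified
  dstep <- stats::runif(n_stations, lt$density_step_range[1], lt$density_step_range[2])
  zstep <- stats::runif(n_stations, lt$step_depth_range[1], lt$step_depth_range[2])
  rho0 <- stats::runif(n_stations, 1025, 1027.5)
  kd_b <- kd_par * stats::runif(n_stations, 1.0, 1.6)
  kd_g <- kd_par * stats::runif(n_stations, 0.7, 1.0)
  kd_r <- kd_par * stats::runif(n_stations, 1.2, 1.6) + 0.12

  station_tab <- data.frame(
    station = stations,
    tss = stats::runif(n_stations, 0, 12),
    salinity = stats::runif(n_stations, 32, 35.5),
    temperature = stats::runif(n_stations, 9, 12),
    din = exp(stats::runif(n_stations, log(1), log(30))),
    po4 = stats::runif(n_stations, 0.05, 1.5),
    si = stats::runif(n_stations, 0.3, 2),
    par_2m = i0 * exp(-2 * kd_par),
    biomass_brown = stats::runif(n_stations, 1, 8),
    biomass_hapto = stats::runif(n_stations, 0.5, 6),
    biomass_crypto = stats::runif(n_stations, 0.05, 1),
    biomass_cyano = stats::runif(n_stations, 0.01, 0.5)
  )

  # --- vertical profiles ---------------------------------------------------
  par_depths <- c(0, seq(0.5, 10, by = 0.5))
  spec_depths <- seq(0.5, 2.5, by = 0.5)
  spec_wl <- seq(400, 700, by = 3)
  # spectral attenuation: interpolate the per-band coefficients across 400-700
  kd_of_wl <- function(s) {
    stats::approx(x = c(400, 450, 530, 650, 700),
                  y = c(kd_b[s], kd_b[s], kd_g[s], kd_r[s], kd_r[s]),
                  xout = spec_wl)$y
  }
  # smooth surface spectral shape (quanta per nm, arbitrary scale)
  surf_shape <- 1 + 0.4 * sin((spec_wl - 400) / 300 * pi)

  par_profiles <- do.call(rbind, lapply(stations, function(s) {
    data.frame(station = s, depth = par_depths,
               par = i0[s] * exp(-kd_par[s] * par_depths))
  }))
  spectral_profiles <- do.call(rbind, lapply(stations, function(s) {
    kdw <- kd_of_wl(s)
    do.call(rbind, lapply(1:3, function(rep_i) {
      do.call(rbind, lapply(spec_depths, function(z) {
        data.frame(station = s, replicate = rep_i, depth = z,
                   wavelength = spec_wl,
                   value = surf_shape * exp(-kdw * z))
      }))
    }))
  }))
  density_profiles <- do.call(rbind, lapply(stations, function(s) {
    zz <- seq(0.5, bottom[s], by = 0.5)
    rho <- rho0[s] + 0.00002 * zz # sub-threshold background gradient
    if (strat[s]) rho <- rho + ifelse(zz >= zstep[s], dstep[s], 0)
    data.frame(station = s, depth = zz, density = rho)
  }))

  ml <- lapply(stations, function(s) {
    mixed_layer(density_profiles$depth[density_profiles$station == s],
                density_profiles$density[density_profiles$station == s])
  })
  station_tab$kd_par_true <- kd_par
  station_tab$i0_true <- i0
  station_tab$z_umixl_true <- vapply(ml, `[[`, numeric(1), "z_umixl")
  station_tab$stratified_true <- vapply(ml, `[[`, logical(1), "stratified")

  # --- per-station photophysiological truth --------------------------------
  effects <- lapply(stations, function(s) draw_station_effects(truth, wl_t_all))

  grid <- expand.grid(station = stations, wavelength = wavelengths,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$station, grid$wavelength), ]
  params_true <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$station[i]
    wl <- grid$wavelength[i]
    wt <- wl - 440
    dev <- effects[[s]]
    val <- function(p) {
      pop_value(truth, p, wt) + dev[[p]]["int"] + dev[[p]]["slp"] * wt
    }
    fvfm <- unname(val("fvfm")); sig <- unname(val("sigma"))
    alpha <- unname(val("r_alpha")); etrmax <- unname(val("r_etrmax"))
    eop <- unname(val("r_eop")); nmx <- unname(val("npq_max"))
    ep <- ep_coefficients(alpha, etrmax, eop)
    tau <- (1 / (sig * NM2_TO_M2 * AVOGADRO * truth$induction_par * UMOL_TO_MOL))
    kconv <- sig * PARII_PER_NM2
    data.frame(
      station = s, wavelength = wl,
      fvfm = fvfm, sigma = sig, tau = tau,
      ep_a = ep[1], ep_b = ep[2], ep_c = ep[3],
      r_alpha = alpha, r_etrmax = etrmax, r_eop = eop, r_ek = etrmax / alpha,
      alpha_ii = 2 * alpha / fvfm,
      etrmax_ii = 2 * kconv * etrmax / fvfm,
      eop_ii = kconv * eop,
      ek_ii = kconv * etrmax / alpha,
      npq_max = nmx, k_half = truth$k_half,
      npq300 = nmx * 300 / (truth$k_half + 300),
      npq1200 = nmx * 1200 / (truth$k_half + 1200),
      row.names = NULL
    )
  }))

  # --- raw measurement streams --------------------------------------------
  n_cells <- nrow(params_true)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_cells * (3L + 18L))
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    sub_seeds[seed_i]
  }

  rlc_list <- vector("list", n_cells * 3L)
  ind_list <- vector("list", n_cells * 6L)
  ri <- 0L; ii <- 0L
  for (i in seq_len(n_cells)) {
    pt <- params_true[i, ]
    fm_level <- 0.5 / (1 - pt$fvfm) # gain-adjusted so dark Ft is ~0.5
    npq_model <- list(model = "michaelis_menten",
                      npq_max = pt$npq_max, k_half = pt$k_half)
    for (rep_i in 1:3) {
      rlc <- simulate_rlc(
        ep = c(pt$ep_a, pt$ep_b, pt$ep_c), fvfm = pt$fvfm,
        npq_model = npq_model, par_steps = truth$par_steps, fm = fm_level,
        noise_sd = truth$noise_sd$fluorescence, seed = next_seed()
      )
      ri <- ri + 1L
      rlc_list[[ri]] <- cbind(
        data.frame(station = pt$station, wavelength = pt$wavelength,
                   replicate = rep_i),
        rlc
      )
    }
    for (sub_i in 1:6) {
      reps <- lapply(1:3, function(r) {
        ic <- simulate_induction(
          tau = pt$tau, f_o = 0.5, f_i1 = 0.5 / (1 - pt$fvfm),
          par = truth$induction_par,
          noise_sd = truth$noise_sd$induction, seed = next_seed()
        )
        cbind(data.frame(station = pt$station, wavelength = pt$wavelength,
                         subsample = sub_i, rep = r), ic)
      })
      ii <- ii + 1L
      ind_list[[ii]] <- do.call(rbind, reps)
    }
  }

  out <- list(
    stations = station_tab,
    rlc = do.call(rbind, rlc_list),
    induction = do.call(rbind, ind_list),
    par_profiles = par_profiles,
    spectral_profiles = spectral_profiles,
    density_profiles = density_profiles,
    params_true = params_true,
    wavelengths = wavelengths,
    truth = truth
  )
  class(out) <- "campaign"
  out
}

#' @export
print.campaign <- function(x, ...) {
  cat("Synthetic multi-wavelength campaign\n")
  cat("  stations:", nrow(x$stations),
      " wavelengths:", paste(x$wavelengths, collapse = ", "), "nm\n")
  cat("  RLC rows:", nrow(x$rlc),
      " induction rows:", nrow(x$induction), "\n")
  cat("  seed:", x$truth$seed, "\n")
  invisible(x)
}
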