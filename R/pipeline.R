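#' Pipeline configuration
#'
#' Collects every tunable of the full analysis chain. All seeds are explicit
#' so a pipeline run is reproducible bit for bit.
#'
#' @param seed master seed; stage-level seeds are derived from it
#' @param wavelengths measuring wavelengths analyzed
#' @param ek_unit unit system of the Ek entering the 8-parameter K-table
#'   roster: `"relative"` or `"absolute"`
#' @param npq_eval_par irradiances at which fitted NPQ is back-calculated
#' @param alpha forward-selection entry threshold
#' @param nperm permutations for the RDA tests
#' @param scale K-table standardization mode (`"sd"` or `"range"`)
#' @param pta_axes number of compromise axes retained for the intrastructure
#' @param abiotic_vars,biotic_vars candidate explanatory variables for the
#'   RDA forward selection; `NULL` uses the full station-record sets. The
#'   all-candidates reference model needs more stations than candidates, so
#'   small campaigns require a reduced pool.
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L, wavelengths = CAMPAIGN_WAVELENGTHS,
                            ek_unit = c("relative", "absolute"),
                            npq_eval_par = c(300, 1200), alpha = 0.05,
                            nperm = 199L, scale = c("sd", "range"),
                            pta_axes = 2L, abiotic_vars = NULL,
                            biotic_vars = NULL) {
  cfg <- list(
    seed = as.integer(seed), wavelengths = wavelengths,
    ek_unit = match.arg(ek_unit), npq_eval_par = npq_eval_par,
    alpha = alpha, nperm = as.integer(nperm), scale = match.arg(scale),
    pta_axes = as.integer(pta_axes),
    abiotic_vars = abiotic_vars, biotic_vars = biotic_vars
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("pipeline config must carry an explicit seed")
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Station light-climate records
#'
#' Derives, for every station of a campaign bundle, the light-field
#' descriptors (Kd(PAR) from the log-linear PAR profile, surface irradiance,
#' euphotic depth, upper-mixed-layer depth and stratification from the
#' density profile, vertically averaged mixed-layer irradiance, and the
#' spectral-band quality ratios over the top 2.5 m) and merges them with the
#' abiotic and biotic station variables.
#'
#' @param campaign a campaign bundle (see [simulate_campaign()]), or any list
#'   with `stations`, `par_profiles`, `spectral_profiles`, `density_profiles`
#' @return data.frame, one row per station
#' @export
compute_station_records <- function(campaign) {
  st <- campaign$stations
  rows <- lapply(st$station, function(s) {
    pp <- campaign$par_profiles[campaign$par_profiles$station == s, ]
    fit <- stats::lm(log(par) ~ depth, data = pp)
    kd <- -unname(stats::coef(fit)[2])
    i0 <- exp(unname(stats::coef(fit)[1]))
    dp <- campaign$density_profiles[campaign$density_profiles$station == s, ]
    ml <- mixed_layer(dp$depth, dp$density)
    sp <- campaign$spectral_profiles[campaign$spectral_profiles$station == s, ]
    br <- band_ratios(sp)
    data.frame(
      station = s, kd_par = kd, i0 = i0,
      z_eu = euphotic_depth(kd),
      z_umixl = ml$z_umixl, stratified = ml$stratified,
      e_avg = averaged_light(i0, kd, ml$z_umixl),
      ratio_rb = br$ratio_rb, ratio_gb = br$ratio_gb, ratio_gr = br$ratio_gr
    )
  })
  rec <- do.call(rbind, rows)
  rec$zeu_zumixl <- rec$z_eu / rec$z_umixl
  merge(rec, st, by = "station", sort = TRUE)
}

#' Derive all photosynthetic parameters of a campaign
#'
#' For every station and wavelength: fits the QA-reduction time constant of
#' each induction subsample (mean over the three consecutive repeats),
#' converts it to Sigma(II) and averages over the six subsamples (the
#' subsample variance is retained for quality control); derives the per-step
#' fluorescence quantities of the triplicate rapid light curves; pools the
#' replicates and fits the Eilers-Peeters PE model in relative (r.ETR vs
#' PAR) and absolute (ETR(II) vs PAR(II)) units and the NPQ light response.
#'
#' @param campaign a campaign bundle
#' @param config a [pipeline_config()]
#' @return data.frame, one row per station x wavelength, with columns
#'   `fvfm`, `sigma`, `sigma_var`, `r_alpha`, `r_etrmax`, `r_eop`, `r_ek`,
#'   `alpha_ii`, `etrmax_ii`, `eop_ii`, `ek_ii`, `npq300`, `npq1200`,
#'   `npq_model`
#' @export
derive_photo_params <- function(campaign, config = pipeline_config()) {
  cells <- unique(campaign$rlc[c("station", "wavelength")])
  cells <- cells[order(cells$station, cells$wavelength), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    s <- cells$station[i]
    wl <- cells$wavelength[i]
    ind <- campaign$induction[campaign$induction$station == s &
                                campaign$induction$wavelength == wl, ]
    sig_subs <- vapply(sort(unique(ind$subsample)), function(sub) {
      d <- ind[ind$subsample == sub, ]
      curves <- lapply(sort(unique(d$rep)), function(r) d[d$rep == r, ])
      tt <- fit_tau(curves)
      sigma_psii(tt$tau, d$actinic_par[1])
    }, numeric(1))
    sigma <- mean(sig_subs)

    rl <- campaign$rlc[campaign$rlc$station == s &
                         campaign$rlc$wavelength == wl, ]
    reps <- lapply(sort(unique(rl$replicate)), function(r) {
      derive_steps(rl[rl$replicate == r, c("par", "f", "fm_prime")], sigma)
    })
    fvfm <- mean(vapply(reps, `[[`, numeric(1), "fvfm"))
    steps <- do.call(rbind, lapply(reps, `[[`, "steps"))

    pe_r <- fit_pe(steps$par, steps$r_etr, unit_system = "relative",
                   seed = config$seed)
    pe_a <- fit_pe(steps$par_ii, steps$etr_ii, unit_system = "absolute",
                   seed = config$seed)
    keep_npq <- steps$par > 0
    nf <- fit_npq(steps$par[keep_npq], steps$npq[keep_npq],
                  eval_par = config$npq_eval_par)
    data.frame(
      station = s, wavelength = wl,
      fvfm = fvfm, sigma = sigma, sigma_var = stats::var(sig_subs),
      r_alpha = pe_r$alpha, r_etrmax = pe_r$etr_max, r_eop = pe_r$e_op,
      r_ek = pe_r$e_k,
      alpha_ii = pe_a$alpha, etrmax_ii = pe_a$etr_max, eop_ii = pe_a$e_op,
      ek_ii = pe_a$e_k,
      npq300 = nf$eval[[1]], npq1200 = nf$eval[[2]],
      npq_model = nf$model
    )
  })
  do.call(rbind, rows)
}

#' Wavelength trends and detrending for all parameters
#'
#' Fits one [fit_lmem()] per parameter and subtracts the population lines.
#'
#' @param params output of [derive_photo_params()]
#' @param parameters parameter columns to analyze
#' @return list: `fits` (named list of `lmem_fit`), `table` (one row per
#'   parameter: fixed effects, SEs, p-values, random-effect SDs, LRT p),
#'   `detrended` (long data.frame station/wavelength/parameter/value/detrended)
#' @export
wavelength_trends <- function(params,
                              parameters = c("fvfm", "sigma", "r_etrmax",
                                             "etrmax_ii", "r_alpha", "alpha_ii",
                                             "r_ek", "ek_ii", "r_eop", "eop_ii",
                                             "npq300", "npq1200")) {
  fits <- list()
  det_list <- list()
  for (p in parameters) {
    d <- data.frame(station = params$station, wavelength = params$wavelength,
                    value = params[[p]])
    f <- fit_lmem(d, parameter = p)
    fits[[p]] <- f
    dd <- detrend(d, f)
    dd$parameter <- p
    det_list[[p]] <- dd
  }
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      parameter = f$parameter,
      intercept = f$beta0, intercept_se = f$se[["intercept"]],
      intercept_p = f$p[["intercept"]],
      slope = f$beta1, slope_se = f$se[["slope"]], slope_p = f$p[["slope"]],
      sd_intercept = f$sd_intercept, sd_slope = f$sd_slope,
      p_random_intercept = f$lrt$p[f$lrt$term == "random_intercept"],
      p_random_slope = f$lrt$p[f$lrt$term == "random_slope"],
      method = f$method
    )
  }))
  rownames(tab) <- NULL
  list(fits = fits, table = tab,
       detrended = do.call(rbind, det_list))
}

pta_roster <- function(config) {
  ek <- if (config$ek_unit == "relative") "r_ek" else "ek_ii"
  c("etrmax_ii", ek, "alpha_ii", "eop_ii", "sigma", "fvfm", "npq300", "npq1200")
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain on a campaign bundle: station light-climate
#' records, photosynthetic-parameter derivation and curve fitting, one
#' linear mixed-effects model per parameter with detrending, partial triadic
#' analysis of the per-wavelength K-tables (8-parameter roster), redundancy
#' analysis with forward selection of the abiotic and biotic explanatory
#' sets for each wavelength, and the spectral photoacclimation indices. Any
#' stage failure aborts with the stage name.
#'
#' @param campaign a campaign bundle ([simulate_campaign()] output or data
#'   read from files arranged the same way)
#' @param config a [pipeline_config()]
#' @param out_dir optional directory; when given, every stage's outputs are
#'   written (CSV for tables, JSON for structured results) together with a
#'   manifest recording the package version, the full configuration and all
#'   seeds
#' @return list of class `pipeline_result`: `stations`, `params`, `trends`,
#'   `stack`, `pta`, `rda`, `indices`, `manifest`
#' @export
run_pipeline <- function(campaign, config = pipeline_config(), out_dir = NULL) {
  stations <- stage("light_climate", compute_station_records(campaign))
  params <- stage("photophysiology", derive_photo_params(campaign, config))
  trends <- stage("population_trend", wavelength_trends(params))

  roster <- pta_roster(config)
  det <- trends$detrended[trends$detrended$parameter %in% roster,
                          c("wavelength", "station", "parameter", "detrended")]
  names(det)[names(det) == "detrended"] <- "value"
  stack <- stage("ktable_stack", build_stack(det, scale = config$scale))
  pta_res <- stage("pta", pta(stack, n_axes = config$pta_axes))

  abiotic_vars <- config$abiotic_vars
  if (is.null(abiotic_vars)) {
    abiotic_vars <- c("kd_par", "z_eu", "z_umixl", "zeu_zumixl", "e_avg",
                      "ratio_rb", "ratio_gb", "ratio_gr", "salinity",
                      "temperature", "din", "po4", "si", "par_2m", "tss")
  }
  biotic_vars <- config$biotic_vars
  if (is.null(biotic_vars)) {
    biotic_vars <- grep("^biomass_", names(stations), value = TRUE)
  }
  rda_res <- stage("rda", {
    lapply(stats::setNames(nm = as.character(stack$wavelengths)), function(w) {
      rows <- match(stack$stations, as.character(stations$station))
      y <- stack$tables[[w]]
      ab <- as.matrix(stations[rows, intersect(abiotic_vars, names(stations))])
      bi <- as.matrix(stations[rows, biotic_vars])
      if (anyNA(ab)) ab <- impute_missing(ab, seed = config$seed)
      wl_i <- match(w, as.character(stack$wavelengths))
      list(
        abiotic = forward_select(y, as.data.frame(ab), alpha = config$alpha,
                                 nperm = config$nperm,
                                 seed = config$seed + 100L * wl_i),
        biotic = forward_select(y, as.data.frame(bi), alpha = config$alpha,
                                nperm = config$nperm,
                                seed = config$seed + 100L * wl_i + 50L)
      )
    })
  })

  indices <- stage("indices", spectral_indices(params, stations))

  manifest <- list(
    package = "aquaphot",
    version = as.character(utils::packageVersion("aquaphot")),
    config = unclass(config),
    campaign_seed = if (!is.null(campaign$truth)) campaign$truth$seed else NA,
    n_stations = nrow(stations),
    wavelengths = stack$wavelengths,
    dropped_stations = stack$dropped_stations
  )

  out <- list(stations = stations, params = params, trends = trends,
              stack = stack, pta = pta_res, rda = rda_res, indices = indices,
              manifest = manifest)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("aquaphot pipeline result:", nrow(x$stations), "stations,",
      length(x$stack$wavelengths), "wavelengths\n")
  cat("  PTA interstructure axes 1-2:",
      sprintf("%.2f%%", sum(x$pta$interstructure$pct_inertia[1:2])), "\n")
  sel <- vapply(x$rda, function(r) {
    if (length(r$abiotic$selected)) paste(r$abiotic$selected, collapse = "+")
    else "none"
  }, character(1))
  cat("  RDA abiotic selections:",
      paste(names(sel), sel, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Serialize a pipeline result
#'
#' @param result a `pipeline_result`
#' @param dir output directory
#' @return invisibly, the files written
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = NA),
                     p, row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }
  wjson <- function(obj, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    files <<- c(files, p)
  }
  wcsv(result$stations, "station_records.csv")
  wcsv(result$params, "photo_params.csv")
  wcsv(result$trends$table, "lmem_table.csv")
  wcsv(result$trends$detrended, "detrended.csv")
  wcsv(result$indices, "indices.csv")
  pta <- result$pta
  wjson(list(
    rv = pta$interstructure$rv,
    eigenvalues = pta$interstructure$eigenvalues,
    pct_inertia = pta$interstructure$pct_inertia,
    weights = as.list(pta$interstructure$weights),
    cos2 = as.list(pta$interstructure$cos2),
    compromise_eigenvalues = pta$compromise$eigenvalues,
    compromise_pct_inertia = pta$compromise$pct_inertia,
    variable_coords = pta$compromise$variable_coords,
    row_coords = pta$compromise$row_coords,
    polygon_areas = as.list(pta$intrastructure$polygon_areas)
  ), "pta.json")
  wjson(lapply(result$rda, function(r) {
    lapply(r, function(fs) list(
      selected = fs$selected,
      path = fs$path,
      global_adj_r2 = fs$global$adj_r2,
      global_p = fs$global$p,
      final_adj_r2 = if (!is.null(fs$model)) fs$model$adj_r2 else NULL,
      constrained_variance = if (!is.null(fs$model)) fs$model$constrained_variance else NULL,
      residual_variance = if (!is.null(fs$model)) fs$model$residual_variance else NULL
    ))
  }), "rda.json")
  wjson(result$manifest, "manifest.json")
  invisible(files)
}
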