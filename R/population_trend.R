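#' Population wavelength trend of a photosynthetic parameter (LMEM)
#'
#' Fits the linear mixed-effects model
#' `value ~ 1 + wl_t + (1 + wl_t | station)` where `wl_t` is the measuring
#' wavelength transposed so that 440 nm maps to 0 (440-625 nm becomes
#' 0-185 nm, which keeps the intercept interpretable as the bright-blue
#' value). The fixed effects are the population trend across wavelengths;
#' the random intercepts and slopes are the station-level departures from it.
#'
#' Fixed effects are estimated by REML with Satterthwaite-approximated t
#' tests; the significance of the random intercept and random slope is
#' assessed by likelihood-ratio tests between maximum-likelihood fits of the
#' nested models. A singular fit triggers an automatic refit without the
#' intercept-slope correlation (flagged in the result); data with no residual
#' variability fall back to ordinary least squares with zero random-effect
#' SDs.
#'
#' @param data data.frame with columns `station`, `wavelength`, `value`
#' @param parameter name of the parameter (bookkeeping only)
#' @param ref_wavelength wavelength mapped to wl_t = 0
#' @return object of class `lmem_fit`: `parameter`, `beta0`, `beta1`, their
#'   `se`, `t`, `df` and `p`, random-effect SDs (`sd_intercept`, `sd_slope`,
#'   `cor_intercept_slope`), residual SD, LRT statistics/p for the random
#'   intercept and slope, `method` and `singular` flags.
#' @export
fit_lmem <- function(data, parameter = "parameter", ref_wavelength = 440) {
  stopifnot(all(c("station", "wavelength", "value") %in% names(data)))
  data <- data[stats::complete.cases(data[c("station", "wavelength", "value")]), ]
  if (length(unique(data$station)) < 2L) stop("need at least 2 stations")
  if (length(unique(data$wavelength)) < 2L) stop("need at least 2 wavelengths")
  d <- data.frame(
    station = factor(data$station),
    wl_t = data$wavelength - ref_wavelength,
    value = data$value
  )

  fit_or_null <- function(formula, reml) {
    f <- try(suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = d, REML = reml,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    )), silent = TRUE)
    if (inherits(f, "try-error")) NULL else f
  }

  method <- "lmem"
  singular <- FALSE
  full <- fit_or_null(value ~ wl_t + (1 + wl_t | station), reml = TRUE)
  if (!is.null(full) && lme4::isSingular(full, tol = 1e-5)) {
    singular <- TRUE
    refit <- fit_or_null(value ~ wl_t + (1 + wl_t || station), reml = TRUE)
    if (!is.null(refit)) {
      full <- refit
      method <- "lmem_uncorrelated"
    }
  }

  if (is.null(full)) {
    # degenerate data (e.g. zero noise, zero random SDs): population trend
    # reduces to ordinary least squares
    ols <- stats::lm(value ~ wl_t, data = d)
    cf <- summary(ols)$coefficients
    out <- list(
      parameter = parameter,
      beta0 = cf[1, 1], beta1 = cf[2, 1],
      se = c(intercept = cf[1, 2], slope = cf[2, 2]),
      t = c(intercept = cf[1, 3], slope = cf[2, 3]),
      df = c(intercept = ols$df.residual, slope = ols$df.residual),
      p = c(intercept = cf[1, 4], slope = cf[2, 4]),
      sd_intercept = 0, sd_slope = 0, cor_intercept_slope = NA_real_,
      sd_residual = summary(ols)$sigma,
      lrt = data.frame(term = c("random_intercept", "random_slope"),
                       chisq = NA_real_, df = NA_real_, p = NA_real_),
      method = "ols_fallback", singular = TRUE,
      ref_wavelength = ref_wavelength
    )
    class(out) <- "lmem_fit"
    return(out)
  }

  cf <- stats::coef(summary(full))
  vc <- lme4::VarCorr(full)$station
  sds <- attr(vc, "stddev")
  corr <- attr(vc, "correlation")
  sd_slope <- if (length(sds) >= 2L) unname(sds[2]) else {
    # uncorrelated parameterization stores the slope in a second block
    vc2 <- lme4::VarCorr(full)
    if (length(vc2) >= 2L) unname(attr(vc2[[2]], "stddev")[1]) else 0
  }
  cor_is <- if (!is.null(corr) && nrow(corr) >= 2L) corr[1, 2] else NA_real_

  # likelihood-ratio tests under ML
  ml_full <- fit_or_null(value ~ wl_t + (1 + wl_t | station), reml = FALSE)
  ml_int <- fit_or_null(value ~ wl_t + (1 | station), reml = FALSE)
  ml_lm <- stats::lm(value ~ wl_t, data = d)
  lrt_row <- function(term, big, small, df) {
    if (is.null(big) || is.null(small)) {
      return(data.frame(term = term, chisq = NA_real_, df = df, p = NA_real_))
    }
    ch <- max(0, 2 * (as.numeric(stats::logLik(big)) - as.numeric(stats::logLik(small))))
    data.frame(term = term, chisq = ch, df = df,
               p = stats::pchisq(ch, df = df, lower.tail = FALSE))
  }
  lrt_int <- if (!is.null(ml_int)) {
    ch <- max(0, 2 * (as.numeric(stats::logLik(ml_int)) - as.numeric(stats::logLik(ml_lm))))
    data.frame(term = "random_intercept", chisq = ch, df = 1,
               p = stats::pchisq(ch, df = 1, lower.tail = FALSE))
  } else {
    data.frame(term = "random_intercept", chisq = NA_real_, df = 1, p = NA_real_)
  }
  lrt_slp <- lrt_row("random_slope", ml_full, ml_int, df = 2)
  lrt <- rbind(lrt_int, lrt_slp)

  out <- list(
    parameter = parameter,
    beta0 = unname(cf[1, "Estimate"]), beta1 = unname(cf[2, "Estimate"]),
    se = c(intercept = unname(cf[1, "Std. Error"]),
           slope = unname(cf[2, "Std. Error"])),
    t = c(intercept = unname(cf[1, "t value"]),
          slope = unname(cf[2, "t value"])),
    df = c(intercept = unname(cf[1, "df"]), slope = unname(cf[2, "df"])),
    p = c(intercept = unname(cf[1, "Pr(>|t|)"]),
          slope = unname(cf[2, "Pr(>|t|)"])),
    sd_intercept = unname(sds[1]), sd_slope = sd_slope,
    cor_intercept_slope = cor_is,
    sd_residual = stats::sigma(full),
    lrt = lrt,
    method = method, singular = singular,
    ref_wavelength = ref_wavelength
  )
  class(out) <- "lmem_fit"
  out
}

#' @export
print.lmem_fit <- function(x, ...) {
  cat("Wavelength-trend LMEM for", x$parameter, "(", x$method, ")\n")
  cat(sprintf("  intercept (at %g nm): %.5g (SE %.3g, p %.3g)\n",
              x$ref_wavelength, x$beta0, x$se["intercept"], x$p["intercept"]))
  cat(sprintf("  slope (per nm):       %.5g (SE %.3g, p %.3g)\n",
              x$beta1, x$se["slope"], x$p["slope"]))
  cat(sprintf("  random SDs: intercept %.3g, slope %.3g; residual %.3g\n",
              x$sd_intercept, x$sd_slope, x$sd_residual))
  invisible(x)
}

#' Detrend parameter values against the population wavelength trend
#'
#' Subtracts the fixed-effect population line (and only the fixed effects:
#' station-level random-effect predictions are deliberately retained in the
#' residual) so that the detrended values are each station's individual
#' departure from the population trend.
#'
#' @param data data.frame with columns `station`, `wavelength`, `value`
#' @param fit an [fit_lmem()] result for the same parameter
#' @return `data` with an added `detrended` column
#' @export
detrend <- function(data, fit) {
  stopifnot(inherits(fit, "lmem_fit"))
  wl_t <- data$wavelength - fit$ref_wavelength
  data$detrended <- data$value - (fit$beta0 + fit$beta1 * wl_t)
  data
}
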