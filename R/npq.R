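#' Fit the non-photochemical quenching light response
#'
#' Fits NPQ versus PAR with two candidate models: a Michaelis-Menten
#' saturation curve \eqn{NPQ(E) = NPQ_{max} E / (k_{1/2} + E)} and a straight
#' line forced through the origin. The Michaelis-Menten fit is disqualified if
#' it fails to converge or yields non-positive parameters; otherwise the model
#' with the lower small-sample-corrected AIC is selected. The fitted model is
#' then evaluated at the reporting irradiances (by default 300 and 1200
#' umol quanta m-2 s-1, i.e. sub-saturating and saturating light).
#'
#' @param e PAR values (>= 0)
#' @param npq NPQ values at those PAR levels
#' @param eval_par irradiances at which fitted NPQ is back-calculated
#' @return object of class `npq_fit`: `model` ("michaelis_menten",
#'   "linear_origin" or "zero"), the model parameters (`npq_max`/`k_half` or
#'   `slope`), `npq300` and `npq1200` (named after the default `eval_par`),
#'   `eval`, `aicc` per candidate, and `rss`.
#' @export
fit_npq <- function(e, npq, eval_par = c(300, 1200)) {
  keep <- is.finite(e) & is.finite(npq) & e >= 0
  e <- e[keep]
  npq <- npq[keep]
  n <- length(e)
  if (n < 5L) stop("fit_npq needs at least 5 points")

  if (all(npq <= 0)) {
    warning("all NPQ values are <= 0; returning the identically-zero model")
    return(npq_result("zero", list(slope = 0), e, npq, eval_par,
                      aicc = c(mm = NA_real_, linear = NA_real_)))
  }

  # linear through origin
  lin <- stats::lm(npq ~ 0 + e)
  slope <- unname(stats::coef(lin))
  rss_lin <- sum(stats::resid(lin)^2)
  aicc_lin <- aicc_from_rss(rss_lin, n, k = 2L) # slope + error variance

  # Michaelis-Menten
  mm_ok <- FALSE
  aicc_mm <- Inf
  pos <- e > 0 & npq > 0
  if (sum(pos) >= 3L) {
    nm0 <- max(npq)
    kh0 <- max(stats::median(e[pos]), 1)
    mm <- try(
      minpack.lm::nlsLM(
        npq ~ nm * e / (kh + e),
        start = list(nm = nm0, kh = kh0),
        lower = c(1e-12, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14),
        data = data.frame(e = e, npq = npq)
      ),
      silent = TRUE
    )
    if (!inherits(mm, "try-error")) {
      cf <- stats::coef(mm)
      if (all(is.finite(cf)) && all(cf > 0)) {
        mm_ok <- TRUE
        rss_mm <- sum(stats::resid(mm)^2)
        aicc_mm <- aicc_from_rss(rss_mm, n, k = 3L) # 2 params + error variance
      }
    }
  }

  aicc <- c(mm = if (mm_ok) aicc_mm else NA_real_, linear = aicc_lin)
  if (mm_ok && aicc_mm <= aicc_lin) {
    npq_result("michaelis_menten",
               list(npq_max = unname(cf["nm"]), k_half = unname(cf["kh"])),
               e, npq, eval_par, aicc)
  } else {
    npq_result("linear_origin", list(slope = slope), e, npq, eval_par, aicc)
  }
}

aicc_from_rss <- function(rss, n, k) {
  if (n - k - 1L <= 0L) return(Inf)
  n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

npq_result <- function(model, pars, e, npq, eval_par, aicc) {
  pred <- function(x) npq_model_predict(model, pars, x)
  ev <- pred(eval_par)
  names(ev) <- paste0("npq", eval_par)
  out <- c(
    list(model = model),
    pars,
    as.list(ev),
    list(
      eval = stats::setNames(ev, as.character(eval_par)),
      aicc = aicc,
      rss = sum((npq - pred(e))^2),
      e = e, npq = npq
    )
  )
  class(out) <- "npq_fit"
  out
}

npq_model_predict <- function(model, pars, e) {
  switch(model,
    michaelis_menten = pars$npq_max * e / (pars$k_half + e),
    linear_origin = pars$slope * e,
    zero = rep(0, length(e)),
    stop("unknown NPQ model: ", model)
  )
}

#' @export
predict.npq_fit <- function(object, e, ...) {
  pars <- object[intersect(names(object), c("npq_max", "k_half", "slope"))]
  npq_model_predict(object$model, pars, e)
}

#' @export
print.npq_fit <- function(x, ...) {
  cat("NPQ light-response fit: model =", x$model, "\n")
  if (x$model == "michaelis_menten") {
    cat(sprintf("  NPQmax = %.4g  k_half = %.4g\n", x$npq_max, x$k_half))
  } else if (x$model == "linear_origin") {
    cat(sprintf("  slope = %.4g per umol quanta m-2 s-1\n", x$slope))
  }
  cat("  back-calculated:",
      paste(names(x$eval), "=", signif(x$eval, 4), collapse = ", "), "\n")
  invisible(x)
}
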