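#' Eilers-Peeters photosynthesis-irradiance model
#'
#' The Eilers-Peeters model describes the production-irradiance (PE) response
#' including photoinhibition at supra-optimal irradiance:
#' \deqn{P(E) = E / (a E^2 + b E + c)}
#' with all three coefficients strictly positive. The familiar photosynthetic
#' parameters are algebraic functions of the coefficients: the light-use
#' efficiency (initial slope) \eqn{\alpha = 1/c}, the maximum rate
#' \eqn{P_{max} = 1/(b + 2\sqrt{ac})}, the optimum irradiance
#' \eqn{E_{op} = \sqrt{c/a}} and the light-saturation parameter
#' \eqn{E_k = P_{max}/\alpha}.
#'
#' @param e irradiance (PAR, umol quanta m-2 s-1, or quanta PSII-1 s-1 in the
#'   absolute unit system)
#' @param a,b,c Eilers-Peeters coefficients (all > 0)
#' @return `ep_predict()`: predicted rates, same length as `e`.
#' @export
ep_predict <- function(e, a, b, c) {
  e / (a * e^2 + b * e + c)
}

#' @rdname ep_predict
#' @return `ep_derived()`: named list with `alpha`, `etr_max`, `e_op`, `e_k`.
#' @export
ep_derived <- function(a, b, c) {
  list(
    alpha = 1 / c,
    etr_max = 1 / (b + 2 * sqrt(a * c)),
    e_op = sqrt(c / a),
    e_k = c / (b + 2 * sqrt(a * c))
  )
}

#' Invert derived PE parameters to Eilers-Peeters coefficients
#'
#' Given light-use efficiency, maximum rate and optimum irradiance, return the
#' (a, b, c) triple that produces them. Used by the synthetic campaign
#' generator so that simulated truth can be specified on the familiar
#' parameter scale.
#'
#' @param alpha initial slope
#' @param etr_max maximum rate
#' @param e_op optimum irradiance
#' @return named numeric vector c(a, b, c)
#' @export
ep_coefficients <- function(alpha, etr_max, e_op) {
  c <- 1 / alpha
  a <- c / e_op^2
  b <- 1 / etr_max - 2 * c / e_op
  if (any(!is.finite(c(a, b, c))) || a <= 0 || b <= 0 || c <= 0) {
    stop(
      "derived Eilers-Peeters coefficients not strictly positive ",
      "(requires E_k < E_op/2): a=", a, " b=", b, " c=", c
    )
  }
  c(a = a, b = b, c = c)
}

# residual-sum-of-squares objective on log-coefficients; built as a closure
# so no data arguments travel through optim's dots (where `p` would
# partially match `par`)
ep_rss_objective <- function(e, p) {
  function(par_log) {
    pr <- ep_predict(e, exp(par_log[1]), exp(par_log[2]), exp(par_log[3]))
    sum((p - pr)^2)
  }
}

#' Fit the Eilers-Peeters PE model
#'
#' Minimizes the residual sum of squares of \eqn{P = E/(aE^2+bE+c)} over
#' strictly positive coefficients using a multi-start strategy: moment-based
#' starting values perturbed on the log scale (deterministically, from `seed`),
#' a Nelder-Mead pass on log-coefficients, and Levenberg-Marquardt refinement.
#' Acceptance of the optimum is judged on the residual sum of squares alone.
#'
#' @param e irradiance values (pooled over replicates; >= 6 distinct values
#'   spanning the sub- and supra-saturating range)
#' @param p measured rates (same length)
#' @param unit_system `"relative"` (r.ETR vs PAR) or `"absolute"`
#'   (ETR(II) vs PAR(II)); recorded in the result
#' @param n_starts number of multi-start perturbations
#' @param seed integer seed controlling the start perturbations only
#' @param eop_max_factor identifiability bound on the optimum irradiance,
#'   as a multiple of the largest measured irradiance. Beyond the sampled
#'   range the photoinhibition coefficient carries no information and the
#'   unconstrained optimum can sit at a = 0 (infinite E_op); fits whose
#'   E_op exceeds the bound are refitted on the constraint boundary
#'   (a tied to c / E_op_max^2) and flagged `eop_censored`.
#' @return object of class `ep_fit`: coefficients `a`, `b`, `c`, derived
#'   `alpha`, `etr_max`, `e_op`, `e_k`, `unit_system`, residual SS `rss`,
#'   `eop_censored`, and `fitted` values.
#' @export
fit_pe <- function(e, p, unit_system = c("relative", "absolute"),
                   n_starts = 6L, seed = 1L, eop_max_factor = 5) {
  unit_system <- match.arg(unit_system)
  keep <- is.finite(e) & is.finite(p)
  e <- e[keep]
  p <- p[keep]
  if (length(unique(e)) < 6L) {
    stop("fit_pe needs at least 6 distinct irradiance values")
  }
  pos <- e > 0 & p > 0
  if (sum(pos) < 4L) stop("fit_pe needs positive rates at positive irradiance")

  # moment starts: alpha from the steepest low-light secant, Pmax from the
  # maximum observed rate, Eop from the irradiance at that maximum
  alpha0 <- max(p[pos] / e[pos])
  pmax0 <- max(p[pos])
  eop0 <- max(e[pos][which.max(p[pos])], stats::median(e[pos]))
  c0 <- 1 / alpha0
  a0 <- c0 / eop0^2
  b0 <- max(1 / pmax0 - 2 * sqrt(a0 * c0), 1e-3 / pmax0)
  start0 <- log(c(a0, b0, c0))

  perturb <- matrix(0, nrow = n_starts, ncol = 3L)
  if (n_starts > 1L) {
    rs <- local_rng(seed)
    perturb[-1L, ] <- matrix(
      stats::rnorm(3L * (n_starts - 1L), sd = 0.7),
      ncol = 3L
    )
    restore_rng(rs)
  }

  objective <- ep_rss_objective(e, p)
  best <- NULL
  for (i in seq_len(n_starts)) {
    st <- start0 + perturb[i, ]
    opt <- try(
      stats::optim(st, objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      silent = TRUE
    )
    if (inherits(opt, "try-error")) next
    cand <- opt$par
    # Levenberg-Marquardt polish on the natural scale, positivity-bounded
    nf <- try(
      minpack.lm::nlsLM(
        p ~ e / (a * e^2 + b * e + cc),
        start = list(a = exp(cand[1]), b = exp(cand[2]), cc = exp(cand[3])),
        lower = c(1e-300, 1e-300, 1e-300),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                             ptol = 1e-15),
        data = data.frame(e = e, p = p)
      ),
      silent = TRUE
    )
    if (!inherits(nf, "try-error")) {
      cf <- stats::coef(nf)
      rss <- sum(stats::resid(nf)^2)
    } else {
      cf <- exp(cand)
      names(cf) <- c("a", "b", "cc")
      rss <- opt$value
    }
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = cf, rss = rss)
    }
  }
  if (is.null(best)) stop("Eilers-Peeters fit did not converge")
  a <- unname(best$coef["a"])
  b <- unname(best$coef["b"])
  cc <- unname(best$coef["cc"])
  if (a <= 0 || b <= 0 || cc <= 0) {
    stop("Eilers-Peeters fit converged to non-positive coefficients")
  }
  eop_cap <- eop_max_factor * max(e)
  eop_censored <- FALSE
  if (sqrt(cc / a) > eop_cap) {
    # constrained refit on the identifiability boundary: a = c / cap^2
    eop_censored <- TRUE
    cap2 <- eop_cap^2
    cf2 <- try(
      minpack.lm::nlsLM(
        p ~ e / (cc * e^2 / cap2 + b * e + cc),
        start = list(b = b, cc = cc),
        lower = c(1e-300, 1e-300),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                             ptol = 1e-15),
        data = data.frame(e = e, p = p, cap2 = cap2)
      ),
      silent = TRUE
    )
    if (!inherits(cf2, "try-error")) {
      cf <- stats::coef(cf2)
      b <- unname(cf["b"])
      cc <- unname(cf["cc"])
      best$rss <- sum(stats::resid(cf2)^2)
    }
    a <- cc / cap2
  }
  out <- c(
    list(a = a, b = b, c = cc),
    ep_derived(a, b, cc),
    list(
      unit_system = unit_system,
      rss = best$rss,
      eop_censored = eop_censored,
      fitted = ep_predict(e, a, b, cc),
      e = e, p = p
    )
  )
  class(out) <- "ep_fit"
  out
}

#' @export
print.ep_fit <- function(x, ...) {
  cat("Eilers-Peeters PE fit (", x$unit_system, " units)\n", sep = "")
  cat(sprintf("  a = %.6g  b = %.6g  c = %.6g   (RSS %.4g)\n",
              x$a, x$b, x$c, x$rss))
  cat(sprintf("  alpha = %.6g  ETRmax = %.6g  Eop = %.6g  Ek = %.6g\n",
              x$alpha, x$etr_max, x$e_op, x$e_k))
  invisible(x)
}
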