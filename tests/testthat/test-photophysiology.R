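test_that("Eilers-Peeters closed forms and fit recovery on noise-free steps", {
  a <- 1.25e-6; b <- 0.015; cc <- 5
  d <- ep_derived(a, b, cc)
  expect_equal(d$alpha, 0.2)
  expect_equal(d$etr_max, 50)
  expect_equal(d$e_op, 2000)
  expect_equal(d$e_k, 250)
  # the supra-saturating step sits exactly at Pmax for this triple
  expect_equal(ep_predict(2000, a, b, cc), 50)
  # round trip through the coefficient inversion
  expect_equal(unname(ep_coefficients(d$alpha, d$etr_max, d$e_op)),
               c(a, b, cc), tolerance = 1e-12)
  expect_error(ep_coefficients(0.2, 1200, 2000), "positive")

  E <- default_par_steps()
  f <- fit_pe(E, ep_predict(E, a, b, cc))
  expect_equal(f$alpha, 0.2, tolerance = 1e-6)
  expect_equal(f$etr_max, 50, tolerance = 1e-6)
  expect_equal(f$e_op, 2000, tolerance = 1e-6)
  expect_equal(f$e_k, 250, tolerance = 1e-6)
  expect_false(f$eop_censored)
  # algebraic identities between the derived quantities
  expect_equal(f$alpha * f$c, 1, tolerance = 1e-9)
  expect_equal(f$e_op^2 * f$a, f$c, tolerance = 1e-6)
  expect_equal(f$e_k * f$alpha, f$etr_max, tolerance = 1e-9)
})

test_that("PE fit is homogeneous in the rate scale", {
  E <- default_par_steps()
  P <- ep_predict(E, 1.25e-6, 0.015, 5)
  f1 <- fit_pe(E, P)
  fk <- fit_pe(E, P * 3.7)
  expect_equal(fk$alpha, 3.7 * f1$alpha, tolerance = 1e-6)
  expect_equal(fk$etr_max, 3.7 * f1$etr_max, tolerance = 1e-6)
  expect_equal(fk$e_k, f1$e_k, tolerance = 1e-5)
  expect_equal(fk$e_op, f1$e_op, tolerance = 1e-5)
})

test_that("PE fit validates its inputs and censors unidentifiable Eop", {
  expect_error(fit_pe(c(0, 10, 50), c(0, 2, 9)), "6 distinct")
  # a rectangular-hyperbola response with no inhibition: Eop runs away and
  # is censored at the identifiability bound
  E <- default_par_steps()
  P <- 60 * E / (300 + E)
  f <- fit_pe(E, P)
  expect_true(f$eop_censored)
  expect_lte(f$e_op, 5 * max(E) + 1e-6)
})

test_that("NPQ model fitting selects, evaluates and degrades correctly", {
  e <- c(25, 50, 110, 170, 260, 390, 580, 860, 1270, 1700, 2000)
  # Michaelis-Menten truth: back-calculation at 300 and 1200 is closed-form
  nf <- fit_npq(e, 3 * e / (600 + e))
  expect_identical(nf$model, "michaelis_menten")
  expect_equal(nf$npq300, 1, tolerance = 1e-8)
  expect_equal(nf$npq1200, 2, tolerance = 1e-8)
  # linear truth
  nl <- fit_npq(e, 0.001 * e)
  expect_identical(nl$model, "linear_origin")
  expect_equal(nl$npq300, 0.3, tolerance = 1e-10)
  expect_equal(nl$npq1200, 1.2, tolerance = 1e-10)
  # all-zero NPQ degrades to the zero model with a warning
  expect_warning(nz <- fit_npq(e, rep(0, length(e))), "zero")
  expect_identical(nz$model, "zero")
  expect_equal(nz$npq300, 0)
  expect_equal(nz$npq1200, 0)
  expect_error(fit_npq(c(100, 300), c(0.5, 1)), "5 points")
})

test_that("fitted NPQ models are non-decreasing with npq300 <= npq1200", {
  set.seed(41)
  e <- c(25, 50, 110, 170, 260, 390, 580, 860, 1270, 1700, 2000)
  for (i in 1:20) {
    nmax <- runif(1, 0.3, 4)
    kh <- runif(1, 200, 1500)
    npq <- pmax(nmax * e / (kh + e) + rnorm(length(e), sd = 0.05), 0)
    nf <- fit_npq(e, npq)
    grid <- predict(nf, seq(0, 2000, by = 50))
    expect_true(all(diff(grid) >= -1e-12))
    expect_lte(nf$npq300, nf$npq1200 + 1e-12)
  }
})

test_that("induction simulation follows the saturating exponential", {
  ic <- simulate_induction(4e-4, 0.2, 0.5, 1500)
  expect_equal(ic$fluorescence[1], 0.2)                    # t = 0 -> F_O
  f_at <- function(t) 0.2 + 0.3 * (1 - exp(-t / 4e-4))
  expect_equal(ic$fluorescence, f_at(ic$time), tolerance = 1e-12)
  # asymptote: at 10 tau the curve is within 0.005% of F_I1
  expect_lt(abs(f_at(10 * 4e-4) - 0.5) / 0.5, 5e-5)
  expect_error(simulate_induction(-1e-4, 0.2, 0.5, 1500), "tau")
  expect_error(simulate_induction(4e-4, 0.2, 0.5, 1500, dt = 2e-3), "dt")
  expect_error(simulate_induction(4e-4, 0.5, 0.2, 1500), "f_o")
})

test_that("tau fitting recovers the time constant and averages repeats", {
  ic <- simulate_induction(4e-4, 0.2, 0.5, 1500)
  tt <- fit_tau(ic)
  expect_equal(tt$tau, 4e-4, tolerance = 1e-9)
  # three repeats with different tau: returned value is their mean
  curves <- lapply(c(3e-4, 4e-4, 5e-4), function(tau) {
    simulate_induction(tau, 0.2, 0.5, 1500)
  })
  tt3 <- fit_tau(curves)
  expect_equal(tt3$tau, 4e-4, tolerance = 1e-8)
  expect_length(tt3$tau_repeats, 3)
  # flat curve carries no kinetic information
  flat <- data.frame(time = seq(0, 1e-3, 2e-5), fluorescence = 0.3)
  expect_error(fit_tau(flat), "no rise")
  # out-of-range tau is flagged, not rejected
  expect_warning(fit_tau(simulate_induction(8e-3, 0.2, 0.5, 30, duration = 5e-2)),
                 "plausible range")
})

test_that("sigma conversion applies Avogadro scaling and inverse proportionality", {
  expect_equal(sigma_psii(4e-4, 1000), 4.151, tolerance = 1e-4)
  expect_equal(sigma_psii(2.731e-4, 1000), 6.08, tolerance = 1e-3)
  expect_equal(sigma_psii(4e-4, 2000), sigma_psii(4e-4, 1000) / 2,
               tolerance = 1e-12)
  expect_error(sigma_psii(0, 1000), "tau")
  expect_error(sigma_psii(4e-4, -5), "par")
})

test_that("per-step derivation reproduces the fluorescence formulas", {
  rlc <- data.frame(par = c(0, 100), f = c(0.24, 0.3), fm_prime = c(0.6, 0.6))
  d <- derive_steps(rlc, sigma = 5)
  expect_equal(d$fvfm, 0.6)
  expect_equal(d$steps$y_ii[2], 0.5)
  expect_equal(d$steps$r_etr[2], 25)
  # PAR(II) = sigma[m2] * L * PAR[mol]: 5 nm2 at PAR 100 -> 301.1
  expect_equal(d$steps$par_ii[2], 301.107038, tolerance = 1e-9)
  # dark step: all rates zero, NPQ zero
  expect_equal(d$steps$r_etr[1], 0)
  expect_equal(d$steps$etr_ii[1], 0)
  expect_equal(d$steps$npq[1], 0)
  # ETR(II) with Y = 0.3 and Fv/Fm = 0.6
  rlc2 <- data.frame(par = c(0, 100), f = c(0.24, 0.42), fm_prime = c(0.6, 0.6))
  d2 <- derive_steps(rlc2, sigma = 5)
  expect_equal(d2$steps$etr_ii[2], 150.5535, tolerance = 1e-4)
  # Fm' = Fm at every step -> NPQ identically zero
  expect_true(all(d$steps$npq == 0))
  expect_error(derive_steps(data.frame(par = c(10, 20), f = 1, fm_prime = 2), 5),
               "dark")
  expect_error(derive_steps(data.frame(par = c(0, 10), f = c(3, 1), fm_prime = c(2, 2)), 5),
               "exceeds")
})

test_that("ETR(II)/r.ETR is a fixed per-curve constant", {
  camp <- small_campaign(noise = FALSE)
  rl <- camp$rlc[camp$rlc$station == 1 & camp$rlc$wavelength == 440 &
                   camp$rlc$replicate == 1, ]
  sig <- camp$params_true$sigma[camp$params_true$station == 1 &
                                  camp$params_true$wavelength == 440]
  d <- derive_steps(rl[, c("par", "f", "fm_prime")], sig)
  ratio <- d$steps$etr_ii[-1] / d$steps$r_etr[-1]
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-9)
})

test_that("spectral indices form ratios and recover an exact regression line", {
  params <- expand.grid(station = 1:4, wavelength = c(440, 540, 625))
  params$r_ek <- 200 + 10 * params$station
  params$ek_ii <- 800 - 20 * params$station
  stations <- data.frame(
    station = 1:4, e_avg = 200 + 10 * (1:4),
    ratio_rb = c(0.8, 0.9, 1.0, 1.1), ratio_gb = 1.5, ratio_gr = 1.6,
    z_eu = c(10, 20, 30, 40), z_umixl = c(10, 10, 15, 20),
    stratified = c(TRUE, FALSE, TRUE, FALSE), tss = 1:4
  )
  idx <- spectral_indices(params, stations)
  # identical Ek across wavelengths -> wavelength ratios exactly 1
  expect_equal(idx$ek_ratio_625_440_r, rep(1, 4))
  expect_equal(idx$ek_ratio_540_440_ii, rep(1, 4))
  # Ek,440 equal to Eavg -> photoacclimation index exactly 1
  expect_equal(idx$ek440_eavg_r, rep(1, 4))
  expect_equal(idx$zeu_zumixl, c(1, 2, 2, 2))

  # OLS recovery of points generated exactly on a known line
  d <- data.frame(x = c(0.4, 0.7, 1.0, 1.3, 1.6))
  d$y <- 0.5789 * d$x + 0.2516
  reg <- index_regression(d, "x", "y")
  expect_equal(reg$slope, 0.5789, tolerance = 1e-10)
  expect_equal(reg$intercept, 0.2516, tolerance = 1e-10)
  expect_equal(reg$r, 1, tolerance = 1e-10)
})

test_that("index regressions split by stratification when asked", {
  set.seed(7)
  d <- data.frame(x = rnorm(12), stratified = rep(c(TRUE, FALSE), 6))
  d$y <- ifelse(d$stratified, 2 * d$x, -2 * d$x)
  reg <- index_regression(d, "x", "y", by_stratification = TRUE)
  expect_setequal(reg$group, c("stratified", "mixed"))
  expect_equal(reg$slope[reg$group == "stratified"], 2, tolerance = 1e-10)
  expect_equal(reg$slope[reg$group == "mixed"], -2, tolerance = 1e-10)
})
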