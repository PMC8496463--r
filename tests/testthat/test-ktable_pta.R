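random_long_stack <- function(seed, n = 4, p = 3, k = 2) {
  set.seed(seed)
  tabs <- lapply(seq_len(k), function(i) matrix(rnorm(n * p), n, p))
  stack_from_matrices(tabs)
}

test_that("stack building standardizes globally, drops incomplete stations, round-trips", {
  set.seed(11)
  d <- expand.grid(wavelength = c(440, 590), station = 1:6,
                   parameter = c("a", "b", "c"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d), mean = rep(c(1, 10, 100), each = 12))
  # remove station 4's 590 nm cells entirely
  d_miss <- d[!(d$station == 4 & d$wavelength == 590), ]
  expect_message(st <- build_stack(d_miss), "dropping")
  expect_identical(st$dropped_stations, "4")
  expect_equal(length(st$stations), 5L)
  # global standardization: stacked columns have mean 0, sd 1
  stacked <- do.call(rbind, st$tables)
  expect_equal(unname(colMeans(stacked)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(stacked, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # round trip back to the original values
  orig <- unscale_stack(st)
  m <- merge(d_miss[d_miss$station != 4, ], orig,
             by = c("wavelength", "station", "parameter"))
  expect_equal(m$value.x, m$value.y, tolerance = 1e-12)
  # already-standardized input leaves a (0, 1) scaling record
  z <- d
  for (p in c("a", "b", "c")) {
    i <- z$parameter == p
    z$value[i] <- (z$value[i] - mean(z$value[i])) / sd(z$value[i])
  }
  stz <- build_stack(z)
  expect_equal(stz$scaling$centre, rep(0, 3), tolerance = 1e-10)
  expect_equal(stz$scaling$scale, rep(1, 3), tolerance = 1e-10)
  # zero-variance parameter is rejected
  dz <- d
  dz$value[dz$parameter == "b"] <- 7
  expect_error(build_stack(dz), "zero variance")
})

test_that("range scaling divides by the global max minus min", {
  d <- random_long_stack(2)
  st <- build_stack(d, scale = "range")
  for (p in unique(d$parameter)) {
    v <- d$value[d$parameter == p]
    expect_equal(st$scaling$scale[st$scaling$parameter == p],
                 max(v) - min(v), tolerance = 1e-12)
  }
})

test_that("identical tables give the degenerate interstructure limits", {
  set.seed(3)
  x <- matrix(rnorm(5 * 4), 5, 4)
  st <- build_stack(stack_from_matrices(rep(list(x), 5)))
  inter <- interstructure(st)
  expect_equal(unname(inter$rv), matrix(1, 5, 5), tolerance = 1e-12)
  expect_equal(unname(inter$weights), rep(1 / sqrt(5), 5), tolerance = 1e-12)
  expect_equal(unname(inter$cos2), rep(1, 5), tolerance = 1e-12)
  # compromise of identical tables has the single-table PCA inertia profile
  comp <- pta_compromise(st, inter$weights)
  single <- eigen(crossprod(st$tables[[1]]), symmetric = TRUE)$values
  single <- single[single > max(single) * 1e-12]
  expect_equal(comp$pct_inertia, 100 * single / sum(single), tolerance = 1e-9)
  # intrastructure: all projections coincide, polygon areas are zero
  intra <- pta_intrastructure(st, comp)
  for (k in 2:5) {
    expect_equal(intra$row_coords[[k]], intra$row_coords[[1]], tolerance = 1e-9)
  }
  expect_equal(unname(intra$polygon_areas), rep(0, 5), tolerance = 1e-12)
})

test_that("RV of a table with itself is one and the RV matrix is PSD", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(2:5, 1)
    tabs <- lapply(seq_len(k), function(i) matrix(rnorm(24), 6, 4))
    st <- build_stack(stack_from_matrices(tabs))
    inter <- interstructure(st)
    expect_equal(unname(diag(inter$rv)), rep(1, k), tolerance = 1e-12)
    expect_true(all(inter$rv > 0 & inter$rv <= 1 + 1e-12))
    expect_true(all(eigen(inter$rv, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
    expect_equal(sum(inter$pct_inertia), 100, tolerance = 1e-9)
    expect_equal(sum(inter$weights^2), 1, tolerance = 1e-12)
    expect_true(all(inter$weights > 0))
  }
})

test_that("all PTA outputs match the brute-force oracle on tiny stacks", {
  for (seed in 1:20) {
    d <- random_long_stack(seed, n = 3, p = 2, k = 2)
    st <- build_stack(d)
    inter <- interstructure(st)
    comp <- pta_compromise(st, inter$weights)
    intra <- pta_intrastructure(st, comp, n_axes = length(comp$eigenvalues))
    orc <- oracle_pta(st$tables)
    expect_equal(unname(inter$rv), orc$rv, tolerance = 1e-9)
    expect_equal(inter$eigenvalues, orc$inter_eigenvalues, tolerance = 1e-9)
    expect_equal(unname(inter$weights), orc$weights, tolerance = 1e-9)
    expect_equal(unname(inter$cos2), orc$cos2, tolerance = 1e-9)
    expect_equal(unname(comp$compromise), unname(orc$compromise), tolerance = 1e-9)
    expect_equal(comp$eigenvalues, orc$comp_eigenvalues, tolerance = 1e-9)
    expect_equal(unname(comp$variable_coords), unname(orc$comp_var_coords),
                 tolerance = 1e-9)
    expect_equal(unname(comp$row_coords), unname(orc$comp_row_coords),
                 tolerance = 1e-9)
    for (k in 1:2) {
      expect_equal(unname(intra$row_coords[[k]]), unname(orc$intra_rows[[k]]),
                   tolerance = 1e-9)
      expect_equal(unname(intra$variable_coords[[k]]), unname(orc$intra_vars[[k]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("compromise inertia shares are invariant to weight rescaling", {
  d <- random_long_stack(9, n = 6, p = 4, k = 3)
  st <- build_stack(d)
  w <- interstructure(st)$weights
  c1 <- pta_compromise(st, w)
  c2 <- pta_compromise(st, 10 * w)
  expect_equal(c1$pct_inertia, c2$pct_inertia, tolerance = 1e-12)
  expect_equal(sum(c1$pct_inertia), 100, tolerance = 1e-9)
  expect_error(pta_compromise(st, w[-1]), "one weight")
  expect_error(pta_compromise(st, -w), "positive")
})

test_that("rank-1 tables concentrate all compromise inertia on axis 1", {
  r <- c(1, -2, 0.5, 3)
  cvec <- c(2, 1, -1)
  tabs <- lapply(c(1, 0.6), function(s) s * outer(r, cvec))
  st <- list(tables = tabs, wavelengths = 1:2,
             stations = as.character(1:4), parameters = paste0("p", 1:3))
  class(st) <- "ktable_stack"
  comp <- pta_compromise(st, c(0.7, 0.7))
  expect_equal(comp$pct_inertia[1], 100, tolerance = 1e-9)
})

test_that("per-table projections are local and average back to the compromise", {
  d <- random_long_stack(13, n = 5, p = 3, k = 3)
  st <- build_stack(d)
  inter <- interstructure(st)
  comp <- pta_compromise(st, inter$weights)
  intra <- pta_intrastructure(st, comp, n_axes = length(comp$eigenvalues))
  # weighted average of per-table row projections = compromise row coordinates
  avg <- Reduce(`+`, Map(`*`, intra$row_coords, comp$alpha))
  expect_equal(unname(avg), unname(comp$row_coords), tolerance = 1e-9)
  # perturbing one table moves only its own projection
  st2 <- st
  st2$tables[[2]] <- st2$tables[[2]] + 0.01
  intra2 <- pta_intrastructure(st2, comp, n_axes = length(comp$eigenvalues))
  expect_equal(intra2$row_coords[[1]], intra$row_coords[[1]], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(intra2$row_coords[[2]], intra$row_coords[[2]],
                                tolerance = 1e-6)))
  expect_error(pta_intrastructure(st, comp, n_axes = 99), "rank")
})
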