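test_that("raw PAM tables round-trip through the CSV writer and reader", {
  camp <- small_campaign(seed = 5, n_stations = 2)
  dir <- withr::local_tempdir()
  write_campaign(camp, dir)
  raw <- read_raw_pam(file.path(dir, "rlc.csv"))
  expect_equal(nrow(raw) + nrow(attr(raw, "rejects")), nrow(camp$rlc))
  m <- merge(raw, camp$rlc,
             by = c("station", "wavelength", "replicate", "par"))
  expect_equal(m$f.x, m$f.y, tolerance = 1e-10)
  expect_equal(m$fm_prime.x, m$fm_prime.y, tolerance = 1e-10)

  lp <- read_light_profiles(file.path(dir, "light_profiles.csv"))
  expect_equal(nrow(lp$par), nrow(camp$par_profiles))
  expect_equal(nrow(lp$spectral), nrow(camp$spectral_profiles))
  dp <- read_density_profiles(file.path(dir, "density_profiles.csv"))
  expect_equal(dp$density, camp$density_profiles$density, tolerance = 1e-10)
})

test_that("the raw reader accepts dialect variants and validates rows", {
  dir <- withr::local_tempdir()
  # header variant "Fm (Fm')", semicolon delimiter, decimal commas
  p1 <- file.path(dir, "v1.csv")
  writeLines(c(
    "wavelength;PAR;F;Fm (Fm')",
    "440;0;0,24;0,6",
    "440;100;0,3;0,6"
  ), p1)
  d1 <- read_raw_pam(p1)
  expect_named(d1, c("wavelength", "par", "f", "fm_prime"))
  expect_equal(d1$f, c(0.24, 0.3))
  # header variant "Fm'" with a zero-offset column subtracted
  p2 <- file.path(dir, "v2.csv")
  writeLines(c(
    "wavelength,PAR,F,Fm',zero_offset",
    "440,0,0.29,0.65,0.05",
    "440,100,0.35,0.65,0.05"
  ), p2)
  d2 <- read_raw_pam(p2)
  expect_equal(d2$f, c(0.24, 0.3))
  expect_equal(d2$fm_prime, c(0.6, 0.6))
  # a row with F > Fm' is routed to the rejects, not dropped silently
  p3 <- file.path(dir, "v3.csv")
  writeLines(c(
    "wavelength,PAR,F,Fm'",
    "440,0,0.24,0.6",
    "440,100,0.7,0.6",
    "440,200,abc,0.6"
  ), p3)
  d3 <- read_raw_pam(p3)
  rej <- attr(d3, "rejects")
  expect_equal(nrow(d3), 1L)
  expect_setequal(rej$reject_reason,
                  c("f_exceeds_fm_prime", "unparseable_or_missing_value"))
  # missing mandatory columns are reported by name
  p4 <- file.path(dir, "v4.csv")
  writeLines(c("wavelength,PAR", "440,0"), p4)
  expect_error(read_raw_pam(p4), "f, fm_prime")
})

test_that("pipeline configuration round-trips through YAML with its seed", {
  cfg <- pipeline_config(seed = 77, ek_unit = "absolute", nperm = 99)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, p)
  cfg2 <- read_pipeline_config(p)
  expect_equal(unclass(cfg2), unclass(cfg))
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(nperm = 99), bad)
  expect_error(read_pipeline_config(bad), "seed")
})

test_that("the pipeline is deterministic and equals its composed stages", {
  camp <- small_campaign(seed = 5, n_stations = 6)
  cfg <- pipeline_config(seed = 4, nperm = 49,
                         abiotic_vars = c("z_eu", "tss", "din"))
  r1 <- run_pipeline(camp, cfg)
  r2 <- run_pipeline(camp, cfg)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))

  # composing the stage functions reproduces the pipeline outputs
  st <- compute_station_records(camp)
  expect_identical(r1$stations, st)
  pp <- derive_photo_params(camp, cfg)
  expect_identical(r1$params, pp)
  tr <- wavelength_trends(pp)
  expect_identical(r1$trends$table, tr$table)
  det <- tr$detrended[tr$detrended$parameter %in% aquaphot:::pta_roster(cfg),
                      c("wavelength", "station", "parameter", "detrended")]
  names(det)[4] <- "value"
  stk <- build_stack(det)
  expect_identical(r1$stack$tables, stk$tables)
  expect_identical(r1$pta$interstructure$rv, interstructure(stk)$rv)
  expect_identical(r1$indices, spectral_indices(pp, st))
})

test_that("pipeline results serialize to a reproducible run directory", {
  camp <- small_campaign(seed = 5, n_stations = 6)
  cfg <- pipeline_config(seed = 4, nperm = 49,
                         abiotic_vars = c("z_eu", "tss", "din"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r <- run_pipeline(camp, cfg, out_dir = d1)
  write_pipeline_result(r, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$config$seed, 4)
  expect_equal(man$campaign_seed, 5)
})

test_that("a station missing one wavelength is dropped from PTA but kept elsewhere", {
  camp <- small_campaign(seed = 5, n_stations = 6)
  camp$rlc <- camp$rlc[!(camp$rlc$station == 2 & camp$rlc$wavelength == 590), ]
  camp$induction <- camp$induction[!(camp$induction$station == 2 &
                                       camp$induction$wavelength == 590), ]
  # with one station dropped only 5 rows reach the RDA, so both candidate
  # pools must stay below n - 1 variables
  cfg <- pipeline_config(seed = 4, nperm = 49,
                         abiotic_vars = c("z_eu", "tss", "din"),
                         biotic_vars = c("biomass_brown", "biomass_hapto"))
  expect_message(res <- run_pipeline(camp, cfg), "dropping incomplete station")
  expect_identical(res$manifest$dropped_stations, "2")
  expect_false("2" %in% res$stack$stations)
  expect_true(2 %in% res$indices$station)
  expect_true(2 %in% res$params$station)
})

test_that("pipeline failures name the failing stage", {
  camp <- small_campaign(seed = 5, n_stations = 6)
  broken <- camp
  broken$par_profiles <- broken$par_profiles[0, ]
  expect_error(run_pipeline(broken, pipeline_config(nperm = 49)),
               "light_climate")
  empty <- list(stations = data.frame(), rlc = data.frame(),
                induction = data.frame())
  expect_error(run_pipeline(empty, pipeline_config(nperm = 49)), "stage")
})
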