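full_series <- function(family = "logistic", params = c(K = 100, N0 = 10, r = 0.5),
                        seed = 1, ...) {
  simulate_series(family, params, seed = seed, ...)
}

test_that("period splitting keeps absolute time and the calendar gaps", {
  s <- full_series()
  subs <- split_periods(s, default_periods())
  expect_equal(nrow(subs$whole), 19)
  expect_equal(nrow(subs$first), 12)  # 1996-2009 minus 1999 and 2001
  expect_equal(nrow(subs$last), 4)    # 2015-2018
  expect_equal(subs$last$t, 20:23)    # not re-zeroed
  expect_equal(subs$first$year, setdiff(1996:2009, c(1999, 2001)))
})

test_that("an empty period carries a structured skip reason", {
  s <- full_series()
  subs <- split_periods(s, list(period_spec("none", 1980, 1990)))
  expect_equal(nrow(subs$none), 0)
  expect_equal(attr(subs$none, "skip_reason"), "no data in period")
})

test_that("restricting to the whole period reproduces the unsplit analysis", {
  s <- full_series(seed = 4)
  whole <- split_periods(s, default_periods())$whole
  for (col in c("year", "t", "mean", "se", "n")) {
    expect_equal(whole[[col]], s[[col]])
  }
  f_whole <- fit_all_growth(whole, seed = 9)
  f_unsplit <- fit_all_growth(s, seed = 9)
  expect_equal(vapply(f_whole, `[[`, numeric(1), "rss"),
               vapply(f_unsplit, `[[`, numeric(1), "rss"))
})

test_that("period invariants are validated", {
  expect_error(period_spec("x", 2010, 2000))
  p <- default_periods()
  expect_lt(p$first$end, p$last$start)
  expect_true(p$whole$start <= p$first$start && p$whole$end >= p$last$end)
})

sim_pisc_dataset <- function(seed = 1) {
  cfg <- community_sim_config(
    trajectories = list(PISC = list(family = "logistic",
                                    params = c(K = 40, N0 = 4, r = 0.5))),
    sites = 2, transects_per_site = 2, sigma_transect = 0.2, seed = seed)
  simulate_survey(cfg)
}

test_that("run_analysis recovers the generating family end to end", {
  ds <- sim_pisc_dataset(seed = 2)
  cfg <- analysis_config(descriptors = "PISC", variables = "density", seed = 2)
  bundle <- run_analysis(ds, cfg)
  cell <- bundle$cells$PISC$density$whole
  expect_null(cell$skip)
  fam <- cell$selection$selected$family
  expect_true(fam %in% c("logistic", "gompertz", "asymptotic",
                         "von_bertalanffy") ||
                "logistic" %in% cell$selection$equivalent_set)
  expect_true(cell$capacity$method %in% c("asymptote", "peak"))
  # density saturates near the generating K = 40
  expect_equal(cell$capacity$value, 40, tolerance = 0.25)
})

test_that("short series propagate structured insufficient-data skips", {
  s <- full_series()
  short <- descriptor_series(s[s$year <= 1998, ], reference_year = 1995)
  fits <- fit_all_growth(short, seed = 1)
  three_param <- vapply(fits, function(f) f$k >= 4 && !f$converged, logical(1))
  expect_true(all(three_param[c("logistic", "gompertz", "ricker",
                                "asymptotic", "von_bertalanffy")]))
  expect_equal(fits$logistic$reason, "insufficient_data")
})

test_that("the last 4-year period has no rankable model under default AICc", {
  s <- full_series(seed = 6)
  last <- split_periods(s)$last
  fits <- fit_all_growth(last, seed = 6)
  expect_true(all(is.na(vapply(fits, `[[`, numeric(1), "aicc"))))
  # the raw parameter count lets 2-parameter families be ranked
  fits2 <- fit_all_growth(last, control = fit_control(k_includes_sigma = FALSE),
                          seed = 6)
  expect_false(is.na(fits2$linear$aicc))
  expect_false(is.na(fits2$exponential$aicc))
})

test_that("bundles are byte-identical across reruns with the same seed", {
  ds <- sim_pisc_dataset(seed = 3)
  cfg <- analysis_config(descriptors = "PISC", variables = "density", seed = 7)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_bundle_json(run_analysis(ds, cfg), p1)
  write_bundle_json(run_analysis(ds, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("control data are summarised but not fitted by default", {
  ds <- sim_pisc_dataset(seed = 5)
  ctrl <- sim_pisc_dataset(seed = 8)
  cfg <- analysis_config(descriptors = "PISC", variables = "density", seed = 5)
  bundle <- run_analysis(ds, cfg, control_dataset = ctrl)
  expect_equal(attr(bundle$control_series$PISC.density, "area"), "control")
  expect_null(bundle$cells$PISC$density$control_whole)
  cfg2 <- analysis_config(descriptors = "PISC", variables = "density",
                          seed = 5, fit_control_area = TRUE)
  bundle2 <- run_analysis(ds, cfg2, control_dataset = ctrl)
  expect_false(is.null(bundle2$cells$PISC$density$control_whole))
  tab <- capacity_table(bundle2)
  expect_true(all(c("variable", "descriptor", "period", "capacity") %in%
                    names(tab)))
})

test_that("YAML configuration round-trips into an analysis_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "descriptors: [PISC]",
    "variables: [density]",
    "reference_year: 1995",
    "periods:",
    "  whole: [1996, 2018]",
    "  first: [1996, 2009]",
    "fit:",
    "  max_restarts: 5",
    "capacity_fraction: 0.9",
    "seed: 42"
  ), path)
  cfg <- read_analysis_config(path)
  expect_equal(cfg$descriptors, "PISC")
  expect_equal(cfg$control$max_restarts, 5)
  expect_equal(cfg$capacity_fraction, 0.9)
  expect_equal(vapply(cfg$periods, `[[`, character(1), "name"),
               c("whole", "first"))
  expect_equal(cfg$seed, 42L)
})
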