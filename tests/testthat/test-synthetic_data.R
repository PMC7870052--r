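test_that("noiseless simulation equals the model curve exactly", {
  s <- simulate_series("logistic", c(K = 100, N0 = 10, r = 0.5), noise = "none")
  model <- growth_model("logistic", c(K = 100, N0 = 10, r = 0.5))
  expect_equal(s$mean, predict(model, s$t))
  expect_equal(s$se, rep(0, nrow(s)))
  expect_equal(s$year, default_survey_years())
})

test_that("simulation is fully determined by its seed", {
  a <- simulate_series("exponential", c(a = 10, b = 0.2), seed = 123)
  b <- simulate_series("exponential", c(a = 10, b = 0.2), seed = 123)
  c <- simulate_series("exponential", c(a = 10, b = 0.2), seed = 124)
  expect_identical(a$mean, b$mean)
  expect_false(identical(a$mean, c$mean))
  cfg <- community_sim_config(
    trajectories = list(HERB = list(family = "linear",
                                    params = c(a = 5, m = 0.2))),
    sites = 1, transects_per_site = 2, seed = 99)
  d1 <- simulate_survey(cfg)
  d2 <- simulate_survey(cfg)
  expect_identical(d1$records, d2$records)
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(simulate_series("linear", c(a = 1, m = 1), seed = 50))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("gaussian noise truncates at zero with a warning", {
  expect_warning(
    s <- simulate_series("linear", c(a = 0.1, m = 0), noise = "gaussian",
                         sd = 5, seed = 2),
    "truncated")
  expect_true(all(s$mean >= 0))
})

test_that("transect-level scatter yields a consistent SE", {
  s <- simulate_series("linear", c(a = 100, m = 0), sigma = 0.1,
                       n_transects = 9, seed = 31)
  expect_true(all(s$se > 0))
  expect_equal(s$n, rep(9, nrow(s)))
  # SE magnitude should be near 100 * sigma / 3 on average
  expect_equal(mean(s$se), 100 * 0.1 / 3, tolerance = 0.35)
})

test_that("series-level lapse depresses the configured window", {
  base <- simulate_series("exponential", c(a = 100, b = 0.1), noise = "none")
  lapsed <- simulate_series("exponential", c(a = 100, b = 0.1), noise = "none",
                            lapse = lapse_spec(2010:2014, 0.3,
                                               persistent = FALSE))
  in_win <- lapsed$year %in% 2010:2014
  expect_equal(lapsed$mean[in_win], 0.3 * base$mean[in_win])
  expect_equal(lapsed$mean[!in_win], base$mean[!in_win])
  persist <- simulate_series("exponential", c(a = 100, b = 0.1), noise = "none",
                             lapse = lapse_spec(2010:2014, 0.3,
                                                persistent = TRUE))
  post <- persist$year > 2014
  expect_equal(persist$mean[post], 0.3 * base$mean[post])
})

test_that("groups without a trajectory stay identically zero", {
  cfg <- community_sim_config(
    trajectories = list(PISC = list(family = "linear",
                                    params = c(a = 10, m = 0))),
    sites = 2, transects_per_site = 2, seed = 1)
  ds <- simulate_survey(cfg)
  for (g in setdiff(trophic_groups(), "PISC")) {
    m <- transect_measures(ds, g)
    expect_true(all(m$density == 0), info = g)
  }
  expect_true(any(transect_measures(ds, "PISC")$density > 0))
})

test_that("the survey round trip recovers the generating trajectory", {
  # simulate -> abundance classes -> midpoints -> yearly series; the
  # class encoder randomises between adjacent midpoints so decoding is
  # unbiased; check relative bias of the recovered yearly means
  years <- default_survey_years()
  truth <- predict(growth_model("logistic", c(K = 30, N0 = 3, r = 0.4)),
                   years - 1995)
  est <- matrix(NA_real_, nrow = 50, ncol = length(years))
  for (sd in 1:50) {
    cfg <- community_sim_config(
      trajectories = list(MACRO = list(family = "logistic",
                                       params = c(K = 30, N0 = 3, r = 0.4))),
      sites = 3, transects_per_site = 3, sigma_transect = 0.2, seed = sd)
    ds <- simulate_survey(cfg)
    s <- yearly_series(transect_measures(ds, "MACRO"), "density")
    est[sd, ] <- s$mean[match(years, s$year)]
  }
  rel_bias <- abs(colMeans(est) - truth) / truth
  expect_lt(mean(rel_bias), 0.10)
  expect_lt(max(rel_bias), 0.20)
})

test_that("a survey-level lapse scales the affected years' means", {
  traj <- list(MICRO = list(family = "linear", params = c(a = 20, m = 0)))
  ratios <- vapply(1:10, function(sd) {
    base <- simulate_survey(community_sim_config(
      trajectories = traj, sites = 3, transects_per_site = 3, seed = sd))
    lapsed <- simulate_survey(community_sim_config(
      trajectories = traj, sites = 3, transects_per_site = 3, seed = sd,
      lapse = lapse_spec(2010:2014, 0.3)))
    sb <- yearly_series(transect_measures(base, "MICRO"), "density")
    sl <- yearly_series(transect_measures(lapsed, "MICRO"), "density")
    win <- sb$year %in% 2010:2014
    mean(sl$mean[win]) / mean(sb$mean[win])
  }, numeric(1))
  expect_gt(mean(ratios), 0.2)
  expect_lt(mean(ratios), 0.4)
})

test_that("class encoding error is bounded by the scheme geometry", {
  # decode(encode(count)) differs from the count by less than the class
  # width relative to the class low bound
  scheme <- abundance_scheme()
  for (count in c(1, 2, 5, 6, 10, 11, 30, 31, 50, 51, 100, 101, 200,
                  201, 500, 501, 999)) {
    cls <- mpagrowth:::abundance_class_for_count(count, scheme)
    mid <- abundance_midpoint(cls, scheme)
    rel_err <- abs(mid - count) / count
    bound <- (scheme$high[cls] - scheme$low[cls] + 1) / scheme$low[cls]
    expect_lte(rel_err, bound)
  }
})

test_that("negative trajectories are rejected", {
  cfg <- community_sim_config(
    trajectories = list(PISC = list(family = "linear",
                                    params = c(a = 1, m = -1))),
    seed = 1)
  expect_error(simulate_survey(cfg), "negative")
})
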