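test_that("AICc follows the least-squares form", {
  # rss = n*e makes the log term exactly 1: 19 + 2*3 + 24/15
  expect_equal(aicc(19 * exp(1), n = 19, k = 3), 19 + 6 + 24 / 15)
  # doubling rss adds n*ln(2)
  expect_equal(aicc(2, 19, 3) - aicc(1, 19, 3), 19 * log(2), tolerance = 1e-12)
  expect_identical(aicc(0, 19, 3), -Inf)       # perfect fit wins outright
  expect_true(is.na(aicc(1, 4, 3)))            # n - k - 1 < 1: undefined
})

test_that("nonlinear R2 is one minus the RSS ratio", {
  expect_equal(r_squared(0, 10), 1)
  expect_equal(r_squared(10, 10), 0)
  expect_equal(r_squared(25, 100), 0.75)
  expect_true(is.na(r_squared(1, 0)))          # constant response
})

test_that("noiseless logistic data are recovered essentially exactly", {
  t <- 1:19
  y <- predict(growth_model("logistic", c(K = 100, N0 = 10, r = 0.5)), t)
  fit <- fit_growth("logistic", series_points(t, y), seed = 1)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-10)
  expect_equal(unname(fit$model$params["K"]), 100, tolerance = 1e-3)
  expect_equal(unname(fit$model$params["r"]), 0.5, tolerance = 1e-3)
})

test_that("a constant series is fitted exactly by the linear family", {
  fit <- fit_growth("linear", series_points(1:10, rep(7, 10)))
  expect_equal(unname(fit$model$params), c(7, 0), tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_true(fit$perfect_fit)
})

test_that("too-short series give a structured insufficient-data result", {
  fit <- fit_growth("logistic", series_points(1:3, c(1, 5, 20)))
  expect_false(fit$converged)
  expect_equal(fit$reason, "insufficient_data")
  expect_true(is.na(fit$aicc))
  # and such fits are excluded from ranking
  ok <- fit_growth("linear", series_points(1:6, c(1, 2, 3.1, 4, 5, 6.2)))
  sel <- select_growth(list(fit, ok))
  expect_equal(sel$selected$family, "linear")
  expect_error(select_growth(list(fit)), "no converged fit")
})

fake_fit <- function(family, aicc, r2, k = 4) {
  structure(list(family = family, model = NULL, rss = 1, sstot = 10,
                 n = 19, k = k, aicc = aicc, r2 = r2, converged = TRUE,
                 n_restarts_used = 0L, perfect_fit = FALSE, reason = NULL),
            class = "growth_fit")
}

test_that("selection applies the delta-AICc <= 2 rule with R2 tie-break", {
  # clear winner: lowest AICc, no equivalence
  sel <- select_growth(list(fake_fit("A", 10, 0.6), fake_fit("B", 13, 0.7)))
  expect_equal(sel$selected$family, "A")
  expect_equal(sel$selection_rule_applied, "lowest_aicc")
  expect_equal(sel$equivalent_set, "A")
  # equivalent support: greatest R2 wins
  sel2 <- select_growth(list(fake_fit("A", 10, 0.6), fake_fit("B", 11.5, 0.7)))
  expect_equal(sel2$selected$family, "B")
  expect_equal(sel2$selection_rule_applied, "tiebreak_r2")
  expect_equal(sort(sel2$equivalent_set), c("A", "B"))
  # tie on R2 within the set: lower AICc wins
  sel3 <- select_growth(list(fake_fit("A", 10, 0.7), fake_fit("B", 11.9, 0.7)))
  expect_equal(sel3$selected$family, "A")
  expect_equal(sel3$selection_rule_applied, "lowest_aicc")
  # tie on R2 and AICc: fewer parameters wins
  sel4 <- select_growth(list(fake_fit("A", 10, 0.7, k = 4),
                             fake_fit("B", 10, 0.7, k = 3)))
  expect_equal(sel4$selected$family, "B")
})

test_that("selection is invariant to fit ordering", {
  fits <- list(fake_fit("A", 10, 0.6), fake_fit("B", 11.5, 0.7),
               fake_fit("C", 11.9, 0.65), fake_fit("D", 30, 0.99))
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 2, 4))) {
    sel <- select_growth(fits[perm])
    expect_equal(sel$selected$family, "B")
    expect_equal(sort(sel$equivalent_set), c("A", "B", "C"))
  }
})

test_that("fits match an independent grid-search minimiser", {
  # 30 random short series; the coarse-to-fine grid search is an
  # independent minimiser of the same unweighted RSS
  grid_rss <- function(family, pts, lo, hi, steps = 12, zooms = 3) {
    best <- Inf
    for (z in 1:zooms) {
      grids <- Map(function(l, h) seq(l, h, length.out = steps), lo, hi)
      combos <- do.call(expand.grid, grids)
      rss <- apply(combos, 1, function(p) {
        yy <- predict(growth_model(family, setNames(as.numeric(p), names(lo))),
                      pts$t)
        sum((pts$mean - yy)^2)
      })
      i <- which.min(rss)
      best <- min(best, rss[i])
      ctr <- as.numeric(combos[i, ])
      span <- (hi - lo) / steps
      lo <- ctr - span
      hi <- ctr + span
    }
    best
  }
  set.seed(11)
  for (i in 1:15) {
    a <- runif(1, 1, 5); b <- runif(1, 0.05, 0.25)
    t <- 1:8
    y <- a * exp(b * t) * exp(rnorm(8, 0, 0.1))
    pts <- series_points(t, y)
    fit <- fit_growth("exponential", pts, seed = i)
    oracle <- grid_rss("exponential", pts, lo = c(a = 0.1, b = 0),
                       hi = c(a = 10, b = 0.5))
    expect_lte(fit$rss, oracle * 1.01)
  }
  for (i in 1:15) {
    K <- runif(1, 50, 150); N0 <- runif(1, 2, 10); r <- runif(1, 0.3, 0.7)
    t <- 1:10
    y <- predict(growth_model("logistic", c(K = K, N0 = N0, r = r)), t) *
      exp(rnorm(10, 0, 0.05))
    pts <- series_points(t, y)
    fit <- fit_growth("logistic", pts, seed = i)
    oracle <- grid_rss("logistic", pts, lo = c(K = 20, N0 = 0.5, r = 0.05),
                       hi = c(K = 300, N0 = 20, r = 1.5), steps = 10)
    expect_lte(fit$rss, oracle * 1.01)
  }
})

test_that("von Bertalanffy and asymptotic reach the same minimal RSS", {
  # the two families coincide under N0 = K(1 - e^(r t0))
  set.seed(3)
  for (i in 1:5) {
    K <- runif(1, 50, 200); r <- runif(1, 0.2, 0.6)
    t <- 1:15
    y <- K * (1 - exp(-r * t)) * exp(rnorm(15, 0, 0.05))
    pts <- series_points(t, y)
    vb <- fit_growth("von_bertalanffy", pts, seed = i)
    as <- fit_growth("asymptotic", pts, seed = i)
    expect_true(vb$converged && as$converged)
    denom <- max(vb$rss, as$rss, 1e-12)
    expect_lt(abs(vb$rss - as$rss) / denom, 1e-6)
  }
})

test_that("restart jitter is seeded and reproducible", {
  t <- 1:12
  set.seed(99)
  y <- 50 / (1 + 9 * exp(-0.4 * t)) * exp(rnorm(12, 0, 0.1))
  f1 <- fit_growth("gompertz", series_points(t, y), seed = 5)
  f2 <- fit_growth("gompertz", series_points(t, y), seed = 5)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$n_restarts_used, f2$n_restarts_used)
  # gompertz fits respect the saturating sign constraints
  expect_lt(f1$model$params[["r"]], 0)
  expect_lt(f1$model$params[["b"]], 0)
})
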