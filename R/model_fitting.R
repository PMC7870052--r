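# Nonlinear least-squares fitting of the growth families and AICc selection.

# Run code under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fitting options
#'
#' @param max_restarts Maximum number of jittered restarts after the
#'   rule-based start (multi-start nonlinear least squares).
#' @param converged_target Stop restarting once this many starts have
#'   converged (the best residual sum of squares is kept).
#' @param jitter_sd Log-scale SD of the multiplicative jitter applied to
#'   start values on restarts.
#' @param k_includes_sigma If `TRUE` (default) the AICc parameter count is
#'   n_params + 1, counting the residual variance as estimated — the
#'   standard convention for least-squares AICc. Setting `FALSE` uses the
#'   raw parameter count, which lets very short series (e.g. a 4-year
#'   period) still be ranked.
#' @return List of class `fit_control`.
#' @export
fit_control <- function(max_restarts = 20, converged_target = 3,
                        jitter_sd = 0.3, k_includes_sigma = TRUE) {
  stopifnot(max_restarts >= 0, converged_target >= 1, jitter_sd >= 0)
  structure(list(max_restarts = max_restarts,
                 converged_target = converged_target,
                 jitter_sd = jitter_sd,
                 k_includes_sigma = k_includes_sigma),
            class = "fit_control")
}

#' Small-sample-corrected AIC for a least-squares fit
#'
#' AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n - k - 1). A zero RSS (perfect fit)
#' returns `-Inf` so the model wins outright; n - k - 1 < 1 returns `NA`
#' (undefined; the model is excluded from ranking).
#'
#' @param rss Residual sum of squares.
#' @param n Number of fitted points.
#' @param k Parameter count (including the error variance under the default
#'   convention).
#' @return AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (n - k - 1 < 1) return(NA_real_)
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Nonlinear coefficient of determination
#'
#' R^2 = 1 - RSS / SStot, with SStot the total sum of squares of the
#' response. Undefined (NA) for a constant response.
#'
#' @param rss Residual sum of squares.
#' @param sstot Total sum of squares.
#' @return R-squared value.
#' @export
r_squared <- function(rss, sstot) {
  if (sstot <= 0) return(NA_real_)
  1 - rss / sstot
}

growth_fit_result <- function(family, n, k, model = NULL, rss = NA_real_,
                              sstot = NA_real_, converged = FALSE,
                              n_restarts_used = 0L, reason = NULL,
                              scale = 1) {
  # numerically exact fits: snap residual dust to the zero-RSS sentinel
  if (converged && is.finite(rss) && rss < 1e-20 * max(scale, 1)) {
    rss <- 0
  }
  structure(list(
    family = family, model = model, rss = rss, sstot = sstot,
    n = n, k = k,
    aicc = if (converged) aicc(rss, n, k) else NA_real_,
    r2 = if (converged) r_squared(rss, sstot) else NA_real_,
    converged = converged, n_restarts_used = n_restarts_used,
    perfect_fit = converged && isTRUE(rss <= 0),
    reason = reason
  ), class = "growth_fit")
}

jitter_start <- function(start, jitter_sd) {
  jit <- start * exp(stats::rnorm(length(start), 0, jitter_sd))
  flat <- start == 0
  jit[flat] <- stats::rnorm(sum(flat), 0, jitter_sd)
  jit
}

family_bounds <- function(family, start) {
  lower <- rep(-Inf, length(start))
  upper <- rep(Inf, length(start))
  names(lower) <- names(upper) <- names(start)
  if (family == "logistic") lower[c("K", "N0")] <- 1e-10
  if (family == "gompertz") upper[c("b", "r")] <- -1e-9  # saturating branch
  list(lower = lower, upper = upper)
}

#' Fit one growth family to a yearly series
#'
#' Minimises the residual sum of squares of the family's curve against the
#' yearly means (unweighted) by Levenberg-Marquardt nonlinear least squares,
#' multi-started from [initial_guess()] plus seeded jittered restarts. The
#' linear family is solved exactly by ordinary least squares. Series shorter
#' than n_params + 2 points yield a structured insufficient-data result.
#'
#' @param family Growth family name.
#' @param points Data frame with columns `t` and `mean` (a
#'   [descriptor_series()] works directly).
#' @param control A [fit_control()].
#' @param seed Optional seed for the restart jitter (restores the caller's
#'   RNG state afterwards).
#' @return Object of class `growth_fit`: family, fitted [growth_model()],
#'   `rss`, `n`, `k`, `aicc`, `r2`, `converged`, `n_restarts_used`.
#' @export
fit_growth <- function(family, points, control = fit_control(), seed = NULL) {
  family <- match.arg(family, names(family_registry))
  pts <- data.frame(t = points$t, mean = points$mean)
  pts <- pts[is.finite(pts$mean), , drop = FALSE]
  n <- nrow(pts)
  p <- length(family_registry[[family]])
  k <- p + if (isTRUE(control$k_includes_sigma)) 1L else 0L
  if (n < p + 2) {
    return(growth_fit_result(family, n, k, reason = "insufficient_data"))
  }
  sstot <- sum((pts$mean - mean(pts$mean))^2)

  start0 <- tryCatch(initial_guess(family, pts), error = function(e) NULL)
  if (is.null(start0)) {
    return(growth_fit_result(family, n, k, reason = "no_starting_values"))
  }

  if (family == "linear") {
    co <- stats::coef(stats::lm(mean ~ t, data = pts))
    model <- growth_model("linear", c(a = unname(co[1]), m = unname(co[2])))
    rss <- sum((pts$mean - predict(model, pts$t))^2)
    return(growth_fit_result(family, n, k, model = model, rss = rss,
                             sstot = sstot, converged = TRUE,
                             scale = sum(pts$mean^2)))
  }

  bounds <- family_bounds(family, start0)
  clamp <- function(s) pmin(pmax(s, bounds$lower + 1e-12), bounds$upper - 1e-12)
  try_start <- function(start) {
    fm <- stats::as.formula(paste(
      "mean ~ eval_family('", family, "', c(",
      paste(sprintf("%s = %s", names(start0), names(start0)), collapse = ", "),
      "), t)", sep = ""))
    tryCatch({
      fit <- minpack.lm::nlsLM(
        fm, data = pts, start = as.list(start),
        lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      )
      est <- stats::coef(fit)
      model <- growth_model(family, est)
      list(model = model, rss = sum((pts$mean - predict(model, pts$t))^2))
    }, error = function(e) NULL, warning = function(w) NULL)
  }

  with_seed(seed, {
    best <- try_start(clamp(start0))
    n_conv <- as.integer(!is.null(best))
    restarts <- 0L
    while (restarts < control$max_restarts &&
           n_conv < control$converged_target) {
      restarts <- restarts + 1L
      cand <- try_start(clamp(jitter_start(start0, control$jitter_sd)))
      if (!is.null(cand)) {
        n_conv <- n_conv + 1L
        if (is.null(best) || cand$rss < best$rss) best <- cand
      }
    }
    if (is.null(best)) {
      growth_fit_result(family, n, k, n_restarts_used = restarts,
                        reason = "no_convergence")
    } else {
      growth_fit_result(family, n, k, model = best$model, rss = best$rss,
                        sstot = sstot, converged = TRUE,
                        n_restarts_used = restarts, scale = sum(pts$mean^2))
    }
  })
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Growth fit:", x$family, "- not converged (", x$reason %||% "", ")\n")
  } else {
    cat(sprintf("Growth fit: %s  RSS=%.4g  AICc=%.3f  R2=%.3f (n=%d, k=%d)\n",
                x$family, x$rss, x$aicc, x$r2, x$n, x$k))
  }
  invisible(x)
}

#' Fit all seven growth families
#'
#' @inheritParams fit_growth
#' @param families Subset of family names; default all seven.
#' @return Named list of `growth_fit` objects.
#' @export
fit_all_growth <- function(points, families = names(family_registry),
                           control = fit_control(), seed = NULL) {
  with_seed(seed, {
    fits <- lapply(families, function(f) fit_growth(f, points, control))
    names(fits) <- families
    fits
  })
}

#' Select the supported model by AICc with an R-squared tie-break
#'
#' The fit with the lowest AICc is best-supported; fits within 2 AICc units
#' of it are treated as equivalently supported, and among those the fit with
#' the greatest R^2 is selected. Ties on R^2 are broken by lower AICc, then
#' by fewer parameters. Non-converged fits and fits with undefined AICc are
#' excluded from ranking.
#'
#' @param fits List of `growth_fit` objects (see [fit_all_growth()]).
#' @return Object of class `selection_result`: `fits` (ranked), `selected`,
#'   `equivalent_set` (family names with delta-AICc <= 2),
#'   `selection_rule_applied` (`"lowest_aicc"` or `"tiebreak_r2"`), `delta`.
#' @export
select_growth <- function(fits) {
  ok <- Filter(function(f) isTRUE(f$converged) && !is.na(f$aicc), fits)
  if (length(ok) == 0) stop_mpag("no converged fit with a defined AICc")
  a <- vapply(ok, `[[`, numeric(1), "aicc")
  ord <- order(a)
  ok <- ok[ord]
  a <- a[ord]
  best_aicc <- a[1]
  delta <- if (is.infinite(best_aicc)) ifelse(is.infinite(a), 0, Inf) else a - best_aicc
  eq <- which(delta <= 2)
  r2 <- vapply(ok, `[[`, numeric(1), "r2")
  kk <- vapply(ok, `[[`, numeric(1), "k")
  # greatest R2 within the equivalent set; ties -> lower AICc -> fewer params
  r2_eq <- r2[eq]
  r2_eq[is.na(r2_eq)] <- -Inf
  pick <- eq[order(-r2_eq, a[eq], kk[eq])][1]
  structure(list(
    fits = ok,
    all_fits = fits,
    selected = ok[[pick]],
    equivalent_set = vapply(ok[eq], `[[`, character(1), "family"),
    delta = stats::setNames(delta, vapply(ok, `[[`, character(1), "family")),
    selection_rule_applied = if (pick == 1) "lowest_aicc" else "tiebreak_r2"
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Model selection:", x$selected$family, "selected (",
      x$selection_rule_applied, ")\n")
  tab <- data.frame(
    family = vapply(x$fits, `[[`, character(1), "family"),
    aicc = round(vapply(x$fits, `[[`, numeric(1), "aicc"), 3),
    delta = round(unname(x$delta), 3),
    r2 = round(vapply(x$fits, `[[`, numeric(1), "r2"), 4)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}
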