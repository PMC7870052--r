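# Carrying-capacity estimates and recovery-time summaries from selected fits.

capacity_estimate <- function(method, value, time_to_capacity = NA_real_,
                              family = NA_character_, params = NULL,
                              fraction = NA_real_, t_end = NA_real_) {
  structure(list(method = method, value = value,
                 time_to_capacity = time_to_capacity,
                 fraction = fraction, t_end = t_end,
                 family = family, params = params),
            class = "capacity_estimate")
}

#' Time for a saturating model to reach a fraction of its capacity
#'
#' Smallest t with y(t) >= f * K, solved in closed form for the logistic
#' (t = ln(((K - N0)/N0) * f/(1 - f)) / r) and asymptotic families and by
#' bisection (tolerance 1e-6 year) for von Bertalanffy and saturating
#' Gompertz.
#'
#' @param model A saturating [growth_model()].
#' @param fraction Target fraction of the carrying capacity, in (0, 1).
#' @return Time in years since protection inception (0 if the series starts
#'   at or above the target level).
#' @export
time_to_fraction <- function(model, fraction) {
  stopifnot(inherits(model, "growth_model"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_mpag("fraction must be strictly between 0 and 1")
  }
  asy <- asymptote(model)
  if (!identical(asy$kind, "carrying_capacity")) {
    stop_mpag("time_to_fraction is defined for saturating models only")
  }
  p <- as.list(model$params)
  target <- fraction * asy$value
  # curves that start at or above the target (e.g. fitted approaches from
  # above, N0 > K) reach it immediately
  if (predict(model, 0) >= target) return(0)
  arg <- switch(model$family,
    logistic = ((p$K - p$N0) / p$N0) * fraction / (1 - fraction),
    asymptotic = (p$K - p$N0) / (p$K * (1 - fraction)),
    NULL
  )
  if (!is.null(arg) && is.finite(arg) && arg > 0) {
    closed <- log(arg) / p$r
    if (is.finite(closed)) return(max(closed, 0))
  }
  # monotone saturating curve: bracket then bisect
  f <- function(t) predict(model, t) - target
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) < 0) {
    warning("target fraction not reached within 1e6 years; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  stats::uniroot(f, c(0, hi), tol = 1e-6)$root
}

#' Carrying capacity implied by a model selection
#'
#' Maps the selected fit's long-run behaviour into a capacity estimate: the
#' asymptote K for saturating families (with the time to reach `fraction`
#' of it), the interior peak for Ricker, and an explicit no-finite-capacity
#' record (not an error) for unbounded linear/exponential selections.
#'
#' @param selection A [select_growth()] result, or a single converged
#'   `growth_fit`.
#' @param fraction Fraction of K defining the "time to capacity" summary
#'   (conventional default 0.95).
#' @return Object of class `capacity_estimate` with `method` one of
#'   `"asymptote"`, `"peak"`, `"constant"`, `"unbounded"`.
#' @export
capacity_from_fit <- function(selection, fraction = 0.95) {
  fit <- if (inherits(selection, "selection_result")) selection$selected else selection
  stopifnot(inherits(fit, "growth_fit"))
  if (!fit$converged) stop_mpag("selected fit did not converge")
  asy <- asymptote(fit$model)
  switch(asy$kind,
    carrying_capacity = capacity_estimate(
      "asymptote", asy$value,
      time_to_capacity = time_to_fraction(fit$model, fraction),
      family = fit$family, params = fit$model$params, fraction = fraction),
    peak = capacity_estimate(
      "peak", asy$value, time_to_capacity = asy$time_at_peak,
      family = fit$family, params = fit$model$params),
    constant = capacity_estimate(
      "constant", asy$value, family = fit$family, params = fit$model$params),
    unbounded = capacity_estimate(
      "unbounded", NA_real_, family = fit$family, params = fit$model$params)
  )
}

#' Capacity projected from a first-period exponential trend
#'
#' When the pre-lapse period grows exponentially while the whole period
#' saturates, a counterfactual capacity is obtained by evaluating the
#' first-period exponential curve a e^(b t) at the whole-study horizon
#' (default t = 23 years). This is an interpretation of "capacity from the
#' initial exponential trend" and is labelled `exponential_projection`,
#' never `asymptote`.
#'
#' @param fit A converged exponential `growth_fit` with growth rate b > 0.
#' @param t_end Projection horizon in years since protection inception.
#' @return A `capacity_estimate` with method `"exponential_projection"`.
#' @export
exponential_projection <- function(fit, t_end = 23) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!fit$converged || fit$family != "exponential") {
    stop_mpag("exponential_projection needs a converged exponential fit")
  }
  b <- fit$model$params[["b"]]
  if (b <= 0) stop_mpag("no growth to project: exponential rate b must be > 0")
  a <- fit$model$params[["a"]]
  capacity_estimate("exponential_projection", a * exp(b * t_end),
                    family = "exponential", params = fit$model$params,
                    t_end = t_end)
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat("Capacity estimate [", x$method, "]: ",
      if (is.na(x$value)) "no finite capacity" else signif(x$value, 5),
      if (!is.na(x$time_to_capacity))
        paste0("  (reached ~", signif(x$time_to_capacity, 4), " y)") else "",
      "  from ", x$family, "\n", sep = "")
  invisible(x)
}
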