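# The seven population-growth families as evaluable parametric curves.
#
#   linear           y = a + m t
#   exponential      y = a e^(b t)
#   von_bertalanffy  y = K (1 - e^(-r (t - t0)))
#   logistic         y = K / (1 + ((K - N0)/N0) e^(-r t))
#   asymptotic       y = K + (N0 - K) e^(-r t)
#   gompertz         y = K e^(b e^(r t))      (saturates at K only for r < 0)
#   ricker           y = N0 + (a t) e^(-b t)  (interior peak, then decline)

family_registry <- list(
  linear          = c("a", "m"),
  exponential     = c("a", "b"),
  von_bertalanffy = c("K", "r", "t0"),
  logistic        = c("K", "N0", "r"),
  asymptotic      = c("K", "N0", "r"),
  gompertz        = c("K", "b", "r"),
  ricker          = c("N0", "a", "b")
)

#' The growth-model registry
#'
#' @return Data frame of family names, parameter names and parameter counts.
#' @export
growth_families <- function() {
  data.frame(
    family = names(family_registry),
    params = vapply(family_registry, paste, character(1), collapse = ","),
    n_params = vapply(family_registry, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Construct a growth model
#'
#' @param family One of `"linear"`, `"exponential"`, `"von_bertalanffy"`,
#'   `"logistic"`, `"asymptotic"`, `"gompertz"`, `"ricker"`.
#' @param params Named numeric vector with exactly the family's parameters.
#' @return Object of class `growth_model`.
#' @export
growth_model <- function(family, params) {
  family <- match.arg(family, names(family_registry))
  expected <- family_registry[[family]]
  if (!setequal(names(params), expected) || length(params) != length(expected)) {
    stop_mpag("family '", family, "' needs parameters ",
              paste(expected, collapse = ", "))
  }
  params <- unlist(params)[expected]
  if (family == "logistic") {
    if (params[["N0"]] == 0) stop_mpag("logistic N0 must be nonzero")
    if (params[["K"]] <= 0 || params[["N0"]] <= 0) {
      stop_mpag("logistic requires K > 0 and N0 > 0")
    }
  }
  structure(list(family = family, params = params), class = "growth_model")
}

eval_family <- function(family, params, t) {
  p <- as.list(params)
  switch(family,
    linear = p$a + p$m * t,
    exponential = p$a * exp(p$b * t),
    von_bertalanffy = p$K * (1 - exp(-p$r * (t - p$t0))),
    logistic = p$K / (1 + ((p$K - p$N0) / p$N0) * exp(-p$r * t)),
    asymptotic = p$K + (p$N0 - p$K) * exp(-p$r * t),
    gompertz = p$K * exp(p$b * exp(p$r * t)),
    ricker = p$N0 + (p$a * t) * exp(-p$b * t),
    stop_mpag("unknown family '", family, "'")
  )
}

#' Evaluate a growth model
#'
#' Pointwise evaluation of the family's equation.
#'
#' @param object A [growth_model()].
#' @param t Time vector (years since protection inception).
#' @param ... Unused.
#' @return Numeric vector of responses.
#' @export
predict.growth_model <- function(object, t, ...) {
  eval_family(object$family, object$params, t)
}

#' @export
print.growth_model <- function(x, ...) {
  cat("Growth model:", x$family, "(",
      paste(names(x$params), signif(x$params, 5), sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

#' Long-run level of a growth model
#'
#' Classifies the model's long-run behaviour and, where one exists, returns
#' its level: the carrying capacity K for the saturating families (logistic,
#' asymptotic, von Bertalanffy, and Gompertz with r < 0), the interior peak
#' N0 + (a/b) e^-1 at t = 1/b for Ricker, a constant for degenerate flat
#' fits, and no finite level for growing linear/exponential fits.
#'
#' @param model A [growth_model()].
#' @return List with `value` (number or `NA`), `kind` (one of
#'   `"carrying_capacity"`, `"peak"`, `"unbounded"`, `"constant"`), and for
#'   peaks `time_at_peak`.
#' @export
asymptote <- function(model) {
  stopifnot(inherits(model, "growth_model"))
  p <- as.list(model$params)
  switch(model$family,
    linear = if (p$m == 0) list(value = p$a, kind = "constant")
             else list(value = NA_real_, kind = "unbounded"),
    exponential = if (p$b == 0) list(value = p$a, kind = "constant")
                  else list(value = NA_real_, kind = "unbounded"),
    von_bertalanffy = list(value = p$K, kind = "carrying_capacity"),
    logistic = list(value = p$K, kind = "carrying_capacity"),
    asymptotic = list(value = p$K, kind = "carrying_capacity"),
    gompertz = if (p$r < 0) {
      list(value = p$K, kind = "carrying_capacity")
    } else {
      warning("Gompertz with r >= 0 does not saturate; no carrying capacity",
              call. = FALSE)
      list(value = NA_real_, kind = "unbounded")
    },
    ricker = if (p$b > 0) {
      list(value = p$N0 + (p$a / p$b) * exp(-1), kind = "peak",
           time_at_peak = 1 / p$b)
    } else {
      list(value = NA_real_, kind = "unbounded")
    }
  )
}

#' Data-driven starting values for fitting
#'
#' Rule-based start values: K from 1.05 x the series maximum, N0 from the
#' first positive mean, slopes from least squares on (t, y) or (t, log y),
#' t0 = 0, and Ricker's decay from the inverse time of the series maximum.
#' Where log-based rules are undefined (non-positive values) documented
#' constants are used instead.
#'
#' @param family Growth family name.
#' @param points Data frame with columns `t` and `mean`.
#' @return Named numeric vector of start values.
#' @export
initial_guess <- function(family, points) {
  family <- match.arg(family, names(family_registry))
  t <- points$t
  y <- points$mean
  if (length(t) < length(family_registry[[family]]) + 1) {
    stop_mpag("need at least n_params + 1 points for a starting guess")
  }
  pos <- y > 0
  if (!any(pos)) stop_mpag("all-zero/negative series: no starting guess")
  K0 <- 1.05 * max(y)
  N0 <- y[which(pos)[1]]
  ls_slope <- stats::coef(stats::lm(y ~ t))
  log_slope <- if (sum(pos) >= 2) {
    stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
  } else c(log(N0), 0.3)
  r0 <- max(abs(log_slope[2]), 0.05)
  switch(family,
    linear = c(a = unname(ls_slope[1]), m = unname(ls_slope[2])),
    exponential = c(a = unname(exp(log_slope[1])), b = unname(log_slope[2])),
    von_bertalanffy = c(K = K0, r = r0, t0 = 0),
    logistic = c(K = K0, N0 = N0, r = r0),
    asymptotic = c(K = K0, N0 = N0, r = r0),
    gompertz = c(K = K0, b = min(log(N0 / K0), -1e-3), r = -r0),
    ricker = {
      ord <- order(t)
      dy <- diff(y[ord]) / diff(t[ord])
      a0 <- if (length(dy) > 0 && is.finite(dy[1]) && dy[1] != 0) dy[1] else
        max(y) / max(t)
      t_max <- t[which.max(y)]
      b0 <- if (t_max > 0) 1 / t_max else 1
      c(N0 = N0, a = a0, b = b0)
    }
  )
}
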