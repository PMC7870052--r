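# Orchestration over enforcement periods: series -> fits -> capacities.

#' Enforcement-period specification
#'
#' @param name Period label (`"whole"`, `"first"`, `"last"`, or any string).
#' @param start,end Inclusive calendar-year range.
#' @return Object of class `period_spec`.
#' @export
period_spec <- function(name, start, end) {
  stopifnot(is.character(name), start <= end)
  structure(list(name = name, start = start, end = end), class = "period_spec")
}

#' The default enforcement periods
#'
#' Whole study (1996--2018); the pre-lapse period of continuous high
#' enforcement (1996--2009); and the post-restoration period (2015--2018).
#' The 2010--2014 surveillance-lapse years belong to the whole period only.
#'
#' @return Named list of [period_spec()]s.
#' @export
default_periods <- function() {
  list(whole = period_spec("whole", 1996, 2018),
       first = period_spec("first", 1996, 2009),
       last  = period_spec("last", 2015, 2018))
}

#' Split a series into period sub-series
#'
#' Filters points by each period's year range. The time coordinate is kept
#' absolute (years since the reference year, not re-zeroed), so parameter
#' semantics are comparable across periods.
#'
#' @param series A [descriptor_series()].
#' @param periods List of [period_spec()]s.
#' @return Named list of sub-series; empty periods carry attribute
#'   `skip_reason = "no data in period"` on an empty series.
#' @export
split_periods <- function(series, periods = default_periods()) {
  out <- lapply(periods, function(p) {
    sub <- series[series$year >= p$start & series$year <= p$end, , drop = FALSE]
    sub <- descriptor_series(sub, descriptor = attr(series, "descriptor"),
                             variable = attr(series, "variable"),
                             area = attr(series, "area"),
                             reference_year = attr(series, "reference_year"))
    if (nrow(sub) == 0) attr(sub, "skip_reason") <- "no data in period"
    sub
  })
  names(out) <- vapply(periods, `[[`, character(1), "name")
  out
}

#' Analysis configuration
#'
#' @param descriptors Descriptor identifiers to analyse.
#' @param variables Response variables.
#' @param periods List of [period_spec()]s.
#' @param reference_year Year zero of the time axis.
#' @param scheme [abundance_scheme()] used to decode abundance classes.
#' @param control [fit_control()] fitting options.
#' @param capacity_fraction Fraction of K defining time-to-capacity.
#' @param projection_t_end Horizon (years) for the first-period exponential
#'   projection.
#' @param fit_control_area If `TRUE`, growth curves are also fitted to
#'   control-area series (by default the control is summarised only).
#' @param seed Integer seed governing all fitting restarts.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(descriptors = default_descriptors(),
                            variables = c("biomass", "density"),
                            periods = default_periods(),
                            reference_year = 1995,
                            scheme = abundance_scheme(),
                            control = fit_control(),
                            capacity_fraction = 0.95,
                            projection_t_end = 23,
                            fit_control_area = FALSE,
                            seed = 1L) {
  structure(list(descriptors = descriptors, variables = variables,
                 periods = periods, reference_year = reference_year,
                 scheme = scheme, control = control,
                 capacity_fraction = capacity_fraction,
                 projection_t_end = projection_t_end,
                 fit_control_area = fit_control_area,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys mirror [analysis_config()] arguments; `periods` is a
#' mapping name -> [start, end]; `scheme` takes `bounds` (list of pairs) and
#' `midpoint_rule`; `fit` takes [fit_control()] fields.
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  periods <- if (!is.null(y$periods)) {
    lapply(names(y$periods), function(nm) {
      period_spec(nm, y$periods[[nm]][[1]], y$periods[[nm]][[2]])
    })
  } else default_periods()
  scheme <- if (!is.null(y$scheme)) {
    abundance_scheme(bounds = lapply(y$scheme$bounds, unlist),
                     midpoint_rule = y$scheme$midpoint_rule %||% "arithmetic")
  } else abundance_scheme()
  ctrl <- if (!is.null(y$fit)) do.call(fit_control, y$fit) else fit_control()
  analysis_config(
    descriptors = y$descriptors %||% default_descriptors(),
    variables = y$variables %||% c("biomass", "density"),
    periods = periods, reference_year = y$reference_year %||% 1995,
    scheme = scheme, control = ctrl,
    capacity_fraction = y$capacity_fraction %||% 0.95,
    projection_t_end = y$projection_t_end %||% 23,
    fit_control_area = isTRUE(y$fit_control_area),
    seed = y$seed %||% 1L
  )
}

analyse_period_series <- function(sub, config, cell_seed) {
  if (!is.null(attr(sub, "skip_reason"))) {
    return(list(skip = attr(sub, "skip_reason")))
  }
  fits <- fit_all_growth(sub, control = config$control, seed = cell_seed)
  sel <- tryCatch(select_growth(fits), error = function(e) NULL)
  if (is.null(sel)) {
    return(list(skip = "no model rankable (insufficient data)", fits = fits))
  }
  cap <- capacity_from_fit(sel, fraction = config$capacity_fraction)
  list(selection = sel, capacity = cap, n_points = nrow(sub))
}

#' Run the full pipeline over descriptors, variables and periods
#'
#' For every requested descriptor x response variable, builds the yearly
#' series from the protected-area dataset, splits it by enforcement period,
#' fits all seven growth families per period, selects the supported model
#' and derives its capacity estimate. Where the whole period saturates and
#' the first period is exponential, the counterfactual
#' [exponential_projection()] is also recorded. Control-area data (if
#' supplied) are summarised as series only, unless `fit_control_area` is
#' set. Per-cell failures are recorded as structured skips, never aborting
#' the bundle.
#'
#' @param dataset Protected-area [survey_dataset()].
#' @param config An [analysis_config()].
#' @param control_dataset Optional control-area [survey_dataset()].
#' @return Object of class `analysis_bundle`: nested list
#'   `cells[[descriptor]][[variable]][[period]]`, `series`,
#'   `control_series`, and run `metadata`.
#' @export
run_analysis <- function(dataset, config = analysis_config(),
                         control_dataset = NULL) {
  cells <- list()
  series_store <- list()
  control_store <- list()
  cell_index <- 0L
  for (d in config$descriptors) {
    meas <- transect_measures(dataset, d, scheme = config$scheme)
    for (v in config$variables) {
      s <- yearly_series(meas, variable = v,
                         reference_year = config$reference_year,
                         area = "protected")
      series_store[[paste(d, v, sep = ".")]] <- s
      subs <- split_periods(s, config$periods)
      per_period <- list()
      for (pn in names(subs)) {
        cell_index <- cell_index + 1L
        per_period[[pn]] <- analyse_period_series(
          subs[[pn]], config, cell_seed = config$seed + cell_index)
      }
      # counterfactual projection when whole saturates but first is exponential
      wh <- per_period[["whole"]]; fi <- per_period[["first"]]
      if (!is.null(wh$capacity) && wh$capacity$method == "asymptote" &&
          !is.null(fi$selection) && fi$selection$selected$family == "exponential" &&
          fi$selection$selected$model$params[["b"]] > 0) {
        per_period[["whole"]]$exponential_projection <-
          exponential_projection(fi$selection$selected,
                                 t_end = config$projection_t_end)
      }
      cells[[d]][[v]] <- per_period
    }
  }
  if (!is.null(control_dataset)) {
    for (d in config$descriptors) {
      meas <- transect_measures(control_dataset, d, scheme = config$scheme)
      for (v in config$variables) {
        s <- yearly_series(meas, variable = v,
                           reference_year = config$reference_year,
                           area = "control")
        control_store[[paste(d, v, sep = ".")]] <- s
        if (isTRUE(config$fit_control_area)) {
          cell_index <- cell_index + 1L
          cells[[d]][[v]][["control_whole"]] <- analyse_period_series(
            s, config, cell_seed = config$seed + cell_index)
        }
      }
    }
  }
  structure(list(cells = cells, series = series_store,
                 control_series = control_store,
                 metadata = list(seed = config$seed,
                                 descriptors = config$descriptors,
                                 variables = config$variables,
                                 periods = lapply(config$periods, unclass),
                                 reference_year = config$reference_year)),
            class = "analysis_bundle")
}

#' Flatten a bundle into a capacity table
#'
#' One row per (variable, descriptor, period): the selected family, its
#' capacity estimate and, where computed, the first-period exponential
#' projection — mirroring a capacity summary table.
#'
#' @param bundle An [run_analysis()] result.
#' @param path Optional CSV output path.
#' @return Data frame.
#' @export
capacity_table <- function(bundle, path = NULL) {
  rows <- list()
  for (d in names(bundle$cells)) {
    for (v in names(bundle$cells[[d]])) {
      for (p in names(bundle$cells[[d]][[v]])) {
        cell <- bundle$cells[[d]][[v]][[p]]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, descriptor = d, period = p,
          selected_family = if (!is.null(cell$selection))
            cell$selection$selected$family else NA_character_,
          method = if (!is.null(cell$capacity)) cell$capacity$method
                   else NA_character_,
          capacity = if (!is.null(cell$capacity)) cell$capacity$value
                     else NA_real_,
          time_to_capacity = if (!is.null(cell$capacity))
            cell$capacity$time_to_capacity else NA_real_,
          projection = if (!is.null(cell$exponential_projection))
            cell$exponential_projection$value else NA_real_,
          skip = cell$skip %||% NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Serialise a bundle's selections to JSON
#'
#' @param bundle An [run_analysis()] result.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_bundle_json <- function(bundle, path) {
  to_plain <- function(cell) {
    if (!is.null(cell$skip)) return(list(skip = cell$skip))
    sel <- cell$selection
    list(
      selected = sel$selected$family,
      rule = sel$selection_rule_applied,
      equivalent_set = sel$equivalent_set,
      fits = lapply(sel$fits, function(f) list(
        family = f$family, params = as.list(f$model$params),
        rss = f$rss, aicc = f$aicc, r2 = f$r2,
        n = f$n, k = f$k, restarts = f$n_restarts_used)),
      capacity = list(method = cell$capacity$method,
                      value = cell$capacity$value,
                      time_to_capacity = cell$capacity$time_to_capacity),
      projection = if (!is.null(cell$exponential_projection))
        cell$exponential_projection$value
    )
  }
  plain <- lapply(bundle$cells, function(dd)
    lapply(dd, function(vv) lapply(vv, to_plain)))
  jsonlite::write_json(list(cells = plain, metadata = bundle$metadata),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Analysis bundle:", length(x$series), "protected series,",
      length(x$control_series), "control series\n")
  print(utils::head(capacity_table(x), 20))
  invisible(x)
}
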