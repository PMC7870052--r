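# Yearly mean +/- SE series per descriptor and response variable.

#' Construct a descriptor series
#'
#' Low-level constructor; most users will call [yearly_series()] or
#' [simulate_series()].
#'
#' @param points Data frame with columns `year`, `t`, `mean`, `se`, `n`.
#' @param descriptor Descriptor identifier.
#' @param variable `"biomass"` or `"density"`.
#' @param area `"protected"` or `"control"`.
#' @param reference_year Year zero of the time axis (protection inception).
#' @return Object of class `descriptor_series` (a data frame of points with
#'   descriptor metadata in attributes).
#' @export
descriptor_series <- function(points, descriptor = "total",
                              variable = c("biomass", "density"),
                              area = c("protected", "control"),
                              reference_year = 1995) {
  variable <- match.arg(variable)
  area <- match.arg(area)
  points <- as.data.frame(points)
  needed <- c("year", "t", "mean", "se", "n")
  missing_cols <- setdiff(needed, names(points))
  if (length(missing_cols) > 0) {
    stop_mpag("series points need column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  points <- points[order(points$year), needed, drop = FALSE]
  if (anyDuplicated(points$year)) stop_mpag("duplicate years in series")
  if (any(points$se < 0, na.rm = TRUE)) stop_mpag("SE must be >= 0")
  if (any(points$t != points$year - reference_year)) {
    stop_mpag("t must equal year - reference_year")
  }
  rownames(points) <- NULL
  structure(points,
            descriptor = descriptor, variable = variable, area = area,
            reference_year = reference_year,
            class = c("descriptor_series", "data.frame"))
}

#' Yearly mean and standard error of transect measures
#'
#' Pools all transects of a year (across sites by default, mirroring a
#' "global yearly mean"), reporting mean, SE (sample SD / sqrt(n)) and the
#' number of transects. Years with no transects are simply absent (the
#' monitoring calendar has gap years). Years with a single transect get
#' SE = 0 and are flagged.
#'
#' @param measures Output of [transect_measures()].
#' @param variable `"biomass"` or `"density"`.
#' @param reference_year Year zero of the time axis; default 1995
#'   (protection inception), so the first survey (1996) is t = 1.
#' @param area Area label stored on the series.
#' @param pooling `"transect"` pools raw transects within the year;
#'   `"site_mean"` averages site means.
#' @return A [descriptor_series()]. Attribute `single_transect_years` lists
#'   years whose SE is 0 because only one transect was surveyed.
#' @export
yearly_series <- function(measures, variable = c("biomass", "density"),
                          reference_year = 1995,
                          area = c("protected", "control"),
                          pooling = c("transect", "site_mean")) {
  variable <- match.arg(variable)
  area <- match.arg(area)
  pooling <- match.arg(pooling)
  if (is.null(measures) || nrow(measures) == 0) stop_mpag("no measures supplied")
  descriptor <- if ("descriptor" %in% names(measures)) {
    as.character(unique(measures$descriptor))[1]
  } else "total"
  y <- measures[[variable]]
  if (pooling == "site_mean") {
    site_means <- stats::aggregate(y, by = list(year = measures$year,
                                                site = measures$site), FUN = mean)
    measures <- data.frame(year = site_means$year, value = site_means$x)
  } else {
    measures <- data.frame(year = measures$year, value = y)
  }
  years <- sort(unique(measures$year))
  pts <- do.call(rbind, lapply(years, function(yr) {
    v <- measures$value[measures$year == yr]
    n <- length(v)
    data.frame(year = yr, t = yr - reference_year, mean = mean(v),
               se = if (n > 1) stats::sd(v) / sqrt(n) else 0, n = n)
  }))
  single <- pts$year[pts$n == 1]
  out <- descriptor_series(pts, descriptor = descriptor,
                           variable = variable, area = area,
                           reference_year = reference_year)
  attr(out, "single_transect_years") <- single
  out
}

#' Number of surveyed years in a series
#'
#' @param series A [descriptor_series()] (or any data frame with a `year`
#'   column).
#' @return Integer count of distinct years.
#' @export
count_survey_years <- function(series) {
  if (is.null(series) || nrow(series) == 0) return(0L)
  length(unique(series$year))
}

#' @export
print.descriptor_series <- function(x, ...) {
  cat("Descriptor series:", attr(x, "descriptor"), attr(x, "variable"),
      paste0("(", attr(x, "area"), "),"), nrow(x), "years",
      if (nrow(x) > 0) paste0(min(x$year), "-", max(x$year)) else "", "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Tidy export of one or more series
#'
#' @param series_list A `descriptor_series` or list of them.
#' @param path Optional CSV path to write to.
#' @return Tidy data frame (descriptor, variable, area, year, t, mean, se, n).
#' @export
series_table <- function(series_list, path = NULL) {
  if (inherits(series_list, "descriptor_series")) series_list <- list(series_list)
  out <- do.call(rbind, lapply(series_list, function(s) {
    cbind(data.frame(descriptor = attr(s, "descriptor"),
                     variable = attr(s, "variable"),
                     area = attr(s, "area"),
                     stringsAsFactors = FALSE),
          as.data.frame(s))
  }))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
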