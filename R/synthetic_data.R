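# Synthetic descriptor series and full transect-level survey datasets
# emulating the belt-transect sampling design.

#' Surveillance-lapse specification for simulations
#'
#' Multiplies expected levels by `factor` within `years`. With
#' `persistent = TRUE` the depression carries forward: growth resumes after
#' the lapse from the depressed level (the trajectory stays at
#' `factor` x trend for all later years), which is how a removal of standing
#' biomass propagates; with `persistent = FALSE` the depression is confined
#' to the lapse years (e.g. a purely observational artefact).
#'
#' @param years Integer vector (or range) of lapse calendar years.
#' @param factor Depression factor in (0, 1].
#' @param persistent Whether the depression carries past the lapse window.
#' @return List of class `lapse_spec`.
#' @export
lapse_spec <- function(years = 2010:2014, factor = 0.3, persistent = TRUE) {
  stopifnot(factor > 0, factor <= 1, length(years) >= 1)
  structure(list(years = as.integer(years), factor = factor,
                 persistent = isTRUE(persistent)),
            class = "lapse_spec")
}

apply_lapse <- function(mu, years, lapse) {
  if (is.null(lapse)) return(mu)
  hit <- if (lapse$persistent) years >= min(lapse$years)
         else years %in% lapse$years
  mu[hit] <- mu[hit] * lapse$factor
  mu
}

#' Simulate a yearly descriptor series from a known growth model
#'
#' Yearly means follow the model curve with multiplicative lognormal noise
#' (the default: positive, right-skewed scatter) or additive Gaussian noise.
#' With more than one transect per year, transect-level values are drawn and
#' the reported mean/SE reflect their scatter. Fully seed-deterministic.
#'
#' @param family,params The generating [growth_model()].
#' @param years Survey calendar (default the 19-year monitoring calendar).
#' @param noise `"lognormal"`, `"gaussian"` or `"none"`.
#' @param sigma Lognormal log-scale SD.
#' @param sd Gaussian SD (response units).
#' @param n_transects Transects simulated per year.
#' @param reference_year Year zero of the time axis.
#' @param lapse Optional [lapse_spec()] depressing expected means.
#' @param seed Integer seed.
#' @param descriptor,variable,area Labels stored on the series.
#' @return A [descriptor_series()]; the generating truth is attached as
#'   attribute `truth`.
#' @export
simulate_series <- function(family, params, years = default_survey_years(),
                            noise = c("lognormal", "gaussian", "none"),
                            sigma = 0.05, sd = 0, n_transects = 1,
                            reference_year = 1995, lapse = NULL, seed = 1L,
                            descriptor = "total",
                            variable = c("biomass", "density"),
                            area = c("protected", "control")) {
  noise <- match.arg(noise)
  variable <- match.arg(variable)
  area <- match.arg(area)
  stopifnot(sigma >= 0, sd >= 0, n_transects >= 1, length(years) >= 1)
  model <- growth_model(family, params)
  years <- sort(unique(as.integer(years)))
  t <- years - reference_year
  mu <- apply_lapse(predict(model, t), years, lapse)
  n_truncated <- 0L
  with_seed(seed, {
    draw <- function(m, size) {
      switch(noise,
        none = rep(m, size),
        lognormal = m * exp(stats::rnorm(size, 0, sigma)),
        gaussian = {
          v <- m + stats::rnorm(size, 0, sd)
          n_truncated <<- n_truncated + sum(v < 0)
          v[v < 0] <- 0
          v
        })
    }
    pts <- do.call(rbind, lapply(seq_along(years), function(i) {
      v <- draw(mu[i], n_transects)
      data.frame(year = years[i], t = t[i], mean = mean(v),
                 se = if (n_transects > 1) stats::sd(v) / sqrt(n_transects) else 0,
                 n = n_transects)
    }))
    if (n_truncated > 0) {
      warning(n_truncated, " negative simulated value(s) truncated at 0",
              call. = FALSE)
    }
    out <- descriptor_series(pts, descriptor = descriptor, variable = variable,
                             area = area, reference_year = reference_year)
    attr(out, "truth") <- list(family = family, params = model$params,
                               noise = noise, sigma = sigma, sd = sd,
                               lapse = lapse, seed = seed)
    out
  })
}

#' Community simulation configuration
#'
#' Defines a full survey-level simulation: per-trophic-group expected
#' density trajectories (individuals 250 m^-2 per transect, as a growth
#' family + parameters), allocated to species proportionally to fixed
#' weights so group totals are exact in expectation; per-species lognormal
#' length distributions binned to 2-cm (5-cm for large-bodied species)
#' classes; and abundance-class encoding under the active scheme.
#'
#' @param traits Trait table (default the packaged 62-species community).
#' @param trajectories Named list: trophic group -> `list(family, params)`
#'   giving the group's expected density per transect over time.
#' @param species_weights Optional named numeric vector of within-group
#'   allocation weights (defaults to equal weights within each group).
#' @param years Survey calendar.
#' @param sites,transects_per_site Sampling effort per year.
#' @param sigma_transect Log-scale SD of transect-to-transect variability
#'   (mean-one lognormal, so expectations are preserved).
#' @param size_meanlog,size_sdlog Default lognormal length distribution
#'   (log-cm); per-species overrides via `size_overrides`, a named list of
#'   `c(meanlog, sdlog)`.
#' @param large_length_cm Species whose median length exceeds this are
#'   recorded in 5-cm classes.
#' @param abundance `"class"` emits nine-class ordinal abundances via
#'   randomised rounding between adjacent class midpoints (unbiased after
#'   decoding); `"count"` emits exact Poisson counts.
#' @param scheme [abundance_scheme()] used for encoding.
#' @param lapse Optional [lapse_spec()]; survey-level lapses default to
#'   within-window-only depression.
#' @param reference_year Year zero of the time axis.
#' @param seed Integer seed.
#' @return List of class `community_sim_config`.
#' @export
community_sim_config <- function(traits = species_traits(),
                                 trajectories,
                                 species_weights = NULL,
                                 years = default_survey_years(),
                                 sites = 3, transects_per_site = 3,
                                 sigma_transect = 0.3,
                                 size_meanlog = log(15), size_sdlog = 0.3,
                                 size_overrides = list(),
                                 large_length_cm = 30,
                                 abundance = c("class", "count"),
                                 scheme = abundance_scheme(),
                                 lapse = NULL,
                                 reference_year = 1995, seed = 1L) {
  abundance <- match.arg(abundance)
  stopifnot(length(trajectories) >= 1)
  bad <- setdiff(names(trajectories), trophic_groups())
  if (length(bad) > 0) stop_mpag("trajectories for unknown group(s): ",
                                 paste(bad, collapse = ", "))
  if (!is.null(lapse) && isTRUE(lapse$persistent)) {
    lapse$persistent <- FALSE  # survey-level lapse is within-window by default
  }
  structure(list(traits = traits, trajectories = trajectories,
                 species_weights = species_weights, years = sort(unique(years)),
                 sites = sites, transects_per_site = transects_per_site,
                 sigma_transect = sigma_transect,
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 size_overrides = size_overrides,
                 large_length_cm = large_length_cm,
                 abundance = abundance, scheme = scheme, lapse = lapse,
                 reference_year = reference_year, seed = as.integer(seed)),
            class = "community_sim_config")
}

# Randomised rounding of a latent expected count onto {absent, class 1..9}
# midpoints: unbiased after midpoint decoding (up to top-class clamping).
encode_latent_class <- function(lambda, scheme) {
  mids <- abundance_midpoint(1:9, scheme)
  vapply(lambda, function(lam) {
    if (lam <= 0) return(NA_integer_)
    if (lam >= mids[9]) return(9L)
    anchors <- c(0, mids)
    j <- findInterval(lam, anchors)  # lam in [anchors[j], anchors[j+1])
    p_up <- (lam - anchors[j]) / (anchors[j + 1] - anchors[j])
    cls <- j - 1L + (stats::runif(1) < p_up)  # class 0 = absent
    if (cls == 0) NA_integer_ else as.integer(cls)
  }, integer(1))
}

#' Simulate a full transect-level survey dataset
#'
#' Draws species sightings per (year, site, transect) whose group-aggregated
#' expected density follows the configured trajectories, encodes counts as
#' abundance classes (or exact counts), and bins visually estimated lengths
#' to 2-cm/5-cm classes. A lapse multiplies the expected group levels within
#' its year window.
#'
#' @param config A [community_sim_config()].
#' @return A [survey_dataset()]; the generating truth is attached as
#'   attribute `truth`.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "community_sim_config"))
  traits <- config$traits
  t_years <- config$years - config$reference_year
  # expected density per group per year (after any lapse)
  group_mu <- lapply(names(config$trajectories), function(g) {
    tr <- config$trajectories[[g]]
    mu <- predict(growth_model(tr$family, tr$params), t_years)
    if (any(mu < 0)) stop_mpag("trajectory for ", g, " is negative at some year")
    apply_lapse(mu, config$years, config$lapse)
  })
  names(group_mu) <- names(config$trajectories)

  # within-group species weights
  weight_for <- function(sp, g) {
    members <- traits$species[traits$trophic_group == g]
    w <- config$species_weights[members]
    if (is.null(config$species_weights) || all(is.na(w))) {
      return(1 / length(members))
    }
    w[is.na(w)] <- 0
    unname(w[sp] / sum(w))
  }

  size_par <- function(sp) {
    ov <- config$size_overrides[[sp]]
    if (!is.null(ov)) c(ov[1], ov[2]) else c(config$size_meanlog, config$size_sdlog)
  }

  rows <- list()
  with_seed(config$seed, {
    for (iy in seq_along(config$years)) {
      yr <- config$years[iy]
      for (si in seq_len(config$sites)) {
        for (tr in seq_len(config$transects_per_site)) {
          for (g in names(group_mu)) {
            members <- traits$species[traits$trophic_group == g]
            for (sp in members) {
              lam0 <- group_mu[[g]][iy] * weight_for(sp, g)
              if (lam0 <= 0) next
              # mean-one lognormal transect effect preserves expectations
              lam <- lam0 * exp(stats::rnorm(1, -config$sigma_transect^2 / 2,
                                             config$sigma_transect))
              sz <- size_par(sp)
              width <- if (exp(sz[1]) > config$large_length_cm) 5 else 2
              len <- stats::rlnorm(1, sz[1], sz[2])
              size_class <- floor(len / width) * width
              if (config$abundance == "class") {
                cls <- encode_latent_class(lam, config$scheme)
                if (is.na(cls)) next
                rows[[length(rows) + 1L]] <- data.frame(
                  year = yr, site = paste0("S", si), transect = paste0("T", tr),
                  species = sp, abundance_class = cls, exact_count = NA_real_,
                  size_class_cm = size_class, size_class_width_cm = width)
              } else {
                cnt <- stats::rpois(1, lam)
                if (cnt == 0) next
                rows[[length(rows) + 1L]] <- data.frame(
                  year = yr, site = paste0("S", si), transect = paste0("T", tr),
                  species = sp, abundance_class = NA_real_, exact_count = cnt,
                  size_class_cm = size_class, size_class_width_cm = width)
              }
            }
          }
        }
      }
    }
  })
  if (length(rows) == 0) stop_mpag("simulation produced no sightings")
  records <- do.call(rbind, rows)
  panel <- expand.grid(transect = paste0("T", seq_len(config$transects_per_site)),
                       site = paste0("S", seq_len(config$sites)),
                       year = config$years, stringsAsFactors = FALSE)
  ds <- survey_dataset(records, traits, transect_area_m2 = 250, panel = panel)
  attr(ds, "truth") <- list(trajectories = config$trajectories,
                            lapse = config$lapse, seed = config$seed,
                            sigma_transect = config$sigma_transect)
  ds
}
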