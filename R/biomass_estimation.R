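# Sightings -> per-transect density (ind. 250 m^-2) and biomass (g 250 m^-2).

#' Abundance-class scheme
#'
#' The nine ordinal abundance classes used to record shoal sizes during the
#' censuses. The default bounds (1; 2-5; 6-10; 11-30; 31-50; 51-100;
#' 101-200; 201-500; 501-1000) are a conventional geometric-like ladder; the
#' scheme is fully configurable since the original class limits are held in
#' field-protocol literature rather than in the data themselves.
#'
#' @param bounds List of 9 integer `c(low, high)` ranges, contiguous,
#'   non-overlapping and ascending, with class 1 starting at >= 1.
#' @param midpoint_rule `"arithmetic"` ((low+high)/2) or `"geometric"`
#'   (sqrt(low*high)).
#' @return Object of class `abundance_scheme`.
#' @export
abundance_scheme <- function(bounds = list(c(1, 1), c(2, 5), c(6, 10),
                                           c(11, 30), c(31, 50), c(51, 100),
                                           c(101, 200), c(201, 500),
                                           c(501, 1000)),
                             midpoint_rule = c("arithmetic", "geometric")) {
  midpoint_rule <- match.arg(midpoint_rule)
  if (length(bounds) != 9) stop_mpag("an abundance scheme has exactly 9 classes")
  lows <- vapply(bounds, `[`, numeric(1), 1)
  highs <- vapply(bounds, `[`, numeric(1), 2)
  if (lows[1] < 1) stop_mpag("class 1 must start at 1 or above")
  if (any(highs < lows)) stop_mpag("each class needs low <= high")
  if (any(lows[-1] != highs[-9] + 1)) {
    stop_mpag("classes must be contiguous, non-overlapping and ascending")
  }
  structure(list(low = lows, high = highs, midpoint_rule = midpoint_rule),
            class = "abundance_scheme")
}

#' Midpoint count for an abundance class
#'
#' @param class_index Integer vector of class indices in 1..9.
#' @param scheme An [abundance_scheme()].
#' @return Numeric vector of representative individual counts.
#' @export
abundance_midpoint <- function(class_index, scheme = abundance_scheme()) {
  if (any(is.na(class_index)) || any(class_index < 1 | class_index > 9) ||
      any(class_index != round(class_index))) {
    stop_mpag("abundance class index must be an integer in 1..9")
  }
  low <- scheme$low[class_index]
  high <- scheme$high[class_index]
  if (scheme$midpoint_rule == "arithmetic") (low + high) / 2 else sqrt(low * high)
}

# Class whose range contains the count; counts above the top range clamp to 9.
abundance_class_for_count <- function(count, scheme = abundance_scheme()) {
  vapply(count, function(k) {
    if (k < scheme$low[1]) return(NA_integer_)
    i <- which(k >= scheme$low & k <= scheme$high)
    if (length(i) == 0) 9L else as.integer(i)
  }, integer(1))
}

#' Midpoint length of a visual size class
#'
#' @param size_class_cm Lower bound of the length class (cm).
#' @param width Class width in cm, 2 or 5.
#' @return Midpoint length in cm.
#' @export
size_midpoint <- function(size_class_cm, width) {
  if (any(!width %in% c(2, 5))) stop_mpag("size class width must be 2 or 5 cm")
  if (any(size_class_cm < 0)) stop_mpag("size class lower bound must be >= 0")
  size_class_cm + width / 2
}

#' Individual weight from total length
#'
#' Allometric length-weight conversion W = a L^b.
#'
#' @param length_cm Total length (cm), >= 0.
#' @param a Coefficient (g cm^-b), > 0.
#' @param b Exponent, > 0.
#' @return Weight in grams.
#' @export
individual_weight <- function(length_cm, a, b) {
  if (any(length_cm < 0)) stop_mpag("length must be non-negative")
  if (any(a <= 0) || any(b <= 0)) stop_mpag("length-weight coefficients must be positive")
  a * length_cm^b
}

# Descriptor name -> species subset of a trait table.
# Accepted: "total", "total_reduced", a trophic group, or "<GROUP>_reduced".
descriptor_species <- function(descriptor, traits) {
  reduced <- grepl("_reduced$", descriptor)
  base <- sub("_reduced$", "", descriptor)
  if (base == "total") {
    keep <- rep(TRUE, nrow(traits))
  } else if (base %in% trophic_groups()) {
    keep <- traits$trophic_group == base
  } else {
    stop_mpag("unknown descriptor '", descriptor, "'; use 'total', one of ",
              paste(trophic_groups(), collapse = "/"),
              ", or their '_reduced' variants")
  }
  if (reduced) keep <- keep & !traits$pelagic
  traits$species[keep]
}

#' All default descriptor names
#'
#' Total, total excluding pelagics, the seven trophic groups, and the
#' piscivore group excluding pelagics (the one reduced trophic descriptor
#' analysed by default).
#'
#' @return Character vector of descriptor identifiers.
#' @export
default_descriptors <- function() {
  c("total", "total_reduced", trophic_groups(), "PISC_reduced")
}

#' Per-transect density and biomass for a descriptor
#'
#' For every surveyed (year, site, transect) in the dataset, sums individual
#' counts (exact counts, or class midpoints under `scheme`) and biomass
#' (count x W(length midpoint)) over the sightings of the descriptor's
#' species, normalised to 250 m^2. Transects with no matching sightings
#' contribute explicit zeros, so yearly means are taken over the full
#' transect panel.
#'
#' @param dataset A [survey_dataset()].
#' @param descriptor Descriptor identifier (see [default_descriptors()]).
#' @param scheme An [abundance_scheme()].
#' @return Data frame with columns `year`, `site`, `transect`, `descriptor`,
#'   `density` (individuals 250 m^-2) and `biomass` (g 250 m^-2).
#' @export
transect_measures <- function(dataset, descriptor,
                              scheme = abundance_scheme()) {
  stopifnot(inherits(dataset, "survey_dataset"))
  species <- descriptor_species(descriptor, dataset$traits)
  rec <- dataset$records
  panel <- dataset$panel

  sub <- rec[rec$species %in% species, , drop = FALSE]
  area_factor <- 250 / dataset$transect_area_m2
  if (nrow(sub) > 0) {
    counts <- sub$exact_count
    from_class <- is.na(counts)
    counts[from_class] <- abundance_midpoint(sub$abundance_class[from_class],
                                             scheme)
    tr <- dataset$traits[match(sub$species, dataset$traits$species), ]
    lengths <- size_midpoint(sub$size_class_cm, sub$size_class_width_cm)
    weights <- individual_weight(lengths, tr$lw_a, tr$lw_b)
    key <- interaction(sub$year, sub$site, sub$transect, drop = FALSE)
    dens <- tapply(counts, key, sum)
    biom <- tapply(counts * weights, key, sum)
    panel_key <- interaction(panel$year, panel$site, panel$transect)
    panel$density <- as.numeric(dens[match(as.character(panel_key), names(dens))])
    panel$biomass <- as.numeric(biom[match(as.character(panel_key), names(biom))])
    panel$density[is.na(panel$density)] <- 0
    panel$biomass[is.na(panel$biomass)] <- 0
  } else {
    panel$density <- 0
    panel$biomass <- 0
  }
  panel$density <- panel$density * area_factor
  panel$biomass <- panel$biomass * area_factor
  panel$descriptor <- descriptor
  rownames(panel) <- NULL
  panel[, c("year", "site", "transect", "descriptor", "density", "biomass")]
}
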