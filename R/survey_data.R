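# UVC survey records, species traits, and their tabular I/O.

sighting_fields <- c("year", "site", "transect", "species",
                     "abundance_class", "exact_count",
                     "size_class_cm", "size_class_width_cm")

#' Validate a table of UVC sighting records
#'
#' One row per observation: a species seen on a belt transect in a given
#' year, with either one of nine ordinal abundance classes or an exact count
#' (exactly one of the two per row), and the lower bound of its visual length
#' class (2-cm classes; 5-cm for large-bodied species).
#'
#' @param records Data frame with columns `year`, `site`, `transect`,
#'   `species`, `size_class_cm`, `size_class_width_cm` and at least one of
#'   `abundance_class` / `exact_count` (the other may be `NA` per row).
#' @param study_years Optional integer range; years outside it are an error.
#' @return The validated data frame with both abundance columns present
#'   (`NA` where absent).
#' @export
validate_sightings <- function(records, study_years = NULL) {
  records <- as.data.frame(records)
  if (!"abundance_class" %in% names(records)) records$abundance_class <- NA_real_
  if (!"exact_count" %in% names(records)) records$exact_count <- NA_real_
  missing_cols <- setdiff(sighting_fields, names(records))
  if (length(missing_cols) > 0) {
    stop_mpag("sightings table is missing mandatory column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  records <- records[, sighting_fields]
  has_class <- !is.na(records$abundance_class)
  has_count <- !is.na(records$exact_count)
  both <- which(has_class & has_count)
  if (length(both) > 0) {
    stop_mpag("rows ", paste(utils::head(both, 5), collapse = ", "),
              ": both abundance_class and exact_count present; exactly one is allowed")
  }
  neither <- which(!has_class & !has_count)
  if (length(neither) > 0) {
    stop_mpag("rows ", paste(utils::head(neither, 5), collapse = ", "),
              ": neither abundance_class nor exact_count present")
  }
  bad_class <- which(has_class &
                       (records$abundance_class < 1 | records$abundance_class > 9 |
                          records$abundance_class != round(records$abundance_class)))
  if (length(bad_class) > 0) {
    stop_mpag("rows ", paste(utils::head(bad_class, 5), collapse = ", "),
              ": abundance_class must be an integer in 1..9 (got ",
              records$abundance_class[bad_class[1]], ")")
  }
  bad_count <- which(has_count & records$exact_count < 0)
  if (length(bad_count) > 0) {
    stop_mpag("rows ", paste(utils::head(bad_count, 5), collapse = ", "),
              ": exact_count must be non-negative")
  }
  bad_width <- which(!records$size_class_width_cm %in% c(2, 5))
  if (length(bad_width) > 0) {
    stop_mpag("rows ", paste(utils::head(bad_width, 5), collapse = ", "),
              ": size_class_width_cm must be 2 or 5")
  }
  if (any(records$size_class_cm < 0, na.rm = TRUE)) {
    stop_mpag("size_class_cm must be non-negative")
  }
  if (!is.null(study_years)) {
    bad_year <- which(!records$year %in% study_years)
    if (length(bad_year) > 0) {
      stop_mpag("rows ", paste(utils::head(bad_year, 5), collapse = ", "),
                ": year outside the configured study range")
    }
  }
  records
}

#' Read UVC sightings from a delimited text file
#'
#' @param path CSV file with a header row.
#' @param col_map Optional named character vector mapping standard field
#'   names (see [validate_sightings()]) to the file's column names, so other
#'   dialects plug in, e.g. `c(species = "taxon")`.
#' @param study_years Optional permitted year range.
#' @return Validated sightings data frame.
#' @export
read_sightings <- function(path, col_map = NULL, study_years = NULL) {
  if (!file.exists(path)) stop_mpag("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(raw)) {
        stop_mpag("column mapping refers to absent column '", src, "'")
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  validate_sightings(raw, study_years = study_years)
}

#' Write sightings back to CSV
#'
#' @param records Validated sightings data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sightings <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a species trait table
#'
#' Expects columns `species`, `trophic_group` (one of the seven labels),
#' `pelagic` (logical) and `present_at_control` (logical; whether the
#' species also occurs at the unprotected reference area). Length-weight
#' coefficients may be supplied as columns `lw_a`/`lw_b` or merged in from a
#' separate coefficient table; species without coefficients fall back to the
#' isometric default W = 0.01 L^3 with a warning.
#'
#' @param path CSV trait table.
#' @param lw_path Optional CSV with columns `species`, `lw_a`, `lw_b`.
#' @param default_a,default_b Fallback length-weight coefficients
#'   (g cm^-b and dimensionless).
#' @return Data frame keyed by `species` with columns `species`,
#'   `trophic_group`, `pelagic`, `present_at_control`, `lw_a`, `lw_b`.
#' @export
read_traits <- function(path, lw_path = NULL, default_a = 0.01, default_b = 3.0) {
  if (!file.exists(path)) stop_mpag("no such file: ", path)
  traits <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "trophic_group", "pelagic", "present_at_control")
  missing_cols <- setdiff(needed, names(traits))
  if (length(missing_cols) > 0) {
    stop_mpag("trait table is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  dup <- traits$species[duplicated(traits$species)]
  if (length(dup) > 0) {
    stop_mpag("duplicate species in trait table: ",
              paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(traits$trophic_group), trophic_groups())
  if (length(bad) > 0) {
    stop_mpag("unknown trophic group label(s): ", paste(bad, collapse = ", "),
              "; valid labels are ", paste(trophic_groups(), collapse = ", "))
  }
  traits$pelagic <- as.logical(traits$pelagic)
  traits$present_at_control <- as.logical(traits$present_at_control)
  if (!is.null(lw_path)) {
    lw <- utils::read.csv(lw_path, stringsAsFactors = FALSE)
    traits <- merge(traits, lw[, c("species", "lw_a", "lw_b")],
                    by = "species", all.x = TRUE, sort = FALSE)
  }
  if (!"lw_a" %in% names(traits)) traits$lw_a <- NA_real_
  if (!"lw_b" %in% names(traits)) traits$lw_b <- NA_real_
  n_default <- sum(is.na(traits$lw_a) | is.na(traits$lw_b))
  if (n_default > 0) {
    warning(n_default, " species without length-weight coefficients; ",
            "using default a = ", default_a, ", b = ", default_b, call. = FALSE)
    traits$lw_a[is.na(traits$lw_a)] <- default_a
    traits$lw_b[is.na(traits$lw_b)] <- default_b
  }
  if (any(traits$lw_a <= 0) || any(traits$lw_b <= 0)) {
    stop_mpag("length-weight coefficients must be positive")
  }
  rownames(traits) <- NULL
  traits
}

#' The packaged reference community trait table
#'
#' The 62-species fish assemblage of the Cabo de Palos-Islas Hormigas MPA
#' (SW Mediterranean), with trophic group, pelagic flag and presence at the
#' Cabo Cope unprotected reference area. Length-weight coefficients default
#' to the isometric fallback unless a coefficient table is supplied.
#'
#' @inheritParams read_traits
#' @return Trait data frame (see [read_traits()]).
#' @export
species_traits <- function(lw_path = NULL, default_a = 0.01, default_b = 3.0) {
  path <- system.file("extdata", "community_traits.csv", package = "mpagrowth")
  suppressWarnings(
    read_traits(path, lw_path = lw_path,
                default_a = default_a, default_b = default_b)
  )
}

#' Community composition by trophic group
#'
#' Species counts and percentages per trophic group; all seven groups are
#' reported, with zero for groups absent from the table. Percentages are
#' rounded to one decimal.
#'
#' @param traits Trait data frame (see [read_traits()]).
#' @return Data frame with columns `trophic_group`, `n_species`, `percent`.
#' @export
composition_summary <- function(traits) {
  if (is.null(traits) || nrow(traits) == 0) {
    stop_mpag("empty trait table")
  }
  counts <- table(factor(traits$trophic_group, levels = trophic_groups()))
  n <- as.integer(counts)
  data.frame(
    trophic_group = trophic_groups(),
    n_species = n,
    percent = round(100 * n / sum(n), 1),
    stringsAsFactors = FALSE
  )
}

#' Assemble a survey dataset
#'
#' Binds validated sightings to a trait table and the transect area. Every
#' species appearing in the records must be present in the traits; unknown
#' species are reported by name rather than silently dropped.
#'
#' @param records Validated sightings data frame.
#' @param traits Trait data frame.
#' @param transect_area_m2 Sampled area per belt transect (50 x 5 m
#'   transects give the default 250).
#' @param panel Optional data frame of all surveyed (year, site, transect)
#'   combinations. Defaults to those appearing in `records`; supplying it
#'   explicitly lets transects with no sightings at all contribute zeros.
#' @return Object of class `survey_dataset`.
#' @export
survey_dataset <- function(records, traits, transect_area_m2 = 250,
                           panel = NULL) {
  records <- validate_sightings(records)
  if (!is.numeric(transect_area_m2) || transect_area_m2 <= 0) {
    stop_mpag("transect_area_m2 must be positive")
  }
  unknown <- setdiff(unique(records$species), traits$species)
  if (length(unknown) > 0) {
    stop_mpag("species in records but absent from trait table: ",
              paste(unknown, collapse = ", "))
  }
  if (is.null(panel)) {
    panel <- unique(records[, c("year", "site", "transect")])
  } else {
    panel <- unique(as.data.frame(panel)[, c("year", "site", "transect")])
  }
  panel <- panel[order(panel$year, panel$site, panel$transect), , drop = FALSE]
  rownames(panel) <- NULL
  structure(
    list(records = records, traits = traits,
         transect_area_m2 = transect_area_m2, panel = panel),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("UVC survey dataset:", nrow(x$records), "sightings,",
      length(unique(x$records$species)), "species,",
      length(unique(x$records$year)), "years;",
      "transect area", x$transect_area_m2, "m2\n")
  invisible(x)
}
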