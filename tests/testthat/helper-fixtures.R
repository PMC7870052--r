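# In-code fixtures shared across test files.

# Minimal trait table covering a handful of species across groups.
toy_traits <- function() {
  data.frame(
    species = c("pisc_pel", "pisc_dem", "macro_dem", "plan_pel", "herb_dem"),
    trophic_group = c("PISC", "PISC", "MACRO", "PLAN", "HERB"),
    pelagic = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    present_at_control = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    lw_a = 0.01, lw_b = 3.0,
    stringsAsFactors = FALSE
  )
}

# One-call sighting row with sensible defaults.
sighting <- function(year = 2000, site = "S1", transect = "T1",
                     species = "pisc_dem", abundance_class = 1,
                     exact_count = NA_real_, size_class_cm = 20,
                     size_class_width_cm = 2) {
  data.frame(year = year, site = site, transect = transect, species = species,
             abundance_class = abundance_class, exact_count = exact_count,
             size_class_cm = size_class_cm,
             size_class_width_cm = size_class_width_cm,
             stringsAsFactors = FALSE)
}

toy_dataset <- function(records) {
  survey_dataset(records, toy_traits())
}

# A tiny noiseless series data frame for fitting tests.
series_points <- function(t, y) data.frame(t = t, mean = y)

# Fast fitting options for Monte-Carlo loops: the rule-based start almost
# always converges, so few restarts are needed.
fast_control <- function() fit_control(max_restarts = 20, converged_target = 1)
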