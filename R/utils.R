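#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mpag <- function(..., call. = FALSE) stop(..., call. = call.)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' The seven trophic-group labels
#'
#' Diet-based species classes used to aggregate the fish assemblage:
#' piscivores (PISC), macro-invertivores (MACRO), micro-invertivores (MICRO),
#' omnivores (OMNI), herbivores (HERB), planktivores (PLAN) and
#' detritivores (DETR).
#'
#' @return Character vector of the seven labels, in conventional order.
#' @export
trophic_groups <- function() {
  c("PISC", "MACRO", "MICRO", "OMNI", "HERB", "PLAN", "DETR")
}

#' Default survey calendar
#'
#' Annual monitoring years of the protected area: 1996--2018 with no surveys
#' in 1999, 2001, 2011 and 2012, i.e. 19 surveyed years over the 23-year
#' study window.
#'
#' @return Integer vector of surveyed calendar years.
#' @export
default_survey_years <- function() {
  setdiff(1996:2018, c(1999, 2001, 2011, 2012))
}
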