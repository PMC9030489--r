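#' Factor levels of the working-posture factorial design
#'
#' The study design crosses three within-subject factors: working posture
#' (`WP`, six levels P1--P6), surface slope (`SS`, flat vs. inclined) and load
#' carriage (`LC`, 0 kg vs. 10 kg in hands).
#'
#' @name design-levels
#' @keywords internal
NULL

wp_levels <- function() paste0("P", 1:6)
ss_levels <- function() c("flat", "inclined")
lc_levels <- function() c("0kg", "10kg")

#' Default sensor placements
#'
#' The eight body segments used for stability assessment: pelvis, sternum
#' (T8), both shoulders, both upper legs and both lower legs.
#'
#' @return Character vector of the eight placement names.
#' @export
default_sensors <- function() {
  c("pelvis", "T8", "shoulder_L", "shoulder_R",
    "upper_leg_L", "upper_leg_R", "lower_leg_L", "lower_leg_R")
}

#' Enumerate all experimental conditions
#'
#' Returns the full factorial of working posture x surface slope x load
#' carriage (6 x 2 x 2 = 24 conditions) in a deterministic order:
#' posture-major, then surface, then load (load varies fastest).
#'
#' @return A data frame with 24 rows and factor columns `posture`, `surface`,
#'   `load`.
#' @examples
#' head(enumerate_conditions())
#' @export
enumerate_conditions <- function() {
  g <- expand.grid(load = lc_levels(), surface = ss_levels(),
                   posture = wp_levels(), stringsAsFactors = FALSE)
  data.frame(
    posture = factor(g$posture, levels = wp_levels()),
    surface = factor(g$surface, levels = ss_levels()),
    load    = factor(g$load, levels = lc_levels())
  )
}
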