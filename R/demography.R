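#' Road-adjusted annual survival of a breeding female
#'
#' When the transportation-mortality mechanism is active, a breeding female
#' whose territory intersects a primary road or the railway has her annual
#' survival reduced from 0.9 to 0.297; if it intersects only a secondary
#' road, to 0.81. When both classes intersect her territory the larger
#' reduction (primary) applies. The test is the presence of a road cell
#' inside the territory, not an encounter process.
#'
#' @param territory_cells integer cell indices of the female's territory
#'   (into the road-class matrix), or `NULL` with `has_primary`/
#'   `has_secondary` given directly.
#' @param roads a [road_layer()] (needed when `territory_cells` is given).
#' @param mechanism_on is the mortality mechanism active?
#' @param params a [tiger_params()].
#' @param has_primary,has_secondary logical shortcut instead of
#'   `territory_cells`.
#' @return Annual survival probability.
#' @examples
#' p <- tiger_params()
#' road_adjusted_annual_survival(has_primary = TRUE, mechanism_on = TRUE)   # 0.297
#' road_adjusted_annual_survival(has_secondary = TRUE, mechanism_on = TRUE) # 0.81
#' @export
road_adjusted_annual_survival <- function(territory_cells = NULL, roads = NULL,
                                          mechanism_on = TRUE,
                                          params = tiger_params(),
                                          has_primary = FALSE,
                                          has_secondary = FALSE) {
  if (!is.null(territory_cells)) {
    cls <- roads$classes[territory_cells]
    has_primary <- any(cls == 2L)
    has_secondary <- any(cls == 1L)
  }
  base <- params$survival[["breeding_female"]]
  if (!mechanism_on) return(base)
  if (has_primary) return(params$survival_primary_road)
  if (has_secondary) return(params$survival_secondary_road)
  base
}

#' Convert an annual survival rate to a monthly one
#'
#' The model steps monthly while the literature reports annual rates; the
#' twelfth root preserves the compounded annual survival exactly.
#'
#' @param annual annual survival in [0, 1].
#' @return Monthly survival probability.
#' @examples
#' monthly_survival(0.9)^12 # 0.9
#' @export
monthly_survival <- function(annual) {
  if (any(annual < 0)) stop("annual survival cannot be negative")
  annual^(1 / 12)
}

#' Resolve a challenge between a dispersing and a resident male
#'
#' The challenger wins with probability `w(c) / (w(c) + w(i))` where `w` is
#' an age-based strength weight ([challenge_weight()]). On a win, all of the
#' incumbent's females transfer to the challenger; each dependent cub of
#' those females dies by infanticide with probability 0.79 and each juvenile
#' with 0.24; the incumbent dies with probability 0.6, otherwise he becomes a
#' dispersing male. On a loss, the challenger dies with probability 0.25,
#' otherwise he keeps dispersing.
#'
#' @param challenger_age,incumbent_age ages in months.
#' @param n_cubs,n_juveniles dependent offspring of the incumbent's females,
#'   exposed to infanticide if the challenger wins.
#' @param params a [tiger_params()].
#' @return List: `challenger_wins`, `challenger_dies`, `incumbent_dies`,
#'   `cub_killed` and `juvenile_killed` (logical vectors of length
#'   `n_cubs`/`n_juveniles`).
#' @export
resolve_challenge <- function(challenger_age, incumbent_age,
                              n_cubs = 0, n_juveniles = 0,
                              params = tiger_params()) {
  wc <- challenge_weight(challenger_age)
  wi <- challenge_weight(incumbent_age)
  wins <- stats::runif(1) < wc / (wc + wi)
  out <- list(challenger_wins = wins, challenger_dies = FALSE,
              incumbent_dies = FALSE,
              cub_killed = logical(n_cubs), juvenile_killed = logical(n_juveniles))
  if (wins) {
    out$incumbent_dies <- stats::runif(1) < params$challenge_death_incumbent
    if (n_cubs) out$cub_killed <- stats::runif(n_cubs) < params$infanticide_cub
    if (n_juveniles) out$juvenile_killed <- stats::runif(n_juveniles) < params$infanticide_juvenile
  } else {
    out$challenger_dies <- stats::runif(1) < params$challenge_death_challenger
  }
  out
}

#' Age-based challenge strength
#'
#' A triangular prime-age curve: strength 1 at 3 years, rising linearly to 2
#' at 5 years, flat through 9 years, declining to 1 at 12+ years. Males of
#' equal age therefore win a challenge with probability 0.5.
#'
#' @param age_months age in months.
#' @return Numeric strength weight(s).
#' @export
challenge_weight <- function(age_months) {
  y <- age_months / 12
  pmax(1, pmin(1 + (y - 3) / 2, 2, 2 - (y - 9) / 3))
}
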