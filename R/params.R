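#' Model parameter bundle
#'
#' Returns the full set of demographic and behavioural parameters used by the
#' simulator, with defaults taken from long-term field studies of tigers in
#' Chitwan National Park and related large-carnivore literature. Every
#' parameter of the model lives here; pass overrides as named arguments.
#'
#' Key groups:
#' \itemize{
#'   \item Litter size distribution over 1..5 cubs (`litter_size_pmf`,
#'     probabilities 0, 0.23, 0.58, 0.17, 0.02) and a 50:50 birth sex ratio.
#'   \item Annual survival by class: breeding male 0.8, breeding (settled)
#'     female 0.9, dispersing/transient male 0.65, transient female 0.7,
#'     juvenile 0.9, cub 0.6. The model steps monthly; annual rates are
#'     converted with [monthly_survival()].
#'   \item Road-effect survival: a breeding female whose territory intersects
#'     a primary road or railway has annual survival `survival_primary_road`
#'     (0.297); intersecting only a secondary road gives
#'     `survival_secondary_road` (0.81).
#'   \item Territory economics: per-cell prey production is cropped at
#'     `utilization_fraction` (0.1); acquisition continues until utilised
#'     prey meets `prey_min` (76 kg/month, the basal metabolic requirement);
#'     `prey_max` (167.3 kg/month) is the never-exceeded intake ceiling from
#'     field consumption rates; at most `max_cells_per_step` (48 cells,
#'     3 km^2) are annexed per month, territories are bounded at
#'     `max_territory_cells` (1500 cells, ~94 km^2), and a dominant (older)
#'     female takes a contested patch with probability
#'     `patch_takeover_prob` (0.25). A female below the requirement whose
#'     territory can no longer grow starves after `starvation_months`
#'     consecutive shortfall months, with a `settle_grace_months` grace
#'     after settling.
#'   \item Dispersal and settlement: natal dispersal caps 66 km (males) and
#'     33 km (females); a dispersing female prospects `settlement_samples`
#'     candidate sites per month for at most `female_search_months`;
#'     settlement requires no other female territory within 2 km (ideal) or
#'     1 km (relaxed); males search a 3 km radius and hold at most 6 female
#'     territories.
#'   \item Reproduction: annual breeding probability 0.9 at age 3, 1.0 at 4+;
#'     gestation 3 or 4 months with equal probability.
#'   \item Male challenges: losing challenger dies with probability 0.25,
#'     losing incumbent with 0.6; after a takeover, infanticide kills cubs
#'     with probability 0.79 and juveniles with 0.24.
#'   \item Prey depletion zone: multiplier rises linearly from 0 on the road
#'     to 1 at `depletion_dist_primary` (5000 m) or
#'     `depletion_dist_secondary` (2000 m).
#' }
#'
#' @param ... named overrides of any default listed above.
#' @return A named list of class `tiger_params`.
#' @examples
#' p <- tiger_params()
#' p$survival["breeding_female"]
#' tiger_params(starvation_months = 2)$starvation_months
#' @export
tiger_params <- function(...) {
  p <- list(
    litter_size_pmf = c(`1` = 0, `2` = 0.23, `3` = 0.58, `4` = 0.17, `5` = 0.02),
    sex_ratio = 0.5,
    survival = c(
      breeding_male   = 0.8,
      breeding_female = 0.9,
      dispersing_male = 0.65,
      transient_male  = 0.65,
      transient_female = 0.7,
      juvenile        = 0.9,
      cub             = 0.6
    ),
    survival_primary_road = 0.297,
    survival_secondary_road = 0.81,
    fecundity_age3 = 0.9,
    fecundity_age4plus = 1.0,
    max_dispersal_m = c(male = 66000, female = 33000),
    prey_min = 76,
    prey_max = 167.3,
    utilization_fraction = 0.1,
    max_cells_per_step = 48L,
    max_territory_cells = 1500L,
    patch_takeover_prob = 0.25,
    male_search_radius_m = 3000,
    max_females_per_male = 6L,
    settle_radius_ideal_m = 2000,
    settle_radius_relaxed_m = 1000,
    settle_prey_radius_m = 1000,
    challenge_death_challenger = 0.25,
    challenge_death_incumbent = 0.6,
    infanticide_cub = 0.79,
    infanticide_juvenile = 0.24,
    gestation_months = c(3L, 4L),
    depletion_dist_primary = 5000,
    depletion_dist_secondary = 2000,
    starvation_months = 3L,
    settle_grace_months = 6L,
    female_search_months = 12L,
    settlement_samples = 12L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(abs(sum(p$litter_size_pmf) - 1) < 1e-12, p$prey_min < p$prey_max)
  structure(p, class = "tiger_params")
}

#' @export
print.tiger_params <- function(x, ...) {
  cat("<tiger_params>\n")
  cat("  annual survival:", paste(names(x$survival), x$survival, collapse = ", "), "\n")
  cat("  road survival: primary", x$survival_primary_road,
      "secondary", x$survival_secondary_road, "\n")
  cat("  prey thresholds:", x$prey_min, "-", x$prey_max,
      "kg/month at utilization", x$utilization_fraction, "\n")
  invisible(x)
}
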