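#' Life-cycle stage for an age in months
#'
#' Stages are a deterministic function of age: cub (0-11 months), juvenile
#' (12-23), transient (24-35), breeding (36+). Tigers enter the breeding
#' stage, and with it the dispersal pool, exactly at 36 months.
#'
#' @param age_months integer vector of ages in months.
#' @return Character vector: `"cub"`, `"juvenile"`, `"transient"` or
#'   `"breeding"`.
#' @examples
#' stage_of_age(c(11, 12, 23, 24, 35, 36))
#' @export
stage_of_age <- function(age_months) {
  cut_idx <- findInterval(age_months, c(12, 24, 36)) + 1L
  c("cub", "juvenile", "transient", "breeding")[cut_idx]
}

#' Advance a tiger's age by one month
#'
#' Increments age and recomputes the stage, applying the 12/24/36 month
#' boundaries exactly.
#'
#' @param tiger a list (or one-row data frame) with at least `age` (months);
#'   `stage` is recomputed.
#' @return The tiger with `age + 1` and updated `stage`.
#' @export
advance_age <- function(tiger) {
  tiger$age <- tiger$age + 1L
  tiger$stage <- stage_of_age(tiger$age)
  tiger
}

#' Sample litters
#'
#' Litter sizes are drawn from the empirical Chitwan distribution
#' (2:0.23, 3:0.58, 4:0.17, 5:0.02; singletons do not occur) and each cub's
#' sex is an independent fair draw.
#'
#' @param n number of litters.
#' @param params a [tiger_params()].
#' @return A list with integer vector `size` (length `n`) and a list `sexes`
#'   of character vectors (`"F"`/`"M"`).
#' @export
sample_litter <- function(n = 1, params = tiger_params()) {
  size <- sample(1:5, n, replace = TRUE, prob = params$litter_size_pmf)
  sexes <- lapply(size, function(s)
    ifelse(stats::runif(s) < params$sex_ratio, "F", "M"))
  list(size = size, sexes = sexes)
}

#' Sample gestation lengths
#'
#' Gestation (about 103 days in the field) is modelled as 3 or 4 months with
#' equal probability.
#'
#' @param n number of draws.
#' @param params a [tiger_params()].
#' @return Integer vector of gestation lengths in months.
#' @export
draw_gestation <- function(n = 1, params = tiger_params()) {
  params$gestation_months[sample.int(length(params$gestation_months), n, replace = TRUE)]
}

#' Monthly conception hazard for a resident female
#'
#' The annual breeding probability (0.9 for 3-year-olds, 1.0 for 4+) is
#' converted to a per-eligible-month hazard `1 - (1 - p)^(1/12)`; an annual
#' probability of 1 makes conception certain in any eligible month.
#'
#' @param age_months female age in months (>= 36).
#' @param params a [tiger_params()].
#' @return Monthly conception probability.
#' @export
conception_hazard <- function(age_months, params = tiger_params()) {
  p <- ifelse(age_months >= 48, params$fecundity_age4plus, params$fecundity_age3)
  1 - (1 - p)^(1 / 12)
}
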