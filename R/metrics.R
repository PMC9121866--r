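#' Per-step population summary across replicates
#'
#' Mean and 95% confidence interval (quantiles of the t-distribution,
#' `mean +/- t[0.975, n-1] * sd / sqrt(n)`) of the monthly counts of adult
#' tigers (36+ months), breeding (territory-holding) females, and dependent
#' offspring, across replicate runs.
#'
#' @param records list of [run_scenario()] records.
#' @return Data frame: `step`, `group`, `mean`, `lo`, `hi`, `n`. With a
#'   single replicate the CI columns are `NA`.
#' @export
population_summary <- function(records) {
  groups <- c("adults", "breeding_females", "dependents")
  nrep <- length(records)
  steps <- records[[1]]$counts$step
  out <- list()
  for (g in groups) {
    m <- vapply(records, function(r) r$counts[[g]], numeric(length(steps)))
    m <- matrix(m, nrow = length(steps))
    mu <- rowMeans(m)
    if (nrep >= 2) {
      sd <- apply(m, 1, stats::sd)
      hw <- stats::qt(0.975, nrep - 1) * sd / sqrt(nrep)
    } else {
      hw <- rep(NA_real_, length(steps))
    }
    out[[g]] <- data.frame(step = steps, group = g, mean = mu,
                           lo = mu - hw, hi = mu + hw, n = nrep)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Proportion of mortality attributed to roads
#'
#' For each experiment month, the proportion of all deaths whose recorded
#' territory-road intersection is non-none (females that died while their
#' territory intersected a road, plus their dependent offspring, tagged with
#' the mother's intersection), by road class and combined. Monthly
#' proportions are averaged within each simulation year; months with no
#' deaths are excluded from the annual average. Replicate means and
#' standard errors are returned.
#'
#' @param records list of [run_scenario()] records.
#' @return Data frame: `year`, `class` (`"primary"`, `"secondary"`,
#'   `"any"`), `mean`, `se`.
#' @export
road_mortality_proportion <- function(records) {
  burn_in <- records[[1]]$burn_in
  nyears <- records[[1]]$experiment %/% 12
  per_rep <- lapply(records, function(r) {
    d <- r$deaths[r$deaths$step > burn_in, , drop = FALSE]
    mo <- d$step - burn_in
    vapply(c(primary = "primary", secondary = "secondary", any = "any"),
           function(cl) {
      hit <- if (cl == "any") d$road != "none" else d$road == cl
      monthly <- vapply(seq_len(nyears * 12), function(m) {
        in_m <- mo == m
        if (!any(in_m)) return(NA_real_)
        mean(hit[in_m])
      }, numeric(1))
      vapply(seq_len(nyears), function(y) {
        v <- monthly[((y - 1) * 12 + 1):(y * 12)]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, numeric(1))
    }, numeric(nyears))
  })
  per_rep <- lapply(per_rep, function(x) matrix(x, nrow = nyears,
                                                dimnames = list(NULL, c("primary", "secondary", "any"))))
  out <- list()
  for (cl in c("primary", "secondary", "any")) {
    m <- vapply(per_rep, function(x) x[, cl], numeric(nyears))
    m <- matrix(m, nrow = nyears)
    out[[cl]] <- data.frame(
      year = seq_len(nyears), class = cl,
      mean = rowMeans(m, na.rm = TRUE),
      se = apply(m, 1, function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Compare two experiments with an unpaired Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test on a per-replicate statistic: the adult
#' population at the last step (`"end_adults"`) or total deaths summed over
#' the experiment window (`"total_deaths"`). Ties are handled by
#' `stats::wilcox.test` (the exact distribution when there are no ties,
#' otherwise the normal approximation with tie correction); degenerate
#' all-equal samples report p = 1.
#'
#' @param records_a,records_b lists of run records for the two experiments.
#' @param what `"end_adults"` or `"total_deaths"`.
#' @return List: `p_value`, `median_a`, `median_b`, `stars`.
#' @export
total_deaths_comparison <- function(records_a, records_b,
                                    what = c("end_adults", "total_deaths")) {
  what <- match.arg(what)
  stat <- function(r) {
    if (what == "end_adults") r$counts$adults[nrow(r$counts)]
    else sum(r$deaths$step > r$burn_in)
  }
  a <- vapply(records_a, stat, numeric(1))
  b <- vapply(records_b, stat, numeric(1))
  if (length(unique(c(a, b))) == 1L) {
    p <- 1
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  list(p_value = p, median_a = stats::median(a), median_b = stats::median(b),
       stars = significance_stars(p))
}

#' Significance bands
#'
#' `ns` (> 0.05), `*` (<= 0.05), `**` (<= 0.01), `***` (<= 0.001),
#' `****` (<= 0.0001).
#'
#' @param p p-value(s).
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  cut(p, c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Mean occupancy map across replicates
#'
#' Per-cell proportion of the 240 experiment months in which the cell
#' belonged to any breeding female's territory, averaged across replicates.
#'
#' @param records list of run records.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
occupancy_map <- function(records) {
  Reduce(`+`, lapply(records, function(r) r$occupancy)) / length(records)
}

#' Occupancy stratified near versus far from roads
#'
#' @param occ an [occupancy_map()] matrix.
#' @param near logical matrix from [near_road_mask()].
#' @param mask optional in-landscape mask.
#' @return Named numeric: mean occupancy `near` and `far`.
#' @export
occupancy_strata <- function(occ, near, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(occ), ncol(occ))
  c(near = mean(occ[near & mask]), far = mean(occ[!near & mask]))
}

#' Baseline quasi-stationarity drift
#'
#' Relative difference between the mean adult count over the last 120
#' burn-in months and the first 120 experiment months; small values indicate
#' the burn-in reached quasi-stationary dynamics.
#'
#' @param records list of run records.
#' @return Relative drift (positive = growth after activation).
#' @export
burnin_drift <- function(records) {
  burn_in <- records[[1]]$burn_in
  pre <- mean(vapply(records, function(r)
    mean(r$counts$adults[(burn_in - 119):burn_in]), numeric(1)))
  post <- mean(vapply(records, function(r)
    mean(r$counts$adults[(burn_in + 1):(burn_in + 120)]), numeric(1)))
  (post - pre) / pre
}
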