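#' Scenario configuration
#'
#' Bundles the experiment design: which transport-infrastructure mechanisms
#' are active after burn-in, the road configuration, run lengths, initial
#' population and replication settings. The default protocol runs 600 inert
#' months of burn-in (roads are drawn on the landscape but affect nothing),
#' switches the configured mechanisms on instantaneously at step 601, and
#' records a 240-month (20-year) experiment window. The baseline is the
#' empty mechanism set.
#'
#' @param mechanisms character subset of `c("mortality", "depletion")`;
#'   empty for the baseline.
#' @param road_config `"existing"` or `"existing_plus_railway"`; with the
#'   railway, a railway corridor (treated as a primary road) is added by the
#'   synthetic landscape generator.
#' @param burn_in,experiment run lengths in months.
#' @param n_females,n_males initial population (14 breeding females, 7
#'   males).
#' @param replicates number of stochastic replicates (28).
#' @param base_seed replicate `r` uses seed `base_seed + r`.
#' @param landscape `NULL` (default synthetic landscape), a [synth_spec()],
#'   or a prebuilt `list(prey = <prey_grid>, roads = <road_layer>)`.
#' @param params a [tiger_params()].
#' @param init_pop optional data frame overriding the standard initial
#'   population; columns `sex`, `age`, and for settled females
#'   `origin_row`, `origin_col` (see [init_state()]).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(mechanisms = character(),
                            road_config = c("existing", "existing_plus_railway"),
                            burn_in = 600L, experiment = 240L,
                            n_females = 14L, n_males = 7L,
                            replicates = 28L, base_seed = 1L,
                            landscape = NULL, params = tiger_params(),
                            init_pop = NULL) {
  road_config <- match.arg(road_config)
  stopifnot(all(mechanisms %in% c("mortality", "depletion")),
            burn_in >= 0, experiment >= 1, replicates >= 1)
  structure(list(mechanisms = mechanisms, road_config = road_config,
                 burn_in = as.integer(burn_in), experiment = as.integer(experiment),
                 n_females = as.integer(n_females), n_males = as.integer(n_males),
                 replicates = as.integer(replicates), base_seed = as.integer(base_seed),
                 landscape = landscape, params = params, init_pop = init_pop),
            class = "scenario_config")
}

#' Build (or pass through) the landscape for a configuration
#'
#' @param config a [scenario_config()].
#' @return `list(prey = <prey_grid>, roads = <road_layer>)`.
#' @export
build_landscape <- function(config) {
  ls <- config$landscape
  if (is.list(ls) && !inherits(ls, "synth_spec") &&
      all(c("prey", "roads") %in% names(ls))) {
    return(ls)
  }
  spec <- if (inherits(ls, "synth_spec")) ls else synth_spec()
  spec$railway <- config$road_config == "existing_plus_railway"
  generate_landscape(spec)
}

# internal stage codes: 1 cub, 2 juvenile, 3 transient, 4 breeding
.stage_code <- function(age) findInterval(age, c(12L, 24L, 36L)) + 1L
.stage_name <- c("cub", "juvenile", "transient", "breeding")

#' Initialize a simulation state
#'
#' Places the initial population on the landscape: female territory origins
#' are sampled at least 2 km apart from cells above the 60th prey
#' percentile, ages uniform on 36-120 months; males start at randomly chosen
#' female origins. The 600-step burn-in is expected to wash out these
#' choices. A custom `init_pop` data frame (columns `sex`, `age`, optional
#' `origin_row`/`origin_col` for pre-settled females) replaces the standard
#' placement, which is useful for controlled experiments.
#'
#' @param config a [scenario_config()].
#' @param landscape as returned by [build_landscape()].
#' @return An environment of class `tiger_state`.
#' @export
init_state <- function(config, landscape = NULL) {
  if (is.null(landscape)) landscape <- build_landscape(config)
  prey <- landscape$prey; roads <- landscape$roads
  nr <- nrow(prey$production); nc <- ncol(prey$production)
  st <- new.env(parent = emptyenv())
  class(st) <- "tiger_state"
  st$params <- config$params
  st$config <- config
  st$prey <- prey
  st$roads <- roads
  st$mask <- prey$mask
  st$cell_size <- prey$cell_size
  st$nr <- nr; st$nc <- nc
  st$prey_eff <- prey$production
  st$prey_smooth <- cpp_focal_disk_sum(st$prey_eff,
                                       st$params$settle_prey_radius_m / st$cell_size)
  st$pri_cells <- which(roads$classes == 2L)
  st$sec_cells <- which(roads$classes == 1L)
  st$rowv <- as.integer(.row(c(nr, nc)))
  st$colv <- as.integer(.col(c(nr, nc)))
  st$owner <- matrix(0L, nr, nc)
  st$occ <- matrix(0L, nr, nc)
  st$step <- 0L
  st$total_steps <- config$burn_in + config$experiment
  st$counts <- matrix(0L, st$total_steps, 3,
                      dimnames = list(NULL, c("adults", "breeding_females", "dependents")))
  st$deaths <- list(step = integer(0), id = integer(0), sex = character(0),
                    stage = character(0), cause = character(0), road = character(0))
  st$extinct_in_burnin <- FALSE
  # population vectors (parallel)
  st$id <- integer(0); st$sex <- character(0); st$age <- integer(0)
  st$stage <- integer(0); st$mother <- integer(0); st$natal <- integer(0)
  st$origin <- integer(0); st$prey_sum <- numeric(0); st$starve <- integer(0)
  st$settle_months <- integer(0); st$expanded <- logical(0)
  st$male <- integer(0); st$gest <- integer(0); st$pos <- integer(0)
  st$next_id <- 1L

  if (!is.null(config$init_pop)) {
    .seed_custom_pop(st, config$init_pop)
  } else {
    .seed_standard_pop(st, config)
  }
  st
}

.add_tigers <- function(st, n, sex, age, mother = NA_integer_, natal,
                        origin = NA_integer_, pos = NA_integer_) {
  ids <- st$next_id + seq_len(n) - 1L
  st$next_id <- st$next_id + n
  st$id <- c(st$id, ids)
  st$sex <- c(st$sex, rep_len(sex, n))
  st$age <- c(st$age, rep_len(as.integer(age), n))
  st$stage <- c(st$stage, .stage_code(rep_len(as.integer(age), n)))
  st$mother <- c(st$mother, rep_len(as.integer(mother), n))
  st$natal <- c(st$natal, rep_len(as.integer(natal), n))
  st$origin <- c(st$origin, rep_len(as.integer(origin), n))
  st$prey_sum <- c(st$prey_sum, rep_len(0, n))
  st$starve <- c(st$starve, rep_len(0L, n))
  st$settle_months <- c(st$settle_months, rep_len(0L, n))
  st$expanded <- c(st$expanded, rep_len(TRUE, n))
  st$male <- c(st$male, rep_len(NA_integer_, n))
  st$gest <- c(st$gest, rep_len(0L, n))
  st$pos <- c(st$pos, rep_len(as.integer(pos), n))
  ids
}

.seed_standard_pop <- function(st, config) {
  pr <- st$prey_eff
  q60 <- stats::quantile(pr[st$mask], 0.6, names = FALSE)
  cand <- which(st$mask & pr >= q60)
  rowm <- ((cand - 1L) %% st$nr) + 1L
  colm <- ((cand - 1L) %/% st$nr) + 1L
  sep_cells <- 2000 / st$cell_size
  # founders cluster in the richest habitat, as a relict core population would
  w <- (st$prey_smooth[cand] / max(st$prey_smooth[cand]))^6
  origins <- integer(0)
  for (i in seq_len(config$n_females)) {
    if (!length(cand)) break
    k <- sample.int(length(cand), 1, prob = w)
    origins <- c(origins, cand[k])
    keep <- (rowm - rowm[k])^2 + (colm - colm[k])^2 > sep_cells^2
    cand <- cand[keep]; rowm <- rowm[keep]; colm <- colm[keep]; w <- w[keep]
  }
  for (o in origins) {
    id <- .add_tigers(st, 1L, "F", sample(36:120, 1), natal = o, origin = o)
    st$owner[o] <- id
    st$prey_sum[match(id, st$id)] <- st$prey_eff[o]
  }
  mo <- origins[sample.int(length(origins), min(config$n_males, length(origins)))]
  for (o in mo) .add_tigers(st, 1L, "M", sample(36:120, 1), natal = o, pos = o)
  invisible(st)
}

.seed_custom_pop <- function(st, pop) {
  n <- nrow(pop)
  if (!n) return(invisible(st))
  origin <- rep(NA_integer_, n)
  if (!is.null(pop$origin_row)) {
    has <- !is.na(pop$origin_row)
    origin[has] <- (as.integer(pop$origin_col[has]) - 1L) * st$nr +
      as.integer(pop$origin_row[has])
  }
  center <- (st$nc %/% 2L) * st$nr + st$nr %/% 2L
  natal <- ifelse(is.na(origin), center, origin)
  pos <- ifelse(pop$sex == "M", natal, NA_integer_)
  ids <- .add_tigers(st, n, pop$sex, as.integer(pop$age), natal = natal,
                     origin = origin, pos = pos)
  settled <- !is.na(origin)
  st$owner[origin[settled]] <- ids[settled]
  st$prey_sum[match(ids[settled], st$id)] <- st$prey_eff[origin[settled]]
  invisible(st)
}

.record_deaths <- function(st, idx, cause, road) {
  st$deaths$step <- c(st$deaths$step, rep_len(st$step, length(idx)))
  st$deaths$id <- c(st$deaths$id, st$id[idx])
  st$deaths$sex <- c(st$deaths$sex, st$sex[idx])
  st$deaths$stage <- c(st$deaths$stage, .stage_name[st$stage[idx]])
  st$deaths$cause <- c(st$deaths$cause, rep_len(cause, length(idx)))
  st$deaths$road <- c(st$deaths$road, road)
  invisible(st)
}

.drop_tigers <- function(st, drop) {
  keep <- !drop
  for (f in c("id", "sex", "age", "stage", "mother", "natal", "origin",
              "prey_sum", "starve", "settle_months", "expanded", "male",
              "gest", "pos")) {
    st[[f]] <- st[[f]][keep]
  }
  invisible(st)
}

# road-intersection tags for settled females: "primary" beats "secondary"
.road_tags <- function(st) {
  ids_pri <- unique(st$owner[st$pri_cells]); ids_pri <- ids_pri[ids_pri > 0L]
  ids_sec <- unique(st$owner[st$sec_cells]); ids_sec <- ids_sec[ids_sec > 0L]
  list(pri = ids_pri, sec = ids_sec)
}

#' Advance the simulation by one month
#'
#' Executes the fixed monthly schedule: (1) age and stage advance;
#' (2) survival draws (road-adjusted for breeding females when the mortality
#' mechanism is active), starvation, and orphan deaths; (3) release of dead
#' owners' cells; (4) settlement of dispersing females, territory expansion
#' and patch contests (older females first); (5) male range assembly,
#' dispersal jumps, challenges and infanticide; (6) conception, gestation
#' and births; (7) metric recording. At the activation step
#' (`burn_in + 1`) the configured mechanisms switch on instantaneously; prey
#' depletion rewrites the effective prey grid once and holds it fixed.
#'
#' @param st a `tiger_state` from [init_state()].
#' @return The state, invisibly (modified in place).
#' @export
sim_step <- function(st) {
  st$step <- st$step + 1L
  p <- st$params
  cfg <- st$config
  active <- st$step > cfg$burn_in
  if (st$step == cfg$burn_in + 1L && "depletion" %in% cfg$mechanisms) {
    st$prey_eff <- apply_depletion(st$prey, st$roads, p)$production
    st$prey_smooth <- cpp_focal_disk_sum(st$prey_eff,
                                         p$settle_prey_radius_m / st$cell_size)
    if (any(st$owner > 0L)) {
      settled <- !is.na(st$origin)
      sums <- tapply(st$prey_eff[st$owner > 0L], st$owner[st$owner > 0L], sum)
      m <- match(st$id[settled], as.integer(names(sums)))
      st$prey_sum[settled] <- ifelse(is.na(m), 0, as.numeric(sums)[m])
    }
  }
  mech_mort <- active && "mortality" %in% cfg$mechanisms

  n <- length(st$id)
  if (n > 0L) {
    ## (1) age/stage
    st$age <- st$age + 1L
    st$stage <- .stage_code(st$age)
    ## tenure clock: months since settling (settled females) or months spent
    ## searching for a territory (dispersing females)
    st$settle_months <- st$settle_months + as.integer(st$stage == 4L & st$sex == "F")

    ## (2) mortality
    settled <- !is.na(st$origin)
    if (mech_mort) {
      ## every settled female needs her road flags for the survival draw
      tags <- .road_tags(st)
      has_pri <- settled & st$id %in% tags$pri
      has_sec <- settled & st$id %in% tags$sec
    } else {
      has_pri <- has_sec <- logical(n)
    }
    resident_males <- unique(st$male[settled & !is.na(st$male)])
    annual <- numeric(n)
    annual[st$stage == 1L] <- p$survival[["cub"]]
    annual[st$stage == 2L] <- p$survival[["juvenile"]]
    annual[st$stage == 3L & st$sex == "M"] <- p$survival[["transient_male"]]
    annual[st$stage == 3L & st$sex == "F"] <- p$survival[["transient_female"]]
    bm <- st$stage == 4L & st$sex == "M"
    annual[bm] <- p$survival[["dispersing_male"]]
    annual[bm & st$id %in% resident_males] <- p$survival[["breeding_male"]]
    bf <- st$stage == 4L & st$sex == "F"
    annual[bf & !settled] <- p$survival[["transient_female"]]
    annual[bf & settled] <- p$survival[["breeding_female"]]
    if (mech_mort) {
      annual[bf & has_sec] <- p$survival_secondary_road
      annual[bf & has_pri] <- p$survival_primary_road
    }
    die <- stats::runif(n) >= monthly_survival(annual)
    ## dispersing females who fail to establish within the search window die
    ## or leave the study area; folded into background mortality
    failed <- st$stage == 4L & st$sex == "F" & is.na(st$origin) &
      st$settle_months > p$female_search_months
    die <- die | failed
    cause <- ifelse(mech_mort & settled & (has_pri | has_sec),
                    "road_enhanced", "background")
    ## starvation of surviving territory holders: a female below the basal
    ## requirement is at risk only once her territory can no longer grow
    ## (blocked frontier), after a settlement grace period long enough to
    ## annex a minimum territory at the 48-cell/month cap; a female still
    ## compensating by expansion is hunting over new ground, not starving
    util <- p$utilization_fraction * st$prey_sum
    low <- settled & !die & util < p$prey_min & !st$expanded &
      st$settle_months > p$settle_grace_months
    bumped <- st$starve[low] + 1L
    st$starve[settled & !die] <- 0L
    st$starve[low] <- bumped
    starved <- settled & !die & st$starve >= p$starvation_months
    die[starved] <- TRUE
    cause[starved] <- "starvation"
    ## road tag at death: own territory for settled females, mother's for
    ## dependents; when the mortality mechanism is off the flags are only
    ## needed for tigers that actually die, so compute them lazily
    if (!mech_mort && (any(die) || any(settled))) {
      need <- settled & (die | st$id %in% st$mother[st$stage <= 2L & die])
      if (any(need)) {
        own_need <- st$owner %in% st$id[need]
        ids_pri <- unique(st$owner[st$pri_cells][own_need[st$pri_cells]])
        ids_sec <- unique(st$owner[st$sec_cells][own_need[st$sec_cells]])
        has_pri <- need & st$id %in% ids_pri
        has_sec <- need & st$id %in% ids_sec
      }
    }
    tag <- rep("none", n)
    tag[has_pri] <- "primary"
    tag[has_sec & !has_pri] <- "secondary"
    dep <- st$stage <= 2L
    tag[dep] <- tag[match(st$mother[dep], st$id)]
    tag[is.na(tag)] <- "none"
    ## orphans: dependents whose mother died this month
    dead_ids <- st$id[die]
    orphan <- dep & !die & st$mother %in% dead_ids
    if (any(die)) .record_deaths(st, which(die), cause[die], tag[die])
    if (any(orphan)) .record_deaths(st, which(orphan), "orphaned", tag[orphan])

    ## (3) release territories of dead owners; clear widow associations
    gone <- die | orphan
    dead_settled <- st$id[gone & settled]
    if (length(dead_settled)) st$owner[st$owner %in% dead_settled] <- 0L
    dead_males <- st$id[gone & st$sex == "M"]
    if (length(dead_males)) st$male[st$male %in% dead_males] <- NA_integer_
    .drop_tigers(st, gone)
  }

  ## (4) settlement and expansion
  n <- length(st$id)
  if (n > 0L) {
    unsettled <- which(st$stage == 4L & st$sex == "F" & is.na(st$origin))
    if (length(unsettled)) {
      ## each dispersing female prospects a monthly sample of sites within
      ## 33 km of her natal center and settles on the best qualifying one
      ## (ideal pass: no territory within 2 km; relaxed pass: 1 km). On an
      ## empty landscape settlement is immediate; near saturation qualifying
      ## sites are rare and searches routinely fail, so recruitment - not
      ## standing vacancy - limits the population.
      unsettled <- unsettled[order(st$id[unsettled])]
      cs <- st$cell_size
      dist_occ <- distance_to_owned(st$owner, cs)
      rmax2 <- (p$max_dispersal_m[["female"]] / cs)^2
      nsamp <- p$settlement_samples
      ncell <- st$nr * st$nc
      ## viability floor: no settling where even a maximal territory around
      ## the site could not meet the basal requirement
      ndisk <- sum(outer((-4):4, (-4):4, function(a, b) a^2 + b^2) <=
                     (p$settle_prey_radius_m / cs)^2 + 1e-9)
      floor_sum <- p$prey_min / (p$utilization_fraction * p$max_territory_cells) * ndisk
      for (i in unsettled) {
        nr0 <- ((st$natal[i] - 1L) %% st$nr) + 1L
        nc0 <- ((st$natal[i] - 1L) %/% st$nr) + 1L
        cand <- sample.int(ncell, min(4L * nsamp, ncell))
        cand <- cand[(st$rowv[cand] - nr0)^2 + (st$colv[cand] - nc0)^2 <= rmax2]
        cand <- utils::head(cand, nsamp)
        cand <- cand[st$mask[cand] & st$owner[cand] == 0L &
                       st$prey_smooth[cand] >= floor_sum]
        if (!length(cand)) next
        ok <- cand[dist_occ[cand] > p$settle_radius_ideal_m]
        if (!length(ok)) ok <- cand[dist_occ[cand] > p$settle_radius_relaxed_m]
        if (!length(ok)) next
        ps <- st$prey_smooth[ok]
        best <- ok[ps == max(ps)]
        k <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
        st$owner[k] <- st$id[i]
        st$origin[i] <- k
        st$prey_sum[i] <- st$prey_eff[k]
        st$starve[i] <- 0L
        st$settle_months[i] <- 0L
        st$expanded[i] <- TRUE
        ## later settlers this month must respect the new territory cell
        kr <- st$rowv[k]; kc <- st$colv[k]
        wr <- max(1L, kr - 8L):min(st$nr, kr + 8L)
        wc <- max(1L, kc - 8L):min(st$nc, kc + 8L)
        dw <- sqrt(outer((wr - kr)^2, (wc - kc)^2, "+")) * cs
        dist_occ[wr, wc] <- pmin(dist_occ[wr, wc], dw)
      }
    }
    settled_i <- which(!is.na(st$origin))
    if (length(settled_i)) {
      grow <- settled_i[p$utilization_fraction * st$prey_sum[settled_i] < p$prey_min]
      grow <- grow[order(-st$age[grow], st$id[grow])]
      fid <- st$id[settled_i]
      fage <- as.numeric(st$age[settled_i])
      forg <- st$origin[settled_i] - 1L
      st$expanded[settled_i] <- FALSE
      for (i in grow) {
        res <- cpp_expand_territory(
          st$owner, st$prey_eff, st$mask, st$id[i], as.numeric(st$age[i]),
          st$origin[i] - 1L, fid, fage, forg,
          st$prey_sum[i], p$utilization_fraction, p$prey_min,
          p$max_cells_per_step, p$patch_takeover_prob,
          p$max_territory_cells)
        st$expanded[i] <- res$added > 0L
        st$prey_sum[i] <- res$prey_sum
        if (length(res$loser_id)) {
          m <- match(res$loser_id, st$id)
          st$prey_sum[m] <- st$prey_sum[m] - res$loser_loss
        }
      }
    }
  }

  ## (5) males: range assembly, dispersal jumps, challenges
  n <- length(st$id)
  if (n > 0L) {
    males <- which(st$stage == 4L & st$sex == "M")
    males <- males[order(st$id[males])]
    dead_now <- logical(n)
    for (mi in males) {
      if (dead_now[mi]) next
      mid <- st$id[mi]
      if (is.na(st$pos[mi])) st$pos[mi] <- st$natal[mi] # first month of dispersal
      fset <- which(!is.na(st$origin) & !dead_now)
      mine <- fset[!is.na(st$male[fset]) & st$male[fset] == mid]
      if (length(mine)) {
        ## resident: sit at the centroid of his females' origins, top up range
        orow <- ((st$origin[mine] - 1L) %% st$nr) + 1L
        ocol <- ((st$origin[mine] - 1L) %/% st$nr) + 1L
        prow <- as.integer(round(mean(orow))); pcol <- as.integer(round(mean(ocol)))
        st$pos[mi] <- (pcol - 1L) * st$nr + prow
        if (length(mine) < p$max_females_per_male && anyNA(st$male[fset])) {
          rng <- .male_range(prow, pcol, st$owner, st$id[fset], st$male[fset],
                             p, st$cell_size, n_have = length(mine))
          if (length(rng$associate)) {
            st$male[match(rng$associate, st$id)] <- mid
          }
        }
      } else {
        ## dispersing: jump to the nearest reachable settled female
        if (!length(fset)) next
        frow <- ((st$origin[fset] - 1L) %% st$nr) + 1L
        fcol <- ((st$origin[fset] - 1L) %/% st$nr) + 1L
        prow <- ((st$pos[mi] - 1L) %% st$nr) + 1L
        pcol <- ((st$pos[mi] - 1L) %/% st$nr) + 1L
        nrow0 <- ((st$natal[mi] - 1L) %% st$nr) + 1L
        ncol0 <- ((st$natal[mi] - 1L) %/% st$nr) + 1L
        dnat <- sqrt((frow - nrow0)^2 + (fcol - ncol0)^2) * st$cell_size
        ok <- dnat <= p$max_dispersal_m[["male"]]
        if (!any(ok)) next
        dpos <- sqrt((frow - prow)^2 + (fcol - pcol)^2) * st$cell_size
        ## vacant ground first: target the nearest unassociated female; only
        ## challenge when no unassociated female is in reach, and only an
        ## incumbent the disperser is at least as strong as (age assessment)
        free <- ok & is.na(st$male[fset])
        if (!any(free)) {
          inc_w <- challenge_weight(st$age[match(st$male[fset], st$id)])
          free <- ok & !is.na(inc_w) & inc_w <= challenge_weight(st$age[mi])
          if (!any(free)) next
        }
        pickfrom <- free
        tgt <- fset[pickfrom][which.min(dpos[pickfrom])]
        st$pos[mi] <- st$origin[tgt]
        if (is.na(st$male[tgt])) {
          st$male[tgt] <- mid
          rng <- .male_range(((st$origin[tgt] - 1L) %% st$nr) + 1L,
                             ((st$origin[tgt] - 1L) %/% st$nr) + 1L,
                             st$owner, st$id[fset], st$male[fset],
                             p, st$cell_size, n_have = 1L)
          if (length(rng$associate)) st$male[match(rng$associate, st$id)] <- mid
        } else {
          ## challenge the incumbent
          inc <- match(st$male[tgt], st$id)
          if (is.na(inc) || dead_now[inc]) { st$male[tgt] <- NA_integer_; next }
          harem <- fset[!is.na(st$male[fset]) & st$male[fset] == st$id[inc]]
          depx <- which(st$stage <= 2L & st$mother %in% st$id[harem] & !dead_now)
          cubs <- depx[st$stage[depx] == 1L]
          juvs <- depx[st$stage[depx] == 2L]
          out <- resolve_challenge(st$age[mi], st$age[inc],
                                   length(cubs), length(juvs), p)
          if (out$challenger_wins) {
            st$male[harem] <- mid
            tags <- .road_tags(st)
            mtag <- function(dep_i) {
              mo <- st$mother[dep_i]
              ifelse(mo %in% tags$pri, "primary",
                     ifelse(mo %in% tags$sec, "secondary", "none"))
            }
            killed <- c(cubs[out$cub_killed], juvs[out$juvenile_killed])
            if (length(killed)) {
              .record_deaths(st, killed, "infanticide", mtag(killed))
              dead_now[killed] <- TRUE
            }
            if (out$incumbent_dies) {
              .record_deaths(st, inc, "challenge", "none")
              dead_now[inc] <- TRUE
              st$male[st$male %in% st$id[inc]] <- NA_integer_
              st$male[harem] <- mid
            }
          } else if (out$challenger_dies) {
            .record_deaths(st, mi, "challenge", "none")
            dead_now[mi] <- TRUE
          }
        }
      }
    }
    if (any(dead_now)) {
      dm <- st$id[dead_now & st$sex == "M"]
      if (length(dm)) st$male[st$male %in% dm] <- NA_integer_
      .drop_tigers(st, dead_now)
    }
  }

  ## (6) reproduction
  n <- length(st$id)
  if (n > 0L) {
    pregnant <- which(st$gest > 0L)
    st$gest[pregnant] <- st$gest[pregnant] - 1L
    born_to <- pregnant[st$gest[pregnant] == 0L]
    born_to <- born_to[!is.na(st$origin[born_to])] # litters need a territory
    if (length(born_to)) {
      lit <- sample_litter(length(born_to), p)
      for (j in seq_along(born_to)) {
        i <- born_to[j]
        .add_tigers(st, lit$size[j], lit$sexes[[j]], age = 0L,
                    mother = st$id[i], natal = st$origin[i])
      }
    }
    dep <- st$stage <= 2L
    ndep <- tabulate(match(st$mother[dep], st$id), nbins = length(st$id))
    eligible <- which(st$stage == 4L & st$sex == "F" & !is.na(st$origin) &
                        !is.na(st$male) & st$gest == 0L & ndep == 0L)
    if (length(eligible)) {
      hz <- conception_hazard(st$age[eligible], p)
      conceive <- eligible[stats::runif(length(eligible)) < hz]
      if (length(conceive)) st$gest[conceive] <- draw_gestation(length(conceive), p)
    }
  }

  ## (7) record
  st$counts[st$step, ] <- c(sum(st$stage == 4L),
                            sum(st$sex == "F" & !is.na(st$origin)),
                            sum(st$stage <= 2L))
  if (st$step > cfg$burn_in) st$occ <- st$occ + (st$owner != 0L)
  if (length(st$id) == 0L && st$step <= cfg$burn_in) st$extinct_in_burnin <- TRUE
  invisible(st)
}

#' Run one scenario replicate
#'
#' Runs burn-in plus experiment under a single RNG stream seeded with
#' `base_seed + replicate` and returns the run record: per-step counts, the
#' death-event log, and the per-cell occupancy accumulator over the
#' experiment window.
#'
#' @param config a [scenario_config()].
#' @param landscape optional prebuilt landscape (shared across replicates);
#'   built from the config when `NULL`.
#' @param replicate replicate number (>= 1).
#' @return A list of class `tiger_run` with elements `counts` (data frame:
#'   step, adults, breeding_females, dependents), `deaths` (data frame),
#'   `occupancy` (matrix of per-cell proportions over the experiment
#'   window), `seed`, `mechanisms`, `road_config`, `burn_in`, `experiment`,
#'   `extinct_in_burnin`.
#' @export
run_scenario <- function(config, landscape = NULL, replicate = 1L) {
  if (is.null(landscape)) landscape <- build_landscape(config)
  seed <- config$base_seed + as.integer(replicate)
  set.seed(seed)
  st <- init_state(config, landscape)
  for (s in seq_len(st$total_steps)) sim_step(st)
  structure(list(
    counts = data.frame(step = seq_len(st$total_steps), st$counts),
    deaths = data.frame(st$deaths, stringsAsFactors = FALSE),
    occupancy = st$occ / config$experiment,
    seed = seed,
    mechanisms = config$mechanisms,
    road_config = config$road_config,
    burn_in = config$burn_in,
    experiment = config$experiment,
    extinct_in_burnin = st$extinct_in_burnin
  ), class = "tiger_run")
}

#' @export
print.tiger_run <- function(x, ...) {
  last <- x$counts[nrow(x$counts), ]
  cat(sprintf("<tiger_run> seed %d, mechanisms {%s}; end: %d adults, %d breeding females, %d dependents; %d deaths\n",
              x$seed, paste(x$mechanisms, collapse = ","),
              last$adults, last$breeding_females, last$dependents,
              nrow(x$deaths)))
  invisible(x)
}

#' Run replicated scenario experiments
#'
#' Replicate `r` is seeded with `base_seed + r`; replicates are independent
#' and share the landscape, so results do not depend on execution order.
#'
#' @param config a [scenario_config()].
#' @param landscape optional prebuilt landscape; built once when `NULL`.
#' @return A list of [run_scenario()] records.
#' @export
run_replicates <- function(config, landscape = NULL) {
  if (is.null(landscape)) landscape <- build_landscape(config)
  lapply(seq_len(config$replicates), function(r)
    run_scenario(config, landscape, replicate = r))
}
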