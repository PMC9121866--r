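#' Find a territory origin for a dispersing female
#'
#' Scans all in-landscape cells within 33 km of the female's natal center.
#' A cell qualifies in the ideal pass if no other female territory cell lies
#' within 2 km; if no such cell exists the rule relaxes to 1 km. Sites whose
#' 1 km prey neighbourhood could not meet the basal requirement even with a
#' maximal territory are never chosen (tigers shift away from prey-poor
#' ground). Among qualifying cells the one maximizing effective prey summed
#' over a 1 km radius is chosen, ties broken uniformly at random.
#'
#' @param owner integer matrix of territory ownership (0 = unowned).
#' @param prey numeric matrix of effective prey production.
#' @param natal `c(row, col)` of the female's natal center.
#' @param params a [tiger_params()].
#' @param mask logical in-landscape matrix (default all `TRUE`).
#' @param cell_size cell edge in meters.
#' @param dist_occupied optional precomputed matrix of distances (m) to the
#'   nearest owned cell (`Inf` when no cell is owned).
#' @param prey_smooth optional precomputed 1 km focal prey sum.
#' @return `c(row, col)` of the chosen origin, or `NULL` when the landscape
#'   is saturated within reach.
#' @export
find_settlement_site <- function(owner, prey, natal, params = tiger_params(),
                                 mask = NULL, cell_size = 250,
                                 dist_occupied = NULL, prey_smooth = NULL) {
  nr <- nrow(owner); nc <- ncol(owner)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (is.null(dist_occupied)) dist_occupied <- distance_to_owned(owner, cell_size)
  if (is.null(prey_smooth)) {
    prey_smooth <- cpp_focal_disk_sum(prey, params$settle_prey_radius_m / cell_size)
  }
  rowm <- .row(c(nr, nc)); colm <- .col(c(nr, nc))
  dnatal <- sqrt((rowm - natal[1])^2 + (colm - natal[2])^2) * cell_size
  rad_cells <- params$settle_prey_radius_m / cell_size
  ndisk <- sum(outer(-floor(rad_cells):floor(rad_cells),
                     -floor(rad_cells):floor(rad_cells),
                     function(a, b) a^2 + b^2) <= rad_cells^2 + 1e-9)
  viable <- prey_smooth >= params$prey_min /
    (params$utilization_fraction * params$max_territory_cells) * ndisk
  reach <- mask & owner == 0L & viable &
    dnatal <= params$max_dispersal_m[["female"]]
  cand <- reach & dist_occupied > params$settle_radius_ideal_m
  if (!any(cand)) cand <- reach & dist_occupied > params$settle_radius_relaxed_m
  if (!any(cand)) return(NULL)
  ps <- prey_smooth[cand]
  idx <- which(cand)[which(ps == max(ps))]
  k <- if (length(idx) > 1) idx[sample.int(length(idx), 1)] else idx
  c(((k - 1) %% nr) + 1, ((k - 1) %/% nr) + 1)
}

#' Distance to the nearest owned territory cell
#'
#' Exact Euclidean cell-center distance (meters) from every cell to the
#' nearest cell owned by any female; `Inf` everywhere when no cell is owned.
#'
#' @param owner integer ownership matrix.
#' @param cell_size cell edge in meters.
#' @return Numeric matrix.
#' @export
distance_to_owned <- function(owner, cell_size = 250) {
  cpp_edt((owner > 0L) + 0L) * cell_size
}

#' Monthly territory expansion for one female
#'
#' Greedy acquisition: the female repeatedly annexes the unowned
#' frontier-adjacent cell (rook adjacency) with the highest effective prey,
#' ties broken at random, up to 48 cells per month, stopping early once her
#' utilized prey (0.1 of the territory production sum) meets the basal
#' metabolic requirement of 76 kg/month (the 167.3 kg/month maximum is an
#' upper ceiling that acquisition never aims past). A frontier cell held by a younger female
#' may be taken with probability 0.25 (patch contest); the subordinate's
#' remnant territory is pruned to the connected component containing her
#' origin, pruned cells becoming unowned. Territories never shed cells
#' voluntarily.
#'
#' @param owner integer ownership matrix (copied, not modified).
#' @param prey numeric matrix of effective prey production.
#' @param id the expanding female's id.
#' @param age her age in months (decides contest dominance; ties by lower
#'   id).
#' @param females data frame of all settled females: columns `id`, `age`,
#'   `origin_row`, `origin_col`.
#' @param params a [tiger_params()].
#' @param mask logical in-landscape matrix.
#' @param prey_sum her current territory prey sum (computed if `NULL`).
#' @return List: updated `owner`, `added` (cells annexed), `prey_sum`, and
#'   named numeric `losses` of prey lost by contested neighbours.
#' @export
expand_territory <- function(owner, prey, id, age, females, params = tiger_params(),
                             mask = NULL, prey_sum = NULL) {
  nr <- nrow(owner)
  if (is.null(mask)) mask <- matrix(TRUE, nr, ncol(owner))
  if (is.null(prey_sum)) prey_sum <- sum(prey[owner == id])
  own <- owner + 0L # force a copy; the C++ routine mutates in place
  fid <- as.integer(females$id)
  forg <- (as.integer(females$origin_col) - 1L) * nr + as.integer(females$origin_row) - 1L
  me <- match(id, fid)
  res <- cpp_expand_territory(
    own, prey, mask, as.integer(id), as.numeric(age),
    forg[me], fid, as.numeric(females$age), forg,
    prey_sum, params$utilization_fraction, params$prey_min,
    params$max_cells_per_step, params$patch_takeover_prob,
    params$max_territory_cells)
  losses <- as.numeric(res$loser_loss)
  names(losses) <- res$loser_id
  list(owner = own, added = res$added, prey_sum = res$prey_sum, losses = losses)
}

#' Assemble a breeding male's range of females
#'
#' A breeding male associates with up to 6 breeding females whose territory
#' cells lie within 3 km of his location, nearest first. Unassociated
#' females join his range directly; females already held by another male are
#' returned separately — gaining them requires challenging that male, never
#' a silent takeover.
#'
#' @param pos `c(row, col)` of the male's location.
#' @param owner integer ownership matrix.
#' @param females data frame of settled females: columns `id` and
#'   `male` (associated male id or `NA`).
#' @param params a [tiger_params()].
#' @param cell_size cell edge in meters.
#' @param n_have females the male already holds (the 6-female cap applies to
#'   the total).
#' @return List: `associate` (female ids to add, nearest first, at most
#'   `6 - n_have`) and `contested` (data frame of in-radius females held by
#'   other males: `id`, `male`, `dist_m`).
#' @export
assemble_male_range <- function(pos, owner, females, params = tiger_params(),
                                cell_size = 250, n_have = 0L) {
  res <- .male_range(pos[1], pos[2], owner, females$id, females$male,
                     params, cell_size, n_have)
  list(associate = res$associate,
       contested = data.frame(id = res$contested_id, male = res$contested_male,
                              dist_m = res$contested_dist))
}

# fast path shared with the engine: vectors in, no data frames
.male_range <- function(prow, pcol, owner, fem_id, fem_male, params,
                        cell_size, n_have = 0L) {
  hit <- cpp_females_in_radius(owner, prow, pcol,
                               params$male_search_radius_m, cell_size)
  assoc <- fem_male[match(hit$id, fem_id)]
  free <- is.na(assoc)
  slots <- max(0L, params$max_females_per_male - n_have)
  list(associate = utils::head(hit$id[free], slots),
       contested_id = hit$id[!free], contested_male = assoc[!free],
       contested_dist = hit$dist_m[!free])
}
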