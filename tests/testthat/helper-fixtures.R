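# shared fixtures and independent oracles

# brute-force all-pairs Euclidean distance (meters) to the nearest TRUE cell
bf_distance <- function(onroad, cell_size = 250) {
  rc <- which(onroad, arr.ind = TRUE)
  out <- matrix(Inf, nrow(onroad), ncol(onroad))
  if (!nrow(rc)) return(out)
  for (i in seq_len(nrow(onroad))) {
    for (j in seq_len(ncol(onroad))) {
      out[i, j] <- sqrt(min((i - rc[, 1])^2 + (j - rc[, 2])^2)) * cell_size
    }
  }
  out
}

# independent greedy expansion oracle: one female, no contests, pure R
greedy_expand_oracle <- function(owner, prey, id, origin, max_add, util_frac,
                                 stop_util) {
  nr <- nrow(owner); nc <- ncol(owner)
  prey_sum <- sum(prey[owner == id])
  added <- 0L
  repeat {
    if (added >= max_add || util_frac * prey_sum >= stop_util) break
    mine <- which(owner == id, arr.ind = TRUE)
    cand <- unique(do.call(rbind, apply(mine, 1, function(rc) {
      rbind(c(rc[1] - 1, rc[2]), c(rc[1] + 1, rc[2]),
            c(rc[1], rc[2] - 1), c(rc[1], rc[2] + 1))
    }, simplify = FALSE)))
    cand <- cand[cand[, 1] >= 1 & cand[, 1] <= nr &
                   cand[, 2] >= 1 & cand[, 2] <= nc, , drop = FALSE]
    cand <- cand[owner[cand] == 0L, , drop = FALSE]
    if (!nrow(cand)) break
    best <- cand[which.max(prey[cand]), , drop = FALSE]
    owner[best] <- id
    prey_sum <- prey_sum + prey[best]
    added <- added + 1L
  }
  list(owner = owner, prey_sum = prey_sum, added = added)
}

# small roadless landscape for engine tests
tiny_landscape <- function(nr = 40, nc = 40, prey = 6, seed = NULL,
                           lines = list()) {
  if (!is.null(seed)) {
    set.seed(seed)
    m <- matrix(runif(nr * nc, 0.5, prey), nr, nc)
  } else {
    m <- matrix(prey, nr, nc)
  }
  pg <- prey_grid(m)
  roads <- if (length(lines)) rasterize_roads(lines, pg) else
    road_layer(matrix(0L, nr, nc))
  list(prey = pg, roads = roads)
}

# rook-connectivity check for one female's cells
is_rook_connected <- function(owner, id) {
  cells <- which(owner == id)
  if (length(cells) <= 1) return(TRUE)
  nr <- nrow(owner)
  seen <- cells[1]
  frontier <- cells[1]
  cellset <- cells
  while (length(frontier)) {
    k <- frontier[1]; frontier <- frontier[-1]
    i <- ((k - 1) %% nr) + 1; j <- ((k - 1) %/% nr) + 1
    nb <- c(if (i > 1) k - 1, if (i < nr) k + 1, k - nr, k + nr)
    nb <- nb[nb %in% cellset & !(nb %in% seen)]
    seen <- c(seen, nb)
    frontier <- c(frontier, nb)
  }
  length(seen) == length(cells)
}
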