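#' Specification for a synthetic Chitwan-like landscape
#'
#' The generator emulates the printed statistics of the Chitwan National
#' Park model layers: a 250 m prey-biomass-production raster spanning about
#' 1,700 km^2 (park plus buffer zone) with values 0-10.46 kg/month and mean
#' 3.78, roughly 198 km of primary roads (including the proposed railway)
#' and 723 km of secondary roads. Mirroring the park's geography, the road
#' network is concentrated in a settled northern band (the buffer-zone
#' periphery) while the prey-rich core lies to the south, so that mean prey
#' near roads falls below the landscape mean and a substantial far-from-road
#' core remains.
#'
#' @param nrow,ncol grid dimensions (default 120 x 227 cells = 30 x 56.75
#'   km, about 27,200 cells).
#' @param cell_size cell edge in meters.
#' @param prey_max,prey_mean target maximum and mean production (kg/month).
#' @param autocorr_cells spatial autocorrelation length of the prey field in
#'   cells (Gaussian kernel sd); 0 gives white noise.
#' @param primary_km,secondary_km target polyline lengths; the primary
#'   target includes the railway corridor, so the existing (no-railway)
#'   network is built to `primary_km` minus the railway length.
#' @param road_band_km width of the northern band holding the road network.
#' @param railway include the proposed railway corridor (rasterized as a
#'   primary road, running parallel to and about 1.2 km south of the main
#'   east-west highway, reaching toward the high-prey core)?
#' @param seed generator seed; landscapes are byte-identical under the same
#'   spec.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(nrow = 120L, ncol = 227L, cell_size = 250,
                       prey_max = 10.46, prey_mean = 3.78,
                       autocorr_cells = 8, primary_km = 198,
                       secondary_km = 723, road_band_km = 14,
                       railway = FALSE, seed = 42L) {
  stopifnot(prey_mean < prey_max, primary_km >= 0, secondary_km >= 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell_size = cell_size, prey_max = prey_max,
                 prey_mean = prey_mean, autocorr_cells = autocorr_cells,
                 primary_km = primary_km, secondary_km = secondary_km,
                 road_band_km = road_band_km, railway = railway,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# periodic Gaussian smoothing by FFT
.smooth_field <- function(x, sigma) {
  if (sigma <= 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-outer(di^2, dj^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

#' Generate a synthetic prey-production raster
#'
#' A spatially autocorrelated random field (FFT-smoothed white noise) shaped
#' by a broad north-south profile — low along the settled northern band and
#' the southern edge, peaking in the park core south of center — then
#' rescaled so the minimum is 0, the maximum equals the target maximum, and
#' (via a monotone power adjustment) the mean matches the target mean.
#'
#' @param spec a [synth_spec()].
#' @return A [prey_grid()]. Deterministic under `spec$seed`.
#' @export
generate_prey <- function(spec = synth_spec()) {
  set.seed(spec$seed)
  nr <- spec$nrow; nc <- spec$ncol
  z <- .smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), spec$autocorr_cells)
  z <- (z - min(z)) / (max(z) - min(z))
  t <- (seq_len(nr) - 0.5) / nr # 0 at the north edge
  profile <- 0.5 + 0.5 * exp(-(t - 0.62)^2 / (2 * 0.25^2))
  z <- (0.3 + 0.7 * z) * matrix(profile, nr, nc)
  z <- (z - min(z)) / (max(z) - min(z)) # in [0, 1], attains both ends
  f <- function(g) mean(z^g) * spec$prey_max - spec$prey_mean
  g <- stats::uniroot(f, c(0.05, 50), tol = 1e-12)$root
  prey_grid(spec$prey_max * z^g, cell_size = spec$cell_size)
}

#' Generate a synthetic road network
#'
#' Primary roads are a small set of long highways in the northern band (an
#' east-west highway, a second partial east-west road, two short
#' connectors, and a top-up spur sized to hit the length target). Secondary
#' roads are denser low-prey-biased random walks confined to the same band,
#' added until their summed polyline length reaches the target. With the
#' railway enabled, a railway corridor (class primary) runs parallel to and
#' about 1.2 km south of the east-west highway toward the high-prey core —
#' the configuration argued to create an ecological trap.
#'
#' @param spec a [synth_spec()].
#' @param prey the [prey_grid()] the roads are placed on.
#' @return A [road_layer()]; lengths are polyline lengths in km.
#'   Deterministic under `spec$seed`.
#' @export
generate_roads <- function(spec = synth_spec(), prey = generate_prey(spec)) {
  set.seed(spec$seed + 1L)
  cs <- spec$cell_size
  W <- spec$ncol * cs; H <- spec$nrow * cs
  band_min_y <- max(1, H - spec$road_band_km * 1000)
  lines <- list()
  meander <- function(x0, x1, y0, amp = 500) {
    xs <- seq(x0, x1, by = 5000)
    if (xs[length(xs)] != x1) xs <- c(xs, x1)
    dy <- stats::rnorm(length(xs), 0, amp)
    dy <- cumsum(dy) - seq(0, 1, length.out = length(xs)) * sum(dy)
    cbind(xs, pmin(H - 1, pmax(band_min_y, y0 + dy)))
  }
  y_hwy <- H - 4000
  if (spec$primary_km > 0) {
    lines[[1]] <- list(coords = meander(1, W - 1, y_hwy), road_class = "primary")
    lines[[2]] <- list(coords = meander(W * 0.15, W * 0.85, H - 6500),
                       road_class = "primary")
    lines[[3]] <- list(coords = cbind(rep(W * 0.30, 2), c(H - 6500, y_hwy)),
                       road_class = "primary")
    lines[[4]] <- list(coords = cbind(rep(W * 0.70, 2), c(H - 6500, y_hwy)),
                       road_class = "primary")
  }
  railway_len <- 33
  if (spec$railway) {
    x0 <- W * 0.30
    rail <- cbind(seq(x0, min(W - 1, x0 + railway_len * 1000), length.out = 40),
                  y_hwy - 1200)
    lines[[length(lines) + 1]] <- list(coords = rail, road_class = "primary")
  }
  rail_real <- if (spec$railway) {
    .polyline_length_m(lines[[length(lines)]]$coords) / 1000
  } else 0
  # the printed primary total includes the railway; the existing network
  # therefore targets primary_km minus the railway corridor
  tot_p <- if (length(lines)) {
    sum(vapply(lines, function(l) .polyline_length_m(l$coords), 0)) / 1000
  } else 0
  need <- (spec$primary_km - railway_len) - (tot_p - rail_real)
  if (spec$primary_km > 0 && need > 1) {
    # serpentine spur: east-west passes within the band until the target is met
    pts <- matrix(c(W * 0.1, H - 8600), 1)
    dir <- 1; left <- need * 1000
    while (left > 0) {
      x <- pts[nrow(pts), 1]; y <- pts[nrow(pts), 2]
      run <- min(left, if (dir > 0) W - 1 - x else x - 1)
      pts <- rbind(pts, c(x + dir * run, y))
      left <- left - run
      if (left > 0) {
        if (y - 1000 < band_min_y) {
          warning("primary road length target unreachable on this grid; scaled down")
          break
        }
        drop <- min(left, 1000)
        pts <- rbind(pts, c(pts[nrow(pts), 1], y - drop))
        left <- left - drop
        dir <- -dir
      }
    }
    lines[[length(lines) + 1]] <- list(coords = pts, road_class = "primary")
  }
  ## secondary roads: dense village webs. Real networks of unpaved local
  ## roads concentrate around settlements, so most of their length overlaps
  ## within small patches; the resulting road-effect zone is a scatter of
  ## pockets that neighbouring territories can straddle, not a solid wall.
  pm <- prey$production
  band_rows <- seq_len(min(spec$nrow, max(1L, floor((H - band_min_y) / cs))))
  wstart <- exp(-as.vector(pm[band_rows, , drop = FALSE]) / 2.5)
  nrb <- length(band_rows)
  tot_s <- 0
  while (tot_s < spec$secondary_km - 1e-9 && spec$secondary_km > 0) {
    k <- sample.int(length(wstart), 1, prob = wstart)
    cxc <- (((k - 1) %/% nrb) + 0.5) * cs
    cyc <- H - (((k - 1) %% nrb) + 0.5) * cs
    cluster_km <- min(stats::runif(1, 8, 18), spec$secondary_km - tot_s + 0.3)
    ckm <- 0
    while (ckm < cluster_km) {
      ang <- stats::runif(1, 0, 2 * pi)
      p0 <- c(cxc + stats::runif(1, 0, 800) * cos(ang),
              cyc + stats::runif(1, 0, 800) * sin(ang))
      hd <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 300, 1200)
      p1 <- p0 + len * c(cos(hd), sin(hd))
      seg <- rbind(p0, p1)
      seg[, 1] <- pmin(W - 1, pmax(1, seg[, 1]))
      seg[, 2] <- pmin(H - 1, pmax(band_min_y, seg[, 2]))
      sl <- .polyline_length_m(seg) / 1000
      if (sl < 0.05) next
      lines[[length(lines) + 1]] <- list(coords = seg, road_class = "secondary")
      ckm <- ckm + sl
    }
    tot_s <- tot_s + ckm
  }
  rasterize_roads(lines, prey)
}

#' Generate a complete synthetic landscape
#'
#' @param spec a [synth_spec()].
#' @return `list(prey = <prey_grid>, roads = <road_layer>)`.
#' @export
generate_landscape <- function(spec = synth_spec()) {
  prey <- generate_prey(spec)
  list(prey = prey, roads = generate_roads(spec, prey))
}
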