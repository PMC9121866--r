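#' Prey-biomass grid
#'
#' Container for the monthly prey biomass production raster. Cells hold the
#' monthly rate of prey biomass production (kg/month) at 250 m resolution by
#' default; cells outside the study landscape are masked and carry zero
#' production.
#'
#' @param production numeric matrix of per-cell production (kg/month); rows
#'   run north to south, columns west to east.
#' @param cell_size cell edge length in meters.
#' @param mask logical matrix of in-landscape cells; defaults to all `TRUE`.
#' @param xll,yll coordinates of the lower-left corner (projected meters).
#' @return An object of class `prey_grid`.
#' @export
prey_grid <- function(production, cell_size = 250, mask = NULL, xll = 0, yll = 0) {
  production <- as.matrix(production)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(production), ncol(production))
  storage.mode(mask) <- "logical"
  if (!all(dim(mask) == dim(production))) stop("mask and production dimensions differ")
  if (any(!is.finite(production[mask]))) stop("non-finite production inside mask")
  neg <- which(production < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative production at cell (row %d, col %d)", neg[1, 1], neg[1, 2]))
  }
  production[!mask] <- 0
  structure(
    list(production = production, mask = mask, cell_size = cell_size,
         xll = xll, yll = yll),
    class = "prey_grid")
}

#' @export
print.prey_grid <- function(x, ...) {
  p <- x$production[x$mask]
  cat(sprintf("<prey_grid> %d x %d cells of %g m; production %.3g-%.3g, mean %.3g kg/month\n",
              nrow(x$production), ncol(x$production), x$cell_size,
              min(p), max(p), mean(p)))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses a single-band ESRI ASCII raster (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header). NODATA cells become masked cells with zero
#' production; other values are preserved exactly.
#'
#' @param path file path.
#' @return A [prey_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- suppressWarnings(as.numeric(tok[2]))
      nhdr <- nhdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need]))) {
    stop("malformed ESRI ASCII header in ", path)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("cell count does not match header in ", path)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  mask <- m != nodata
  m[!mask] <- 0
  neg <- which(m < 0 & mask, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative production at cell (row %d, col %d) in %s",
                 neg[1, 1], neg[1, 2], path))
  }
  prey_grid(m, cell_size = hdr$cellsize, mask = mask,
            xll = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
            yll = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner)
}

#' Write a matrix or prey grid as an ESRI ASCII grid
#'
#' @param x a [prey_grid()] or a plain numeric matrix.
#' @param path output path.
#' @param nodata value used for masked cells.
#' @param cell_size,xll,yll header fields when `x` is a plain matrix.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, nodata = -9999, cell_size = 250,
                             xll = 0, yll = 0) {
  if (inherits(x, "prey_grid")) {
    m <- x$production
    m[!x$mask] <- nodata
    cell_size <- x$cell_size; xll <- x$xll; yll <- x$yll
  } else {
    m <- as.matrix(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", xll), paste("yllcorner", yll),
    paste("cellsize", cell_size), paste("NODATA_value", nodata)), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

# road class codes used throughout: 0 none, 1 secondary, 2 primary
.road_code <- c(none = 0L, secondary = 1L, primary = 2L)

#' Road-class layer
#'
#' Per-cell road classification aligned with a prey grid. The railway, when
#' present, is rasterized as class primary: it is assumed to affect tigers
#' like a primary road.
#'
#' @param classes integer matrix with values 0 (none), 1 (secondary),
#'   2 (primary).
#' @param lengths_km named numeric, polyline length per class in km
#'   (`primary`, `secondary`); taken from source geometries when available.
#' @param lines optional list of source polylines (each a list with `coords`,
#'   an n x 2 matrix in meters, and `road_class`).
#' @param cell_size cell edge in meters.
#' @return An object of class `road_layer`.
#' @export
road_layer <- function(classes, lengths_km = NULL, lines = NULL, cell_size = 250) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  if (!all(classes %in% 0:2)) stop("road classes must be 0 (none), 1 (secondary) or 2 (primary)")
  if (is.null(lengths_km)) {
    lengths_km <- c(primary = sum(classes == 2L) * cell_size / 1000,
                    secondary = sum(classes == 1L) * cell_size / 1000)
  }
  structure(list(classes = classes, lengths_km = lengths_km, lines = lines,
                 cell_size = cell_size),
            class = "road_layer")
}

#' @export
print.road_layer <- function(x, ...) {
  cat(sprintf("<road_layer> %d x %d cells; %d primary, %d secondary road cells; %.1f / %.1f km\n",
              nrow(x$classes), ncol(x$classes),
              sum(x$classes == 2L), sum(x$classes == 1L),
              x$lengths_km[["primary"]], x$lengths_km[["secondary"]]))
  invisible(x)
}

.polyline_length_m <- function(coords) {
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}

#' Read a GeoJSON road network
#'
#' Reads a FeatureCollection of LineString features carrying a `road_class`
#' property (`"primary"` or `"secondary"`). Coordinates are projected meters
#' in the grid frame (x east, y north from the grid's lower-left corner).
#'
#' @param path GeoJSON file path.
#' @return A list of polylines suitable for [rasterize_roads()].
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  lapply(feats, function(f) {
    cls <- f$properties$road_class
    if (is.null(cls) || !cls %in% c("primary", "secondary")) {
      stop("feature with unknown road_class: ", if (is.null(cls)) "<missing>" else cls)
    }
    if (!identical(f$geometry$type, "LineString")) {
      stop("only LineString geometries are supported, got ", f$geometry$type)
    }
    coords <- do.call(rbind, lapply(f$geometry$coordinates, function(p) c(p[[1]], p[[2]])))
    list(coords = coords, road_class = cls)
  })
}

#' Write road polylines as GeoJSON
#'
#' @param lines list of polylines (`coords` n x 2 matrix in meters,
#'   `road_class`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roads_geojson <- function(lines, path) {
  feats <- lapply(lines, function(l) {
    list(type = "Feature",
         properties = list(road_class = l$road_class),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(l$coords)),
                                              function(i) as.numeric(l$coords[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize road polylines onto the model grid
#'
#' Every cell whose interior is crossed by a polyline is assigned that line's
#' class; where a primary and a secondary line hit the same cell, primary
#' wins. Class lengths are reported as polyline length (km), not rasterized
#' cell count. Geometry is sampled densely (cell_size/8) along each segment,
#' which marks every crossed cell at these scales.
#'
#' @param lines list of polylines as from [read_roads_geojson()].
#' @param grid a [prey_grid()] giving dimensions, cell size and origin.
#' @return A [road_layer()].
#' @export
rasterize_roads <- function(lines, grid) {
  nr <- nrow(grid$production); nc <- ncol(grid$production)
  cs <- grid$cell_size
  classes <- matrix(0L, nr, nc)
  len_km <- c(primary = 0, secondary = 0)
  for (l in lines) {
    code <- unname(.road_code[l$road_class])
    if (is.na(code)) stop("unknown road class tag: ", l$road_class)
    len_km[l$road_class] <- len_km[l$road_class] + .polyline_length_m(l$coords) / 1000
    co <- l$coords
    for (i in seq_len(nrow(co) - 1)) {
      a <- co[i, ]; b <- co[i + 1, ]
      n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / (cs / 8)))
      xs <- seq(a[1], b[1], length.out = n)
      ys <- seq(a[2], b[2], length.out = n)
      col <- floor((xs - grid$xll) / cs) + 1L
      row <- nr - floor((ys - grid$yll) / cs)
      inb <- col >= 1 & col <= nc & row >= 1 & row <= nr
      if (!all(inb)) warning("road geometry outside grid bounds was clipped")
      idx <- cbind(row[inb], col[inb])
      classes[idx] <- pmax(classes[idx], code)
    }
  }
  road_layer(classes, lengths_km = len_km, lines = lines, cell_size = cs)
}

#' Distance to the nearest road of a class
#'
#' Exact Euclidean distance (meters, cell center to cell center) from every
#' cell to the nearest road cell of the given class, computed with an exact
#' two-pass distance transform; 0 on road cells. When the class is absent
#' the distance is `Inf` everywhere, which makes the depletion multiplier 1
#' everywhere.
#'
#' @param roads a [road_layer()].
#' @param class `"primary"` or `"secondary"`.
#' @return Numeric matrix of distances in meters.
#' @export
distance_to_class <- function(roads, class = c("primary", "secondary")) {
  class <- match.arg(class)
  code <- .road_code[[class]]
  onroad <- roads$classes == code
  cpp_edt(onroad + 0L) * roads$cell_size
}

#' Linear prey-depletion multiplier
#'
#' Prey abundance is zero on a road or railway and recovers linearly with
#' distance, reaching the undisturbed level at 5 km from a primary road or
#' railway and 2 km from a secondary road; beyond those distances prey is
#' unaffected.
#'
#' @param distance distance(s) from the road in meters; `Inf` allowed.
#' @param class `"primary"` or `"secondary"`.
#' @param params a [tiger_params()] (holds the 5000/2000 m zone widths).
#' @return Multiplier(s) in `[0, 1]`.
#' @examples
#' depletion_multiplier(0, "primary")      # 0 on the road
#' depletion_multiplier(2500, "primary")   # 0.5 at the midpoint
#' depletion_multiplier(3000, "secondary") # 1 beyond the zone
#' @export
depletion_multiplier <- function(distance, class = c("primary", "secondary"),
                                 params = tiger_params()) {
  class <- match.arg(class)
  if (any(distance < 0, na.rm = TRUE)) stop("negative distance")
  D <- if (class == "primary") params$depletion_dist_primary else params$depletion_dist_secondary
  pmin(distance / D, 1)
}

#' Apply road-induced prey depletion
#'
#' Multiplies per-cell production by the depletion multiplier. Where both
#' classes act on a cell the minimum multiplier (the stronger depletion)
#' wins, so a cell on any road has zero effective prey. The input grid is
#' not modified; applying depletion twice to the same road layer is
#' idempotent in the sense that multipliers are recomputed from distance, not
#' compounded.
#'
#' @param prey a [prey_grid()].
#' @param roads a [road_layer()] aligned with `prey`.
#' @param params a [tiger_params()].
#' @return A new [prey_grid()] with effective (depleted) production.
#' @export
apply_depletion <- function(prey, roads, params = tiger_params()) {
  if (!all(dim(prey$production) == dim(roads$classes))) {
    stop("prey grid and road layer are misaligned")
  }
  m <- pmin(
    depletion_multiplier(distance_to_class(roads, "primary"), "primary", params),
    depletion_multiplier(distance_to_class(roads, "secondary"), "secondary", params))
  out <- prey
  out$production <- prey$production * m
  out
}

#' Near-road cell mask
#'
#' Cells within 2 km of a secondary road or 5 km of a primary road (the
#' road-effect zone used to stratify occupancy into near- and far-from-road
#' cells).
#'
#' @inheritParams apply_depletion
#' @return Logical matrix.
#' @export
near_road_mask <- function(roads, params = tiger_params()) {
  distance_to_class(roads, "secondary") <= params$depletion_dist_secondary |
    distance_to_class(roads, "primary") <= params$depletion_dist_primary
}
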