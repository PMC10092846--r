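#' Longitude-latitude analysis grid
#'
#' Regular grid of half-open cells \code{[west, east) x [south, north)}.
#' The analysis resolution is 0.5 degrees; 0.25 degrees is used for
#' visualisation matrices.
#'
#' @param resolution Cell size in degrees.
#' @param lon_range,lat_range Extent, degrees.
#' @return Object of class \code{"geo_grid"}: \code{resolution},
#'   \code{lon_range}, \code{lat_range}, \code{nx}, \code{ny},
#'   \code{n_cells}. Cells are indexed column-major: west-to-east fast,
#'   south-to-north slow.
#' @export
make_grid <- function(resolution = 0.5, lon_range = c(-180, 180),
                      lat_range = c(-90, 90)) {
  stopifnot(resolution > 0, diff(lon_range) > 0, diff(lat_range) > 0)
  nx <- as.integer(round(diff(lon_range) / resolution))
  ny <- as.integer(round(diff(lat_range) / resolution))
  structure(list(resolution = resolution, lon_range = lon_range,
                 lat_range = lat_range, nx = nx, ny = ny,
                 n_cells = nx * ny), class = "geo_grid")
}

#' Cell centre coordinates
#'
#' @param grid A \code{\link{make_grid}} object.
#' @param cells Optional integer cell indices (default all).
#' @return \code{data.frame} with \code{cell}, \code{lon}, \code{lat}.
#' @export
cell_centers <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(grid$n_cells)
  ix <- (cells - 1L) %% grid$nx
  iy <- (cells - 1L) %/% grid$nx
  data.frame(cell = cells,
             lon = grid$lon_range[1] + (ix + 0.5) * grid$resolution,
             lat = grid$lat_range[1] + (iy + 0.5) * grid$resolution)
}

#' Build a species range polygon set
#'
#' Plain-vertex polygon representation: each polygon is a two-column
#' (lon, lat) matrix with integer attribute codes. Seasonal codes follow
#' the range-map convention (1 resident, 2 breeding season, 3
#' non-breeding, ...), origin codes (1 native, 2 re-introduced, ...) and
#' presence codes (1 extant, ...).
#'
#' @param species_id Taxon name.
#' @param polygons List of two-column numeric matrices (vertices in
#'   order, unclosed is fine).
#' @param seasonal,origin,presence Integer vectors, one code per
#'   polygon.
#' @return Object of class \code{"range_set"}.
#' @export
range_polygons <- function(species_id, polygons, seasonal, origin, presence) {
  stopifnot(length(polygons) == length(seasonal),
            length(polygons) == length(origin),
            length(polygons) == length(presence))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3)
    p
  })
  structure(list(species_id = species_id, polygons = polygons,
                 seasonal = as.integer(seasonal),
                 origin = as.integer(origin),
                 presence = as.integer(presence)), class = "range_set")
}

#' Filter range polygons to native breeding/resident extant records
#'
#' Keeps polygons with seasonal code 1 (resident) or 2 (breeding
#' season), origin 1 (native) or 2 (re-introduced), and presence 1
#' (extant); everything else is dropped.
#'
#' @param ranges A \code{\link{range_polygons}} object.
#' @return Filtered \code{"range_set"} (possibly with zero polygons, in
#'   which case the species is flagged by downstream steps).
#' @export
filter_ranges <- function(ranges) {
  stopifnot(inherits(ranges, "range_set"))
  keep <- ranges$seasonal %in% c(1L, 2L) &
    ranges$origin %in% c(1L, 2L) & ranges$presence == 1L
  range_polygons(ranges$species_id, ranges$polygons[keep],
                 ranges$seasonal[keep], ranges$origin[keep],
                 ranges$presence[keep])
}

# shoelace area (planar degrees^2); sign dropped
.poly_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clip of polygon p to an axis-aligned rectangle
.clip_rect <- function(p, xmin, xmax, ymin, ymax) {
  clip_half <- function(pts, keep, cross) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), 0, 2)
    prev <- pts[n, ]
    prev_in <- keep(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; cur_in <- keep(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, cross(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, cross(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  ix <- function(a, b, x) {           # intersection with vertical line
    t <- (x - a[1]) / (b[1] - a[1]); c(x, a[2] + t * (b[2] - a[2]))
  }
  iy <- function(a, b, y) {
    t <- (y - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), y)
  }
  p <- clip_half(p, function(v) v[1] >= xmin, function(a, b) ix(a, b, xmin))
  p <- clip_half(p, function(v) v[1] <= xmax, function(a, b) ix(a, b, xmax))
  p <- clip_half(p, function(v) v[2] >= ymin, function(a, b) iy(a, b, ymin))
  p <- clip_half(p, function(v) v[2] <= ymax, function(a, b) iy(a, b, ymax))
  p
}

# split polygons that extend past 180 degrees longitude (vertices may be
# given in 0..360-style continuation); returns a list of polygons in
# [-180, 180]
.split_antimeridian <- function(p) {
  lon <- p[, 1]
  # unwrap jumps > 180 into a continuous coordinate
  if (any(abs(diff(lon)) > 180)) {
    lon <- lon[1] + c(0, cumsum(((d <- diff(lon)) + 180) %% 360 - 180))
    p[, 1] <- lon
  }
  if (all(p[, 1] <= 180) && all(p[, 1] >= -180)) return(list(p))
  pieces <- list()
  lo <- floor((min(p[, 1]) + 180) / 360)
  hi <- floor((max(p[, 1]) - 1e-12 + 180) / 360)
  for (k in lo:hi) {
    piece <- .clip_rect(p, -180 + 360 * k, 180 + 360 * k, -90, 90)
    if (nrow(piece) >= 3) {
      piece[, 1] <- piece[, 1] - 360 * k
      pieces[[length(pieces) + 1L]] <- piece
    }
  }
  pieces
}

# occupied cell indices for a list of polygons
.cells_for_polys <- function(polys, grid, min_cover = 0) {
  res <- grid$resolution
  cell_area <- res * res
  occupied <- integer(0)
  for (p0 in polys) {
    for (p in .split_antimeridian(p0)) {
      xr <- range(p[, 1]); yr <- range(p[, 2])
      ix0 <- max(0L, floor((xr[1] - grid$lon_range[1]) / res))
      ix1 <- min(grid$nx - 1L, floor((xr[2] - grid$lon_range[1] - 1e-12) / res))
      iy0 <- max(0L, floor((yr[1] - grid$lat_range[1]) / res))
      iy1 <- min(grid$ny - 1L, floor((yr[2] - grid$lat_range[1] - 1e-12) / res))
      if (ix1 < ix0 || iy1 < iy0) {
        warning("polygon outside grid extent; ignored")
        next
      }
      for (iy in iy0:iy1) for (ix in ix0:ix1) {
        xmin <- grid$lon_range[1] + ix * res
        ymin <- grid$lat_range[1] + iy * res
        clip <- .clip_rect(p, xmin, xmin + res, ymin, ymin + res)
        if (nrow(clip) >= 3) {
          a <- .poly_area(clip)
          thr <- max(min_cover * cell_area, 1e-12 * cell_area)
          if (a > thr) occupied <- c(occupied, iy * grid$nx + ix + 1L)
        }
      }
    }
  }
  sort(unique(occupied))
}

#' Rasterise species ranges to a presence-absence matrix
#'
#' A cell is occupied when any retained polygon intersects it with
#' positive area (the any-overlap rule; a minimum cover fraction is
#' available for sensitivity checks).
#'
#' @param ranges A single \code{"range_set"} or a list of them (one per
#'   species), already filtered with \code{\link{filter_ranges}}.
#' @param grid A \code{\link{make_grid}} object.
#' @param min_cover Minimum covered fraction of a cell (default 0 = any
#'   positive overlap).
#' @return Object of class \code{"presence_matrix"}: sparse logical
#'   species x cell matrix (\code{Matrix}), plus \code{grid} and
#'   \code{flagged} (species with zero occupied cells).
#' @export
rasterize_presence <- function(ranges, grid, min_cover = 0) {
  if (inherits(ranges, "range_set")) ranges <- list(ranges)
  sp <- vapply(ranges, `[[`, character(1), "species_id")
  cells <- lapply(ranges, function(r) .cells_for_polys(r$polygons, grid,
                                                       min_cover))
  i <- rep(seq_along(ranges), lengths(cells))
  M <- Matrix::sparseMatrix(i = i, j = unlist(cells), x = TRUE,
                            dims = c(length(ranges), grid$n_cells),
                            dimnames = list(sp, NULL))
  structure(list(matrix = M, grid = grid,
                 flagged = sp[lengths(cells) == 0L]),
            class = "presence_matrix")
}

#' Occupied cell indices of one species
#'
#' @param pm A \code{"presence_matrix"}.
#' @param species_id Species name (row).
#' @return Integer vector of occupied cell indices.
#' @export
occupied_cells <- function(pm, species_id) {
  stopifnot(inherits(pm, "presence_matrix"))
  which(pm$matrix[species_id, ])
}

#' Range midpoint, hemisphere and climate zone
#'
#' The midpoint is the unweighted mean of occupied-cell centres. The
#' hemisphere is northern iff midpoint latitude >= 0 (equator ties break
#' north). Climate zones split at the tropics: northern temperate above
#' 23.5 N, southern temperate below 23.5 S, tropical in between.
#'
#' @param cells Integer vector of occupied cell indices.
#' @param grid The grid the cells index into.
#' @return List: \code{midpoint_lon}, \code{midpoint_lat},
#'   \code{hemisphere} ("north"/"south"), \code{climate_zone}
#'   ("north_temperate"/"south_temperate"/"tropical").
#' @export
range_midpoint <- function(cells, grid) {
  if (length(cells) < 1L) stop("no occupied cells")
  cc <- cell_centers(grid, cells)
  lat <- mean(cc$lat); lon <- mean(cc$lon)
  zone <- if (lat > 23.5) "north_temperate"
          else if (lat < -23.5) "south_temperate" else "tropical"
  list(midpoint_lon = lon, midpoint_lat = lat,
       hemisphere = if (lat >= 0) "north" else "south",
       climate_zone = zone)
}

#' Breeding-season month window for a climate zone
#'
#' Northern temperate species use March-June, southern temperate
#' September-December, tropical species the full year.
#'
#' @param zone \code{"north_temperate"}, \code{"south_temperate"} or
#'   \code{"tropical"}.
#' @return Integer vector of month indices.
#' @export
climate_months <- function(zone) {
  switch(match.arg(zone, c("north_temperate", "south_temperate", "tropical")),
         north_temperate = 3:6,
         south_temperate = 9:12,
         tropical = 1:12)
}

#' Mean climate over a species range
#'
#' For each occupied cell the mean over the selected months is taken;
#' those cell values are then averaged (unweighted) across the range.
#' Cells with no climate data are excluded from the cell average.
#'
#' @param cells Occupied cell indices.
#' @param monthly Matrix of cell x 12 monthly values aligned to the
#'   grid (rows = cell index).
#' @param months Month indices (see \code{\link{climate_months}}).
#' @return Mean value, or \code{NA} (with a warning) when every occupied
#'   cell lacks data.
#' @export
species_climate <- function(cells, monthly, months) {
  stopifnot(ncol(monthly) == 12, all(months %in% 1:12))
  vals <- rowMeans(monthly[cells, months, drop = FALSE])
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) {
    warning("no climate data over occupied cells")
    return(NA_real_)
  }
  mean(vals)
}

#' Classify a species as insular
#'
#' Marine islands are filtered to areas strictly between 1 km^2 and the
#' upper threshold (2,000,000 km^2, the size of Greenland, by default; a
#' 2,000 km^2 alternative probes small-island effects). The island layer
#' is rasterised with the fraction-greater-than-zero rule; a species is
#' insular iff the insular share of its occupied cells strictly exceeds
#' 0.9.
#'
#' @param cells Occupied cell indices of the species.
#' @param islands List of island polygons, each a two-column matrix with
#'   an \code{area_km2} attribute (or a list with elements \code{coords}
#'   and \code{area_km2}).
#' @param grid The analysis grid.
#' @param upper_area_threshold km^2, default 2e6.
#' @param lower_area_threshold km^2, default 1.
#' @param proportion_threshold Default 0.9 (strict inequality).
#' @return List: \code{insular}, \code{proportion}, \code{island_cells}.
#' @export
classify_insularity <- function(cells, islands, grid,
                                upper_area_threshold = 2e6,
                                lower_area_threshold = 1,
                                proportion_threshold = 0.9) {
  if (length(cells) < 1L) stop("no occupied cells")
  polys <- lapply(islands, function(isl) {
    if (is.list(isl) && !is.matrix(isl)) {
      if (is.null(isl$area_km2)) stop("island missing area_km2")
      structure(as.matrix(isl$coords), area_km2 = isl$area_km2)
    } else {
      if (is.null(attr(isl, "area_km2"))) stop("island missing area_km2")
      isl
    }
  })
  areas <- vapply(polys, attr, numeric(1), "area_km2")
  keep <- areas > lower_area_threshold & areas < upper_area_threshold
  island_cells <- .cells_for_polys(polys[keep], grid, min_cover = 0)
  prop <- mean(cells %in% island_cells)
  list(insular = prop > proportion_threshold, proportion = prop,
       island_cells = island_cells)
}

#' Per-species geographic summary table
#'
#' Runs the full range workflow for each species: filter, rasterise,
#' midpoint/hemisphere/zone, breeding-season climate and insularity at
#' both island-size thresholds.
#'
#' @param ranges List of \code{"range_set"} objects (one per species).
#' @param grid Analysis grid.
#' @param temperature,precipitation Cell x 12 monthly matrices.
#' @param islands Island polygon layer (see
#'   \code{\link{classify_insularity}}).
#' @return \code{data.frame}, one row per species with midpoint,
#'   hemisphere, climate zone, mean breeding-season temperature and
#'   precipitation, insularity flags at the large and small thresholds
#'   and the insular proportion. Species whose filtered range is empty
#'   get NA rows and are listed in the \code{"flagged"} attribute.
#' @export
species_geo_summary <- function(ranges, grid, temperature, precipitation,
                                islands) {
  if (inherits(ranges, "range_set")) ranges <- list(ranges)
  filtered <- lapply(ranges, filter_ranges)
  pm <- rasterize_presence(filtered, grid)
  rows <- lapply(seq_along(filtered), function(i) {
    sp <- filtered[[i]]$species_id
    base <- data.frame(species_id = sp, midpoint_lon = NA_real_,
                       midpoint_lat = NA_real_, hemisphere = NA_character_,
                       climate_zone = NA_character_,
                       mean_temperature = NA_real_,
                       mean_precipitation = NA_real_,
                       insular_large_threshold = NA,
                       insular_small_threshold = NA,
                       insular_proportion = NA_real_)
    cells <- which(pm$matrix[i, ])
    if (length(cells) == 0L) return(base)
    mp <- range_midpoint(cells, grid)
    months <- climate_months(mp$climate_zone)
    ins_l <- classify_insularity(cells, islands, grid)
    ins_s <- classify_insularity(cells, islands, grid,
                                 upper_area_threshold = 2000)
    base$midpoint_lon <- mp$midpoint_lon; base$midpoint_lat <- mp$midpoint_lat
    base$hemisphere <- mp$hemisphere; base$climate_zone <- mp$climate_zone
    base$mean_temperature <- species_climate(cells, temperature, months)
    base$mean_precipitation <- species_climate(cells, precipitation, months)
    base$insular_large_threshold <- ins_l$insular
    base$insular_small_threshold <- ins_s$insular
    base$insular_proportion <- ins_l$proportion
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "flagged") <- pm$flagged
  out
}

#' Write a presence matrix as sparse triplets
#'
#' @param pm A \code{"presence_matrix"}.
#' @param path Output TSV path (columns species, cell).
#' @export
write_presence_matrix <- function(pm, path) {
  tr <- Matrix::summary(Matrix::Matrix(pm$matrix, sparse = TRUE))
  df <- data.frame(species = rownames(pm$matrix)[tr$i], cell = tr$j)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
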