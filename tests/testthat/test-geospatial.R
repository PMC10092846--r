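test_that("range filtering keeps native breeding/resident extant polygons", {
  rs <- range_polygons("sp", list(rect_poly(0, 1, 0, 1),
                                  rect_poly(1, 2, 0, 1),
                                  rect_poly(2, 3, 0, 1),
                                  rect_poly(3, 4, 0, 1)),
                       seasonal = c(3L, 1L, 2L, 1L),
                       origin = c(1L, 1L, 2L, 1L),
                       presence = c(1L, 1L, 1L, 3L))
  kept <- filter_ranges(rs)
  # non-breeding (seasonal 3) and presence 3 dropped; the rest kept
  expect_length(kept$polygons, 2)
  expect_equal(kept$seasonal, c(1L, 2L))
})

test_that("rasterisation follows the any-overlap rule", {
  grid <- make_grid(0.5, c(0, 10), c(0, 10))
  # 1x1 degree square aligned to the half-degree grid covers 4 cells
  rs <- range_polygons("sp", list(rect_poly(2, 3, 2, 3)), 1L, 1L, 1L)
  pm <- rasterize_presence(rs, grid)
  expect_equal(sum(pm$matrix), 4)

  # a sliver covering 1% of one cell still occupies it under any-overlap
  sliver <- range_polygons("sp", list(rect_poly(2, 2.05, 2, 2.05)),
                           1L, 1L, 1L)
  expect_equal(sum(rasterize_presence(sliver, grid)$matrix), 1)
  # but not under a 5% minimum-cover rule (area fraction 0.01)
  expect_equal(sum(rasterize_presence(sliver, grid,
                                      min_cover = 0.05)$matrix), 0)

  empty <- filter_ranges(range_polygons("none", list(rect_poly(0, 1, 0, 1)),
                                        3L, 1L, 1L))
  pm0 <- rasterize_presence(empty, grid)
  expect_equal(sum(pm0$matrix), 0)
  expect_equal(pm0$flagged, "none")
})

test_that("occupancy is monotone under union and grid refinement", {
  set.seed(22)
  for (i in 1:10) {
    g5 <- make_grid(0.5, c(0, 20), c(0, 20))
    g25 <- make_grid(0.25, c(0, 20), c(0, 20))
    p1 <- rect_poly(runif(1, 0, 10), runif(1, 10, 19), runif(1, 0, 10),
                    runif(1, 10, 19))
    p2 <- rect_poly(runif(1, 0, 10), runif(1, 10, 19), runif(1, 0, 10),
                    runif(1, 10, 19))
    one <- rasterize_presence(range_polygons("s", list(p1), 1L, 1L, 1L), g5)
    both <- rasterize_presence(range_polygons("s", list(p1, p2),
                                              c(1L, 1L), c(1L, 1L),
                                              c(1L, 1L)), g5)
    expect_true(all(which(one$matrix[1, ]) %in% which(both$matrix[1, ])))
    fine <- rasterize_presence(range_polygons("s", list(p1), 1L, 1L, 1L), g25)
    expect_gte(sum(fine$matrix), sum(one$matrix))
  }
})

test_that("antimeridian-crossing polygons are split at 180 degrees", {
  grid <- make_grid(1, c(-180, 180), c(-90, 90))
  # a range spanning 170E..170W expressed as 170..190
  rs <- range_polygons("sp", list(rect_poly(170, 190, 0, 2)), 1L, 1L, 1L)
  pm <- rasterize_presence(rs, grid)
  cc <- cell_centers(grid, which(pm$matrix[1, ]))
  expect_equal(sum(pm$matrix), 40)   # 20 degrees lon x 2 degrees lat
  expect_true(any(cc$lon > 170) && any(cc$lon < -170))
  expect_false(any(cc$lon > -170 & cc$lon < 170))
})

test_that("midpoint, hemisphere and climate zone follow the rules", {
  grid <- make_grid(0.5, c(-180, 180), c(-90, 90))
  find_cell <- function(lon, lat) {
    ix <- floor((lon - grid$lon_range[1]) / 0.5)
    iy <- floor((lat - grid$lat_range[1]) / 0.5)
    as.integer(iy * grid$nx + ix + 1)
  }
  mp <- range_midpoint(c(find_cell(10.25, 40.25), find_cell(10.25, 42.25)),
                       grid)
  expect_equal(mp$midpoint_lat, 41.25)
  expect_equal(mp$climate_zone, "north_temperate")
  expect_equal(mp$hemisphere, "north")

  expect_equal(range_midpoint(find_cell(0.25, -10.25), grid)$climate_zone,
               "tropical")
  s <- range_midpoint(find_cell(5.25, -30.25), grid)
  expect_equal(s$climate_zone, "south_temperate")
  expect_equal(s$hemisphere, "south")
  # equator midpoint ties break north
  eq <- range_midpoint(c(find_cell(0.25, 0.25), find_cell(0.25, -0.25)), grid)
  expect_equal(eq$midpoint_lat, 0)
  expect_equal(eq$hemisphere, "north")
  expect_error(range_midpoint(integer(0), grid), "no occupied cells")
})

test_that("breeding-season month windows match the zone rules", {
  expect_equal(climate_months("north_temperate"), 3:6)
  expect_equal(climate_months("south_temperate"), 9:12)
  expect_equal(climate_months("tropical"), 1:12)
})

test_that("species climate averages months within cells, then cells", {
  monthly <- matrix(10, nrow = 20, ncol = 12)
  expect_equal(species_climate(1:7, monthly, 3:6), 10)

  m2 <- matrix(0, 4, 12); m2[2, ] <- 5; m2[3, ] <- 15
  expect_equal(species_climate(c(2, 3), m2, 1:12), 10)
  # order of cells is irrelevant
  expect_equal(species_climate(c(3, 2), m2, 1:12), 10)
  # cells with no data are excluded from the cell average
  m2[3, ] <- NA
  expect_equal(species_climate(c(2, 3), m2, 1:12), 5)
  expect_warning(out <- species_climate(3, m2, 1:12), "no climate data")
  expect_true(is.na(out))
})

test_that("insularity uses island area bounds and the strict 90% rule", {
  grid <- make_grid(0.5, c(0, 10), c(0, 10))
  km <- 111  # ~km per degree used by the toy geography
  mk_island <- function(x0, y0, area_km2) {
    side <- sqrt(area_km2) / km
    structure(rect_poly(x0, x0 + side, y0, y0 + side), area_km2 = area_km2)
  }
  islands <- list(mk_island(1, 1, 5e5), mk_island(9.5, 0.5, 0.5),
                  mk_island(8, 8, 3e6))
  # species wholly on a 500,000 km^2 island
  cells_on <- cupnest:::.cells_for_polys(list(islands[[1]]), grid)
  ins <- classify_insularity(cells_on, islands, grid)
  expect_true(ins$insular)
  expect_equal(ins$proportion, 1.0)
  # the 2000 km^2 upper threshold excludes that island
  ins2 <- classify_insularity(cells_on, islands, grid,
                              upper_area_threshold = 2000)
  expect_false(ins2$insular)
  expect_equal(ins2$proportion, 0)
  # sub-1 km^2 and Greenland-sized landmasses never count as islands
  cells_tiny <- cupnest:::.cells_for_polys(list(islands[[2]]), grid)
  expect_false(classify_insularity(cells_tiny, islands, grid)$insular)

  # proportions at and below 0.9 are not insular (strictly greater than)
  island_cells <- classify_insularity(cells_on, islands, grid)$island_cells
  mainland <- setdiff(seq_len(grid$n_cells), island_cells)
  mixed_half <- c(island_cells[1], mainland[1])
  expect_false(classify_insularity(mixed_half, islands, grid)$insular)
  ins9 <- classify_insularity(c(island_cells[1:9], mainland[1]), islands,
                              grid)
  expect_equal(ins9$proportion, 0.9)
  expect_false(ins9$insular)

  bad <- list(rect_poly(0, 1, 0, 1))
  expect_error(classify_insularity(1L, bad, grid), "area")
})

test_that("small-threshold island cells are a subset of the large-threshold cells", {
  grid <- make_grid(0.5, c(0, 10), c(0, 10))
  km <- 111
  mk <- function(x0, y0, a) {
    structure(rect_poly(x0, x0 + sqrt(a) / km, y0, y0 + sqrt(a) / km),
              area_km2 = a)
  }
  islands <- list(mk(1, 1, 500), mk(3, 3, 1500), mk(5, 5, 5e4), mk(8, 8, 9e5))
  all_cells <- seq_len(grid$n_cells)
  big <- classify_insularity(all_cells, islands, grid)$island_cells
  small <- classify_insularity(all_cells, islands, grid,
                               upper_area_threshold = 2000)$island_cells
  expect_true(all(small %in% big))
  expect_lt(length(small), length(big))
})

test_that("the per-species geographic summary table assembles end to end", {
  sc <- nest_scenario(seed = 5)
  geo <- simulate_geography(sc, n_geo_species = 12)
  summ <- species_geo_summary(geo$ranges, geo$grid, geo$temperature,
                              geo$precipitation, geo$islands)
  expect_equal(nrow(summ), 12)
  expect_true(all(abs(summ$midpoint_lat) <= 90, na.rm = TRUE))
  expect_true(all(summ$insular_proportion >= 0 &
                    summ$insular_proportion <= 1, na.rm = TRUE))
  # insular flags consistent with the strict 90% rule
  ok <- !is.na(summ$insular_large_threshold)
  expect_equal(summ$insular_large_threshold[ok],
               summ$insular_proportion[ok] > 0.9)
  # precipitation is uniform in the toy geography
  expect_true(all(abs(summ$mean_precipitation[ok] - 100) < 1e-9))
  p <- file.path(tempdir(), "pm.tsv")
  pm <- rasterize_presence(lapply(geo$ranges, filter_ranges), geo$grid)
  write_presence_matrix(pm, p)
  tri <- read.delim(p)
  expect_equal(sort(unique(tri$species)),
               sort(rownames(pm$matrix)[Matrix::rowSums(pm$matrix) > 0]))
})
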