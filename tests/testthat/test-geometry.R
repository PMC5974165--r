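test_that("haversine distances match the closed form on printed cases", {
  expect_equal(haversine_km(0, 0, 1, 0), 111.1949, tolerance = 1e-4)
  expect_lte(haversine_km(0, 0, 1, 0), 500)
  expect_gt(haversine_km(0, 0, 5, 0), 500)
  expect_equal(haversine_km(0, 0, 5, 0), 555.9746, tolerance = 1e-4)
  set.seed(4)
  lon1 <- runif(50, 0, 360); lat1 <- runif(50, -60, 60)
  lon2 <- runif(50, 0, 360); lat2 <- runif(50, -60, 60)
  expect_equal(haversine_km(lon1, lat1, lon2, lat2),
               oracle_haversine(lon1, lat1, lon2, lat2), tolerance = 1e-6)
})

test_that("convex hulls contain their records and match the cubic oracle", {
  tri <- tibble::tibble(lon = c(100, 110, 105), lat = c(0, 0, 8))
  h <- mcp_hull(tri, "t")
  expect_equal(nrow(h$vertices), 3)
  expect_true(all(points_are_inside <- mapply(function(x, y) {
    dist_to_ring(x, y, h$vertices$lon, h$vertices$lat) < 1e-9 ||
      oracle_in_poly(x, y, h$vertices$lon, h$vertices$lat)
  }, tri$lon, tri$lat)))
  # unit square corners plus center: 4 vertices, center interior
  sq <- tibble::tibble(lon = c(100, 101, 101, 100, 100.5),
                       lat = c(0, 0, 1, 1, 0.5))
  hs <- mcp_hull(sq, "s")
  expect_equal(nrow(hs$vertices), 4)
  expect_true(oracle_in_poly(100.5, 0.5, hs$vertices$lon, hs$vertices$lat))
  # random instances vs the O(n^3) hull oracle
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(5:50, 1)
    pts <- tibble::tibble(lon = runif(n, 100, 140), lat = runif(n, -20, 20))
    hv <- mcp_hull(pts, "r")$vertices
    ov <- oracle_hull_vertices(pts$lon, pts$lat)
    expect_setequal(paste(hv$lon, hv$lat),
                    paste(pts$lon[ov], pts$lat[ov]))
  }
})

test_that("hulls are counter-clockwise and order-invariant", {
  set.seed(30)
  pts <- tibble::tibble(lon = runif(12, 100, 140), lat = runif(12, -20, 20))
  h1 <- mcp_hull(pts, "a")$vertices
  h2 <- mcp_hull(pts[sample(12), ], "a")$vertices
  expect_setequal(paste(h1$lon, h1$lat), paste(h2$lon, h2$lat))
  area <- function(v) sum(v$lon * c(v$lat[-1], v$lat[1]) -
                            c(v$lon[-1], v$lon[1]) * v$lat) / 2
  expect_gt(area(h1), 0)
  expect_gt(area(h2), 0)
})

test_that("records straddling the antimeridian hull contiguously", {
  pts <- tibble::tibble(lon = c(179, -179, 179.5), lat = c(0, 0, 5))
  h <- mcp_hull(pts, "x")
  span <- diff(range(h$vertices$lon))
  expect_equal(span, 2)
  expect_true(all(h$vertices$lon >= 179 & h$vertices$lon <= 181))
})

test_that("degenerate record sets signal the fallback condition", {
  expect_error(mcp_hull(tibble::tibble(lon = c(1, 2), lat = c(3, 4)), "p"),
               class = "richstack_fallback")
  expect_error(
    mcp_hull(tibble::tibble(lon = c(1, 2, 3, 4), lat = c(1, 2, 3, 4)), "c"),
    class = "richstack_fallback")
  # duplicated points collapse before the count
  expect_error(
    mcp_hull(tibble::tibble(lon = c(1, 1, 2), lat = c(3, 3, 4)), "d"),
    class = "richstack_fallback")
})

test_that("geodesic buffers cover their centers and nest with radius", {
  g <- tiny_grid()
  # points near cell centers so even the 100 km buffer reaches its own center
  ctr <- cell_centers(g, point_to_cell(g, c(120, 151), c(0, -10)))
  pts <- tibble::tibble(lon = ctr$lon + 0.1, lat = ctr$lat - 0.1)
  b100 <- geodesic_buffer_cells(pts, 100, g)
  b500 <- geodesic_buffer_cells(pts, 500, g)
  b2500 <- geodesic_buffer_cells(pts, 2500, g)
  own <- point_to_cell(g, pts$lon, pts$lat)
  expect_true(all(b100[own]))
  expect_true(all(b500[b100]))
  expect_true(all(b2500[b500]))
  # every marked cell center really is within range of some point
  cc <- cell_centers(g, which(b500))
  dmin <- pmin(haversine_km(pts$lon[1], pts$lat[1], cc$lon, cc$lat),
               haversine_km(pts$lon[2], pts$lat[2], cc$lon, cc$lat))
  expect_true(all(dmin <= 500))
  # and no unmarked cell is
  cc_out <- cell_centers(g, which(!b500))
  dmin_out <- pmin(haversine_km(pts$lon[1], pts$lat[1], cc_out$lon, cc_out$lat),
                   haversine_km(pts$lon[2], pts$lat[2], cc_out$lon, cc_out$lat))
  expect_true(all(dmin_out > 500))
  expect_error(geodesic_buffer_cells(pts, -5, g), "positive")
})

test_that("rasterization follows the boundary-inclusive center rule", {
  g <- tiny_grid()
  # a polygon covering the whole extent marks every cell
  big <- structure(list(species_id = "b", vertices = tibble::tibble(
    lon = c(80, 180, 180, 80), lat = c(-40, -40, 40, 40))),
    class = "range_polygon")
  expect_true(all(rasterize_polygon(big, g)))
  # a triangle whose vertices are three adjacent cell centers marks them
  cc <- cell_centers(g)
  v <- tibble::tibble(lon = c(101, 105, 103), lat = c(-1, -1, 3))
  tri <- structure(list(species_id = "t", vertices = v),
                   class = "range_polygon")
  ras <- rasterize_polygon(tri, g)
  expect_true(all(ras[point_to_cell(g, v$lon, v$lat)]))
})

test_that("rasterization agrees with a winding-number scan off the boundary", {
  g10 <- generate_env_grid(extent = c(100, 120, -10, 10), cell_size = 2,
                           n_layers = 2, correlation = 0, seed = 2)
  set.seed(25)
  for (rep in 1:5) {
    pts <- tibble::tibble(lon = runif(6, 100, 120), lat = runif(6, -10, 10))
    poly <- mcp_hull(pts, "o")
    ras <- rasterize_polygon(poly, g10)
    cc <- cell_centers(g10)
    for (i in seq_len(nrow(cc))) {
      d <- dist_to_ring(cc$lon[i], cc$lat[i],
                        poly$vertices$lon, poly$vertices$lat)
      if (d < 1e-6) next  # boundary rule may differ between methods
      expect_equal(ras[cc$cell[i]],
                   oracle_in_poly(cc$lon[i], cc$lat[i],
                                  poly$vertices$lon, poly$vertices$lat))
    }
  }
})

test_that("polygon text rings round-trip", {
  set.seed(9)
  pts <- tibble::tibble(lon = runif(8, 100, 140), lat = runif(8, -20, 20))
  poly <- mcp_hull(pts, "spZ")
  path <- withr::local_tempfile(fileext = ".txt")
  write_range_polygon(poly, path)
  back <- read_range_polygon(path)
  expect_equal(back$species_id, "spZ")
  expect_equal(back$vertices, poly$vertices)
})
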