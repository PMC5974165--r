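fixture_ranges <- function() {
  st <- tiny_study()
  mask <- buffer_reef_mask(st$reef, st$grid, 100)
  ranges <- lapply(split(st$occurrences, st$occurrences$species_id),
                   function(occ) {
                     suppressWarnings(hybrid_range(occ, "MCP", st$grid, mask))
                   })
  list(study = st, mask = mask, ranges = unname(ranges))
}

test_that("hybrid routing partitions species across MCP, SDM and buffer", {
  st <- tiny_study()
  mask <- buffer_reef_mask(st$reef, st$grid, 100)
  rare <- st$species$species_id[st$species$n_records < 3][1]
  occ_rare <- dplyr::filter(st$occurrences, species_id == rare)
  r_mcp <- suppressWarnings(hybrid_range(occ_rare, "MCP", st$grid, mask))
  r_sdm <- suppressWarnings(hybrid_range(occ_rare, "SDM", st$grid, mask))
  expect_equal(r_mcp$provenance, "buffer500")
  expect_equal(r_sdm$provenance, "buffer500")
  # data-rich species get a real polygon, containing its on-mask record cells
  rich <- st$species$species_id[which.max(st$species$n_records)]
  occ <- dplyr::filter(st$occurrences, species_id == rich)
  r <- hybrid_range(occ, "MCP", st$grid, mask)
  expect_equal(r$provenance, "MCP")
  rec_cells <- unique(point_to_cell(st$grid, occ$lon, occ$lat))
  on_mask <- rec_cells[mask$mask[rec_cells]]
  expect_true(all(r$cells[on_mask]))
  # masking never adds cells
  poly <- mcp_hull(occ, rich)
  unmasked <- rasterize_polygon(poly, st$grid)
  unmasked[rec_cells] <- TRUE
  expect_true(all(which(r$cells) %in% which(unmasked)))
  expect_true(all(mask$mask[r$cells]))
})

test_that("an unbuffered mask triggers a warning", {
  st <- tiny_study()
  occ <- dplyr::filter(st$occurrences,
                       species_id == st$species$species_id[1])
  expect_warning(hybrid_range(occ, "MCP", st$grid, st$reef), "not buffered")
})

test_that("stacking sums ranges cellwise and validates lattices", {
  fx <- fixture_ranges()
  m <- stack_ranges(fx$ranges)
  # brute-force per-cell double loop over a window
  sub <- m$values[1:10, 1:10]
  oracle <- matrix(0L, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    for (r in fx$ranges) oracle[i, j] <- oracle[i, j] + r$cells[i, j]
  }
  expect_identical(sub, oracle)
  expect_lte(max(m$values), m$n_species)
  expect_true(all(m$values[!fx$mask$mask] == 0))
  # k identical ranges give value k inside, 0 outside
  k <- 4
  m_k <- stack_ranges(rep(fx$ranges[3], k))
  expect_setequal(unique(as.vector(m_k$values)), c(0L, k))
  # empty stack via the explicit empty map
  m0 <- empty_richness_map(fx$study$grid)
  expect_true(all(m0$values == 0))
  # lattice mismatch errors
  other <- tiny_grid(extent = c(90, 170, -20, 20))
  bad <- binary_range("x", matrix(FALSE, length(other$lat_centers),
                                  length(other$lon_centers)),
                      "MCP", other)
  expect_error(stack_ranges(c(fx$ranges[1], list(bad))), "lattice")
})

test_that("adding a range never decreases any cell", {
  fx <- fixture_ranges()
  for (k in 2:length(fx$ranges)) {
    prev <- stack_ranges(fx$ranges[seq_len(k - 1)])
    curr <- stack_ranges(fx$ranges[seq_len(k)])
    expect_true(all(curr$values >= prev$values))
  }
})

test_that("richness classes partition values with either anchoring", {
  fx <- fixture_ranges()
  m <- stack_ranges(fx$ranges)
  cls <- classify_richness(m, bin_width = 5)
  expect_identical(cls[m$values == 0], rep(0L, sum(m$values == 0)))
  nz <- m$values > 0
  expect_identical(cls[nz], as.integer(ceiling(m$values[nz] / 5)))
  # default boundaries partition 1..n with no overlap
  v <- seq_len(60)
  k <- ceiling(v / 5)
  expect_true(all(table(k) == 5))
  # anchored at the observed maximum, the top class spans (anchor-5, anchor]
  m$values[1, 1] <- 56L
  cls56 <- classify_richness(m, bin_width = 5, anchor = 56)
  top <- cls56[1, 1]
  covered <- (52:56)
  for (val in covered) {
    m2 <- m; m2$values[1, 1] <- as.integer(val)
    expect_equal(classify_richness(m2, 5, anchor = 56)[1, 1], top)
  }
  m2 <- m; m2$values[1, 1] <- 51L
  expect_equal(classify_richness(m2, 5, anchor = 56)[1, 1], top - 1L)
  expect_error(classify_richness(m, bin_width = 0), "bin_width")
})

test_that("gradient bins reproduce direct quantile computations", {
  # one populated 3-degree bin holding exactly the values 1..5
  g <- generate_env_grid(extent = c(100, 110, 0, 3), cell_size = 1,
                         n_layers = 2, correlation = 0, seed = 6,
                         land_fraction = 0.001)
  mask <- structure(list(mask = matrix(FALSE, 3, 10), buffered = TRUE,
                         lat_centers = g$lat_centers,
                         lon_centers = g$lon_centers), class = "reef_mask")
  mask$mask[1, 1:5] <- TRUE
  m <- empty_richness_map(g)
  m$values[1, 1:5] <- 1:5
  gr <- richness_gradient(m, mask, "latitude", bin_deg = 3)
  row <- gr[gr$n_cells > 0, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$median, 3)
  expect_equal(row$q1, 2)
  expect_equal(row$q3, 4)
  expect_equal(row$max, 5)
  expect_equal(row$whisker_low, 1)
  expect_equal(row$whisker_high, 5)
  expect_equal(row$min, 1)
})

test_that("a uniform map yields constant statistics and flagged empty bins", {
  st <- tiny_study()
  mask <- buffer_reef_mask(st$reef, st$grid, 100)
  m <- empty_richness_map(st$grid)
  m$values[mask$mask] <- 7L
  for (axis in c("latitude", "longitude")) {
    gr <- richness_gradient(m, mask, axis)
    busy <- gr[gr$n_cells > 0, ]
    expect_true(all(busy$median == 7 & busy$q1 == 7 & busy$q3 == 7 &
                      busy$whisker_low == 7 & busy$whisker_high == 7 &
                      busy$max == 7))
    empty <- gr[gr$n_cells == 0, ]
    expect_true(all(is.na(empty$median)))
    # boxplot ordering invariant in every populated bin
    expect_true(all(busy$whisker_low <= busy$q1 & busy$q1 <= busy$median &
                      busy$median <= busy$q3 & busy$q3 <= busy$whisker_high &
                      busy$whisker_high <= busy$max))
  }
  expect_error(richness_gradient(m, mask, "depth"), "arg")
})

test_that("a unimodal richness field peaks in the right latitude bin", {
  g <- tiny_grid()
  mask <- structure(list(mask = g$valid_mask, buffered = TRUE,
                         lat_centers = g$lat_centers,
                         lon_centers = g$lon_centers), class = "reef_mask")
  m <- empty_richness_map(g)
  cc <- cell_centers(g)
  # richness falls off with distance from 10 degrees north
  m$values[] <- as.integer(round(30 * exp(-((cc$lat - 10) / 12)^2)))
  m$values[!mask$mask] <- 0L
  gr <- richness_gradient(m, mask, "latitude")
  expect_lte(abs(gradient_peak(gr) - 10), 3 + 1.5)
})

test_that("richness maps and gradients render as ggplot objects", {
  fx <- fixture_ranges()
  m <- stack_ranges(fx$ranges)
  expect_s3_class(autoplot(m), "ggplot")
  gr <- richness_gradient(m, fx$mask, "longitude")
  expect_s3_class(autoplot(gr), "ggplot")
})
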