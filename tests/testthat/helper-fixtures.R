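# Small fast fixtures shared across test files. All are pure functions of
# their seeds.

tiny_grid <- function(seed = 11, extent = c(90, 170, -30, 30), cell_size = 2,
                      n_layers = 5, correlation = 0.6) {
  generate_env_grid(extent = extent, cell_size = cell_size,
                    n_layers = n_layers, correlation = correlation,
                    seed = seed)
}

tiny_study <- function(seed = 42) {
  synthetic_study(seed = seed, n_species = 8, n_sites = 80,
                  n_records_total = 300, extent = c(90, 170, -30, 30),
                  cell_size = 2, n_layers = 5, correlation = 0.6,
                  reef_coverage = 0.15, n_rare = 2, n_range_limited = 1)
}

# A peaked niche anchored at a given reef cell.
peaked_niche <- function(grid, reef, id = "spX", width = 0.7,
                         cell_rank = 10L) {
  cells <- which(reef$mask)
  anchor <- cells[min(cell_rank, length(cells))]
  opt <- grid_values_at(grid, anchor)[1, ]
  sds <- vapply(grid$layers, function(m) sd(as.vector(m)), 0)
  niche_spec(id, opt, setNames(sds * width, names(opt)))
}

flat_niche <- function(grid, id = "null") {
  nm <- names(grid$layers)
  niche_spec(id, setNames(rep(0, length(nm)), nm),
             setNames(rep(Inf, length(nm)), nm))
}
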