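make_pc_fixture <- function(n_layers = 3, seed = 21) {
  g <- tiny_grid(seed = seed, n_layers = n_layers)
  pca <- fit_env_pca(sample_env_cells(g, 400, seed = seed))
  list(grid = g,
       pc = project_pcs(g, pca, n_components = max(pca$n_retained, 2)))
}

test_that("feature construction yields scaled linear+quadratic pairs", {
  fx <- make_pc_fixture(n_layers = 6)
  bg <- which(fx$pc$valid_mask)[1:300]
  fs <- build_features(fx$pc, bg)
  k <- length(fx$pc$layers)
  expect_equal(nrow(fs$definitions), 2 * k)
  expect_setequal(unique(fs$definitions$transform), c("linear", "quadratic"))
  X <- feature_matrix(fs, fx$pc, bg)
  # background min/max map to exactly 0 and 1
  expect_equal(unname(apply(X, 2, min)), rep(0, 2 * k))
  expect_equal(unname(apply(X, 2, max)), rep(1, 2 * k))
  # scaling is affine, not clipped: off-background cells may exceed [0, 1]
  other <- setdiff(which(fx$pc$valid_mask), bg)
  Xo <- feature_matrix(fs, fx$pc, other)
  expect_true(any(Xo < 0 | Xo > 1))
})

test_that("constant PC layers are dropped from the feature set with a warning", {
  fx <- make_pc_fixture()
  fx$pc$layers$flat <- matrix(1, length(fx$pc$lat_centers),
                              length(fx$pc$lon_centers))
  bg <- which(fx$pc$valid_mask)[1:200]
  expect_warning(fs <- build_features(fx$pc, bg), "constant")
  expect_false(any(fs$definitions$layer == "flat"))
})

test_that("infinite shrinkage returns the uniform distribution", {
  set.seed(2)
  Xb <- matrix(runif(200), 100, 2)
  Xp <- matrix(runif(10), 5, 2)
  m <- fit_maxent(Xp, Xb, beta = 1e6)
  expect_equal(unname(m$weights), c(0, 0))
  expect_equal(m$entropy, log(100), tolerance = 1e-12)
  # uniform model scores exactly 0.5 at every background cell
  expect_equal(predict_logistic(m, Xb), rep(0.5, 100))
})

test_that("a 1-D unpenalised fit matches the root of the moment condition", {
  Xb <- matrix(c(0, 0.25, 0.5, 0.75, 1), ncol = 1)
  Xp <- matrix(c(0.5, 1), ncol = 1)  # presence mean 0.75
  m <- fit_maxent(Xp, Xb, beta = 0, tol = 1e-12, max_iter = 2000)
  # oracle: solve E_q[f](lambda) = mean presence f by 1-D root finding
  moment_gap <- function(lam) {
    q <- exp(Xb * lam)
    q <- q / sum(q)
    sum(q * Xb) - 0.75
  }
  lam_star <- uniroot(moment_gap, c(-50, 50), tol = 1e-12)$root
  expect_equal(unname(m$weights), lam_star, tolerance = 1e-4)
})

test_that("unpenalised fits match presence feature means (moment matching)", {
  set.seed(7)
  for (rep in 1:4) {
    p <- sample(2:5, 1)
    Xb <- matrix(runif(60 * p), 60, p)
    Xp <- Xb[sample(60, 12), , drop = FALSE] + matrix(rnorm(12 * p, 0, 0.05), 12, p)
    m <- fit_maxent(Xp, Xb, beta = 0, tol = 1e-12, max_iter = 5000)
    q <- exp(drop(Xb %*% m$weights) - m$log_z)
    expect_equal(drop(crossprod(Xb, q)), colMeans(Xp), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("penalised fits satisfy the KKT feature-discrepancy bounds", {
  set.seed(19)
  for (rep in 1:4) {
    p <- sample(2:6, 1)
    Xb <- matrix(runif(80 * p), 80, p)
    Xp <- Xb[sample(80, 15), , drop = FALSE]
    beta <- runif(p, 0.005, 0.05)
    m <- fit_maxent(Xp, Xb, beta = beta, tol = 1e-12, max_iter = 5000)
    q <- exp(drop(Xb %*% m$weights) - m$log_z)
    gap <- abs(colMeans(Xp) - drop(crossprod(Xb, q)))
    expect_true(all(gap <= beta + 1e-6))
    # active features sit exactly on the bound
    active <- abs(m$weights) > 1e-8
    if (any(active)) {
      expect_equal(unname(gap[active]), unname(beta[active]), tolerance = 1e-4)
    }
  }
})

test_that("the fit is convex: perturbed starts reach the same optimum", {
  set.seed(3)
  Xb <- matrix(runif(300), 100, 3)
  Xp <- Xb[sample(100, 20), ] + 0.1
  beta <- c(0.01, 0.02, 0.01)
  m0 <- fit_maxent(Xp, Xb, beta = beta, tol = 1e-10, max_iter = 3000)
  m1 <- fit_maxent(Xp, Xb, beta = beta, tol = 1e-10, max_iter = 3000,
                   init = c(2, -1, 0.5))
  expect_equal(m0$objective, m1$objective, tolerance = 1e-6)
  expect_equal(m0$weights, m1$weights, tolerance = 1e-3)
  # and identical calls are bit-deterministic
  m2 <- fit_maxent(Xp, Xb, beta = beta, tol = 1e-10, max_iter = 3000)
  expect_identical(m0$weights, m2$weights)
})

test_that("non-finite features are rejected", {
  Xb <- matrix(c(0, 1, NA, 0.5), 2, 2)
  expect_error(fit_maxent(matrix(1, 1, 2), Xb), "non-finite")
})

test_that("logistic output is a monotone transform of the raw density", {
  set.seed(5)
  Xb <- matrix(runif(200), 100, 2)
  Xp <- Xb[1:10, ] + 0.2
  m <- fit_maxent(Xp, Xb, beta = 0.01)
  raw <- predict(m, Xb, type = "raw")
  logi <- predict(m, Xb, type = "logistic")
  expect_true(all(logi > 0 & logi < 1))
  expect_equal(order(raw), order(logi))
})

test_that("AUC matches its closed-form examples and handles ties", {
  expect_equal(auc_score(c(0.9, 0.4), c(0.5, 0.1, 0.3)), 5 / 6)
  expect_equal(auc_score(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc_score(rep(0.5, 4), rep(0.5, 7)), 0.5)
  expect_error(auc_score(numeric(), 1), "non-empty")
  expect_equal(auc_interpretation(c(0.65, 0.75, 0.85, 0.95)),
               c("poor", "useful", "good", "very good"))
})

test_that("rank-based AUC equals the brute-force pairwise count exactly", {
  set.seed(13)
  for (rep in 1:6) {
    np <- sample(1:200, 1)
    nb <- sample(1:200, 1)
    # discretised scores force plenty of ties
    p <- round(runif(np), 2)
    b <- round(runif(nb), 2)
    expect_equal(auc_score(p, b), oracle_auc(p, b), tolerance = 1e-12)
  }
})

test_that("the equal sensitivity-specificity threshold matches the scan oracle", {
  expect_equal(equal_ss_threshold(c(0.8, 0.9), c(0.1, 0.2)), 0.8)
  expect_equal(equal_ss_threshold(c(0.6, 0.2), c(0.5, 0.3)),
               oracle_threshold(c(0.6, 0.2), c(0.5, 0.3)))
  set.seed(17)
  for (rep in 1:10) {
    p <- round(runif(sample(2:30, 1)), 2)
    b <- round(runif(sample(2:60, 1)), 2)
    if (max(c(p, b)) == min(c(p, b))) next
    t_star <- equal_ss_threshold(p, b)
    expect_equal(t_star, oracle_threshold(p, b))
    # argmin contract: no other candidate has a smaller sens/spec gap
    gap <- function(t) abs(mean(p >= t) - mean(b < t))
    expect_true(all(gap(t_star) <= sapply(unique(c(p, b)), gap) + 1e-12))
  }
  expect_error(equal_ss_threshold(rep(1, 3), rep(1, 5)), "identical")
})

test_that("ensembles split, evaluate, merge and binarise per species", {
  st <- tiny_study()
  mask <- buffer_reef_mask(st$reef, st$grid, 100)
  pca <- fit_env_pca(sample_env_cells(st$grid, 600, seed = 2))
  pc <- project_pcs(st$grid, pca, n_components = max(pca$n_retained, 2))
  sp <- st$species$species_id[which.max(st$species$n_records)]
  occ <- dplyr::filter(st$occurrences, species_id == sp)
  ens <- run_sdm_ensemble(occ, pc, mask, n_replicates = 4,
                          background_size = 500, seed = 77, species_id = sp)
  expect_true(ens$eligible)
  expect_equal(nrow(ens$replicates), 4)
  expect_equal(unique(ens$replicates$n_train + ens$replicates$n_test),
               ens$n_presence_cells)
  expect_equal(unique(ens$replicates$n_test),
               max(1, round(0.2 * ens$n_presence_cells)))
  # mean probability lives on the mask only, within (0, 1)
  expect_true(all(is.na(ens$mean_probability[!mask$mask])))
  vals <- ens$mean_probability[mask$mask]
  expect_true(all(vals > 0 & vals < 1))
  # binary = mean probability >= threshold, restricted to the mask
  expect_identical(ens$binary[mask$mask], vals >= ens$threshold)
  expect_false(any(ens$binary[!mask$mask]))
  # determinism per seed
  ens2 <- run_sdm_ensemble(occ, pc, mask, n_replicates = 4,
                           background_size = 500, seed = 77, species_id = sp)
  expect_identical(ens$mean_probability, ens2$mean_probability)
  expect_identical(ens$threshold, ens2$threshold)
})

test_that("species below the record floor are routed to the fallback", {
  st <- tiny_study()
  mask <- buffer_reef_mask(st$reef, st$grid, 100)
  pca <- fit_env_pca(sample_env_cells(st$grid, 600, seed = 2))
  pc <- project_pcs(st$grid, pca, n_components = max(pca$n_retained, 2))
  rare <- st$species$species_id[st$species$n_records < 3][1]
  occ <- dplyr::filter(st$occurrences, species_id == rare)
  expect_message(
    ens <- run_sdm_ensemble(occ, pc, mask, seed = 1, species_id = rare),
    "buffer fallback")
  expect_false(ens$eligible)
  expect_match(ens$reason, "presence cells")
})

test_that("the range constraint only removes cells and keeps record cells", {
  st <- tiny_study()
  mask <- buffer_reef_mask(st$reef, st$grid, 100)
  pca <- fit_env_pca(sample_env_cells(st$grid, 600, seed = 2))
  pc <- project_pcs(st$grid, pca, n_components = max(pca$n_retained, 2))
  sp <- st$species$species_id[which.max(st$species$n_records)]
  occ <- dplyr::filter(st$occurrences, species_id == sp)
  ens <- run_sdm_ensemble(occ, pc, mask, n_replicates = 3,
                          background_size = 500, seed = 77, species_id = sp)
  before <- sum(ens$binary)
  cons <- constrain_range(ens, occ, st$grid, radius_km = 2500)
  expect_lte(sum(cons$binary), before)
  # cells farther than the radius from every record are excluded
  far <- which(ens$binary &
                 !geodesic_buffer_cells(occ, 2500, st$grid))
  expect_false(any(cons$binary[far]))
  # occupied record cells that were predicted stay predicted
  rec_cells <- unique(point_to_cell(st$grid, occ$lon, occ$lat))
  kept <- rec_cells[ens$binary[rec_cells]]
  expect_true(all(cons$binary[kept]))
})
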