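logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Build linear + quadratic features from principal-component layers
#'
#' One linear and one quadratic feature per PC layer, each affinely rescaled
#' so that the background cells span exactly `[0, 1]`. Scaling is derived
#' from the background only and is not clipped: cells outside the background
#' range of a PC can map outside `[0, 1]`.
#'
#' @param pc_grid An [env_grid] of principal-component layers.
#' @param background_cells Integer cell ids of the background sample.
#' @return An object of class `feature_set`: `definitions` tibble
#'   (`feature`, `layer`, `transform`) and `scaling` tibble
#'   (`feature`, `min`, `max`).
#' @export
build_features <- function(pc_grid, background_cells) {
  layers <- grid_layer_names(pc_grid)
  if (length(layers) < 1L) abort("at least one PC layer is required.")
  X <- grid_values_at(pc_grid, background_cells)
  defs <- tibble(
    feature = as.vector(rbind(layers, paste0(layers, "_sq"))),
    layer = rep(layers, each = 2L),
    transform = rep(c("linear", "quadratic"), length(layers)))
  raw <- raw_feature_values(defs, X)
  lo <- apply(raw, 2L, min)
  hi <- apply(raw, 2L, max)
  keep <- hi - lo > 1e-12
  if (!all(keep)) {
    warn(paste0("dropping constant feature(s): ",
                paste(defs$feature[!keep], collapse = ", ")))
  }
  structure(
    list(definitions = defs[keep, ],
         scaling = tibble(feature = defs$feature[keep],
                          min = lo[keep], max = hi[keep])),
    class = "feature_set")
}

raw_feature_values <- function(defs, X) {
  out <- matrix(NA_real_, nrow(X), nrow(defs))
  colnames(out) <- defs$feature
  for (f in seq_len(nrow(defs))) {
    v <- X[, defs$layer[f]]
    out[, f] <- if (defs$transform[f] == "quadratic") v^2 else v
  }
  out
}

#' Evaluate a feature set at grid cells
#'
#' @param features A [build_features] result.
#' @param pc_grid The PC [env_grid].
#' @param cells Integer cell ids.
#' @return Numeric matrix, cells x features, scaled by the background
#'   min/max (affine, not clipped).
#' @export
feature_matrix <- function(features, pc_grid, cells) {
  X <- grid_values_at(pc_grid, cells, unique(features$definitions$layer))
  raw <- raw_feature_values(features$definitions, X)
  sweep(sweep(raw, 2L, features$scaling$min, `-`), 2L,
        features$scaling$max - features$scaling$min, `/`)
}

#' Fit a maximum-entropy presence/background distribution model
#'
#' Starting from the uniform distribution over the background cells, finds
#' the Gibbs distribution `q(x) = exp(lambda . f(x)) / Z` whose feature
#' expectations match the presence sample, by maximising the L1-penalised
#' log-likelihood
#' `mean_presence(lambda . f) - log Z(lambda) - sum_j beta_j |lambda_j|`.
#' The problem is convex; it is solved by accelerated proximal gradient
#' ascent with backtracking line search from `lambda = 0`, so the fit is
#' deterministic. At the optimum the KKT conditions bound every feature
#' discrepancy: `|E_q[f_j] - mean_presence(f_j)| <= beta_j`.
#'
#' @param presence Feature matrix of presence cells (rows = presences), or
#'   integer cell ids when `features` and `pc_grid` are supplied.
#' @param background Feature matrix (or cell ids) of background cells.
#' @param beta Nonnegative L1 penalty, scalar or per-feature vector.
#' @param features Optional [build_features] result used to turn cell ids
#'   into feature values.
#' @param pc_grid Optional PC [env_grid] (required with `features`).
#' @param tol Convergence tolerance on the penalised objective improvement.
#' @param max_iter Iteration cap.
#' @param init Optional starting weights (default all zero, the uniform
#'   distribution); the problem is convex, so any start reaches the same
#'   optimum.
#' @return An object of class `maxent_model`: `weights`, `beta`, `log_z`
#'   (over background), `entropy` (of the fitted distribution over
#'   background), `objective`, `converged`, `n_iter`, `feature_set`,
#'   `n_background`.
#' @export
fit_maxent <- function(presence, background, beta = 0, features = NULL,
                       pc_grid = NULL, tol = 1e-7, max_iter = 500L,
                       init = NULL) {
  if (!is.null(features)) {
    stopifnot(!is.null(pc_grid))
    presence <- feature_matrix(features, pc_grid, presence)
    background <- feature_matrix(features, pc_grid, background)
  }
  Xp <- as.matrix(presence)
  Xb <- as.matrix(background)
  if (nrow(Xp) < 1L) abort("at least one presence cell is required.")
  if (!all(is.finite(Xp)) || !all(is.finite(Xb))) {
    abort("non-finite feature values in presence or background.")
  }
  p <- ncol(Xb)
  beta <- rep_len(beta, p)
  if (any(beta < 0)) abort("`beta` must be nonnegative.")
  fmean <- colMeans(Xp)

  smooth_val <- function(lam) {
    s <- drop(Xb %*% lam)
    sum(fmean * lam) - logsumexp(s)
  }
  smooth_grad <- function(lam) {
    s <- drop(Xb %*% lam)
    q <- exp(s - logsumexp(s))
    fmean - drop(crossprod(Xb, q))
  }
  penalty <- function(lam) sum(beta * abs(lam))

  lam <- if (is.null(init)) numeric(p) else rep_len(as.numeric(init), p)
  y <- lam
  t_acc <- 1
  L <- 1
  obj <- smooth_val(lam) - penalty(lam)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- smooth_grad(y)
    fy <- smooth_val(y)
    repeat {
      cand <- soft_threshold(y + g / L, beta / L)
      d <- cand - y
      if (smooth_val(cand) >= fy + sum(g * d) - (L / 2) * sum(d^2) ||
          L > 1e12) break
      L <- L * 2
    }
    obj_new <- smooth_val(cand) - penalty(cand)
    if (obj_new < obj) {
      # momentum overshoot: restart acceleration from the last iterate
      y <- lam
      t_acc <- 1
      g <- smooth_grad(y)
      fy <- smooth_val(y)
      repeat {
        cand <- soft_threshold(y + g / L, beta / L)
        d <- cand - y
        if (smooth_val(cand) >= fy + sum(g * d) - (L / 2) * sum(d^2) ||
            L > 1e12) break
        L <- L * 2
      }
      obj_new <- smooth_val(cand) - penalty(cand)
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- cand + ((t_acc - 1) / t_new) * (cand - lam)
    lam_prev <- lam
    lam <- cand
    t_acc <- t_new
    L <- max(L / 1.5, 1e-8)
    if (abs(obj_new - obj) < tol && it > 1L) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  if (!converged) {
    warn(sprintf("maxent fit did not converge in %d iterations (last improvement %.3g)",
                 max_iter, abs(obj_new - obj)))
  }
  s <- drop(Xb %*% lam)
  lz <- logsumexp(s)
  q <- exp(s - lz)
  H <- -sum(q * log(pmax(q, .Machine$double.xmin)))
  names(lam) <- colnames(Xb) %||% paste0("f", seq_len(p))
  structure(
    list(weights = lam, beta = setNames(beta, names(lam)), log_z = lz,
         entropy = H, objective = obj, converged = converged, n_iter = it,
         feature_set = features, n_background = nrow(Xb)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d feature(s), %d nonzero weight(s); entropy %.4f over %d background cells%s\n",
    length(x$weights), sum(x$weights != 0), x$entropy, x$n_background,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
tidy.maxent_model <- function(x, ...) {
  tibble(feature = names(x$weights), weight = unname(x$weights),
         beta = unname(x$beta))
}

#' @export
glance.maxent_model <- function(x, ...) {
  tibble(n_features = length(x$weights),
         n_nonzero = sum(x$weights != 0),
         entropy = x$entropy, log_z = x$log_z,
         objective = x$objective, n_iter = x$n_iter,
         converged = x$converged)
}

#' Logistic suitability output of a fitted maxent model
#'
#' Transforms the raw Gibbs density `q` into the conventional logistic
#' suitability `p = exp(H) q / (1 + exp(H) q)`, where `H` is the entropy of
#' the fitted distribution over background; under this default-prevalence
#' convention a completely uninformative model scores 0.5 everywhere on the
#' background.
#'
#' @param model A [fit_maxent] model.
#' @param X Feature matrix of the cells to score, or integer cell ids when
#'   `pc_grid` is given (the model must then carry its `feature_set`).
#' @param pc_grid Optional PC [env_grid].
#' @return Numeric vector of suitabilities in (0, 1).
#' @export
predict_logistic <- function(model, X, pc_grid = NULL) {
  if (!is.null(pc_grid)) {
    if (is.null(model$feature_set)) {
      abort("model carries no feature_set; pass a feature matrix instead.")
    }
    X <- feature_matrix(model$feature_set, pc_grid, X)
  }
  log_q <- drop(as.matrix(X) %*% model$weights) - model$log_z
  plogis(model$entropy + log_q)
}

#' @export
predict.maxent_model <- function(object, newdata, pc_grid = NULL,
                                 type = c("logistic", "raw"), ...) {
  type <- match.arg(type)
  if (type == "logistic") return(predict_logistic(object, newdata, pc_grid))
  if (!is.null(pc_grid)) {
    newdata <- feature_matrix(object$feature_set, pc_grid, newdata)
  }
  exp(drop(as.matrix(newdata) %*% object$weights) - object$log_z)
}

#' Area under the ROC curve for presence vs background scores
#'
#' Rank-based AUC: the probability that a randomly chosen presence outscores
#' a randomly chosen background point, with ties counted one half. Values
#' run from 0 (worse than random) through 0.5 (no better than random) to 1
#' (perfect discrimination).
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(presence_scores, background_scores) {
  np <- length(presence_scores)
  nb <- length(background_scores)
  if (np == 0L || nb == 0L) abort("score vectors must be non-empty.")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Discrimination bands for AUC interpretation
#'
#' Conventional cutpoints: > 0.9 very good, > 0.8 good, > 0.7 useful
#' discrimination; at or below 0.7, poor.
#'
#' @param auc Numeric vector of AUC values.
#' @return Character vector of band labels.
#' @export
auc_interpretation <- function(auc) {
  cut(auc, breaks = c(-Inf, AUC_BANDS, Inf),
      labels = c("poor", "useful", "good", "very good"),
      right = TRUE) |> as.character()
}

#' @rdname auc_interpretation
#' @format `AUC_BANDS`: named numeric vector of the three cutpoints.
#' @export
AUC_BANDS <- c(useful = 0.7, good = 0.8, very_good = 0.9)

#' Equal sensitivity-specificity threshold
#'
#' The binarisation cutoff at which the fraction of presences scored at or
#' above the threshold (sensitivity) equals the fraction of background
#' scored below it (specificity), used as the minimum threshold above which
#' a species is considered present. The threshold is chosen from the
#' observed score values by exhaustive scan, minimising
#' `|sensitivity - specificity|`; ties break toward the smaller threshold
#' (the more inclusive range).
#'
#' @param presence_scores,background_scores Non-empty numeric vectors, not
#'   all values identical.
#' @return The threshold.
#' @export
equal_ss_threshold <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0L || length(background_scores) == 0L) {
    abort("score vectors must be non-empty.")
  }
  all_scores <- c(presence_scores, background_scores)
  if (max(all_scores) == min(all_scores)) {
    abort("all scores identical: degenerate model, no threshold exists.")
  }
  cand <- sort(unique(all_scores))
  gap <- vapply(cand, function(t) {
    abs(mean(presence_scores >= t) - mean(background_scores < t))
  }, 0)
  cand[which.min(gap)]  # which.min takes the first (smallest) on ties
}

#' Fit a replicate ensemble of maxent models for one species
#'
#' The full per-species distribution-modeling procedure: presence records
#' are snapped to grid cells and deduplicated; a fixed background sample of
#' analysis-mask cells is drawn once per species; `n_replicates` models are
#' fitted, each on a fresh random 80/20 train/test split of the presence
#' cells, and evaluated by test AUC against the background. The replicate
#' logistic surfaces are averaged into one probability surface, thresholded
#' at the equal sensitivity-specificity value computed on that merged
#' surface, and cut to a binary presence/absence map on the mask.
#'
#' Species with fewer distinct presence cells than `min_records` are not
#' modelable; the returned object has `eligible = FALSE` and the caller is
#' expected to fall back to geodesic buffering.
#'
#' @param occ Data frame of one species' records with columns `lon`, `lat`
#'   (and optionally `species_id`).
#' @param pc_grid PC [env_grid] of predictors.
#' @param mask Buffered `reef_mask` delimiting the analysis region.
#' @param n_replicates Number of bootstrap replicates (default 10).
#' @param train_fraction Fraction of presence cells used for training
#'   (default 0.8).
#' @param background_size Background sample size (default 10000; capped at
#'   the number of mask cells).
#' @param beta0 Regularisation scale; the per-feature penalty is
#'   `beta0 * sd(feature over background) / sqrt(n_train)`.
#' @param min_records Minimum distinct presence cells for eligibility
#'   (default 8).
#' @param seed Per-species seed (background and splits derive from it).
#' @param species_id Identifier (taken from `occ` if present).
#' @return An object of class `sdm_ensemble`. When eligible: `replicates`
#'   tibble (`replicate`, `auc_train`, `auc_test`, `n_train`, `n_test`,
#'   `converged`), `models`, `mean_probability` (full-grid matrix, `NA` off
#'   the mask), `threshold`, `binary` (logical matrix), `background_cells`,
#'   `presence_cells`, `feature_set`. When not: `eligible = FALSE` and a
#'   `reason`.
#' @export
run_sdm_ensemble <- function(occ, pc_grid, mask, n_replicates = 10,
                             train_fraction = 0.8, background_size = 10000,
                             beta0 = 1, min_records = 8, seed = 1L,
                             species_id = NULL) {
  species_id <- species_id %||%
    (if ("species_id" %in% names(occ)) occ$species_id[1] else NA_character_)
  stopifnot(train_fraction > 0, train_fraction < 1, n_replicates >= 1)
  cells <- unique(point_to_cell(pc_grid, occ$lon, occ$lat))
  cells <- cells[!is.na(cells)]
  if (length(cells) < min_records) {
    inform(sprintf(
      "species '%s': %d distinct presence cell(s) < %d required; routed to buffer fallback",
      species_id, length(cells), min_records))
    return(structure(list(species_id = species_id, eligible = FALSE,
                          n_presence_cells = length(cells),
                          reason = sprintf("%d distinct presence cells < %d",
                                           length(cells), min_records)),
                     class = "sdm_ensemble"))
  }
  mask_cells <- which(mask$mask)
  set.seed(child_seed(seed, "background", species_id))
  bg <- sort(sample(mask_cells, min(background_size, length(mask_cells))))
  fs <- build_features(pc_grid, bg)
  Xb <- feature_matrix(fs, pc_grid, bg)
  Xp <- feature_matrix(fs, pc_grid, cells)
  sd_bg <- apply(Xb, 2L, sd)
  score_cells <- sort(unique(c(mask_cells, cells)))
  Xscore <- feature_matrix(fs, pc_grid, score_cells)

  np <- length(cells)
  n_test <- max(1L, as.integer(round((1 - train_fraction) * np)))
  n_train <- np - n_test
  beta <- beta0 * sd_bg / sqrt(n_train)

  models <- vector("list", n_replicates)
  reps <- vector("list", n_replicates)
  prob_sum <- numeric(length(score_cells))
  for (r in seq_len(n_replicates)) {
    set.seed(child_seed(seed, "split", species_id, r))
    test_idx <- sample.int(np, n_test)
    train_idx <- setdiff(seq_len(np), test_idx)
    m <- withCallingHandlers(
      fit_maxent(Xp[train_idx, , drop = FALSE], Xb, beta = beta),
      warning = function(w) invokeRestart("muffleWarning"))
    bg_scores <- predict_logistic(m, Xb)
    reps[[r]] <- tibble(
      replicate = r,
      auc_train = auc_score(predict_logistic(m, Xp[train_idx, , drop = FALSE]),
                            bg_scores),
      auc_test = auc_score(predict_logistic(m, Xp[test_idx, , drop = FALSE]),
                           bg_scores),
      n_train = n_train, n_test = n_test, converged = m$converged)
    models[[r]] <- m
    prob_sum <- prob_sum + predict_logistic(m, Xscore)
  }
  mean_scores <- prob_sum / n_replicates
  pres_pos <- match(cells, score_cells)
  bg_pos <- match(bg, score_cells)
  threshold <- equal_ss_threshold(mean_scores[pres_pos], mean_scores[bg_pos])

  nr <- length(pc_grid$lat_centers)
  nc <- length(pc_grid$lon_centers)
  mean_prob <- matrix(NA_real_, nr, nc)
  mask_pos <- match(mask_cells, score_cells)
  mean_prob[mask_cells] <- mean_scores[mask_pos]
  binary <- matrix(FALSE, nr, nc)
  binary[mask_cells] <- mean_scores[mask_pos] >= threshold

  structure(
    list(species_id = species_id, eligible = TRUE,
         n_presence_cells = np,
         replicates = bind_rows(reps), models = models,
         mean_probability = mean_prob, threshold = threshold,
         binary = binary, background_cells = bg, presence_cells = cells,
         feature_set = fs, constrained = FALSE,
         lat_centers = pc_grid$lat_centers,
         lon_centers = pc_grid$lon_centers),
    class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  if (!x$eligible) {
    cat(sprintf("<sdm_ensemble> species '%s': not modelable (%s)\n",
                x$species_id, x$reason))
  } else {
    cat(sprintf(
      "<sdm_ensemble> species '%s': %d replicates, mean test AUC %.3f, threshold %.3f, %d presence cells%s\n",
      x$species_id, nrow(x$replicates), mean(x$replicates$auc_test),
      x$threshold, x$n_presence_cells,
      if (x$constrained) " (range-constrained)" else ""))
  }
  invisible(x)
}

#' @export
tidy.sdm_ensemble <- function(x, ...) {
  if (!x$eligible) {
    return(tibble(replicate = integer(), auc_train = numeric(),
                  auc_test = numeric(), n_train = integer(),
                  n_test = integer(), converged = logical()))
  }
  x$replicates
}

#' @export
glance.sdm_ensemble <- function(x, ...) {
  if (!x$eligible) {
    return(tibble(species_id = x$species_id, eligible = FALSE,
                  n_presence_cells = x$n_presence_cells,
                  mean_auc_train = NA_real_, mean_auc_test = NA_real_,
                  threshold = NA_real_, n_cells_present = NA_integer_))
  }
  tibble(species_id = x$species_id, eligible = TRUE,
         n_presence_cells = x$n_presence_cells,
         mean_auc_train = mean(x$replicates$auc_train),
         mean_auc_test = mean(x$replicates$auc_test),
         threshold = x$threshold,
         n_cells_present = sum(x$binary))
}

#' Constrain a predicted range to a geodesic disc union around the records
#'
#' For species with limited distribution ranges the purely environmental
#' prediction can overshoot into distant, unreachable seas; this intersects
#' the binary map with the union of geodesic discs (default radius 2,500 km)
#' centred on the species' occurrence records.
#'
#' @param ens An eligible [run_sdm_ensemble] result.
#' @param occ The species' records (`lon`, `lat`).
#' @param grid The [env_grid] lattice.
#' @param radius_km Disc radius in km (default 2500).
#' @return The ensemble with its `binary` map constrained and
#'   `constrained = TRUE`.
#' @export
constrain_range <- function(ens, occ, grid, radius_km = 2500) {
  stopifnot(inherits(ens, "sdm_ensemble"), isTRUE(ens$eligible))
  allowed <- geodesic_buffer_cells(occ, radius_km, grid)
  ens$binary <- ens$binary & allowed
  ens$constrained <- TRUE
  ens
}
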