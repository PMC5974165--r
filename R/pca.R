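#' Sample environmental values at random valid cells
#'
#' Draws `n` distinct marine cells without replacement and returns their
#' environmental values; this is the sample the principal component analysis
#' is fitted on before being projected back to the whole grid.
#'
#' @param grid An [env_grid].
#' @param n Number of cells, at most the number of valid cells.
#' @param seed Integer seed.
#' @return A tibble with columns `cell`, `lon`, `lat` and one column per
#'   environmental layer.
#' @export
sample_env_cells <- function(grid, n = 10000, seed = 1L) {
  valid <- which(grid$valid_mask)
  if (n > length(valid)) {
    abort(sprintf("requested %d cells but only %d valid cells are available",
                  n, length(valid)))
  }
  set.seed(as.integer(seed))
  cells <- sort(sample(valid, n))
  cc <- cell_centers(grid, cells)
  vals <- as_tibble(as.data.frame(grid_values_at(grid, cells)))
  dplyr::bind_cols(cc, vals)
}

#' Principal component analysis of environmental variables
#'
#' Correlation-matrix PCA (each variable standardised to mean 0, sd 1) of a
#' table of sampled environmental values, removing multi-collinearity among
#' predictors. Components are retained by the Kaiser rule (eigenvalue > 1).
#' Loading signs follow a fixed convention — the largest-magnitude loading of
#' each component is positive — so results are reproducible across runs.
#'
#' @param samples Data frame of sampled values; columns named `cell`, `lon`,
#'   `lat` are treated as metadata and excluded from the analysis.
#' @return An object of class `env_pca` with elements `loadings`
#'   (variables x components, orthonormal columns), `eigenvalues`
#'   (non-increasing), `variance_fraction` (sums to 1), `n_retained`,
#'   `means`, `sds`, `sample_cells`, `n_rows`.
#' @export
fit_env_pca <- function(samples) {
  meta <- intersect(c("cell", "lon", "lat"), names(samples))
  vars <- setdiff(names(samples), meta)
  if (length(vars) < 2L) abort("PCA needs at least 2 variables.")
  X <- as.matrix(samples[vars])
  if (!is.numeric(X)) abort("environmental columns must be numeric.")
  if (nrow(X) < 2L) abort("PCA needs at least 2 rows.")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    abort(paste0("constant column(s) with zero variance: ",
                 paste(vars[sds == 0], collapse = ", ")))
  }
  if (nrow(X) < ncol(X)) {
    warn(sprintf("fewer rows (%d) than variables (%d); PCA is rank-deficient",
                 nrow(X), ncol(X)))
  }
  means <- colMeans(X)
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  load <- pc$rotation
  # deterministic sign: largest-magnitude loading of each component positive
  for (k in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, k])), k] < 0) load[, k] <- -load[, k]
  }
  structure(
    list(loadings = load,
         eigenvalues = ev,
         variance_fraction = ev / sum(ev),
         n_retained = sum(ev > 1),
         means = means, sds = sds,
         sample_cells = if ("cell" %in% names(samples)) samples$cell else NULL,
         n_rows = nrow(X)),
    class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf(
    "<env_pca> %d variables, %d rows; %d component(s) retained (Kaiser), %.2f%% of variance\n",
    nrow(x$loadings), x$n_rows, x$n_retained,
    100 * sum(x$variance_fraction[seq_len(max(x$n_retained, 1))])))
  invisible(x)
}

#' @export
tidy.env_pca <- function(x, ...) {
  load <- x$loadings
  tibble(variable = rep(rownames(load), ncol(load)),
         component = rep(colnames(load), each = nrow(load)),
         loading = as.vector(load))
}

#' @export
glance.env_pca <- function(x, ...) {
  k <- x$n_retained
  tibble(n_variables = nrow(x$loadings),
         n_rows = x$n_rows,
         n_retained = k,
         variance_retained = sum(x$variance_fraction[seq_len(max(k, 1))]) *
           (k > 0),
         eigenvalue_1 = x$eigenvalues[1])
}

#' Project principal components into geographic space
#'
#' Applies the standardisation and loadings of a fitted [fit_env_pca] to
#' every grid cell, producing a new raster stack whose layers are the
#' retained principal-component scores.
#'
#' @param grid An [env_grid] with the variables the PCA was fitted on.
#' @param pca An `env_pca`.
#' @param n_components Number of leading components to project (default: the
#'   Kaiser-retained count).
#' @return An [env_grid] with layers `PC1`, `PC2`, ...
#' @export
project_pcs <- function(grid, pca, n_components = NULL) {
  k <- n_components %||% pca$n_retained
  if (k < 1L) abort("no components to project (n_retained is 0).")
  vars <- rownames(pca$loadings)
  missing <- setdiff(vars, grid_layer_names(grid))
  if (length(missing)) {
    abort(paste0("grid lacks variable(s) required by the PCA: ",
                 paste(missing, collapse = ", ")))
  }
  cells <- seq_len(n_grid_cells(grid))
  X <- grid_values_at(grid, cells, vars)
  Xs <- sweep(sweep(X, 2L, pca$means[vars], `-`), 2L, pca$sds[vars], `/`)
  scores <- Xs %*% pca$loadings[vars, seq_len(k), drop = FALSE]
  nr <- length(grid$lat_centers)
  nc <- length(grid$lon_centers)
  layers <- lapply(seq_len(k), function(j) matrix(scores[, j], nr, nc))
  names(layers) <- colnames(pca$loadings)[seq_len(k)]
  env_grid(layers, grid$lat_centers, grid$lon_centers, grid$cell_size,
           grid$valid_mask)
}

#' Serialize a fitted PCA to a JSON sidecar
#'
#' @param pca An `env_pca`.
#' @param path Output file.
#' @return `read_env_pca()` returns the `env_pca`.
#' @export
write_env_pca <- function(pca, path) {
  jsonlite::write_json(
    list(variables = rownames(pca$loadings),
         components = colnames(pca$loadings),
         loadings = unclass(as.data.frame(pca$loadings)),
         eigenvalues = pca$eigenvalues,
         variance_fraction = pca$variance_fraction,
         n_retained = pca$n_retained,
         means = as.list(pca$means), sds = as.list(pca$sds),
         sample_cells = pca$sample_cells, n_rows = pca$n_rows),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_env_pca
#' @export
read_env_pca <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  load <- as.matrix(as.data.frame(j$loadings))
  rownames(load) <- j$variables
  colnames(load) <- j$components
  structure(
    list(loadings = load, eigenvalues = j$eigenvalues,
         variance_fraction = j$variance_fraction, n_retained = j$n_retained,
         means = unlist(j$means)[j$variables],
         sds = unlist(j$sds)[j$variables],
         sample_cells = j$sample_cells, n_rows = j$n_rows),
    class = "env_pca")
}
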