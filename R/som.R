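#' Grid coordinate helpers
#'
#' Units are indexed 1..grid_side^2 in row-major order with row 1 at the top:
#' unit `u` sits at row `(u - 1) %/% side + 1`, column `(u - 1) %% side + 1`.
#' `grid_from_units()` folds a unit-ordered vector into the grid matrix;
#' `units_from_grid()` is its inverse.
#'
#' @param side grid side length.
#' @param u unit indices.
#' @name grid-helpers
NULL

#' @rdname grid-helpers
#' @export
unit_coords <- function(u, side) {
  cbind(row = (u - 1) %/% side + 1, col = (u - 1) %% side + 1)
}

#' @rdname grid-helpers
#' @param values numeric vector of length `side^2` in unit order.
#' @export
grid_from_units <- function(values, side) {
  matrix(values, side, side, byrow = TRUE)
}

#' @rdname grid-helpers
#' @param grid a `side x side` matrix.
#' @export
units_from_grid <- function(grid) as.vector(t(grid))

#' Training schedule for the batch SOM
#'
#' Two-phase batch training with a Gaussian neighborhood: a coarse ordering
#' phase shrinking the radius from half the grid side to 3 units, then a
#' fine-tuning phase shrinking it from 3 to 1. Radii decay linearly per
#' epoch within each phase. Initialization spans the lattice linearly over
#' the first two principal components of the combined profiles, which makes
#' training deterministic.
#'
#' @param epochs_phase1,epochs_phase2 epoch counts for the two phases.
#' @param radius_start phase-1 start radius; `NULL` means `grid_side / 2`.
#' @param radius_mid radius at the phase boundary.
#' @param radius_end final radius. The default ends below one grid unit:
#'   with a Gaussian kernel of width 1 a direct neighbour still receives
#'   61% of the central weight, which blends prototypes across module
#'   borders; 0.7 keeps mild topological coupling while letting boundary
#'   units specialize.
#' @param init initialization scheme; only `"pca"` is implemented.
#' @return a `som_config` list.
#' @export
som_config <- function(epochs_phase1 = 20, epochs_phase2 = 30,
                       radius_start = NULL, radius_mid = 3, radius_end = 0.7,
                       init = "pca") {
  structure(list(epochs_phase1 = epochs_phase1, epochs_phase2 = epochs_phase2,
                 radius_start = radius_start, radius_mid = radius_mid,
                 radius_end = radius_end, init = match.arg(init, "pca")),
            class = "som_config")
}

# squared Euclidean distances between rows of X (n x d) and rows of W (m x d)
cross_dist2 <- function(X, W) {
  d2 <- outer(rowSums(X^2), rowSums(W^2), "+") - 2 * tcrossprod(X, W)
  d2[d2 < 0] <- 0
  d2
}

#' Train a self-organizing map on combined multi-omics profiles
#'
#' Batch Kohonen training on a quadratic grid. Each epoch assigns every gene
#' to its best-matching unit (BMU, smallest Euclidean distance, ties to the
#' lowest unit index) and replaces every unit vector by the Gaussian-kernel
#' weighted mean of the gene vectors, with kernel width set by the current
#' neighborhood radius. The trained units are the "metagenes"; the final
#' gene-to-unit assignment is the exact argmin over unit distances.
#'
#' @param profiles a `combined_profiles` object from [combine_modalities()].
#' @param grid_side side length of the quadratic grid (default 45).
#' @param config a [som_config()].
#' @param seed integer seed recorded in the model; training itself is
#'   deterministic (PCA initialization), the seed also guards any future
#'   stochastic scheme.
#' @return a `som_model`: `unit_vectors` (grid_side^2 x 3S), `assignment`
#'   (named unit index per gene), `weights`, `block_boundaries`,
#'   `sample_ids`, `grid_side`, `training_config`, and the quantization
#'   error at initialization and after each phase (`qe`).
#' @export
train_som <- function(profiles, grid_side = 45, config = som_config(),
                      seed = 1L) {
  stopifnot(inherits(profiles, "combined_profiles"))
  X <- profiles$vectors
  if (!all(is.finite(X))) stop("combined profiles contain non-finite values")
  if (grid_side < 2) stop("grid_side must be >= 2")
  n_units <- grid_side^2
  if (nrow(X) < n_units / 10)
    warning("fewer than grid_side^2 / 10 genes; the map will be sparsely populated")
  set.seed(as.integer(seed))

  coords <- unit_coords(seq_len(n_units), grid_side)
  grid_d2 <- cross_dist2(coords, coords)

  # PCA lattice initialization: span the grid over the first two PCs
  W <- som_init_pca(X, coords, grid_side)

  cfg <- config
  if (is.null(cfg$radius_start)) cfg$radius_start <- grid_side / 2
  radii <- c(
    seq(cfg$radius_start, cfg$radius_mid, length.out = max(cfg$epochs_phase1, 1)),
    seq(cfg$radius_mid, cfg$radius_end, length.out = max(cfg$epochs_phase2, 1)))
  qe <- numeric(0)
  d2 <- cross_dist2(X, W)
  qe["init"] <- mean(sqrt(apply(d2, 1, min)))

  phase_end <- cumsum(c(max(cfg$epochs_phase1, 1), max(cfg$epochs_phase2, 1)))
  for (e in seq_along(radii)) {
    bmu <- max.col(-d2, ties.method = "first")
    H <- exp(-grid_d2 / (2 * radii[e]^2))    # units x units kernel
    rs <- rowsum(X, bmu)
    sums <- matrix(0, n_units, ncol(X))
    sums[as.integer(rownames(rs)), ] <- rs
    counts <- tabulate(bmu, nbins = n_units)
    W <- (H %*% sums) / as.vector(H %*% counts)
    d2 <- cross_dist2(X, W)
    if (e %in% phase_end)
      qe[paste0("phase", which(phase_end == e))] <- mean(sqrt(apply(d2, 1, min)))
  }
  assignment <- max.col(-d2, ties.method = "first")
  names(assignment) <- rownames(X)
  dimnames(W) <- list(NULL, colnames(X))

  structure(list(grid_side = grid_side, unit_vectors = W,
                 weights = profiles$weights,
                 block_boundaries = profiles$block_boundaries,
                 sample_ids = profiles$sample_ids,
                 assignment = assignment,
                 training_config = c(cfg, list(seed = as.integer(seed))),
                 qe = qe),
            class = "som_model")
}

som_init_pca <- function(X, coords, grid_side) {
  Xc <- sweep(X, 2, colMeans(X))
  # right singular vectors via the small Gram matrix; deterministic sign fix
  sv <- La.svd(Xc, nu = 0, nv = 2)
  v <- t(sv$vt[1:2, , drop = FALSE])
  for (j in 1:2) if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  sdev <- sv$d[1:2] / sqrt(max(nrow(X) - 1, 1))
  ax <- 2 * sdev[1] * (2 * (coords[, "col"] - 1) / (grid_side - 1) - 1)
  ay <- 2 * sdev[2] * (2 * (coords[, "row"] - 1) / (grid_side - 1) - 1)
  matrix(colMeans(X), nrow(coords), ncol(X), byrow = TRUE) +
    ax %*% t(v[, 1]) + ay %*% t(v[, 2])
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %dx%d grid, %d genes, %d samples, weights %s\n",
              x$grid_side, x$grid_side, length(x$assignment),
              length(x$sample_ids),
              paste(format(unclass(x$weights), digits = 3), collapse = "/")))
  cat("  quantization error:",
      paste(names(x$qe), format(x$qe, digits = 4), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Assign genes to their best-matching units
#'
#' Exhaustive nearest-unit search in Euclidean distance; ties broken by the
#' lowest unit index.
#'
#' @param profiles a `combined_profiles` (or any matrix with matching vector
#'   length in `$vectors`).
#' @param model a `som_model`.
#' @return named integer vector of unit indices per gene.
#' @export
assign_bmu <- function(profiles, model) {
  X <- if (inherits(profiles, "combined_profiles")) profiles$vectors else profiles
  if (ncol(X) != ncol(model$unit_vectors))
    stop("vector length mismatch: profiles have ", ncol(X),
         " entries, units ", ncol(model$unit_vectors))
  d2 <- cross_dist2(X, model$unit_vectors)
  bmu <- max.col(-d2, ties.method = "first")
  names(bmu) <- rownames(X)
  bmu
}

#' Count genes per map unit
#'
#' @param model a `som_model`.
#' @return `grid_side x grid_side` integer matrix; entries sum to the number
#'   of genes.
#' @export
population_map <- function(model) {
  stopifnot(inherits(model, "som_model"))
  counts <- tabulate(model$assignment, nbins = model$grid_side^2)
  grid_from_units(counts, model$grid_side)
}
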