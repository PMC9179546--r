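#' Centralize a matrix by removing per-gene means
#'
#' Subtracts from every gene row its mean over all samples, so each gene's
#' profile expresses the deviation from its cohort average (the delta scores
#' used throughout the portrayal).
#'
#' @param x an [omics_matrix()], not yet centralized, with at least two
#'   samples.
#' @return the centralized [omics_matrix()].
#' @export
centralize <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$centralized) stop("matrix is already centralized")
  if (ncol(x$values) < 2)
    stop("centralization needs >= 2 samples (row mean of one value is degenerate)")
  v <- x$values - rowMeans(x$values)
  omics_matrix(v, x$modality, centralized = TRUE, harmonized = FALSE)
}

#' Harmonize modality scales across a dataset
#'
#' Divides each modality's centralized matrix by that modality's global
#' standard deviation computed over all its entries, making the numeric
#' scales of expression, methylation and copy-number scores comparable
#' before they are merged. An all-constant modality (global SD 0) is left
#' as zeros with a warning.
#'
#' @param dataset a [multiomics_dataset()] whose three matrices are
#'   centralized.
#' @return the dataset with harmonized matrices.
#' @export
harmonize <- function(dataset) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  h <- lapply(dataset[c("gex", "dme", "cnv")], function(m) {
    if (!m$centralized)
      stop("harmonize() requires centralized matrices (", m$modality, " is not)")
    s <- stats::sd(as.vector(m$values))
    if (s == 0) {
      warning("modality ", m$modality, " has zero global SD; left unscaled")
      return(omics_matrix(m$values, m$modality, centralized = TRUE,
                          harmonized = TRUE))
    }
    omics_matrix(m$values / s, m$modality, centralized = TRUE,
                 harmonized = TRUE)
  })
  multiomics_dataset(h$gex, h$dme, h$cnv, dataset$annotations,
                     dataset$gene_sets)
}

#' Merge the three omics layers into weighted combined profiles
#'
#' Per gene, the three sample-length profiles are concatenated into one
#' vector of length `3 * S` with fixed block order Gex, Dme, CNV; block `b`
#' is multiplied by its weight `w_b`. Euclidean distance between two combined
#' vectors then decomposes as `sqrt(sum_b w_b^2 * d_b^2)` over per-modality
#' distances, so the weights set the relative influence of each layer on the
#' map topology.
#'
#' @param dataset a harmonized [multiomics_dataset()].
#' @param weights a [weight_config()] or preset name accepted by
#'   [weight_preset()].
#' @return a `combined_profiles` object: matrix `vectors` (genes x 3S),
#'   `weights`, `block_boundaries`, `sample_ids`.
#' @export
combine_modalities <- function(dataset, weights = weight_preset("balanced")) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  if (is.character(weights)) weights <- weight_preset(weights)
  if (!inherits(weights, "weight_config"))
    stop("'weights' must be a weight_config or preset name")
  mats <- dataset[c("gex", "dme", "cnv")]
  for (m in mats)
    if (!m$harmonized) stop("combine_modalities() requires harmonized matrices")
  s <- ncol(mats$gex$values)
  blocks <- lapply(seq_along(MODALITIES), function(b)
    mats[[b]]$values * unclass(weights)[b])
  vectors <- do.call(cbind, blocks)
  colnames(vectors) <- paste(rep(MODALITIES, each = s),
                             rep(colnames(mats$gex$values), 3), sep = ".")
  bb <- lapply(seq_along(MODALITIES), function(b) ((b - 1) * s + 1):(b * s))
  names(bb) <- MODALITIES
  structure(list(vectors = vectors, weights = weights,
                 block_boundaries = bb,
                 sample_ids = colnames(mats$gex$values)),
            class = "combined_profiles")
}

#' @export
print.combined_profiles <- function(x, ...) {
  cat(sprintf("<combined_profiles> %d genes x %d samples x 3 modalities (w = %s)\n",
              nrow(x$vectors), length(x$sample_ids),
              paste(format(unclass(x$weights), digits = 3), collapse = "/")))
  invisible(x)
}

#' Decompose trained metagenes into per-modality components
#'
#' Inverts the weighted block concatenation: block `b` of every unit vector
#' is divided by its weight `w_b`, recovering metagene matrices on the
#' harmonized single-omics scale. A modality trained with weight 0 carries no
#' information and is returned as all-`NA` with a warning.
#'
#' @param model a `som_model` from [train_som()].
#' @return named list `Gex`/`Dme`/`CNV` of unit-by-sample metagene matrices.
#' @export
decompose_model <- function(model) {
  stopifnot(inherits(model, "som_model"))
  w <- unclass(model$weights)
  bb <- model$block_boundaries
  s <- length(model$sample_ids)
  if (!identical(sort(unname(unlist(bb))), seq_len(3 * s)) ||
      !all(lengths(bb) == s))
    stop("corrupted block boundaries in model")
  out <- lapply(seq_along(MODALITIES), function(b) {
    block <- model$unit_vectors[, bb[[b]], drop = FALSE]
    colnames(block) <- model$sample_ids
    if (w[b] == 0) {
      warning("modality ", MODALITIES[b],
              " was trained with weight 0; returning NA component")
      block[] <- NA_real_
      return(block)
    }
    block / w[b]
  })
  names(out) <- MODALITIES
  out
}
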