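#' Portrait objects
#'
#' A portrait is one grid-valued map: a sample's metagene scores in one
#' modality, a group mean, a variance map, a ScoV map or a hazard-ratio map.
#' Only the numeric grid is part of the contract; rendering is a side effect.
#'
#' @param grid `side x side` numeric matrix.
#' @param kind what the grid holds: a modality or a derived-map tag.
#' @param subject sample id, group label or `"global"`.
#' @return a `portrait` object.
#' @export
portrait <- function(grid, kind, subject = "global") {
  if (!is.matrix(grid) || nrow(grid) != ncol(grid))
    stop("portrait grid must be a square matrix")
  allow_na <- kind %in% c("HR", "ScoV", "Gex", "Dme", "CNV")
  if (!allow_na && any(!is.finite(grid)))
    stop("non-finite entries in a ", kind, " portrait")
  structure(list(grid = grid, kind = kind, subject = subject),
            class = "portrait")
}

#' @export
print.portrait <- function(x, ...) {
  cat(sprintf("<portrait> %s of %s (%dx%d), range [%.3g, %.3g]\n",
              x$kind, x$subject, nrow(x$grid), ncol(x$grid),
              min(x$grid, na.rm = TRUE), max(x$grid, na.rm = TRUE)))
  invisible(x)
}

#' Render one sample's metagene portrait in one modality
#'
#' Grid cell (r, c) carries the decomposed metagene score of the unit at that
#' position for the chosen sample. Because all modalities share the trained
#' grid, the Gex, Dme and CNV portraits of a sample are aligned cell by cell
#' and gene by gene.
#'
#' @param model a `som_model`.
#' @param decomposed output of [decompose_model()].
#' @param sample_id sample identifier.
#' @param modality `"Gex"`, `"Dme"` or `"CNV"`.
#' @return a [portrait()].
#' @export
sample_portrait <- function(model, decomposed, sample_id,
                            modality = c("Gex", "Dme", "CNV")) {
  modality <- match.arg(modality)
  if (!sample_id %in% model$sample_ids)
    stop("unknown sample: ", sample_id)
  vals <- decomposed[[modality]][, sample_id]
  portrait(grid_from_units(vals, model$grid_side), modality, sample_id)
}

#' Average portraits cell-wise over a sample group
#'
#' @param portraits non-empty list of [portrait()] objects on the same grid.
#' @param label group label recorded as the subject.
#' @return a [portrait()] holding the cell-wise arithmetic mean.
#' @export
group_mean_portrait <- function(portraits, label = "group") {
  if (length(portraits) == 0) stop("empty group")
  dims <- vapply(portraits, function(p) dim(p$grid), numeric(2))
  if (any(dims != dims[, 1])) stop("portraits disagree in grid shape")
  acc <- Reduce(`+`, lapply(portraits, `[[`, "grid"))
  portrait(acc / length(portraits), portraits[[1]]$kind, label)
}

group_mean_from_units <- function(decomposed, modality, samples, side, label) {
  vals <- rowMeans(decomposed[[modality]][, samples, drop = FALSE])
  portrait(grid_from_units(vals, side), modality, label)
}

#' Map the cross-sample variance of each metagene
#'
#' Cell value is the variance (denominator S - 1) of that unit's decomposed
#' metagene profile across all samples; high-variance regions mark where the
#' modality differentiates the cohort.
#'
#' @param decomposed output of [decompose_model()].
#' @param modality modality to map.
#' @param side grid side length.
#' @return a [portrait()] of kind `"Variance"`.
#' @export
variance_map <- function(decomposed, modality, side) {
  m <- decomposed[[modality]]
  if (ncol(m) < 2) stop("variance map needs >= 2 samples")
  v <- apply(m, 1, stats::var)
  portrait(grid_from_units(v, side), "Variance", modality)
}

#' Map the mean gene-to-metagene covariance per unit
#'
#' For each unit, the mean over its assigned genes of the covariance (across
#' samples) between the gene's harmonized profile and the unit's decomposed
#' metagene profile. Empty units map to 0. High values mark units whose
#' metagene tightly represents many genes.
#'
#' @param model a `som_model`.
#' @param dataset the harmonized [multiomics_dataset()] used for training.
#' @param modality modality to map.
#' @return a [portrait()] of kind `"Covariance"`.
#' @export
metagene_covariance_map <- function(model, dataset,
                                    modality = c("Gex", "Dme", "CNV")) {
  modality <- match.arg(modality)
  dec <- decompose_model(model)
  slot <- c(Gex = "gex", Dme = "dme", CNV = "cnv")[[modality]]
  G <- dataset[[slot]]$values
  M <- dec[[modality]]
  n_units <- model$grid_side^2
  s <- ncol(G)
  # cov(gene, metagene) = (gene - mean) . (meta - mean) / (S - 1), per gene
  Gc <- G - rowMeans(G)
  Mc <- M - rowMeans(M)
  bmu <- model$assignment[rownames(G)]
  cov_gm <- rowSums(Gc * Mc[bmu, , drop = FALSE]) / (s - 1)
  sums <- numeric(n_units)
  rs <- rowsum(cov_gm, bmu)
  sums[as.integer(rownames(rs))] <- rs
  counts <- tabulate(bmu, nbins = n_units)
  vals <- ifelse(counts > 0, sums / pmax(counts, 1), 0)
  portrait(grid_from_units(vals, model$grid_side), "Covariance", modality)
}

#' Build the per-group mean portraits for all groups and modalities
#'
#' Convenience wrapper used by the spot summary and the pipeline.
#'
#' @param model a `som_model`.
#' @param decomposed output of [decompose_model()].
#' @param annotations annotation data frame with `sample_id` and `group`.
#' @return nested list: `[[group]][[modality]]` of [portrait()]s.
#' @export
group_portraits <- function(model, decomposed, annotations) {
  ann <- validate_annotations(annotations)
  groups <- unique(ann$group)
  out <- lapply(groups, function(g) {
    samples <- intersect(ann$sample_id[ann$group == g], model$sample_ids)
    if (length(samples) == 0) stop("group ", g, " has no samples in the model")
    mods <- lapply(MODALITIES, function(m) {
      if (all(is.na(decomposed[[m]]))) return(NULL)
      group_mean_from_units(decomposed, m, samples, model$grid_side, g)
    })
    names(mods) <- MODALITIES
    mods[!vapply(mods, is.null, logical(1))]
  })
  names(out) <- groups
  out
}
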