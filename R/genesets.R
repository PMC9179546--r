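#' Sample-wise gene-set Z score (GSZ)
#'
#' For each sample, the set's mean centralized score is contrasted with the
#' all-gene mean of that sample and scaled by the all-gene standard
#' deviation over sqrt of the set size:
#' `GSZ_s = (mean_members - mean_all) / (sd_all / sqrt(n_members))`.
#' A positive GSZ means the set's genes score above the sample's background
#' in that modality; the score is invariant to rescaling the matrix.
#'
#' @param x a centralized [omics_matrix()].
#' @param set a [gene_set()]; membership is intersected with the matrix's
#'   gene ids.
#' @return a `gsz_result`: `set_name`, `modality`, `scores` (named per
#'   sample), `n_members` (overlap size).
#' @export
gsz <- function(x, set) {
  stopifnot(inherits(x, "omics_matrix"), inherits(set, "gene_set"))
  members <- intersect(set$members, rownames(x$values))
  if (length(members) == 0)
    stop("gene set '", set$name, "' shares no genes with the matrix")
  v <- x$values
  mu_all <- colMeans(v)
  sd_all <- apply(v, 2, stats::sd)
  mu_set <- colMeans(v[members, , drop = FALSE])
  scores <- (mu_set - mu_all) / (sd_all / sqrt(length(members)))
  structure(list(set_name = set$name, modality = x$modality,
                 scores = scores, n_members = length(members)),
            class = "gsz_result")
}

#' Ternary Gex/Dme/CNV composition of gene-set scores
#'
#' Transforms the three modality GSZ scores of each sample into percentages
#' of their absolute values, `p_b = 100 * |GSZ_b| / sum_b |GSZ_b|`, keeping
#' the signs as separate tags. Samples whose three scores are all zero get
#' `(0, 0, 0)` and are flagged degenerate.
#'
#' @param gsz_e,gsz_m,gsz_c `gsz_result`s of the same set in the three
#'   modalities, over the same samples.
#' @return data frame: `sample_id`, `p_Gex`, `p_Dme`, `p_CNV`, sign columns,
#'   `degenerate`.
#' @export
ternary_coordinates <- function(gsz_e, gsz_m, gsz_c) {
  ids <- names(gsz_e$scores)
  if (!identical(ids, names(gsz_m$scores)) ||
      !identical(ids, names(gsz_c$scores)))
    stop("the three GSZ results cover different samples")
  z <- cbind(Gex = gsz_e$scores, Dme = gsz_m$scores, CNV = gsz_c$scores)
  tot <- rowSums(abs(z))
  degenerate <- tot == 0
  p <- 100 * abs(z) / ifelse(degenerate, 1, tot)
  p[degenerate, ] <- 0
  data.frame(sample_id = ids,
             p_Gex = p[, "Gex"], p_Dme = p[, "Dme"], p_CNV = p[, "CNV"],
             sign_Gex = sign(z[, "Gex"]), sign_Dme = sign(z[, "Dme"]),
             sign_CNV = sign(z[, "CNV"]),
             degenerate = degenerate, row.names = NULL)
}

#' Map where a gene set's members live on the grid
#'
#' @param model a `som_model`.
#' @param set a [gene_set()].
#' @return integer grid of member-gene counts per unit; sums to the overlap
#'   between the set and the trained genes. Empty overlap gives a zero grid
#'   with a warning.
#' @export
signature_map <- function(model, set) {
  stopifnot(inherits(model, "som_model"), inherits(set, "gene_set"))
  members <- intersect(set$members, names(model$assignment))
  if (length(members) == 0) {
    warning("gene set '", set$name, "' shares no genes with the model")
    return(grid_from_units(integer(model$grid_side^2), model$grid_side))
  }
  counts <- tabulate(model$assignment[members], nbins = model$grid_side^2)
  grid_from_units(counts, model$grid_side)
}

#' Rank samples by their gene-set score
#'
#' Ascending by score; ties are resolved by sample id so the ranking is
#' stable and reproducible. The group track allows colouring the ranked bar
#' by sample group.
#'
#' @param gz a `gsz_result`.
#' @param annotations optional annotation data frame supplying group labels.
#' @return data frame: `rank`, `sample_id`, `score`, `group`.
#' @export
ranked_profile <- function(gz, annotations = NULL) {
  ids <- names(gz$scores)
  ord <- order(gz$scores, ids)
  out <- data.frame(rank = seq_along(ord), sample_id = ids[ord],
                    score = as.numeric(gz$scores[ord]), row.names = NULL)
  if (!is.null(annotations)) {
    ann <- validate_annotations(annotations)
    out$group <- ann$group[match(out$sample_id, ann$sample_id)]
  }
  out
}

#' GSZ scores of every set in every modality, as one long table
#'
#' @param dataset a centralized (or harmonized) [multiomics_dataset()] with
#'   gene sets attached, or pass `sets` explicitly.
#' @param sets optional list of [gene_set()]s overriding `dataset$gene_sets`.
#' @return data frame: `set`, `modality`, `sample_id`, `score`.
#' @export
gsz_table <- function(dataset, sets = NULL) {
  sets <- if (is.null(sets)) dataset$gene_sets else sets
  if (is.null(sets) || length(sets) == 0) stop("no gene sets supplied")
  slot <- c(Gex = "gex", Dme = "dme", CNV = "cnv")
  do.call(rbind, lapply(sets, function(gs) {
    do.call(rbind, lapply(MODALITIES, function(m) {
      z <- gsz(dataset[[slot[[m]]]], gs)
      data.frame(set = gs$name, modality = m,
                 sample_id = names(z$scores), score = as.numeric(z$scores),
                 row.names = NULL)
    }))
  }))
}
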