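#' Signed square-root covariance (ScoV) between two omics layers
#'
#' ScoV maps couple two modalities cell by cell on the shared grid. For a
#' single sample the coupling is the signed-root product of the two metagene
#' scores (the one-sample analogue of a covariance on centralized data); for
#' a group it is the true covariance across the group's samples. In both
#' cases the signed square root `sign(c) * sqrt(|c|)` compresses the dynamic
#' range while preserving the sign: negative cells mark repressive coupling
#' (e.g. methylation vs expression), positive cells dose-response coupling
#' (e.g. copy number vs expression).
#'
#' @param portrait_a,portrait_b two [portrait()]s of the same sample on the
#'   same grid.
#' @return a [portrait()] of kind `"ScoV"` tagged with the ordered pair.
#' @export
scov_sample <- function(portrait_a, portrait_b) {
  if (!identical(dim(portrait_a$grid), dim(portrait_b$grid)))
    stop("portrait shapes differ")
  s <- portrait_a$grid * portrait_b$grid
  p <- portrait(signed_sqrt(s), "ScoV", portrait_a$subject)
  p$pair <- paste(portrait_a$kind, portrait_b$kind, sep = "·")
  p
}

#' @rdname scov_sample
#' @param decomposed output of [decompose_model()].
#' @param modality_a,modality_b the two modalities to couple.
#' @param samples character vector of >= 2 sample ids defining the group.
#' @param side grid side length.
#' @param label subject label for the resulting portrait.
#' @export
scov_group <- function(decomposed, modality_a, modality_b, samples, side,
                       label = "group") {
  if (length(samples) < 2)
    stop("group ScoV needs >= 2 samples (covariance is undefined for 1)")
  A <- decomposed[[modality_a]][, samples, drop = FALSE]
  B <- decomposed[[modality_b]][, samples, drop = FALSE]
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  cv <- rowSums(Ac * Bc) / (length(samples) - 1)
  p <- portrait(grid_from_units(signed_sqrt(cv), side), "ScoV", label)
  p$pair <- paste(modality_a, modality_b, sep = "·")
  p
}

signed_sqrt <- function(x) sign(x) * sqrt(abs(x))
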