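#' Pairwise correlation between sample portraits
#'
#' Pearson correlation between the flattened metagene portraits of all
#' sample pairs in one modality; the heatmap analogue of the portrait
#' gallery. Zero-variance portraits yield `NA` rows/columns with a warning.
#'
#' @param decomposed output of [decompose_model()].
#' @param modality modality to correlate.
#' @return symmetric sample-by-sample correlation matrix with unit diagonal.
#' @export
portrait_correlation_matrix <- function(decomposed,
                                        modality = c("Gex", "Dme", "CNV")) {
  modality <- match.arg(modality)
  M <- decomposed[[modality]]
  if (ncol(M) < 2) stop("need >= 2 samples")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance portrait(s): ",
            paste(colnames(M)[sds == 0], collapse = ", "))
  C <- suppressWarnings(stats::cor(M))
  diag(C)[sds > 0] <- 1
  C
}

#' Build a top-k sample-similarity network
#'
#' Every sample is connected to its `k` most correlated neighbours
#' (ties resolved by sample order); the union of these directed picks forms
#' an undirected graph. A seeded Fruchterman-Reingold layout provides
#' reproducible 2-D coordinates.
#'
#' @param C correlation matrix from [portrait_correlation_matrix()].
#' @param k neighbours per sample (default 3); must be `< ncol(C)`.
#' @param seed layout seed.
#' @return list with `graph` (igraph), `edges` (data frame from/to/weight)
#'   and `layout` (data frame sample_id/x/y).
#' @export
similarity_network <- function(C, k = 3, seed = 1L) {
  n <- ncol(C)
  if (k >= n) stop("k must be smaller than the number of samples")
  ids <- colnames(C)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- C[i, ]
    r[i] <- -Inf
    r[is.na(r)] <- -Inf
    ord <- order(-r, seq_len(n))[seq_len(k)]
    data.frame(from = ids[i], to = ids[ord], weight = C[i, ord])
  }))
  # undirected union of the per-node picks
  key <- apply(edges[, c("from", "to")], 1, function(p) paste(sort(p), collapse = "|"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  set.seed(as.integer(seed))
  xy <- igraph::layout_with_fr(g)
  list(graph = g, edges = edges,
       layout = data.frame(sample_id = ids, x = xy[, 1], y = xy[, 2]))
}

#' Modularity of a sample partition on the similarity network
#'
#' @param net output of [similarity_network()].
#' @param groups named group labels (names = sample ids) or an annotation
#'   data frame.
#' @return Newman modularity of the given partition.
#' @export
network_modularity <- function(net, groups) {
  if (is.data.frame(groups)) {
    ann <- validate_annotations(groups)
    groups <- stats::setNames(ann$group, ann$sample_id)
  }
  member <- as.integer(factor(groups[igraph::V(net$graph)$name]))
  igraph::modularity(net$graph, member)
}

#' Agreement between portrait clusters and annotated groups
#'
#' Average-linkage hierarchical clustering of `1 - correlation` distances,
#' cut at the number of annotated groups, compared with the annotation by
#' the adjusted Rand index (chance-corrected, 1 = identical partitions,
#' about 0 for random labels).
#'
#' @param C correlation matrix.
#' @param groups named group labels or annotation data frame.
#' @return list with `contingency` (table), `ari`, `clusters` (named).
#' @export
group_agreement <- function(C, groups) {
  if (is.data.frame(groups)) {
    ann <- validate_annotations(groups)
    groups <- stats::setNames(ann$group, ann$sample_id)
  }
  groups <- groups[colnames(C)]
  k <- length(unique(groups))
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  cl <- stats::cutree(hc, k = k)
  list(contingency = table(cluster = cl, group = groups),
       ari = mclust::adjustedRandIndex(cl, groups),
       clusters = cl)
}
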