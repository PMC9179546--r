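#' Construct an omics matrix
#'
#' An `omics_matrix` holds one modality's gene-by-sample score matrix together
#' with flags recording whether it has been centralized (per-gene mean
#' removed) and harmonized (divided by the modality's global standard
#' deviation). Gene and sample identifiers live in the dimnames and must be
#' unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers, colnames sample identifiers.
#' @param modality one of `"Gex"`, `"Dme"`, `"CNV"` (log expression,
#'   methylation score, gene-centric copy-number score).
#' @param centralized,harmonized logical state flags; set by [centralize()]
#'   and [harmonize()], rarely by hand.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, modality = c("Gex", "Dme", "CNV"),
                         centralized = FALSE, harmonized = FALSE) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  x <- structure(
    list(values = values, modality = modality,
         centralized = isTRUE(centralized), harmonized = isTRUE(harmonized)),
    class = "omics_matrix")
  validate_omics_matrix(x)
  x
}

validate_omics_matrix <- function(x) {
  v <- x$values
  gid <- rownames(v); sid <- colnames(v)
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (x$centralized && nrow(v) > 0) {
    if (max(abs(rowMeans(v))) > 1e-9)
      stop("centralized flag set but some gene row mean exceeds 1e-9")
  }
  if (x$harmonized && length(v) > 1) {
    s <- stats::sd(as.vector(v))
    if (!(abs(s - 1) < 1e-6 || all(v == 0)))
      stop("harmonized flag set but global SD is neither 1 nor matrix all-zero")
  }
  invisible(x)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d genes x %d samples (centralized=%s, harmonized=%s)\n",
              x$modality, nrow(x$values), ncol(x$values),
              x$centralized, x$harmonized))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Modality weight configuration
#'
#' Weights `w_e`, `w_m`, `w_c` scale the expression, methylation and
#' copy-number blocks of the combined per-gene vector. They must be
#' non-negative and sum to 1; a zero weight switches a modality off
#' ("bi-variant" training).
#'
#' @param w_e,w_m,w_c weights in `[0, 1]` summing to 1 (tolerance 1e-9).
#' @return a `weight_config` object (named numeric vector).
#' @seealso [weight_preset()]
#' @export
weight_config <- function(w_e, w_m, w_c) {
  w <- c(Gex = w_e, Dme = w_m, CNV = w_c)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(w), digits = 12), ")")
  structure(w, class = "weight_config")
}

#' Named weight presets
#'
#' `"balanced"` uses equal weights 1/3 for all three layers; the dominant
#' presets put 0.99 on one layer and split the remaining 0.01 equally, which
#' keeps the sum-to-one constraint while making the map topology effectively
#' single-ome; `"gex-dme-bivariant"` drops the CNV layer entirely.
#'
#' @param name preset name.
#' @return a [weight_config()].
#' @export
weight_preset <- function(name = c("balanced", "gex-dominant", "dme-dominant",
                                   "cnv-dominant", "gex-dme-bivariant")) {
  name <- match.arg(name)
  switch(name,
    "balanced"          = weight_config(1/3, 1/3, 1/3),
    "gex-dominant"      = weight_config(0.99, 0.005, 0.005),
    "dme-dominant"      = weight_config(0.005, 0.99, 0.005),
    "cnv-dominant"      = weight_config(0.005, 0.005, 0.99),
    "gex-dme-bivariant" = weight_config(0.5, 0.5, 0))
}

#' Bundle aligned matrices, annotations and gene sets into one dataset
#'
#' @param gex,dme,cnv `omics_matrix` objects sharing identical gene and
#'   sample ids in identical order.
#' @param annotations data frame with columns `sample_id`, `group` and
#'   optionally `time` (survival, months) and `event` (0/1 death flag); may
#'   be `NULL`.
#' @param gene_sets list of gene sets as returned by [read_gmt()]; may be
#'   `NULL`.
#' @return a `multiomics_dataset`.
#' @export
multiomics_dataset <- function(gex, dme, cnv, annotations = NULL,
                               gene_sets = NULL) {
  for (m in list(gex, dme, cnv))
    if (!inherits(m, "omics_matrix")) stop("inputs must be omics_matrix objects")
  if (gex$modality != "Gex" || dme$modality != "Dme" || cnv$modality != "CNV")
    stop("matrices must carry modalities Gex, Dme, CNV in that order")
  if (!identical(gene_ids(gex), gene_ids(dme)) ||
      !identical(gene_ids(gex), gene_ids(cnv)))
    stop("gene ids differ between modalities; run align_dataset() first")
  if (!identical(sample_ids(gex), sample_ids(dme)) ||
      !identical(sample_ids(gex), sample_ids(cnv)))
    stop("sample ids differ between modalities; run align_dataset() first")
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations)
    if (!all(annotations$sample_id %in% sample_ids(gex)))
      stop("annotation sample ids absent from the matrices: ",
           paste(setdiff(annotations$sample_id, sample_ids(gex)), collapse = ", "))
  }
  if (!is.null(gene_sets)) validate_gene_sets(gene_sets)
  structure(list(gex = gex, dme = dme, cnv = cnv,
                 annotations = annotations, gene_sets = gene_sets),
            class = "multiomics_dataset")
}

validate_annotations <- function(ann) {
  if (!is.data.frame(ann) || !all(c("sample_id", "group") %in% names(ann)))
    stop("annotations need at least columns 'sample_id' and 'group'")
  ann$sample_id <- as.character(ann$sample_id)
  ann$group <- as.character(ann$group)
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample ids in annotations")
  if ("time" %in% names(ann)) {
    bad <- !is.na(ann$time) & ann$time < 0
    if (any(bad)) stop("negative survival times for: ",
                       paste(ann$sample_id[bad], collapse = ", "))
    if ("event" %in% names(ann)) {
      orphan <- is.na(ann$time) & !is.na(ann$event)
      if (any(orphan)) stop("event flag defined without survival time for: ",
                            paste(ann$sample_id[orphan], collapse = ", "))
    }
  }
  ann
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> %d genes x %d samples\n",
              nrow(x$gex$values), ncol(x$gex$values)))
  cat(sprintf("  annotations: %s; gene sets: %s\n",
              if (is.null(x$annotations)) "none" else nrow(x$annotations),
              if (is.null(x$gene_sets)) "none" else length(x$gene_sets)))
  invisible(x)
}

#' Create a gene set
#'
#' @param name unique set name.
#' @param members character vector of member gene identifiers (non-empty).
#' @param category free-text category tag.
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, members, category = "custom") {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("gene set '", name, "' has no members")
  structure(list(name = as.character(name), category = as.character(category),
                 members = members),
            class = "gene_set")
}

validate_gene_sets <- function(sets) {
  if (!all(vapply(sets, inherits, logical(1), "gene_set")))
    stop("gene_sets must be a list of gene_set objects")
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate gene set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  invisible(sets)
}

#' Restrict three modality matrices to their common genes and samples
#'
#' Realizes the patient-matched contract: the returned dataset covers the
#' intersection of gene ids and of sample ids across the three matrices, with
#' rows and columns in identical order (order of the expression matrix). The
#' number of genes/samples dropped from each modality is reported via a
#' message.
#'
#' @inheritParams multiomics_dataset
#' @return a [multiomics_dataset()].
#' @export
align_dataset <- function(gex, dme, cnv, annotations = NULL, gene_sets = NULL) {
  mats <- list(gex = gex, dme = dme, cnv = cnv)
  for (m in mats) {
    if (!inherits(m, "omics_matrix")) stop("inputs must be omics_matrix objects")
    if (nrow(m$values) == 0 || ncol(m$values) == 0)
      stop("empty input matrix (", m$modality, ")")
  }
  g <- Reduce(intersect, lapply(mats, gene_ids))
  s <- Reduce(intersect, lapply(mats, sample_ids))
  if (length(g) == 0) stop("empty gene intersection")
  if (length(s) == 0) stop("empty sample intersection")
  # keep the expression matrix's ordering for reproducible layouts
  g <- gene_ids(gex)[gene_ids(gex) %in% g]
  s <- sample_ids(gex)[sample_ids(gex) %in% s]
  dropped <- vapply(mats, function(m)
    length(gene_ids(m)) - length(g) + length(sample_ids(m)) - length(s),
    numeric(1))
  if (any(dropped > 0))
    message("align_dataset: dropped rows+columns per modality: ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "))
  sub <- function(m) omics_matrix(m$values[g, s, drop = FALSE], m$modality,
                                  centralized = m$centralized,
                                  harmonized = m$harmonized)
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations)
    annotations <- annotations[annotations$sample_id %in% s, , drop = FALSE]
  }
  multiomics_dataset(sub(gex), sub(dme), sub(cnv), annotations, gene_sets)
}
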