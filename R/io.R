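#' Read a gene-by-sample score matrix from tab-separated text
#'
#' Expected dialect: header row of sample ids, first column gene ids (header
#' token `gene_id`), numeric body with decimal points; empty cells or `NA`
#' denote missing values. Missing entries are imputed with the gene's row
#' mean so that downstream centralization still yields exact zero row means;
#' rows that are entirely missing are dropped with a warning.
#'
#' @param path file path.
#' @param modality one of `"Gex"`, `"Dme"`, `"CNV"`.
#' @return an [omics_matrix()] with both state flags `FALSE`.
#' @export
read_omics_matrix <- function(path, modality = c("Gex", "Dme", "CNV")) {
  modality <- match.arg(modality)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("matrix file needs a gene-id column plus >=1 sample column")
  gid <- as.character(df[[1]])
  if (anyDuplicated(gid))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(gid, colnames(body)))
  for (j in seq_len(ncol(body))) {
    raw <- trimws(body[[j]])
    raw[raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & toupper(raw) != "NA")
    if (length(bad))
      stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                   gid[bad[1]], colnames(body)[j], raw[bad[1]]))
    vals[, j] <- num
  }
  all_na <- rowSums(!is.na(vals)) == 0
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " all-missing gene row(s): ",
            paste(utils::head(gid[all_na], 5), collapse = ", "),
            if (sum(all_na) > 5) ", ..." else "")
    vals <- vals[!all_na, , drop = FALSE]
  }
  if (anyNA(vals)) {
    rm <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm[idx[, 1]]
  }
  omics_matrix(vals, modality)
}

#' Write an omics matrix as tab-separated text
#'
#' Values are formatted with 10 significant digits, enough for a lossless
#' read/write/read round trip at working precision.
#'
#' @param x an [omics_matrix()].
#' @param path output file path.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(gene_id = rownames(x$values),
                   signif(x$values, 10), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated with columns `sample_id`, `group` and optionally `time`
#' (survival time in months) and `event` (0/1).
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotations(ann)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description/category, then member gene ids, all
#' tab-separated.
#'
#' @param path file path.
#' @return list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(list())
  }
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    gene_set(f[1], f[-(1:2)], category = f[2])
  })
  validate_gene_sets(sets)
  sets
}

#' Write gene sets in GMT format
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  validate_gene_sets(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$category, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Persist / restore a trained SOM model
#'
#' The model is stored as an RDS container holding all arrays (unit vectors,
#' assignment, weights, training configuration); the round trip is bit-exact.
#'
#' @param model a `som_model` from [train_som()].
#' @param path file path (conventionally `.rds`).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns the restored `som_model`.
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "som_model"))
    stop("file does not contain a som_model: ", path)
  model
}
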