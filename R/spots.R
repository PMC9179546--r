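#' Label 8-connected components of a logical grid
#'
#' Iterative breadth-first labelling; diagonal neighbours connect. Used by
#' spot detection and exposed for testing.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background), labelled in
#'   order of first (row-major) occurrence.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      rr <- cur[1] + offs$dr; cc <- cur[2] + offs$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      rr <- rr[ok]; cc <- cc[ok]
      for (k in seq_along(rr)) {
        if (mask[rr[k], cc[k]] && lab[rr[k], cc[k]] == 0L) {
          lab[rr[k], cc[k]] <- nxt
          queue <- rbind(queue, c(rr[k], cc[k]))
        }
      }
    }
  }
  lab
}

#' Detect spot modules in one portrait
#'
#' Cells whose score reaches the threshold fraction of the portrait's
#' extreme value are selected and split into 8-connected components. For
#' `sign = "over"` the threshold is `threshold_fraction * max(grid)` and the
#' maximum must be positive (otherwise an empty list is returned with a
#' warning); `sign = "under"` mirrors this with the minimum. Components
#' smaller than `min_size` cells are discarded as speckle.
#'
#' @param p a [portrait()].
#' @param threshold_fraction fraction of the extreme value, in (0, 1);
#'   default 0.9 ("90% of maximum").
#' @param sign `"over"` for high-score spots, `"under"` for low-score spots.
#' @param min_size minimum component size in cells.
#' @return list of spot stubs: `member_units` (unit indices), `sign`,
#'   `source` (the portrait's kind and subject).
#' @export
detect_spots <- function(p, threshold_fraction = 0.9,
                         sign = c("over", "under"), min_size = 3) {
  sign <- match.arg(sign)
  if (!(threshold_fraction > 0 && threshold_fraction < 1))
    stop("threshold_fraction must lie in (0, 1)")
  g <- p$grid
  if (sign == "over") {
    mx <- max(g, na.rm = TRUE)
    if (!(mx > 0)) {
      warning("portrait maximum is not positive; no over-spots")
      return(list())
    }
    mask <- !is.na(g) & g >= threshold_fraction * mx
  } else {
    mn <- min(g, na.rm = TRUE)
    if (!(mn < 0)) {
      warning("portrait minimum is not negative; no under-spots")
      return(list())
    }
    mask <- !is.na(g) & g <= threshold_fraction * mn
  }
  lab <- label_components(mask)
  out <- list()
  for (l in seq_len(max(lab))) {
    cells <- which(t(lab) == l)   # t(): row-major cell index = unit index
    if (length(cells) < min_size) next
    out[[length(out) + 1]] <- list(member_units = sort(cells), sign = sign,
                                   source = paste(p$kind, p$subject))
  }
  out
}

#' Summarize spots across all group portraits and modalities
#'
#' Runs [detect_spots()] at both signs on every group-mean portrait of every
#' modality and merges detections that share cells into one module. Both
#' signs are cut at `threshold_fraction` of the portrait's absolute extreme,
#' so only sides carrying signal comparable to the portrait's dominant
#' feature contribute detections. Components are labelled `A`, `B`, ... in clockwise order of
#' their centroid angle around the grid centre, starting at the top-left
#' diagonal. Each spot is annotated with its member genes (all genes whose
#' BMU lies in the spot), its dominant modality (largest variance of the
#' spot's mean profile across group means) and its per-modality mean
#' profiles over samples.
#'
#' @param model a `som_model`.
#' @param decomposed output of [decompose_model()].
#' @param gportraits nested list from [group_portraits()].
#' @param threshold_fraction,min_size passed to [detect_spots()].
#' @return list with `spots` (list of `spot_module`) and `label_grid`
#'   (character matrix, `""` outside spots).
#' @export
spot_summary_map <- function(model, decomposed, gportraits,
                             threshold_fraction = 0.9, min_size = 3) {
  if (length(gportraits) == 0) stop("need at least one group portrait")
  side <- model$grid_side
  comps <- list()
  for (g in gportraits) for (p in g) {
    # both signs are thresholded on the portrait's absolute extreme, so a
    # side whose extreme is only noise produces no detections
    M <- max(abs(p$grid), na.rm = TRUE)
    if (M == 0) next
    for (sgn in c("over", "under")) {
      ext <- if (sgn == "over") max(p$grid, na.rm = TRUE)
             else -min(p$grid, na.rm = TRUE)
      f <- threshold_fraction * M / ext
      if (!is.finite(f) || f >= 1 || ext <= 0) next
      stubs <- withCallingHandlers(
        detect_spots(p, f, sgn, min_size),
        warning = function(w) invokeRestart("muffleWarning"))
      for (st in stubs) comps[[length(comps) + 1]] <- st$member_units
    }
  }
  # merge components that share at least one cell (union-find over overlaps)
  parent <- seq_along(comps)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(comps)) for (j in seq_len(i - 1)) {
    if (length(intersect(comps[[i]], comps[[j]])) > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(comps), find, integer(1))
  comp_units <- lapply(unique(roots), function(r)
    sort(unique(unlist(comps[roots == r]))))
  comp_units <- comp_units[lengths(comp_units) >= min_size]
  if (length(comp_units) == 0)
    return(list(spots = list(), label_grid = matrix("", side, side)))

  # clockwise ordering of centroids around the grid centre, zero angle at
  # the top-left diagonal
  centre <- (side + 1) / 2
  ang <- vapply(comp_units, function(u) {
    rc <- unit_coords(u, side)
    x <- mean(rc[, "col"]) - centre
    y <- mean(rc[, "row"]) - centre
    (atan2(x, -y) + pi / 4) %% (2 * pi)
  }, numeric(1))
  ord <- order(ang)
  labels <- make_spot_labels(length(ord))

  spots <- vector("list", length(ord))
  label_grid <- matrix("", side, side)
  for (i in seq_along(ord)) {
    units <- comp_units[[ord[i]]]
    genes <- names(model$assignment)[model$assignment %in% units]
    sp <- structure(list(label = labels[i], member_units = units,
                         member_genes = genes, sign = spot_sign(decomposed, units),
                         profiles = spot_profiles_units(decomposed, units)),
                    class = "spot_module")
    sp$dominant_modality <- dominant_modality(sp$profiles, gportraits, units)
    spots[[i]] <- sp
    label_grid[unit_coords(units, side)] <- labels[i]
  }
  list(spots = spots, label_grid = label_grid)
}

make_spot_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}

spot_sign <- function(decomposed, units) {
  m <- vapply(decomposed, function(d) {
    if (all(is.na(d))) return(0)
    v <- d[units, , drop = FALSE]
    v[which.max(abs(v))]
  }, numeric(1))
  if (m[which.max(abs(m))] >= 0) "over" else "under"
}

spot_profiles_units <- function(decomposed, units) {
  lapply(decomposed, function(d) colMeans(d[units, , drop = FALSE]))
}

dominant_modality <- function(profiles, gportraits, units) {
  # variance of the spot's mean value across group-mean portraits; with a
  # single group, its absolute mean value decides instead
  v <- vapply(MODALITIES, function(m) {
    means <- vapply(gportraits, function(g) {
      if (is.null(g[[m]])) return(NA_real_)
      mean(g[[m]]$grid[unit_coords(units, nrow(g[[m]]$grid))])
    }, numeric(1))
    means <- means[!is.na(means)]
    if (length(means) == 0) return(-Inf)
    if (length(means) == 1) return(abs(means))
    stats::var(means)
  }, numeric(1))
  MODALITIES[which.max(v)]
}

#' Triple-omics profiles of a spot
#'
#' Per modality, the mean decomposed metagene value over the spot's member
#' units, one value per sample. A modality trained with weight 0 yields an
#' all-`NA` profile.
#'
#' @param spot a `spot_module`.
#' @param decomposed output of [decompose_model()].
#' @return named list of sample-length numeric vectors.
#' @export
spot_profiles <- function(spot, decomposed) {
  spot_profiles_units(decomposed, spot$member_units)
}

#' Per-gene cross-modality scatter and correlation for a spot
#'
#' For each member gene, its mean score in modality a and modality b across
#' the chosen samples, plus the Pearson correlation over genes. Negative
#' correlations indicate repressive coupling, positive ones dose-response.
#'
#' @param spot a `spot_module`.
#' @param dataset the harmonized [multiomics_dataset()].
#' @param modality_a,modality_b the two modalities.
#' @param samples sample ids to average over; default all.
#' @return list with `points` (data frame gene/a/b) and `r`.
#' @export
spot_correlation <- function(spot, dataset, modality_a, modality_b,
                             samples = NULL) {
  slot <- c(Gex = "gex", Dme = "dme", CNV = "cnv")
  genes <- spot$member_genes
  if (length(genes) < 3) stop("spot has fewer than 3 member genes")
  if (is.null(samples)) samples <- colnames(dataset$gex$values)
  a <- rowMeans(dataset[[slot[[modality_a]]]]$values[genes, samples, drop = FALSE])
  b <- rowMeans(dataset[[slot[[modality_b]]]]$values[genes, samples, drop = FALSE])
  list(points = data.frame(gene = genes, a = a, b = b, row.names = NULL),
       r = stats::cor(a, b))
}

#' Spot-count distribution per sample group
#'
#' Counts, for every sample, the spots detected on its own portrait in one
#' modality (over- and under-spots) and tabulates per group the fraction of
#' samples with each spot count. The fractions of each group sum to 1.
#'
#' @param model a `som_model`.
#' @param decomposed output of [decompose_model()].
#' @param annotations annotation data frame (`sample_id`, `group`).
#' @param modality modality to analyse.
#' @param threshold_fraction,min_size passed to [detect_spots()].
#' @return list with `counts` (named integer per sample) and `table`
#'   (data frame group / n_spots / fraction).
#' @export
spot_frequencies <- function(model, decomposed, annotations,
                             modality = c("Gex", "Dme", "CNV"),
                             threshold_fraction = 0.9, min_size = 3) {
  modality <- match.arg(modality)
  ann <- validate_annotations(annotations)
  counts <- vapply(model$sample_ids, function(s) {
    p <- sample_portrait(model, decomposed, s, modality)
    n <- 0L
    for (sgn in c("over", "under"))
      n <- n + length(withCallingHandlers(
        detect_spots(p, threshold_fraction, sgn, min_size),
        warning = function(w) invokeRestart("muffleWarning")))
    n
  }, integer(1))
  rows <- do.call(rbind, lapply(unique(ann$group), function(g) {
    cg <- counts[intersect(ann$sample_id[ann$group == g], names(counts))]
    tb <- table(cg) / length(cg)
    data.frame(group = g, n_spots = as.integer(names(tb)),
               fraction = as.numeric(tb))
  }))
  list(counts = counts, table = rows)
}
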