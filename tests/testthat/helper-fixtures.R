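# Shared fixtures and independent oracles for the suite.

.fixture_cache <- new.env(parent = emptyenv())

# The default synthetic cohort, preprocessed and trained once per test run.
cohort_fixture <- function(seed = 7, grid_side = 20) {
  key <- sprintf("cohort_%d_%d", seed, grid_side)
  if (!exists(key, envir = .fixture_cache)) {
    sim <- default_cohort(seed = seed)
    ds <- sim$dataset
    ds2 <- multiomics_dataset(centralize(ds$gex), centralize(ds$dme),
                              centralize(ds$cnv), ds$annotations,
                              ds$gene_sets)
    ds2 <- harmonize(ds2)
    profiles <- combine_modalities(ds2, "balanced")
    model <- train_som(profiles, grid_side = grid_side, seed = seed)
    dec <- decompose_model(model)
    gp <- group_portraits(model, dec, ds2$annotations)
    assign(key, list(sim = sim, ds = ds2, profiles = profiles, model = model,
                     dec = dec, gp = gp), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small random dataset already centralized + harmonized (for oracle tests).
tiny_dataset <- function(n_genes = 30, n_samples = 8, seed = 42) {
  set.seed(seed)
  mk <- function(modality) {
    v <- matrix(rnorm(n_genes * n_samples), n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    centralize(omics_matrix(v, modality))
  }
  harmonize(multiomics_dataset(mk("Gex"), mk("Dme"), mk("CNV")))
}

# Independent recursive flood fill (8-connectivity), deliberately naive.
flood_fill_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  fill <- function(r, c, l) {
    stack <- list(c(r, c))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- p[1]; c <- p[2]
      if (r < 1 || r > nr || c < 1 || c > nc) next
      if (!mask[r, c] || lab[r, c] != 0L) next
      lab[r, c] <<- l
      for (dr in -1:1) for (dc in -1:1)
        if (dr != 0 || dc != 0) stack[[length(stack) + 1]] <- c(r + dr, c + dc)
    }
  }
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (mask[r, c] && lab[r, c] == 0L) { nxt <- nxt + 1L; fill(r, c, nxt) }
  lab
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Best Jaccard match of a planted module among detected spots.
best_spot_match <- function(spots, module_genes) {
  j <- vapply(spots, function(s) jaccard(s$member_genes, module_genes),
              numeric(1))
  list(jaccard = max(j), spot = spots[[which.max(j)]])
}

write_tsv_matrix <- function(values, path) {
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
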