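#' Run the full portrayal workflow
#'
#' Chains simulation/ingest, preprocessing, SOM training, decomposition,
#' group portraits, ScoV maps, spot detection, gene-set scoring, prognostic
#' maps and cohort similarity into one call, writing all numeric maps as TSV
#' plus a manifest recording inputs, checksums, parameters and per-stage
#' timings. Re-running the same configuration reproduces the outputs (the
#' whole chain is seeded and deterministic).
#'
#' @param config a list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{input}{either `list(simulate = TRUE, seed = <int>)` or paths
#'       `gex`, `dme`, `cnv`, `annotations` (TSV) and optionally `gmt`.}
#'     \item{weights}{preset name (see [weight_preset()]) or three numbers.}
#'     \item{grid_side}{SOM grid side (default 45).}
#'     \item{seed}{training seed (default 1).}
#'     \item{threshold_fraction}{spot threshold (default 0.9).}
#'   }
#' @param out_dir output directory, created if missing.
#' @return (invisibly) list with the trained `model`, `decomposed` maps,
#'   `spots` and the manifest path.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  weights <- config$weights %||% "balanced"
  weights <- if (is.character(weights)) weight_preset(weights)
             else weight_config(weights[1], weights[2], weights[3])
  grid_side <- config$grid_side %||% 45
  seed <- as.integer(config$seed %||% 1L)
  thr <- config$threshold_fraction %||% 0.9
  inp <- config$input %||% list(simulate = TRUE, seed = seed)

  # pre-flight: all declared inputs must exist before any computation
  if (!isTRUE(inp$simulate)) {
    paths <- unlist(inp[c("gex", "dme", "cnv", "annotations", "gmt")])
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("missing input file(s): ",
                              paste(missing, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  message("pipeline: seed=", seed, " grid=", grid_side, " weights=",
          paste(format(unclass(weights), digits = 4), collapse = "/"))

  checksums <- list()
  if (isTRUE(inp$simulate)) {
    sim <- generate_cohort(synthetic_config(), seed = inp$seed %||% seed)
    raw <- sim$dataset
    utils::write.table(sim$truth$samples,
                       file.path(out_dir, "ground_truth_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$genes[, c("gene_id", "module")],
                       file.path(out_dir, "ground_truth_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gex <- read_omics_matrix(inp$gex, "Gex")
    dme <- read_omics_matrix(inp$dme, "Dme")
    cnv <- read_omics_matrix(inp$cnv, "CNV")
    ann <- read_annotations(inp$annotations)
    sets <- if (!is.null(inp$gmt)) read_gmt(inp$gmt) else NULL
    raw <- align_dataset(gex, dme, cnv, ann, sets)
    checksums <- lapply(inp[c("gex", "dme", "cnv", "annotations")],
                        function(p) unname(tools::md5sum(p)))
  }
  tick("ingest")

  ds <- multiomics_dataset(centralize(raw$gex), centralize(raw$dme),
                           centralize(raw$cnv), raw$annotations, raw$gene_sets)
  ds <- harmonize(ds)
  profiles <- combine_modalities(ds, weights)
  tick("preprocess")

  model <- train_som(profiles, grid_side = grid_side, seed = seed)
  write_model(model, file.path(out_dir, "model.rds"))
  dec <- decompose_model(model)
  tick("train")

  write_grid <- function(grid, name)
    utils::write.table(grid, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_grid(population_map(model), "population_map.tsv")
  gp <- group_portraits(model, dec, ds$annotations)
  for (g in names(gp)) for (m in names(gp[[g]]))
    write_grid(signif(gp[[g]][[m]]$grid, 8),
               sprintf("portrait_%s_%s.tsv", gsub("[^A-Za-z0-9]", "_", g), m))
  for (m in MODALITIES)
    if (!all(is.na(dec[[m]])))
      write_grid(signif(variance_map(dec, m, grid_side)$grid, 8),
                 sprintf("variance_%s.tsv", m))
  tick("portraits")

  pairs <- list(c("Gex", "Dme"), c("Gex", "CNV"), c("Dme", "CNV"))
  for (p in pairs) {
    if (all(is.na(dec[[p[1]]])) || all(is.na(dec[[p[2]]]))) next
    sc <- scov_group(dec, p[1], p[2], model$sample_ids, grid_side, "cohort")
    write_grid(signif(sc$grid, 8), sprintf("scov_%s_%s.tsv", p[1], p[2]))
  }
  tick("scov")

  summ <- spot_summary_map(model, dec, gp, threshold_fraction = thr)
  spot_tab <- do.call(rbind, lapply(summ$spots, function(s)
    data.frame(label = s$label, sign = s$sign,
               n_units = length(s$member_units),
               n_genes = length(s$member_genes),
               dominant_modality = s$dominant_modality,
               genes = paste(s$member_genes, collapse = ","))))
  if (!is.null(spot_tab))
    utils::write.table(spot_tab, file.path(out_dir, "spots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tick("spots")

  if (!is.null(ds$gene_sets)) {
    utils::write.table(gsz_table(ds), file.path(out_dir, "gsz.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("genesets")

  ann <- ds$annotations
  if (!is.null(ann) && all(c("time", "event") %in% names(ann))) {
    for (m in MODALITIES) {
      if (all(is.na(dec[[m]]))) next
      hm <- hr_map(dec, m, ann, grid_side)
      write_grid(signif(hm$hr$grid, 8), sprintf("hr_%s.tsv", m))
    }
  }
  tick("prognosis")

  for (m in MODALITIES) {
    if (all(is.na(dec[[m]]))) next
    C <- portrait_correlation_matrix(dec, m)
    utils::write.table(signif(C, 8),
                       file.path(out_dir, sprintf("correlation_%s.tsv", m)),
                       sep = "\t", quote = FALSE)
    net <- similarity_network(C, k = min(3, ncol(C) - 1), seed = seed)
    utils::write.table(net$edges,
                       file.path(out_dir, sprintf("network_%s_edges.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(signif_df(net$layout),
                       file.path(out_dir, sprintf("network_%s_layout.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("cohort")

  outputs <- list.files(out_dir)
  outputs <- setdiff(outputs, "manifest.yaml")
  manifest <- list(
    package_version = as.character(utils::packageVersion("combisom")),
    seed = seed, grid_side = grid_side,
    weights = as.list(unclass(weights)),
    threshold_fraction = thr,
    input = inp, input_checksums = checksums,
    output_checksums = as.list(tools::md5sum(file.path(out_dir, outputs))),
    timings_sec = as.list(timings))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  message("pipeline: wrote ", length(outputs), " files to ", out_dir)
  invisible(list(model = model, decomposed = dec, spots = summ,
                 manifest = file.path(out_dir, "manifest.yaml")))
}

signif_df <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 8)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
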