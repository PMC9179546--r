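#' Configuration of the synthetic multi-omics cohort
#'
#' The generator emulates the statistical structure the portrayal method
#' assumes: genetic groups with arm-level trinary copy-number segments and a
#' positive CNV-to-expression dose-response, repressive methylation modules
#' (promoter hyper-methylation coupled to reduced expression), a global
#' group-level methylation gradient, pure-expression (TF-driven) modules,
#' a fraction of low-tumour-content samples whose group effects are
#' attenuated, and exponential survival with group-dependent hazards.
#'
#' The default cohort holds 2000 genes and 120 samples in three groups:
#' \describe{
#'   \item{IDHwt-like (30)}{one gained segment (dose-responsive, "Chr7-like")
#'     and one lost segment ("Chr10-like"); low methylation; hazard
#'     multiplier 3.}
#'   \item{IDHA-like (50)}{strongest repressive hyper-methylation module
#'     shift, an intermediate broad methylation gradient, and a
#'     pure-expression (TF-driven) module.}
#'   \item{IDHO-like (40)}{two co-deleted segments ("Chr1p/19q-like") and the
#'     highest methylation gradient plus the strongest repressive module
#'     shift.}
#' }
#' This plants five modules in total: the gained segment, the lost segment,
#' the co-deleted segment pair (one module: both ranges share one profile),
#' the repressive methylation module, and the pure-expression module.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param groups list of group definitions (name, size, cnv_segments as
#'   list of `c(from, to, state)`, dme_gradient amplitude, dme_shift and
#'   gex_shift applied to the respective modules, hazard multiplier).
#' @param modules gene-index ranges of the planted modules.
#' @param gamma positive CNV-to-expression dose-response slope.
#' @param beta negative methylation-to-expression repression slope.
#' @param effect_mult_range per-gene susceptibility multiplier range for
#'   module genes (uniform). The narrow default models arm-level events and
#'   concerted modules whose members respond near-uniformly, which keeps
#'   planted modules recoverable through the sharp 90%-of-maximum spot
#'   threshold; widen it (e.g. `c(0.5, 1.5)`) to emulate heterogeneous
#'   susceptibility and obtain informative per-gene cross-omics scatter
#'   plots.
#' @param noise_sd per-modality Gaussian noise standard deviations.
#' @param low_purity_fraction fraction of samples per group with attenuated
#'   group effects; `alpha` is the attenuation factor.
#' @param alpha attenuation multiplier in (0, 1] for low-purity samples.
#' @param baseline_rate exponential baseline event rate per month.
#' @param censor_range administrative censoring window (months).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_genes = 2000, n_samples = 120,
    groups = list(
      list(name = "IDHwt-like", size = 30,
           cnv_segments = list(gain = c(1, 150, +1), loss = c(201, 350, -1)),
           dme_gradient = 0.0, dme_shift = 0.0, gex_shift = 0.0, hazard = 3.0),
      list(name = "IDHA-like", size = 50, cnv_segments = list(),
           dme_gradient = 0.35, dme_shift = 1.2, gex_shift = 0.9,
           hazard = 1.0),
      list(name = "IDHO-like", size = 40,
           cnv_segments = list(codel = c(401, 500, -1), codel2 = c(501, 620, -1)),
           dme_gradient = 0.7, dme_shift = 1.1, gex_shift = 0.0, hazard = 1.0)),
    modules = list(gain = c(1, 150), loss = c(201, 350),
                   codel = c(401, 620), repressive = c(701, 800),
                   pure_gex = c(901, 1000)),
    gamma = 0.7, beta = -0.8,
    effect_mult_range = c(0.95, 1.05),
    noise_sd = c(Gex = 0.35, Dme = 0.3, CNV = 0.25),
    low_purity_fraction = 0.1, alpha = 0.4,
    baseline_rate = 1 / 60, censor_range = c(48, 120)) {
  cfg <- structure(list(n_genes = n_genes, n_samples = n_samples,
                        groups = groups, modules = modules, gamma = gamma,
                        beta = beta, effect_mult_range = effect_mult_range,
                        noise_sd = noise_sd,
                        low_purity_fraction = low_purity_fraction,
                        alpha = alpha, baseline_rate = baseline_rate,
                        censor_range = censor_range),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  sizes <- vapply(cfg$groups, `[[`, numeric(1), "size")
  if (sum(sizes) != cfg$n_samples)
    stop("group sizes sum to ", sum(sizes), ", not n_samples = ", cfg$n_samples)
  rng <- c(unlist(lapply(cfg$groups, function(g)
    lapply(g$cnv_segments, function(s) s[1:2]))),
    unlist(lapply(cfg$modules, function(m) m[1:2])))
  if (length(rng) && (min(rng) < 1 || max(rng) > cfg$n_genes))
    stop("module or segment gene indices fall outside 1..n_genes")
  if (cfg$gamma < 0) stop("gamma (dose-response) must be >= 0")
  if (cfg$beta > 0) stop("beta (repression) must be <= 0")
  if (!(cfg$alpha > 0 && cfg$alpha <= 1)) stop("alpha must lie in (0, 1]")
  r <- cfg$effect_mult_range
  if (length(r) != 2 || r[1] <= 0 || r[1] > r[2])
    stop("effect_mult_range must be an increasing positive pair")
  invisible(cfg)
}

#' Generate a synthetic multi-omics cohort with ground truth
#'
#' Deterministic per seed. Per gene g and sample s of group k with purity
#' `p_s` (1, or `alpha` for low-purity samples):
#' \itemize{
#'   \item CNV: `state_gk * p_s + noise`, state from the group's segments;
#'   \item Dme: `baseline_g + (shift_gk + gradient_k * loading_g) * p_s +
#'     noise`, shift at the repressive module only;
#'   \item Gex: `baseline_g + (gamma * state_gk + beta * shift_gk +
#'     gexshift_gk) * p_s + noise`, combining dose-response, repression and
#'     the pure-expression module.
#' }
#' Survival times are exponential with rate `baseline_rate * hazard_k`,
#' censored administratively at a uniform time in `censor_range`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer RNG seed.
#' @return list with `dataset` (raw, un-centralized [multiomics_dataset()]
#'   including annotations and per-module gene sets) and `truth`
#'   (gene-level module labels, sample-level group/purity/hazard, module
#'   definitions, and the noise-free signal matrices).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1L) {
  validate_synthetic_config(config)
  set.seed(as.integer(seed))
  ng <- config$n_genes; ns <- config$n_samples
  gids <- sprintf("g%04d", seq_len(ng))
  sids <- sprintf("S%03d", seq_len(ns))
  grp <- rep(vapply(config$groups, `[[`, character(1), "name"),
             vapply(config$groups, `[[`, numeric(1), "size"))

  # low-purity samples drawn per group
  purity <- rep(1, ns)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    n_low <- round(config$low_purity_fraction * length(idx))
    if (n_low > 0) purity[sample(idx, n_low)] <- config$alpha
  }

  mod_of_gene <- rep(NA_character_, ng)
  for (m in names(config$modules)) {
    r <- config$modules[[m]]
    mod_of_gene[r[1]:r[2]] <- m
  }

  # per-gene deterministic structure; the global methylation gradient is a
  # background process and leaves the planted modules untouched
  gradient_loading <- stats::runif(ng, 0, 0.5)
  gradient_loading[!is.na(mod_of_gene)] <- 0
  # module genes respond with heterogeneous susceptibility: per-gene effect
  # multiplier on segment states, methylation shifts and expression shifts,
  # so cross-gene scatter plots reproduce the planted couplings
  effect_mult <- rep(1, ng)
  effect_mult[!is.na(mod_of_gene)] <-
    stats::runif(sum(!is.na(mod_of_gene)),
                 config$effect_mult_range[1], config$effect_mult_range[2])
  base_gex <- stats::rnorm(ng, 7, 1)
  base_dme <- stats::runif(ng, 0.3, 0.7)

  state <- matrix(0, ng, ns)          # CNV segment state per gene x sample
  dme_shift <- matrix(0, ng, ns)      # repressive-module methylation shift
  gex_shift <- matrix(0, ng, ns)      # pure-expression module shift
  gradient <- matrix(0, ng, ns)       # global methylation gradient
  rep_rng <- config$modules$repressive
  pure_rng <- config$modules$pure_gex
  for (gdef in config$groups) {
    cols <- which(grp == gdef$name)
    for (seg in gdef$cnv_segments)
      state[seg[1]:seg[2], cols] <- seg[3]
    dme_shift[rep_rng[1]:rep_rng[2], cols] <- gdef$dme_shift
    gex_shift[pure_rng[1]:pure_rng[2], cols] <- gdef$gex_shift
    gradient[, cols] <- gdef$dme_gradient * gradient_loading
  }
  pw <- matrix(purity, ng, ns, byrow = TRUE)
  state <- state * effect_mult
  dme_shift <- dme_shift * effect_mult
  gex_shift <- gex_shift * effect_mult

  sig_cnv <- state * pw
  sig_dme <- base_dme + (dme_shift + gradient) * pw
  sig_gex <- base_gex +
    (config$gamma * state + config$beta * dme_shift + gex_shift) * pw

  noise <- function(sd) matrix(stats::rnorm(ng * ns, 0, sd), ng, ns)
  dn <- list(gids, sids)
  mk <- function(sig, sd, modality) {
    v <- sig + noise(sd)
    dimnames(v) <- dn
    omics_matrix(v, modality)
  }
  gex <- mk(sig_gex, config$noise_sd[["Gex"]], "Gex")
  dme <- mk(sig_dme, config$noise_sd[["Dme"]], "Dme")
  cnv <- mk(sig_cnv, config$noise_sd[["CNV"]], "CNV")

  hazard <- vapply(config$groups, `[[`, numeric(1), "hazard")
  names(hazard) <- vapply(config$groups, `[[`, character(1), "name")
  death <- stats::rexp(ns, rate = config$baseline_rate * hazard[grp])
  censor <- stats::runif(ns, config$censor_range[1], config$censor_range[2])
  ann <- data.frame(sample_id = sids, group = grp,
                    time = pmin(death, censor),
                    event = as.integer(death <= censor))

  sets <- lapply(names(config$modules), function(m) {
    r <- config$modules[[m]]
    gene_set(paste0("module_", m), gids[r[1]:r[2]], category = "planted")
  })

  dataset <- multiomics_dataset(gex, dme, cnv, annotations = ann,
                                gene_sets = sets)
  truth <- list(
    genes = data.frame(gene_id = gids, module = mod_of_gene,
                       gradient_loading = gradient_loading,
                       effect_mult = effect_mult),
    samples = data.frame(sample_id = sids, group = grp, purity = purity,
                         hazard = as.numeric(hazard[grp])),
    modules = lapply(config$modules, function(r)
      gids[r[1]:r[2]]),
    signals = list(Gex = sig_gex, Dme = sig_dme, CNV = sig_cnv),
    config = config, seed = as.integer(seed))
  list(dataset = dataset, truth = truth)
}

#' The default synthetic cohort used throughout examples and tests
#'
#' @param seed integer RNG seed.
#' @return as [generate_cohort()], using [synthetic_config()] defaults.
#' @export
default_cohort <- function(seed = 7L) {
  generate_cohort(synthetic_config(), seed = seed)
}
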