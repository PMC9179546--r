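test_that("component labelling agrees with a naive flood fill", {
  set.seed(51)
  for (i in 1:10) {
    mask <- matrix(runif(15 * 15) < 0.35, 15, 15)
    lab <- label_components(mask)
    oracle <- flood_fill_oracle(mask)
    # same partition: identical component memberships (labels may renumber,
    # but both label in row-major discovery order, so they match exactly)
    expect_identical(lab, oracle)
  }
})

test_that("spot detection thresholds at a fraction of the extreme value", {
  g <- matrix(0, 10, 10)
  g[3:5, 3:5] <- 1
  p <- portrait(g, "Gex", "s")
  spots <- detect_spots(p, 0.9, "over")
  expect_length(spots, 1)
  expect_length(spots[[1]]$member_units, 9)

  # two plateaus separated by a gap give two spots
  g2 <- g; g2[8:10, 8:10] <- 1
  spots2 <- detect_spots(portrait(g2, "Gex", "s"), 0.9, "over")
  expect_length(spots2, 2)

  # under-spots mirror with the minimum
  spots3 <- detect_spots(portrait(-g2, "Gex", "s"), 0.9, "under")
  expect_length(spots3, 2)

  # a non-positive maximum yields an empty result with a warning
  expect_warning(none <- detect_spots(portrait(-g, "Gex", "s"), 0.9, "over"),
                 "not positive")
  expect_length(none, 0)
  expect_error(detect_spots(p, 1.2, "over"), "threshold_fraction")
})

test_that("speckles below min_size are discarded", {
  g <- matrix(0, 8, 8)
  g[1, 1] <- 1          # single-cell speckle
  g[5:6, 5:6] <- 1      # 4-cell plateau
  spots <- detect_spots(portrait(g, "Gex", "s"), 0.9, "over", min_size = 3)
  expect_length(spots, 1)
  expect_length(spots[[1]]$member_units, 4)
})

test_that("raising the threshold never selects more cells", {
  set.seed(52)
  fx <- cohort_fixture()
  p <- fx$gp[[1]][["Gex"]]
  sizes <- sapply(c(0.5, 0.7, 0.9, 0.95), function(tf) {
    sp <- withCallingHandlers(detect_spots(p, tf, "over", min_size = 1),
                              warning = function(w) invokeRestart("muffleWarning"))
    sum(lengths(lapply(sp, `[[`, "member_units")))
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("summary spots are labelled clockwise from the top-left diagonal", {
  side <- 9
  mk_portrait <- function(cells) {
    g <- matrix(0, side, side)
    g[cells] <- 1
    portrait(g, "Gex", "grp")
  }
  model <- structure(list(grid_side = side,
                          assignment = setNames(integer(0), character(0)),
                          weights = weight_preset("balanced"),
                          sample_ids = paste0("s", 1:2)),
                     class = "som_model")
  dec <- list(Gex = matrix(0.5, side^2, 2, dimnames = list(NULL, paste0("s", 1:2))),
              Dme = matrix(0, side^2, 2), CNV = matrix(0, side^2, 2))
  # plateau top-left and bottom-right
  g <- matrix(0, side, side)
  g[1:2, 1:2] <- 1
  g[8:9, 8:9] <- 1
  gp <- list(grp = list(Gex = portrait(g, "Gex", "grp")))
  summ <- spot_summary_map(model, dec, gp)
  expect_length(summ$spots, 2)
  expect_identical(summ$spots[[1]]$label, "A")
  # A is the top-left plateau (angle zero starts at the up-left diagonal)
  rcA <- unit_coords(summ$spots[[1]]$member_units, side)
  expect_true(all(rcA <= 2))
  expect_identical(summ$spots[[2]]$label, "B")
  expect_identical(sort(unique(summ$label_grid[rcA])), "A")
})

test_that("planted modules are recovered as distinct spots", {
  fx <- cohort_fixture()
  summ <- spot_summary_map(fx$model, fx$dec, fx$gp)
  truth <- fx$sim$truth
  expect_identical(length(summ$spots), length(truth$modules))
  matched <- character(0)
  for (m in names(truth$modules)) {
    bm <- best_spot_match(summ$spots, truth$modules[[m]])
    expect_gte(bm$jaccard, 0.8)
    matched <- c(matched, bm$spot$label)
  }
  # one-to-one: no spot absorbs two modules
  expect_identical(anyDuplicated(matched), 0L)
})

test_that("spot gene lists are exactly the genes of their member units", {
  fx <- cohort_fixture()
  summ <- spot_summary_map(fx$model, fx$dec, fx$gp)
  for (s in summ$spots) {
    inside <- names(fx$model$assignment)[fx$model$assignment %in% s$member_units]
    expect_setequal(s$member_genes, inside)
  }
})

test_that("spot profiles average the member units per sample", {
  fx <- cohort_fixture()
  summ <- spot_summary_map(fx$model, fx$dec, fx$gp)
  sp <- summ$spots[[1]]
  prof <- spot_profiles(sp, fx$dec)
  for (m in c("Gex", "Dme", "CNV")) {
    expected <- colMeans(fx$dec[[m]][sp$member_units, , drop = FALSE])
    expect_equal(prof[[m]], expected, tolerance = 1e-12)
  }
  # singleton-unit spot equals that unit's profile
  single <- structure(list(member_units = 5L), class = "spot_module")
  expect_equal(spot_profiles(single, fx$dec)$Gex, fx$dec$Gex[5, ],
               tolerance = 1e-12)
})

test_that("spot correlations recover the planted couplings", {
  # heterogeneous susceptibility spreads genes along the coupling axis,
  # which is what makes per-gene cross-omics scatter plots informative
  sim <- generate_cohort(synthetic_config(effect_mult_range = c(0.5, 1.5)),
                         seed = 54)
  ds <- sim$dataset
  ds2 <- harmonize(multiomics_dataset(
    centralize(ds$gex), centralize(ds$dme), centralize(ds$cnv),
    ds$annotations, ds$gene_sets))
  truth <- sim$truth
  ann <- ds2$annotations
  wt <- ann$sample_id[ann$group == "IDHwt-like"]
  mk_spot <- function(genes) structure(list(member_genes = genes),
                                       class = "spot_module")
  # repression: hyper-methylated genes are the down-expressed ones
  r_ed <- spot_correlation(mk_spot(truth$modules$repressive), ds2,
                           "Gex", "Dme", samples = wt)
  expect_lte(r_ed$r, -0.9)
  # dose-response: copy-number state drives expression up
  r_ec <- spot_correlation(mk_spot(truth$modules$gain), ds2,
                           "Gex", "CNV", samples = wt)
  expect_gte(r_ec$r, 0.9)
  # identical modalities correlate perfectly
  r_self <- spot_correlation(mk_spot(truth$modules$gain), ds2, "Gex", "Gex")
  expect_equal(r_self$r, 1)
  tiny <- mk_spot(c("g0001", "g0002"))
  expect_error(spot_correlation(tiny, ds2, "Gex", "Dme"), "fewer than 3")
})

test_that("spot frequencies tabulate per-sample spot counts by group", {
  fx <- cohort_fixture()
  ann <- fx$ds$annotations
  sf <- spot_frequencies(fx$model, fx$dec, ann, "Gex")
  # fractions per group sum to 1
  agg <- aggregate(fraction ~ group, sf$table, sum)
  expect_equal(agg$fraction, rep(1, nrow(agg)), tolerance = 1e-9)
  # counts match a per-sample loop
  set.seed(53)
  for (sid in sample(fx$model$sample_ids, 5)) {
    p <- sample_portrait(fx$model, fx$dec, sid, "Gex")
    n <- 0
    for (sgn in c("over", "under"))
      n <- n + length(withCallingHandlers(
        detect_spots(p, 0.9, sgn),
        warning = function(w) invokeRestart("muffleWarning")))
    expect_identical(unname(sf$counts[sid]), as.integer(n))
  }
})
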