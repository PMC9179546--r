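test_that("sample portraits index the decomposed metagenes on the grid", {
  fx <- cohort_fixture()
  sid <- fx$model$sample_ids[3]
  p <- sample_portrait(fx$model, fx$dec, sid, "Gex")
  side <- fx$model$grid_side
  # independent loop over units
  for (u in c(1, 2, side, side + 1, side^2)) {
    rc <- unit_coords(u, side)
    expect_identical(p$grid[rc[1, "row"], rc[1, "col"]],
                     unname(fx$dec$Gex[u, sid]))
  }
  # recomputation from the raw unit vectors and weights
  w <- unclass(fx$model$weights)[["Gex"]]
  bb <- fx$model$block_boundaries$Gex
  man <- fx$model$unit_vectors[, bb][, 3] / w
  expect_equal(units_from_grid(p$grid), unname(man), tolerance = 1e-12)

  # the three modality portraits share shape (cell-to-gene alignment)
  pd <- sample_portrait(fx$model, fx$dec, sid, "Dme")
  pc <- sample_portrait(fx$model, fx$dec, sid, "CNV")
  expect_identical(dim(p$grid), dim(pd$grid))
  expect_identical(dim(p$grid), dim(pc$grid))
  expect_error(sample_portrait(fx$model, fx$dec, "nope", "Gex"),
               "unknown sample")
})

test_that("group mean portraits average cell-wise", {
  g1 <- portrait(matrix(1, 3, 3), "Gex", "a")
  g3 <- portrait(matrix(3, 3, 3), "Gex", "b")
  expect_equal(group_mean_portrait(list(g1, g3))$grid, matrix(2, 3, 3))
  expect_equal(group_mean_portrait(list(g1))$grid, g1$grid)
  expect_error(group_mean_portrait(list()), "empty group")

  set.seed(31)
  ps <- lapply(1:5, function(i) portrait(matrix(rnorm(9), 3, 3), "Dme", i))
  m <- group_mean_portrait(ps)$grid
  for (r in 1:3) for (c in 1:3)
    expect_equal(m[r, c], mean(sapply(ps, function(p) p$grid[r, c])),
                 tolerance = 1e-12)
})

test_that("cohort mean equals the mean over any grouping partition", {
  fx <- cohort_fixture()
  ids <- fx$model$sample_ids
  all_p <- lapply(ids, function(s) sample_portrait(fx$model, fx$dec, s, "Gex"))
  total <- group_mean_portrait(all_p)$grid
  # partition into arbitrary halves, then average the group means weighted
  h1 <- group_mean_portrait(all_p[1:40])$grid
  h2 <- group_mean_portrait(all_p[41:120])$grid
  expect_equal((40 * h1 + 80 * h2) / 120, total, tolerance = 1e-12)
})

test_that("cohort mean portrait of an identity-assignment model is zero", {
  ds <- tiny_dataset(16, 4, seed = 32)
  w <- weight_preset("balanced")
  pr <- combine_modalities(ds, w)
  model <- structure(list(grid_side = 4, unit_vectors = unname(pr$vectors),
                          weights = w, block_boundaries = pr$block_boundaries,
                          sample_ids = pr$sample_ids,
                          assignment = setNames(1:16, rownames(pr$vectors))),
                     class = "som_model")
  dec <- decompose_model(model)
  ids <- pr$sample_ids
  ps <- lapply(ids, function(s) sample_portrait(model, dec, s, "Gex"))
  expect_lt(max(abs(group_mean_portrait(ps)$grid)), 1e-9)
})

test_that("variance maps hold the cross-sample metagene variance", {
  dec <- list(Gex = matrix(c(5, 5, 5, 5,
                             -1, 1, -1, 1,
                             0, 0, 1, 1,
                             2, 4, 6, 8), 4, 4, byrow = TRUE))
  vm <- variance_map(dec, "Gex", 2)
  expect_equal(units_from_grid(vm$grid), apply(dec$Gex, 1, var),
               tolerance = 1e-12)
  expect_identical(vm$grid[1, 1], 0)          # constant profile
  # two-point profile (-1, 1) has variance 2
  expect_equal(variance_map(list(Gex = matrix(c(-1, 1), 1, 2)), "Gex", 1)
               $grid[1, 1], 2)
  expect_error(variance_map(list(Gex = matrix(1, 4, 1)), "Gex", 2),
               ">= 2 samples")
})

test_that("metagene covariance maps match a double-loop computation", {
  fx <- cohort_fixture(seed = 7, grid_side = 20)
  cm <- metagene_covariance_map(fx$model, fx$ds, "Dme")
  G <- fx$ds$dme$values
  M <- fx$dec$Dme
  side <- fx$model$grid_side
  vals <- units_from_grid(cm$grid)
  set.seed(33)
  for (u in sample(side^2, 25)) {
    genes <- names(fx$model$assignment)[fx$model$assignment == u]
    expected <- if (length(genes) == 0) 0 else
      mean(vapply(genes, function(g) cov(G[g, ], M[u, ]), numeric(1)))
    expect_equal(vals[u], expected, tolerance = 1e-9)
  }
  # empty units are exactly zero
  empty_units <- which(tabulate(fx$model$assignment, side^2) == 0)
  if (length(empty_units) > 0)
    expect_true(all(vals[empty_units] == 0))
})

test_that("a unit whose single gene equals its metagene maps to var(p)", {
  ds <- tiny_dataset(4, 3, seed = 34)
  w <- weight_preset("balanced")
  pr <- combine_modalities(ds, w)
  model <- structure(list(grid_side = 2, unit_vectors = unname(pr$vectors),
                          weights = w, block_boundaries = pr$block_boundaries,
                          sample_ids = pr$sample_ids,
                          assignment = setNames(1:4, rownames(pr$vectors))),
                     class = "som_model")
  cm <- metagene_covariance_map(model, ds, "Gex")
  expect_equal(units_from_grid(cm$grid),
               unname(apply(ds$gex$values, 1, var)), tolerance = 1e-12)
})
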