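test_that("generation is a deterministic function of the configuration", {
  cfg <- sim_config(n_cells = 80, n_genes = 15, n_zones = 3, seed = 40)
  d1 <- generate_spatial_dataset(cfg)
  d2 <- generate_spatial_dataset(cfg)
  expect_identical(d1$profile$values, d2$profile$values)
  expect_identical(d1$coords, d2$coords)
  expect_identical(d1$profile$cell_types, d2$profile$cell_types)
  d3 <- generate_spatial_dataset(sim_config(n_cells = 80, n_genes = 15,
                                            n_zones = 3, seed = 41))
  expect_false(identical(d1$profile$values, d3$profile$values))
  expect_true(all(d1$profile$values >= 0))
  expect_equal(length(unique(d1$profile$cell_types)), 3L)
})

test_that("zone programs are recoverable in the noise-free limit", {
  cfg <- sim_config(n_cells = 150, n_genes = 40, n_zones = 3,
                    dispersion = 1e-6, nuisance = 0, seed = 11)
  ds <- generate_spatial_dataset(cfg)
  X <- log1p(ds$profile$values)
  D <- as.matrix(dist(X)); diag(D) <- Inf
  pred <- ds$profile$cell_types[apply(D, 1, which.min)]
  expect_equal(mean(pred == ds$profile$cell_types), 1)
})

test_that("very smooth noise-free expression carries no neighbor signal", {
  cfg <- sim_config(n_cells = 200, n_genes = 20, n_zones = 1,
                    smoothness = 1e3, dispersion = 1e-9, nuisance = 0,
                    seed = 12)
  ds <- generate_spatial_dataset(cfg)
  # expression is constant in space up to numerical noise
  expect_lt(max(apply(ds$profile$values, 2, sd) /
                  colMeans(ds$profile$values)), 1e-4)
})

test_that("spatial autocorrelation decays with distance", {
  cfg <- sim_config(n_cells = 300, n_genes = 50, n_zones = 4,
                    nuisance = 0.5, seed = 13)
  ds <- generate_spatial_dataset(cfg)
  X <- scale(log1p(ds$profile$values))
  d <- as.matrix(dist(ds$coords))
  bins <- list(c(0, 0.05), c(0.1, 0.15), c(0.25, 0.3))
  corr <- vapply(bins, function(b) {
    sel <- d > b[1] & d <= b[2] & upper.tri(d)
    idx <- which(sel, arr.ind = TRUE)
    mean(rowMeans(X[idx[, 1], ] * X[idx[, 2], ]))
  }, numeric(1))
  expect_gt(corr[1], corr[2])
  expect_gt(corr[2], corr[3])
})

test_that("query replicates share the tissue but not the noise", {
  ds <- small_reference(seed = 42)$raw
  q1 <- make_query(ds, seed = 100)
  q2 <- make_query(ds, seed = 100)
  expect_identical(q1$profile$values, q2$profile$values)
  q3 <- make_query(ds, seed = 101)
  expect_false(identical(q1$profile$values, q3$profile$values))
  # identity configuration: reference's own seed reproduces it exactly
  q0 <- make_query(ds, jitter = 0, dropout_rate = 0, seed = 42)
  expect_equal(unname(q0$profile$values), unname(ds$profile$values))
  expect_equal(unname(q0$true_coords), unname(ds$coords))
  expect_equal(nrow(q1$true_coords), nrow(q1$profile$values))
  expect_error(make_query(ds, dropout_rate = 1), "dropout_rate")
})

test_that("dropout zeroes the expected fraction of entries", {
  ds <- small_reference(n = 200, g = 30, seed = 43)$raw
  q0 <- make_query(ds, seed = 50, dropout_rate = 0)
  q5 <- make_query(ds, seed = 50, dropout_rate = 0.5)
  pos <- q0$profile$values > 0
  frac <- mean(q5$profile$values[pos] == 0)
  se <- sqrt(0.25 / sum(pos))
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("binning to spots conserves counts and respects the grid", {
  cfg <- sim_config(n_cells = 900, n_genes = 10, n_zones = 3,
                    noise_model = "poisson", seed = 44)
  ds <- generate_spatial_dataset(cfg)
  spots <- quiet(bin_to_spots(ds, spot_bin = 9))   # ~10 x 10 grid
  expect_s3_class(spots, "spatial_dataset")
  expect_identical(spots$platform, "spot")
  expect_lte(nrow(spots$profile$values), 100L)
  expect_equal(colSums(spots$profile$values), colSums(ds$profile$values),
               ignore_attr = TRUE)
  expect_false(is.null(spots$profile$cell_types))
  # spot_bin = 1: as many spots as occupied fine-grid cells (near identity)
  one <- quiet(bin_to_spots(ds, spot_bin = 1))
  expect_gt(nrow(one$profile$values), 0.5 * nrow(ds$profile$values))
  expect_equal(colSums(one$profile$values), colSums(ds$profile$values),
               ignore_attr = TRUE)
})
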