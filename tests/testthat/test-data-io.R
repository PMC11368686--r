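test_that("csv datasets round-trip with coordinates and labels", {
  vals <- matrix(c(1, 2, 0, 4, 5, 3), 3, 2)
  ds <- spatial_dataset(counts_profile(vals, genes = c("g1", "g2"),
                                       types = c("a", "a", "b")),
                        coords = cbind(c(0, 1, 2), c(2, 1, 0)))
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f, "csv")
  back <- load_dataset(f, "csv")
  expect_s3_class(back, "spatial_dataset")
  expect_equal(dim(back), c(3L, 2L))
  expect_equal(unname(back$profile$values), unname(vals))
  expect_equal(unname(back$coords), unname(ds$coords))
  expect_equal(back$profile$cell_types, c("a", "a", "b"))
})

test_that("mtx_dir load equals csv load and real values survive to 1e-12", {
  set.seed(4)
  vals <- matrix(rpois(50, 5), 10, 5)
  prof <- counts_profile(vals)
  fc <- tempfile(fileext = ".csv")
  fm <- tempfile("mtx")
  write_dataset(prof, fc, "csv")
  write_dataset(prof, fm, "mtx_dir")
  a <- load_dataset(fc, "csv")
  b <- load_dataset(fm, "mtx_dir")
  expect_equal(a$values, b$values)
  expect_identical(a$gene_ids, b$gene_ids)
  # real-valued round trip through csv
  realp <- expression_profile(matrix(runif(20), 4, 5), is_lognorm = TRUE)
  fr <- tempfile(fileext = ".csv")
  write_dataset(realp, fr, "csv")
  back <- load_dataset(fr, "csv", is_lognorm = TRUE)
  expect_equal(unname(back$values), unname(realp$values), tolerance = 1e-12)
})

test_that("h5ad bridge round-trips expression, coordinates and labels", {
  ds <- small_reference(n = 15, g = 6, zones = 2)$raw
  f <- tempfile(fileext = ".h5ad")
  write_dataset(ds, f, "h5ad")
  back <- load_dataset(f, "h5ad")
  expect_s3_class(back, "spatial_dataset")
  expect_equal(unname(back$profile$values), unname(ds$profile$values),
               tolerance = 1e-9)
  expect_equal(unname(back$coords), unname(ds$coords), tolerance = 1e-9)
  expect_identical(back$profile$cell_types, ds$profile$cell_types)
})

test_that("duplicate gene ids are rejected and named", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,g1,g1", "c1,1,2", "c2,3,4"), f)
  expect_error(load_dataset(f, "csv"), "g1")
  expect_error(counts_profile(matrix(1:4, 2), genes = c("g1", "g1")), "g1")
})

test_that("log_normalize scales to the target and applies log1p", {
  p <- counts_profile(matrix(c(1, 2, 1, 2), 2, 2))
  out <- log_normalize(p, target_sum = 2)
  expect_equal(unname(out$values),
               matrix(log(2), 2, 2), tolerance = 1e-12)
  expect_true(out$is_lognorm)
  # single cell, target equal to its total: plain log1p
  p2 <- counts_profile(matrix(c(4, 0), 1, 2))
  out2 <- log_normalize(p2, target_sum = 4)
  expect_equal(unname(out2$values), matrix(c(log(5), 0), 1, 2),
               tolerance = 1e-12)
  # median target: cells with equal composition normalize identically
  p3 <- counts_profile(matrix(c(1, 2, 4, 1, 2, 4), 3, 2))
  out3 <- log_normalize(p3, "median")
  expect_equal(out3$values[1, ], out3$values[2, ], tolerance = 1e-12)
  expect_equal(out3$values[2, ], out3$values[3, ], tolerance = 1e-12)
})

test_that("log_normalize rejects zero cells and re-application", {
  p <- counts_profile(matrix(c(1, 0, 2, 0), 2, 2),
                      cells = c("ok", "empty"))
  expect_error(log_normalize(p), "empty")
  ln <- log_normalize(counts_profile(matrix(1:4, 2, 2)))
  expect_error(log_normalize(ln), "already log-normalized")
})

test_that("align_genes intersects in reference order, symmetric content", {
  sc <- counts_profile(matrix(1:6, 2, 3), genes = c("a", "b", "c"))
  st <- counts_profile(matrix(1:6, 2, 3), genes = c("b", "c", "d"))
  out <- quiet(align_genes(sc, st))
  expect_identical(out$sc$gene_ids, c("b", "c"))
  expect_identical(out$st$gene_ids, c("b", "c"))
  expect_equal(out$sc$values[, "b"], sc$values[, "b"])
  # identical gene sets: values unchanged
  same <- quiet(align_genes(sc, sc))
  expect_equal(same$sc$values, sc$values)
  # disjoint sets: error
  st2 <- counts_profile(matrix(1:4, 2, 2), genes = c("x", "y"))
  expect_error(quiet(align_genes(sc, st2)), "no shared genes")
})

test_that("select_hvg keeps the most dispersed genes in input order", {
  set.seed(9)
  n <- 40
  vals <- cbind(rep(3, n),                 # constant: zero variance
                rexp(n, 1),                # moderate
                c(rep(0, n / 2), rep(50, n / 2)))  # planted high variance
  p <- counts_profile(vals, genes = c("flat", "mid", "planted"))
  top1 <- select_hvg(p, 1)
  expect_identical(top1$gene_ids, "planted")
  top2 <- select_hvg(p, 2)
  expect_identical(top2$gene_ids, c("mid", "planted"))  # input order kept
  expect_false("flat" %in% top2$gene_ids)
  expect_equal(select_hvg(p, 3)$values, p$values)       # identity at n_top = n
  expect_error(select_hvg(p, 4), "n_top")
})
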