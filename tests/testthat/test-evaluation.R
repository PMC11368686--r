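test_that("neighbor hit equals a set-intersection oracle on random instances", {
  set.seed(23)
  for (r in 1:10) {
    n <- sample(30:120, 1)
    coords <- cbind(runif(n), runif(n))
    kmax <- 10L
    pred <- t(replicate(n, sample.int(n, kmax)))
    got <- neighbor_hit(pred, coords, k_values = c(3L, 10L))
    # oracle: sort distances per cell, intersect explicitly
    d <- as.matrix(dist(coords)); diag(d) <- Inf
    for (k in c(3L, 10L)) {
      hits <- vapply(seq_len(n), function(i) {
        truek <- order(d[i, ])[seq_len(k)]
        sum(pred[i, seq_len(k)] %in% truek)
      }, numeric(1))
      expect_equal(unname(got[paste0("k", k)]), mean(hits))
    }
  }
})

test_that("neighbor hit identity and disjoint limits", {
  set.seed(24)
  coords <- cbind(runif(60), runif(60))
  tk <- build_spatial_knn(coords, 10)$neighbor_idx
  expect_equal(unname(neighbor_hit(tk, coords, c(5L, 10L))), c(5, 10))
  # predictions disjoint from the truth score zero: point to cells far in
  # the ranking by reversing the full ordering
  full <- build_spatial_knn(coords, 59)$neighbor_idx
  worst <- full[, 59:50]
  expect_equal(unname(neighbor_hit(worst, coords, 10L)), 0)
  expect_error(neighbor_hit(tk[-1, ], coords, 10L), "different cell counts")
})

test_that("random predictions match the hypergeometric expectation", {
  set.seed(25)
  n <- 500L; k <- 20L
  coords <- cbind(runif(n), runif(n))
  tk <- build_spatial_knn(coords, k)$neighbor_idx
  trials <- vapply(1:200, function(t) {
    pred <- t(replicate(n, sample.int(n, k)))
    hits <- vapply(seq_len(n), function(i) sum(pred[i, ] %in% tk[i, ]),
                   numeric(1))
    mean(hits)
  }, numeric(1))
  expected <- k^2 / (n - 1)
  se <- sd(trials) / sqrt(length(trials))
  expect_lt(abs(mean(trials) - expected), 3 * se + 1e-3)
})

test_that("neighborhood JSD matches a direct KL computation and its bounds", {
  set.seed(26)
  js <- spatialcontrast:::js_distance
  for (r in 1:50) {
    m <- sample(2:6, 1)
    P <- as.numeric(rmultinom(1, 20, runif(m))) / 20
    Q <- as.numeric(rmultinom(1, 20, runif(m))) / 20
    # direct KL-based oracle
    M <- (P + Q) / 2
    kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
    expect_equal(js(P, Q), sqrt((kl(P, M) + kl(Q, M)) / 2),
                 tolerance = 1e-10)
    expect_equal(js(P, Q), js(Q, P), tolerance = 1e-12)
    expect_gte(js(P, Q), 0)
    expect_lte(js(P, Q), sqrt(log(2)) + 1e-12)
  }
  expect_equal(js(c(1, 0), c(1, 0)), 0)
  expect_equal(js(c(1, 0), c(0, 1)), sqrt(log(2)), tolerance = 1e-12)
  expect_equal(js(c(1, 0), c(0, 1), base = 2), 1, tolerance = 1e-12)
})

test_that("per-cell neighborhood JSD is zero when predictions equal truth", {
  set.seed(27)
  n <- 80
  coords <- cbind(runif(n), runif(n))
  types <- sample(c("a", "b", "c"), n, replace = TRUE)
  tk <- build_spatial_knn(coords, 10)$neighbor_idx
  out <- neighborhood_jsd(tk, coords, types, k = 10)
  expect_equal(out$per_cell, rep(0, n))
  expect_equal(unname(out$per_type), rep(0, 3))
  expect_named(out$per_type, c("a", "b", "c"))
  expect_error(neighborhood_jsd(tk, coords, NULL, 10), "cell_types")
})

test_that("global Spearman is 1 under isometry and ~0 under shuffling", {
  set.seed(28)
  n <- 300
  coords <- cbind(runif(n), runif(n))
  expect_equal(global_spearman(coords, coords)$mean, 1)
  # rotation + translation + uniform scaling preserves distance ranks
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  iso <- 3.2 * coords %*% R + matrix(c(10, -4), n, 2, byrow = TRUE)
  expect_equal(global_spearman(iso, coords)$mean, 1)
  shuf <- coords[sample.int(n), ]
  expect_lt(abs(global_spearman(shuf, coords)$mean), 0.1)
  # constant distance vectors are excluded and counted
  degen <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(2, 2))
  same <- degen; same[4, ] <- c(9, 9)
  res <- global_spearman(matrix(c(0, 0), 4, 2, byrow = TRUE) + 0 * degen,
                         degen)
  expect_equal(res$n_undefined, 4L)
})

test_that("shuffled null is seeded and degenerates correctly", {
  set.seed(29)
  n <- 60
  coords <- cbind(runif(n), runif(n))
  types_one <- rep("only", n)
  pred <- build_spatial_knn(coords, 10)$neighbor_idx
  null1 <- shuffled_null(function(shuf)
    mean(neighborhood_jsd(pred, shuf, types_one, k = 10)$per_cell),
    coords, n_perm = 5, seed = 3)
  expect_equal(null1$values, rep(0, 5))      # a single type: JSD always 0
  null2 <- shuffled_null(function(shuf)
    global_spearman(shuf, coords)$mean, coords, n_perm = 8, seed = 3)
  null3 <- shuffled_null(function(shuf)
    global_spearman(shuf, coords)$mean, coords, n_perm = 8, seed = 3)
  expect_identical(null2$values, null3$values)
  expect_error(shuffled_null(function(x) 0, coords, n_perm = 0), "n_perm")
})

test_that("evaluation report aggregates and serializes", {
  set.seed(30)
  n <- 60
  coords <- cbind(runif(n), runif(n))
  types <- sample(c("a", "b"), n, replace = TRUE)
  tk <- build_spatial_knn(coords, 20)$neighbor_idx
  rep1 <- evaluation_report(tk, coords, cell_types = types,
                            pred_coords = coords, k_values = c(10L, 20L),
                            jsd_k = 10L)
  expect_equal(unname(rep1$hit_curve), c(10, 20))
  expect_equal(unname(rep1$hit_ratio), c(1, 1))
  expect_equal(rep1$jsd_mean, 0)
  expect_equal(rep1$spearman_mean, 1)
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  write_evaluation(rep1, jf, tf)
  expect_true(file.exists(jf) && file.exists(tf))
  parsed <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(parsed$spearman_mean, 1)
})
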