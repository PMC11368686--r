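test_that("cosine similarity handles identity, orthogonality and scaling", {
  A <- rbind(c(1, 0), c(0, 1), c(1, 2))
  S <- cosine_similarity(A)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 2], 0)
  expect_equal(cosine_similarity(rbind(c(1, 2)), rbind(c(2, 4)))[1, 1], 1)
  expect_error(cosine_similarity(rbind(c(0, 0), c(1, 1))), "zero-norm")
})

test_that("predict_neighbors equals a full-sort oracle and honors ties", {
  set.seed(14)
  for (r in 1:20) {
    n <- sample(10:200, 1)
    reps <- matrix(rnorm(n * 6), n)
    k <- sample(1:(n - 1), 1)
    got <- predict_neighbors(reps, k)
    # oracle: explicit cosine + full sort per row
    nr <- reps / sqrt(rowSums(reps^2))
    S <- nr %*% t(nr)
    for (i in sample(n, min(n, 5))) {
      s <- S[i, ]; s[i] <- -Inf
      expect_identical(got[i, ], order(-s, seq_len(n))[seq_len(k)])
    }
  }
  # duplicates list each other first; k = n-1 is a full ranking
  reps <- rbind(c(1, 1), c(1, 1), c(-3, 1), c(0, 1))
  nb <- predict_neighbors(reps, 3)
  expect_equal(nb[1, 1], 2L)
  expect_equal(nb[2, 1], 1L)
  expect_setequal(nb[4, ], c(1L, 2L, 3L))
  # 1-D gradient on the circle: interior cells pick sequence neighbors
  theta <- seq(0, 1, length.out = 12)
  circ <- cbind(cos(theta), sin(theta))
  nbc <- predict_neighbors(circ, 2)
  for (i in 2:11) expect_setequal(nbc[i, ], c(i - 1L, i + 1L))
  expect_error(predict_neighbors(circ, 12), "k must")
})

test_that("mds_embed recovers exact planar dissimilarity structure", {
  set.seed(5)
  pts <- cbind(runif(50), runif(50))
  reps <- planar_reps(pts)
  X <- mds_embed(reps, seed = 1)
  rho <- cor(as.vector(dist(X)), as.vector(dist(pts)), method = "spearman")
  expect_gte(rho, 0.99)
  expect_identical(X, mds_embed(reps, seed = 1))
  # identical representations: all embedded distances collapse to ~0
  same <- matrix(rep(c(1, 2, 3), each = 5), 5)
  X0 <- mds_embed(same, seed = 1)
  expect_lt(max(dist(X0)), 1e-8)
})

test_that("weighted similarity collapses to 2x cosine at K = 1", {
  set.seed(6)
  sc <- matrix(rnorm(8 * 4), 8)
  st <- matrix(rnorm(12 * 4), 12)
  S1 <- weighted_similarity(sc, st, K = 1)
  expect_equal(S1, 2 * cosine_similarity(sc, st), tolerance = 1e-12)
  # per-row argmax at any K matches the plain-cosine argmax here
  S3 <- weighted_similarity(sc, st, K = 3)
  expect_equal(dim(S3), c(8L, 12L))
  expect_equal(apply(S1, 1, which.max),
               apply(cosine_similarity(sc, st), 1, which.max))
  # identical query cells give identical rows at any K
  sc_same <- matrix(rep(c(1, 2, 0, 1), each = 5), 5)
  Ss <- weighted_similarity(sc_same, st, K = 2)
  for (i in 2:5) expect_equal(Ss[i, ], Ss[1, ], tolerance = 1e-12)
  expect_error(weighted_similarity(sc, st, K = 9), "K must")
})

test_that("map_to_reference takes the argmax, allows clumping, is equivariant", {
  S <- rbind(c(0.1, 0.9, 0.3),
             c(0.1, 0.9, 0.3),
             c(0.5, 0.5, 0.2))   # tie in row 3 -> lower index
  coords <- cbind(c(0, 1, 2), c(5, 6, 7))
  m <- map_to_reference(S, coords)
  expect_equal(m$assigned_st_index, c(2L, 2L, 1L))
  expect_equal(unname(m$coords[1, ]), c(1, 6))
  # permuting reference rows permutes assignments accordingly
  perm <- c(3L, 1L, 2L)
  m2 <- map_to_reference(S[, perm], coords[perm, ])
  expect_equal(m2$coords, m$coords)
  expect_error(map_to_reference(S, coords[0, ]), "empty")
})

test_that("confidence scores are entropy-normalized into [0, 1]", {
  set.seed(15)
  st_coords <- cbind(runif(40), runif(40))
  # uniform similarities: every cell at maximal entropy -> all C = 0
  S_unif <- matrix(0.5, 6, 40)
  C0 <- confidence_scores(S_unif, st_coords, n_top = 5, m_exclude = 2)
  expect_equal(unname(C0), rep(0, 6), tolerance = 1e-12)
  # one concentrated cell (H ~ 0) -> C ~ 1; spread cell -> C = 0
  S <- matrix(rnorm(2 * 40, sd = 0.1), 2, 40)
  S[1, ] <- -50; S[1, 7] <- 50
  C <- confidence_scores(S, st_coords, n_top = 5, m_exclude = 2)
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(C[1], 1, tolerance = 1e-6)
  expect_equal(C[2], 0, tolerance = 1e-12)  # entropy maximizer
  expect_error(confidence_scores(S, st_coords, n_top = 40), "n_top")
})

test_that("gene contribution matches the linear-encoder closed form", {
  set.seed(16)
  g <- 6; d <- 4; n <- 5
  W <- matrix(rnorm(g * d), g, d)
  st <- linear_state(W)
  prof <- expression_profile(matrix(runif(n * g), n, g), is_lognorm = TRUE)
  C <- gene_contribution(st, prof, epsilon = 0.01)
  for (j in seq_len(g))
    expect_equal(unname(C[, j]), rep(sqrt(sum(W[j, ]^2)), n),
                 tolerance = 1e-5)
  # identity map: contribution 1 everywhere
  Ci <- gene_contribution(linear_state(diag(g)), prof)
  expect_equal(unname(Ci), matrix(1, n, g), tolerance = 1e-9)
  # a gene the encoder ignores contributes 0
  W0 <- W; W0[3, ] <- 0
  C0 <- gene_contribution(linear_state(W0), prof)
  expect_equal(unname(C0[, 3]), rep(0, n))
  expect_error(gene_contribution(st, prof, epsilon = 0), "epsilon")
})

test_that("predict() dispatches the full query workflow", {
  sr <- small_reference()
  fit <- quiet(spatialcontrast(sr$ref, small_config(5L)))
  q <- make_query(sr$raw, seed = 31)
  qln <- log_normalize(q$profile)
  reps <- predict(fit, qln, type = "representation")
  expect_equal(dim(reps), c(120L, 32L))
  nb <- predict(fit, qln, type = "neighbors", k = 7)
  expect_equal(dim(nb), c(120L, 7L))
  xy <- predict(fit, qln, type = "mds", seed = 4)
  expect_equal(dim(xy), c(120L, 2L))
  mp <- predict(fit, qln, type = "mapping", n_top = 10, m_exclude = 5)
  expect_s3_class(mp, "data.frame")
  expect_true(all(mp$confidence >= 0 & mp$confidence <= 1, na.rm = TRUE))
  expect_true(all(mp$st_index %in% seq_len(120)))
  gc_tab <- predict(fit, qln, type = "genes")
  expect_equal(dim(gc_tab), c(120L, 24L))
  expect_true(all(gc_tab >= 0))
})
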