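# shared fixtures, built in code

quiet <- function(expr) suppressMessages(expr)

# counts profile with named genes/cells
counts_profile <- function(values, genes = NULL, cells = NULL, types = NULL) {
  values <- as.matrix(values)
  expression_profile(values,
                     gene_ids = genes %||% paste0("g", seq_len(ncol(values))),
                     cell_ids = cells %||% paste0("c", seq_len(nrow(values))),
                     cell_types = types)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# encoder state that is a pure linear map X %*% W (no norm, no activation)
linear_state <- function(W, gene_ids = paste0("g", seq_len(nrow(W)))) {
  structure(list(encoder = list(list(type = "linear",
                                     par = list(W = W,
                                                b = rep(0, ncol(W))))),
                 input_gene_ids = gene_ids,
                 config = NULL),
            class = "encoder_state")
}

# unit-norm representations whose pairwise cosine equals 1 - c * D for the
# Euclidean distance matrix D of 2-D points (exact planar dissimilarity
# structure; the Gram matrix 1 - cD is PSD for small c)
planar_reps <- function(points, shrink = 0.5) {
  D <- as.matrix(stats::dist(points))
  M <- 1 - (shrink / max(D)) * D
  e <- eigen(M, symmetric = TRUE)
  stopifnot(min(e$values) > -1e-10)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)))
}

# naive double-loop infoNCE oracle (independent of the vectorized path)
nce_oracle <- function(Z, tau, mode = "with_positive") {
  Z <- Z / sqrt(rowSums(Z^2))
  N <- nrow(Z)
  half <- N / 2
  total <- 0
  for (i in seq_len(N)) {
    p <- if (i <= half) i + half else i - half
    num <- exp(sum(Z[i, ] * Z[p, ]) / tau)
    den <- 0
    for (j in seq_len(N)) {
      if (j == i) next
      if (mode == "negatives_only" && j == p) next
      den <- den + exp(sum(Z[i, ] * Z[j, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / N
}

# small log-normalized synthetic reference + raw dataset, shared by the
# quick training tests
small_reference <- function(n = 120, g = 24, zones = 3, seed = 21) {
  ds <- generate_spatial_dataset(sim_config(n_cells = n, n_genes = g,
                                            n_zones = zones, seed = seed))
  ref <- spatial_dataset(log_normalize(ds$profile), ds$coords, ds$platform)
  attr(ref, "generator") <- attr(ds, "generator")
  list(raw = ds, ref = ref)
}

small_config <- function(epochs, seed = 21L, ...) {
  model_config(epochs = epochs, batch_size = 16L, positive_knn = 8L,
               encoder_dims = c(64L, 32L), projector_dims = c(32L, 16L),
               seed = seed, ...)
}
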