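#' Configuration for the synthetic spatial-expression generator
#'
#' The generator emulates the structure the contrastive method assumes:
#' cells scattered in the unit square whose expression varies smoothly in
#' space, with discrete zone (cell-type) programs layered on top. Zones are
#' Voronoi regions around seeded centers; continuous variation comes from
#' per-gene Gaussian-bump gradient fields with a given length-scale; counts
#' are drawn from a chosen noise model around the resulting spatial mean.
#' In addition, a small number of non-spatial latent factors (cell state,
#' cycle) with dense gene loadings enter every cell's log-mean: dissociated
#' single-cell data are dominated by such variation, which is why raw
#' expression similarity is a poor predictor of spatial proximity and a
#' learned representation is needed at all.
#'
#' @param n_cells number of cells (default 800).
#' @param n_genes number of genes (default 100).
#' @param n_zones number of Voronoi zones / cell types (default 5).
#' @param smoothness spatial kernel length-scale of the gradient fields, in
#'   unit-square units (default 0.15); larger values give flatter fields.
#' @param noise_model `"gaussian"` (multiplicative, truncated at zero),
#'   `"poisson"`, or `"negative_binomial"`.
#' @param dispersion noise level: the relative standard deviation for the
#'   gaussian model, or the negative-binomial dispersion (`size =
#'   1/dispersion`); ignored by the Poisson model. Default 0.8.
#' @param nuisance standard deviation of the non-spatial factor loadings
#'   (default 1: non-spatial variation on the order of the spatial signal,
#'   as in dissociated single-cell data; 0 disables the factors).
#' @param spot_bin optional target number of cells per spot, used by
#'   [bin_to_spots()].
#' @param seed integer seed; the full dataset is a deterministic function
#'   of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 800L, n_genes = 100L, n_zones = 5L,
                       smoothness = 0.15,
                       noise_model = c("gaussian", "poisson",
                                       "negative_binomial"),
                       dispersion = 0.8, nuisance = 1.0, spot_bin = NULL,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  n_cells <- as.integer(n_cells); n_genes <- as.integer(n_genes)
  n_zones <- as.integer(n_zones)
  if (n_cells < 1L || n_genes < 1L || n_zones < 1L)
    stop("n_cells, n_genes and n_zones must be positive")
  if (n_zones > n_cells) stop("n_zones cannot exceed n_cells")
  if (!is.finite(smoothness) || smoothness <= 0)
    stop("smoothness must be positive")
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("dispersion must be positive")
  if (!is.finite(nuisance) || nuisance < 0)
    stop("nuisance must be non-negative")
  structure(list(n_cells = n_cells, n_genes = n_genes, n_zones = n_zones,
                 smoothness = smoothness, noise_model = noise_model,
                 dispersion = dispersion, nuisance = nuisance,
                 spot_bin = if (is.null(spot_bin)) NULL
                            else as.integer(spot_bin),
                 seed = as.integer(seed)),
            class = "sim_config")
}

N_BUMPS <- 8L          # gradient-field basis bumps
ZONE_MARKER_FRAC <- 0.3
GRADIENT_GENE_FRAC <- 0.5
N_NUISANCE <- 3L       # non-spatial latent factors (cell state, cycle)

# latent generative state: everything except the noise draw
make_generator <- function(config) {
  set.seed(config$seed)
  g <- config$n_genes
  list(config = config,
       positions = cbind(stats::runif(config$n_cells),
                         stats::runif(config$n_cells)),
       zone_centers = cbind(stats::runif(config$n_zones),
                            stats::runif(config$n_zones)),
       base = stats::rnorm(g, mean = log(5), sd = 0.4),
       zone_effect = matrix(
         ifelse(stats::runif(config$n_zones * g) < ZONE_MARKER_FRAC,
                stats::rnorm(config$n_zones * g, 1.2, 0.4), 0),
         config$n_zones, g),
       bump_centers = cbind(stats::runif(N_BUMPS), stats::runif(N_BUMPS)),
       amplitude = matrix(
         ifelse(stats::runif(N_BUMPS * g) < GRADIENT_GENE_FRAC,
                stats::rnorm(N_BUMPS * g, 0, 0.8), 0),
         N_BUMPS, g),
       nuisance_loadings = matrix(stats::rnorm(N_NUISANCE * g, 0,
                                               config$nuisance),
                                  N_NUISANCE, g))
}

zone_of <- function(positions, centers) {
  d2 <- outer(rowSums(positions^2), rep(1, nrow(centers))) -
    2 * positions %*% t(centers) +
    outer(rep(1, nrow(positions)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

# spatial log-mean expression at given positions
sim_log_mean <- function(positions, gen) {
  cfg <- gen$config
  zones <- zone_of(positions, gen$zone_centers)
  # RBF features [n, N_BUMPS]
  d2 <- outer(rowSums(positions^2), rep(1, N_BUMPS)) -
    2 * positions %*% t(gen$bump_centers) +
    outer(rep(1, nrow(positions)), rowSums(gen$bump_centers^2))
  phi <- exp(-d2 / (2 * cfg$smoothness^2))
  lam <- matrix(gen$base, nrow(positions), cfg$n_genes, byrow = TRUE) +
    gen$zone_effect[zones, , drop = FALSE] +
    phi %*% gen$amplitude
  list(log_mean = lam, zones = zones)
}

# draw expression at given log-means: per-cell non-spatial factor scores
# (cell state unrelated to position) enter the log-mean, then per-entry
# noise per the configured model
sim_expression <- function(log_mean, gen, noise_seed) {
  config <- gen$config
  set.seed(noise_seed)
  scores <- matrix(stats::rnorm(nrow(log_mean) * N_NUISANCE),
                   nrow(log_mean), N_NUISANCE)
  mu <- exp(log_mean + scores %*% gen$nuisance_loadings)
  n <- length(mu)
  switch(config$noise_model,
    gaussian = matrix(pmax(0, mu * (1 + config$dispersion *
                                      stats::rnorm(n))),
                      nrow(mu), ncol(mu)),
    poisson = matrix(stats::rpois(n, mu), nrow(mu), ncol(mu)),
    negative_binomial = matrix(
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion),
      nrow(mu), ncol(mu)))
}

#' Generate a synthetic spatial reference
#'
#' Draws a [spatial_dataset()] from the generative model described in
#' [sim_config()]: uniform cell positions, Voronoi zone labels, smooth
#' per-gene gradient fields, and per-entry noise. The latent generative
#' state is attached (attribute `"generator"`) so that [make_query()] can
#' draw independent replicates from the same tissue.
#'
#' @param config a [sim_config()].
#' @return A `spatial_dataset` of raw (non-negative) counts with cell-type
#'   labels `zone_1..zone_K`, fully reproducible from `config`.
#' @export
generate_spatial_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  gen <- make_generator(config)
  lm <- sim_log_mean(gen$positions, gen)
  values <- sim_expression(lm$log_mean, gen, noise_seed = config$seed)
  dimnames(values) <- NULL
  prof <- expression_profile(values,
                             gene_ids = sprintf("g%03d", seq_len(config$n_genes)),
                             cell_ids = sprintf("cell_%04d",
                                                seq_len(config$n_cells)),
                             cell_types = paste0("zone_", lm$zones),
                             is_lognorm = FALSE)
  ds <- spatial_dataset(prof, gen$positions, platform = "single_cell")
  attr(ds, "generator") <- gen
  ds
}

#' Draw an independent query replicate from a synthetic reference
#'
#' Produces a query expression profile from the same generative process as
#' the reference (same tissue layout and gene programs, new noise), with
#' optional coordinate jitter and per-entry dropout. True coordinates are
#' withheld from the profile and returned separately for evaluation.
#'
#' @param reference a dataset from [generate_spatial_dataset()].
#' @param jitter standard deviation of Gaussian positional jitter
#'   (unit-square units; 0 keeps reference positions).
#' @param dropout_rate probability of zeroing each entry, in `[0, 1)`.
#' @param seed seed for the replicate's noise (a replicate with the
#'   reference's own seed, no jitter and no dropout reproduces the
#'   reference expression exactly).
#' @return List with `profile` (an [expression_profile()] without
#'   coordinates) and `true_coords` (matrix `[n, 2]`).
#' @export
make_query <- function(reference, jitter = 0, dropout_rate = 0,
                       seed = 2L) {
  gen <- attr(reference, "generator")
  if (is.null(gen))
    stop("reference carries no generator state; use ",
         "generate_spatial_dataset()")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (jitter < 0) stop("jitter must be non-negative")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  pos <- gen$positions
  if (jitter > 0) {
    set.seed(seed + 1L)
    pos <- pos + matrix(stats::rnorm(length(pos), 0, jitter),
                        nrow(pos), 2L)
  }
  lm <- sim_log_mean(pos, gen)
  values <- sim_expression(lm$log_mean, gen, noise_seed = seed)
  if (dropout_rate > 0) {
    set.seed(seed + 2L)
    keep <- stats::runif(length(values)) >= dropout_rate
    values <- values * keep
  }
  dimnames(values) <- NULL
  prof <- expression_profile(values,
                             gene_ids = sprintf("g%03d",
                                                seq_len(gen$config$n_genes)),
                             cell_ids = sprintf("query_%04d",
                                                seq_len(nrow(pos))),
                             cell_types = paste0("zone_", lm$zones),
                             is_lognorm = FALSE)
  colnames(pos) <- c("x", "y")
  list(profile = prof, true_coords = pos)
}

#' Pool a single-cell dataset into regular spots
#'
#' Aggregates cells on a regular square grid into multi-cell spots,
#' emulating spot-resolution platforms: spot expression is the sum over
#' member cells, the spot coordinate is the grid-cell center, and the
#' majority cell type is recorded. Empty grid cells are dropped (their
#' count is reported in a message).
#'
#' @param dataset a [spatial_dataset()].
#' @param spot_bin target average number of cells per spot (`>= 1`); the
#'   grid side is `round(sqrt(n_cells / spot_bin))`.
#' @return A `spatial_dataset` with `platform = "spot"`.
#' @export
bin_to_spots <- function(dataset, spot_bin) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  spot_bin <- as.integer(spot_bin)
  if (spot_bin < 1L) stop("spot_bin must be at least 1")
  coords <- dataset$coords
  n <- nrow(coords)
  side <- max(1L, as.integer(round(sqrt(n / spot_bin))))
  rng_x <- range(coords[, 1L]); rng_y <- range(coords[, 2L])
  span <- function(r) if (diff(r) > 0) r else r + c(-0.5, 0.5)
  rng_x <- span(rng_x); rng_y <- span(rng_y)
  bx <- pmin(side, 1L + floor((coords[, 1L] - rng_x[1L]) /
                                diff(rng_x) * side))
  by <- pmin(side, 1L + floor((coords[, 2L] - rng_y[1L]) /
                                diff(rng_y) * side))
  bin <- (by - 1L) * side + bx
  occupied <- sort(unique(bin))
  message("bin_to_spots: ", side, "x", side, " grid, ", length(occupied),
          " occupied spots, ", side^2 - length(occupied), " empty dropped")
  vals <- rowsum(dataset$profile$values, group = bin)  # sorted by bin id
  cx <- rng_x[1L] + ((occupied - 1L) %% side + 0.5) / side * diff(rng_x)
  cy <- rng_y[1L] + ((occupied - 1L) %/% side + 0.5) / side * diff(rng_y)
  majority <- NULL
  if (!is.null(dataset$profile$cell_types)) {
    majority <- vapply(occupied, function(b) {
      tt <- table(dataset$profile$cell_types[bin == b])
      names(tt)[which.max(tt)]
    }, character(1))
  }
  prof <- expression_profile(unname(vals),
                             gene_ids = dataset$profile$gene_ids,
                             cell_ids = sprintf("spot_%04d",
                                                seq_along(occupied)),
                             cell_types = majority,
                             is_lognorm = FALSE)
  spatial_dataset(prof, cbind(cx, cy), platform = "spot")
}
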