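# true spatial kNN used by the evaluation metrics (self excluded)
true_knn <- function(coords, k) build_spatial_knn(coords, k)$neighbor_idx

#' Neighbor-hit curve
#'
#' For each cell, counts how many of its true spatial k-nearest neighbors
#' (Euclidean, self excluded) appear among its predicted k nearest
#' neighbors, and averages over cells for every requested `k`. A random
#' predictor scores about `k^2 / (n - 1)` in expectation.
#'
#' @param pred_knn integer matrix `[n, k_max]` of predicted neighbor
#'   indices (descending similarity).
#' @param true_coords coordinate matrix `[n, 2]` of the same cells.
#' @param k_values neighbor counts to evaluate (default `seq(20, 200, 20)`),
#'   each at most `ncol(pred_knn)`.
#' @return Named numeric vector: mean hit count per `k`.
#' @export
neighbor_hit <- function(pred_knn, true_coords,
                         k_values = seq(20L, 200L, by = 20L)) {
  pred_knn <- as.matrix(pred_knn)
  true_coords <- as.matrix(true_coords)
  n <- nrow(pred_knn)
  if (nrow(true_coords) != n)
    stop("pred_knn and true_coords describe different cell counts")
  k_values <- as.integer(k_values)
  if (any(k_values > ncol(pred_knn)))
    stop("k_values exceed the prediction width (", ncol(pred_knn), ")")
  if (any(k_values >= n))
    stop("k_values must be smaller than the number of cells")
  tk <- true_knn(true_coords, max(k_values))
  out <- vapply(k_values, function(k) {
    hits <- vapply(seq_len(n), function(i)
      length(intersect(pred_knn[i, seq_len(k)], tk[i, seq_len(k)])),
      integer(1))
    mean(hits)
  }, numeric(1))
  names(out) <- paste0("k", k_values)
  out
}

#' Jensen-Shannon distance of neighborhood cell-type composition
#'
#' Compares, per cell, the cell-type proportion vectors of its predicted
#' and true k-nearest neighborhoods via the Jensen-Shannon distance
#' `sqrt(KL(P||M)/2 + KL(Q||M)/2)`, `M = (P+Q)/2`. With the natural
#' logarithm (default) the distance lies in `[0, sqrt(log 2)]`; `base = 2`
#' rescales to `[0, 1]`.
#'
#' @param pred_knn predicted neighbor index matrix `[n, >=k]`.
#' @param true_coords coordinates of the same cells.
#' @param cell_types character vector of labels, one per cell, no missing
#'   values.
#' @param k neighborhood size (default 20).
#' @param base logarithm base, `exp(1)` or `2`.
#' @return List with `per_cell` (numeric vector) and `per_type` (named
#'   vector of means grouped by the focal cell's type).
#' @export
neighborhood_jsd <- function(pred_knn, true_coords, cell_types, k = 20L,
                             base = exp(1)) {
  pred_knn <- as.matrix(pred_knn)
  true_coords <- as.matrix(true_coords)
  n <- nrow(pred_knn)
  if (nrow(true_coords) != n)
    stop("pred_knn and true_coords describe different cell counts")
  if (is.null(cell_types) || length(cell_types) != n || anyNA(cell_types))
    stop("cell_types must be present for every cell")
  k <- as.integer(k)
  if (k > ncol(pred_knn))
    stop("k exceeds the prediction width")
  cell_types <- as.character(cell_types)
  types <- sort(unique(cell_types))
  tk <- true_knn(true_coords, k)
  comp <- function(idx) {
    tab <- table(factor(cell_types[idx], levels = types))
    as.numeric(tab) / length(idx)
  }
  per_cell <- vapply(seq_len(n), function(i)
    js_distance(comp(pred_knn[i, seq_len(k)]), comp(tk[i, ]), base),
    numeric(1))
  per_type <- c(tapply(per_cell, factor(cell_types, levels = types), mean))
  list(per_cell = per_cell, per_type = per_type)
}

# Jensen-Shannon distance between two probability vectors
js_distance <- function(P, Q, base = exp(1)) {
  M <- (P + Q) / 2
  kl <- function(A, B) {
    nz <- A > 0
    sum(A[nz] * (log(A[nz], base = base) - log(B[nz], base = base)))
  }
  d2 <- kl(P, M) / 2 + kl(Q, M) / 2
  sqrt(max(d2, 0))
}

#' Per-cell Spearman correlation of global distance structure
#'
#' For each cell, the Spearman rank correlation between its predicted and
#' true Euclidean distances to all other cells; an isometric (rotated,
#' translated, uniformly scaled) prediction scores 1 for every cell.
#'
#' @param pred_coords predicted coordinates `[n, 2]`.
#' @param true_coords true coordinates `[n, 2]`, same cells, `n >= 3`.
#' @return List with `per_cell` (vector; `NA` where a distance vector is
#'   constant), `mean` (over defined cells) and `n_undefined`.
#' @export
global_spearman <- function(pred_coords, true_coords) {
  pred_coords <- as.matrix(pred_coords)
  true_coords <- as.matrix(true_coords)
  n <- nrow(pred_coords)
  if (nrow(true_coords) != n)
    stop("coordinate matrices describe different cell counts")
  if (n < 3L) stop("need at least 3 cells")
  dp <- as.matrix(stats::dist(pred_coords))
  dt <- as.matrix(stats::dist(true_coords))
  per_cell <- vapply(seq_len(n), function(i) {
    a <- dp[i, -i]; b <- dt[i, -i]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = "spearman")
  }, numeric(1))
  list(per_cell = per_cell,
       mean = mean(per_cell, na.rm = TRUE),
       n_undefined = sum(is.na(per_cell)))
}

#' Shuffled-location null distribution of a metric
#'
#' Recomputes a user metric under random permutations of the true
#' locations, giving the no-spatial-signal baseline the paper-style
#' evaluation compares against.
#'
#' @param metric function taking a permuted coordinate matrix (and, when
#'   `pass_types = TRUE`, the cell types) and returning a numeric scalar.
#' @param true_coords coordinate matrix to permute.
#' @param cell_types optional labels forwarded to `metric`.
#' @param n_perm number of permutations, at least 1.
#' @param seed RNG seed.
#' @param pass_types forward `cell_types` as the metric's second argument.
#' @return List with `values` (length `n_perm`), `mean`, `sd` and
#'   `quantiles` (2.5/25/50/75/97.5%).
#' @export
shuffled_null <- function(metric, true_coords, cell_types = NULL,
                          n_perm = 100L, seed = 1L, pass_types = FALSE) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  true_coords <- as.matrix(true_coords)
  n <- nrow(true_coords)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(p) {
    perm <- sample.int(n)
    shuf <- true_coords[perm, , drop = FALSE]
    if (pass_types) metric(shuf, cell_types) else metric(shuf)
  }, numeric(1))
  list(values = vals, mean = mean(vals), sd = stats::sd(vals),
       quantiles = stats::quantile(vals,
                                   c(0.025, 0.25, 0.5, 0.75, 0.975)))
}

#' Full evaluation report
#'
#' Convenience wrapper computing the neighbor-hit curve, per-cell and
#' per-type neighborhood JSD, and the global Spearman summary in one call.
#'
#' @param pred_knn predicted neighbor index matrix.
#' @param true_coords true coordinates of the evaluated cells.
#' @param cell_types optional labels (JSD is skipped without them).
#' @param pred_coords optional predicted coordinates (Spearman is skipped
#'   without them).
#' @param k_values neighbor-hit curve ks.
#' @param jsd_k JSD neighborhood size.
#' @return List of class `evaluation_report` with components `hit_curve`,
#'   `hit_ratio` (hit/k), `jsd_per_cell`, `jsd_per_type`, `jsd_mean`,
#'   `spearman_per_cell`, `spearman_mean`.
#' @export
evaluation_report <- function(pred_knn, true_coords, cell_types = NULL,
                              pred_coords = NULL,
                              k_values = seq(20L, 200L, by = 20L),
                              jsd_k = 20L) {
  k_values <- k_values[k_values <= ncol(as.matrix(pred_knn))]
  hit <- neighbor_hit(pred_knn, true_coords, k_values)
  out <- list(hit_curve = hit, hit_ratio = hit / k_values,
              jsd_per_cell = NULL, jsd_per_type = NULL, jsd_mean = NA_real_,
              spearman_per_cell = NULL, spearman_mean = NA_real_)
  if (!is.null(cell_types)) {
    jsd <- neighborhood_jsd(pred_knn, true_coords, cell_types, k = jsd_k)
    out$jsd_per_cell <- jsd$per_cell
    out$jsd_per_type <- jsd$per_type
    out$jsd_mean <- mean(jsd$per_cell)
  }
  if (!is.null(pred_coords)) {
    sp <- global_spearman(pred_coords, true_coords)
    out$spearman_per_cell <- sp$per_cell
    out$spearman_mean <- sp$mean
  }
  class(out) <- "evaluation_report"
  out
}

#' @export
#' @method print evaluation_report
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  cat("  mean neighbor hit:\n")
  print(round(x$hit_curve, 3))
  if (!is.na(x$jsd_mean))
    cat(sprintf("  mean neighborhood JSD (k=20): %.4f\n", x$jsd_mean))
  if (!is.na(x$spearman_mean))
    cat(sprintf("  mean global Spearman rho: %.4f\n", x$spearman_mean))
  invisible(x)
}

#' Write an evaluation report to disk
#' @param report an [evaluation_report()].
#' @param json_path,tsv_path output files (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_evaluation <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(hit_curve = as.list(report$hit_curve),
           hit_ratio = as.list(report$hit_ratio),
           jsd_mean = report$jsd_mean,
           jsd_per_type = as.list(report$jsd_per_type),
           spearman_mean = report$spearman_mean),
      json_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (!is.null(tsv_path)) {
    df <- data.frame(metric = c(names(report$hit_curve),
                                "jsd_mean", "spearman_mean"),
                     value = c(unname(report$hit_curve),
                               report$jsd_mean, report$spearman_mean))
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(report)
}
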