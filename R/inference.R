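#' Cosine similarity between representation matrices
#'
#' @param A,B numeric matrices with cells in rows and a shared
#'   representation dimension; `B` defaults to `A`.
#' @return Matrix `[nrow(A), nrow(B)]` of cosine similarities in `[-1, 1]`.
#' @export
cosine_similarity <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("representation dimensions differ (", ncol(A), " vs ", ncol(B), ")")
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0))
    stop("zero-norm representation at row ", which(na == 0)[1L], " of A")
  if (any(nb == 0))
    stop("zero-norm representation at row ", which(nb == 0)[1L], " of B")
  S <- tcrossprod(A / na, B / nb)
  pmin(pmax(S, -1), 1)
}

#' Representation-space nearest neighbors
#'
#' For each cell, the indices of the `k` other cells with the highest
#' cosine similarity of representations. Self is excluded; ties are broken
#' by lower index.
#'
#' @param reps numeric representation matrix `[n, d]`.
#' @param k number of neighbors, `1 <= k < n`.
#' @return Integer matrix `[n, k]`, each row in descending similarity.
#' @export
predict_neighbors <- function(reps, k) {
  reps <- as.matrix(reps)
  n <- nrow(reps)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop("k must satisfy 1 <= k < n (n = ", n, ")")
  S <- cosine_similarity(reps)
  diag(S) <- -Inf
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(-S[i, ], seq_len(n))   # descending sim, ties to lower index
    out[i, ] <- ord[seq_len(k)]
  }
  out
}

#' Metric MDS pseudo-space embedding
#'
#' Embeds representations into 2-D by stress-majorization (SMACOF) on the
#' dissimilarities `1 - cosine similarity`. The configuration is
#' initialized from classical scaling (principal coordinates), which is
#' deterministic; `seed` only matters in the degenerate case where
#' classical scaling fails to produce two usable axes and a random start is
#' drawn instead.
#'
#' @param reps representation matrix `[n, d]`, `n >= 3`.
#' @param seed integer seed for the (rarely used) random fallback start.
#' @param max_iter,tol majorization iteration controls.
#' @return Numeric matrix `[n, 2]` of pseudo-space coordinates.
#' @export
mds_embed <- function(reps, seed = 1L, max_iter = 300L, tol = 1e-9) {
  reps <- as.matrix(reps)
  n <- nrow(reps)
  if (n < 3L) stop("need at least 3 cells for an MDS embedding")
  D <- 1 - cosine_similarity(reps)
  if (anyNA(D) || any(!is.finite(D))) stop("non-finite dissimilarity")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (all(D == 0)) return(matrix(0, n, 2L))
  X <- tryCatch(suppressWarnings(stats::cmdscale(D, k = 2L)),
                error = function(e) NULL)
  if (is.null(X) || ncol(X) < 2L || !all(is.finite(X))) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    X <- matrix(stats::runif(n * 2L, -0.5, 0.5), n, 2L)
  }
  # SMACOF with unit weights: X <- (1/n) B(X) X
  stress_of <- function(X) {
    dX <- as.matrix(stats::dist(X))
    sum((D - dX)^2) / 2
  }
  s_old <- stress_of(X)
  for (it in seq_len(max_iter)) {
    dX <- as.matrix(stats::dist(X))
    ratio <- ifelse(dX > 0, D / dX, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    s_new <- stress_of(X)
    if (s_old - s_new < tol * max(s_old, .Machine$double.eps)) break
    s_old <- s_new
  }
  colnames(X) <- c("x", "y")
  X
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Neighborhood-smoothed query-to-reference similarity
#'
#' For query representations `R_i` and reference representations `R_j`,
#' computes
#' \deqn{s_{i,j} = \cos(R_i, R_j) + \frac{1}{K}\sum_{k=1}^{K}
#'   e^{-(1-\cos(R_i,R_k))^2}\,\cos(R_k, R_j)}
#' where `R_k` ranges over the `K` nearest query-side neighbors of cell `i`
#' under query-query cosine similarity, counting the cell itself as its own
#' first neighbor. `K = 1` therefore uses no neighborhood information and
#' collapses to `2 * cos(R_i, R_j)`, which has the same per-row argmax as
#' plain cosine similarity; larger `K` smooths the query-to-reference
#' similarity over the inferred query neighborhood graph.
#'
#' @param sc_reps query representation matrix `[n_sc, d]`.
#' @param st_reps reference representation matrix `[n_st, d]`.
#' @param K number of query-side neighbors (including self).
#' @return Numeric matrix `[n_sc, n_st]` of weighted similarities.
#' @export
weighted_similarity <- function(sc_reps, st_reps, K = 1L) {
  sc_reps <- as.matrix(sc_reps); st_reps <- as.matrix(st_reps)
  K <- as.integer(K)
  n_sc <- nrow(sc_reps)
  if (K < 1L || K > n_sc)
    stop("K must satisfy 1 <= K <= n_sc (n_sc = ", n_sc, ")")
  cross <- cosine_similarity(sc_reps, st_reps)
  if (K == 1L) return(2 * cross)
  self_sim <- cosine_similarity(sc_reps)
  S <- cross
  for (i in seq_len(n_sc)) {
    ord <- order(-self_sim[i, ], seq_len(n_sc))  # self first (sim = 1)
    nb <- ord[seq_len(K)]
    w <- exp(-(1 - self_sim[i, nb])^2)
    S[i, ] <- cross[i, ] + colSums(w * cross[nb, , drop = FALSE]) / K
  }
  S
}

#' Assign query cells to reference coordinates
#'
#' Each query cell is assigned the reference location with the maximal
#' weighted similarity (ties go to the lower reference index). Several
#' query cells may share a location ("cell clumping").
#'
#' @param S weighted-similarity matrix `[n_sc, n_st]`, finite.
#' @param st_coords reference coordinate matrix `[n_st, 2]`.
#' @return A list of class `mapping_result`: `assigned_st_index` (integer
#'   per query cell), `coords` (`[n_sc, 2]`, copied from the reference).
#' @export
map_to_reference <- function(S, st_coords) {
  S <- as.matrix(S)
  st_coords <- as.matrix(st_coords)
  if (nrow(st_coords) == 0L) stop("empty reference")
  if (ncol(S) != nrow(st_coords))
    stop("S has ", ncol(S), " columns but the reference has ",
         nrow(st_coords), " locations")
  if (anyNA(S) || any(!is.finite(S))) stop("S contains non-finite values")
  idx <- apply(S, 1L, which.max)          # which.max takes the first maximum
  structure(list(assigned_st_index = as.integer(idx),
                 coords = st_coords[idx, , drop = FALSE]),
            class = "mapping_result")
}

#' Entropy-based mapping confidence scores
#'
#' For every query cell, up to `n_top` reference locations are selected
#' greedily in descending weighted similarity, skipping any candidate that
#' lies within the spatial `m_exclude`-nearest-neighborhood of an already
#' selected location (or vice versa), so the selected locations are
#' mutually distant. The similarities of the selected locations are turned
#' into probabilities by a softmax, their Shannon entropy `H` (natural log)
#' is computed, and the confidence is `C = 1 - H / max(H)` with the max
#' taken over all query cells. A cell whose probability mass concentrates
#' on a single distant location gets `C` near 1; the most ambiguous cell
#' gets 0. If every cell has zero entropy all confidences are 1.
#'
#' @param S weighted-similarity matrix `[n_sc, n_st]`.
#' @param st_coords reference coordinates `[n_st, 2]`.
#' @param n_top maximal number of selected locations (default 20).
#' @param m_exclude spatial neighborhood size used for the mutual-exclusion
#'   rule (default 80); must be smaller than `n_st`.
#' @return Numeric vector of confidences in `[0, 1]`; cells with fewer than
#'   two selectable locations get `NA` and are reported in the
#'   `"undefined"` attribute.
#' @export
confidence_scores <- function(S, st_coords, n_top = 20L, m_exclude = 80L) {
  S <- as.matrix(S)
  st_coords <- as.matrix(st_coords)
  n_st <- nrow(st_coords)
  n_top <- as.integer(n_top); m_exclude <- as.integer(m_exclude)
  if (n_st <= n_top)
    stop("need more reference locations (", n_st, ") than n_top (",
         n_top, ")")
  if (m_exclude >= n_st)
    stop("m_exclude must be smaller than the number of reference locations")
  nn <- if (m_exclude >= 1L)
    build_spatial_knn(st_coords, m_exclude)$neighbor_idx
  else matrix(integer(0), n_st, 0L)
  n_sc <- nrow(S)
  H <- rep(NA_real_, n_sc)
  for (i in seq_len(n_sc)) {
    ord <- order(-S[i, ], seq_len(n_st))
    sel <- integer(0)
    for (j in ord) {
      if (length(sel) >= n_top) break
      clash <- length(sel) &&
        (any(j == nn[sel, ]) || any(sel %in% nn[j, ]))
      if (!clash) sel <- c(sel, j)
    }
    if (length(sel) < 2L) next              # undefined, flagged below
    s <- S[i, sel]
    p <- exp(s - max(s))
    p <- p / sum(p)
    H[i] <- -sum(p * log(p))
  }
  undef <- which(is.na(H))
  Hmax <- suppressWarnings(max(H, na.rm = TRUE))
  C <- if (!is.finite(Hmax)) rep(NA_real_, n_sc)
       else if (Hmax == 0) ifelse(is.na(H), NA_real_, 1)
       else 1 - H / Hmax
  if (length(undef)) {
    warning(length(undef), " cell(s) had fewer than 2 selectable ",
            "locations; confidence undefined (NA)")
    attr(C, "undefined") <- undef
  }
  C
}

#' Gene contribution to the learned representation
#'
#' Sensitivity of the encoder output to each gene: the expression of gene
#' `j` in cell `i` is perturbed by a small `epsilon` and the contribution is
#' the rate of representation change,
#' `C[i, j] = ||R_i - R_i^j||_2 / ||X_i - X_i^j||_2`, where the denominator
#' equals `epsilon` by construction. Large values mark genes the spatial
#' representation reacts to.
#'
#' @param state an `encoder_state` or fitted [spatialcontrast()] model.
#' @param profile log-normalized [expression_profile()] aligned to the
#'   encoder's genes.
#' @param epsilon perturbation size, positive (default 0.01).
#' @return Non-negative matrix `[n_cells, n_genes]` of contributions, with
#'   cell and gene names.
#' @export
gene_contribution <- function(state, profile, epsilon = 0.01) {
  if (inherits(state, "spatialcontrast")) state <- state$encoder_state
  stopifnot(inherits(state, "encoder_state"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive number")
  prof <- as_profile(profile)
  R0 <- encode(state, prof)
  n <- nrow(prof$values); g <- ncol(prof$values)
  out <- matrix(NA_real_, n, g,
                dimnames = list(prof$cell_ids, prof$gene_ids))
  for (j in seq_len(g)) {
    Xp <- prof$values
    Xp[, j] <- Xp[, j] + epsilon
    Rj <- encoder_forward(state$encoder, Xp)
    out[, j] <- sqrt(rowSums((R0 - Rj)^2)) / epsilon
  }
  out
}
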