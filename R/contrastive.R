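#' Spatial k-nearest-neighbor graph
#'
#' Euclidean k-nearest neighbors of every cell in coordinate space, self
#' excluded, ties broken by lower cell index. The graph supplies the
#' positive-pair pool for contrastive training.
#'
#' @param coords numeric matrix `[n, 2]` of cell coordinates.
#' @param k neighborhood size, `1 <= k < n`.
#' @return An object of class `spatial_knn` with fields `neighbor_idx`
#'   (integer matrix `[n, k]`, each row sorted by ascending distance) and
#'   `k`.
#' @export
build_spatial_knn <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop("k must satisfy 1 <= k < n_cells (n = ", n, ")")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))   # stable: ties to lower index
    nn[i, ] <- ord[seq_len(k)]
  }
  structure(list(neighbor_idx = nn, k = k, n = n), class = "spatial_knn")
}

#' Sample a contrastive training batch
#'
#' Given `N/2` anchor cells, draws one positive partner per anchor
#' uniformly from its spatial k-nearest neighbors. Within the resulting
#' batch of `N` cells every non-partner cell acts as a negative.
#'
#' @param graph a [build_spatial_knn()] result.
#' @param anchors integer vector of distinct anchor indices (length `N/2`).
#' @return An object of class `contrastive_batch` with fields `anchor_idx`
#'   and `positive_idx`. Sampling uses R's current RNG stream, so it is
#'   reproducible under `set.seed()`.
#' @export
sample_batch <- function(graph, anchors) {
  stopifnot(inherits(graph, "spatial_knn"))
  anchors <- as.integer(anchors)
  if (anyDuplicated(anchors)) stop("anchors must be distinct")
  if (length(anchors) > graph$n)
    stop("more anchors than cells in the graph")
  if (any(anchors < 1L | anchors > graph$n))
    stop("anchor index out of range")
  pick <- sample.int(graph$k, length(anchors), replace = TRUE)
  positives <- graph$neighbor_idx[cbind(anchors, pick)]
  structure(list(anchor_idx = anchors, positive_idx = as.integer(positives)),
            class = "contrastive_batch")
}

#' infoNCE contrastive loss
#'
#' Mean infoNCE loss over a batch of projection vectors arranged as
#' anchor/positive pairs. Rows `1..N/2` of `projections` are the anchors
#' and rows `N/2+1..N` their positives, so row `i` is paired with row
#' `i +/- N/2`. Every row acts once as the query `q`; its pair partner is
#' the positive key and all remaining rows are negatives. Projections are
#' L2-normalized internally, so similarities are cosines:
#' \deqn{L_q = -\log \frac{\exp(q\cdot k_+/\tau)}{\sum_i \exp(q\cdot k_i/\tau)}}
#' With `denominator_mode = "with_positive"` (the conventional form) the
#' denominator sums over the positive plus the `N-2` negatives and the loss
#' is non-negative; with `"negatives_only"` it sums over the `N-2`
#' negatives alone and can be negative when the positive dominates.
#'
#' @param projections numeric matrix `[N, d]`, `N` even, no zero rows.
#' @param tau temperature, positive.
#' @param denominator_mode `"with_positive"` or `"negatives_only"`.
#' @return The scalar batch mean loss.
#' @export
info_nce_loss <- function(projections, tau = 0.05,
                          denominator_mode = c("with_positive",
                                               "negatives_only")) {
  denominator_mode <- match.arg(denominator_mode)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive number")
  Z <- as.matrix(projections)
  if (anyNA(Z) || any(!is.finite(Z)))
    stop("projections contain non-finite values")
  N <- nrow(Z)
  if (N < 4L || N %% 2L != 0L)
    stop("batch size must be even and at least 4")
  Z <- l2_normalize(Z)
  info_nce_core(Z, tau, denominator_mode)$loss
}

# rows scaled to unit L2 norm; zero rows rejected
l2_normalize <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm == 0)) stop("zero projection vector at row ",
                          which(nrm == 0)[1L])
  Z / nrm
}

# loss and gradient w.r.t. the *normalized* projections.
# Z: [N, d] unit rows; pairing i <-> i +/- N/2.
info_nce_core <- function(Z, tau, mode, want_grad = FALSE) {
  N <- nrow(Z)
  half <- N %/% 2L
  partner <- c(seq_len(half) + half, seq_len(half))
  S <- tcrossprod(Z) / tau                      # [N, N] logits
  pos <- S[cbind(seq_len(N), partner)]
  # mask: allowed denominator entries per row
  M <- matrix(TRUE, N, N)
  diag(M) <- FALSE
  if (mode == "negatives_only") M[cbind(seq_len(N), partner)] <- FALSE
  Sm <- S
  Sm[!M] <- -Inf
  mx <- apply(Sm, 1L, max)
  E <- exp(Sm - mx)
  E[!M] <- 0
  lse <- mx + log(rowSums(E))
  loss <- mean(lse - pos)
  if (!want_grad) return(list(loss = loss))
  P <- E / rowSums(E)                           # softmax over denominator
  G <- P
  G[cbind(seq_len(N), partner)] <- G[cbind(seq_len(N), partner)] - 1
  G <- G / (N * tau)
  dZ <- G %*% Z + crossprod(G, Z)               # query + key roles
  list(loss = loss, dZ = dZ)
}
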