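#' Training configuration for the contrastive encoder
#'
#' Collects the architecture and optimization hyper-parameters. Defaults
#' follow the published setup: a two-layer encoder (1024, 512) with batch
#' normalization and leaky-ReLU, a two-layer projection head (256, 128)
#' with a rectifier after its first layer, temperature 0.05, batch size 64,
#' SGD with momentum 0.9 and weight decay 5e-4, initial learning rate 0.1
#' under cosine decay, and 3000 epochs. The positive-pair neighborhood size
#' defaults to 80 for single-cell-resolution references and 20 for
#' spot-resolution references, reflecting their different spatial
#' granularity; pass `positive_knn` to override.
#'
#' When the input has fewer genes than the first encoder layer is wide, the
#' first layer is shrunk to `min(1024, 4 * n_genes)` at fit time (and
#' logged), so small panels do not get a needlessly over-parameterized
#' first layer.
#'
#' @param encoder_dims integer vector of encoder layer widths.
#' @param projector_dims integer vector of projection-head layer widths.
#' @param temperature infoNCE temperature, positive.
#' @param batch_size even integer `>= 4`.
#' @param positive_knn spatial neighborhood size for positive pairs;
#'   `NULL` resolves by platform at fit time (80 single-cell, 20 spot).
#' @param lr0 initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay SGD weight decay.
#' @param epochs number of training epochs.
#' @param seed integer seed driving all training randomness
#'   (initialization, anchor order, positive choice).
#' @param denominator_mode `"with_positive"` (conventional infoNCE,
#'   default) or `"negatives_only"` (denominator restricted to the `N-2`
#'   negatives).
#' @return A list of class `contrast_config`.
#' @export
model_config <- function(encoder_dims = c(1024L, 512L),
                         projector_dims = c(256L, 128L),
                         temperature = 0.05,
                         batch_size = 64L,
                         positive_knn = NULL,
                         lr0 = 0.1,
                         momentum = 0.9,
                         weight_decay = 5e-4,
                         epochs = 3000L,
                         seed = 1L,
                         denominator_mode = c("with_positive",
                                              "negatives_only")) {
  denominator_mode <- match.arg(denominator_mode)
  encoder_dims <- as.integer(encoder_dims)
  projector_dims <- as.integer(projector_dims)
  batch_size <- as.integer(batch_size)
  epochs <- as.integer(epochs)
  if (any(encoder_dims <= 0L) || any(projector_dims <= 0L))
    stop("layer widths must be positive")
  if (batch_size < 4L || batch_size %% 2L != 0L)
    stop("batch_size must be even and at least 4")
  if (temperature <= 0) stop("temperature must be positive")
  if (epochs < 0L) stop("epochs must be non-negative")
  structure(list(encoder_dims = encoder_dims,
                 projector_dims = projector_dims,
                 temperature = temperature, batch_size = batch_size,
                 positive_knn = if (is.null(positive_knn)) NULL
                                else as.integer(positive_knn),
                 lr0 = lr0, momentum = momentum,
                 weight_decay = weight_decay, epochs = epochs,
                 seed = as.integer(seed),
                 denominator_mode = denominator_mode),
            class = "contrast_config")
}

resolve_knn_default <- function(config, platform) {
  if (!is.null(config$positive_knn)) return(config)
  config$positive_knn <- if (platform == "spot") 20L else 80L
  config
}

#' Fit a contrastive spatial encoder
#'
#' Trains a multilayer-perceptron encoder on a spatial transcriptomics
#' reference so that spatially proximate cells obtain similar latent
#' representations. Training batches pair each anchor cell with one of its
#' `positive_knn` spatial nearest neighbors; all other batch members act as
#' negatives, and the infoNCE loss on the projection head's L2-normalized
#' outputs pulls positives together while pushing negatives apart. After
#' training the projection head is discarded: inference uses the encoder
#' output alone.
#'
#' One epoch partitions all reference cells into anchor sets of size
#' `batch_size/2` without replacement (in a seeded random order), so every
#' cell anchors exactly once per epoch.
#'
#' @param reference a [spatial_dataset()] with log-normalized expression.
#' @param config a [model_config()].
#' @param verbose print the loss every few hundred epochs.
#' @return An object of class `spatialcontrast` holding the trained
#'   encoder, the gene ids it expects, the resolved configuration, the
#'   per-epoch mean loss trajectory, and the reference coordinates and
#'   representations needed for query-to-reference mapping.
#' @seealso [predict.spatialcontrast()], [encode()], [info_nce_loss()]
#' @export
spatialcontrast <- function(reference, config = model_config(),
                            verbose = FALSE) {
  stopifnot(inherits(reference, "spatial_dataset"),
            inherits(config, "contrast_config"))
  prof <- reference$profile
  if (!prof$is_lognorm)
    stop("reference expression must be log-normalized (see log_normalize())")
  n <- nrow(prof$values)
  if (n <= config$batch_size)
    stop("need more cells (", n, ") than the batch size (",
         config$batch_size, ")")
  config <- resolve_knn_default(config, reference$platform)
  if (config$positive_knn >= n)
    stop("positive_knn must be smaller than the number of cells")
  n_genes <- ncol(prof$values)
  if (n_genes < config$encoder_dims[1L]) {
    config$encoder_dims[1L] <- min(config$encoder_dims[1L], 4L * n_genes)
    message("first encoder layer shrunk to ", config$encoder_dims[1L],
            " units for a ", n_genes, "-gene input")
  }

  set.seed(config$seed)
  net <- init_network(n_genes, config$encoder_dims, config$projector_dims)
  graph <- build_spatial_knn(reference$coords, config$positive_knn)
  X <- prof$values
  half <- config$batch_size %/% 2L
  opt_state <- list()
  loss_log <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(config$lr0, epoch, config$epochs)
    perm <- sample.int(n)
    n_batches <- ceiling(n / half)
    epoch_loss <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      anchors <- perm[(((b - 1L) * half + 1L):min(b * half, n))]
      if (length(anchors) < 2L) { epoch_loss[b] <- NA_real_; next }
      batch <- sample_batch(graph, anchors)
      idx <- c(batch$anchor_idx, batch$positive_idx)
      Xb <- X[idx, , drop = FALSE]

      fe <- forward_layers(net$encoder, Xb, training = TRUE)
      net$encoder <- fe$layers
      fp <- forward_layers(net$projector, fe$out, training = TRUE)
      net$projector <- fp$layers
      U <- fp$out
      nrm <- sqrt(rowSums(U^2))
      if (any(nrm == 0)) stop("zero projection vector during training")
      Z <- U / nrm

      res <- info_nce_core(Z, config$temperature, config$denominator_mode,
                           want_grad = TRUE)
      if (!is.finite(res$loss))
        stop("non-finite loss at epoch ", epoch, ", batch ", b,
             " (lr = ", signif(lr, 3), "); training aborted")
      epoch_loss[b] <- res$loss

      # back through row L2 normalization: dU = (dZ - (dZ.Z) Z) / |U|
      dZ <- res$dZ
      dU <- (dZ - Z * rowSums(dZ * Z)) / nrm
      gp <- backward_layers(net$projector, fp$caches, dU)
      dEnc <- grad_input(net$projector, fp$caches, dU)
      ge <- backward_layers(net$encoder, fe$caches, dEnc)

      st <- sgd_step(net$projector, gp, opt_state$proj %||% list(), lr,
                     config$momentum, config$weight_decay)
      net$projector <- st$layers; opt_state$proj <- st$state
      st <- sgd_step(net$encoder, ge, opt_state$enc %||% list(), lr,
                     config$momentum, config$weight_decay)
      net$encoder <- st$layers; opt_state$enc <- st$state
    }
    loss_log[epoch] <- mean(epoch_loss, na.rm = TRUE)
    if (verbose && (epoch %% 100L == 0L || epoch == 1L))
      message(sprintf("epoch %d/%d  lr %.4f  loss %.4f",
                      epoch, config$epochs, lr, loss_log[epoch]))
  }

  state <- structure(list(encoder = net$encoder,
                          input_gene_ids = prof$gene_ids,
                          config = config),
                     class = "encoder_state")
  ref_reps <- encode(state, prof)
  structure(list(encoder_state = state,
                 input_gene_ids = prof$gene_ids,
                 config = config,
                 loss = loss_log,
                 reference = list(coords = reference$coords,
                                  platform = reference$platform,
                                  cell_ids = prof$cell_ids,
                                  cell_types = prof$cell_types,
                                  representations = ref_reps),
                 call = match.call()),
            class = "spatialcontrast")
}

# input gradient of a forward pass (re-runs backward without keeping
# parameter grads; backward_layers already propagates dY, so reuse it)
grad_input <- function(layers, caches, dY) {
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "linear") {
      dY <- tcrossprod(dY, l$par$W)
    } else if (l$type == "bn") {
      cch <- caches[[i]]
      xhat <- cch$xhat
      n <- nrow(xhat)
      dxhat <- sweep(dY, 2L, l$par$gamma, "*")
      t1 <- sweep(dxhat, 2L, colMeans(dxhat))
      t2 <- sweep(xhat, 2L, colSums(dxhat * xhat) / n, "*")
      dY <- sweep(t1 - t2, 2L, cch$inv_std, "*")
    } else if (l$type == "lrelu") {
      dY <- dY * ifelse(caches[[i]]$mask, 1, LRELU_SLOPE)
    } else if (l$type == "relu") {
      dY <- dY * caches[[i]]$mask
    }
  }
  dY
}

#' Encode expression into the learned representation space
#'
#' Deterministic inference-mode forward pass through the trained encoder
#' (batch-normalization uses frozen running statistics; the projection head
#' is not applied). Gene ids of the input must match the genes the encoder
#' was trained on, in the same order — use [align_genes()] first.
#'
#' @param state an `encoder_state` or a fitted [spatialcontrast()] model.
#' @param profile a log-normalized [expression_profile()] (or matrix with
#'   matching columns).
#' @return Numeric matrix `[n_cells, rep_dim]` of representations.
#' @export
encode <- function(state, profile) {
  if (inherits(state, "spatialcontrast")) state <- state$encoder_state
  stopifnot(inherits(state, "encoder_state"))
  prof <- as_profile(profile)
  if (!identical(prof$gene_ids, state$input_gene_ids)) {
    missing_g <- setdiff(state$input_gene_ids, prof$gene_ids)
    if (length(missing_g))
      stop("profile is missing ", length(missing_g), " encoder genes: ",
           paste(utils::head(missing_g, 5L), collapse = ", "))
    stop("profile gene order differs from the encoder's input genes; ",
         "reorder with align_genes()")
  }
  reps <- encoder_forward(state$encoder, prof$values)
  rownames(reps) <- prof$cell_ids
  reps
}

#' @export
#' @method print spatialcontrast
print.spatialcontrast <- function(x, ...) {
  cfg <- x$config
  cat("spatialcontrast model\n")
  cat("  input genes:  ", length(x$input_gene_ids), "\n", sep = "")
  cat("  encoder:      ", paste(cfg$encoder_dims, collapse = " -> "),
      " (batch norm + leaky ReLU)\n", sep = "")
  cat("  projector:    ", paste(cfg$projector_dims, collapse = " -> "),
      " (training only)\n", sep = "")
  cat("  reference:    ", nrow(x$reference$coords), " cells [",
      x$reference$platform, "]\n", sep = "")
  cat("  epochs:       ", cfg$epochs, "; final loss ",
      if (cfg$epochs > 0) sprintf("%.4f", x$loss[cfg$epochs]) else "NA",
      "\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary spatialcontrast
summary.spatialcontrast <- function(object, ...) {
  cfg <- object$config
  out <- list(config = cfg,
              n_reference = nrow(object$reference$coords),
              n_genes = length(object$input_gene_ids),
              loss_first = if (cfg$epochs > 0) object$loss[1L] else NA_real_,
              loss_final = if (cfg$epochs > 0)
                object$loss[cfg$epochs] else NA_real_)
  class(out) <- "summary.spatialcontrast"
  out
}

#' @export
#' @method print summary.spatialcontrast
print.summary.spatialcontrast <- function(x, ...) {
  cat("Contrastive spatial encoder\n")
  cat(sprintf("  reference cells: %d, genes: %d\n", x$n_reference,
              x$n_genes))
  cat(sprintf("  temperature %.3g, batch size %d, positive kNN %s\n",
              x$config$temperature, x$config$batch_size,
              x$config$positive_knn %||% "(by platform)"))
  cat(sprintf("  loss: %.4f (first epoch) -> %.4f (final epoch)\n",
              x$loss_first, x$loss_final))
  invisible(x)
}

#' @export
coef.spatialcontrast <- function(object, ...) {
  lin <- Filter(function(l) l$type == "linear", object$encoder_state$encoder)
  lapply(lin, function(l) l$par$W)
}

#' Plot the training loss trajectory
#' @param x a fitted [spatialcontrast()] model.
#' @param ... passed to [plot()].
#' @export
plot.spatialcontrast <- function(x, ...) {
  if (!length(x$loss)) stop("no loss trajectory (epochs = 0)")
  plot(seq_along(x$loss), x$loss, type = "l", xlab = "epoch",
       ylab = "mean infoNCE loss", ...)
  invisible(x)
}

#' Predict spatial structure for query cells
#'
#' Applies a fitted contrastive encoder to a query expression profile and
#' returns, depending on `type`:
#'
#' * `"representation"` — the encoder output matrix.
#' * `"neighbors"` — indices of the `k` most cosine-similar query cells per
#'   query cell ([predict_neighbors()]).
#' * `"mds"` — 2-D pseudo-space coordinates from metric MDS on
#'   `1 - cosine` dissimilarities ([mds_embed()]).
#' * `"mapping"` — assignment of every query cell to the reference
#'   coordinate with maximal weighted similarity, plus an entropy-based
#'   confidence score ([map_to_reference()], [confidence_scores()]);
#'   returned as a data frame with columns `cell_id`, `st_index`, `st_id`,
#'   `x`, `y`, `confidence`.
#' * `"genes"` — per-cell gene contributions to the representation
#'   ([gene_contribution()]).
#'
#' @param object a fitted [spatialcontrast()] model.
#' @param newdata a log-normalized [expression_profile()] with the model's
#'   genes in order.
#' @param type what to predict; see above.
#' @param k neighbor count (`type = "neighbors"`).
#' @param K number of query-side neighbors in the weighted similarity
#'   (`type = "mapping"`; `K = 1` uses the cell itself only).
#' @param n_top,m_exclude confidence-score parameters; see
#'   [confidence_scores()].
#' @param seed seed for the MDS embedding.
#' @param epsilon perturbation for gene contributions.
#' @param ... unused.
#' @return See `type`.
#' @export
predict.spatialcontrast <- function(object, newdata,
                                    type = c("representation", "neighbors",
                                             "mds", "mapping", "genes"),
                                    k = 20L, K = 1L, n_top = 20L,
                                    m_exclude = 80L, seed = 1L,
                                    epsilon = 0.01, ...) {
  type <- match.arg(type)
  prof <- as_profile(newdata)
  if (type == "genes")
    return(gene_contribution(object, prof, epsilon = epsilon))
  reps <- encode(object, prof)
  switch(type,
    representation = reps,
    neighbors = predict_neighbors(reps, k),
    mds = mds_embed(reps, seed = seed),
    mapping = {
      S <- weighted_similarity(reps, object$reference$representations, K)
      mres <- map_to_reference(S, object$reference$coords)
      conf <- confidence_scores(S, object$reference$coords,
                                n_top = n_top, m_exclude = m_exclude)
      data.frame(cell_id = prof$cell_ids,
                 st_index = mres$assigned_st_index,
                 st_id = object$reference$cell_ids[mres$assigned_st_index],
                 x = mres$coords[, 1L], y = mres$coords[, 2L],
                 confidence = conf, stringsAsFactors = FALSE)
    })
}

#' Save and restore a fitted model as a plain-text checkpoint
#'
#' The checkpoint is a single JSON file holding every encoder parameter,
#' the input gene ids, the resolved configuration and the reference
#' coordinates/representations, so that a restored model reproduces
#' [encode()] output exactly (up to double-precision text round-trip,
#' ~1e-15).
#'
#' @param object a fitted [spatialcontrast()] model.
#' @param path checkpoint file path.
#' @return `path` (for `save_checkpoint`); a `spatialcontrast` object (for
#'   `load_checkpoint`).
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "spatialcontrast"))
  ser_layers <- function(layers) lapply(layers, function(l) {
    if (is.null(l$par)) list(type = l$type)
    else list(type = l$type, par = lapply(l$par, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }))
  })
  payload <- list(
    package = "spatialcontrast", version = "0.1.0",
    input_gene_ids = object$input_gene_ids,
    config = unclass(object$config),
    loss = object$loss,
    encoder = ser_layers(object$encoder_state$encoder),
    reference = list(coords = as.numeric(object$reference$coords),
                     n = nrow(object$reference$coords),
                     platform = object$reference$platform,
                     cell_ids = object$reference$cell_ids,
                     cell_types = object$reference$cell_types,
                     representations =
                       as.numeric(object$reference$representations),
                     rep_dim = ncol(object$reference$representations)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path checkpoint file path.
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  deser_layers <- function(ls) lapply(ls, function(l) {
    if (is.null(l$par)) return(list(type = chr(l$type)))
    par <- lapply(l$par, function(q) {
      d <- unlist(q$dim)
      if (!is.null(d) && length(d) == 2L) matrix(num(q$data), d[1L], d[2L])
      else num(q$data)
    })
    list(type = chr(l$type), par = par)
  })
  p <- list(
    input_gene_ids = chr(raw$input_gene_ids),
    config = lapply(raw$config, unlist),
    loss = num(raw$loss),
    encoder = raw$encoder,
    reference = list(coords = num(raw$reference$coords),
                     n = as.integer(unlist(raw$reference$n)),
                     platform = chr(raw$reference$platform),
                     cell_ids = chr(raw$reference$cell_ids),
                     cell_types = if (is.null(raw$reference$cell_types))
                       NULL else chr(raw$reference$cell_types),
                     representations = num(raw$reference$representations),
                     rep_dim = as.integer(unlist(raw$reference$rep_dim))))
  cfg <- p$config
  config <- model_config(encoder_dims = cfg$encoder_dims,
                         projector_dims = cfg$projector_dims,
                         temperature = cfg$temperature,
                         batch_size = cfg$batch_size,
                         positive_knn = cfg$positive_knn,
                         lr0 = cfg$lr0, momentum = cfg$momentum,
                         weight_decay = cfg$weight_decay,
                         epochs = cfg$epochs, seed = cfg$seed,
                         denominator_mode = cfg$denominator_mode)
  # read_json may simplify the layer list; normalize to a list of layers
  enc <- deser_layers(p$encoder)
  state <- structure(list(encoder = enc,
                          input_gene_ids = p$input_gene_ids,
                          config = config),
                     class = "encoder_state")
  n <- p$reference$n
  coords <- matrix(p$reference$coords, n, 2L,
                   dimnames = list(p$reference$cell_ids, c("x", "y")))
  reps <- matrix(p$reference$representations, n, p$reference$rep_dim,
                 dimnames = list(p$reference$cell_ids, NULL))
  structure(list(encoder_state = state,
                 input_gene_ids = p$input_gene_ids,
                 config = config, loss = as.numeric(p$loss),
                 reference = list(coords = coords,
                                  platform = p$reference$platform,
                                  cell_ids = p$reference$cell_ids,
                                  cell_types = p$reference$cell_types,
                                  representations = reps),
                 call = NULL),
            class = "spatialcontrast")
}
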