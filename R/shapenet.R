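#' Model configuration
#'
#' Hyperparameters of the shape-layer network. Defaults are the published
#' operating point of the method: 7 shape layers, filter size 64, dropout
#' ratio 0.5, SGD with learning rate 0.05 and momentum 0.95, 1500 epochs.
#' Desk-scale experiments typically reduce `epochs` and `filter_size`; see
#' the package vignette.
#'
#' @param n_shape_layers Number of stacked shape layers (each adds one bp of
#'   flanking-region influence).
#' @param filter_size Width of the node feature vectors.
#' @param dropout_ratio Dropout fraction on the head branch during training.
#' @param learning_rate,momentum SGD parameters.
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size; variable-length sequences are grouped
#'   by length so no padding is ever needed.
#' @param bn_momentum,bn_eps Batch-normalization running-average momentum
#'   and variance floor.
#' @param seed Integer seed controlling initialization, batch order and
#'   dropout; identical seeds give bit-identical training runs.
#' @return A list of class `"shapenet_config"`.
#' @export
shapenet_config <- function(n_shape_layers = 7L, filter_size = 64L,
                            dropout_ratio = 0.5, learning_rate = 0.05,
                            momentum = 0.95, epochs = 1500L,
                            batch_size = 32L, bn_momentum = 0.1,
                            bn_eps = 1e-5, seed = 1L) {
  stopifnot(n_shape_layers >= 1L, filter_size >= 1L,
            dropout_ratio >= 0, dropout_ratio < 1,
            learning_rate > 0, momentum >= 0, momentum < 1,
            epochs >= 1L, batch_size >= 1L)
  structure(list(n_shape_layers = as.integer(n_shape_layers),
                 filter_size = as.integer(filter_size),
                 dropout_ratio = dropout_ratio,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 seed = as.integer(seed)),
            class = "shapenet_config")
}

# Run body with a private, seeded RNG stream; caller's RNG is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Build the capped encoded node chain + target/mask vectors for one record.
sn_prepare_example <- function(seq, values, node_kind, stats) {
  enc <- add_caps(if (node_kind == "step") encode_di(seq) else encode_mono(seq))
  if (!is.null(values)) {
    n_nodes <- nrow(enc$matrix) - 2L
    if (length(values) != n_nodes)
      stop("record has ", length(values), " values but ", n_nodes,
           " ", node_kind, " node(s)", call. = FALSE)
    tgt <- c(NA_real_, normalize_shape(values, stats), NA_real_)
    msk <- c(FALSE, is.finite(values), FALSE)
  } else {
    tgt <- msk <- NULL
  }
  list(E = enc$matrix, targets = tgt, mask = msk)
}

#' Fit a shape-layer network to per-position shape data
#'
#' Trains one model for one DNA shape feature by stochastic gradient
#' descent with momentum on the multi-layer masked mean-absolute-error loss
#' (every layer's output head contributes equally, which keeps deep layers
#' honest and lets the flanking-region influence be selected at prediction
#' time). Inter-bp (step) features are encoded as dinucleotide nodes,
#' per-bp features as nucleotide nodes; every chain is N-capped. Targets
#' are normalized with the dataset's percentile stats; positions whose
#' value is undefined (`NA`, e.g. MGW at terminal base pairs) are masked
#' out of the loss entirely.
#'
#' @param data A `"shape_dataset"` from [load_training_file()] or
#'   [sample_corpus()]'s training file, or a list of records
#'   `list(id=, seq=, values=)` plus `stats`.
#' @param feature Feature name (determines node kind and units), e.g.
#'   `"MGW"`.
#' @param config A [shapenet_config()].
#' @param seed Overrides `config$seed` when given.
#' @param verbose Print the loss every few epochs.
#' @return An object of class `"shapenet"` with components `feature`
#'   (registry row), `config`, `params`, `bn_run`, `stats`
#'   (normalization), `loss_history` (per-epoch training loss) and
#'   `n_examples`.
#' @seealso [predict.shapenet()], [receptive_radius()], [grid_search()]
#' @export
shapenet <- function(data, feature, config = shapenet_config(),
                     seed = config$seed, verbose = FALSE) {
  spec <- shape_feature(feature)
  ds <- as_shape_dataset(data)
  if (length(ds$records) == 0L) stop("empty dataset", call. = FALSE)
  stats <- ds$stats
  exs <- lapply(ds$records, function(r)
    sn_prepare_example(r$seq, r$values, spec$node_kind, stats))
  if (!any(unlist(lapply(exs, `[[`, "mask"))))
    stop("no defined target positions in dataset", call. = FALSE)

  n_channels <- ncol(exs[[1L]]$E)
  n_nodes <- vapply(exs, function(e) nrow(e$E), 0L)

  # stack each chain-length group once; per epoch only rows are permuted
  gdata <- lapply(split(seq_along(exs), n_nodes), function(ix) {
    list(m = n_nodes[ix[1L]], n = length(ix),
         E1 = do.call(rbind, lapply(exs[ix], function(e) cbind(e$E, 1))),
         tgt = unlist(lapply(exs[ix], `[[`, "targets")),
         msk = unlist(lapply(exs[ix], `[[`, "mask")))
  })
  nbr_cache <- new.env(parent = emptyenv())
  neighbors_for <- function(m, b) {
    key <- paste0(m, "_", b)
    got <- nbr_cache[[key]]
    if (is.null(got)) {
      nb <- neighbor_indices(m)
      off <- rep((seq_len(b) - 1L) * m, each = m)
      got <- list(prev = rep(nb$prev, b) + off, nxt = rep(nb$nxt, b) + off)
      nbr_cache[[key]] <- got
    }
    got
  }

  fit <- with_seed(seed, {
    params <- sn_init_params(n_channels, config)
    bn_run <- sn_init_bn(config)
    vel <- sn_zero_grads(params)
    loss_hist <- numeric(config$epochs)

    for (ep in seq_len(config$epochs)) {
      batches <- unlist(lapply(seq_along(gdata), function(gi) {
        perm <- sample.int(gdata[[gi]]$n)
        lapply(unname(split(perm, ceiling(seq_along(perm) / config$batch_size))),
               function(ch) list(gi = gi, ch = ch))
      }), recursive = FALSE)
      batches <- batches[sample.int(length(batches))]
      ep_loss <- 0
      ep_ndef <- 0
      for (bt in batches) {
        g <- gdata[[bt$gi]]
        rows <- rep((bt$ch - 1L) * g$m, each = g$m) + seq_len(g$m)
        E1 <- g$E1[rows, , drop = FALSE]
        nbr <- neighbors_for(g$m, length(bt$ch))
        tgt <- g$tgt[rows]
        msk <- g$msk[rows]

        fw <- sn_forward(params, E1, nbr$prev, nbr$nxt, bn_run, config,
                         training = TRUE, keep_cache = TRUE)
        bn_run <- fw$bn_run
        lo <- mae_loss_grad(fw$Y, tgt, msk)
        if (!is.finite(lo$loss))
          stop("training diverged at epoch ", ep, " (loss ", lo$loss,
               "); lower the learning rate", call. = FALSE)
        grads <- sn_backward(params, E1, nbr$prev, nbr$nxt, fw$cache, lo$dY,
                             config)
        st <- sn_sgd_step(params, grads, vel, config$learning_rate,
                          config$momentum)
        params <- st$params
        vel <- st$vel
        nd <- sum(msk)
        ep_loss <- ep_loss + lo$loss * nd
        ep_ndef <- ep_ndef + nd
      }
      loss_hist[ep] <- ep_loss / ep_ndef
      if (verbose && (ep %% max(1L, config$epochs %/% 20L) == 0L))
        message(sprintf("epoch %d/%d loss %.5f", ep, config$epochs,
                        loss_hist[ep]))
    }
    list(params = params, bn_run = bn_run, loss_hist = loss_hist)
  })

  structure(list(feature = spec, config = config, params = fit$params,
                 bn_run = fit$bn_run, stats = stats,
                 loss_history = fit$loss_hist,
                 n_examples = length(exs), seed = seed,
                 version = "deepshape-model-1"),
            class = "shapenet")
}

# Loss + gradient of the multi-layer masked MAE for the optimizer.
mae_loss_grad <- function(Y, targets, mask) {
  L <- ncol(Y)
  ndef <- sum(mask)
  if (ndef == 0L) stop("no defined target nodes in batch", call. = FALSE)
  R <- Y[mask, , drop = FALSE] - targets[mask]
  dY <- matrix(0, nrow(Y), L)
  dY[mask, ] <- sign(R) / (ndef * L)
  list(loss = sum(abs(R)) / (ndef * L), dY = dY)
}

#' Multi-layer masked mean absolute error
#'
#' The training loss: for each layer, the mean absolute error between the
#' layer's head output and the target over *defined* nodes only; layers are
#' then averaged with equal weight. Masked nodes contribute nothing, so
#' undefined terminal values place no constraint on the model.
#'
#' @param preds Node-by-layer matrix of predictions, or a list with one
#'   numeric vector per layer.
#' @param targets Numeric vector of targets (values at masked nodes are
#'   ignored and may be `NA`).
#' @param mask Logical vector; `TRUE` where the target is defined.
#' @return The scalar loss.
#' @export
multi_layer_masked_mae <- function(preds, targets, mask) {
  if (is.list(preds)) preds <- do.call(cbind, preds)
  if (is.null(dim(preds))) preds <- matrix(preds, ncol = 1L)
  stopifnot(nrow(preds) == length(targets), length(targets) == length(mask))
  mae_loss_grad(preds, targets, mask)$loss
}

# Inference forward on one sequence; returns nodes x L normalized head
# outputs with cap rows removed.
sn_infer <- function(object, seq) {
  ex <- sn_prepare_example(seq, NULL, object$feature$node_kind, object$stats)
  n <- nrow(ex$E)
  nb <- neighbor_indices(n)
  fw <- sn_forward(object$params, cbind(ex$E, 1), nb$prev, nb$nxt,
                   object$bn_run, object$config, training = FALSE)
  fw$Y[-c(1L, n), , drop = FALSE]
}

#' Predict a shape profile
#'
#' Encodes the sequence (nucleotide or dinucleotide nodes as the feature
#' requires), adds N caps, runs the network, keeps the output head of layer
#' `depth`, strips the caps and undoes the normalization. `depth` selects
#' how many base pairs of flanking region influence each position: layer k
#' considers k bp of flanks.
#'
#' @param object A fitted `"shapenet"`.
#' @param seq Sequence string (or character vector of sequences).
#' @param depth Shape layer to read out (default: the deepest).
#' @param symmetrize Average the profile with the reverse-complement
#'   strand's prediction mapped back through [rc_transform_profile()], so
#'   that a sequence and its reverse complement give mirror-consistent
#'   profiles.
#' @param normalized Return the normalized (tanh-bounded) values instead of
#'   feature units.
#' @param ... Unused.
#' @return A numeric profile (length n for per-bp features, n-1 for step
#'   features), or a list of profiles when `seq` has several elements.
#' @export
predict.shapenet <- function(object, seq, depth = object$config$n_shape_layers,
                             symmetrize = FALSE, normalized = FALSE, ...) {
  if (depth < 1L || depth > object$config$n_shape_layers)
    stop("depth must be in 1..", object$config$n_shape_layers, call. = FALSE)
  one <- function(s) {
    y <- sn_infer(object, s)[, depth]
    if (symmetrize) {
      yrc <- sn_infer(object, revcomp(s))[, depth]
      y <- (y + rc_transform_profile(yrc, object$feature)) / 2
    }
    if (normalized) y else denormalize_shape(y, object$stats)
  }
  if (length(seq) == 1L) one(seq) else lapply(seq, one)
}

#' Per-layer masked MAE of a fitted model on a dataset
#'
#' @param object A `"shapenet"`.
#' @param data A `"shape_dataset"` (targets are normalized with the
#'   *model's* stats so errors are comparable across datasets).
#' @return Numeric vector of length `n_shape_layers`: masked MAE of each
#'   layer's head on the normalized scale.
#' @export
shapenet_eval <- function(object, data) {
  ds <- as_shape_dataset(data)
  L <- object$config$n_shape_layers
  tot <- numeric(L)
  ndef <- 0
  for (r in ds$records) {
    ex <- sn_prepare_example(r$seq, r$values, object$feature$node_kind,
                             object$stats)
    n <- nrow(ex$E)
    nb <- neighbor_indices(n)
    fw <- sn_forward(object$params, cbind(ex$E, 1), nb$prev, nb$nxt,
                     object$bn_run, object$config, training = FALSE)
    m <- ex$mask
    if (!any(m)) next
    tot <- tot + colSums(abs(fw$Y[m, , drop = FALSE] - ex$targets[m]))
    ndef <- ndef + sum(m)
  }
  if (ndef == 0L) stop("no defined positions in evaluation data", call. = FALSE)
  tot / ndef
}

#' Perturbation-probed receptive radius
#'
#' Measures, for a given readout depth, the largest distance (in bp) at
#' which a single-nucleotide substitution can change the prediction at a
#' centre position. By construction each shape layer passes information one
#' node further, so the radius equals `depth` for per-bp features and
#' `depth + 1` for step features (a substitution touches two step nodes;
#' positions are indexed by the 5' base of the step). Probing is empirical:
#' random sequences are mutated base by base at increasing distance and the
#' change in the centre prediction is measured, so the result holds for the
#' model's actual weights, not just the architecture on paper.
#'
#' @param object A `"shapenet"` (trained or freshly initialized).
#' @param depth Readout layer.
#' @param n_probes Number of random background sequences.
#' @param tol Absolute change (normalized scale) below which a prediction
#'   is considered unaffected. Beyond the architectural radius the change
#'   is exactly zero, so any positive tolerance gives the same answer.
#' @param seed Seed for the probe sequences.
#' @return The radius in bp (integer).
#' @export
receptive_radius <- function(object, depth = object$config$n_shape_layers,
                             n_probes = 3L, tol = 1e-9, seed = 7L) {
  stopifnot(inherits(object, "shapenet"))
  if (depth < 1L || depth > object$config$n_shape_layers)
    stop("depth must be in 1..", object$config$n_shape_layers, call. = FALSE)
  dmax <- depth + 2L
  len <- 2L * (dmax + 1L) + 1L
  center <- dmax + 2L          # bp index of the probed position
  with_seed(seed, {
    radius <- 0L
    for (pr in seq_len(n_probes)) {
      chars <- sample(BASES, len, replace = TRUE)
      base_seq <- paste(chars, collapse = "")
      y0 <- sn_infer(object, base_seq)[center, depth]
      for (d in seq_len(dmax)) {
        for (pos in c(center - d, center + d)) {
          for (b in setdiff(BASES, chars[pos])) {
            mut <- chars
            mut[pos] <- b
            y1 <- sn_infer(object, paste(mut, collapse = ""))[center, depth]
            if (abs(y1 - y0) > tol) radius <- max(radius, d)
          }
        }
      }
    }
    radius
  })
}

#' Save / load a fitted model
#'
#' A single versioned container holding the manifest (feature, config,
#' normalization stats) and all weight arrays at full double precision;
#' a reloaded model produces bit-identical predictions.
#'
#' @param object A `"shapenet"`.
#' @param path File path (conventionally `.rds`).
#' @export
save_shapenet <- function(object, path) {
  stopifnot(inherits(object, "shapenet"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_shapenet
#' @export
load_shapenet <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "shapenet") ||
      !identical(object$version, "deepshape-model-1"))
    stop("not a deepshape model file: ", path, call. = FALSE)
  object
}

#' @export
print.shapenet <- function(x, ...) {
  cat(sprintf("shapenet: %s (%s nodes, %s), %d shape layers x %d filters\n",
              x$feature$name, x$feature$node_kind, x$feature$units,
              x$config$n_shape_layers, x$config$filter_size))
  cat(sprintf("  trained on %d sequences, %d epochs; final loss %.5f\n",
              x$n_examples, length(x$loss_history),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' @method summary shapenet
#' @export
summary.shapenet <- function(object, ...) {
  n_par <- sum(rapply(object$params, length, how = "unlist"))
  cat(sprintf("Shape-layer network for %s\n", object$feature$name))
  print(object$config)
  cat(sprintf("  parameters: %d; normalization median %.4g, range %.4g\n",
              n_par, object$stats$median, object$stats$p99 - object$stats$p1))
  cat(sprintf("  training loss: %.5f (first) -> %.5f (final)\n",
              object$loss_history[1L],
              object$loss_history[length(object$loss_history)]))
  invisible(object)
}

#' @export
print.shapenet_config <- function(x, ...) {
  cat(sprintf(paste0("shapenet_config: %d layers, filter %d, dropout %.2f, ",
                     "lr %g, momentum %g, %d epochs, batch %d, seed %d\n"),
              x$n_shape_layers, x$filter_size, x$dropout_ratio,
              x$learning_rate, x$momentum, x$epochs, x$batch_size, x$seed))
  invisible(x)
}

#' @method plot shapenet
#' @export
plot.shapenet <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "training MAE (normalized)",
                 main = paste("shapenet:", x$feature$name), ...)
  invisible(x)
}

#' @method coef shapenet
#' @export
coef.shapenet <- function(object, ...) {
  # named algebraic views (omega1/2, theta1/2, B1/2, GRU and batchnorm
  # weights per layer) rather than the fused storage matrices
  sn_unpack_params(object$params, object$config$filter_size)
}
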