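#' Gated-attention MIL aggregation
#'
#' Computes the standard gated attention over a bag of instances: for
#' each tile feature vector h_k, the attention logit is
#' `w . (tanh(V h_k) * sigmoid(U h_k))`, the weights are the softmax of
#' the logits over the bag, and the pooled slide representation is the
#' attention-weighted sum of the h_k.
#'
#' @param features K x D matrix of per-tile features.
#' @param params list with matrices `V` (H x D), `U` (H x D) and vector
#'   `w` (length H), as from [init_gma_params()].
#' @return List with `weights` (K non-negative reals summing to 1) and
#'   `pooled` (length-D vector).
#' @export
gated_attention <- function(features, params) {
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("at least one instance is required")
  if (!all(is.finite(features))) stop("non-finite features")
  stopifnot(ncol(params$V) == ncol(features), ncol(params$U) == ncol(features),
            length(params$w) == nrow(params$V))
  Tn <- tanh(features %*% t(params$V))         # K x H
  S <- plogis(features %*% t(params$U))        # K x H
  e <- as.vector((Tn * S) %*% params$w)        # K
  e <- e - max(e)
  a <- exp(e) / sum(exp(e))
  pooled <- as.vector(crossprod(features, a))
  list(weights = a, pooled = pooled)
}

#' Initialize gated-attention parameters
#'
#' @param d feature width D.
#' @param hidden attention hidden width H.
#' @param seed integer seed.
#' @param init_sd SD of the Gaussian initialization.
#' @return List with `V`, `U` (H x D), `w` (H), `beta` (D head weights)
#'   and scalar intercept `b0`.
#' @export
init_gma_params <- function(d, hidden = 128L, seed = 1L, init_sd = 0.1) {
  with_seed(split_seed(seed, "init"), {
    list(V = matrix(rnorm(hidden * d, sd = init_sd), hidden, d),
         U = matrix(rnorm(hidden * d, sd = init_sd), hidden, d),
         w = rnorm(hidden, sd = init_sd),
         beta = rep(0, d), b0 = 0)
  })
}

#' Predict the slide-level mutation probability
#'
#' Applies the model's feature normalization, gated attention pooling and
#' logistic linear head. The probability is invariant to any permutation
#' of the tiles (bag property); with an all-zero head it is exactly 0.5.
#'
#' @param features K x D matrix of per-tile features for one slide.
#' @param model a `mil_model` (from [train_mil()]) or a bare parameter
#'   list with `V`, `U`, `w`, `beta`, `b0`.
#' @param slide_id identifier echoed in the result.
#' @return An object of class `slide_prediction`: list with `probability`,
#'   `attention_weights` and `slide_id`.
#' @export
predict_slide <- function(features, model, slide_id = "slide") {
  features <- as.matrix(features)
  p <- if (inherits(model, "mil_model")) model$params else model
  if (ncol(features) != ncol(p$V))
    stop("feature width mismatch: expected ", ncol(p$V), " got ", ncol(features))
  if (inherits(model, "mil_model") && !is.null(model$center)) {
    features <- sweep(features, 2, model$center)
    features <- sweep(features, 2, model$scale, "/")
  }
  ga <- gated_attention(features, p)
  prob <- plogis(sum(p$beta * ga$pooled) + p$b0)
  structure(list(probability = prob, attention_weights = ga$weights,
                 slide_id = slide_id), class = "slide_prediction")
}

#' Sample tiles from a grid for one training step
#'
#' Draws `n` tiles uniformly at random. When the grid holds fewer than
#' `n` tiles the behavior depends on `replace`: with `replace = FALSE`
#' (default) all tiles are returned exactly once; with `replace = TRUE`
#' tiles are drawn with replacement up to `n`, keeping the step size
#' exact.
#'
#' @param grid a non-empty [tile_grid()].
#' @param n number of tiles to draw.
#' @param seed integer seed.
#' @param replace sample with replacement.
#' @return A [tile_grid()] subset (possibly with repeated tiles when
#'   `replace = TRUE`).
#' @export
sample_patches <- function(grid, n, seed = 1L, replace = FALSE) {
  stopifnot(inherits(grid, "tile_grid"), n >= 1)
  K <- nrow(grid$tiles)
  if (K == 0L) stop("empty tile grid")
  idx <- with_seed(split_seed(seed, "sample_patches"), {
    if (replace) sample.int(K, n, replace = TRUE)
    else if (n >= K) seq_len(K)
    else sample.int(K, n)
  })
  out <- grid
  out$tiles <- grid$tiles[idx, , drop = FALSE]
  rownames(out$tiles) <- NULL
  # repeated tiles are allowed in a sampled training bag
  attr(out, "sampled") <- TRUE
  class(out) <- "tile_grid"
  out
}

#' Training configuration for the MIL model
#'
#' @param patches_per_step tiles sampled per slide per training step
#'   (desk default 256; the full-scale reference configuration samples
#'   6,624 per step, reportedly split as 96 patches across 23 encoding
#'   workers -- figures that are mutually inconsistent, so both are
#'   surfaced here without resolving intent).
#' @param epochs training epochs (full-scale reference: 20).
#' @param hidden attention hidden width H.
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed integer seed governing init, shuffling and sampling.
#' @param encoder patch encoder used when slides carry raw images.
#' @param half_precision if TRUE, features are rounded to half precision
#'   before aggregation (emulating 16-bit encoding; default off).
#' @return An object of class `train_config`.
#' @export
train_config <- function(patches_per_step = 256L, epochs = 20L, hidden = 128L,
                         lr = 1e-4, weight_decay = 1e-4, seed = 1L,
                         encoder = stats_encoder(), half_precision = FALSE) {
  stopifnot(patches_per_step >= 1, epochs >= 1, hidden >= 1, lr > 0)
  structure(list(patches_per_step = as.integer(patches_per_step),
                 epochs = as.integer(epochs), hidden = as.integer(hidden),
                 lr = lr, weight_decay = weight_decay, seed = as.integer(seed),
                 encoder = encoder, half_precision = half_precision),
            class = "train_config")
}

# Round to IEEE half precision (10-bit mantissa).
to_half <- function(x) {
  e <- floor(log2(pmax(abs(x), 2^-24)))
  round(x / 2^(e - 10)) * 2^(e - 10)
}

#' Train the gated-attention MIL classifier
#'
#' Single-process training of the aggregator and linear head by AdamW on
#' the per-slide binary cross-entropy, with per-step uniform patch
#' sampling. Slides may carry precomputed `features` (K x D matrices) or
#' raw `image` + `grid` pairs, which are encoded once up front with the
#' config's encoder. Features are standardized over the training patches;
#' the normalization is stored on the model. Fully reproducible by seed.
#'
#' @param slides list of slides; each element is a list with `label`
#'   ("mutant"/"wild-type" or 1/0) and either `features` or `image` +
#'   `grid`.
#' @param config a [train_config()].
#' @return An object of class `mil_model`: parameters, normalization,
#'   per-epoch mean loss (`loss_history`), config echo.
#' @export
train_mil <- function(slides, config = train_config()) {
  stopifnot(inherits(config, "train_config"), length(slides) >= 2)
  labels <- vapply(slides, function(s) {
    l <- s$label
    if (is.character(l)) as.integer(l == "mutant") else as.integer(l)
  }, integer(1))
  if (length(unique(labels)) < 2L)
    stop("training requires both classes to be present")

  feats <- lapply(slides, function(s) {
    f <- if (!is.null(s$features)) as.matrix(s$features)
    else encode_patches(s$image, s$grid, config$encoder)
    f
  })
  d <- ncol(feats[[1]])
  all_rows <- do.call(rbind, feats)
  center <- colMeans(all_rows)
  scale <- pmax(apply(all_rows, 2, sd), 1e-8)
  feats <- lapply(feats, function(f) sweep(sweep(f, 2, center), 2, scale, "/"))
  if (config$half_precision) feats <- lapply(feats, function(f) {
    matrix(to_half(f), nrow(f), ncol(f))
  })

  p <- init_gma_params(d, config$hidden, config$seed)
  # AdamW state per tensor
  m <- lapply(p, function(x) x * 0); v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_history <- numeric(config$epochs)

  order_seed <- split_seed(config$seed, "epoch_order")
  samp_seed <- split_seed(config$seed, "step_sampling")
  n_slides <- length(slides)

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(order_seed + epoch, sample.int(n_slides))
    epoch_loss <- 0
    for (si in ord) {
      F <- feats[[si]]
      K <- nrow(F)
      n_take <- config$patches_per_step
      if (n_take < K) {
        idx <- with_seed(samp_seed + step, sample.int(K, n_take))
        F <- F[idx, , drop = FALSE]
      }
      y <- labels[si]

      # forward
      Tn <- tanh(F %*% t(p$V)); S <- plogis(F %*% t(p$U))
      e <- as.vector((Tn * S) %*% p$w)
      e <- e - max(e)
      a <- exp(e) / sum(exp(e))
      z <- as.vector(crossprod(F, a))
      logit <- sum(p$beta * z) + p$b0
      prob <- plogis(logit)
      epoch_loss <- epoch_loss - (y * log(max(prob, 1e-12)) +
                                  (1 - y) * log(max(1 - prob, 1e-12)))

      # backward
      g <- prob - y
      grad <- list()
      grad$beta <- g * z
      grad$b0 <- g
      dz <- g * p$beta
      da <- as.vector(F %*% dz)
      de <- a * (da - sum(a * da))
      grad$w <- as.vector(crossprod(Tn * S, de))
      M1 <- (de %o% p$w) * S * (1 - Tn^2)
      M2 <- (de %o% p$w) * Tn * S * (1 - S)
      grad$V <- crossprod(M1, F)
      grad$U <- crossprod(M2, F)

      step <- step + 1L
      for (nm in names(grad)) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grad[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grad[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^step)
        vhat <- v[[nm]] / (1 - b2^step)
        p[[nm]] <- p[[nm]] - config$lr *
          (mhat / (sqrt(vhat) + eps) + config$weight_decay * p[[nm]])
      }
    }
    loss_history[epoch] <- epoch_loss / n_slides
  }

  structure(list(params = p, center = center, scale = scale,
                 loss_history = loss_history, config = config,
                 feature_dim = d),
            class = "mil_model")
}

#' Save / load a trained MIL model as a text checkpoint
#'
#' The checkpoint is a directory with a JSON manifest (dimensions, seed,
#' training configuration) and one CSV per weight tensor; it round-trips
#' exactly at full double precision.
#'
#' @param model a `mil_model`.
#' @param path checkpoint directory.
#' @return `load_mil_model` returns the `mil_model`.
#' @export
save_mil_model <- function(model, path) {
  stopifnot(inherits(model, "mil_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  manifest <- list(
    feature_dim = model$feature_dim,
    hidden = nrow(model$params$V),
    seed = cfg$seed, epochs = cfg$epochs,
    patches_per_step = cfg$patches_per_step,
    lr = cfg$lr, weight_decay = cfg$weight_decay,
    encoder = attr(cfg$encoder, "name") %||% "external",
    loss_history = model$loss_history)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  wt <- function(x, f) write.csv(as.data.frame(x), file.path(path, f),
                                 row.names = FALSE)
  wt(model$params$V, "V.csv"); wt(model$params$U, "U.csv")
  wt(data.frame(w = model$params$w), "w.csv")
  wt(data.frame(beta = model$params$beta, center = model$center,
                scale = model$scale), "head.csv")
  wt(data.frame(b0 = model$params$b0), "b0.csv")
  invisible(path)
}

#' @rdname save_mil_model
#' @export
load_mil_model <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  rd <- function(f) as.matrix(read.csv(file.path(path, f)))
  head_df <- read.csv(file.path(path, "head.csv"))
  params <- list(V = unname(rd("V.csv")), U = unname(rd("U.csv")),
                 w = read.csv(file.path(path, "w.csv"))$w,
                 beta = head_df$beta,
                 b0 = read.csv(file.path(path, "b0.csv"))$b0)
  structure(list(params = params, center = head_df$center,
                 scale = head_df$scale,
                 loss_history = manifest$loss_history,
                 config = manifest, feature_dim = manifest$feature_dim),
            class = "mil_model")
}
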