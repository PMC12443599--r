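#' Patch encoders
#'
#' An encoder is any callable that maps one tile image (tile_size x
#' tile_size x 3 array in `[0, 1]`) to a fixed-width numeric feature
#' vector; the feature width is exposed through the `dim` attribute. Two
#' desk-scale encoders ship with the package; external encoders (e.g.
#' precomputed foundation-model features) plug in through the same
#' interface by supplying features directly to [train_mil()].
#'
#' `stats_encoder()` is a deterministic hand-crafted descriptor: channel
#' means and SDs, saturation and value statistics, gray-level quantiles
#' and histogram, and gradient / high-frequency energy (27 features).
#'
#' `conv_encoder()` is a seeded random convolutional filter bank: `n_filters`
#' random 5x5 kernels applied to the gray channel, mean absolute response
#' pooled per kernel, concatenated with mean RGB.
#'
#' @param n_filters number of random kernels for `conv_encoder`.
#' @param seed seed fixing the random kernels.
#' @return A function of class `patch_encoder` with a `dim` attribute.
#' @export
stats_encoder <- function() {
  f <- function(tile) {
    r <- tile[, , 1]; g <- tile[, , 2]; b <- tile[, , 3]
    gray <- (r + g + b) / 3
    mx <- pmax(r, g, b); mn <- pmin(r, g, b)
    sat <- (mx - mn) / pmax(mx, 1e-8)
    dx <- abs(gray[, -1] - gray[, -ncol(gray)])
    dy <- abs(gray[-1, ] - gray[-nrow(gray), ])
    lag4x <- abs(gray[, -(1:4)] - gray[, seq_len(ncol(gray) - 4)])
    lag4y <- abs(gray[-(1:4), ] - gray[seq_len(nrow(gray) - 4), ])
    hist8 <- tabulate(pmin(floor(gray * 8) + 1L, 8L), 8L) / length(gray)
    c(mean(r), mean(g), mean(b), sd(r), sd(g), sd(b),
      mean(sat), sd(sat), mean(mx), sd(mx),
      quantile(gray, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE),
      mean(dx), mean(dy), mean(lag4x), mean(lag4y),
      hist8)
  }
  structure(f, feature_dim = 27L, name = "stats", class = c("patch_encoder", "function"))
}

#' @rdname stats_encoder
#' @export
conv_encoder <- function(n_filters = 16L, seed = 1L) {
  kernels <- with_seed(split_seed(seed, "conv_encoder"), {
    lapply(seq_len(n_filters), function(i) {
      k <- matrix(rnorm(25), 5, 5)
      k - mean(k)
    })
  })
  f <- function(tile) {
    gray <- (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
    resp <- vapply(kernels, function(k) {
      # valid-region convolution via shifted sums
      h <- nrow(gray) - 4L; w <- ncol(gray) - 4L
      acc <- matrix(0, h, w)
      for (i in 1:5) for (j in 1:5) {
        acc <- acc + k[i, j] * gray[i:(i + h - 1L), j:(j + w - 1L)]
      }
      mean(abs(acc))
    }, numeric(1))
    c(resp, mean(tile[, , 1]), mean(tile[, , 2]), mean(tile[, , 3]))
  }
  structure(f, feature_dim = n_filters + 3L, name = "conv",
            class = c("patch_encoder", "function"))
}

#' Encode tile patches into per-tile feature vectors
#'
#' Extracts each tile of the grid from the image and applies the encoder;
#' row k of the result corresponds to tile k of the grid, so permuting
#' the grid permutes the rows identically.
#'
#' @param image slide raster at the grid's working resolution.
#' @param grid a [tile_grid()]; all tiles must lie within the image.
#' @param encoder a patch encoder ([stats_encoder()] by default).
#' @return A K x D numeric matrix of class `patch_features`.
#' @export
encode_patches <- function(image, grid, encoder = stats_encoder()) {
  stopifnot(inherits(grid, "tile_grid"))
  K <- nrow(grid$tiles)
  if (K == 0L) stop("no tissue: tile grid is empty")
  ts <- grid$tile_size
  if (any(grid$tiles$x + ts > ncol(image)) || any(grid$tiles$y + ts > nrow(image)))
    stop("grid tiles fall outside the image")
  D <- attr(encoder, "feature_dim")
  out <- matrix(NA_real_, K, D)
  for (k in seq_len(K)) {
    ys <- grid$tiles$y[k] + seq_len(ts)
    xs <- grid$tiles$x[k] + seq_len(ts)
    out[k, ] <- encoder(image[ys, xs, , drop = FALSE])
  }
  if (!all(is.finite(out))) stop("encoder produced non-finite features")
  class(out) <- c("patch_features", class(out))
  out
}
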