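#' Z-score a slide's attention weights
#'
#' Standardizes the attention weights across the slide's tiles using the
#' population standard deviation and clips to `[-4, 4]` (the display
#' range used for attention masks). A zero-variance input (e.g. uniform
#' attention) maps to all zeros. Because z-scoring removes location and
#' scale, the result is invariant to positive rescaling of the weights.
#'
#' @param weights attention weight vector (or a `slide_prediction`).
#' @param grid optional [tile_grid()] aligned with the weights.
#' @param clip clipping bound (default 4).
#' @return An object of class `attention_map`: list with `z`, `grid`.
#' @export
zscore_attention <- function(weights, grid = NULL, clip = 4) {
  if (inherits(weights, "slide_prediction")) weights <- weights$attention_weights
  if (length(weights) == 0L) stop("empty attention vector")
  mu <- mean(weights)
  sdev <- sqrt(mean((weights - mu)^2))  # population SD
  z <- if (sdev < 1e-15) rep(0, length(weights)) else (weights - mu) / sdev
  z <- pmin(pmax(z, -clip), clip)
  if (!is.null(grid)) stopifnot(inherits(grid, "tile_grid"),
                                nrow(grid$tiles) == length(z))
  structure(list(z = z, grid = grid, clip = clip), class = "attention_map")
}

#' Extract the high-attention region of an attention map
#'
#' Marks tiles with z-score strictly above `threshold` (default 3, the
#' conventional "high attention" cut) and reports the corresponding pixel
#' count (marked tiles x tile_size^2).
#'
#' @param map an [zscore_attention()] result with a grid attached.
#' @param threshold z-score cut; tiles are marked iff z > threshold.
#' @return An object of class `high_attention_region`: per-tile logical
#'   `marked`, `pixel_count`, `threshold` and the grid.
#' @export
high_attention_mask <- function(map, threshold = 3) {
  stopifnot(inherits(map, "attention_map"))
  marked <- map$z > threshold
  ts <- if (!is.null(map$grid)) map$grid$tile_size else 224L
  structure(list(marked = marked, grid = map$grid,
                 pixel_count = sum(marked) * as.double(ts)^2,
                 threshold = threshold),
            class = "high_attention_region")
}

# Rasterize a high-attention region to a pixel-level logical matrix.
region_pixel_mask <- function(region, height, width) {
  stopifnot(inherits(region, "high_attention_region"), !is.null(region$grid))
  ts <- region$grid$tile_size
  m <- matrix(FALSE, height, width)
  sel <- which(region$marked)
  for (k in sel) {
    ys <- region$grid$tiles$y[k] + seq_len(ts)
    xs <- region$grid$tiles$x[k] + seq_len(ts)
    m[ys[ys <= height], xs[xs <= width]] <- TRUE
  }
  m
}

#' Locate the densest high-attention window
#'
#' Scans every axis-aligned `window` x `window` placement over the pixel
#' mask and returns the one containing the most high-attention pixels.
#' Ties are broken by the smallest (y, x) in row-major order. An empty
#' mask returns the degenerate box at (0, 0) flagged `no_high_attention`.
#'
#' @param region a [high_attention_mask()] result, or a logical pixel
#'   matrix.
#' @param window window side in pixels; must not exceed either slide
#'   dimension.
#' @param height,width slide dimensions (required when `region` is a
#'   region object).
#' @return List `box` with 0-based `x`, `y`, `w`, `h`, the contained
#'   `count`, and `no_high_attention` flag.
#' @export
densest_region <- function(region, window, height = NULL, width = NULL) {
  mask <- if (is.matrix(region)) region
  else region_pixel_mask(region, height, width)
  h <- nrow(mask); w <- ncol(mask)
  if (window > h || window > w) stop("window larger than slide extent")
  if (!any(mask)) {
    return(list(x = 0L, y = 0L, w = as.integer(window), h = as.integer(window),
                count = 0L, no_high_attention = TRUE))
  }
  S <- rbind(0, apply(mask, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  ny <- h - window + 1L; nx <- w - window + 1L
  ys <- seq_len(ny); xs <- seq_len(nx)
  counts <- S[ys + window, xs + window, drop = FALSE] -
    S[ys, xs + window, drop = FALSE] -
    S[ys + window, xs, drop = FALSE] + S[ys, xs, drop = FALSE]
  best <- max(counts)
  hits <- which(t(counts) == best)  # transpose -> row-major (y, then x)
  first <- hits[1]
  by <- (first - 1L) %/% nx
  bx <- (first - 1L) %% nx
  list(x = as.integer(bx), y = as.integer(by),
       w = as.integer(window), h = as.integer(window),
       count = as.integer(best), no_high_attention = FALSE)
}

# Diverging blue-white-red colormap anchored at 0 over [-clip, clip].
diverging_color <- function(z, clip = 4) {
  t <- (pmin(pmax(z, -clip), clip) + clip) / (2 * clip)
  lo <- c(0.13, 0.40, 0.67); mid <- c(0.97, 0.97, 0.97); hi <- c(0.70, 0.09, 0.17)
  col <- matrix(0, length(z), 3)
  low <- t <= 0.5
  for (k in 1:3) {
    col[low, k] <- lo[k] + (mid[k] - lo[k]) * (t[low] / 0.5)
    col[!low, k] <- mid[k] + (hi[k] - mid[k]) * ((t[!low] - 0.5) / 0.5)
  }
  col
}

#' Render an attention overlay image
#'
#' Produces a deterministic overlay with the same dimensions as the
#' input image. Three modes: `"full"` alpha-blends the full diverging
#' attention spectrum over every tile; `"high"` colors only tiles whose
#' z-score exceeds the threshold; `"inverted"` obscures everything
#' except the high-attention tiles.
#'
#' @param image slide raster (h x w x 3 in `[0, 1]`).
#' @param map an [zscore_attention()] result with a grid, or a
#'   `high_attention_region` for the masked modes.
#' @param mode one of "full", "high", "inverted".
#' @param threshold z cut used by the "high" and "inverted" modes.
#' @param alpha overlay opacity in "full" mode.
#' @return The overlay image array, same dimensions as `image`.
#' @export
render_overlay <- function(image, map, mode = c("full", "high", "inverted"),
                           threshold = 3, alpha = 0.5) {
  mode <- match.arg(mode)
  if (inherits(map, "high_attention_region")) {
    region <- map
    grid <- region$grid
    z <- ifelse(region$marked, threshold + 1, 0)
  } else {
    stopifnot(inherits(map, "attention_map"), !is.null(map$grid))
    grid <- map$grid
    z <- map$z
  }
  ts <- grid$tile_size
  h <- nrow(image); w <- ncol(image)
  if (any(grid$tiles$x + ts > w) || any(grid$tiles$y + ts > h))
    stop("attention grid is misaligned with the image")
  out <- image
  if (mode == "inverted") {
    keep <- matrix(FALSE, h, w)
    for (k in which(z > threshold)) {
      keep[grid$tiles$y[k] + seq_len(ts), grid$tiles$x[k] + seq_len(ts)] <- TRUE
    }
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[!keep] <- plane[!keep] * 0.15 + 0.05
      out[, , ch] <- plane
    }
    return(out)
  }
  cols <- diverging_color(z, clip = if (!is.null(map$clip)) map$clip else 4)
  for (k in seq_along(z)) {
    if (mode == "high" && z[k] <= threshold) next
    ys <- grid$tiles$y[k] + seq_len(ts)
    xs <- grid$tiles$x[k] + seq_len(ts)
    for (ch in 1:3) {
      out[ys, xs, ch] <- (1 - alpha) * out[ys, xs, ch] + alpha * cols[k, ch]
    }
  }
  out
}

#' Write region metadata as a JSON sidecar
#'
#' @param region a [high_attention_mask()] result.
#' @param box a [densest_region()] box.
#' @param path output JSON path.
#' @export
write_region_json <- function(region, box, path) {
  jsonlite::write_json(
    list(threshold = region$threshold, pixel_count = region$pixel_count,
         box = box[c("x", "y", "w", "h", "count", "no_high_attention")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
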