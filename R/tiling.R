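#' Detect tissue on a slide raster
#'
#' Computes per-pixel saturation ((max - min) / max over RGB channels),
#' thresholds it with Otsu's method (floored at `min_saturation` so that
#' blank, near-white slides yield an empty mask), and removes connected
#' components smaller than `min_object_px`. Deterministic.
#'
#' @param image height x width x 3 array in `[0, 1]` (or a grayscale
#'   matrix, in which case darkness is used instead of saturation).
#' @param mpp microns per pixel of `image`; carried on the mask.
#' @param min_saturation absolute saturation floor below which a pixel is
#'   never tissue.
#' @param min_object_px connected components smaller than this many
#'   pixels are discarded.
#' @return An object of class `tissue_mask`: list with logical `mask`,
#'   `mpp` and dimensions.
#' @export
detect_tissue <- function(image, mpp = NULL, min_saturation = 0.07,
                          min_object_px = 256L) {
  if (length(image) == 0L) stop("zero-size image")
  if (length(dim(image)) == 3L) {
    mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
    mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
    sat <- (mx - mn) / pmax(mx, 1e-8)
  } else {
    sat <- 1 - image  # grayscale: dark = tissue
  }
  if (max(sat) <= min_saturation) {
    mask <- matrix(FALSE, nrow(sat), ncol(sat))
  } else {
    thr <- max(EBImage::otsu(sat, range = c(0, 1)), min_saturation)
    mask <- sat > thr
    if (any(mask) && min_object_px > 1L) {
      lab <- EBImage::bwlabel(mask)
      sizes <- tabulate(lab)
      keep <- which(sizes >= min_object_px)
      mask <- matrix(lab %in% keep & lab > 0L, nrow(mask), ncol(mask))
    }
  }
  structure(list(mask = mask, mpp = mpp, height = nrow(mask),
                 width = ncol(mask)), class = "tissue_mask")
}

#' Construct a tile grid object
#'
#' Tiles are axis-aligned `tile_size` squares at the working resolution,
#' 0-based, origin at the top-left, half-open `[x, x + tile_size)`, with
#' coordinates that are multiples of `tile_size` (regular grid).
#'
#' @param tiles data.frame with integer columns `x`, `y`.
#' @param slide_id slide identifier.
#' @param tile_size tile side in pixels (default 224).
#' @param mpp working resolution in microns per pixel (default 0.5).
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(tiles, slide_id = "slide", tile_size = 224L, mpp = 0.5) {
  stopifnot(tile_size > 0, mpp > 0,
            all(c("x", "y") %in% names(tiles)))
  if (nrow(tiles) > 0) {
    stopifnot(all(tiles$x %% tile_size == 0), all(tiles$y %% tile_size == 0),
              !anyDuplicated(tiles[c("x", "y")]))
  }
  structure(list(slide_id = slide_id, tile_size = as.integer(tile_size),
                 mpp = mpp, tiles = as.data.frame(tiles)),
            class = "tile_grid")
}

#' Lay a patch grid over detected tissue
#'
#' Resamples the tissue mask to the working resolution when the source
#' mpp differs from `mpp`, then includes exactly the full grid cells
#' whose tissue coverage is at least `min_tissue_fraction`, in row-major
#' order (top row first, left to right).
#'
#' @param mask a [detect_tissue()] result (its `mpp` must be known, or be
#'   supplied via `source_mpp`).
#' @param tile_size tile side in pixels at the working resolution.
#' @param mpp target working resolution (microns per pixel).
#' @param min_tissue_fraction minimum per-tile tissue coverage.
#' @param slide_id slide identifier carried on the grid.
#' @param source_mpp mpp of the mask when not recorded on it.
#' @return A [tile_grid()] whose `tiles` also carry `coverage`.
#' @export
grid_tiles <- function(mask, tile_size = 224L, mpp = 0.5,
                       min_tissue_fraction = 0.25, slide_id = "slide",
                       source_mpp = NULL) {
  stopifnot(inherits(mask, "tissue_mask"))
  smpp <- mask$mpp %||% source_mpp
  if (is.null(smpp))
    stop("unknown mpp: supply resolution metadata for the source image")
  m <- mask$mask
  if (abs(smpp - mpp) > 1e-9) {
    scale <- smpp / mpp
    m <- resample_raster(m, round(nrow(m) * scale), round(ncol(m) * scale))
  }
  cov <- block_sums(m, tile_size) / tile_size^2
  if (length(cov) == 0L) {
    return(tile_grid(data.frame(x = integer(0), y = integer(0)),
                     slide_id, tile_size, mpp))
  }
  sel <- which(t(cov) >= min_tissue_fraction)  # transpose -> row-major order
  ntx <- ncol(cov)
  xs <- ((sel - 1L) %% ntx) * tile_size
  ys <- ((sel - 1L) %/% ntx) * tile_size
  tiles <- data.frame(x = as.integer(xs), y = as.integer(ys),
                      coverage = t(cov)[sel])
  tile_grid(tiles, slide_id, tile_size, mpp)
}

#' Tissue surface area of a tile grid
#'
#' Area in mm^2 implied by the tiles used for inference:
#' n_tiles x (tile_size x mpp / 1000)^2. One 224 px tile at 0.5 um/px is
#' a 112 um square, 0.012544 mm^2.
#'
#' @param grid a [tile_grid()].
#' @return Area in mm^2.
#' @export
tissue_area_mm2 <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  nrow(grid$tiles) * (grid$tile_size * grid$mpp / 1000)^2
}

#' Assign samples to tissue-area decile buckets
#'
#' Buckets by the empirical deciles of `areas`; with distinct values each
#' bucket holds n/10 samples within one. Ties that collapse the decile
#' breaks are handled by merging the affected buckets; a fully constant
#' input lands in a single bucket and the result is flagged degenerate.
#'
#' @param areas numeric vector of at least 10 areas.
#' @return Integer bucket indices in 1..10, with attribute `degenerate`
#'   when decile breaks collapsed.
#' @export
area_deciles <- function(areas) {
  if (length(areas) < 10L) stop("at least 10 samples are required")
  br <- quantile(areas, probs = seq(0, 1, by = 0.1), names = FALSE)
  ub <- unique(br)
  degenerate <- length(ub) < 11L
  if (length(ub) == 1L) {
    out <- rep(1L, length(areas))
  } else {
    cutlab <- cut(areas, breaks = ub, include.lowest = TRUE, labels = FALSE)
    # map each (possibly merged) interval back onto the 1..10 decile scale:
    # an interval ending at break ub[j+1] gets the highest decile index
    # whose break equals it
    pos <- vapply(ub, function(v) max(which(br == v)), integer(1)) - 1L
    out <- pos[cutlab + 1L]
  }
  structure(out, degenerate = degenerate)
}

#' Write / read a tile grid as CSV
#'
#' Columns: slide_id, x, y, tile_size, mpp (one row per tile).
#' @param grid a [tile_grid()].
#' @param path file path.
#' @return `read_tile_grid` returns the [tile_grid()].
#' @export
write_tile_grid <- function(grid, path) {
  stopifnot(inherits(grid, "tile_grid"))
  df <- data.frame(slide_id = grid$slide_id,
                   x = grid$tiles$x, y = grid$tiles$y,
                   tile_size = grid$tile_size, mpp = grid$mpp)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tile_grid
#' @export
read_tile_grid <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty tile grid file")
  tile_grid(df[c("x", "y")], slide_id = df$slide_id[1],
            tile_size = df$tile_size[1], mpp = df$mpp[1])
}

#' Write a tissue mask as PNG
#' @param mask a [detect_tissue()] result.
#' @param path output PNG path.
#' @export
write_tissue_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"))
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}
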