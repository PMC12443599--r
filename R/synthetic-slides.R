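#' Specification of a synthetic labeled slide
#'
#' Describes a raster "slide" with a near-white background, contiguous
#' eosin-pink tissue regions covering approximately `tissue_fraction` of
#' the pixels and, for mutant slides, a `signal_fraction` of tissue tiles
#' carrying a distinct high-frequency texture that stands in for the
#' mutation-associated morphology. The generator is plumbing for testing
#' the downstream pipeline, not a histology synthesizer.
#'
#' @param width,height slide dimensions in pixels.
#' @param mpp microns per pixel of the raster.
#' @param tissue_fraction fraction of pixels covered by tissue, in `[0, 1]`.
#' @param signal_fraction fraction of tissue tiles carrying the signal
#'   texture; must be 0 when `label` is "wild-type".
#' @param label slide label, "mutant" or "wild-type".
#' @param tile_size tile size in pixels used to place the signal texture.
#' @return An object of class `slide_spec`.
#' @export
slide_spec <- function(width, height, mpp = 0.5, tissue_fraction = 0.6,
                       signal_fraction = 0, label = c("wild-type", "mutant"),
                       tile_size = 224L) {
  label <- match.arg(label)
  stopifnot(width >= 1, height >= 1, mpp > 0, tile_size >= 1)
  if (tissue_fraction < 0 || tissue_fraction > 1)
    stop("impossible geometry: tissue_fraction must lie in [0, 1]")
  if (signal_fraction < 0 || signal_fraction > 1)
    stop("signal_fraction must lie in [0, 1]")
  if (label == "wild-type" && signal_fraction != 0)
    stop("signal_fraction must be 0 for wild-type slides")
  if (width < tile_size || height < tile_size)
    stop("slide must admit at least one tile at the tiling size")
  structure(list(width = as.integer(width), height = as.integer(height),
                 mpp = mpp, tissue_fraction = tissue_fraction,
                 signal_fraction = signal_fraction, label = label,
                 tile_size = as.integer(tile_size)),
            class = "slide_spec")
}

#' Generate a synthetic slide image with ground-truth masks
#'
#' Tissue is laid down by thresholding a smooth random field at the
#' empirical quantile matching `tissue_fraction`, which yields contiguous
#' blob-like regions covering the requested pixel share. For mutant
#' slides, a round(signal_fraction x n) subset of the tissue-bearing
#' tiles receives a fine checker texture; `signal_mask` marks exactly the
#' textured pixels (tile rectangle intersected with tissue). Output is
#' deterministic in `seed`.
#'
#' @param spec a [slide_spec()].
#' @param seed integer seed.
#' @return A list with `image` (height x width x 3 array in `[0, 1]`),
#'   `signal_mask` and `tissue_mask` (logical matrices), `mpp`, `label`
#'   and the tile coordinates that received signal texture.
#' @export
generate_slide <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "slide_spec"))
  h <- spec$height; w <- spec$width; ts <- spec$tile_size
  with_seed(split_seed(seed, "slide"), {
    # smooth random field -> contiguous tissue blobs at the exact fraction
    nc <- max(4L, round(w / 168)); nr <- max(4L, round(h / 168))
    field <- bilinear_upsample(matrix(runif(nr * nc), nr, nc), h, w)
    tissue <- if (spec$tissue_fraction >= 1) {
      matrix(TRUE, h, w)
    } else if (spec$tissue_fraction <= 0) {
      matrix(FALSE, h, w)
    } else {
      field > quantile(field, 1 - spec$tissue_fraction, names = FALSE)
    }

    # background: near-white with mild scanner noise
    img <- array(0, dim = c(h, w, 3))
    noise <- matrix(runif(h * w, -0.015, 0.015), h, w)
    for (k in 1:3) img[, , k] <- 0.965 + noise

    # tissue: eosin pink with low-frequency intensity variation
    tex <- bilinear_upsample(matrix(runif(64), 8, 8), h, w)
    base <- c(0.80, 0.55, 0.70)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[tissue] <- base[k] + 0.08 * (tex[tissue] - 0.5) +
        runif(sum(tissue), -0.02, 0.02)
      img[, , k] <- ch
    }

    # signal tiles: distinct high-frequency checker texture on tissue pixels
    signal <- matrix(FALSE, h, w)
    signal_tiles <- data.frame(x = integer(0), y = integer(0))
    cov <- block_sums(tissue, ts) / ts^2
    if (spec$signal_fraction > 0 && length(cov) > 0) {
      cand <- which(cov >= 0.25, arr.ind = TRUE)  # tissue-bearing tiles
      n_sig <- round(spec$signal_fraction * nrow(cand))
      if (n_sig > 0) {
        pick <- cand[sample(nrow(cand), n_sig), , drop = FALSE]
        checker <- outer(seq_len(h) %/% 4L, seq_len(w) %/% 4L, "+") %% 2L == 0L
        for (i in seq_len(nrow(pick))) {
          ys <- (pick[i, 1] - 1L) * ts + seq_len(ts)
          xs <- (pick[i, 2] - 1L) * ts + seq_len(ts)
          sub <- matrix(FALSE, h, w)
          sub[ys, xs] <- TRUE
          signal <- signal | (sub & tissue)
        }
        dark <- signal & checker
        img[, , 1][dark] <- img[, , 1][dark] - 0.30
        img[, , 2][dark] <- img[, , 2][dark] - 0.25
        img[, , 3][dark] <- img[, , 3][dark] - 0.05
        signal_tiles <- data.frame(x = (pick[, 2] - 1L) * ts,
                                   y = (pick[, 1] - 1L) * ts)
      }
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, signal_mask = signal, tissue_mask = tissue,
         mpp = spec$mpp, label = spec$label, signal_tiles = signal_tiles)
  })
}

#' Write a slide image with microns-per-pixel metadata
#'
#' Writes PNG (default) or TIFF, and always a JSON sidecar echoing the
#' mpp and dimensions so the resolution survives format round-trips.
#'
#' @param slide a list with `image` and `mpp` (as from [generate_slide()]),
#'   or a bare array plus `mpp=`.
#' @param path output path ending in .png or .tif/.tiff.
#' @param mpp microns per pixel when `slide` is a bare array.
#' @return `read_slide` returns a list with `image` and `mpp`.
#' @export
write_slide <- function(slide, path, mpp = NULL) {
  if (is.list(slide)) { img <- slide$image; mpp <- slide$mpp } else img <- slide
  if (is.null(mpp)) stop("mpp metadata is required")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output")
    # TIFF resolution tags are pixels/cm: 10,000 um per cm / mpp
    tiff::writeTIFF(img, path, resolution = rep(10000 / mpp, 2))
  } else stop("unsupported image format: ", ext)
  sidecar <- sub("\\.[A-Za-z]+$", ".json", path)
  jsonlite::write_json(list(mpp = mpp, width = ncol(img), height = nrow(img)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slide
#' @export
read_slide <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF input")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  sidecar <- sub("\\.[A-Za-z]+$", ".json", path)
  mpp <- if (file.exists(sidecar)) jsonlite::read_json(sidecar)$mpp else NULL
  list(image = img, mpp = mpp)
}
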