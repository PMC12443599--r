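#' milscreen: weakly supervised slide classification and screening triage
#'
#' Tools for attention-based multiple-instance learning (MIL) on
#' whole-slide images and for calibrating an AI-assisted dual-threshold
#' screening workflow against a historical rapid-test benchmark. All
#' stages can be exercised end to end on synthetic slides and cohorts
#' with known ground truth.
#'
#' @importFrom stats median quantile rnorm runif rbinom rlnorm pnorm qnorm
#'   plogis sd cor kruskal.test wilcox.test p.adjust setNames rpois aggregate
#' @importFrom utils read.csv write.csv
#' @keywords internal
"_PACKAGE"

#' Derive a component seed from a global seed
#'
#' A single run seed fans out to independent per-component seeds so that
#' adding a pipeline stage never perturbs another stage's random stream.
#' The mapping is a deterministic polynomial hash of the component name
#' folded into the global seed, reduced modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param component character scalar naming the consumer (e.g. "labels").
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' split_seed(1, "labels")
#' split_seed(1, "scores")
split_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  m <- 2147483647
  s <- as.double(seed %% m)
  for (code in utf8ToInt(component)) {
    s <- (s * 31 + code) %% m
  }
  as.integer(s %% (m - 1L) + 1L)
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the
#' caller's RNG state afterwards, so seeded helpers never perturb an
#' enclosing simulation stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Bilinear upsampling of a coarse matrix to h x w. Used for smooth random
# fields (tissue blobs) and image resampling.
bilinear_upsample <- function(C, h, w) {
  nr <- nrow(C); nc <- ncol(C)
  stopifnot(nr >= 2, nc >= 2, h >= 1, w >= 1)
  ri <- seq(1, nr, length.out = h)
  ci <- seq(1, nc, length.out = w)
  r0 <- pmin(floor(ri), nr - 1L); rf <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); cf <- ci - c0
  wa <- (1 - rf) %o% (1 - cf)
  wb <- rf %o% (1 - cf)
  wd <- (1 - rf) %o% cf
  we <- rf %o% cf
  C[r0, c0] * wa + C[r0 + 1, c0] * wb + C[r0, c0 + 1] * wd + C[r0 + 1, c0 + 1] * we
}

#' Resample a raster to new dimensions
#'
#' Nearest-neighbour for logical masks, bilinear for numeric matrices
#' and h x w x 3 image arrays. Used to bring non-native-resolution
#' scans to the model's working microns-per-pixel.
#'
#' @param x logical matrix, numeric matrix or h x w x 3 array.
#' @param new_h,new_w target dimensions in pixels.
#' @return The resampled raster.
#' @export
resample_raster <- function(x, new_h, new_w) {
  if (is.logical(x) || length(dim(x)) == 2L && is.logical(x[1])) {
    ri <- pmin(pmax(round(seq(1, nrow(x), length.out = new_h)), 1L), nrow(x))
    ci <- pmin(pmax(round(seq(1, ncol(x), length.out = new_w)), 1L), ncol(x))
    return(x[ri, ci])
  }
  if (length(dim(x)) == 2L) return(bilinear_upsample(x, new_h, new_w))
  out <- array(0, dim = c(new_h, new_w, dim(x)[3]))
  for (k in seq_len(dim(x)[3])) out[, , k] <- bilinear_upsample(x[, , k], new_h, new_w)
  out
}

# Sum of mask values over non-overlapping ts x ts blocks; returns an
# n_row_tiles x n_col_tiles matrix. Integral-image formulation.
block_sums <- function(mask, ts) {
  h <- nrow(mask); w <- ncol(mask)
  nty <- h %/% ts; ntx <- w %/% ts
  if (nty == 0L || ntx == 0L) return(matrix(0, 0, 0))
  m <- mask[seq_len(nty * ts), seq_len(ntx * ts), drop = FALSE]
  S <- rbind(0, apply(m, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  ys <- seq(0, nty * ts, by = ts) + 1L
  xs <- seq(0, ntx * ts, by = ts) + 1L
  S[ys[-1], xs[-1], drop = FALSE] - S[ys[-(nty + 1)], xs[-1], drop = FALSE] -
    S[ys[-1], xs[-(ntx + 1)], drop = FALSE] + S[ys[-(nty + 1)], xs[-(ntx + 1)], drop = FALSE]
}

# ISO-8601 UTC formatting used by all cohort timestamp columns.
format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parse_iso8601 <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

`%||%` <- function(a, b) if (is.null(a)) b else a
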