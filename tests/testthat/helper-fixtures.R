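# Shared fixtures and independent oracles, built in code at test time.

# --- independent oracles ----------------------------------------------------

# AUC by exhaustive pair enumeration, ties counted 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Assisted metrics by per-sample enumeration through screen_sample().
brute_assisted <- function(cohort, thresholds) {
  calls <- character(nrow(cohort))
  used <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    r <- screen_sample(cohort$score[i], thresholds, cohort$rapid_call[i])
    calls[i] <- r$call
    used[i] <- r$rapid_used
  }
  y <- cohort$ngs_label == "mutant"
  neg <- calls == "negative"; pos <- calls == "positive"
  list(npv = if (any(neg)) mean(!y[neg]) else NA_real_,
       ppv = if (any(pos)) mean(y[pos]) else NA_real_,
       test_reduction = mean(!used))
}

# Gated attention by scalar-by-scalar arithmetic.
brute_gated_attention <- function(features, params) {
  K <- nrow(features)
  e <- numeric(K)
  for (k in seq_len(K)) {
    h <- features[k, ]
    gate <- tanh(as.vector(params$V %*% h)) *
      (1 / (1 + exp(-as.vector(params$U %*% h))))
    e[k] <- sum(params$w * gate)
  }
  a <- exp(e - max(e)); a <- a / sum(a)
  pooled <- numeric(ncol(features))
  for (k in seq_len(K)) pooled <- pooled + a[k] * features[k, ]
  list(weights = a, pooled = pooled)
}

# Densest window by exhaustive scan with row-major tie-break.
brute_densest <- function(mask, window) {
  h <- nrow(mask); w <- ncol(mask)
  best <- -1; bx <- 0; by <- 0
  for (y in 0:(h - window)) for (x in 0:(w - window)) {
    cnt <- sum(mask[y + seq_len(window), x + seq_len(window)])
    if (cnt > best) { best <- cnt; bx <- x; by <- y }
  }
  list(x = bx, y = by, count = best)
}

# Random cohort with rapid calls and optional score ties.
random_cohort <- function(n, seed, prevalence = 0.4, ties = FALSE) {
  set.seed(seed)
  y <- rbinom(n, 1, prevalence)
  score <- if (ties) round(runif(n), 2) else runif(n)
  score <- pmin(pmax(score + 0.15 * y, 0), 1)
  data.frame(sample_id = sprintf("R%04d", seq_len(n)), score = score,
             ngs_label = ifelse(y == 1, "mutant", "wild-type"),
             rapid_call = ifelse(y == 1,
                                 ifelse(runif(n) < 0.9, "positive", "negative"),
                                 ifelse(runif(n) < 0.97, "negative", "positive")),
             stringsAsFactors = FALSE)
}

# --- shared slide fixture (built once per test run) -------------------------

.fixture_env <- new.env(parent = emptyenv())

# Small labeled slide set with encoded features; cached across test files.
slide_fixture <- function(n = 12, px = 448, signal_fraction = 0.3, seed = 42) {
  key <- paste("slides", n, px, signal_fraction, seed, sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  labels <- rep(c("mutant", "wild-type"), length.out = n)
  slides <- lapply(seq_len(n), function(i) {
    sp <- slide_spec(px, px, tissue_fraction = 0.6,
                     signal_fraction = if (labels[i] == "mutant") signal_fraction else 0,
                     label = labels[i])
    sl <- generate_slide(sp, seed = split_seed(seed, paste0("slide", i)))
    mask <- detect_tissue(sl$image, mpp = 0.5)
    grid <- grid_tiles(mask, slide_id = sprintf("SL%03d", i))
    feats <- encode_patches(sl$image, grid)
    list(features = feats, label = labels[i], grid = grid,
         image = sl$image, signal_tiles = sl$signal_tiles,
         signal_mask = sl$signal_mask, tissue_mask = sl$tissue_mask)
  })
  .fixture_env[[key]] <- slides
  slides
}
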