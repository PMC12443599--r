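test_that("gated attention matches hand arithmetic on a 2x2 instance", {
  # hand-set parameters, H = 2, D = 2, K = 2
  params <- list(V = matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2),
                 U = matrix(c(-0.1, 0.4, 0.7, -0.6), 2, 2),
                 w = c(1.2, -0.7))
  F <- matrix(c(0.3, -1.1, 0.9, 0.4), 2, 2)
  got <- gated_attention(F, params)
  exp <- brute_gated_attention(F, params)
  expect_equal(got$weights, exp$weights, tolerance = 1e-9)
  expect_equal(got$pooled, exp$pooled, tolerance = 1e-9)
})

test_that("gated attention agrees with brute force on random small bags", {
  set.seed(77)
  for (i in 1:25) {
    K <- sample(1:5, 1); D <- sample(1:4, 1); H <- sample(1:4, 1)
    F <- matrix(rnorm(K * D), K, D)
    params <- list(V = matrix(rnorm(H * D), H, D),
                   U = matrix(rnorm(H * D), H, D), w = rnorm(H))
    got <- gated_attention(F, params)
    exp <- brute_gated_attention(F, params)
    expect_equal(got$weights, exp$weights, tolerance = 1e-9)
    expect_equal(got$pooled, exp$pooled, tolerance = 1e-9)
    expect_equal(sum(got$weights), 1, tolerance = 1e-9)
    expect_true(all(got$weights >= 0))
  }
})

test_that("attention weights degenerate correctly", {
  params <- list(V = matrix(0.3, 2, 3), U = matrix(-0.2, 2, 3), w = c(1, 1))
  same <- matrix(rep(c(0.1, 0.5, -0.4), each = 4), 4, 3)
  expect_equal(gated_attention(same, params)$weights, rep(0.25, 4),
               tolerance = 1e-12)
  one <- matrix(rnorm(3), 1, 3)
  expect_identical(gated_attention(one, params)$weights, 1)
  bad <- matrix(c(1, NA, 2, 3, 4, 5), 2, 3)
  expect_error(gated_attention(bad, params), "finite")
})

test_that("slide probability is a bag function: permutation invariant", {
  set.seed(5)
  D <- 6
  F <- matrix(rnorm(10 * D), 10, D)
  p <- init_gma_params(D, hidden = 4, seed = 2)
  p$beta <- rnorm(D)
  pr1 <- predict_slide(F, p)
  perm <- sample(10)
  pr2 <- predict_slide(F[perm, ], p)
  expect_equal(pr1$probability, pr2$probability, tolerance = 1e-12)
  expect_equal(pr1$attention_weights[perm], pr2$attention_weights,
               tolerance = 1e-12)

  # zero head -> logistic(0) = 0.5
  p$beta <- rep(0, D); p$b0 <- 0
  expect_equal(predict_slide(F, p)$probability, 0.5)

  # toy composition: logistic of the hand-chained pooled vector
  p$beta <- seq_len(D) / 10; p$b0 <- -0.2
  ga <- brute_gated_attention(F, p)
  expect_equal(predict_slide(F, p)$probability,
               plogis(sum(p$beta * ga$pooled) - 0.2), tolerance = 1e-9)

  expect_error(predict_slide(F[, 1:3], p), "width mismatch")
})

test_that("encode_patches is a pure per-tile map", {
  slides <- slide_fixture()
  s <- slides[[1]]
  F <- s$features
  expect_equal(nrow(F), nrow(s$grid$tiles))
  expect_equal(ncol(F), attr(stats_encoder(), "feature_dim"))

  # permuting the grid permutes rows identically
  perm <- rev(seq_len(nrow(s$grid$tiles)))
  g2 <- s$grid; g2$tiles <- g2$tiles[perm, ]
  F2 <- encode_patches(s$image, g2)
  expect_equal(unclass(F2), unclass(F)[perm, ], ignore_attr = TRUE)

  # constant image -> identical rows
  flat <- array(0.5, dim = c(448, 448, 3))
  gflat <- tile_grid(data.frame(x = c(0L, 224L), y = c(0L, 0L)))
  Fc <- encode_patches(flat, gflat)
  expect_equal(Fc[1, ], Fc[2, ])

  empty <- tile_grid(data.frame(x = integer(0), y = integer(0)))
  expect_error(encode_patches(flat, empty), "no tissue")
})

test_that("conv_encoder is seeded and deterministic", {
  enc1 <- conv_encoder(8, seed = 3)
  enc2 <- conv_encoder(8, seed = 3)
  tile <- array(runif(224 * 224 * 3), dim = c(224, 224, 3))
  expect_identical(enc1(tile), enc2(tile))
  expect_equal(length(enc1(tile)), attr(enc1, "feature_dim"))
})

test_that("sample_patches draws uniform seeded subsets", {
  g <- tile_grid(expand.grid(x = seq(0L, 224L * 3L, by = 224L),
                             y = seq(0L, 224L * 3L, by = 224L)))
  all16 <- sample_patches(g, 20, seed = 1)
  expect_equal(nrow(all16$tiles), 16L)  # replacement-off: each tile once
  s1 <- sample_patches(g, 5, seed = 9)
  s2 <- sample_patches(g, 5, seed = 9)
  expect_identical(s1$tiles, s2$tiles)
  rep20 <- sample_patches(g, 20, seed = 2, replace = TRUE)
  expect_equal(nrow(rep20$tiles), 20L)
  expect_error(sample_patches(tile_grid(data.frame(x = integer(0),
                                                   y = integer(0))), 3),
               "empty")

  # frequency over many draws is uniform (chi-square on counts)
  counts <- integer(16)
  for (i in 1:4000) {
    s <- sample_patches(g, 4, seed = i)
    idx <- match(paste(s$tiles$x, s$tiles$y), paste(g$tiles$x, g$tiles$y))
    counts[idx] <- counts[idx] + 1L
  }
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("training reduces loss, is seeded, and rejects single-class input", {
  slides <- slide_fixture()
  tc <- train_config(patches_per_step = 64, epochs = 12, hidden = 16,
                     lr = 1e-2, seed = 3)
  m1 <- train_mil(slides, tc)
  expect_lt(m1$loss_history[length(m1$loss_history)], m1$loss_history[1])
  m2 <- train_mil(slides, tc)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)

  onlymut <- Filter(function(s) s$label == "mutant", slides)
  expect_error(train_mil(onlymut, tc), "both classes")
})

test_that("trained attention prefers ground-truth signal tiles", {
  slides <- slide_fixture()
  tc <- train_config(patches_per_step = 64, epochs = 12, hidden = 16,
                     lr = 1e-2, seed = 3)
  model <- train_mil(slides, tc)
  w_sig <- c(); w_non <- c()
  for (s in slides) {
    if (s$label != "mutant") next
    pr <- predict_slide(s$features, model)
    sig <- paste(s$grid$tiles$x, s$grid$tiles$y) %in%
      paste(s$signal_tiles$x, s$signal_tiles$y)
    w_sig <- c(w_sig, pr$attention_weights[sig])
    w_non <- c(w_non, pr$attention_weights[!sig])
  }
  expect_gt(mean(w_sig), mean(w_non))
})

test_that("model checkpoints round-trip through the text format", {
  slides <- slide_fixture()
  tc <- train_config(patches_per_step = 64, epochs = 6, hidden = 8,
                     lr = 1e-2, seed = 4)
  model <- train_mil(slides, tc)
  dir <- tempfile("ckpt_")
  save_mil_model(model, dir)
  back <- load_mil_model(dir)
  F <- slides[[1]]$features
  expect_equal(predict_slide(F, back)$probability,
               predict_slide(F, model)$probability, tolerance = 1e-12)
  expect_equal(back$loss_history, model$loss_history, tolerance = 1e-12)
})

test_that("half-precision flag only perturbs features at 2^-10 scale", {
  slides <- slide_fixture()
  tc <- train_config(patches_per_step = 64, epochs = 4, hidden = 8,
                     lr = 1e-2, seed = 5, half_precision = TRUE)
  m <- train_mil(slides, tc)
  expect_true(all(is.finite(m$loss_history)))
})
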