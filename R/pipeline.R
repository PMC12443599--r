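#' Replay a timestamped cohort into turnaround records
#'
#' Computes per-sample, per-test turnaround times (hours from molecular
#' accession to result availability). Accepts either the wide cohort
#' format (ISO-8601 columns `ts_accession`, `ts_ai_result`,
#' `ts_rapid_result`, `ts_ngs_result`, and one or more `ts_scan*`
#' columns) or a long event table with columns `sample_id`, `event`,
#' `time`. When a sample has several slide-scan events the earliest is
#' used; event order in the input is irrelevant (times are compared, not
#' positions). A result preceding its accession raises an error.
#'
#' @param cohort wide cohort data.frame or long event data.frame.
#' @return data.frame of turnaround records: `sample_id`, `test_name`
#'   ("ai"/"rapid"/"ngs"), `delta_t` (hours), plus `ts_scan_used` per
#'   sample attached as an attribute.
#' @export
replay_cohort <- function(cohort) {
  if (all(c("sample_id", "event", "time") %in% names(cohort))) {
    ev <- cohort
    ev$time <- if (inherits(ev$time, "POSIXct")) ev$time else parse_iso8601(ev$time)
  } else {
    stopifnot("ts_accession" %in% names(cohort))
    scan_cols <- grep("^ts_scan", names(cohort), value = TRUE)
    res_cols <- c(ai_result = "ts_ai_result", rapid_result = "ts_rapid_result",
                  ngs_result = "ts_ngs_result")
    res_cols <- res_cols[res_cols %in% names(cohort)]
    ev <- do.call(rbind, c(
      list(data.frame(sample_id = cohort$sample_id, event = "molecular_accession",
                      time = parse_iso8601(cohort$ts_accession))),
      lapply(scan_cols, function(cl)
        data.frame(sample_id = cohort$sample_id, event = "slide_scan",
                   time = parse_iso8601(cohort[[cl]]))),
      lapply(names(res_cols), function(nm)
        data.frame(sample_id = cohort$sample_id, event = nm,
                   time = parse_iso8601(cohort[[res_cols[nm]]])))))
  }
  ids <- unique(ev$sample_id)
  recs <- lapply(ids, function(id) {
    e <- ev[ev$sample_id == id, , drop = FALSE]
    acc <- e$time[e$event == "molecular_accession"]
    if (length(acc) == 0L) stop("sample ", id, " lacks a molecular-accession event")
    acc <- min(acc)
    tests <- c(ai_result = "ai", rapid_result = "rapid", ngs_result = "ngs")
    out <- lapply(names(tests), function(evname) {
      tt <- e$time[e$event == evname]
      if (length(tt) == 0L) return(NULL)
      res <- min(tt)  # earliest result (first scanned slide drives the first call)
      dt <- as.numeric(difftime(res, acc, units = "hours"))
      if (dt < 0) stop("result precedes accession for sample ", id)
      data.frame(sample_id = id, test_name = tests[[evname]], delta_t = dt)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic pipeline
#'
#' Orchestrates every stage on synthetic data: slide simulation, tissue
#' detection and tiling, MIL training and inference, attention-map
#' rendering for one slide, cohort simulation, threshold-grid
#' calibration with noninferiority selection, deployment evaluation on
#' an independent cohort, and a turnaround replay. All outputs (CSV,
#' PNG, JSON) land in `out_dir` together with a JSON manifest of inputs,
#' seeds and output hashes; metric outputs are byte-reproducible for a
#' fixed config.
#'
#' @param config named list or path to a YAML file. Recognized keys
#'   (all optional): `seed`, `out_dir`, `n_train_slides`,
#'   `n_test_slides`, `slide_px`, `signal_fraction`, `epochs`, `hidden`,
#'   `lr`, `patches_per_step`, `cohort_n`, `target_auc`, `grid_step`,
#'   `n_boot`, `k_points`.
#' @return The output directory, invisibly; the manifest lists every
#'   artifact written.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  bad <- setdiff(names(config),
                 c("seed", "out_dir", "n_train_slides", "n_test_slides",
                   "slide_px", "signal_fraction", "epochs", "hidden", "lr",
                   "patches_per_step", "cohort_n", "target_auc", "grid_step",
                   "n_boot", "k_points"))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- list(seed = 1L, out_dir = tempfile("milscreen_run_"),
              n_train_slides = 16L, n_test_slides = 8L, slide_px = 672L,
              signal_fraction = 0.3, epochs = 15L, hidden = 32L, lr = 1e-2,
              patches_per_step = 256L, cohort_n = 2000L, target_auc = 0.89,
              grid_step = 0.002, n_boot = 200L, k_points = 3L)
  cfg[names(config)] <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  put <- function(f) { artifacts <<- c(artifacts, f); f }

  # --- slides: simulate, tile, train, infer -------------------------------
  n_sl <- cfg$n_train_slides + cfg$n_test_slides
  labels <- rep(c("mutant", "wild-type"), length.out = n_sl)
  slides <- lapply(seq_len(n_sl), function(i) {
    sp <- slide_spec(cfg$slide_px, cfg$slide_px, mpp = 0.5,
                     tissue_fraction = 0.6,
                     signal_fraction = if (labels[i] == "mutant") cfg$signal_fraction else 0,
                     label = labels[i])
    sl <- generate_slide(sp, seed = split_seed(cfg$seed, paste0("slide", i)))
    mask <- detect_tissue(sl$image, mpp = 0.5)
    grid <- grid_tiles(mask, slide_id = sprintf("SL%03d", i))
    list(image = sl$image, grid = grid, label = labels[i], slide = sl)
  })
  tc <- train_config(patches_per_step = cfg$patches_per_step,
                     epochs = cfg$epochs, hidden = cfg$hidden, lr = cfg$lr,
                     seed = split_seed(cfg$seed, "train"))
  train_idx <- seq_len(cfg$n_train_slides)
  model <- train_mil(slides[train_idx], tc)
  save_mil_model(model, put(file.path(cfg$out_dir, "model")))

  preds <- vapply(slides, function(s) {
    predict_slide(encode_patches(s$image, s$grid, tc$encoder), model,
                  s$grid$slide_id)$probability
  }, numeric(1))
  slide_df <- data.frame(slide_id = sprintf("SL%03d", seq_len(n_sl)),
                         label = labels, probability = preds,
                         split = ifelse(seq_len(n_sl) %in% train_idx,
                                        "train", "test"))
  write.csv(slide_df, put(file.path(cfg$out_dir, "slide_predictions.csv")),
            row.names = FALSE)
  test_df <- slide_df[slide_df$split == "test", ]
  slide_auc <- roc_auc(test_df$probability, test_df$label == "mutant")

  # --- attention introspection on the first mutant test slide -------------
  at_i <- which(labels == "mutant" & !(seq_len(n_sl) %in% train_idx))[1]
  s <- slides[[at_i]]
  pred <- predict_slide(encode_patches(s$image, s$grid, tc$encoder), model)
  amap <- zscore_attention(pred$attention_weights, s$grid)
  region <- high_attention_mask(amap)
  box <- densest_region(region, window = round(cfg$slide_px / 10),
                        height = cfg$slide_px, width = cfg$slide_px)
  png::writePNG(render_overlay(s$image, amap, "full"),
                put(file.path(cfg$out_dir, "attention_full.png")))
  png::writePNG(render_overlay(s$image, region, "inverted"),
                put(file.path(cfg$out_dir, "attention_inverted.png")))
  write_region_json(region, box, put(file.path(cfg$out_dir, "attention_region.json")))

  # --- cohorts: calibrate and deploy --------------------------------------
  ref <- idylla_benchmark()
  prev <- implied_prevalence(ref)
  cal <- simulate_cohort(score_model_params(cfg$cohort_n, prev, cfg$target_auc,
                                            seed = split_seed(cfg$seed, "cal")))
  dep <- simulate_cohort(score_model_params(cfg$cohort_n, prev, cfg$target_auc,
                                            seed = split_seed(cfg$seed, "dep")))
  write_cohort(cal, put(file.path(cfg$out_dir, "cohort_calibration.csv")))
  write_cohort(dep, put(file.path(cfg$out_dir, "cohort_deployment.csv")))
  # benchmark = rapid test's empirical performance on the calibration
  # cohort; the (0, 1) corner then always lies in the noninferiority region
  ycal <- cal$ngs_label == "mutant"
  bench <- idylla_benchmark(
    sensitivity = mean(cal$rapid_call[ycal] == "positive"),
    specificity = mean(cal$rapid_call[!ycal] == "negative"),
    ppv = mean(ycal[cal$rapid_call == "positive"]),
    npv = mean(!ycal[cal$rapid_call == "negative"]),
    source = "rapid test, calibration cohort")
  surfaces <- grid_evaluate(cal, step = cfg$grid_step)
  write_surfaces(surfaces, put(file.path(cfg$out_dir, "surfaces.csv")))
  region_ni <- noninferiority_region(surfaces, bench)
  points <- select_operating_points(surfaces, region_ni, bench, k = cfg$k_points)
  reports <- evaluate_deployment(dep, points, n_boot = cfg$n_boot,
                                 seed = split_seed(cfg$seed, "deploy"),
                                 cohort_label = "deployment",
                                 selection_label = "calibration")
  write_deployment_report(reports, put(file.path(cfg$out_dir, "deployment_report.json")))
  plot_triage_surfaces(surfaces, bench, put(file.path(cfg$out_dir, "reduction_heatmap.png")))

  # --- turnaround replay ---------------------------------------------------
  tat <- tat_summary(replay_cohort(dep))
  write.csv(tat, put(file.path(cfg$out_dir, "tat_summary.csv")), row.names = FALSE)

  metrics <- list(
    held_out_slide_auc = slide_auc,
    cohort_auc = roc_auc(cal$score, cal$ngs_label),
    implied_prevalence = prev,
    operating_points = lapply(points, function(p)
      list(t_neg = p$t_neg, t_pos = p$t_pos, reduction = p$reduction)),
    tat_median_hours = setNames(as.list(tat$median_hours), tat$test_name))
  jsonlite::write_json(metrics, put(file.path(cfg$out_dir, "metrics.json")),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    version = as.character(utils::packageVersion("milscreen")),
    generated_at = format_iso8601(Sys.time()),  # wall-clock, informational
    artifacts = lapply(basename(artifacts), function(b) {
      f <- file.path(cfg$out_dir, b)
      list(file = b, md5 = if (file.exists(f) && !dir.exists(f))
        unname(tools::md5sum(f)) else NA)
    }))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cfg$out_dir)
}
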