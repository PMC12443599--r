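#' Parameters for the binormal score-cohort simulator
#'
#' The simulated classifier score follows a probit-transformed binormal
#' model: a latent z is drawn from N(-mu/2, 1) for wild-type samples and
#' N(+mu/2, 1) for mutants, and the reported score is Phi(z). Under this
#' model the population AUC is Phi(mu / sqrt(2)), so a target AUC can be
#' hit exactly by [auc_to_separation()].
#'
#' @param n_samples number of samples (>= 0).
#' @param prevalence mutation prevalence, strictly in (0, 1). The default
#'   0.39 is the prevalence implied by jointly inverting the historical
#'   rapid-test sensitivity/specificity/PPV (see [implied_prevalence()]);
#'   it is a derived quantity, not a reported one.
#' @param target_auc population AUC of the score, strictly in (0.5, 1).
#' @param seed integer seed; fans out to per-component streams.
#' @return An object of class `score_model_params`.
#' @export
score_model_params <- function(n_samples, prevalence = 0.39,
                               target_auc = 0.89, seed = 1L) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 0)
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must be strictly inside (0, 1)")
  if (!(target_auc > 0.5 && target_auc < 1))
    stop("target_auc must be strictly inside (0.5, 1)")
  structure(list(n_samples = as.integer(n_samples), prevalence = prevalence,
                 target_auc = target_auc, seed = as.integer(seed)),
            class = "score_model_params")
}

#' Parameters of the simulated rapid test
#'
#' @param sensitivity probability a mutant sample is called positive.
#' @param specificity probability a wild-type sample is called negative.
#' @param seed integer seed.
#' @return An object of class `rapid_test_params`.
#' @export
rapid_test_params <- function(sensitivity, specificity, seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 seed = as.integer(seed)), class = "rapid_test_params")
}

#' Binormal separation achieving a target AUC
#'
#' Inverts AUC = Phi(mu / sqrt(2)) for the class separation mu of two
#' unit-variance normal latents. Monotone in the target AUC;
#' `auc_to_separation(0.5)` is 0 (chance level, no separation).
#'
#' @param target_auc AUC in `[0.5, 1)`.
#' @return The separation mu (non-negative real).
#' @export
#' @examples
#' auc_to_separation(0.896) # ~1.781
auc_to_separation <- function(target_auc) {
  if (any(!is.finite(target_auc)) || any(target_auc < 0.5) || any(target_auc >= 1))
    stop("target_auc must lie in [0.5, 1)")
  sqrt(2) * qnorm(target_auc)
}

#' Variant subtypes recognized by the cohort simulator
#' @export
egfr_variant_levels <- function() {
  c("exon19del", "L858R", "exon20ins", "T790M", "other")
}

#' Simulate a score--label cohort
#'
#' Draws NGS labels Bernoulli(prevalence), binormal latents separated by
#' [auc_to_separation()] of the target AUC, probit scores in (0, 1),
#' rapid-test calls at the configured operating characteristics, variant
#' subtypes for mutants, sample sites, per-sample tile counts, and event
#' timestamps (molecular accession, slide scan, and ai/rapid/ngs results
#' whose median turnaround times default to 0.74, 48.78 and 435.26 hours).
#'
#' @param params a [score_model_params()] object.
#' @param rapid a [rapid_test_params()] object or NULL to skip rapid calls.
#' @param variant_probs named probabilities over [egfr_variant_levels()]
#'   used to assign subtypes to mutants; default uniform.
#' @param metastatic_fraction fraction of samples from metastatic sites.
#' @param tat_medians named vector of median turnaround hours for the ai,
#'   rapid and ngs results.
#' @return A data.frame of class `cohort` with columns sample_id, score,
#'   ngs_label, rapid_call, site, variant, tile_count and ISO-8601
#'   timestamp columns `ts_accession`, `ts_scan`, `ts_ai_result`,
#'   `ts_rapid_result`, `ts_ngs_result`.
#' @export
simulate_cohort <- function(params,
                            rapid = rapid_test_params(0.918, 0.993,
                                                      seed = params$seed),
                            variant_probs = NULL,
                            metastatic_fraction = 0.4,
                            tat_medians = c(ai = 0.74, rapid = 48.78,
                                            ngs = 435.26)) {
  stopifnot(inherits(params, "score_model_params"))
  n <- params$n_samples
  if (n < 0) stop("n_samples must be non-negative")
  lev <- egfr_variant_levels()
  if (is.null(variant_probs)) {
    variant_probs <- setNames(rep(1 / length(lev), length(lev)), lev)
  }
  stopifnot(setequal(names(variant_probs), lev), all(variant_probs >= 0))
  variant_probs <- variant_probs[lev] / sum(variant_probs)

  mu <- auc_to_separation(params$target_auc)
  y <- with_seed(split_seed(params$seed, "labels"),
                 rbinom(n, 1L, params$prevalence))
  z <- with_seed(split_seed(params$seed, "scores"),
                 rnorm(n, mean = ifelse(y == 1L, mu / 2, -mu / 2), sd = 1))
  eps <- .Machine$double.eps
  score <- pmin(pmax(pnorm(z), eps), 1 - eps)
  ngs_label <- ifelse(y == 1L, "mutant", "wild-type")

  rapid_call <- rep("not_performed", n)
  if (!is.null(rapid) && n > 0) {
    rapid_call <- simulate_rapid_test(ngs_label, rapid)
  }

  variant <- rep("none", n)
  if (any(y == 1L)) {
    variant[y == 1L] <- with_seed(
      split_seed(params$seed, "variants"),
      sample(lev, sum(y == 1L), replace = TRUE, prob = variant_probs))
  }

  site <- character(n)
  if (n > 0) {
    locations <- c("lymph_node", "brain", "bone", "liver", "pleura")
    site <- with_seed(split_seed(params$seed, "sites"), {
      met <- runif(n) < metastatic_fraction
      ifelse(met, paste0("metastatic:", sample(locations, n, replace = TRUE)),
             "primary")
    })
  }

  tile_count <- with_seed(split_seed(params$seed, "tiles"),
                          1L + rpois(n, lambda = 400))

  origin <- as.POSIXct("2024-05-01 08:00:00", tz = "UTC")
  ts <- with_seed(split_seed(params$seed, "timestamps"), {
    accession <- origin + runif(n, 0, 120 * 86400)
    scan <- accession - runif(n, 1, 72) * 3600  # slides scanned before accession
    list(accession = accession, scan = scan,
         ai = accession + rlnorm(n, log(tat_medians[["ai"]]), 0.3) * 3600,
         rapid = accession + rlnorm(n, log(tat_medians[["rapid"]]), 0.3) * 3600,
         ngs = accession + rlnorm(n, log(tat_medians[["ngs"]]), 0.2) * 3600)
  })

  out <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    score = score,
    ngs_label = ngs_label,
    rapid_call = rapid_call,
    site = site,
    variant = variant,
    tile_count = tile_count,
    ts_accession = format_iso8601(ts$accession),
    ts_scan = format_iso8601(ts$scan),
    ts_ai_result = format_iso8601(ts$ai),
    ts_rapid_result = format_iso8601(ts$rapid),
    ts_ngs_result = format_iso8601(ts$ngs),
    stringsAsFactors = FALSE
  )
  if (n == 0L) out <- out[0, , drop = FALSE]
  class(out) <- c("cohort", "data.frame")
  out
}

#' Simulate rapid-test calls for a vector of NGS labels
#'
#' Mutant samples are called positive with probability `sensitivity`;
#' wild-type samples are called negative with probability `specificity`;
#' calls are independent across samples.
#'
#' @param labels character vector with values "mutant" / "wild-type".
#' @param params a [rapid_test_params()] object.
#' @return Character vector of "positive" / "negative" calls.
#' @export
simulate_rapid_test <- function(labels, params) {
  stopifnot(inherits(params, "rapid_test_params"))
  if (length(labels) == 0L) stop("labels must be non-empty")
  if (!all(labels %in% c("mutant", "wild-type")))
    stop("labels must be 'mutant' or 'wild-type'")
  with_seed(split_seed(params$seed, "rapid_test"), {
    u <- runif(length(labels))
    ifelse(labels == "mutant",
           ifelse(u < params$sensitivity, "positive", "negative"),
           ifelse(u < params$specificity, "negative", "positive"))
  })
}

#' Write / read a cohort table as CSV
#'
#' Round-trips all cohort columns, including ISO-8601 timestamps.
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character"))
  class(out) <- c("cohort", "data.frame")
  out
}
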