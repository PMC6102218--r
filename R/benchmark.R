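#' Network and sampling settings for the synthetic benchmark
#'
#' The reduced-geometry benchmark trains the standard architecture (input
#' sized to the 401-px feature) with a per-class quota of 2000 and at most
#' 120 epochs; all other settings are the package defaults.
#'
#' @param seed Master seed.
#' @return List with `network` ([network_config()]) and `budget`
#'   ([training_budget()]).
#' @export
benchmark_settings <- function(seed = 1L) {
  list(network = network_config(max_epochs = 120, seed = derive_seed(seed, 41)),
       budget = training_budget(per_class_quota = 2000))
}

#' End-to-end synthetic benchmark
#'
#' Builds a 12-eye synthetic cohort at the reduced benchmark geometry
#' (64 x 128 x 512, [benchmark_scene_config()]), extracts the labeled feature
#' pool, and runs 10-iteration Monte Carlo cross-validation. Also measures
#' RPE localization accuracy against the synthetic ground truth: the maximum
#' absolute error on a noiseless render and the median absolute error under
#' default speckle, both over all labeled A-scans of one eye.
#'
#' @param seed Master seed for cohort generation, splitting and training.
#' @param n_eyes Cohort size (default 12).
#' @param n_iterations Monte Carlo iterations (default 10).
#' @return List with `report` (the [monte_carlo_cv()] result), `accuracy`
#'   (per-class test accuracy mean/SD, percent), `rpe_noiseless_max_px`,
#'   `rpe_speckle_median_px`, `dataset_n`, and `class_counts`.
#' @export
synthetic_benchmark <- function(seed = 1L, n_eyes = 12, n_iterations = 10) {
  template <- benchmark_scene_config(seed = seed)
  cohort <- make_cohort(n_eyes, template, seed = seed)
  fs <- build_dataset(lapply(cohort, `[[`, "volume"),
                      lapply(cohort, `[[`, "label_map"))
  st <- benchmark_settings(seed)
  report <- monte_carlo_cv(fs, split_spec(seed = derive_seed(seed, 7)),
                           st$network, st$budget, n_iterations = n_iterations)
  rpe <- benchmark_rpe_error(template, seed)
  list(report = report,
       accuracy = cv_class_accuracy(report, "test"),
       rpe_noiseless_max_px = rpe$noiseless_max,
       rpe_speckle_median_px = rpe$speckle_median,
       dataset_n = nrow(fs$features),
       class_counts = table(fs$labels))
}

# RPE localization error against ground truth on one synthetic eye, with and
# without speckle. Errors are taken over labeled (i.e. all) A-scan columns.
benchmark_rpe_error <- function(template = benchmark_scene_config(), seed = 1L) {
  cfg <- template
  cfg$seed <- derive_seed(seed, 13)
  drawn <- with_seed(cfg$seed, list(
    ped = random_bumps(2, cfg$n_bscans, cfg$n_ascans,
                       c(0.05, 0.12) * cfg$n_bscans, c(0.05, 0.12) * cfg$n_ascans,
                       c(8, 28)),
    rd = random_bumps(1, cfg$n_bscans, cfg$n_ascans,
                      c(0.10, 0.22) * cfg$n_bscans, c(0.10, 0.22) * cfg$n_ascans,
                      c(10, 40))))
  cfg$ped_bumps <- drawn$ped
  cfg$rd_bumps <- drawn$rd
  scene <- make_scene(cfg)
  fpar <- feature_params()
  noiseless_cfg <- cfg
  noiseless_cfg$speckle_shape <- 0
  err <- function(config) {
    vol <- render_volume(scene, config)
    pp <- preprocess_volume(vol)
    abs(locate_rpe_volume(pp, fpar) - scene$rpe_depth_true)
  }
  list(noiseless_max = max(err(noiseless_cfg)),
       speckle_median = stats::median(err(cfg)))
}

#' Whole-eye generalization on disjoint synthetic eyes
#'
#' Trains a single model on one synthetic cohort and evaluates it, with the
#' frozen normalizer, on a disjoint cohort of unseen eyes drawn from an
#' independent seed stream — the patient-level counterpart of the A-scan-level
#' cross-validation.
#'
#' @param seed Master seed.
#' @param n_train_eyes,n_unseen_eyes Cohort sizes (defaults 6 and 3).
#' @return List with `class_accuracy` (named percent per class on the unseen
#'   eyes), `confusion`, `metrics`, and `n_unseen_ascans`.
#' @export
unseen_generalization <- function(seed = 1L, n_train_eyes = 6, n_unseen_eyes = 3) {
  template <- benchmark_scene_config(seed = seed)
  train_cohort <- make_cohort(n_train_eyes, template, seed = derive_seed(seed, 1001))
  fitted <- train_cohort_model(train_cohort, seed = seed)
  unseen <- make_cohort(n_unseen_eyes, template, seed = derive_seed(seed, 2002))
  for (i in seq_along(unseen)) {
    id <- sprintf("unseen%03d", i)
    unseen[[i]]$volume$eye_id <- id
    unseen[[i]]$label_map$eye_id <- id
  }
  res <- evaluate_unseen(fitted$model, fitted$norm,
                         lapply(unseen, `[[`, "volume"),
                         lapply(unseen, `[[`, "label_map"),
                         training_eye_ids = fitted$eye_ids)
  acc <- stats::setNames(diag(res$confusion$percent), signature_classes())
  list(class_accuracy = acc, confusion = res$confusion, metrics = res$metrics,
       n_unseen_ascans = sum(res$confusion$counts))
}

#' Train one model on a full synthetic cohort
#'
#' Balanced-samples the whole labeled pool of the cohort, fits the
#' normalizer on that sample, and trains a single network with the benchmark
#' settings; used for patient-level (whole-eye) generalization checks via
#' [evaluate_unseen()].
#'
#' @param cohort A [make_cohort()] result.
#' @param seed Training seed.
#' @return List with `model`, `norm`, `eye_ids`.
#' @export
train_cohort_model <- function(cohort, seed = 1L) {
  fs <- build_dataset(lapply(cohort, `[[`, "volume"),
                      lapply(cohort, `[[`, "label_map"))
  st <- benchmark_settings(seed)
  bal <- balanced_sample(fs, st$budget, seed = derive_seed(seed, 3))
  norm <- fit_normalizer(bal$features)
  x <- apply_normalizer(norm, bal$features)
  model <- train_mlp(init_network(st$network), x, one_hot(bal$labels))
  list(model = model, norm = norm,
       eye_ids = vapply(cohort, function(e) e$volume$eye_id, character(1)))
}
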