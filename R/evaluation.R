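#' Random split specification
#'
#' The labeled A-scan pool is split 80:20 into a training share and a test
#' set, with a validation set carved from the training share for early
#' stopping: 64/16/20 by default.
#'
#' @param fractions Named or ordered fractions `c(train, validation, test)`,
#'   summing to 1.
#' @param seed Split seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.64, validation = 0.16, test = 0.20),
                       seed = 1L) {
  if (length(fractions) != 3 || any(fractions < 0) || any(fractions > 1))
    abort_validation("fractions must be three values in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9)
    abort_validation("fractions must sum to 1 (got %.12f)", sum(fractions))
  names(fractions) <- c("train", "validation", "test")
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

# Largest-remainder apportionment of n samples to the three fractions.
split_sizes <- function(n, fractions) {
  exact <- fractions * n
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a dataset into train/validation/test
#'
#' Disjoint, exhaustive partition of the sample rows; sizes follow the
#' fractions under largest-remainder rounding; the permutation is seeded.
#'
#' @param dataset A [labeled_feature_set()].
#' @param spec A [split_spec()].
#' @return Named list of three [labeled_feature_set()] objects (`train`,
#'   `validation`, `test`), plus `indices` giving the original rows.
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(dataset, "labeled_feature_set"), inherits(spec, "split_spec"))
  n <- nrow(dataset$features)
  if (n < 1) abort_validation("cannot split an empty dataset")
  sizes <- split_sizes(n, spec$fractions)
  perm <- with_seed(spec$seed, sample.int(n))
  idx <- list(train = perm[seq_len(sizes[1])],
              validation = perm[sizes[1] + seq_len(sizes[2])],
              test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  list(train = subset_feature_set(dataset, idx$train),
       validation = subset_feature_set(dataset, idx$validation),
       test = subset_feature_set(dataset, idx$test),
       indices = idx)
}

#' Confusion matrix summary
#'
#' Counts with rows = actual class and columns = predicted class, in the
#' fixed order PED, RD, NEITHER, plus the row-normalized percentage matrix
#' (each non-empty row sums to 100). Rows with no actual samples are all-zero
#' and flagged in `empty_rows`.
#'
#' @param actual,predicted Vectors (factor or character) over
#'   [signature_classes()], equal length.
#' @return An object of class `confusion_summary` with fields `counts`,
#'   `percent`, `empty_rows`.
#' @export
confusion_summary <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1)
    abort_validation("actual and predicted must be non-empty and equal length")
  fa <- factor(as.character(actual), levels = signature_classes())
  fp <- factor(as.character(predicted), levels = signature_classes())
  if (anyNA(fa) || anyNA(fp))
    abort_validation("labels must be PED, RD, or NEITHER")
  counts <- unclass(table(fa, fp))
  dimnames(counts) <- list(actual = signature_classes(),
                           predicted = signature_classes())
  rs <- rowSums(counts)
  percent <- counts * 0
  nz <- rs > 0
  percent[nz, ] <- 100 * counts[nz, , drop = FALSE] / rs[nz]
  structure(list(counts = counts, percent = percent, empty_rows = !nz),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, digits = 2, ...) {
  cat("<confusion_summary> row-normalized percent (actual x predicted):\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' One-vs-rest sensitivity and specificity
#'
#' For each class `k`: sensitivity is the diagonal count over the actual-`k`
#' row total; specificity is the share of actual-non-`k` samples not
#' predicted as `k`. Zero denominators yield `NA` rather than errors.
#'
#' @param counts 3 x 3 non-negative integer matrix (rows = actual), e.g.
#'   `confusion_summary(...)$counts`.
#' @return Data frame with columns `class`, `sensitivity`, `specificity`.
#' @export
sensitivity_specificity <- function(counts) {
  if (inherits(counts, "confusion_summary")) counts <- counts$counts
  if (!is.matrix(counts) || !identical(dim(counts), c(3L, 3L)))
    abort_validation("counts must be a 3 x 3 matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    abort_validation("counts must be non-negative integers")
  out <- data.frame(class = signature_classes(),
                    sensitivity = NA_real_, specificity = NA_real_)
  for (k in 1:3) {
    pos <- sum(counts[k, ])
    if (pos > 0) out$sensitivity[k] <- counts[k, k] / pos
    neg <- sum(counts[-k, ])
    if (neg > 0) out$specificity[k] <- sum(counts[-k, -k]) / neg
  }
  out
}

cv_aggregate <- function(mats) {
  arr <- simplify2array(mats)
  list(mean = apply(arr, c(1, 2), mean), sd = apply(arr, c(1, 2), stats::sd))
}

#' Monte Carlo cross-validation
#'
#' Repeats, for `n_iterations` independently seeded iterations: a fresh
#' random train/validation/test split of the labeled pool, class-balanced
#' subsampling of the training portion, normalizer fitting on that training
#' sample only, network training, and evaluation on the (balanced) training
#' sample and on the untouched test split. Reports the per-cell mean and
#' standard deviation of the row-normalized percentage confusion matrices and
#' of the per-class sensitivity/specificity; the SDs across iterations serve
#' as the generalization metric.
#'
#' @param dataset A [labeled_feature_set()] containing all three classes.
#' @param spec A [split_spec()]; its seed is the master seed.
#' @param config A [network_config()].
#' @param budget A [training_budget()].
#' @param n_iterations Number of Monte Carlo iterations (default 10).
#' @return An object of class `evaluation_report`: lists `train` and `test`,
#'   each with `percent_mean`, `percent_sd`, `counts` (last iteration);
#'   `metrics_test`/`metrics_train` with per-class mean/SD sensitivity and
#'   specificity; `per_iteration` details.
#' @export
monte_carlo_cv <- function(dataset, spec = split_spec(),
                           config = network_config(),
                           budget = training_budget(),
                           n_iterations = 10) {
  stopifnot(inherits(dataset, "labeled_feature_set"))
  if (!is_count(n_iterations)) abort_validation("n_iterations must be >= 1")
  if (ncol(dataset$features) != config$layer_sizes[1])
    abort_validation("feature length (%d) does not match the network input (%d)",
                     ncol(dataset$features), config$layer_sizes[1])
  iter <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    it_seed <- derive_seed(spec$seed, it)
    parts <- split_dataset(dataset, split_spec(spec$fractions, seed = it_seed))
    bal <- balanced_sample(parts$train, budget, seed = derive_seed(it_seed, 1))
    norm <- fit_normalizer(bal$features)
    xtr <- apply_normalizer(norm, bal$features)
    ytr <- one_hot(bal$labels)
    xval <- apply_normalizer(norm, parts$validation$features)
    yval <- one_hot(parts$validation$labels)
    cfg <- config
    cfg$seed <- derive_seed(it_seed, 2)
    model <- train_mlp(init_network(cfg), xtr, ytr, xval, yval)
    pred_tr <- predict_label(model, xtr)
    xte <- apply_normalizer(norm, parts$test$features)
    pred_te <- predict_label(model, xte)
    cm_tr <- confusion_summary(bal$labels, pred_tr)
    cm_te <- confusion_summary(parts$test$labels, pred_te)
    iter[[it]] <- list(train = cm_tr, test = cm_te,
                       metrics_train = sensitivity_specificity(cm_tr),
                       metrics_test = sensitivity_specificity(cm_te),
                       epochs = nrow(model$history))
  }
  agg_metrics <- function(key) {
    arr <- simplify2array(lapply(iter, function(i)
      as.matrix(i[[key]][, c("sensitivity", "specificity")])))
    data.frame(class = signature_classes(),
               sensitivity_mean = apply(arr[, 1, , drop = FALSE], 1, mean),
               sensitivity_sd = apply(arr[, 1, , drop = FALSE], 1, stats::sd),
               specificity_mean = apply(arr[, 2, , drop = FALSE], 1, mean),
               specificity_sd = apply(arr[, 2, , drop = FALSE], 1, stats::sd))
  }
  tr <- cv_aggregate(lapply(iter, function(i) i$train$percent))
  te <- cv_aggregate(lapply(iter, function(i) i$test$percent))
  structure(
    list(train = list(percent_mean = tr$mean, percent_sd = tr$sd),
         test = list(percent_mean = te$mean, percent_sd = te$sd),
         metrics_train = agg_metrics("metrics_train"),
         metrics_test = agg_metrics("metrics_test"),
         per_iteration = iter,
         n_iterations = n_iterations),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(m, s) matrix(sprintf("%.2f +/- %.2f", m, s), 3, 3,
                               dimnames = dimnames(m))
  cat(sprintf("<evaluation_report> %d Monte Carlo iteration(s)\n", x$n_iterations))
  cat("Training confusion (percent, actual x predicted):\n")
  print(fmt(x$train$percent_mean, x$train$percent_sd), quote = FALSE)
  cat("Testing confusion (percent, actual x predicted):\n")
  print(fmt(x$test$percent_mean, x$test$percent_sd), quote = FALSE)
  invisible(x)
}

#' Per-class accuracy from a cross-validation report
#'
#' The per-class accuracy is the diagonal of the row-normalized confusion
#' matrix (the share of each actual class predicted correctly).
#'
#' @param report An [monte_carlo_cv()] `evaluation_report`.
#' @param split `"test"` or `"train"`.
#' @return Data frame with `class`, `accuracy_mean`, `accuracy_sd` (percent).
#' @export
cv_class_accuracy <- function(report, split = c("test", "train")) {
  stopifnot(inherits(report, "evaluation_report"))
  split <- match.arg(split)
  data.frame(class = signature_classes(),
             accuracy_mean = diag(report[[split]]$percent_mean),
             accuracy_sd = diag(report[[split]]$percent_sd),
             row.names = NULL)
}

#' Evaluate a frozen model on held-out eyes
#'
#' Applies the full pipeline (preprocess, RPE location, crop, the *frozen*
#' normalizer, the trained model) to eyes disjoint from training, and scores
#' only labeled A-scans (UNLABELED excluded). Any eye whose id appears in
#' `training_eye_ids` is rejected.
#'
#' @param model Trained `mlp_model`.
#' @param norm The training [fit_normalizer()] result.
#' @param volumes,label_maps Held-out eyes.
#' @param training_eye_ids Character vector of eye ids seen in training.
#' @param preprocess,params Pipeline parameters.
#' @return List with `confusion` ([confusion_summary()]), `metrics`
#'   (sensitivity/specificity), and `predictions` (per-A-scan data frame with
#'   probabilities, predicted and actual class).
#' @export
evaluate_unseen <- function(model, norm, volumes, label_maps,
                            training_eye_ids = character(0),
                            preprocess = preprocess_params(),
                            params = feature_params()) {
  ids <- vapply(volumes, function(v) v$eye_id, character(1))
  clash <- intersect(ids, training_eye_ids)
  if (length(clash))
    abort_validation("unseen eyes overlap the training set: %s",
                     paste(clash, collapse = ", "))
  fs <- build_dataset(volumes, label_maps, preprocess, params)
  if (nrow(fs$features) == 0) abort_validation("held-out eyes contain no labeled A-scans")
  xp <- apply_normalizer(norm, fs$features)
  proba <- predict_proba(model, xp)
  pred <- factor(signature_classes()[max.col(proba, ties.method = "first")],
                 levels = signature_classes())
  cm <- confusion_summary(fs$labels, pred)
  preds <- data.frame(fs$positions,
                      p_PED = proba[, 1], p_RD = proba[, 2], p_NEITHER = proba[, 3],
                      predicted = as.character(pred),
                      actual = as.character(fs$labels))
  list(confusion = cm, metrics = sensitivity_specificity(cm), predictions = preds)
}

#' Write an evaluation report as JSON and CSV tables
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_evaluation_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n_iterations = report$n_iterations,
         train = lapply(report$train, function(m) as.data.frame(m)),
         test = lapply(report$test, function(m) as.data.frame(m)),
         metrics_test = report$metrics_test,
         metrics_train = report$metrics_train),
    file.path(dir, "evaluation_report.json"), digits = NA)
  for (split in c("train", "test")) {
    utils::write.csv(report[[split]]$percent_mean,
                     file.path(dir, sprintf("confusion_%s_mean.csv", split)))
    utils::write.csv(report[[split]]$percent_sd,
                     file.path(dir, sprintf("confusion_%s_sd.csv", split)))
  }
  utils::write.csv(report$metrics_test, file.path(dir, "metrics_test.csv"),
                   row.names = FALSE)
  invisible(dir)
}
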