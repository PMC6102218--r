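test_that("splits are exhaustive, disjoint, exactly sized, and seeded", {
  fs <- counted_feature_set(40, 30, 30, seed = 1)
  sp <- split_spec(seed = 13)
  parts <- split_dataset(fs, sp)
  expect_identical(vapply(parts[1:3], function(p) nrow(p$features), integer(1)),
                   c(train = 64L, validation = 16L, test = 20L))
  all_idx <- sort(as.integer(unlist(parts$indices)))
  expect_identical(all_idx, 1:100)
  expect_identical(split_dataset(fs, sp)$indices, parts$indices)
  expect_false(identical(split_dataset(fs, split_spec(seed = 14))$indices,
                         parts$indices))
  # largest-remainder rounding on awkward sizes still partitions exactly
  fs2 <- counted_feature_set(3, 2, 2)
  p2 <- split_dataset(fs2, sp)
  expect_identical(sum(vapply(p2[1:3], function(p) nrow(p$features), integer(1))), 7L)
  expect_validation_error(split_spec(fractions = c(0.5, 0.3, 0.3)))
})

test_that("confusion matrices match a counting oracle and normalize rows to 100", {
  cls <- signature_classes()
  # perfect predictions: percentage matrix is 100 * I
  perfect <- rep(cls, each = 10)
  cm <- confusion_summary(perfect, perfect)
  expect_equal(cm$percent, diag(3) * 100, ignore_attr = TRUE)
  # forced arithmetic on a 4-sample example
  cm2 <- confusion_summary(c("PED", "PED", "RD", "NEITHER"),
                           c("PED", "RD", "RD", "NEITHER"))
  expect_identical(as.vector(cm2$counts["PED", ]), c(1L, 1L, 0L))
  expect_equal(as.vector(cm2$percent["PED", ]), c(50, 50, 0))
  # random pairs against a dictionary-counting oracle
  set.seed(19)
  a <- sample(cls, 1000, replace = TRUE)
  p <- sample(cls, 1000, replace = TRUE)
  cm3 <- confusion_summary(a, p)
  for (i in cls) for (j in cls)
    expect_identical(cm3$counts[i, j], sum(a == i & p == j))
  expect_equal(unname(rowSums(cm3$percent)), rep(100, 3), tolerance = 1e-6)
  expect_identical(sum(cm3$counts), 1000L)
  expect_validation_error(confusion_summary(c("PED", "FOO"), c("PED", "RD")))
  # an absent actual class yields a flagged zero row
  cm4 <- confusion_summary(c("PED", "RD"), c("PED", "RD"))
  expect_true(cm4$empty_rows["NEITHER"])
  expect_equal(sum(cm4$percent["NEITHER", ]), 0)
})

test_that("sensitivity/specificity agree with one-vs-rest TP/TN counting", {
  expect_equal(sensitivity_specificity(diag(c(5L, 5L, 5L)))$sensitivity, rep(1, 3))
  expect_equal(sensitivity_specificity(diag(c(5L, 5L, 5L)))$specificity, rep(1, 3))
  m <- matrix(c(8, 1, 1, 2, 6, 2, 0, 1, 9), 3, 3, byrow = TRUE)
  got <- sensitivity_specificity(m)
  expect_equal(got$sensitivity[1], 0.8)
  expect_equal(got$specificity[1], 18 / 20)
  # oracle: binarize a random labeled sample one class at a time
  set.seed(23)
  a <- sample(signature_classes(), 500, replace = TRUE, prob = c(0.2, 0.3, 0.5))
  p <- sample(signature_classes(), 500, replace = TRUE)
  got2 <- sensitivity_specificity(confusion_summary(a, p))
  for (k in seq_along(signature_classes())) {
    kk <- signature_classes()[k]
    tp <- sum(a == kk & p == kk); fn <- sum(a == kk & p != kk)
    tn <- sum(a != kk & p != kk); fp <- sum(a != kk & p == kk)
    expect_equal(got2$sensitivity[k], tp / (tp + fn))
    expect_equal(got2$specificity[k], tn / (tn + fp))
  }
  # zero denominators are NA, never errors
  z <- matrix(0L, 3, 3); z[2, 2] <- 4L
  zz <- sensitivity_specificity(z)
  expect_true(is.na(zz$sensitivity[1]))
  expect_equal(zz$specificity[1], 1)
  expect_validation_error(sensitivity_specificity(matrix(-1L, 3, 3)))
})

# Small but non-trivial feature pool for cross-validation mechanics: the toy
# clusters stand in for RPE-anchored crops so each CV test runs in seconds.
toy_feature_set <- function(n_per_class = 120, seed = 2) {
  toy <- toy_clusters(n_per_class, seed = seed)
  n <- nrow(toy$x)
  labeled_feature_set(toy$x, toy$labels,
                      data.frame(eye_id = "toy", bscan = rep(1L, n), ascan = seq_len(n)),
                      rep(1L, n))
}

toy_net <- function(seed = 1) network_config(layer_sizes = c(2, 8, 3), batch_size = 32,
                                             learning_rate = 0.01,
                                             max_epochs = 80, patience = 10, seed = seed)

test_that("Monte Carlo CV reports degenerate SDs at one iteration and valid rows always", {
  fs <- toy_feature_set()
  rep1 <- monte_carlo_cv(fs, split_spec(seed = 5), toy_net(), training_budget(100),
                         n_iterations = 1)
  expect_true(all(rep1$test$percent_sd == 0 | is.na(rep1$test$percent_sd)))
  rep3 <- monte_carlo_cv(fs, split_spec(seed = 5), toy_net(), training_budget(100),
                         n_iterations = 3)
  for (split in c("train", "test"))
    expect_equal(unname(rowSums(rep3[[split]]$percent_mean)), rep(100, 3),
                 tolerance = 1e-6)
  acc <- cv_class_accuracy(rep3)
  expect_true(all(acc$accuracy_mean > 90))  # separable toy problem
  expect_identical(rep3$n_iterations, 3)
  expect_identical(length(rep3$per_iteration), 3L)
  # report serialization produces the JSON and per-matrix CSV tables
  d <- withr::local_tempdir()
  write_evaluation_report(rep3, d)
  expect_true(file.exists(file.path(d, "evaluation_report.json")))
  csv <- read.csv(file.path(d, "confusion_test_mean.csv"), row.names = 1)
  expect_equal(unname(as.matrix(csv)), unname(rep3$test$percent_mean))
})

test_that("no statistic of validation/test data reaches the normalizer or sampler", {
  fs <- toy_feature_set(80, seed = 6)
  sp <- split_spec(seed = 31)
  fit_chain <- function(pool) {
    parts <- split_dataset(pool, sp)
    bal <- balanced_sample(parts$train, training_budget(50), seed = 77)
    fit_normalizer(bal$features)
  }
  n1 <- fit_chain(fs)
  perturbed <- fs
  parts <- split_dataset(fs, sp)
  test_rows <- parts$indices$test
  perturbed$features[test_rows, ] <- perturbed$features[test_rows, ] + 100
  n2 <- fit_chain(perturbed)
  expect_identical(n1$mean, n2$mean)
  expect_identical(n1$var, n2$var)
})

test_that("unseen-eye evaluation enforces eye disjointness and matches recomputation", {
  cfg <- tiny_scene_config()
  train_cohort <- make_cohort(2, cfg, seed = 51, randomize_lesions = FALSE)
  unseen <- make_cohort(1, cfg, seed = 99)
  fp <- feature_params(anterior_px = 40, posterior_px = 20)
  fs <- build_dataset(lapply(train_cohort, `[[`, "volume"),
                      lapply(train_cohort, `[[`, "label_map"),
                      params = fp)
  bal <- balanced_sample(fs, training_budget(300), seed = 1)
  norm <- fit_normalizer(bal$features)
  net <- network_config(layer_sizes = c(61, 16, 3), batch_size = 32,
                        max_epochs = 40, patience = 6, seed = 2)
  model <- train_mlp(init_network(net), apply_normalizer(norm, bal$features),
                     one_hot(bal$labels))
  train_ids <- vapply(train_cohort, function(e) e$volume$eye_id, character(1))
  # same ids as training -> rejected
  expect_validation_error(
    evaluate_unseen(model, norm, lapply(train_cohort, `[[`, "volume"),
                    lapply(train_cohort, `[[`, "label_map"),
                    training_eye_ids = train_ids, params = fp))
  unseen[[1]]$volume$eye_id <- "held-out"
  unseen[[1]]$label_map$eye_id <- "held-out"
  res <- evaluate_unseen(model, norm, list(unseen[[1]]$volume),
                         list(unseen[[1]]$label_map),
                         training_eye_ids = train_ids, params = fp)
  # metrics equal recomputing the confusion matrix from the prediction dump
  cm2 <- confusion_summary(res$predictions$actual, res$predictions$predicted)
  expect_identical(res$confusion$counts, cm2$counts)
  expect_equal(res$metrics, sensitivity_specificity(cm2))
  expect_identical(sum(res$confusion$counts), nrow(res$predictions))
})
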