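# Shared fixtures, built in code at test time.

# Small random volume with values in [0, 1].
random_volume <- function(b = 2, a = 4, d = 8, seed = 1, eye_id = "fix") {
  set.seed(seed)
  oct_volume(array(runif(b * a * d), dim = c(b, a, d)), eye_id = eye_id)
}

# Tiny lesioned scene at a geometry small enough for per-test rendering.
tiny_scene_config <- function(seed = 1, speckle_shape = 0, ...) {
  scene_config(n_bscans = 8, n_ascans = 24, depth = 256,
               baseline_rpe_depth = 180,
               ped_bumps = list(c(4, 6, 2, 3, 15)),
               rd_bumps = list(c(5, 17, 2.5, 4, 20)),
               speckle_shape = speckle_shape, seed = seed, ...)
}

# A separable three-class toy feature problem (not OCT-derived): Gaussian
# clusters in 2-D, one per signature class.
toy_clusters <- function(n_per_class = 100, seed = 42, sd = 0.25) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 3, 0, 0, 3), ncol = 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per_class, centers[k, 1], sd),
          rnorm(n_per_class, centers[k, 2], sd))))
  list(x = x, labels = factor(rep(signature_classes(), each = n_per_class),
                              levels = signature_classes()))
}

# Feature set with arbitrary class counts and tiny feature width, for
# sampling/splitting tests that do not care about feature content.
counted_feature_set <- function(n_ped, n_rd, n_neither, width = 2, seed = 7) {
  set.seed(seed)
  n <- n_ped + n_rd + n_neither
  labels <- rep(signature_classes(), c(n_ped, n_rd, n_neither))
  labeled_feature_set(
    matrix(runif(n * width), n, width),
    labels,
    data.frame(eye_id = "cnt", bscan = rep(1L, n), ascan = seq_len(n)),
    rep(1L, n))
}

expect_validation_error <- function(expr) {
  expect_error(expr, class = "ascansig_validation_error")
}
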