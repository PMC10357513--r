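# synthetic window-level feature datasets with session structure
toy_dataset <- function(n_sessions_per_class = 4, n_windows = 10, p = 6,
                        sep = 0, session_sd = 0, seed = 1,
                        classes = c("joy", "sadness", "fear", "neutral")) {
  set.seed(seed)
  X <- NULL; y <- character(); grp <- integer()
  sid <- 0L
  for (ci in seq_along(classes)) {
    mu <- rep(0, p); mu[ci] <- sep
    for (s in seq_len(n_sessions_per_class)) {
      sid <- sid + 1L
      sess_shift <- rnorm(p, 0, session_sd)
      Xi <- matrix(rnorm(n_windows * p), n_windows, p)
      Xi <- sweep(Xi, 2, mu + sess_shift, `+`)
      X <- rbind(X, Xi)
      y <- c(y, rep(classes[ci], n_windows))
      grp <- c(grp, rep(sid, n_windows))
    }
  }
  structure(list(X = X, y = factor(y), groups = grp, band = "gamma",
                 kind = "DE"), class = "feature_dataset")
}

test_that("group folds keep sessions intact and classes in every training fold", {
  ds <- toy_dataset(n_sessions_per_class = 2)
  folds <- hapticEEG:::group_folds(ds$groups, ds$y, k = 4, seed = 3)
  expect_length(folds, 8)
  expect_setequal(unique(folds), 1:4)
  # the two sessions of each class land in different folds
  cls <- rep(c("joy", "sadness", "fear", "neutral"), each = 2)
  for (cl in unique(cls))
    expect_length(unique(folds[cls == cl]), 2)
  expect_error(hapticEEG:::group_folds(ds$groups, ds$y, k = 9, seed = 1),
               "exceeds")
})

test_that("separable classes reach 100%, and accuracy is deterministic", {
  ds <- toy_dataset(sep = 10, seed = 5)
  expect_equal(crossval_svm(ds, seed = 7), 100)
  noisy <- toy_dataset(sep = 1.2, session_sd = 0.5, seed = 6)
  a1 <- crossval_svm(noisy, seed = 9)
  a2 <- crossval_svm(noisy, seed = 9)
  expect_identical(a1, a2)
  expect_true(a1 > 25 && a1 < 100)
})

test_that("accuracy is invariant to feature permutation and affine rescaling", {
  ds <- toy_dataset(sep = 1.5, session_sd = 0.3, seed = 8)
  base <- crossval_svm(ds, seed = 2)
  perm <- sample(ncol(ds$X))
  ds_p <- ds; ds_p$X <- ds$X[, perm]
  expect_equal(crossval_svm(ds_p, seed = 2), base)
  ds_a <- ds; ds_a$X <- ds$X * 7 - 3
  expect_equal(crossval_svm(ds_a, seed = 2), base)
})

test_that("windows of one session never span the train/test split", {
  ds <- toy_dataset(sep = 2, seed = 11)
  folds <- hapticEEG:::group_folds(ds$groups, ds$y, k = 4, seed = 4)
  for (f in 1:4) {
    test_sessions <- names(folds)[folds == f]
    in_test <- ds$groups %in% test_sessions
    # each session is entirely in or entirely out
    for (s in unique(ds$groups))
      expect_length(unique(in_test[ds$groups == s]), 1)
  }
})

test_that("corrupting test-fold features leaves the fitted model unchanged", {
  ds <- toy_dataset(sep = 1.5, seed = 12)
  folds <- hapticEEG:::group_folds(ds$groups, ds$y, k = 4, seed = 1)
  test <- ds$groups %in% names(folds)[folds == 1]
  fit_on <- function(X) {
    Xtr <- X[!test, ]
    mu <- colMeans(Xtr); sdv <- pmax(apply(Xtr, 2, sd), 1e-8)
    e1071::svm(sweep(sweep(Xtr, 2, mu), 2, sdv, `/`),
               droplevels(ds$y[!test]), kernel = "linear", scale = FALSE)
  }
  X_corrupt <- ds$X
  X_corrupt[test, ] <- 1e6
  f1 <- fit_on(ds$X); f2 <- fit_on(X_corrupt)
  expect_identical(f1$coefs, f2$coefs)
  expect_identical(f1$rho, f2$rho)
})

test_that("degenerate class/fold structures are rejected", {
  expect_error(crossval_svm(toy_dataset(n_sessions_per_class = 1, seed = 1)),
               "at least 2 sessions")
  one_class <- toy_dataset(classes = "joy", seed = 2)
  expect_error(crossval_svm(one_class), "at least 2 classes")
})

test_that("accuracy grid covers the factor grid and records absent cells as NA", {
  cfg <- tiny_config()
  pre <- preprocess_chain(generate_subject(cfg, 1))
  tab <- subject_accuracy_grid(pre, kinds = "DE",
                               band_rows = c("gamma", "total"), seed = 3)
  expect_equal(nrow(tab), 2 * 2 * 1 * 2)  # pattern x condition x kind x band
  expect_true(all(!is.na(tab$accuracy)))
  expect_setequal(unique(tab$pattern), c("haptic1", "haptic2"))
  expect_setequal(unique(tab$condition), c("non-haptic", "haptic"))
})
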