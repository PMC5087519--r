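test_that("LS-SVM separates trivially separable data and satisfies KKT", {
  x <- matrix(c(-5, -4, 4, 5), ncol = 1)
  y <- c("SS", "SS", "IS", "IS")
  m <- fit_lssvm(x, y, gamma = 1, sigma = 1)
  expect_equal(mean(predict(m, x) == y), 1)
  expect_lt(m$kkt_residual, 1e-8)
})

test_that("the RBF LS-SVM resolves the XOR pattern", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), ncol = 2, byrow = TRUE)
  y <- c("a", "a", "b", "b")
  m <- fit_lssvm(x, y, gamma = 100, sigma = 0.5)
  expect_equal(mean(predict(m, x) == y), 1)
  expect_lt(m$kkt_residual, 1e-8)
})

test_that("every LS-SVM fit keeps a small relative KKT residual", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    x <- matrix(rnorm(2 * n), ncol = 2)
    y <- factor(sample(c("SS", "IS"), n, replace = TRUE))
    if (nlevels(droplevels(y)) < 2) next
    m <- fit_lssvm(x, y, gamma = 10^runif(1, -1, 2),
                   sigma = 10^runif(1, -0.5, 0.5))
    expect_lt(m$kkt_residual, 1e-8)
  }
})

test_that("logistic regression finds a symmetric decision boundary", {
  x <- c(1, 2, 3, 7, 8, 9)  # symmetric around 5
  y <- factor(c("SS", "SS", "SS", "IS", "IS", "IS"), levels = c("SS", "IS"))
  m <- fit_blr(x, y)
  boundary <- -m$intercept / m$slopes
  expect_equal(boundary, 5, tolerance = 1e-6)
  # data are separable: flagged, yet training classification is perfect
  expect_true(m$separated)
  expect_equal(mean(predict(m, x) == y), 1)
})

test_that("IRLS logistic fit matches glm and keeps the likelihood monotone", {
  set.seed(42)
  n <- 500
  x <- rnorm(n, 0, 2)
  p <- plogis(-2 + 0.8 * x)
  y <- factor(ifelse(runif(n) < p, "IS", "SS"), levels = c("SS", "IS"))
  m <- fit_blr(x, y)
  expect_false(m$separated)
  expect_true(m$converged)
  expect_false(is.unsorted(m$ll_trace))

  g <- glm(I(y == "IS") ~ x, family = binomial)
  expect_equal(m$intercept, unname(coef(g)[1]), tolerance = 1e-6)
  expect_equal(unname(m$slopes), unname(coef(g)[2]), tolerance = 1e-6)

  # parameter recovery within 3 SE of the generating values
  se <- sqrt(diag(vcov(g)))
  expect_lt(abs(m$intercept - (-2)), 3 * se[1])
  expect_lt(abs(m$slopes - 0.8), 3 * se[2])
})

test_that("repeated stratified splits estimate chance on shuffled labels", {
  set.seed(23)
  x <- matrix(rnorm(60 * 3), ncol = 3)
  y <- sample(rep(c("SS", "IS"), 30))  # labels independent of features
  ev <- split_evaluate(x, y, "lssvm", n_repeats = 30, seed = 5)
  se <- ev$accuracy_sd / sqrt(length(ev$accuracies))
  expect_lt(abs(ev$accuracy_mean - 0.5), max(3 * se, 0.12))
  expect_gte(min(ev$accuracies), 0)
  expect_lte(max(ev$accuracies), 1)
  expect_equal(sum(ev$confusion), ev$n_test * 30)
})

test_that("color features separate high-contrast synthetic patch classes", {
  pp <- patch_sim_params(con = 30, seed = 0)
  samples <- generate_dataset(15, "rgb", pp, seed = 77)
  feats <- t(vapply(samples, function(s) color_features(s$patch),
                    numeric(6)))
  labels <- vapply(samples, `[[`, character(1), "label")
  ev <- split_evaluate(feats, labels, "lssvm", n_repeats = 20, seed = 9,
                       gamma = 10, sigma = 1)
  expect_gte(ev$accuracy_mean, 0.90)
})

test_that("LS-SVM accuracy does not degrade as contrast grows", {
  accs <- vapply(c(0, 10, 20, 30), function(con) {
    pp <- patch_sim_params(con = con, n_lenticels = 0, seed = 0)
    samples <- generate_dataset(12, "rgb", pp, seed = 41)
    feats <- t(vapply(samples, function(s) color_features(s$patch),
                      numeric(6)))
    labels <- vapply(samples, `[[`, character(1), "label")
    split_evaluate(feats, labels, "lssvm", n_repeats = 15, seed = 3,
                   gamma = 10, sigma = 1)$accuracy_mean
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.05))  # non-decreasing up to split noise
  expect_gt(accs[4], accs[1])
})

test_that("scalar BA separates slow- from fast-decorrelating stacks", {
  sp <- speckle_sim_params(height = 64, width = 64, n_frames = 125)
  samples <- generate_dataset(9, "speckle", sp, class_rhos = c(0.95, 0.5),
                              seed = 19)
  ba <- vapply(samples, function(s) biospeckle_activity(s$sequence)$ba,
               numeric(1))
  labels <- vapply(samples, `[[`, character(1), "label")
  ev <- split_evaluate(matrix(ba, ncol = 1), labels, "blr",
                       n_repeats = 20, seed = 7)
  expect_gte(ev$accuracy_mean, 0.85)
})

test_that("hyperparameter search honours its grid and tie-break contract", {
  set.seed(29)
  x <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1)
  y <- rep(c("SS", "IS"), each = 20)
  # single-point grid is returned as-is
  one <- tune_lssvm(x, y, gamma_grid = 2, sigma_grid = 3, k_folds = 3)
  expect_equal(one$gamma, 2)
  expect_equal(one$sigma, 3)
  # separable data: some configuration reaches CV accuracy 1
  best <- tune_lssvm(x, y, gamma_grid = c(1, 10), sigma_grid = c(1, 2),
                     k_folds = 4)
  expect_equal(best$cv_accuracy, 1)
  # ties resolve to the smallest gamma then smallest sigma
  expect_equal(best$gamma, 1)
  expect_equal(best$sigma, 1)
})

test_that("degenerate classifier inputs are rejected", {
  expect_error(fit_lssvm(matrix(1:4, ncol = 1), rep("SS", 4)), "two classes")
  expect_error(fit_blr(1:4, rep("IS", 4)), "two classes")
  expect_error(fit_lssvm(matrix(1:4, ncol = 1), c("a", "a", "b", "b"),
                         gamma = -1), "positive")
})
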