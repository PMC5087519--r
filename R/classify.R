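#' Fit a least-squares support vector machine (RBF kernel)
#'
#' The LS-SVM replaces the SVM's inequality constraints with equality
#' constraints, so training reduces to one linear (KKT) system in the dual
#' variables alpha and the bias b:
#' \deqn{\begin{pmatrix} 0 & 1^T \\ 1 & K + I/\gamma \end{pmatrix}
#'       \begin{pmatrix} b \\ \alpha \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ y \end{pmatrix}}
#' with labels y encoded +/-1 and RBF kernel
#' `K(x, z) = exp(-||x - z||^2 / (2 sigma^2))`. Features are standardized
#' (z-score) using statistics of the training set, which the model retains
#' for prediction.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Labels: factor or character/numeric with exactly 2 classes.
#' @param gamma Regularization parameter (> 0); larger fits harder.
#' @param sigma RBF kernel width (> 0).
#' @return An `lssvm_model` with dual weights `alpha`, `bias`, the
#'   standardized training matrix, scaling statistics, the class level
#'   encoding, and `kkt_residual` (relative residual of the solved system).
#' @export
fit_lssvm <- function(x, y, gamma = 1, sigma = 1) {
  x <- as.matrix(x)
  if (gamma <= 0 || sigma <= 0)
    stop("'gamma' and 'sigma' must be positive", call. = FALSE)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L)
    stop("exactly two classes must be present in the training labels",
         call. = FALSE)
  y <- droplevels(y)
  yy <- ifelse(y == levels(y)[2], 1, -1)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  n <- nrow(xs)
  k <- .rbf_kernel(xs, xs, sigma)
  a <- rbind(c(0, rep(1, n)),
             cbind(1, k + diag(n) / gamma))
  rhs <- c(0, yy)
  sol <- tryCatch(solve(a, rhs), error = function(e)
    stop("the LS-SVM KKT system is numerically singular; ",
         "try a smaller gamma or a larger sigma", call. = FALSE))
  resid <- sqrt(sum((a %*% sol - rhs)^2)) / sqrt(sum(rhs^2))
  structure(list(alpha = sol[-1], bias = sol[1], gamma = gamma,
                 sigma = sigma, x_train = xs, center = ctr, scale = scl,
                 levels = levels(y), kkt_residual = resid),
            class = "lssvm_model")
}

.rbf_kernel <- function(a, b, sigma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' @describeIn fit_lssvm Decision values and class predictions.
#' @param object An `lssvm_model`.
#' @param newdata Matrix of samples to classify.
#' @param type `"class"` (default) or `"decision"`.
#' @param ... Unused.
#' @export
predict.lssvm_model <- function(object, newdata, type = c("class", "decision"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  k <- .rbf_kernel(xs, object$x_train, object$sigma)
  f <- drop(k %*% object$alpha) + object$bias
  if (type == "decision") return(f)
  factor(ifelse(f >= 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' with step-halving, so the log-likelihood is non-decreasing across
#' iterations by construction. Complete separation is detected (coefficients
#' diverging past `coef_cap`) and reported via the `separated` flag, with
#' coefficients capped at that magnitude; classification on separated data
#' remains perfect. The decision threshold is probability 0.5.
#'
#' @param x Numeric matrix or vector of features.
#' @param y Labels with exactly two classes; the second factor level is
#'   modelled as the positive class.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param coef_cap Magnitude at which coefficients are declared separated.
#' @return A `blr_model` with `intercept`, `slopes`, `converged`, `n_iter`,
#'   `separated`, `ll_trace` and the class level encoding.
#' @export
fit_blr <- function(x, y, max_iter = 100L, tol = 1e-10, coef_cap = 30) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L)
    stop("exactly two classes must be present in the training labels",
         call. = FALSE)
  yy <- as.numeric(y == levels(y)[2])
  # standardize internally for numerical stability; coefficients mapped back
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  xmat <- cbind(1, xs)
  beta <- rep(0, ncol(xmat))
  loglik <- function(b) {
    eta <- drop(xmat %*% b)
    # log(1 + e^eta) computed overflow-free
    sum(yy * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  ll <- loglik(beta)
  ll_trace <- ll
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(xmat %*% beta)
    p <- stats::plogis(eta)
    wts <- pmax(p * (1 - p), 1e-10)
    z <- eta + (yy - p) / wts
    fit <- stats::lm.wfit(xmat, z, wts)
    step <- fit$coefficients - beta
    # step-halve until the log-likelihood does not decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
    ll_trace <- c(ll_trace, max(ll_new, ll))
    if (abs(ll_new - ll) < tol) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
    if (max(abs(beta)) > coef_cap) break
  }
  separated <- max(abs(beta)) > coef_cap
  if (separated) beta <- pmin(pmax(beta, -coef_cap), coef_cap)
  # map standardized coefficients back to the original feature scale
  slopes <- unname(beta[-1] / scl)
  intercept <- unname(beta[1] - sum(beta[-1] * ctr / scl))
  structure(list(intercept = intercept, slopes = slopes,
                 converged = converged, n_iter = it,
                 separated = separated, ll_trace = ll_trace,
                 levels = levels(y)),
            class = "blr_model")
}

#' @describeIn fit_blr Probabilities or class predictions.
#' @param object A `blr_model`.
#' @param newdata Matrix or vector of features.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @export
predict.blr_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  p <- stats::plogis(object$intercept + drop(newdata %*% object$slopes))
  if (type == "prob") return(p)
  factor(ifelse(p >= 0.5, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Repeated stratified split evaluation
#'
#' Draws stratified random train/test splits (default 2:1, the study's
#' training-to-prediction ratio), fits the chosen classifier on the
#' training part and scores accuracy on the held-out part, repeating
#' `n_repeats` times with seeds derived from the master seed.
#'
#' @param x Feature matrix (samples x features) or vector for a scalar
#'   feature.
#' @param y Two-class labels.
#' @param model_kind `"lssvm"` or `"blr"`.
#' @param train_fraction Fraction of each class used for training; default
#'   2/3 (a 2:1 split).
#' @param n_repeats Number of random splits; default 50.
#' @param seed Master seed.
#' @param gamma,sigma LS-SVM hyperparameters (ignored for BLR).
#' @return An `eval_report`: list with `accuracy_mean`, `accuracy_sd`,
#'   `accuracies`, `n_train`, `n_test`, `split_ratio`, `confusion`
#'   (summed over repeats), `model_kind`, `seed`.
#' @export
split_evaluate <- function(x, y, model_kind = c("lssvm", "blr"),
                           train_fraction = 2 / 3, n_repeats = 50L,
                           seed = 1L, gamma = 10, sigma = 1) {
  model_kind <- match.arg(model_kind)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("two classes required", call. = FALSE)
  idx_by_class <- split(seq_along(y), y)
  n_tr_by_class <- vapply(idx_by_class, function(i)
    as.integer(max(1, round(length(i) * train_fraction))), integer(1))
  if (any(vapply(idx_by_class, length, integer(1)) - n_tr_by_class < 1L))
    stop("not enough samples in a class for a stratified split",
         call. = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  accs <- numeric(n_repeats)
  confusion <- matrix(0L, 2, 2, dimnames = list(truth = levels(y),
                                                predicted = levels(y)))
  for (r in seq_len(n_repeats)) {
    set.seed(rep_seeds[r])
    tr <- unlist(mapply(function(i, k) sample(i, k), idx_by_class,
                        n_tr_by_class, SIMPLIFY = FALSE))
    te <- setdiff(seq_along(y), tr)
    model <- if (model_kind == "lssvm")
      fit_lssvm(x[tr, , drop = FALSE], y[tr], gamma = gamma, sigma = sigma)
    else fit_blr(x[tr, , drop = FALSE], y[tr])
    pred <- predict(model, x[te, , drop = FALSE])
    accs[r] <- mean(pred == y[te])
    confusion <- confusion + table(truth = y[te], predicted = pred)
  }
  structure(list(accuracy_mean = mean(accs), accuracy_sd = stats::sd(accs),
                 accuracies = accs,
                 n_train = sum(n_tr_by_class),
                 n_test = length(y) - sum(n_tr_by_class),
                 split_ratio = sprintf("%.3g:%.3g", train_fraction,
                                       1 - train_fraction),
                 confusion = confusion, model_kind = model_kind,
                 seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s, %d train / %d test, mean accuracy %.3f (SD %.3f)\n",
              x$model_kind, x$n_train, x$n_test, x$accuracy_mean,
              x$accuracy_sd))
  invisible(x)
}

#' Grid-search LS-SVM hyperparameters by cross-validation
#'
#' Exhaustive search over `(gamma, sigma)` maximizing the mean k-fold
#' cross-validated accuracy, with deterministic tie-breaking: smallest
#' gamma first, then smallest sigma.
#'
#' @param x Feature matrix; @param y two-class labels.
#' @param gamma_grid,sigma_grid Non-empty numeric grids.
#' @param k_folds Number of folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @return List with `gamma`, `sigma`, `cv_accuracy`.
#' @export
tune_lssvm <- function(x, y, gamma_grid = c(0.1, 1, 10, 100),
                       sigma_grid = c(0.5, 1, 2, 4), k_folds = 5L,
                       seed = 1L) {
  if (length(gamma_grid) == 0 || length(sigma_grid) == 0)
    stop("grids must be non-empty", call. = FALSE)
  if (k_folds < 2L) stop("'k_folds' must be at least 2", call. = FALSE)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  set.seed(seed)
  # stratified fold assignment
  folds <- integer(length(y))
  for (cls in levels(y)) {
    i <- which(y == cls)
    folds[i] <- sample(rep_len(seq_len(k_folds), length(i)))
  }
  grid <- expand.grid(gamma = sort(gamma_grid), sigma = sort(sigma_grid))
  grid <- grid[order(grid$gamma, grid$sigma), ]
  best <- NULL
  for (row in seq_len(nrow(grid))) {
    accs <- vapply(seq_len(k_folds), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2L || !any(!tr)) return(NA_real_)
      m <- fit_lssvm(x[tr, , drop = FALSE], y[tr],
                     gamma = grid$gamma[row], sigma = grid$sigma[row])
      mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    acc <- mean(accs, na.rm = TRUE)
    if (is.null(best) || acc > best$cv_accuracy + 1e-12)
      best <- list(gamma = grid$gamma[row], sigma = grid$sigma[row],
                   cv_accuracy = acc)
  }
  best
}
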