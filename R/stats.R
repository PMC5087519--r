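#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper around the usual Pearson estimate with its t-distribution
#' p-value, used for the windowed-BA correlation tables.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("at least 3 observations are required",
                           call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' One-way analysis of variance
#'
#' Standard between/within variance decomposition across k groups. With two
#' groups the F statistic equals the square of the pooled two-sample t
#' statistic.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return An `anova_result`: list with `f_value`, `p_value`, `df_between`,
#'   `df_within`, `group_means`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  values <- unlist(groups)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- stats::anova(stats::lm(values ~ labels))
  structure(list(f_value = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
                 df_between = fit$Df[1], df_within = fit$Df[2],
                 group_means = vapply(groups, mean, numeric(1))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_value, x$p_value))
  invisible(x)
}

#' Per-group mean and standard deviation summaries
#'
#' Mean and sample SD (n - 1 denominator) per group, in the reporting style
#' "mean +/- SD". A single-value group has no defined SD; it is reported as
#' 0 and flagged.
#'
#' @param values_by_group Named list of numeric vectors.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`,
#'   `sd_undefined`.
#' @export
group_summary <- function(values_by_group) {
  if (length(values_by_group) == 0L)
    stop("at least one group is required", call. = FALSE)
  nm <- names(values_by_group)
  if (is.null(nm)) nm <- as.character(seq_along(values_by_group))
  rows <- lapply(seq_along(values_by_group), function(i) {
    v <- values_by_group[[i]]
    if (length(v) == 0L) stop("empty group", call. = FALSE)
    single <- length(v) == 1L
    data.frame(group = nm[i], n = length(v), mean = mean(v),
               sd = if (single) 0 else stats::sd(v),
               sd_undefined = single)
  })
  do.call(rbind, rows)
}

#' Pairwise Welch comparisons with Bonferroni correction
#'
#' Simple pairwise group comparisons offered in place of letter-style
#' post-hoc groupings: Welch two-sample t-tests for every pair of groups
#' with Bonferroni-adjusted p-values.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 values each).
#' @return Data frame with columns `group1`, `group2`, `t`, `p`, `p_adj`.
#' @export
pairwise_welch <- function(values_by_group) {
  k <- length(values_by_group)
  if (k < 2L) stop("at least two groups are required", call. = FALSE)
  nm <- names(values_by_group)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(pr) {
    tt <- stats::t.test(values_by_group[[pr[1]]], values_by_group[[pr[2]]])
    data.frame(group1 = nm[pr[1]], group2 = nm[pr[2]],
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  out
}
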