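#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak correction: raw p-values are ordered ascending and the
#' i-th smallest is adjusted to `1 - (1 - p)^(m - i + 1)`, with a
#' cumulative-maximum pass to keep the adjusted values monotone.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

shapiro_p <- function(x) {
  if (length(unique(x)) < 3L || length(x) < 3L) return(NA_real_)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
}

#' Two-group comparison with a normality gate
#'
#' Both the unpaired Student's t-test (equal variances) and the
#' Mann-Whitney (Wilcoxon rank-sum) test are computed; the primary result
#' follows the normality gate: Student's t when both groups pass
#' Shapiro-Wilk at `normality_alpha`, Mann-Whitney otherwise. Groups with
#' zero variance are flagged degenerate (Shapiro-Wilk and the t branch
#' are undefined there) and routed to the rank test.
#'
#' @param a,b Numeric vectors (each `n >= 3`).
#' @param paired Use the paired variants.
#' @param normality_alpha Shapiro-Wilk significance level for the gate.
#' @return An object of class `test_result`: list with `test_name`,
#'   `statistic`, `p_value`, `normality_p` (length 2), `decision_path`
#'   ("parametric", "nonparametric" or "degenerate"), and `all_tests`
#'   (p-values of both branches).
#' @export
compare_two <- function(a, b, paired = FALSE, normality_alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("insufficient data: each group needs n >= 3", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("values must be finite", call. = FALSE)
  }
  norm_p <- c(shapiro_p(a), shapiro_p(b))
  degenerate <- stats::var(a) == 0 && stats::var(b) == 0
  t_res <- tryCatch(
    stats::t.test(a, b, paired = paired, var.equal = TRUE),
    error = function(e) NULL)
  w_res <- tryCatch(
    suppressWarnings(stats::wilcox.test(a, b, paired = paired)),
    error = function(e) NULL)
  t_p <- if (is.null(t_res)) NA_real_ else t_res$p.value
  w_p <- if (is.null(w_res)) NA_real_ else w_res$p.value
  if (degenerate) {
    path <- "degenerate"
    primary <- list(name = "none (degenerate: zero variance)",
                    statistic = NA_real_, p = NA_real_)
  } else if (!anyNA(norm_p) && all(norm_p > normality_alpha)) {
    path <- "parametric"
    primary <- list(name = if (paired) "paired t" else "unpaired Student's t",
                    statistic = unname(t_res$statistic), p = t_p)
  } else {
    path <- "nonparametric"
    primary <- list(name = "Mann-Whitney",
                    statistic = if (is.null(w_res)) NA_real_ else
                      unname(w_res$statistic),
                    p = w_p)
  }
  structure(
    list(test_name = primary$name, statistic = primary$statistic,
         p_value = primary$p, normality_p = norm_p,
         decision_path = path,
         all_tests = c(t = t_p, mann_whitney = w_p)),
    class = "test_result")
}

# Dunn's post test: pairwise z statistics on mean ranks after a
# Kruskal-Wallis omnibus, with the tie correction, Bonferroni-adjusted.
dunn_test <- function(values, groups) {
  r <- rank(values)
  n_tot <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  base_var <- n_tot * (n_tot + 1) / 12 - tie_term
  lev <- unique(groups)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    z <- (mean_rank[[i]] - mean_rank[[j]]) /
      sqrt(base_var * (1 / n_g[[i]] + 1 / n_g[[j]]))
    data.frame(group1 = i, group2 = j, statistic = z,
               p_raw = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p_raw * nrow(out), 1)
  out
}

#' Multi-group comparison with the Shapiro-Wilk decision tree
#'
#' Every group is tested for normality (Shapiro-Wilk at
#' `normality_alpha`). When all groups pass, a one-way ANOVA is followed
#' by all pairwise comparisons using the pooled residual variance with
#' Holm-Sidak correction; when any group fails, a Kruskal-Wallis test is
#' followed by Dunn's multiple comparisons (Bonferroni-adjusted z tests
#' on mean ranks).
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each
#'   `n >= 3`).
#' @param normality_alpha Shapiro-Wilk significance level for the gate.
#' @return An object of class `test_result`: list with `test_name`,
#'   `statistic` and `p_value` of the omnibus test, `normality_p` per
#'   group, `decision_path`, and `comparisons` (data.frame with columns
#'   `group1`, `group2`, `statistic`, `p_raw`, `p_adj`).
#' @export
compare_multi <- function(groups, normality_alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L) {
    stop("need a named list of >= 3 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(lengths(groups) < 3L)) {
    stop("insufficient data: each group needs n >= 3", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  labels <- rep(names(groups), lengths(groups))
  norm_p <- vapply(groups, shapiro_p, numeric(1))
  parametric <- !anyNA(norm_p) && all(norm_p > normality_alpha)
  if (parametric) {
    fit <- stats::aov(values ~ factor(labels))
    an <- summary(fit)[[1]]
    mse <- an["Residuals", "Mean Sq"]
    df_res <- an["Residuals", "Df"]
    means <- tapply(values, labels, mean)
    ns <- tapply(values, labels, length)
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      i <- pr[1]; j <- pr[2]
      tstat <- (means[[i]] - means[[j]]) /
        sqrt(mse * (1 / ns[[i]] + 1 / ns[[j]]))
      data.frame(group1 = i, group2 = j, statistic = tstat,
                 p_raw = 2 * stats::pt(-abs(tstat), df_res))
    })
    comparisons <- do.call(rbind, rows)
    comparisons$p_adj <- holm_sidak_adjust(comparisons$p_raw)
    res <- list(test_name = "one-way ANOVA + Holm-Sidak",
                statistic = an[1, "F value"],
                p_value = an[1, "Pr(>F)"],
                decision_path = "parametric")
  } else {
    kw <- stats::kruskal.test(values, factor(labels))
    comparisons <- dunn_test(values, labels)
    res <- list(test_name = "Kruskal-Wallis + Dunn",
                statistic = unname(kw$statistic),
                p_value = kw$p.value,
                decision_path = "nonparametric")
  }
  structure(c(res, list(normality_p = norm_p, comparisons = comparisons)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s [%s]: statistic=%.4g, p=%.4g\n",
              x$test_name, x$decision_path, x$statistic, x$p_value))
  if (!is.null(x$comparisons)) {
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
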