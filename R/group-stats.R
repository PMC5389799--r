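#' One-way (single-factor) analysis of variance
#'
#' Standard between/within sum-of-squares decomposition across k groups,
#' with the p value from the F distribution. Used to test whether an
#' endpoint (an enrichment rate, a time-point enrichment, a concentration)
#' differs among experimental groups. With zero within-group variance and
#' unequal means the F statistic is reported as `Inf` and flagged.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @return Object of class `"ecflux_anova"`: `f`, `df_between`, `df_within`,
#'   `p`, `msw`, `means`, `ns`, `degenerate`.
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  ns <- table(groups)
  if (length(ns) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(as.numeric(ns) * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df_b <- length(ns) - 1L
  df_w <- length(values) - length(ns)
  msw <- ssw / df_w
  degenerate <- ssw == 0
  f <- if (degenerate) {
    if (ssb > 0) Inf else 0
  } else {
    (ssb / df_b) / msw
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(f = f, df_between = df_b, df_within = df_w, p = p,
                 msw = msw, means = means, ns = as.numeric(ns),
                 degenerate = degenerate),
            class = "ecflux_anova")
}

#' @export
print.ecflux_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.3g%s\n",
              x$df_between, x$df_within, x$f, x$p,
              if (x$degenerate) " [degenerate: zero within-group variance]"
              else ""))
  invisible(x)
}

#' One-way ANOVA from printed group summaries
#'
#' Reconstructs the F test from per-group means, standard errors of the
#' mean and sample sizes, as printed in a results table: the within sum of
#' squares is the sum of (n - 1) * (SE * sqrt(n))^2 and the between sum of
#' squares comes from the means and ns. Lets published group summaries be
#' compared without raw data (note that rounded summaries give a rounded F).
#'
#' @param means Group means.
#' @param ses Standard errors of the group means (> 0).
#' @param ns Group sizes (>= 2).
#' @return An `"ecflux_anova"` object, as [one_way_anova()].
#' @export
anova_from_summary <- function(means, ses, ns) {
  stopifnot(length(means) == length(ses), length(means) == length(ns))
  if (length(means) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  if (any(ns < 2L)) stop("group sizes must be >= 2", call. = FALSE)
  sds <- ses * sqrt(ns)
  ssw <- sum((ns - 1) * sds^2)
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  df_b <- length(means) - 1L
  df_w <- sum(ns) - length(means)
  msw <- ssw / df_w
  f <- (ssb / df_b) / msw
  nms <- names(means) %||% as.character(seq_along(means))
  structure(list(f = f, df_between = df_b, df_within = as.integer(df_w),
                 p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
                 msw = msw, means = stats::setNames(means, nms), ns = ns,
                 degenerate = FALSE),
            class = "ecflux_anova")
}

pairwise_grid <- function(labels) {
  idx <- utils::combn(seq_along(labels), 2)
  tibble::tibble(group1 = labels[idx[1, ]], group2 = labels[idx[2, ]])
}

#' Scheffe post-hoc pairwise comparisons
#'
#' For each pair (i, j) the contrast statistic
#' F' = (mean_i - mean_j)^2 / (MSW * (1/n_i + 1/n_j)) is referred to
#' (k - 1) * F_crit(k - 1, N - k); equivalently p = P(F >= F'/(k - 1)).
#' Conservative for pairwise contrasts but valid for arbitrary contrasts.
#'
#' @param values,groups As [one_way_anova()].
#' @param alphas Significance levels flagged in the output.
#' @return Tibble: `method`, `group1`, `group2`, `diff`, `statistic`, `p`,
#'   and one logical `sig_<alpha>` column per level.
#' @export
scheffe <- function(values, groups, alphas = c(0.05, 0.01)) {
  aov1 <- one_way_anova(values, groups)
  k <- aov1$df_between + 1L
  pairs <- pairwise_grid(names(aov1$means))
  ns <- stats::setNames(aov1$ns, names(aov1$means))
  diff <- aov1$means[pairs$group1] - aov1$means[pairs$group2]
  fprime <- diff^2 / (aov1$msw * (1 / ns[pairs$group1] + 1 / ns[pairs$group2]))
  p <- stats::pf(fprime / (k - 1), k - 1, aov1$df_within, lower.tail = FALSE)
  posthoc_table("scheffe", pairs, as.numeric(diff), as.numeric(fprime),
                as.numeric(p), alphas)
}

#' Tukey-Kramer post-hoc pairwise comparisons
#'
#' Tukey's honestly-significant-difference test in the Kramer form for
#' unequal group sizes: q = |mean_i - mean_j| /
#' sqrt(MSW/2 * (1/n_i + 1/n_j)), referred to the studentized range
#' distribution with k groups and N - k error degrees of freedom (critical
#' values from the distribution function, not a table).
#'
#' @inheritParams scheffe
#' @return Tibble as [scheffe()].
#' @export
tukey_kramer <- function(values, groups, alphas = c(0.05, 0.01)) {
  aov1 <- one_way_anova(values, groups)
  k <- aov1$df_between + 1L
  pairs <- pairwise_grid(names(aov1$means))
  ns <- stats::setNames(aov1$ns, names(aov1$means))
  diff <- aov1$means[pairs$group1] - aov1$means[pairs$group2]
  q <- abs(diff) /
    sqrt(aov1$msw / 2 * (1 / ns[pairs$group1] + 1 / ns[pairs$group2]))
  p <- stats::ptukey(q, nmeans = k, df = aov1$df_within, lower.tail = FALSE)
  posthoc_table("tukey", pairs, as.numeric(diff), as.numeric(q),
                as.numeric(p), alphas)
}

posthoc_table <- function(method, pairs, diff, statistic, p, alphas) {
  out <- tibble::tibble(method = method, group1 = pairs$group1,
                        group2 = pairs$group2, diff = diff,
                        statistic = statistic, p = p)
  for (a in sort(alphas, decreasing = TRUE)) {
    out[[paste0("sig_", a)]] <- p < a
  }
  out
}
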