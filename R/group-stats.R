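#' Build group samples for replicate-level comparison
#'
#' @param ... named numeric vectors, one per group (wells are the unit of
#'   replication), or a single named list of numeric vectors.
#' @return a `group_samples` list of numeric vectors.
#' @export
group_samples <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) && !is.numeric(gs[[1]])) gs <- gs[[1]]
  if (is.null(names(gs)) || any(names(gs) == "")) {
    names(gs) <- paste0("group", seq_along(gs))
  }
  gs <- lapply(gs, as.numeric)
  structure(gs, class = "group_samples")
}

validate_groups <- function(groups, min_groups = 2) {
  if (inherits(groups, "group_samples")) groups <- unclass(groups)
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < min_groups) {
    stop_domain("need at least ", min_groups, " groups")
  }
  n <- vapply(groups, length, 0L)
  if (any(n < 2)) {
    stop_domain("every group needs n >= 2 for variance estimation")
  }
  groups
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F statistic with (k - 1, N - k)
#' degrees of freedom and its p value. When every observation is
#' identical the statistic is defined as F = 0, p = 1.
#'
#' @param groups a `group_samples` object, a named list of numeric
#'   vectors, or a long data.frame with columns `group` and `value`.
#' @return list with `F`, `p`, `df` (c(between, within)), `ms_within`,
#'   `group_means`, `n`.
#' @export
one_way_anova <- function(groups) {
  g <- validate_groups(groups)
  n <- vapply(g, length, 0L)
  k <- length(g)
  N <- sum(n)
  means <- vapply(g, mean, 0)
  grand <- sum(unlist(g)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  df1 <- k - 1; df2 <- N - k
  if (ssb <= 0 && ssw <= 0) {
    Fst <- 0; p <- 1
  } else if (ssw <= 0) {
    Fst <- Inf; p <- 0
  } else {
    Fst <- (ssb / df1) / (ssw / df2)
    p <- pf(Fst, df1, df2, lower.tail = FALSE)
  }
  list(F = Fst, p = p, df = c(df1, df2), ms_within = if (df2 > 0) ssw / df2 else NA_real_,
       group_means = means, n = n)
}

#' Tukey-Kramer multiple comparisons
#'
#' Studentized-range pairwise comparisons after one-way ANOVA, with the
#' Kramer correction for unequal group sizes: for groups i, j the
#' standard error is `sqrt(MSE/2 (1/ni + 1/nj))`, the adjusted p value
#' comes from the studentized range distribution with k groups and N - k
#' degrees of freedom, and the simultaneous confidence intervals use the
#' corresponding range quantile. With equal n this reduces to the plain
#' Tukey HSD.
#'
#' @inheritParams one_way_anova
#' @param level simultaneous confidence level for the intervals (default
#'   0.99, matching a significance threshold of 0.01).
#' @return a `comparison_report`: the ANOVA `F` and `p`, a `pairwise`
#'   data.frame (`comparison`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`), and the `level`.
#' @export
tukey_kramer <- function(groups, level = 0.99) {
  g <- validate_groups(groups, min_groups = 2)
  if (length(g) < 2) stop_domain("need at least 2 groups")
  aov1 <- one_way_anova(g)
  k <- length(g)
  df2 <- aov1$df[2]
  mse <- aov1$ms_within
  nm <- names(g)
  combs <- utils::combn(k, 2)
  qcrit <- qtukey(level, k, df2)
  rows <- apply(combs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- aov1$group_means[j] - aov1$group_means[i]
    se <- sqrt(mse / 2 * (1 / aov1$n[i] + 1 / aov1$n[j]))
    if (se == 0) {
      p <- if (d == 0) 1 else 0
      lwr <- d; upr <- d
    } else {
      p <- ptukey(abs(d) / se, k, df2, lower.tail = FALSE)
      lwr <- d - qcrit * se
      upr <- d + qcrit * se
    }
    data.frame(comparison = paste(nm[j], "-", nm[i]), diff = d,
               lwr = lwr, upr = upr, p_adj = p,
               significant = p < (1 - level),
               stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, rows)
  rownames(pairwise) <- NULL
  structure(list(F = aov1$F, p = aov1$p, pairwise = pairwise,
                 level = level),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> one-way ANOVA F = %.4g, p = %.4f\n",
              x$F, x$p))
  print(transform(x$pairwise, p_adj = round(p_adj, 4)))
  invisible(x)
}
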