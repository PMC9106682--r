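#' Hierarchical ("SuperPlot") per-cell summary
#'
#' Muscle cells, not myofibrils, are the unit of biological replication:
#' per-myofibril values are first averaged within each cell, and the overall
#' mean and standard error are computed over the cell means
#' (`SE = SD(cell means) / sqrt(n_cells)`; `NA` for a single cell).
#'
#' @param value numeric per-myofibril measurements.
#' @param cell cell identifier for every value (no missing entries).
#' @param group optional group label per value (constant within a cell).
#' @return list of class `superplot_table` with `cells` (cell_id, group,
#'   n_values, cell_mean) and `overall` (per group: mean, se, n_cells).
#' @export
superplot_table <- function(value, cell, group = NULL) {
  if (length(value) == 0L) stop("no values", call. = FALSE)
  if (length(cell) != length(value) || anyNA(cell)) {
    stop("every value must be tagged with a cell id", call. = FALSE)
  }
  if (anyNA(value)) stop("missing values are not allowed", call. = FALSE)
  if (is.null(group)) group <- rep("all", length(value))
  if (length(group) != length(value)) {
    stop("group must match values in length", call. = FALSE)
  }
  key <- paste(group, cell, sep = "\r")
  s <- split(seq_along(value), key)
  cells <- data.frame(
    cell_id = vapply(s, function(i) as.character(cell[i[1]]), character(1)),
    group = vapply(s, function(i) as.character(group[i[1]]), character(1)),
    n_values = vapply(s, length, integer(1)),
    cell_mean = vapply(s, function(i) mean(value[i]), numeric(1)),
    row.names = NULL)
  g <- split(seq_len(nrow(cells)), cells$group)
  overall <- data.frame(
    group = names(g),
    mean = vapply(g, function(i) mean(cells$cell_mean[i]), numeric(1)),
    se = vapply(g, function(i) {
      n <- length(i)
      if (n < 2L) NA_real_ else stats::sd(cells$cell_mean[i]) / sqrt(n)
    }, numeric(1)),
    n_cells = vapply(g, length, integer(1)),
    row.names = NULL)
  structure(list(cells = cells, overall = overall),
            class = "superplot_table")
}

#' @export
print.superplot_table <- function(x, ...) {
  cat("<superplot_table> ", nrow(x$cells), " cells\n", sep = "")
  print(x$overall, row.names = FALSE)
  invisible(x)
}

# Brown-Forsythe test of variance equality: one-way ANOVA on absolute
# deviations from the group medians
brown_forsythe_test <- function(groups) {
  z <- unlist(lapply(groups, function(x) abs(x - stats::median(x))))
  g <- factor(rep(names(groups), lengths(groups)))
  if (length(unique(round(z, 12))) == 1L) {
    return(list(statistic = 0, p_value = 1))
  }
  fit <- stats::oneway.test(z ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

# Dunn's rank-based all-pairs comparisons with tie correction and
# family-wise (Bonferroni) adjustment
dunn_test <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)                             # average ranks: deterministic
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(p) {
    z <- (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt(s2 * (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             statistic = res["z", ],
             p_value = res["p", ],
             p_adjusted = pmin(1, res["p", ] * ncol(pairs)),
             row.names = NULL)
}

#' Compare muscle groups with the variance-gated decision tree
#'
#' For more than two groups: one-way ANOVA, with a Brown-Forsythe test
#' gating the post hoc branch -- Tukey's HSD when group variances are
#' compatible, Dunn's all-pairs rank comparisons (Bonferroni family-wise
#' correction) when they differ. For two groups: Shapiro-Wilk normality
#' gates between the two-sided independent t-test and the rank-based
#' fallback. The fallback is implemented as the independent-samples
#' Wilcoxon rank-sum test (a signed-rank test would require paired data;
#' the divergence is recorded in the result's `notes`). Alpha is 0.05
#' throughout. All branches are deterministic; `seed` is accepted for
#' interface uniformity.
#'
#' @param groups named list (>= 2) of numeric vectors of cell means.
#' @param alpha significance level for the gates (0.05).
#' @param seed unused (kept for reproducible-pipeline call signatures).
#' @return object of class `group_comparison`: per-group summary, the gate
#'   p-values, chosen `branch` (`"tukey"`, `"dunn"`, `"t_test"`,
#'   `"wilcoxon"`, or `"descriptive"` when any group has < 2 values),
#'   `pairwise` p-value table, `alpha`, `notes`.
#' @export
compare_groups <- function(groups, alpha = 0.05, seed = 1L) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  groups <- lapply(groups, as.numeric)
  summary_df <- data.frame(
    group = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    se = vapply(groups, function(x)
      if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x)),
      numeric(1)),
    row.names = NULL)
  notes <- character()
  res <- list(summary = summary_df, alpha = alpha, anova_p = NA_real_,
              variance_test_p = NA_real_, normality_p = NA_real_,
              pairwise = NULL)
  if (any(lengths(groups) < 2L)) {
    res$branch <- "descriptive"
    res$notes <- "a group has < 2 replicates: descriptive output only"
    class(res) <- "group_comparison"
    return(res)
  }
  if (length(groups) == 2L) {
    sw <- vapply(groups, function(x) {
      if (length(x) < 3L || length(unique(x)) == 1L) NA_real_
      else stats::shapiro.test(x)$p.value
    }, numeric(1))
    res$normality_p <- sw
    normal <- all(!is.na(sw)) && all(sw > alpha)
    if (any(is.na(sw))) {
      notes <- c(notes, "normality untestable (n < 3 or constant): using the rank-based branch")
    }
    if (normal) {
      tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      res$branch <- "t_test"
      pw <- data.frame(group1 = names(groups)[1], group2 = names(groups)[2],
                       statistic = unname(tt$statistic),
                       p_value = tt$p.value, p_adjusted = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                                exact = FALSE))
      res$branch <- "wilcoxon"
      notes <- c(notes,
                 "rank-based fallback uses the independent-samples rank-sum test")
      pw <- data.frame(group1 = names(groups)[1], group2 = names(groups)[2],
                       statistic = unname(wt$statistic),
                       p_value = wt$p.value, p_adjusted = wt$p.value)
    }
    res$pairwise <- pw
  } else {
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)))
    fit <- stats::aov(x ~ g)
    res$anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    bf <- brown_forsythe_test(groups)
    res$variance_test_p <- bf$p_value
    if (bf$p_value <= alpha) {
      res$branch <- "dunn"
      res$pairwise <- dunn_test(groups)
    } else {
      res$branch <- "tukey"
      th <- stats::TukeyHSD(fit)$g
      nm <- strsplit(rownames(th), "-", fixed = TRUE)
      res$pairwise <- data.frame(
        group1 = vapply(nm, `[`, character(1), 2),
        group2 = vapply(nm, `[`, character(1), 1),
        statistic = th[, "diff"],
        p_value = th[, "p adj"],
        p_adjusted = th[, "p adj"], row.names = NULL)
    }
  }
  res$notes <- notes
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> branch: ", x$branch, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (!is.na(x$anova_p)) cat("  one-way ANOVA p = ", format.pval(x$anova_p),
                             "; Brown-Forsythe p = ",
                             format.pval(x$variance_test_p), "\n", sep = "")
  if (!is.null(x$pairwise)) {
    cat("  pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}
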