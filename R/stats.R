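#' One-way ANOVA across groups
#'
#' Classic (equal-variance) one-way ANOVA. Degenerate inputs are
#' resolved explicitly: zero between-group variance gives F = 0, p = 1;
#' zero within-group variance with distinct group means gives F = Inf
#' and p reported as the smallest positive double rather than NaN.
#'
#' @param values_by_group named list of numeric vectors (>= 2 groups,
#'   each with >= 2 observations).
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values_by_group) {
  if (length(values_by_group) < 2) stopf("need at least 2 groups")
  ns <- vapply(values_by_group, length, integer(1))
  small <- names(values_by_group)[ns < 2]
  if (length(small))
    stopf("group '%s' has fewer than 2 observations", small[1])
  g_means <- vapply(values_by_group, mean, numeric(1))
  grand <- sum(g_means * ns) / sum(ns)
  ss_b <- sum(ns * (g_means - grand)^2)
  ss_w <- sum(vapply(values_by_group, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- length(values_by_group) - 1L
  df_w <- sum(ns) - length(values_by_group)
  if (ss_b <= 0) return(list(F = 0, p = 1, df_between = df_b, df_within = df_w))
  if (ss_w <= 0)
    return(list(F = Inf, p = .Machine$double.xmin, df_between = df_b, df_within = df_w))
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(F = f, p = pf(f, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Recomputes the F statistic from group sizes, means and SDs via the
#' standard sum-of-squares decomposition — algebraically identical to
#' [anova_oneway()] on the raw data and usable when only summaries are
#' available.
#'
#' @param n,means,sds equal-length vectors of group sizes, means, SDs.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_from_summary <- function(n, means, sds) {
  stopifnot(length(n) == length(means), length(n) == length(sds))
  grand <- sum(means * n) / sum(n)
  ss_b <- sum(n * (means - grand)^2)
  ss_w <- sum((n - 1) * sds^2)
  df_b <- length(n) - 1L
  df_w <- sum(n) - length(n)
  if (ss_b <= 0) return(list(F = 0, p = 1, df_between = df_b, df_within = df_w))
  if (ss_w <= 0)
    return(list(F = Inf, p = .Machine$double.xmin, df_between = df_b, df_within = df_w))
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(F = f, p = pf(f, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w)
}

#' Holm step-down adjustment
#'
#' Explicit implementation of Holm's procedure: order the m raw
#' p-values increasingly, multiply the i-th by (m - i + 1), enforce
#' monotonicity by a running maximum, and cap at 1.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Post-hoc pairwise comparisons
#'
#' `method = "holm"` (default): Welch two-sample t tests for every group
#' pair with Holm step-down adjustment. `method = "tukey"`: Tukey's HSD
#' on the classic one-way fit (adjusted p from the studentized range).
#' Pair labels are sorted so results are invariant to group order.
#'
#' @param values_by_group named list of numeric vectors.
#' @param method "holm" or "tukey".
#' @return data.frame with `pair`, `group1`, `group2`, `diff`, `raw_p`,
#'   `adj_p`, `method`.
#' @export
posthoc_pairwise <- function(values_by_group, method = c("holm", "tukey")) {
  method <- match.arg(method)
  gs <- sort(names(values_by_group))
  if (length(gs) < 2) stopf("need at least 2 groups")
  pairs <- utils::combn(gs, 2)
  if (method == "holm") {
    res <- apply(pairs, 2, function(pr) {
      tt <- t.test(values_by_group[[pr[1]]], values_by_group[[pr[2]]])
      c(diff = unname(diff(rev(tt$estimate))), p = tt$p.value)
    })
    out <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                      group1 = pairs[1, ], group2 = pairs[2, ],
                      diff = res["diff", ], raw_p = res["p", ],
                      adj_p = holm_adjust(res["p", ]),
                      method = "holm")
  } else {
    df <- data.frame(
      value = unlist(values_by_group, use.names = FALSE),
      group = factor(rep(names(values_by_group),
                         vapply(values_by_group, length, integer(1))),
                     levels = gs))
    tk <- TukeyHSD(aov(value ~ group, data = df))$group
    # TukeyHSD labels pairs "b-a" with b later in factor order
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    g1 <- vapply(nm, function(x) sort(x)[1], character(1))
    g2 <- vapply(nm, function(x) sort(x)[2], character(1))
    out <- data.frame(pair = paste(g1, g2, sep = "-"), group1 = g1, group2 = g2,
                      diff = -tk[, "diff"], raw_p = tk[, "p adj"],
                      adj_p = tk[, "p adj"], method = "tukey")
    out <- out[order(out$pair), ]
  }
  rownames(out) <- NULL
  out
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction (the common default for r x c tables);
#' flags the result when any expected count is below 5.
#'
#' @param counts_table matrix of non-negative integer counts.
#' @return list with `statistic`, `p`, `df`, `expected`,
#'   `low_expected_counts` (logical flag).
#' @export
chi_square_categorical <- function(counts_table) {
  m <- as.matrix(counts_table)
  if (any(m < 0) || any(m != round(m))) stopf("counts must be non-negative integers")
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  low <- any(res$expected < 5)
  if (low) warnf("expected counts below 5; chi-squared approximation is doubtful")
  list(statistic = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), expected = res$expected,
       low_expected_counts = low)
}

#' Normal quantile-quantile report
#'
#' Emits theoretical-vs-empirical normal quantile pairs for visual
#' normality assessment (no automatic rejection), with the slope and
#' intercept of the quartile line.
#'
#' @param values numeric vector, n >= 2.
#' @return data.frame (`theoretical`, `empirical`) with attributes
#'   `slope`, `intercept`, `degenerate` (TRUE for constant samples).
#' @export
qq_report <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stopf("need at least 2 values for a QQ report")
  emp <- sort(values)
  theo <- qnorm(ppoints(length(emp)))
  degenerate <- sd(emp) == 0
  if (degenerate) {
    slope <- 0; intercept <- emp[1]
  } else {
    qy <- quantile(emp, c(0.25, 0.75), type = 7)
    qx <- qnorm(c(0.25, 0.75))
    slope <- diff(qy) / diff(qx)
    intercept <- qy[1] - slope * qx[1]
  }
  out <- data.frame(theoretical = theo, empirical = emp)
  attr(out, "slope") <- unname(slope)
  attr(out, "intercept") <- unname(intercept)
  attr(out, "degenerate") <- degenerate
  out
}

#' Significance stars
#'
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p numeric vector of (adjusted) p-values.
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x < 1e-4) "****"
    else if (x < 1e-3) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Compare one feature across groups
#'
#' Group means +/- SD, one-way ANOVA, and adjusted pairwise
#' comparisons for a single feature.
#'
#' @param values_by_group named list of numeric vectors.
#' @param feature_name label.
#' @param method post-hoc method ("holm" or "tukey").
#' @return object of class `group_comparison`.
#' @export
compare_groups <- function(values_by_group, feature_name = "feature",
                           method = "holm") {
  an <- anova_oneway(values_by_group)
  pw <- posthoc_pairwise(values_by_group, method = method)
  pw$stars <- significance_stars(pw$adj_p)
  gm <- data.frame(group = names(values_by_group),
                   n = vapply(values_by_group, length, integer(1)),
                   mean = vapply(values_by_group, mean, numeric(1)),
                   sd = vapply(values_by_group, sd, numeric(1)))
  rownames(gm) <- NULL
  structure(list(feature_name = feature_name, group_means_sds = gm,
                 anova_F = an$F, anova_p = an$p, pairwise = pw,
                 adjust_method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: ANOVA F = %.3f, p = %.3g (%s post-hoc)\n",
              x$feature_name, x$anova_F, x$anova_p, x$adjust_method))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %s: adj p = %.3g %s\n", x$pairwise$pair[i],
                x$pairwise$adj_p[i], x$pairwise$stars[i]))
  invisible(x)
}

#' Full group-comparison report
#'
#' Runs [compare_groups()] for every requested feature of the
#' per-subject table (statistical unit: subject) and the per-cell
#' morphometry table (statistical unit: cell), writes one CSV per
#' feature plus a JSON summary when `outdir` is given, and draws
#' box/violin plots. Features with fewer than 2 groups present are
#' skipped with a warning.
#'
#' @param subject_summaries data.frame with `group` plus subject-level
#'   feature columns (e.g. `mean_gp`, covariates).
#' @param cell_table data.frame with `group` plus cell-level feature
#'   columns (e.g. `n_domains`, `mean_feret_um`, `mean_circularity`).
#' @param subject_features,cell_features character vectors of columns to
#'   compare.
#' @param method post-hoc method.
#' @param outdir optional output directory for CSV/JSON/plots.
#' @return named list of `group_comparison` objects plus `plots` (named
#'   list of ggplot objects).
#' @export
full_report <- function(subject_summaries, cell_table = NULL,
                        subject_features = "mean_gp",
                        cell_features = c("n_domains", "mean_feret_um",
                                          "mean_circularity"),
                        method = "holm", outdir = NULL) {
  comps <- list()
  plots <- list()
  harvest <- function(df, feature, unit) {
    if (is.null(df) || !feature %in% names(df)) return(NULL)
    d <- df[!is.na(df[[feature]]), c("group", feature)]
    vb <- split(d[[feature]], d$group)
    vb <- vb[vapply(vb, length, integer(1)) >= 2]
    if (length(vb) < 2) {
      warnf("feature '%s' skipped: fewer than 2 groups with data", feature)
      return(NULL)
    }
    cmp <- compare_groups(vb, feature_name = feature, method = method)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data[[feature]],
                                         fill = .data$group)) +
      (if (unit == "subject") ggplot2::geom_boxplot()
       else ggplot2::geom_violin()) +
      ggplot2::labs(title = feature, x = NULL) +
      ggplot2::theme_minimal() + ggplot2::theme(legend.position = "none")
    list(cmp = cmp, plot = p)
  }
  for (f in subject_features) {
    h <- harvest(subject_summaries, f, "subject")
    if (!is.null(h)) { comps[[f]] <- h$cmp; plots[[f]] <- h$plot }
  }
  for (f in cell_features) {
    h <- harvest(cell_table, f, "cell")
    if (!is.null(h)) { comps[[f]] <- h$cmp; plots[[f]] <- h$plot }
  }
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    summary_list <- list()
    for (f in names(comps)) {
      cmp <- comps[[f]]
      tab <- merge(cmp$group_means_sds,
                   data.frame(feature = f), by = NULL)
      write.csv(tab, file.path(outdir, paste0(f, ".csv")), row.names = FALSE,
                fileEncoding = "UTF-8")
      summary_list[[f]] <- list(anova_F = cmp$anova_F, anova_p = cmp$anova_p,
                                pairwise = cmp$pairwise)
      ggplot2::ggsave(file.path(outdir, paste0(f, ".png")), plots[[f]],
                      width = 4, height = 4, dpi = 150)
    }
    jsonlite::write_json(summary_list, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  c(comps, list(plots = plots))
}

#' Power of the DM vs DM+PAD GP comparison by simulation
#'
#' Simulates subject-level GP cohorts at the preset effect sizes and
#' cohort sizes, applies ANOVA + Holm-adjusted pairwise tests, and
#' returns the fraction of replicates in which the stated pair reaches
#' adjusted p < alpha — a detectability check of the design, performed
#' at the subject level (no image simulation).
#'
#' @param presets list of [group_preset()]s.
#' @param n_reps number of simulation replicates.
#' @param seed RNG seed.
#' @param pair character(2): the groups whose comparison is scored.
#' @param alpha significance level.
#' @return list with `fraction_significant`, `n_reps`, `adj_p` (vector).
#' @export
gp_power_replicates <- function(presets = group_presets(), n_reps = 100L,
                                seed = 1L, pair = c("DM", "DM_PAD"),
                                alpha = 0.05) {
  pair_lab <- paste(sort(pair), collapse = "-")
  adj <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    vb <- lapply(presets, function(p)
      rnorm(p$n_subjects, p$mean_gp, p$subject_sd_gp))
    names(vb) <- vapply(presets, `[[`, character(1), "group_name")
    pw <- posthoc_pairwise(vb, method = "holm")
    pw$adj_p[pw$pair == pair_lab]
  }, numeric(1)))
  list(fraction_significant = mean(adj < alpha), n_reps = n_reps, adj_p = adj)
}
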