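test_that("ANOVA handles identical groups and degenerate variances", {
  an <- anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
  an2 <- anova_oneway(list(a = c(0, 0, 0), b = c(1, 1, 1)))
  expect_true(is.infinite(an2$F))
  expect_false(is.nan(an2$p))
  expect_gt(an2$p, 0)
  expect_lte(an2$p, .Machine$double.xmin)
  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "'a'")
  expect_error(anova_oneway(list(a = c(1, 2))), "2 groups")
})

test_that("ANOVA equals the summary-statistics decomposition and base aov", {
  set.seed(21)
  for (k in 1:20) {
    vb <- lapply(1:3, function(i) rnorm(sample(3:30, 1), mean = i * runif(1)))
    names(vb) <- c("a", "b", "c")
    an <- anova_oneway(vb)
    an2 <- anova_from_summary(vapply(vb, length, integer(1)),
                              vapply(vb, mean, numeric(1)),
                              vapply(vb, sd, numeric(1)))
    expect_equal(an$F, an2$F, tolerance = 1e-10)
    expect_equal(an$p, an2$p, tolerance = 1e-10)
    # independent oracle: base R aov
    df <- data.frame(v = unlist(vb), g = rep(names(vb), lengths(vb)))
    ref <- summary(aov(v ~ g, df))[[1]]
    expect_equal(an$F, ref[1, "F value"], tolerance = 1e-8)
  }
})

test_that("ANOVA is invariant to constant shifts and group relabeling", {
  set.seed(5)
  vb <- list(x = rnorm(8, 1), y = rnorm(9, 1.5), z = rnorm(10, 2))
  f0 <- anova_oneway(vb)$F
  expect_equal(anova_oneway(lapply(vb, `+`, 17.3))$F, f0, tolerance = 1e-10)
  expect_equal(anova_oneway(vb[c(3, 1, 2)])$F, f0, tolerance = 1e-12)
})

test_that("Holm adjustment matches the hand-computed step-down and p.adjust", {
  # step-down: 3*0.01, max(2*0.02, 0.03), max(1*0.04, 0.04)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(c(0.04, 0.01, 0.02)), c(0.04, 0.03, 0.04))
  set.seed(31)
  for (k in 1:50) {
    p <- runif(sample(1:8, 1))
    expect_equal(holm_adjust(p), p.adjust(p, "holm"), tolerance = 1e-15)
  }
  # monotone in raw p and bounded by 1
  p <- sort(runif(6))
  a <- holm_adjust(p)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= p & a <= 1))
})

test_that("pairwise post-hoc: identity for two groups, label invariance, Tukey", {
  set.seed(41)
  vb2 <- list(a = rnorm(10), b = rnorm(10, 1))
  pw2 <- posthoc_pairwise(vb2, "holm")
  expect_equal(pw2$adj_p, pw2$raw_p)
  vb3 <- list(a = rnorm(10), b = rnorm(10, 0.5), c = rnorm(10, 1))
  pw <- posthoc_pairwise(vb3, "holm")
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$adj_p >= pw$raw_p))
  pw_perm <- posthoc_pairwise(vb3[c(2, 3, 1)], "holm")
  expect_equal(pw$adj_p, pw_perm$adj_p[match(pw$pair, pw_perm$pair)])
  tk <- posthoc_pairwise(vb3, "tukey")
  expect_equal(sort(tk$pair), sort(pw$pair))
  expect_true(all(tk$method == "tukey"))
  expect_error(posthoc_pairwise(vb3, "bonferroni"))
})

test_that("chi-squared matches the direct formula and flags sparse tables", {
  res0 <- chi_square_categorical(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # identical proportions across groups
  tbl <- rbind(c(20, 40, 60), c(10, 20, 30))
  expect_equal(chi_square_categorical(tbl)$statistic, 0, tolerance = 1e-12)
  # direct-formula oracle: [[20,5],[5,20]] -> all E = 12.5, sum (O-E)^2/E = 18
  res <- chi_square_categorical(matrix(c(20, 5, 5, 20), 2))
  expect_equal(res$statistic, 18)
  expect_warning(chi_square_categorical(matrix(c(3, 2, 2, 3), 2)), "below 5")
  expect_error(chi_square_categorical(matrix(c(-1, 2, 2, 3), 2)), "non-negative")
})

test_that("QQ reports have unit slope for normal samples and flag degeneracy", {
  set.seed(51)
  q <- qq_report(rnorm(1000))
  expect_equal(attr(q, "slope"), 1, tolerance = 0.1)
  expect_equal(nrow(q), 1000)
  qc <- qq_report(rep(2, 10))
  expect_true(attr(qc, "degenerate"))
  expect_error(qq_report(5), "at least 2")
})

test_that("significance stars follow the reporting convention", {
  expect_equal(significance_stars(c(0.008, 0.03, 0.5, 5e-5, 5e-4)),
               c("**", "*", "ns", "****", "***"))
})

test_that("group comparison bundles means, ANOVA and pairwise results", {
  set.seed(61)
  vb <- list(CTRL = rnorm(10, 0.534, 0.018), DM = rnorm(12, 0.519, 0.007),
             DM_PAD = rnorm(15, 0.501, 0.026))
  cmp <- compare_groups(vb, "mean_gp")
  expect_equal(nrow(cmp$pairwise), 3)
  expect_equal(cmp$group_means_sds$n, c(10L, 12L, 15L))
  expect_true(all(c("CTRL-DM", "CTRL-DM_PAD", "DM-DM_PAD") %in% cmp$pairwise$pair))
})

test_that("full report covers requested features and skips missing groups", {
  set.seed(71)
  subj <- data.frame(group = rep(c("CTRL", "DM", "DM_PAD"), times = c(5, 5, 5)),
                     mean_gp = rnorm(15, 0.52, 0.02),
                     hba1c = rnorm(15, 6.5, 1))
  cells <- data.frame(group = rep(c("CTRL", "DM"), each = 10),
                      n_domains = rpois(20, 50),
                      mean_feret_um = runif(20, 0.2, 1),
                      mean_circularity = runif(20, 0.6, 1),
                      only_ctrl = c(rnorm(10), rep(NA, 10)))
  outdir <- tempfile()
  rep <- suppressWarnings(
    full_report(subj, cells, subject_features = c("mean_gp", "hba1c"),
                cell_features = c("n_domains", "only_ctrl"), outdir = outdir))
  expect_true(all(c("mean_gp", "hba1c", "n_domains") %in% names(rep)))
  expect_false("only_ctrl" %in% names(rep))   # single-group feature skipped
  expect_equal(nrow(rep$mean_gp$pairwise), 3)
  expect_true(file.exists(file.path(outdir, "summary.json")))
  expect_true(file.exists(file.path(outdir, "mean_gp.csv")))
  expect_true(file.exists(file.path(outdir, "mean_gp.png")))
})

test_that("power replicates are deterministic given the seed", {
  a <- gp_power_replicates(n_reps = 30, seed = 5)
  b <- gp_power_replicates(n_reps = 30, seed = 5)
  expect_identical(a$adj_p, b$adj_p)
  expect_true(a$fraction_significant >= 0 && a$fraction_significant <= 1)
})
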