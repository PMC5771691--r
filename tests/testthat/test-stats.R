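test_that("pooled t from summaries matches the published cortex comparison", {
  res <- t_test_two_sample(
    nhe6_cell("thickness", "cortex", 22, "WT"),
    nhe6_cell("thickness", "cortex", 22, "MUT")
  )
  expect_equal(res$statistic, 3.5158, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p.value, 0.0245, tolerance = 5e-3)

  same <- t_test_two_sample(summary_cell(1, 0.1, 3), summary_cell(1, 0.1, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("raw-mode t equals summary-mode t and stats::t.test, both variants", {
  set.seed(5)
  a <- rnorm(6, 10, 2)
  b <- rnorm(4, 8, 1)
  raw <- t_test_two_sample(a, b)
  summ <- t_test_two_sample(
    summary_cell(mean(a), sd(a) / sqrt(6), 6),
    summary_cell(mean(b), sd(b) / sqrt(4), 4)
  )
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$p.value, summ$p.value, tolerance = 1e-12)

  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(raw$p.value, ref$p.value, tolerance = 1e-12)

  welch <- t_test_two_sample(a, b, var_equal = FALSE)
  refw <- stats::t.test(a, b)
  expect_equal(welch$statistic, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-12)
  expect_equal(welch$p.value, refw$p.value, tolerance = 1e-12)
})

test_that("degenerate t inputs are handled explicitly", {
  expect_warning(res <- t_test_two_sample(c(1, 1, 1), c(2, 2, 2)),
    "zero pooled variance")
  expect_equal(res$p.value, 0)
  expect_error(t_test_two_sample(1, 2))
  expect_error(t_test_two_sample(summary_cell(1, 0, 1), summary_cell(2, 0, 1)))
})

test_that("one-way ANOVA from summaries reproduces the published region effect", {
  cells <- tibble::tibble(
    region = c("primary_fissure", "anterior_lobe", "flocculonodular_lobe"),
    mean = c(1.02, 0.84, 3.24), sem = c(0.38, 0.58, 0.54), n = 3L
  )
  fit <- one_way_anova_tukey(cells)
  tab <- tidy(fit)
  expect_equal(tab$statistic[1], 6.94, tolerance = 1e-3)
  expect_equal(tab$df, c(2, 6))
  expect_equal(tab$p.value[1], 0.0275, tolerance = 1e-3)
  expect_equal(sum(tab$pct_total_variance), 100, tolerance = 1e-9)
  expect_equal(nrow(fit$tukey), 3)

  expect_error(
    one_way_anova_tukey(tibble::tibble(mean = c(1, 2), sem = c(0, 0.1),
      n = c(1L, 3L))),
    "n >= 2"
  )
})

test_that("one-way ANOVA raw mode agrees with aov/TukeyHSD and summary mode", {
  set.seed(9)
  groups <- list(a = rnorm(5, 1), b = rnorm(4, 1.4), c = rnorm(6, 0.7))
  fit <- one_way_anova_tukey(groups)

  df <- data.frame(
    g = factor(rep(names(groups), lengths(groups))),
    y = unlist(groups)
  )
  ref <- aov(y ~ g, data = df)
  ref_tab <- summary(ref)[[1]]
  expect_equal(fit$anova$statistic[1], ref_tab$`F value`[1], tolerance = 1e-10)
  expect_equal(fit$anova$p.value[1], ref_tab$`Pr(>F)`[1], tolerance = 1e-10)

  ref_tukey <- as.data.frame(stats::TukeyHSD(ref)$g)
  ours <- fit$tukey
  key <- paste(ours$group2, ours$group1, sep = "-")  # aov orders by level
  expect_equal(unname(sort(ref_tukey[key, "p adj"])),
    unname(sort(ours$adj.p.value)), tolerance = 1e-8)

  summ <- one_way_anova_tukey(tibble::tibble(
    g = names(groups),
    mean = vapply(groups, mean, 1),
    sem = vapply(groups, function(x) sd(x) / sqrt(length(x)), 1),
    n = lengths(groups)
  ))
  expect_equal(summ$anova$statistic[1], fit$anova$statistic[1],
    tolerance = 1e-12)
  expect_equal(summ$tukey$adj.p.value, fit$tukey$adj.p.value,
    tolerance = 1e-12)
})

test_that("identical groups give F = 0 and Tukey p = 1", {
  cells <- tibble::tibble(g = c("a", "b", "c"), mean = 2, sem = 0.3, n = 4L)
  fit <- one_way_anova_tukey(cells)
  expect_equal(fit$anova$statistic[1], 0)
  expect_equal(fit$tukey$adj.p.value, rep(1, 3))
})

test_that("balanced two-way ANOVA reproduces the published genotype effect", {
  cells <- tibble::tibble(
    genotype = rep(c("WT", "MUT"), 2),
    age = rep(c(2, 22), each = 2),
    mean = c(1.154, 1.126, 1.210, 1.090),
    sem = c(0.018, 0.029, 0.029, 0.018),
    n = 3L
  )
  fit <- two_way_anova_tukey(cells, a = "genotype", b = "age")
  tab <- tidy(fit)
  geno <- tab[tab$term == "genotype", ]
  expect_equal(geno$statistic, 9.401, tolerance = 1e-3)
  expect_equal(geno$df, 1)
  expect_equal(tab[tab$term == "residual", ]$df, 8)
  expect_equal(geno$pct_total_variance, 44.33, tolerance = 1e-3)
  expect_equal(sum(tab$pct_total_variance), 100, tolerance = 1e-9)
  # post hoc cell comparisons exist for all 6 pairs
  expect_equal(nrow(fit$tukey), 6)

  # all-equal cells: every F is 0
  flat <- two_way_anova_tukey(tibble::tibble(
    a = rep(c("x", "y"), 2), b = rep(c(1, 2), each = 2),
    mean = 5, sem = 0.2, n = 3L
  ))
  expect_equal(tidy(flat)$statistic[1:3], rep(0, 3))

  expect_error(
    two_way_anova_tukey(cells[-1, ], a = "genotype", b = "age"),
    "incomplete"
  )
  expect_error(
    two_way_anova_tukey(dplyr::mutate(cells, n = c(1L, 3L, 3L, 3L)),
      a = "genotype", b = "age"),
    "n >= 2"
  )
})

test_that("balanced decomposition equals Type III; unbalanced matches car", {
  set.seed(21)
  raw <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"),
    i = 1:4)
  raw$value <- rnorm(nrow(raw), 1 + (raw$a == "x") * 0.5 + (raw$b == "u") * 0.2)
  fit <- two_way_anova_tukey(raw)
  d <- raw
  d$fa <- factor(d$a); d$fb <- factor(d$b)
  m <- lm(value ~ fa * fb, data = d,
    contrasts = list(fa = "contr.sum", fb = "contr.sum"))
  ref <- car::Anova(m, type = 3)
  expect_equal(fit$anova$sumsq[1:3],
    ref$`Sum Sq`[rownames(ref) %in% c("fa", "fb", "fa:fb")],
    tolerance = 1e-10)

  # unbalanced: drop two observations, Type III route
  raw_u <- raw[-c(1, 6), ]
  fit_u <- two_way_anova_tukey(raw_u)
  d <- raw_u
  d$fa <- factor(d$a); d$fb <- factor(d$b)
  m <- lm(value ~ fa * fb, data = d,
    contrasts = list(fa = "contr.sum", fb = "contr.sum"))
  ref <- car::Anova(m, type = 3)
  expect_equal(fit_u$anova$sumsq[1:3],
    ref$`Sum Sq`[rownames(ref) %in% c("fa", "fb", "fa:fb")],
    tolerance = 1e-10)
  expect_match(fit_u$method, "Type III")

  # summary mode on the realized summaries reproduces the raw result
  summ <- raw_u |>
    dplyr::group_by(a, b) |>
    dplyr::summarise(mean = mean(value), sem = sd(value) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
  fit_s <- two_way_anova_tukey(summ)
  expect_equal(fit_s$anova$sumsq, fit_u$anova$sumsq, tolerance = 1e-9)
  expect_equal(fit_s$anova$p.value, fit_u$anova$p.value, tolerance = 1e-9)
})

test_that("slope comparison reproduces the published trajectory slopes", {
  # observations realizing the published cortex-thickness summaries
  wt <- c(realize_values(1.154, 0.018 * sqrt(3), 3),
          realize_values(1.210, 0.029 * sqrt(3), 3))
  mut <- c(realize_values(1.126, 0.029 * sqrt(3), 3),
           realize_values(1.090, 0.018 * sqrt(3), 3))
  obs <- tibble::tibble(
    group = rep(c("WT", "MUT"), each = 6),
    age = rep(rep(c(2, 22), each = 3), 2),
    value = c(wt, mut)
  )
  res <- slope_compare(obs)
  sl <- res$slopes
  expect_equal(sl$slope[sl$group == "WT"], 0.0028, tolerance = 1e-10)
  expect_equal(sl$se[sl$group == "WT"], 0.0017, tolerance = 2e-2)
  expect_equal(sl$slope[sl$group == "MUT"], -0.0018, tolerance = 1e-10)
  expect_gt(res$comparison$p.value, 0.05)  # published: not significant

  # unbalanced two-cluster slope equals delta-mean over delta-age
  mutcb <- tibble::tibble(
    group = c(rep("WT", 5), rep("MUT", 7)),
    age = c(2, 2, 2, 22, 22, 2, 2, 2, 22, 22, 22, 22),
    value = c(realize_values(6.53, 0.15 * sqrt(3), 3),
              realize_values(7.128, 0.014 * sqrt(2), 2),
              realize_values(5.91, 0.16 * sqrt(3), 3),
              realize_values(4.586, 0.089 * sqrt(4), 4))
  )
  res2 <- slope_compare(mutcb)
  sl2 <- res2$slopes
  expect_equal(sl2$slope[sl2$group == "MUT"], (4.586 - 5.91) / 20,
    tolerance = 1e-10)
  expect_lt(res2$comparison$p.value, 0.0001)

  # identical groups: zero difference, p = 1
  dup <- obs
  dup$group <- rep(c("g1", "g2"), 6)
  dup$value <- rep(obs$value[1:6], each = 2)
  dup$age <- rep(obs$age[1:6], each = 2)
  res3 <- slope_compare(dup)
  expect_equal(res3$comparison$estimate, 0, tolerance = 1e-12)
  expect_equal(res3$comparison$p.value, 1, tolerance = 1e-9)

  expect_error(
    slope_compare(tibble::tibble(group = c("a", "a", "b", "b"),
      age = c(1, 1, 1, 2), value = 1:4)),
    "single age"
  )
})

test_that("t and F are invariant to relabeling and affine unit rescaling", {
  set.seed(33)
  a <- rnorm(5, 2, 0.5)
  b <- rnorm(5, 2.5, 0.5)
  base <- t_test_two_sample(a, b)
  scaled <- t_test_two_sample(10 * a + 3, 10 * b + 3)
  expect_equal(base$p.value, scaled$p.value, tolerance = 1e-12)
  flipped <- t_test_two_sample(b, a)
  expect_equal(abs(base$statistic), abs(flipped$statistic), tolerance = 1e-12)

  groups <- list(g1 = a, g2 = b, g3 = rnorm(5, 2.2, 0.5))
  f1 <- one_way_anova_tukey(groups)$anova$p.value[1]
  f2 <- one_way_anova_tukey(rev(lapply(groups, function(x) 4 * x - 1)))$anova$p.value[1]
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("p_stars bins follow the reporting thresholds", {
  expect_equal(
    p_stars(c(0.2, 0.05, 0.01, 0.001, 0.0001, NA)),
    c("", "*", "**", "***", "****", "")
  )
})
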