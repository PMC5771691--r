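#' Two-sample t test from raw values or summary cells
#'
#' Two-tailed Student's t test between two groups, runnable either from raw
#' values or from published (mean, SEM, n) cells; group SDs are reconstructed
#' from summaries as `SEM * sqrt(n)`, so the two input modes agree to machine
#' precision whenever the raw data realize the summary. The default is the
#' pooled-variance Student t with `df = n_a + n_b - 2`; `var_equal = FALSE`
#' selects the Welch variant (Satterthwaite df).
#'
#' If the pooled variance is exactly zero while the means differ, the null
#' is contradicted by constant data; the test reports `p = 0` with a
#' warning. Two groups of one value each carry no variance information and
#' raise an error.
#'
#' @param a,b Numeric vectors of raw values, or one-row summary cells (see
#'   [summary_cell()]).
#' @param var_equal Pool the variances (classical Student t, default) or use
#'   the Welch correction.
#' @return A one-row tibble of class `btj_test`: `statistic`,
#'   `statistic_name` ("t"), `df`, `p.value`, `tails`, `estimate` (mean
#'   difference a - b), `method`.
#' @export
#' @examples
#' t_test_two_sample(summary_cell(1.210, 0.029, 3), summary_cell(1.090, 0.018, 3))
t_test_two_sample <- function(a, b, var_equal = TRUE) {
  sa <- .suff_stats(a, "a")
  sb <- .suff_stats(b, "b")
  if (sa$n + sb$n < 3) abort("need n_a + n_b >= 3 observations")
  if (sa$n == 1 && sb$n == 1) abort("both groups have n = 1; no variance information")
  est <- sa$mean - sb$mean
  if (var_equal) {
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / (sa$n + sb$n - 2)
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
    method <- "Two-tailed Student's t test (pooled variance)"
  } else {
    va <- sa$sd^2 / sa$n
    vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
    method <- "Two-tailed Welch t test"
  }
  if (se == 0) {
    if (est == 0) {
      statistic <- 0
      p <- 1
    } else {
      warn("zero pooled variance with unequal means; reporting p = 0")
      statistic <- sign(est) * Inf
      p <- 0
    }
  } else {
    statistic <- est / se
    p <- 2 * pt(-abs(statistic), df)
  }
  out <- tibble(
    statistic = statistic,
    statistic_name = "t",
    df = df,
    p.value = p,
    tails = "two",
    estimate = est,
    method = method
  )
  class(out) <- c("btj_test", class(out))
  out
}

# groups -> list of (mean, sd, n); accepts a list of numeric vectors or a
# data frame of summary cells (columns mean, sem, n; optional group labels).
.group_stats <- function(groups, require_n2 = TRUE) {
  if (is.data.frame(groups)) {
    if (!all(c("mean", "sem", "n") %in% names(groups))) {
      abort("summary-mode groups need columns mean, sem, n")
    }
    if (require_n2 && any(groups$n < 2)) {
      abort("every summary cell needs n >= 2: within-group variance is undefined at n = 1")
    }
    label_col <- setdiff(names(groups), c("mean", "sem", "n", "sem_undefined"))
    labels <- if (length(label_col) > 0) {
      do.call(paste, c(groups[label_col], sep = ":"))
    } else {
      paste0("group", seq_len(nrow(groups)))
    }
    tibble(
      group = labels,
      mean = groups$mean,
      sd = groups$sem * sqrt(groups$n),
      n = as.integer(groups$n)
    )
  } else if (is.list(groups)) {
    labels <- names(groups) %||% paste0("group", seq_along(groups))
    stats <- purrr::map(groups, .suff_stats)
    if (require_n2 && any(purrr::map_int(stats, "n") < 2)) {
      abort("every group needs n >= 2 observations")
    }
    tibble(
      group = labels,
      mean = purrr::map_dbl(stats, "mean"),
      sd = purrr::map_dbl(stats, "sd"),
      n = purrr::map_int(stats, "n")
    )
  } else {
    abort("groups must be a list of numeric vectors or a summary-cell data frame")
  }
}

# Tukey-Kramer all-pairs comparisons given cell stats and the residual MS.
.tukey_pairs <- function(stats, ms_within, df_within, k = nrow(stats)) {
  pairs <- utils::combn(nrow(stats), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- stats$mean[i1] - stats$mean[i2]
    se <- sqrt(ms_within / 2 * (1 / stats$n[i1] + 1 / stats$n[i2]))
    q <- abs(diff) / se
    tibble(
      group1 = stats$group[i1],
      group2 = stats$group[i2],
      estimate = diff,
      q = q,
      adj.p.value = ptukey(q, k, df_within, lower.tail = FALSE)
    )
  })
}

.new_anova <- function(table, tukey, method) {
  structure(
    list(anova = table, tukey = tukey, method = method),
    class = "btj_anova"
  )
}

#' One-way ANOVA with Tukey HSD, from raw groups or summary cells
#'
#' Classical one-way analysis of variance computed from the groups'
#' sufficient statistics: between-group SS from the cell means, within-group
#' SS from the (reconstructed) cell SDs, `F` on `(k - 1, N - k)` degrees of
#' freedom. All-pairs post hoc comparisons use the Tukey HSD criterion with
#' studentized-range p values ([stats::ptukey]) and the Tukey-Kramer
#' harmonic-mean correction for unbalanced pairs. Raw and summary modes
#' agree to machine precision whenever the raw data realize the summaries.
#'
#' @param groups A named list of numeric vectors (raw mode) or a data frame
#'   of summary cells with columns `mean`, `sem`, `n` plus optional label
#'   columns (summary mode). Summary cells with `n = 1` are rejected: the
#'   within-group variance is undefined.
#' @return A `btj_anova` object: `$anova` (term table with SS, df, MS, F, p,
#'   and percent of total variance) and `$tukey` (pairwise comparisons).
#' @export
#' @examples
#' cells <- tibble::tibble(
#'   region = c("primary_fissure", "anterior_lobe", "flocculonodular"),
#'   mean = c(1.02, 0.84, 3.24), sem = c(0.38, 0.58, 0.54), n = 3
#' )
#' one_way_anova_tukey(cells)
one_way_anova_tukey <- function(groups) {
  stats <- .group_stats(groups)
  k <- nrow(stats)
  if (k < 2) abort("need at least 2 groups")
  n_tot <- sum(stats$n)
  if (n_tot <= k) abort("total n must exceed the number of groups")
  grand <- sum(stats$n * stats$mean) / n_tot
  ss_between <- sum(stats$n * (stats$mean - grand)^2)
  ss_within <- sum((stats$n - 1) * stats$sd^2)
  df_b <- k - 1
  df_w <- n_tot - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  f <- if (ms_w == 0) {
    if (ms_b == 0) 0 else Inf
  } else {
    ms_b / ms_w
  }
  ss_total <- ss_between + ss_within
  table <- tibble(
    term = c("group", "residual"),
    sumsq = c(ss_between, ss_within),
    df = c(df_b, df_w),
    meansq = c(ms_b, ms_w),
    statistic = c(f, NA_real_),
    p.value = c(pf(f, df_b, df_w, lower.tail = FALSE), NA_real_),
    pct_total_variance = 100 * c(ss_between, ss_within) / ss_total
  )
  tukey <- .tukey_pairs(stats, ms_w, df_w, k)
  .new_anova(table, tukey, "One-way ANOVA + Tukey HSD")
}

#' Two-way ANOVA with Tukey HSD, from raw data or a summary-cell grid
#'
#' Two-factor analysis of variance over a complete `a x b` grid of cells.
#' Balanced designs use the classical cell-means decomposition (main
#' effects, interaction, residual) computed from the cell sufficient
#' statistics. Unbalanced designs are analysed with Type III sums of squares
#' under sum-to-zero contrasts (via [car::Anova]) on data that exactly
#' realize the cell summaries — the convention of the commercial software
#' the published tables came from. Each term additionally reports its share
#' of the total (corrected) sum of squares in percent.
#'
#' Post hoc Tukey-Kramer comparisons are made across all cell means, with
#' the residual mean square as the error term.
#'
#' @param cells A data frame. Summary mode: one row per cell with factor
#'   columns `a` and `b` plus `mean`, `sem`, `n` (every cell needs
#'   `n >= 2`). Raw mode: one row per observation with factor columns `a`
#'   and `b` plus `value`.
#' @param a,b Names of the two factor columns (default `"a"`, `"b"`).
#' @param value Name of the observation column in raw mode.
#' @return A `btj_anova` object (see [one_way_anova_tukey()]); terms are
#'   named after the factor columns.
#' @export
#' @examples
#' cells <- tibble::tibble(
#'   genotype = rep(c("WT", "MUT"), 2),
#'   age = rep(c(2, 22), each = 2),
#'   mean = c(1.154, 1.126, 1.210, 1.090),
#'   sem = c(0.018, 0.029, 0.029, 0.018),
#'   n = 3
#' )
#' fit <- two_way_anova_tukey(cells, a = "genotype", b = "age")
#' tidy(fit)
two_way_anova_tukey <- function(cells, a = "a", b = "b", value = "value") {
  cells <- as_tibble(cells)
  if (!all(c(a, b) %in% names(cells))) {
    abort(paste0("cells must contain factor columns '", a, "' and '", b, "'"))
  }
  summary_mode <- all(c("mean", "sem", "n") %in% names(cells))
  if (summary_mode) {
    if (any(cells$n < 2)) {
      abort("every cell needs n >= 2: within-cell variance is undefined at n = 1")
    }
    grid <- cells
    raw <- tidyr::unnest(
      dplyr::mutate(cells, value = purrr::pmap(
        list(.data$mean, .data$sem * sqrt(.data$n), .data$n), realize_values
      )),
      "value"
    )
  } else {
    if (!value %in% names(cells)) {
      abort(paste0("raw mode needs an observation column '", value, "'"))
    }
    raw <- dplyr::rename(cells, value = dplyr::all_of(value))
    grid <- raw |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(a, b)))) |>
      dplyr::summarise(
        mean = mean(.data$value),
        sem = sd(.data$value) / sqrt(dplyr::n()),
        n = dplyr::n(), .groups = "drop"
      )
    if (any(grid$n < 2)) abort("every cell needs n >= 2 observations")
  }
  la <- unique(grid[[a]])
  lb <- unique(grid[[b]])
  full <- tidyr::expand_grid(.a = la, .b = lb)
  have <- paste(grid[[a]], grid[[b]])
  if (!all(paste(full$.a, full$.b) %in% have)) {
    abort("the a x b cell grid is incomplete; every cell must be observed")
  }

  balanced <- length(unique(grid$n)) == 1
  ss_within <- sum((grid$n - 1) * (grid$sem * sqrt(grid$n))^2)
  df_within <- sum(grid$n) - nrow(grid)
  ms_within <- ss_within / df_within

  if (balanced) {
    nc <- grid$n[1]
    grand <- mean(grid$mean)
    ma <- tapply(grid$mean, grid[[a]], mean)
    mb <- tapply(grid$mean, grid[[b]], mean)
    ss_a <- nc * length(lb) * sum((ma - grand)^2)
    ss_b <- nc * length(la) * sum((mb - grand)^2)
    inter <- grid$mean - ma[as.character(grid[[a]])] -
      mb[as.character(grid[[b]])] + grand
    ss_ab <- nc * sum(inter^2)
    tab <- tibble(
      term = c(a, b, paste0(a, ":", b), "residual"),
      sumsq = c(ss_a, ss_b, ss_ab, ss_within),
      df = c(length(la) - 1, length(lb) - 1,
             (length(la) - 1) * (length(lb) - 1), df_within)
    )
  } else {
    df_fit <- raw
    df_fit$.fa <- factor(df_fit[[a]])
    df_fit$.fb <- factor(df_fit[[b]])
    fit <- lm(value ~ .fa * .fb, data = df_fit,
      contrasts = list(.fa = "contr.sum", .fb = "contr.sum"))
    aov3 <- car::Anova(fit, type = 3)
    rows <- rownames(aov3)
    keep <- !rows %in% c("(Intercept)")
    term_map <- c(".fa" = a, ".fb" = b, ".fa:.fb" = paste0(a, ":", b),
      "Residuals" = "residual")
    tab <- tibble(
      term = unname(term_map[rows[keep]]),
      sumsq = aov3$`Sum Sq`[keep],
      df = aov3$Df[keep]
    )
  }
  tab$meansq <- tab$sumsq / tab$df
  is_resid <- tab$term == "residual"
  tab$statistic <- ifelse(is_resid, NA_real_, tab$meansq / ms_within)
  tab$p.value <- ifelse(is_resid, NA_real_,
    pf(tab$statistic, tab$df, df_within, lower.tail = FALSE))
  # total corrected SS from the realized/raw data, so variance shares match
  # the "% of total variation" convention
  ss_total <- sum((raw$value - mean(raw$value))^2)
  tab$pct_total_variance <- 100 * tab$sumsq / ss_total

  cell_stats <- tibble(
    group = paste(grid[[a]], grid[[b]], sep = ":"),
    mean = grid$mean,
    sd = grid$sem * sqrt(grid$n),
    n = as.integer(grid$n)
  )
  tukey <- .tukey_pairs(cell_stats, ms_within, df_within, nrow(cell_stats))
  .new_anova(tab, tukey,
    paste0("Two-way ANOVA (", if (balanced) "balanced cell-means"
           else "Type III, sum-to-zero contrasts", ") + Tukey HSD"))
}

#' Compare linear-regression slopes between two groups
#'
#' Fits an ordinary least-squares line of value on age within each group and
#' tests the equality of the two slopes with
#' `t = (b1 - b2) / sqrt(SE1^2 + SE2^2)` on the summed residual degrees of
#' freedom. With observations clustered at two ages the fitted slope equals
#' the difference of the age-group means divided by the age difference, so
#' slopes are exactly recomputable from published group means.
#'
#' @param data A data frame of observations with a group column, an age
#'   column, and a value column.
#' @param group,age,value Column names (defaults `"group"`, `"age"`,
#'   `"value"`).
#' @return A `btj_slopes` object: `$slopes` (per-group slope, SE, residual
#'   df) and `$comparison` (one-row tibble with the slope difference, t, df,
#'   p.value).
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   group = rep(c("WT", "MUT"), each = 6),
#'   age = rep(c(2, 2, 2, 22, 22, 22), 2),
#'   value = c(1.16, 1.15, 1.15, 1.22, 1.21, 1.20,
#'             1.13, 1.12, 1.13, 1.10, 1.09, 1.08)
#' )
#' slope_compare(obs)
slope_compare <- function(data, group = "group", age = "age",
                          value = "value") {
  data <- as_tibble(data)
  if (!all(c(group, age, value) %in% names(data))) {
    abort(paste0("data must contain columns '", group, "', '", age,
      "', '", value, "'"))
  }
  split_groups <- split(data, data[[group]])
  if (length(split_groups) != 2) abort("slope comparison needs exactly 2 groups")
  slopes <- purrr::imap_dfr(split_groups, function(d, g) {
    if (length(unique(d[[age]])) < 2) {
      abort(paste0("group '", g, "' spans a single age; slope undefined"))
    }
    fit <- lm(d[[value]] ~ d[[age]])
    sm <- summary(fit)
    tibble(
      group = g,
      slope = unname(coef(fit)[2]),
      se = sm$coefficients[2, 2],
      df = fit$df.residual,
      n = nrow(d)
    )
  })
  diff <- slopes$slope[1] - slopes$slope[2]
  se <- sqrt(sum(slopes$se^2))
  df <- sum(slopes$df)
  statistic <- diff / se
  comparison <- tibble(
    estimate = diff,
    statistic = statistic,
    statistic_name = "t",
    df = df,
    p.value = 2 * pt(-abs(statistic), df),
    method = "OLS slope equality test"
  )
  structure(list(slopes = slopes, comparison = comparison),
    class = "btj_slopes")
}

#' Significance stars for figure-style p-value binning
#'
#' Report-layer binning only; analyses keep full-precision p values.
#' Thresholds: `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001,
#' `****` p <= 0.0001.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of star labels ("" when p > 0.05).
#' @export
#' @examples
#' p_stars(c(0.2, 0.03, 0.0005))
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 0.0001 ~ "****",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' @export
print.btj_anova <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  print(x$anova, ...)
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$tukey, ...)
  invisible(x)
}

#' @export
print.btj_slopes <- function(x, ...) {
  cat("<slope comparison>\n")
  print(x$slopes, ...)
  print(x$comparison, ...)
  invisible(x)
}

#' Tidy an ANOVA result
#'
#' @param x A `btj_anova`.
#' @param ... Unused.
#' @return The per-term ANOVA tibble (SS, df, MS, F, p, percent of total
#'   variance).
#' @export
tidy.btj_anova <- function(x, ...) x$anova

#' One-row summary of an ANOVA result
#'
#' @param x A `btj_anova`.
#' @param ... Unused.
#' @return A one-row tibble: method, residual df, residual MS, and the
#'   smallest term p value.
#' @export
glance.btj_anova <- function(x, ...) {
  resid <- x$anova[x$anova$term == "residual", ]
  tibble(
    method = x$method,
    df_residual = resid$df,
    ms_residual = resid$meansq,
    min_p = suppressWarnings(min(x$anova$p.value, na.rm = TRUE))
  )
}

#' Tidy a slope comparison
#'
#' @param x A `btj_slopes`.
#' @param ... Unused.
#' @return Per-group slopes with the comparison statistics appended as
#'   columns `diff_estimate`, `diff_statistic`, `diff_p.value`.
#' @export
tidy.btj_slopes <- function(x, ...) {
  dplyr::mutate(x$slopes,
    diff_estimate = x$comparison$estimate,
    diff_statistic = x$comparison$statistic,
    diff_p.value = x$comparison$p.value
  )
}

#' Variance-decomposition bar chart for an ANOVA result
#'
#' @param object A `btj_anova`.
#' @param ... Unused.
#' @return A ggplot of each term's share of total variance.
#' @export
autoplot.btj_anova <- function(object, ...) {
  tab <- object$anova
  ggplot2::ggplot(tab, ggplot2::aes(
    x = stats::reorder(.data$term, .data$pct_total_variance),
    y = .data$pct_total_variance
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of total variance",
      title = object$method)
}
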