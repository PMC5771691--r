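#' Interval rate of change in area
#'
#' The piecewise model treats a cross-sectional trajectory of group-mean
#' areas as a sequence of intervals and summarises each interval by its
#' average rate of change, `(A_end - A_start) / (t_end - t_start)`, in area
#' units per month. The sign is preserved: growth intervals have positive
#' rates, shrinking intervals negative rates.
#'
#' @param a_start,a_end Area at the start and end of the interval.
#' @param t_start,t_end Interval boundaries in months; `t_end > t_start`.
#' @return Rate of change (area/month). Vectorised.
#' @export
#' @examples
#' interval_rate(0.0316, 0.2188, 0, 1)
interval_rate <- function(a_start, a_end, t_start, t_end) {
  if (any(t_end <= t_start)) {
    abort("t_end must be strictly greater than t_start")
  }
  (a_end - a_start) / (t_end - t_start)
}

#' Net per-area coefficient of an interval
#'
#' Converts an interval rate into the net coefficient `k = G - D` of the
#' kinetic model `dA/dt = (G - D) A`, using the end-anchored discrete
#' convention: `k = rate / A(t_end)`, i.e. the `k` for which
#' `rate = k * A_end`. Under the model's identifying assumptions a positive
#' `k` is attributed entirely to growth (`G = k, D = 0`) and a negative `k`
#' entirely to degeneration (`G = 0, D = -k`).
#'
#' The end-anchored convention is the package default because it is the one
#' the published coefficient tables are consistent with; see the methods
#' vignette for the alternatives considered.
#'
#' @inheritParams interval_rate
#' @return Net coefficient in month^-1. Vectorised.
#' @export
#' @examples
#' net_coefficient(0.0316, 0.2188, 0, 1)   # ~0.8556: strong early growth
#' net_coefficient(0.3006, 0.2483, 6, 23)  # negative: net degeneration
net_coefficient <- function(a_start, a_end, t_start, t_end) {
  if (any(a_end <= 0)) {
    abort("a_end must be strictly positive")
  }
  interval_rate(a_start, a_end, t_start, t_end) / a_end
}

.as_anchors <- function(anchors) {
  if (is.data.frame(anchors)) {
    cols <- intersect(c("t", "age_months"), names(anchors))
    vcol <- intersect(c("area", "mean", "value"), names(anchors))
    if (length(cols) == 0 || length(vcol) == 0) {
      abort("anchors need a time column (t or age_months) and an area column (area, mean or value)")
    }
    out <- tibble(t = anchors[[cols[1]]], area = anchors[[vcol[1]]])
  } else {
    abort("anchors must be a data frame of (t, area) pairs")
  }
  if (nrow(out) < 2) abort("need at least 2 anchors")
  if (any(diff(out$t) <= 0)) abort("anchor times must be strictly increasing")
  out
}

.new_trajectory_fit <- function(phases, anchors, growth_phase_end,
                                variant, region = NA_character_,
                                genotype = NA_character_) {
  structure(
    list(
      phases = phases,
      anchors = anchors,
      growth_phase_end = growth_phase_end,
      variant = variant,
      region = region,
      genotype = genotype
    ),
    class = "trajectory_fit"
  )
}

#' Fit the baseline growth-degeneration trajectory
#'
#' Fits per-interval growth (`G`) and degeneration (`D`) coefficients of the
#' model `dA/dt = (G - D) A` to an ordered set of `(t, area)` anchors under
#' the identifying assumptions of the baseline variant: degeneration is
#' negligible during the growth phase (`D = 0` for intervals ending at or
#' before `growth_phase_end`) and growth is negligible afterwards (`G = 0`
#' for intervals starting at or after it). Each interval therefore pins one
#' coefficient to zero and assigns the net coefficient (see
#' [net_coefficient()]) to the other.
#'
#' @param anchors Data frame of ordered `(t, area)` pairs (columns `t` or
#'   `age_months`, and `area`/`mean`/`value`). Typically group means at the
#'   cross-sectional ages.
#' @param growth_phase_end Age in months separating the growth phase from the
#'   degeneration phase (default 6). No anchor interval may straddle it.
#' @param region,genotype Optional labels carried into the fit.
#' @return A `trajectory_fit` object; see [tidy.trajectory_fit()] for the
#'   per-phase coefficient table.
#' @export
#' @examples
#' wt <- tibble::tibble(t = c(0, 1, 2, 6, 23),
#'                      area = c(0.0316, 0.2188, 0.2913, 0.3006, 0.2483))
#' fit <- fit_baseline(wt, genotype = "WT", region = "cerebellum")
#' tidy(fit)
fit_baseline <- function(anchors, growth_phase_end = 6,
                         region = NA_character_, genotype = NA_character_) {
  anchors <- .as_anchors(anchors)
  t0 <- head(anchors$t, -1)
  t1 <- tail(anchors$t, -1)
  straddle <- t0 < growth_phase_end & t1 > growth_phase_end
  if (any(straddle)) {
    abort(paste0(
      "anchor interval [", t0[straddle][1], ", ", t1[straddle][1],
      "] straddles growth_phase_end = ", growth_phase_end,
      "; phase boundaries must align with an anchor"
    ))
  }
  a0 <- head(anchors$area, -1)
  a1 <- tail(anchors$area, -1)
  rate <- interval_rate(a0, a1, t0, t1)
  k <- net_coefficient(a0, a1, t0, t1)
  growth <- t1 <= growth_phase_end
  phases <- tibble(
    t_start = t0, t_end = t1,
    rate = rate, net = k,
    G = ifelse(growth, k, 0),
    D = ifelse(growth, 0, -k),
    model_variant = "baseline"
  )
  phases$feasible <- phases$G >= 0 & phases$D >= 0
  .new_trajectory_fit(phases, anchors, growth_phase_end, "baseline",
    region, genotype)
}

#' Fit a counterfactual trajectory against a control fit
#'
#' Repartitions the mutant's observed net interval coefficients between
#' growth and degeneration under one of two counterfactual hypotheses,
#' holding the other coefficient at the control (baseline) level:
#'
#' * `undergrowth_only`: differences from control are explained entirely by
#'   altered growth. During the growth phase `D` is held at the control value
#'   (zero under the baseline assumptions) and `G = net + D_control`; after
#'   `growth_phase_end` the no-growth assumption `G = 0` still applies, so
#'   `D` absorbs the observed net rate.
#' * `degeneration_only`: differences are explained entirely by accelerated
#'   degeneration. `G` is held at the control value in every phase and
#'   `D = G_control - net`.
#'
#' A negative fitted coefficient means the hypothesis cannot explain the
#' data in that interval; it is reported verbatim with `feasible = FALSE`
#' rather than truncated, because the infeasibility itself is the diagnostic
#' output (a model that requires negative degeneration is rejected).
#'
#' @param anchors Mutant `(t, area)` anchors; must align with the control
#'   fit's phase boundaries.
#' @param control_fit A baseline `trajectory_fit` for the control group.
#' @param variant `"undergrowth_only"` or `"degeneration_only"`.
#' @param region,genotype Optional labels carried into the fit.
#' @return A `trajectory_fit` object.
#' @export
#' @examples
#' wt <- tibble::tibble(t = c(0, 1), area = c(0.244, 0.7527))
#' mut <- tibble::tibble(t = c(0, 1), area = c(0.2499, 0.766))
#' ctrl <- fit_baseline(wt)
#' tidy(fit_counterfactual(mut, ctrl, "degeneration_only"))
fit_counterfactual <- function(anchors, control_fit,
                               variant = c("undergrowth_only",
                                           "degeneration_only"),
                               region = NULL, genotype = NA_character_) {
  variant <- match.arg(variant)
  stopifnot(inherits(control_fit, "trajectory_fit"))
  anchors <- .as_anchors(anchors)
  ctrl <- control_fit$phases
  if (nrow(anchors) != nrow(ctrl) + 1 ||
      any(anchors$t != control_fit$anchors$t)) {
    abort("mutant anchors must align with the control fit's phase boundaries")
  }
  gpe <- control_fit$growth_phase_end
  t0 <- head(anchors$t, -1)
  t1 <- tail(anchors$t, -1)
  a0 <- head(anchors$area, -1)
  a1 <- tail(anchors$area, -1)
  rate <- interval_rate(a0, a1, t0, t1)
  k <- net_coefficient(a0, a1, t0, t1)
  growth <- t1 <= gpe
  if (variant == "undergrowth_only") {
    G <- ifelse(growth, k + ctrl$D, ctrl$G)
    D <- ifelse(growth, ctrl$D, ctrl$G - k)
  } else {
    G <- ctrl$G
    D <- ctrl$G - k
  }
  phases <- tibble(
    t_start = t0, t_end = t1,
    rate = rate, net = k,
    G = G, D = D,
    model_variant = variant
  )
  phases$feasible <- phases$G >= 0 & phases$D >= 0
  .new_trajectory_fit(phases, anchors, gpe, variant,
    region %||% control_fit$region, genotype)
}

#' Forward-simulate a fitted trajectory
#'
#' Reconstructs anchor areas from a fitted (or hypothesised) trajectory.
#' `mode = "discrete"` inverts the end-anchored fitting rule exactly:
#' `A_end = A_start / (1 - k * dt)` with `k = G - D`, so
#' `fit_baseline(simulate_trajectory(fit, A0))` recovers the coefficients of
#' a feasible fit to machine precision. `mode = "continuous"` uses the exact
#' solution of the underlying ordinary differential equation,
#' `A_end = A_start * exp(k * dt)`; the two modes agree only as
#' `k * dt -> 0`.
#'
#' @param fit A `trajectory_fit` (only `t_start`, `t_end`, `G`, `D` are
#'   used), or a data frame with those columns.
#' @param a0 Area at the first phase boundary; must be positive.
#' @param mode `"discrete"` (default; inverse of the fitting rule) or
#'   `"continuous"`.
#' @return A tibble of `(t, area)` anchors, one more row than phases.
#' @export
#' @examples
#' wt <- tibble::tibble(t = c(0, 1, 2), area = c(0.0316, 0.2188, 0.2913))
#' fit <- fit_baseline(wt)
#' simulate_trajectory(fit, 0.0316)  # reproduces the anchors
simulate_trajectory <- function(fit, a0, mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  if (a0 <= 0) abort("a0 must be positive")
  phases <- if (inherits(fit, "trajectory_fit")) fit$phases else as_tibble(fit)
  stopifnot(all(c("t_start", "t_end", "G", "D") %in% names(phases)))
  k <- phases$G - phases$D
  dt <- phases$t_end - phases$t_start
  area <- numeric(nrow(phases) + 1)
  area[1] <- a0
  for (i in seq_len(nrow(phases))) {
    if (mode == "discrete") {
      if (k[i] * dt[i] >= 1) {
        abort(paste0("discrete inversion is singular: k * dt = ",
          format(k[i] * dt[i]), " >= 1 in phase ", i))
      }
      area[i + 1] <- area[i] / (1 - k[i] * dt[i])
    } else {
      area[i + 1] <- area[i] * exp(k[i] * dt[i])
    }
  }
  tibble(t = c(phases$t_start[1], phases$t_end), area = area)
}

#' Percent decrease between a reference and a test group
#'
#' Atrophy summary for a pair of group cells: the percent decrease of the
#' test (typically mutant) mean relative to the reference (typically
#' wild-type) mean, `100 * (ref - test) / ref`, with an uncertainty in
#' percentage points. The default uncertainty convention is
#' `100 * sem_test / mean_ref` — the convention the published "x% +/- y%"
#' values follow; `method = "delta"` gives first-order propagation of both
#' SEMs instead.
#'
#' @param ref,test One-row summary cells (see [summary_cell()]) or numeric
#'   vectors of raw values. `ref` mean must be positive.
#' @param method Uncertainty convention: `"sem_ratio"` (default) or
#'   `"delta"`.
#' @return A one-row tibble: `percent_decrease`, `uncertainty`, `ref_mean`,
#'   `test_mean`, `method`.
#' @export
#' @examples
#' percent_decrease(summary_cell(7.128, 0.014, 2), summary_cell(4.586, 0.089, 4))
percent_decrease <- function(ref, test, method = c("sem_ratio", "delta")) {
  method <- match.arg(method)
  r <- .suff_stats(ref, "ref")
  s <- .suff_stats(test, "test")
  if (r$mean <= 0) abort("reference mean must be positive")
  sem_r <- r$sd / sqrt(r$n)
  sem_t <- s$sd / sqrt(s$n)
  pd <- 100 * (r$mean - s$mean) / r$mean
  unc <- if (method == "sem_ratio") {
    100 * sem_t / r$mean
  } else {
    100 * sqrt(sem_t^2 / r$mean^2 + s$mean^2 * sem_r^2 / r$mean^4)
  }
  tibble(
    percent_decrease = pd,
    uncertainty = unc,
    ref_mean = r$mean,
    test_mean = s$mean,
    method = method
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("<trajectory_fit> variant:", x$variant)
  if (!is.na(x$region)) cat("  region:", x$region)
  if (!is.na(x$genotype)) cat("  genotype:", x$genotype)
  cat("\n  growth phase ends at", x$growth_phase_end, "mo\n")
  print(x$phases, ...)
  invisible(x)
}

#' Tidy a trajectory fit into a per-phase coefficient table
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return A tibble with one row per phase: interval, rate (area/month), net
#'   coefficient, `G`, `D` (month^-1), variant, feasibility flag, and the
#'   region/genotype labels.
#' @export
tidy.trajectory_fit <- function(x, ...) {
  dplyr::mutate(x$phases,
    region = x$region, genotype = x$genotype,
    .before = 1
  )
}

#' One-row summary of a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variant, number of phases, span, whether every
#'   phase is feasible, and the peak fitted area.
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble(
    variant = x$variant,
    region = x$region,
    genotype = x$genotype,
    n_phases = nrow(x$phases),
    t_min = min(x$anchors$t),
    t_max = max(x$anchors$t),
    feasible = all(x$phases$feasible),
    peak_area = max(x$anchors$area)
  )
}

#' Plot a fitted trajectory and its anchors
#'
#' @param object A `trajectory_fit`.
#' @param ... Unused.
#' @return A ggplot: anchor areas over age with the fitted piecewise
#'   trajectory, phases coloured by their dominant coefficient.
#' @export
autoplot.trajectory_fit <- function(object, ...) {
  ph <- object$phases
  seg <- tibble(
    t = ph$t_start, tend = ph$t_end,
    a = head(object$anchors$area, -1), aend = tail(object$anchors$area, -1),
    phase = ifelse(ph$G >= ph$D, "growth-dominated", "degeneration-dominated")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$t, xend = .data$tend,
                   y = .data$a, yend = .data$aend,
                   colour = .data$phase)
    ) +
    ggplot2::geom_point(
      data = object$anchors,
      ggplot2::aes(x = .data$t, y = .data$area)
    ) +
    ggplot2::geom_vline(xintercept = object$growth_phase_end,
      linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "age (months)", y = "area",
      colour = NULL,
      title = paste0("Trajectory fit (", object$variant, ")"),
      subtitle = if (!is.na(object$region)) object$region else NULL
    )
}
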