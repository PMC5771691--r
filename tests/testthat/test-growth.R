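test_that("interval_rate is the signed area change per month", {
  expect_equal(interval_rate(0.0316, 0.2188, 0, 1), 0.1872, tolerance = 1e-12)
  expect_equal(interval_rate(0.3006, 0.2483, 6, 23), -0.0523 / 17,
    tolerance = 1e-12)
  expect_equal(interval_rate(0.7, 0.7, 0, 5), 0)
  expect_error(interval_rate(1, 2, 3, 3), "strictly greater")
})

test_that("net_coefficient uses the end-anchored discrete rule", {
  # closed form: (2 - 1) / (1 * 2) = 0.5
  expect_equal(net_coefficient(1, 2, 0, 1), 0.5)
  expect_equal(net_coefficient(0.0316, 0.2188, 0, 1),
    (0.2188 - 0.0316) / 0.2188, tolerance = 1e-12)
  expect_error(net_coefficient(1, 0, 0, 1), "positive")
})

test_that("fit_baseline pins one coefficient per phase and splits at the boundary", {
  fit <- fit_baseline(nhe6_anchors("cortex", "WT"))
  ph <- fit$phases
  # growth phases: D pinned at 0, G = net; decline: G = 0, D = -net
  expect_equal(ph$D[ph$t_end <= 6], rep(0, 3))
  expect_equal(ph$G[ph$t_start >= 6], 0)
  expect_equal(ph$G[1], 0.5087 / 0.7527, tolerance = 1e-12)
  expect_equal(ph$G[2], interval_rate(0.7527, 0.908, 1, 2) / 0.908,
    tolerance = 1e-12)
  expect_equal(ph$D[4], -net_coefficient(0.949, 0.7723, 6, 23),
    tolerance = 1e-12)
  expect_true(all(ph$feasible))

  # constant anchors: all coefficients zero
  flat <- fit_baseline(tibble::tibble(t = c(0, 2, 6, 10), area = 1))
  expect_equal(flat$phases$G, rep(0, 3))
  expect_equal(flat$phases$D, rep(0, 3))

  expect_error(
    fit_baseline(tibble::tibble(t = c(0, 5, 23), area = c(1, 2, 1.5))),
    "straddles"
  )
  expect_error(fit_baseline(tibble::tibble(t = 1, area = 2)), "at least 2")
})

test_that("counterfactual variants repartition but never change the net rate", {
  ctrl <- fit_baseline(nhe6_anchors("cortex", "WT"))
  mut <- nhe6_anchors("cortex", "MUT")
  for (v in c("undergrowth_only", "degeneration_only")) {
    fit <- fit_counterfactual(mut, ctrl, v)
    expect_equal(fit$phases$G - fit$phases$D, fit$phases$net,
      tolerance = 1e-12, label = v)
  }
  # baseline conserves too
  expect_equal(ctrl$phases$G - ctrl$phases$D, ctrl$phases$net,
    tolerance = 1e-12)
})

test_that("degeneration-only coefficients equal control G minus mutant net", {
  ctrl <- fit_baseline(nhe6_anchors("cortex", "WT"))
  mut <- nhe6_anchors("cortex", "MUT")
  fit <- fit_counterfactual(mut, ctrl, "degeneration_only")
  # independent arithmetic for the first phase
  g_ctrl <- net_coefficient(0.244, 0.7527, 0, 1)
  net_mut <- net_coefficient(0.2499, 0.766, 0, 1)
  expect_equal(fit$phases$G[1], g_ctrl, tolerance = 1e-12)
  expect_equal(fit$phases$D[1], g_ctrl - net_mut, tolerance = 1e-12)
  # 2-6 mo: mutant grew faster than control -> negative D, flagged infeasible
  expect_lt(fit$phases$D[3], 0)
  expect_false(fit$phases$feasible[3])
  # decline phase: G held at control 0, D absorbs the mutant net
  expect_equal(fit$phases$G[4], 0)
  expect_equal(fit$phases$D[4], -net_coefficient(0.907, 0.7501, 6, 23),
    tolerance = 1e-12)
})

test_that("undergrowth-only keeps control degeneration in the growth phase", {
  ctrl <- fit_baseline(nhe6_anchors("cerebellum", "WT"))
  mut <- nhe6_anchors("cerebellum", "MUT")
  fit <- fit_counterfactual(mut, ctrl, "undergrowth_only")
  expect_equal(fit$phases$D[1:3], rep(0, 3))        # control D is 0 there
  expect_equal(fit$phases$G[1:3], fit$phases$net[1:3], tolerance = 1e-12)
  expect_equal(fit$phases$G[4], 0)                  # no growth after 6 mo

  # mutant identical to control reproduces the control coefficients
  same <- fit_counterfactual(ctrl$anchors, ctrl, "undergrowth_only")
  expect_equal(same$phases$G, ctrl$phases$G, tolerance = 1e-12)
  expect_equal(same$phases$D, ctrl$phases$D, tolerance = 1e-12)

  expect_error(
    fit_counterfactual(tibble::tibble(t = c(0, 1), area = c(1, 2)), ctrl,
      "undergrowth_only"),
    "align"
  )
})

test_that("discrete simulation inverts the fit exactly; continuous differs", {
  set.seed(101)
  for (rep in 1:20) {
    # keep k * dt < 1 so the discrete inversion is regular (2-6 mo has dt = 4)
    g <- c(runif(2, 0, 0.8), runif(1, 0, 0.2))
    d <- runif(1, 0, 0.04)
    phases <- tibble::tibble(
      t_start = c(0, 1, 2, 6), t_end = c(1, 2, 6, 23),
      G = c(g, 0), D = c(0, 0, 0, d)
    )
    a0 <- runif(1, 0.05, 1)
    anchors <- simulate_trajectory(phases, a0, "discrete")
    refit <- fit_baseline(anchors)
    expect_equal(refit$phases$G, phases$G, tolerance = 1e-12)
    expect_equal(refit$phases$D, phases$D, tolerance = 1e-12)
  }

  # closed forms at k = 0.5, dt = 1
  ph <- tibble::tibble(t_start = 0, t_end = 1, G = 0.5, D = 0)
  expect_equal(simulate_trajectory(ph, 1, "continuous")$area[2], exp(0.5),
    tolerance = 1e-12)
  expect_equal(simulate_trajectory(ph, 1, "discrete")$area[2], 2,
    tolerance = 1e-12)

  # zero net coefficient: constant trajectory in both modes
  ph0 <- tibble::tibble(t_start = 0, t_end = 4, G = 0.2, D = 0.2)
  expect_equal(simulate_trajectory(ph0, 3, "discrete")$area, c(3, 3))
  expect_equal(simulate_trajectory(ph0, 3, "continuous")$area, c(3, 3))

  # singular inversion
  ph1 <- tibble::tibble(t_start = 0, t_end = 2, G = 0.6, D = 0)
  expect_error(simulate_trajectory(ph1, 1, "discrete"), "singular")
  expect_error(simulate_trajectory(ph1, -1), "positive")
})

test_that("percent_decrease follows the SEM-ratio convention and is monotone", {
  est <- percent_decrease(summary_cell(7.128, 0.014, 2),
    summary_cell(4.586, 0.089, 4))
  expect_equal(est$percent_decrease, 100 * (7.128 - 4.586) / 7.128,
    tolerance = 1e-12)
  expect_equal(est$uncertainty, 100 * 0.089 / 7.128, tolerance = 1e-12)

  same <- percent_decrease(summary_cell(2, 0.1, 3), summary_cell(2, 0.1, 3))
  expect_equal(same$percent_decrease, 0)

  # strictly decreasing in the test mean
  pds <- vapply(seq(1.0, 1.9, by = 0.1), function(m) {
    percent_decrease(summary_cell(2, 0.1, 3), summary_cell(m, 0.1, 3))$percent_decrease
  }, numeric(1))
  expect_true(all(diff(pds) < 0))

  # delta-method option widens the band when the reference is noisy
  delta <- percent_decrease(summary_cell(7.128, 0.5, 2),
    summary_cell(4.586, 0.089, 4), method = "delta")
  expect_gt(delta$uncertainty, est$uncertainty)

  expect_error(percent_decrease(summary_cell(0, 0, 2), summary_cell(1, 0, 2)),
    "positive")
})

test_that("trajectory fits tidy, glance and plot", {
  fit <- fit_baseline(nhe6_anchors("cerebellum", "WT"),
    region = "cerebellum", genotype = "WT")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_equal(unique(td$region), "cerebellum")
  gl <- glance(fit)
  expect_equal(gl$n_phases, 4)
  expect_true(gl$feasible)
  expect_s3_class(autoplot(fit), "ggplot")
})
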