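# Run code under a local, named RNG state and restore the caller's state.
# All generator randomness flows through this helper: one seed in the spec,
# substreams derived by documented additive splitting.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

#' Derive a substream seed
#'
#' Deterministic splitting of one master seed into per-group substreams:
#' `seed + 10007 * k`, kept inside the 32-bit integer range. Recorded here
#' so outputs can state exactly how their stream was derived.
#'
#' @param seed Master seed (integer).
#' @param k Substream index (0, 1, 2, ...).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(k)) %% .Machine$integer.max)
}

#' Specify a synthetic cross-sectional cohort
#'
#' Bundles everything [gen_cohort()] needs: the true trajectory of each
#' region x genotype group (piecewise growth/degeneration coefficients and
#' the area at the first boundary), the sampling design (animals per age),
#' the noise model, and the seed. Defaults reproduce the structure of a
#' two-genotype cross-sectional ageing study: ages at the phase boundaries
#' 0, 1, 2, 6 and 23 months, 8 animals per age point, multiplicative normal
#' noise with a 5% coefficient of variation (the scale of published gross
#' area SEM/mean ratios).
#'
#' @param trajectories A tibble with columns `region`, `genotype`, `a0`
#'   (area at the first boundary) and per-phase rows `t_start`, `t_end`,
#'   `G`, `D`. See [default_trajectories()].
#' @param n_per_age Animals per age point (>= 1).
#' @param cv Coefficient of variation of the noise (>= 0).
#' @param noise `"normal_cv"` (multiplicative normal, default) or
#'   `"lognormal"` (strictly positive, same CV, mean preserved).
#' @param measure_kind,units Measure recorded for each animal.
#' @param seed Master seed; all substreams derive from it (see
#'   [substream_seed()]).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(trajectories = default_trajectories(),
                        n_per_age = 8, cv = 0.05,
                        noise = c("normal_cv", "lognormal"),
                        measure_kind = "gross_area",
                        units = canonical_units(measure_kind),
                        seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(cv >= 0, n_per_age >= 1)
  needed <- c("region", "genotype", "a0", "t_start", "t_end", "G", "D")
  if (!all(needed %in% names(trajectories))) {
    abort(paste0("trajectories need columns: ", paste(needed, collapse = ", ")))
  }
  structure(
    list(
      trajectories = as_tibble(trajectories),
      n_per_age = as.integer(n_per_age),
      cv = cv, noise = noise,
      measure_kind = measure_kind, units = units,
      seed = as.integer(seed),
      rng = "Mersenne-Twister"
    ),
    class = "cohort_spec"
  )
}

#' Default true trajectories for the cohort generator
#'
#' Per-phase growth/degeneration coefficients for wild-type and mutant
#' cortex and cerebellum, obtained by fitting the baseline model to the
#' packaged published group means ([nhe6_group_summaries()]). These are the study
#' conditions the generator emulates: rapid early growth, a plateau, and a
#' late decline that is steeper in the mutant cerebellum.
#'
#' @return A tibble with columns `region`, `genotype`, `a0`, `t_start`,
#'   `t_end`, `G`, `D`.
#' @export
default_trajectories <- function() {
  cells <- nhe6_group_summaries()
  cells <- cells[cells$measure_kind == "gross_area" &
                 cells$region %in% c("cortex", "cerebellum"), ]
  purrr::map_dfr(
    split(cells, list(cells$region, cells$genotype)),
    function(d) {
      d <- d[order(d$age_months), ]
      fit <- fit_baseline(
        tibble(t = d$age_months, area = d$mean),
        genotype = d$genotype[1], region = d$region[1]
      )
      dplyr::mutate(
        fit$phases[, c("t_start", "t_end", "G", "D")],
        region = d$region[1], genotype = d$genotype[1],
        a0 = d$mean[1], .before = 1
      )
    }
  )
}

#' Generate a synthetic cross-sectional cohort
#'
#' Draws animal-level measurement records around the true trajectories in a
#' [cohort_spec()]: the true area at each age comes from forward-simulating
#' the per-phase coefficients (discrete rule, so the fitting pipeline can
#' recover them exactly at zero noise), and each animal's value is the true
#' area times an independent noise draw. Deterministic given the spec's
#' seed; each region x genotype group uses its own substream.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of measurement records (one row per animal x age) with
#'   attributes `truth` (tibble of true areas per group x age) and `meta`
#'   (seed, RNG, spec hash).
#' @export
#' @examples
#' spec <- cohort_spec(n_per_age = 3, cv = 0, seed = 42)
#' recs <- gen_cohort(spec)
#' summarize_groups(recs)
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- split(
    spec$trajectories,
    paste(spec$trajectories$region, spec$trajectories$genotype)
  )
  group_keys <- sort(names(groups))
  records <- purrr::imap_dfr(setNames(seq_along(group_keys), group_keys),
    function(gi, key) {
      d <- groups[[key]]
      d <- d[order(d$t_start), ]
      anchors <- simulate_trajectory(
        d[, c("t_start", "t_end", "G", "D")], a0 = d$a0[1], mode = "discrete"
      )
      .with_seed(substream_seed(spec$seed, gi), {
        purrr::map_dfr(seq_len(nrow(anchors)), function(i) {
          true_a <- anchors$area[i]
          noise <- switch(spec$noise,
            normal_cv = rnorm(spec$n_per_age, 1, spec$cv),
            lognormal = {
              s <- sqrt(log(1 + spec$cv^2))
              exp(rnorm(spec$n_per_age, -s^2 / 2, s))
            }
          )
          tibble(
            subject_id = sprintf("%s_%s_t%g_%02d", d$region[1], d$genotype[1],
              anchors$t[i], seq_len(spec$n_per_age)),
            genotype = d$genotype[1],
            sex = "M",
            age_months = anchors$t[i],
            region = d$region[1],
            measure_kind = spec$measure_kind,
            value = true_a * noise,
            units = spec$units
          )
        })
      })
    })
  truth <- purrr::map_dfr(group_keys, function(key) {
    d <- groups[[key]]
    d <- d[order(d$t_start), ]
    anchors <- simulate_trajectory(
      d[, c("t_start", "t_end", "G", "D")], a0 = d$a0[1], mode = "discrete"
    )
    tibble(region = d$region[1], genotype = d$genotype[1],
      age_months = anchors$t, true_area = anchors$area)
  })
  attr(records, "truth") <- truth
  attr(records, "meta") <- list(
    seed = spec$seed, rng = spec$rng, noise = spec$noise, cv = spec$cv,
    n_per_age = spec$n_per_age, spec_hash = rlang::hash(spec)
  )
  records
}

# Fill a disk of radius r (pixels) centred at (cx, cy) (0-based) with value.
.draw_disk <- function(px, cx, cy, r, value) {
  nr <- nrow(px); nc <- ncol(px)
  rows <- max(1, floor(cy - r) + 1):min(nr, ceiling(cy + r) + 1)
  cols <- max(1, floor(cx - r) + 1):min(nc, ceiling(cx + r) + 1)
  for (i in rows) {
    dy2 <- (i - 1 - cy)^2
    dx2 <- (cols - 1 - cx)^2
    hit <- cols[dx2 + dy2 <= r^2]
    if (length(hit) > 0) px[i, hit] <- value
  }
  px
}

#' Generate a synthetic Purkinje-cell-layer image
#'
#' Emulates a calbindin-stained cerebellar section: soma disks placed along
#' a folium-like sinusoidal layer path at a target linear density, with an
#' optional dropout fraction removing a deterministic share of cells (the
#' degeneration phenotype), plus Gaussian intensity noise. The returned
#' ground truth lists the surviving soma centres, the layer path, and the
#' realised density, so morphometry operators can be validated exactly.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @param density_per_100um Target linear density before dropout (cells per
#'   100 um of layer path).
#' @param dropout Fraction of placed cells removed (0-1); the surviving
#'   count is `round((1 - dropout) * n_placed)`.
#' @param soma_radius_um Soma radius in micrometres.
#' @param fg,bg Foreground (soma) and background intensities in `[0, 1]`.
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param amplitude_px,period_px Geometry of the sinusoidal layer path.
#' @param seed Seed for placement jitter, dropout choice and noise.
#' @return A `synthetic_image` (channel `"calbindin"`) whose `$truth` holds
#'   `cells` (soma centres, pixel coordinates), `path` (polyline),
#'   `placed_density_per_100um`, `coverage_pct` (noise-free stain coverage),
#'   `soma_radius_um` and the seed.
#' @export
gen_pc_layer_image <- function(width_px = 1024, height_px = 256,
                               pixel_size_um = 1,
                               density_per_100um = 3.3, dropout = 0,
                               soma_radius_um = 8,
                               fg = 0.9, bg = 0.1, noise_sd = 0.02,
                               amplitude_px = 60, period_px = 512,
                               seed = 1L) {
  stopifnot(density_per_100um >= 0, dropout >= 0, dropout <= 1)
  xs <- seq(0, width_px - 1, by = 4)
  path <- tibble(
    x = xs,
    y = height_px / 2 + amplitude_px * sin(2 * pi * xs / period_px)
  )
  seg_len <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  cum <- c(0, cumsum(seg_len))
  len_um <- cum[length(cum)] * pixel_size_um
  n_place <- round(density_per_100um * len_um / 100)

  .with_seed(seed, {
    centers <- if (n_place > 0) {
      spacing <- cum[length(cum)] / n_place
      # jitter bounded to 20% of the spacing keeps neighbouring somata from
      # merging at published densities
      s <- (seq_len(n_place) - 0.5) * spacing +
        runif(n_place, -0.2, 0.2) * spacing
      s <- pmin(pmax(s, 0), cum[length(cum)])
      idx <- findInterval(s, cum, rightmost.closed = TRUE)
      frac <- (s - cum[idx]) / pmax(seg_len[idx], 1e-9)
      tibble(
        x = path$x[idx] + frac * (path$x[idx + 1] - path$x[idx]),
        y = path$y[idx] + frac * (path$y[idx + 1] - path$y[idx])
      )
    } else {
      tibble(x = numeric(), y = numeric())
    }
    n_keep <- round((1 - dropout) * nrow(centers))
    keep <- sort(sample.int(max(nrow(centers), 1), n_keep))
    centers <- centers[keep, , drop = FALSE]

    px <- matrix(bg, height_px, width_px)
    r_px <- soma_radius_um / pixel_size_um
    for (i in seq_len(nrow(centers))) {
      px <- .draw_disk(px, centers$x[i], centers$y[i], r_px, fg)
    }
    coverage_pct <- 100 * mean(px == fg)
    if (noise_sd > 0) {
      px <- px + matrix(rnorm(length(px), 0, noise_sd), nrow(px))
    }
    px <- pmin(pmax(px, 0), 1)
    synthetic_image(px, pixel_size_um, channel = "calbindin", truth = list(
      cells = centers,
      path = path,
      placed_density_per_100um = 100 * nrow(centers) / len_um,
      path_length_um = len_um,
      coverage_pct = coverage_pct,
      soma_radius_um = soma_radius_um,
      seed = seed
    ))
  })
}

#' Generate a synthetic microglia field with optional lysosomal puncta
#'
#' Emulates a two-channel Iba1/CD68 tile: cell centres from a homogeneous
#' Poisson process at the stated intensity, each cell drawn as a disk in the
#' cell channel, and (optionally) per-cell puncta whose areas are drawn from
#' a gamma distribution with the stated mean. The ground truth lists every
#' cell and every punctum with its analytic (pre-rasterisation) area.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @param intensity_per_um2 Poisson intensity of cell centres (cells per
#'   square micrometre).
#' @param cell_radius_um Cell body radius.
#' @param puncta_per_cell Mean number of puncta per cell (Poisson); 0
#'   disables the puncta channel content.
#' @param puncta_mean_area_um2 Mean punctum area (gamma-distributed).
#' @param puncta_shape Gamma shape parameter of the punctum area
#'   distribution.
#' @param fg,bg,noise_sd Intensities and Gaussian noise SD, as in
#'   [gen_pc_layer_image()].
#' @param seed Seed.
#' @return A list: `cells` and `puncta` (`synthetic_image`s, channels
#'   `"iba1"` / `"cd68"`), and `truth` (tibbles `cells` and `puncta`, the
#'   intensity, and the seed).
#' @export
gen_cell_field_image <- function(width_px = 912, height_px = 912,
                                 pixel_size_um = 1,
                                 intensity_per_um2 = 1.9e-4,
                                 cell_radius_um = 10,
                                 puncta_per_cell = 0,
                                 puncta_mean_area_um2 = 20,
                                 puncta_shape = 6,
                                 fg = 0.9, bg = 0.05, noise_sd = 0.02,
                                 seed = 1L) {
  stopifnot(intensity_per_um2 >= 0)
  area_um2 <- width_px * height_px * pixel_size_um^2
  .with_seed(seed, {
    n_cells <- rpois(1, intensity_per_um2 * area_um2)
    cells <- tibble(
      x = runif(n_cells, 0, width_px - 1e-9),
      y = runif(n_cells, 0, height_px - 1e-9)
    )
    cell_px <- matrix(bg, height_px, width_px)
    r_cell <- cell_radius_um / pixel_size_um
    for (i in seq_len(n_cells)) {
      cell_px <- .draw_disk(cell_px, cells$x[i], cells$y[i], r_cell, fg)
    }

    puncta <- tibble(cell = integer(), x = numeric(), y = numeric(),
      area_um2 = numeric())
    puncta_px <- matrix(bg, height_px, width_px)
    if (puncta_per_cell > 0 && n_cells > 0) {
      for (i in seq_len(n_cells)) {
        np <- rpois(1, puncta_per_cell)
        if (np == 0) next
        areas <- rgamma(np, shape = puncta_shape,
          scale = puncta_mean_area_um2 / puncta_shape)
        for (a in areas) {
          r_p <- sqrt(a / pi) / pixel_size_um
          # place inside the cell body, retrying to avoid merging with
          # previously placed puncta
          placed <- FALSE
          for (try in seq_len(30)) {
            ang <- runif(1, 0, 2 * pi)
            rad <- runif(1, 0, max(r_cell - r_p, 0))
            cx <- cells$x[i] + rad * cos(ang)
            cy <- cells$y[i] + rad * sin(ang)
            if (nrow(puncta) > 0) {
              d <- sqrt((puncta$x - cx)^2 + (puncta$y - cy)^2)
              r_prev <- sqrt(puncta$area_um2 / pi) / pixel_size_um
              if (any(d < r_p + r_prev + 1.5)) next
            }
            puncta <- dplyr::bind_rows(puncta,
              tibble(cell = i, x = cx, y = cy, area_um2 = a))
            puncta_px <- .draw_disk(puncta_px, cx, cy, r_p, fg)
            placed <- TRUE
            break
          }
          # unplaceable punctum (crowded cell): dropped from image and truth
        }
      }
    }
    if (noise_sd > 0) {
      cell_px <- cell_px + matrix(rnorm(length(cell_px), 0, noise_sd),
        nrow(cell_px))
      puncta_px <- puncta_px + matrix(rnorm(length(puncta_px), 0, noise_sd),
        nrow(puncta_px))
    }
    cell_px <- pmin(pmax(cell_px, 0), 1)
    puncta_px <- pmin(pmax(puncta_px, 0), 1)
    truth <- list(cells = cells, puncta = puncta,
      intensity_per_um2 = intensity_per_um2,
      cell_radius_um = cell_radius_um, seed = seed)
    list(
      cells = synthetic_image(cell_px, pixel_size_um, "iba1", truth),
      puncta = synthetic_image(puncta_px, pixel_size_um, "cd68", truth),
      truth = truth
    )
  })
}
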