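test_that("connected-component labeling respects connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE  # touches (1,1) only diagonally
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0)
  expect_error(label_components(m, 6), "connectivity")
})

test_that("4-connected labeling agrees with EBImage::bwlabel", {
  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(runif(40 * 40) < 0.3, 40, 40)
    ours <- label_components(m, 4)
    ref <- EBImage::bwlabel(m * 1)
    expect_equal(max(ours), max(ref))
    # same partition: each of our labels maps to exactly one reference label
    cross <- table(ours[m], ref[m])
    expect_true(all(rowSums(cross > 0) == 1))
    expect_true(all(colSums(cross > 0) == 1))
  }
})

test_that("component stats report pixel and physical areas with centroids", {
  m <- matrix(FALSE, 10, 12)
  m[3:6, 2:6] <- TRUE  # 4 x 5 = 20 px block
  st <- component_stats(label_components(m), pixel_size_um = 2)
  expect_equal(st$area_px, 20L)
  expect_equal(st$area_um2, 80)  # 20 px * (2 um)^2
  expect_equal(st$x, mean(1:5))  # 0-based column centroid
  expect_equal(st$y, mean(2:5))
})

test_that("pc_linear_density is a count per 100 um of path", {
  path <- tibble::tibble(x = c(0, 1000), y = c(0, 0))
  cells <- tibble::tibble(x = seq(5, 995, length.out = 30), y = 2)
  res <- pc_linear_density(cells, path, pixel_size_um = 1)
  expect_equal(res$n_cells, 30L)
  expect_equal(res$density_per_100um, 3)

  empty <- pc_linear_density(cells[0, ], path, 1)
  expect_equal(empty$density_per_100um, 0)

  # somata beyond the capture distance do not count
  far <- tibble::tibble(x = 500, y = 50)
  expect_equal(pc_linear_density(far, path, 1)$n_cells, 0L)

  expect_error(
    pc_linear_density(cells, tibble::tibble(x = c(3, 3), y = c(4, 4)), 1),
    "zero length"
  )

  # translation of detections and path together leaves density unchanged
  shift <- function(d) dplyr::mutate(d, x = x + 17, y = y + 5)
  res2 <- pc_linear_density(shift(cells), shift(path), 1)
  expect_equal(res2$density_per_100um, res$density_per_100um)
})

test_that("signal_area_fraction respects rules and is monotone in threshold", {
  zero <- matrix(0, 20, 20)
  expect_equal(
    signal_area_fraction(zero, rule = "fixed", value = 0.5)$fraction_pct, 0
  )
  half <- matrix(c(rep(0, 200), rep(1, 200)), 20, 20)
  expect_equal(
    signal_area_fraction(half, rule = "fixed", value = 0.5)$fraction_pct, 50
  )
  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  fr <- vapply(seq(0.1, 0.9, by = 0.1), function(v) {
    signal_area_fraction(img, rule = "fixed", value = v)$fraction_pct
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))

  expect_error(
    resolve_threshold(img, "background_mean_plus_k_sd",
      background_mask = matrix(FALSE, 20, 20)),
    "background region is empty"
  )
})

test_that("otsu threshold separates a bimodal image and matches EBImage", {
  set.seed(8)
  img <- matrix(c(rnorm(300, 0.2, 0.03), rnorm(100, 0.8, 0.03)), 20, 20)
  img <- pmin(pmax(img, 0), 1)
  thr <- threshold_otsu(img)
  expect_gt(thr, 0.3)
  expect_lt(thr, 0.7)
  # any cut in the inter-mode gap is optimal; agree with EBImage to gap scale
  ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  expect_equal(thr, ref, tolerance = 0.15)
})

test_that("tile counts are half-open, summed, and bounded by the image", {
  # 10 cells in each of 16 fields of a 912 px image at 1 um/px, 228-um fields
  centers <- tidyr::expand_grid(fx = 0:3, fy = 0:3, i = 1:10)
  set.seed(2)
  centers$x <- centers$fx * 228 + runif(nrow(centers), 0, 227.9)
  centers$y <- centers$fy * 228 + runif(nrow(centers), 0, 227.9)
  res <- tile_cell_density(centers, c(912, 912), 228, 16, 1)
  expect_equal(res$summary$total_count, 160L)
  expect_equal(res$fields$count, rep(10L, 16))

  none <- tile_cell_density(centers[0, ], c(912, 912), 228, 16, 1)
  expect_equal(none$summary$total_count, 0L)

  # a centroid on a shared edge is counted once (half-open intervals)
  edge <- tibble::tibble(x = 228, y = 10)
  res_e <- tile_cell_density(edge, c(912, 912), 228, 16, 1)
  expect_equal(res_e$summary$total_count, 1L)

  expect_error(tile_cell_density(centers, c(100, 100), 228, 1, 1), "larger")
  expect_error(tile_cell_density(centers, c(912, 912), 228, 17, 1), "complete")
})

test_that("puncta sizes are masked, filtered, and scale with pixel size", {
  mask <- matrix(FALSE, 30, 30)
  mask[5:20, 5:20] <- TRUE
  puncta <- matrix(FALSE, 30, 30)
  puncta[6:10, 7:10] <- TRUE       # 5 x 4 = 20 px inside the mask
  puncta[25:28, 25:28] <- TRUE     # outside every mask
  puncta[15, 15] <- TRUE           # 1 px, below min size

  res <- puncta_size_stats(puncta, mask, pixel_size_um = 1)
  expect_equal(res$summary$n_puncta, 1L)
  expect_equal(res$summary$mean_area_um2, 20)

  # quadratic scaling with pixel size
  for (ps in c(0.5, 2)) {
    r <- puncta_size_stats(puncta, mask, pixel_size_um = ps)
    expect_equal(r$summary$mean_area_um2, 20 * ps^2)
  }

  expect_warning(
    empty <- puncta_size_stats(puncta, matrix(FALSE, 30, 30), 1),
    "no mask-positive"
  )
  expect_equal(empty$summary$n_puncta, 0L)
  expect_error(puncta_size_stats(puncta, matrix(TRUE, 3, 3), 1), "geometry")
})

test_that("images round-trip through TIFF and PNG", {
  set.seed(4)
  img <- synthetic_image(matrix(runif(64), 8, 8), 1, "iba1")
  # 16-bit TIFF, 8-bit PNG: quantisation bounds the round-trip error
  for (spec in list(list(ext = ".tiff", tol = 1 / 65535),
                    list(ext = ".png", tol = 1 / 255))) {
    path <- tempfile(fileext = spec$ext)
    write_image(img, path)
    back <- read_image(path, 1, "iba1")
    expect_lt(max(abs(back$pixels - img$pixels)), spec$tol)
  }
})
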