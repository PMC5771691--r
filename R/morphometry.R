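#' Construct a single-channel synthetic image
#'
#' Container for the morphometry operators: a numeric pixel matrix (rows are
#' image rows, values in `[0, 1]`), the physical pixel size, a channel label
#' naming the stain the image emulates, and optional ground truth from the
#' generator that produced it.
#'
#' Pixel coordinates throughout the package are 0-based `(x, y)` with `x`
#' along columns and `y` along rows, row-major.
#'
#' @param pixels Numeric matrix, values in `[0, 1]`.
#' @param pixel_size_um Physical edge length of one pixel in micrometres.
#' @param channel Stain label: `"calbindin"`, `"iba1"`, `"cd68"`, or
#'   `"nuclei"`.
#' @param truth Optional ground-truth list (object tables, layer path).
#' @return A `synthetic_image` object.
#' @export
synthetic_image <- function(pixels, pixel_size_um, channel = "calbindin",
                            truth = NULL) {
  stopifnot(is.matrix(pixels), length(pixels) > 0, pixel_size_um > 0)
  channel <- match.arg(channel, c("calbindin", "iba1", "cd68", "nuclei"))
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel = channel, truth = truth),
    class = "synthetic_image"
  )
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat("<synthetic_image> ", ncol(x$pixels), "x", nrow(x$pixels),
    " px @ ", x$pixel_size_um, " um/px, channel: ", x$channel,
    if (!is.null(x$truth)) ", with ground truth" else "", "\n", sep = "")
  invisible(x)
}

#' Raster view of a synthetic image
#'
#' @param object A `synthetic_image`.
#' @param ... Unused.
#' @return A ggplot raster of the pixel intensities with physical axes in
#'   micrometres.
#' @export
autoplot.synthetic_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(y = seq_len(nrow(px)) - 1, x = seq_len(ncol(px)) - 1)
  df$intensity <- as.vector(t(px))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x * object$pixel_size_um,
    y = .data$y * object$pixel_size_um,
    fill = .data$intensity
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = object$channel)
}

#' Read or write a single-channel image
#'
#' Thin wrappers over the TIFF and PNG readers; the format is chosen by
#' file extension. Multi-channel files are reduced to their first channel
#' with a warning.
#'
#' @param path File path (`.tif`/`.tiff` or `.png`).
#' @param pixel_size_um Pixel size to attach to the image (metadata is not
#'   read from the file).
#' @param channel Channel label for the returned image.
#' @return `read_image()` returns a `synthetic_image`; `write_image()`
#'   returns `path` invisibly.
#' @export
read_image <- function(path, pixel_size_um, channel = "calbindin") {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    abort(paste0("unsupported image format: .", ext))
  )
  if (length(dim(px)) == 3) {
    warn("multi-channel image; using channel 1")
    px <- px[, , 1]
  }
  synthetic_image(px, pixel_size_um, channel)
}

#' @rdname read_image
#' @param image A `synthetic_image` or numeric matrix in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "synthetic_image")) image$pixels else image
  px <- pmin(pmax(px, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "tif" = ,
    "tiff" = tiff::writeTIFF(px, path, bits.per.sample = 16),
    "png" = png::writePNG(px, path),
    abort(paste0("unsupported image format: .", ext))
  )
  invisible(path)
}

.image_pixels <- function(image) {
  if (inherits(image, "synthetic_image")) image$pixels
  else if (is.matrix(image)) image
  else abort("image must be a synthetic_image or a numeric matrix")
}

#' Otsu threshold of an intensity image
#'
#' Histogram-based Otsu threshold: the cut maximising the between-class
#' variance of the binarisation. Returned on the intensity scale of the
#' input.
#'
#' @param x Numeric matrix or vector of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value.
#' @export
threshold_otsu <- function(x, n_bins = 256) {
  x <- as.vector(x)
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("no finite intensities")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  mu_t <- mu[n_bins]
  n <- w[n_bins]
  between <- (mu_t * w - mu * n)^2 / (w * (n - w))
  between[!is.finite(between)] <- 0
  # the criterion plateaus across an empty gap between modes; cut mid-gap
  best <- which(between == max(between))
  mean(mids[best])
}

#' Resolve a threshold rule to a cutoff intensity
#'
#' Threshold rules for positive-signal detection. The default,
#' `background_mean_plus_k_sd`, emulates setting a cutoff against the dark
#' background: the background population is either a supplied mask or, by
#' default, the pixels below the Otsu cut, and the threshold is its mean
#' plus `k` standard deviations.
#'
#' @param image A `synthetic_image` or matrix.
#' @param rule `"background_mean_plus_k_sd"` (default), `"otsu"`, or
#'   `"fixed"`.
#' @param k Multiplier on the background SD (default 3).
#' @param value Cutoff for `rule = "fixed"`.
#' @param background_mask Optional logical matrix marking background pixels
#'   for the background rule.
#' @return The threshold intensity.
#' @export
resolve_threshold <- function(image,
                              rule = c("background_mean_plus_k_sd",
                                       "otsu", "fixed"),
                              k = 3, value = NULL, background_mask = NULL) {
  rule <- match.arg(rule)
  px <- .image_pixels(image)
  switch(rule,
    fixed = {
      if (is.null(value)) abort("rule = 'fixed' needs a threshold value")
      value
    },
    otsu = threshold_otsu(px),
    background_mean_plus_k_sd = {
      bg <- if (!is.null(background_mask)) {
        px[background_mask]
      } else {
        px[px < threshold_otsu(px)]
      }
      if (length(bg) == 0) abort("background region is empty; cannot apply background rule")
      sdbg <- if (length(bg) > 1) sd(bg) else 0
      thr <- mean(bg) + k * sdbg
      if (sdbg == 0) {
        # constant background: "above background" must exclude the
        # background itself
        thr <- thr + max(abs(thr), 1) * 1e-9
      }
      thr
    }
  )
}

#' Label connected components of a binary mask
#'
#' Labels each connected set of `TRUE` pixels with a distinct integer,
#' under 4- or 8-connectivity (8 by default, matching common image-analysis
#' practice). Implemented by iterated label min-propagation, which converges
#' for any mask and is fast for the compact blobs (somata, puncta) these
#' analyses deal with.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix; 0 is background, components are numbered
#'   `1..n` in raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8")
  mask <- mask != 0
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  idx <- matrix(seq_len(nr * nc), nr, nc)
  idx[!mask] <- NA_integer_
  lab_full <- matrix(NA_integer_, nr, nc)
  lab_full[mask] <- which(mask)

  shift <- function(m, dr, dc, fill = NA) {
    out <- matrix(fill, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    rsrc <- rs - dr; csrc <- cs - dc
    rok <- rsrc >= 1 & rsrc <= nr
    cok <- csrc >= 1 & csrc <= nc
    out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
    out
  }
  offsets <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8) {
    offsets <- c(offsets, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  cur <- lab_full
  repeat {
    nxt <- cur
    for (off in offsets) {
      nb <- shift(cur, off[1], off[2])
      upd <- mask & !is.na(nb) & (is.na(nxt) | nb < nxt)
      nxt[upd] <- nb[upd]
    }
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  out <- matrix(0L, nr, nc)
  if (any(mask)) {
    vals <- cur[mask]
    uniq <- unique(vals)
    # number components in raster order of their minimum pixel index
    ord <- order(uniq)
    remap <- integer(max(uniq))
    remap[uniq[ord]] <- seq_along(uniq)
    out[mask] <- remap[vals]
  }
  out
}

#' Per-component areas and centroids
#'
#' @param labels Integer label matrix from [label_components()].
#' @param pixel_size_um Pixel size in micrometres.
#' @return A tibble with one row per component: `label`, `area_px`,
#'   `area_um2`, and the centroid in 0-based pixel coordinates (`x`, `y`).
#' @export
component_stats <- function(labels, pixel_size_um = 1) {
  ks <- sort(unique(labels[labels > 0]))
  if (length(ks) == 0) {
    return(tibble(label = integer(), area_px = integer(),
      area_um2 = numeric(), x = numeric(), y = numeric()))
  }
  pos <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  tibble(
    label = ks,
    area_px = as.integer(tabulate(lab)[ks]),
    area_um2 = tabulate(lab)[ks] * pixel_size_um^2,
    x = as.numeric(tapply(pos[, "col"] - 1, lab, mean)[as.character(ks)]),
    y = as.numeric(tapply(pos[, "row"] - 1, lab, mean)[as.character(ks)])
  )
}

# min distance from points (x, y) to a polyline; all in pixel units
.dist_to_polyline <- function(x, y, path) {
  px <- path$x; py <- path$y
  n <- length(px) - 1
  d2 <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    ax <- px[i]; ay <- py[i]
    bx <- px[i + 1]; by <- py[i + 1]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
    dx <- x - (ax + t * vx)
    dy <- y - (ay + t * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

.polyline_length <- function(path) {
  sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
}

#' Purkinje-cell linear density along a layer path
#'
#' Counts detected (or ground-truth) somata lying within a capture distance
#' of the cell-layer polyline and divides by the measured layer length,
#' reported per 100 micrometres of layer — cell bodies per length of the
#' layer, the standard readout for a cell type arranged in a single row.
#'
#' @param centers Data frame of soma centres in 0-based pixel coordinates
#'   (columns `x`, `y`); may be empty.
#' @param path Data frame polyline (columns `x`, `y`, pixel coordinates)
#'   tracing the cell layer.
#' @param pixel_size_um Pixel size in micrometres.
#' @param capture_dist_um Maximum distance from the path for a soma to count
#'   (default 12 um, i.e. 1.5 x a typical 8-um soma radius).
#' @return A one-row tibble: `n_cells`, `path_length_um`,
#'   `density_per_100um`.
#' @export
#' @examples
#' path <- tibble::tibble(x = c(0, 1000), y = c(0, 0))
#' cells <- tibble::tibble(x = seq(5, 995, length.out = 30), y = 2)
#' pc_linear_density(cells, path, pixel_size_um = 1)
pc_linear_density <- function(centers, path, pixel_size_um,
                              capture_dist_um = 12) {
  stopifnot(pixel_size_um > 0)
  len_um <- .polyline_length(path) * pixel_size_um
  if (!is.finite(len_um) || len_um <= 0) abort("layer path has zero length")
  n <- if (is.null(centers) || nrow(centers) == 0) {
    0L
  } else {
    d_um <- .dist_to_polyline(centers$x, centers$y, path) * pixel_size_um
    sum(d_um <= capture_dist_um)
  }
  tibble(
    n_cells = as.integer(n),
    path_length_um = len_um,
    density_per_100um = 100 * n / len_um
  )
}

#' Stain-positive area fraction of an image
#'
#' Percentage of pixels at or above a threshold — the overall positive
#' signal of a stain, e.g. calbindin coverage of a cerebellar section. The
#' threshold is set by [resolve_threshold()].
#'
#' @inheritParams resolve_threshold
#' @return A one-row tibble: `threshold`, `positive_px`, `total_px`,
#'   `fraction_pct`.
#' @export
signal_area_fraction <- function(image,
                                 rule = c("background_mean_plus_k_sd",
                                          "otsu", "fixed"),
                                 k = 3, value = NULL,
                                 background_mask = NULL) {
  px <- .image_pixels(image)
  thr <- resolve_threshold(image, rule, k = k, value = value,
    background_mask = background_mask)
  pos <- sum(px >= thr)
  tibble(
    threshold = thr,
    positive_px = as.integer(pos),
    total_px = length(px),
    fraction_pct = 100 * pos / length(px)
  )
}

#' Tile-based cell counts over square fields
#'
#' Lays a grid of square fields (side `field_size_um`) over the image area
#' from the top-left corner, keeps the first `n_fields` complete fields in
#' raster order, and counts the cells whose centroid falls in each field.
#' Field membership is half-open — top/left edges inclusive, bottom/right
#' exclusive — so no centroid is counted twice. Reports per-field counts,
#' the summed total, and the density per field.
#'
#' @param centers Data frame of cell centroids (0-based pixel `x`, `y`).
#' @param image_dim Image size as `c(width_px, height_px)`, or a
#'   `synthetic_image` from which it is taken.
#' @param field_size_um Field side length in micrometres.
#' @param n_fields Number of fields to analyse; must fit in the image.
#' @param pixel_size_um Pixel size in micrometres.
#' @return A list: `$fields` (tibble with field origin and count) and
#'   `$summary` (one-row tibble: `n_fields`, `total_count`,
#'   `mean_count_per_field`, `field_area_um2`).
#' @export
tile_cell_density <- function(centers, image_dim, field_size_um, n_fields,
                              pixel_size_um) {
  if (inherits(image_dim, "synthetic_image")) {
    image_dim <- c(ncol(image_dim$pixels), nrow(image_dim$pixels))
  }
  stopifnot(length(image_dim) == 2, pixel_size_um > 0, field_size_um > 0)
  side_px <- field_size_um / pixel_size_um
  nx <- floor(image_dim[1] / side_px)
  ny <- floor(image_dim[2] / side_px)
  if (nx < 1 || ny < 1) abort("field is larger than the image")
  if (n_fields > nx * ny) {
    abort(paste0("image holds only ", nx * ny, " complete ",
      field_size_um, "-um fields; ", n_fields, " requested"))
  }
  grid <- tidyr::expand_grid(fy = seq_len(ny) - 1, fx = seq_len(nx) - 1)
  grid <- grid[seq_len(n_fields), ]
  counts <- purrr::map2_int(grid$fx, grid$fy, function(fx, fy) {
    if (is.null(centers) || nrow(centers) == 0) return(0L)
    x0 <- fx * side_px; y0 <- fy * side_px
    sum(centers$x >= x0 & centers$x < x0 + side_px &
        centers$y >= y0 & centers$y < y0 + side_px)
  })
  fields <- tibble(
    field = seq_len(n_fields),
    x0_px = grid$fx * side_px,
    y0_px = grid$fy * side_px,
    count = counts
  )
  list(
    fields = fields,
    summary = tibble(
      n_fields = n_fields,
      total_count = sum(counts),
      mean_count_per_field = mean(counts),
      field_area_um2 = field_size_um^2
    )
  )
}

#' Size of stain-positive puncta inside cell masks
#'
#' Quantifies phagocytic activation: connected components of the thresholded
#' puncta channel (e.g. CD68) are measured, keeping only components that
#' overlap a positive cell mask (e.g. Iba1-positive microglia), and their
#' areas are reported in square micrometres (`pixel count x pixel_size^2`).
#' Components smaller than `min_size_px` pixels are treated as noise and
#' dropped.
#'
#' If no cell mask pixel is positive the result is empty, with a warning —
#' a region with too few marker-positive cells yields no size analysis
#' rather than an error.
#'
#' @param puncta A `synthetic_image`/matrix of puncta-channel intensities,
#'   or a logical matrix already thresholded.
#' @param cell_mask Logical (or 0/1) matrix of cell-positive pixels; same
#'   geometry as `puncta`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param rule,k,value,background_mask Threshold rule for an intensity
#'   puncta channel (see [resolve_threshold()]); ignored for logical input.
#' @param min_size_px Minimum component size in pixels (default 2).
#' @param connectivity Component connectivity, 4 or 8 (default 8).
#' @return A list: `$puncta` (tibble of kept components with `area_um2`)
#'   and `$summary` (one-row tibble: `n_puncta`, `mean_area_um2`).
#' @export
puncta_size_stats <- function(puncta, cell_mask, pixel_size_um,
                              rule = "fixed", k = 3, value = 0.5,
                              background_mask = NULL,
                              min_size_px = 2, connectivity = 8) {
  px <- .image_pixels(puncta)
  cell_mask <- cell_mask != 0
  if (!all(dim(px) == dim(cell_mask))) {
    abort("puncta channel and cell mask must share geometry")
  }
  if (!any(cell_mask)) {
    warn("no mask-positive cells; returning empty puncta size result")
    return(list(
      puncta = tibble(label = integer(), area_px = integer(),
        area_um2 = numeric(), x = numeric(), y = numeric()),
      summary = tibble(n_puncta = 0L, mean_area_um2 = NA_real_)
    ))
  }
  mask <- if (is.logical(px)) px else {
    thr <- resolve_threshold(px, rule, k = k, value = value,
      background_mask = background_mask)
    px >= thr
  }
  labels <- label_components(mask, connectivity)
  stats <- component_stats(labels, pixel_size_um)
  stats <- stats[stats$area_px >= min_size_px, , drop = FALSE]
  if (nrow(stats) > 0) {
    in_cell <- vapply(stats$label, function(l) {
      any(cell_mask[labels == l])
    }, logical(1))
    stats <- stats[in_cell, , drop = FALSE]
  }
  list(
    puncta = stats,
    summary = tibble(
      n_puncta = nrow(stats),
      mean_area_um2 = if (nrow(stats) > 0) mean(stats$area_um2) else NA_real_
    )
  )
}
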