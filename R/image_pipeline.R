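#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence image as the surface
#' traced by a ball of radius `ball_radius_px` rolled under the intensity
#' landscape -- computed as grayscale morphological opening with a
#' hemispherical (non-flat) ball structuring element -- and subtracts it.
#' Features smaller than the ball (cells) are preserved; smooth large-scale
#' background (uneven illumination, lamp gradients) is removed. The output
#' is non-negative because the opening never exceeds the image.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param ball_radius_px Ball radius in pixels (default 20, >= 1; must be
#'   smaller than half the smallest image dimension).
#' @return Background-subtracted image, same dimensions.
#' @export
subtract_background <- function(image, ball_radius_px = 20L) {
  image <- as_intensity_matrix(image)
  r <- as.integer(ball_radius_px)
  if (r < 1L) stop("`ball_radius_px` must be >= 1")
  if (r >= min(dim(image)) / 2) {
    stop("`ball_radius_px` must be below half the smallest image dimension")
  }
  bg <- ball_opening_cpp(image, r)
  pmax(image - bg, 0)
}

as_intensity_matrix <- function(image) {
  if (is.data.frame(image)) image <- as.matrix(image)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix")
  }
  if (any(dim(image) < 64L)) stop("image must be at least 64 x 64 pixels")
  if (any(image < 0)) stop("image intensities must be non-negative")
  storage.mode(image) <- "double"
  image
}

#' Bandpass cell mask
#'
#' Enhances cell edges with a difference-of-Gaussians bandpass (sigmas
#' `small_px / 2` and `large_px / 2`, passing structures between the two
#' scales), thresholds automatically (Otsu), and fills interior holes. The
#' mask is invariant to adding a constant to the image (the bandpass has no
#' DC response) and fully deterministic.
#'
#' @param image Numeric matrix, normally the output of
#'   [subtract_background()].
#' @param small_px Smallest structure size passed, in pixels (default 3).
#' @param large_px Largest structure size passed, in pixels (default 40).
#' @param threshold_method Currently `"otsu"`.
#' @return Logical matrix: `TRUE` inside cells. A flat filtered image
#'   yields an empty mask with a warning.
#' @export
bandpass_mask <- function(image, small_px = 3, large_px = 40,
                          threshold_method = "otsu") {
  image <- as_intensity_matrix(image)
  stopifnot(small_px > 0, small_px < large_px)
  threshold_method <- match.arg(threshold_method, "otsu")
  dog <- gaussian_blur(image, small_px / 2) - gaussian_blur(image, large_px / 2)
  rng <- range(dog)
  if (diff(rng) < 1e-9) {
    warning("filtered image is flat; returning an empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  dogn <- (dog - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(dogn), range = c(0, 1))
  fill_holes(dogn > thr)
}

gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  # default kernel radius is 2*ceiling(3*sigma)+1; clamp to the image size
  # (odd) so wide low-pass scales work on small fields
  radius <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
                min(dim(image)) - (min(dim(image)) + 1L) %% 2L)
  EBImage::imageData(EBImage::gblur(EBImage::Image(image), sigma = sigma,
                                    radius = radius))
}

# Fill interior holes of a binary mask: background components (4-connected)
# not touching the image border are holes.
fill_holes <- function(mask) {
  bg <- label_components_cpp(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  hole <- matrix(!(bg %in% c(0L, border)), nrow(mask), ncol(mask))
  mask | hole
}

#' Crofton perimeter of a binary shape
#'
#' Estimates the perimeter from boundary crossings with line grids in four
#' directions (horizontal, vertical, both diagonals), the Crofton-formula
#' construction: `P = pi/2 * mean(crossings * spacing)`. For a rasterized
#' disk this converges to `2*pi*r` without the overestimation of naive
#' boundary-pixel counting.
#'
#' @param mask Logical matrix, `TRUE` inside the shape.
#' @return Estimated perimeter in pixel units.
#' @export
crofton_perimeter <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  i_h <- sum(m[, -1] != m[, -nc])                 # crossings along rows
  i_v <- sum(m[-1, ] != m[-nr, ])                 # crossings along columns
  i_d1 <- sum(m[-1, -1] != m[-nr, -nc])           # diagonal "\"
  i_d2 <- sum(m[-1, -nc] != m[-nr, -1])           # diagonal "/"
  # parallel diagonal grid lines are 1/sqrt(2) apart
  pi / 2 * mean(c(i_h, i_v, i_d1 / sqrt(2), i_d2 / sqrt(2)))
}

#' Segment and filter particles, measuring per-cell intensity
#'
#' Labels the mask's 8-connected components, measures each component's area
#' (converted to um^2 through the pixel size), circularity
#' (`4*pi*area/perimeter^2` with the Crofton perimeter, capped at 1) and the
#' median intensity of the background-subtracted image inside it, then
#' keeps components whose area and circularity fall inside the given ranges
#' (both bounds inclusive).
#'
#' @param mask Logical segmentation mask.
#' @param intensity_image Background-subtracted intensity matrix, same
#'   dimensions as `mask`.
#' @param pixel_size_um Microns per pixel; required, since the size filter
#'   is in um^2.
#' @param size_range_um2 Inclusive area filter in um^2 (default
#'   `c(80, 2000)`).
#' @param circularity_range Inclusive circularity filter (default
#'   `c(0.1, 1.0)`).
#' @return Data frame with one row per retained particle: `label`,
#'   `area_um2`, `circularity`, `median_intensity`, `centroid_row`,
#'   `centroid_col`.
#' @export
analyze_particles <- function(mask, intensity_image, pixel_size_um,
                              size_range_um2 = c(80, 2000),
                              circularity_range = c(0.1, 1.0)) {
  if (missing(pixel_size_um) || is.null(pixel_size_um) ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` is required: the area filter is in um^2")
  }
  stopifnot(is.logical(mask), identical(dim(mask), dim(intensity_image)))
  labels <- label_components_cpp(mask, 8L)
  measure_particles(labels, intensity_image, pixel_size_um,
                    size_range_um2, circularity_range)
}

measure_particles <- function(labels, intensity_image, pixel_size_um,
                              size_range_um2 = c(80, 2000),
                              circularity_range = c(0.1, 1.0)) {
  n_lab <- max(labels)
  out <- data.frame(label = integer(0), area_um2 = numeric(0),
                    circularity = numeric(0), median_intensity = numeric(0),
                    centroid_row = numeric(0), centroid_col = numeric(0))
  if (n_lab == 0L) return(out)
  idx <- which(labels > 0)
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  labs <- labels[idx]
  for (l in seq_len(n_lab)) {
    sel <- labs == l
    area_px <- sum(sel)
    r <- rows[sel]; c <- cols[sel]
    box <- matrix(FALSE, diff(range(r)) + 3L, diff(range(c)) + 3L)
    box[cbind(r - min(r) + 2L, c - min(c) + 2L)] <- TRUE
    per <- crofton_perimeter(box)
    circ <- min(4 * pi * area_px / per^2, 1)
    area_um2 <- area_px * pixel_size_um^2
    if (area_um2 < size_range_um2[1] || area_um2 > size_range_um2[2]) next
    if (circ < circularity_range[1] || circ > circularity_range[2]) next
    out <- rbind(out, data.frame(
      label = l, area_um2 = area_um2, circularity = circ,
      median_intensity = stats::median(intensity_image[cbind(r, c)]),
      centroid_row = mean(r), centroid_col = mean(c)))
  }
  rownames(out) <- NULL
  out
}

#' Summarize one condition across replicate fields
#'
#' Computes the per-field median of the per-cell median intensities and the
#' replicate-averaged intensity histogram: each field's particle
#' intensities are binned on shared edges and normalized to unit area, then
#' the histograms are averaged bin-wise with a standard deviation band.
#' Fields without particles are excluded with a warning.
#'
#' @param particle_sets List of [analyze_particles()] data frames, one per
#'   replicate field.
#' @param bin_edges Shared histogram bin edges; `NULL` derives 50 bins from
#'   the pooled 1st-99th percentile range.
#' @param n_bins Number of bins when `bin_edges` is `NULL`.
#' @return A `condition_summary`: list with `field_medians`, `bin_edges`,
#'   `hist_mean`, `hist_sd` and `n_replicates`.
#' @export
summarize_condition <- function(particle_sets, bin_edges = NULL,
                                n_bins = 50L) {
  stopifnot(is.list(particle_sets))
  empty <- vapply(particle_sets, function(p) nrow(p) == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " field(s) with zero particles excluded")
    particle_sets <- particle_sets[!empty]
  }
  if (!length(particle_sets)) stop("no fields with particles")
  values <- lapply(particle_sets, function(p) p$median_intensity)
  if (is.null(bin_edges)) {
    pooled <- unlist(values)
    rng <- stats::quantile(pooled, c(0.01, 0.99), names = FALSE)
    if (diff(rng) <= 0) rng <- range(pooled) + c(-0.5, 0.5)
    bin_edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  hists <- vapply(values, function(v) {
    v <- pmin(pmax(v, bin_edges[1]), bin_edges[length(bin_edges)])
    h <- graphics::hist(v, breaks = bin_edges, plot = FALSE)
    h$counts / sum(h$counts)
  }, numeric(length(bin_edges) - 1L))
  hists <- matrix(hists, ncol = length(values))
  structure(list(
    field_medians = vapply(values, stats::median, numeric(1)),
    bin_edges = bin_edges,
    hist_mean = rowMeans(hists),
    hist_sd = if (ncol(hists) >= 2L) apply(hists, 1, stats::sd) else
      rep(NA_real_, nrow(hists)),
    n_replicates = length(values)), class = "condition_summary")
}

#' One-sided Welch test for tandem-tag amplification
#'
#' Welch's unequal-variance two-sample t-test comparing per-field median
#' intensities of the single-tag (1x) and tandem (5x) conditions, with the
#' one-sided alternative that the 1x mean minus the 5x mean is below zero
#' (i.e. the tandem tag is brighter). Also reports the amplification fold,
#' the ratio of condition means of field medians.
#'
#' @param medians_1x,medians_5x Numeric vectors of per-field median
#'   intensities (each length >= 2).
#' @return An `amplification_result`: list with `fold_change`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `alternative` and a
#'   `degenerate` flag (both samples constant and equal, where p = 0.5 by
#'   convention).
#' @export
welch_one_sided <- function(medians_1x, medians_5x) {
  stopifnot(length(medians_1x) >= 2L, length(medians_5x) >= 2L)
  degenerate <- stats::var(medians_1x) == 0 && stats::var(medians_5x) == 0
  if (degenerate && mean(medians_1x) != mean(medians_5x)) {
    stop("zero variance with unequal means: t is undefined")
  }
  if (degenerate) {
    tt <- list(statistic = c(t = 0),
               parameter = c(df = length(medians_1x) + length(medians_5x) - 2),
               p.value = 0.5)
  } else {
    tt <- stats::t.test(medians_1x, medians_5x, alternative = "less",
                        var.equal = FALSE)
  }
  structure(list(fold_change = mean(medians_5x) / mean(medians_1x),
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 alternative = "mean(1x) - mean(5x) < 0",
                 degenerate = degenerate),
            class = "amplification_result")
}

#' @export
print.amplification_result <- function(x, ...) {
  cat(sprintf(
    "<amplification_result> fold %.3f, t = %.3f, df = %.2f, one-sided p = %.4g\n",
    x$fold_change, x$t_statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Run the microscopy quantification pipeline
#'
#' For every field of every condition: rolling-ball background subtraction,
#' bandpass segmentation, particle filtering and per-cell median
#' intensities -- in that fixed order -- then per-condition summaries and,
#' when both comparison conditions are present with at least two fields
#' each, the one-sided Welch amplification test.
#'
#' @param image_sets Named list (condition -> list of intensity matrices),
#'   e.g. the `image` elements of [simulate_imaging_experiment()] output.
#' @param pixel_size_um Microns per pixel.
#' @param ball_radius_px Rolling-ball radius (default 20).
#' @param small_px,large_px Bandpass scales (defaults 3 and 40).
#' @param size_range_um2,circularity_range Particle filters (defaults
#'   80-2000 um^2 and 0.1-1.0).
#' @param compare Length-2 character: reference and test condition names
#'   for the Welch test (default `c("1x", "5x")`).
#' @return An `image_report`: list with `particles` (per condition, per
#'   field), `summaries` (per condition), and `amplification` (the Welch
#'   result, or `NULL` if the comparison could not run).
#' @export
run_image_analysis <- function(image_sets, pixel_size_um = 0.65,
                               ball_radius_px = 20L,
                               small_px = 3, large_px = 40,
                               size_range_um2 = c(80, 2000),
                               circularity_range = c(0.1, 1.0),
                               compare = c("1x", "5x")) {
  stopifnot(is.list(image_sets), !is.null(names(image_sets)))
  particles <- lapply(image_sets, function(fields) {
    lapply(fields, function(img) {
      if (is.list(img)) img <- img$image
      bgsub <- subtract_background(img, ball_radius_px)
      mask <- bandpass_mask(bgsub, small_px, large_px)
      analyze_particles(mask, bgsub, pixel_size_um,
                        size_range_um2, circularity_range)
    })
  })
  summaries <- lapply(particles, summarize_condition)
  amplification <- NULL
  if (all(compare %in% names(summaries))) {
    m1 <- summaries[[compare[1]]]$field_medians
    m2 <- summaries[[compare[2]]]$field_medians
    if (length(m1) >= 2L && length(m2) >= 2L) {
      amplification <- welch_one_sided(m1, m2)
    } else {
      warning("fewer than 2 replicate fields; Welch test skipped")
    }
  }
  structure(list(particles = particles, summaries = summaries,
                 amplification = amplification,
                 settings = list(pixel_size_um = pixel_size_um,
                                 ball_radius_px = ball_radius_px,
                                 small_px = small_px, large_px = large_px,
                                 size_range_um2 = size_range_um2,
                                 circularity_range = circularity_range)),
            class = "image_report")
}

#' @export
print.image_report <- function(x, ...) {
  cat("<image_report>\n")
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-6s %d fields, mean of field medians %.1f\n", nm,
                s$n_replicates, mean(s$field_medians)))
  }
  if (!is.null(x$amplification)) print(x$amplification)
  invisible(x)
}

#' Replicate-averaged intensity histograms per condition
#'
#' @param summaries Named list of `condition_summary` objects sharing bin
#'   edges.
#' @return A ggplot object: mean histogram per condition with an sd ribbon.
#' @export
plot_condition_histograms <- function(summaries) {
  dfs <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    mid <- (s$bin_edges[-1] + s$bin_edges[-length(s$bin_edges)]) / 2
    data.frame(condition = nm, intensity = mid, density = s$hist_mean,
               sd = s$hist_sd)
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intensity, y = .data$density,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$density - .data$sd, 0),
                                      ymax = .data$density + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "per-cell median intensity",
                  y = "mean normalized frequency") +
    ggplot2::theme_minimal()
}
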