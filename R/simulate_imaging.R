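#' Configuration for the synthetic microscopy-field generator
#'
#' Describes fluorescence microscopy fields of tagged nuclei: elliptical
#' cells of roughly `cell_radius_px_mean` pixels placed without overlap,
#' each with a log-normal per-cell intensity whose mean is
#' `intensity_scale` times the condition fold factor, over an additive
#' background plane with a lateral gradient, degraded by Poisson photon
#' noise and Gaussian read noise, quantized to 16 bits.
#'
#' @param field_shape Image dimensions in pixels (rows, cols), each >= 64.
#' @param pixel_size_um Microns per pixel (default 0.65: a 6.5 um camera
#'   pixel at 10x magnification).
#' @param n_cells Cells attempted per field.
#' @param cell_radius_px_mean,cell_radius_px_sd Nuclear radius distribution
#'   in pixels.
#' @param intensity_scale Mean per-cell intensity (counts) at fold 1.
#' @param intensity_cv Cell-to-cell coefficient of variation of intensity.
#' @param background_level Constant background (counts).
#' @param background_gradient Amplitude of a left-to-right linear background
#'   ramp (counts).
#' @param noise_poisson Logical: apply Poisson photon noise.
#' @param noise_gaussian_sd Gaussian read-noise standard deviation (counts).
#' @param n_replicates Fields per condition (default 4).
#' @param replicate_cv Between-replicate coefficient of variation of
#'   `intensity_scale` (staining/expression day-to-day variation);
#'   0 disables jitter.
#' @param seed Master random seed.
#' @return A validated `imaging_sim_config` list.
#' @export
imaging_sim_config <- function(field_shape = c(256L, 256L),
                               pixel_size_um = 0.65,
                               n_cells = 40L,
                               cell_radius_px_mean = 12,
                               cell_radius_px_sd = 1.5,
                               intensity_scale = 3000,
                               intensity_cv = 0.35,
                               background_level = 200,
                               background_gradient = 100,
                               noise_poisson = TRUE,
                               noise_gaussian_sd = 10,
                               n_replicates = 4L,
                               replicate_cv = 0.1,
                               seed = 1L) {
  cfg <- list(field_shape = as.integer(field_shape),
              pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
              cell_radius_px_mean = cell_radius_px_mean,
              cell_radius_px_sd = cell_radius_px_sd,
              intensity_scale = intensity_scale, intensity_cv = intensity_cv,
              background_level = background_level,
              background_gradient = background_gradient,
              noise_poisson = isTRUE(noise_poisson),
              noise_gaussian_sd = noise_gaussian_sd,
              n_replicates = as.integer(n_replicates),
              replicate_cv = replicate_cv, seed = as.integer(seed))
  stopifnot(length(cfg$field_shape) == 2L, all(cfg$field_shape >= 64L),
            cfg$pixel_size_um > 0, cfg$n_cells >= 0,
            cfg$cell_radius_px_mean > 0, cfg$cell_radius_px_sd >= 0,
            cfg$intensity_scale > 0, cfg$intensity_cv >= 0,
            cfg$background_level >= 0, cfg$background_gradient >= 0,
            cfg$noise_gaussian_sd >= 0, cfg$n_replicates >= 1L,
            cfg$replicate_cv >= 0)
  structure(cfg, class = "imaging_sim_config")
}

#' Render one synthetic microscopy field with ground truth
#'
#' Places elliptical nuclei at random non-overlapping positions, assigns
#' each a log-normal intensity with mean
#' `intensity_scale * condition_fold`, adds the background plane and
#' gradient, applies Poisson and Gaussian noise, and quantizes to a 16-bit
#' integer image. Cells that cannot be placed without overlap or leaving
#' the field are skipped with a warning, so the label mask can carry fewer
#' than `n_cells` labels.
#'
#' @param config An [imaging_sim_config()].
#' @param condition_fold Per-condition intensity fold factor (> 0).
#' @param seed Seed for this field (default: the config seed).
#' @return List with `image` (integer matrix, 16-bit range), `labels`
#'   (integer ground-truth label mask), `cells` (data frame: label, centre,
#'   radius, axis ratio, true intensity) and `n_placed`.
#' @export
render_field <- function(config, condition_fold = 1, seed = config$seed) {
  cfg <- config
  stopifnot(inherits(cfg, "imaging_sim_config"), condition_fold > 0)
  set.seed(seed)
  nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
  sdlog <- sqrt(log(1 + cfg$intensity_cv^2))
  labels <- matrix(0L, nr, nc)
  signal <- matrix(0, nr, nc)
  cells <- data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      radius = numeric(0), axis_ratio = numeric(0),
                      theta = numeric(0), intensity = numeric(0))
  placed <- 0L
  for (i in seq_len(cfg$n_cells)) {
    radius <- max(3, stats::rnorm(1, cfg$cell_radius_px_mean,
                                  cfg$cell_radius_px_sd))
    axis_ratio <- stats::runif(1, 0.75, 1)
    theta <- stats::runif(1, 0, pi)
    intensity <- cfg$intensity_scale * condition_fold *
      stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    ok <- FALSE
    for (try in 1:300) {
      r0 <- stats::runif(1, radius + 2, nr - radius - 1)
      c0 <- stats::runif(1, radius + 2, nc - radius - 1)
      if (nrow(cells) == 0L ||
          all(sqrt((cells$row - r0)^2 + (cells$col - c0)^2) >
              cells$radius + radius + 2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) next
    placed <- placed + 1L
    cells <- rbind(cells, data.frame(label = placed, row = r0, col = c0,
                                     radius = radius, axis_ratio = axis_ratio,
                                     theta = theta, intensity = intensity))
    # rasterize the ellipse within its bounding box
    rr <- max(1, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
    cc <- max(1, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
    dr <- outer(rr - r0, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - c0)
    u <- dr * cos(theta) + dc * sin(theta)
    v <- -dr * sin(theta) + dc * cos(theta)
    inside <- (u / radius)^2 + (v / (radius * axis_ratio))^2 <= 1
    labels[rr, cc][inside] <- placed
    signal[rr, cc][inside] <- intensity
  }
  if (placed < cfg$n_cells) {
    warning(sprintf("placed %d of %d cells without overlap", placed,
                    cfg$n_cells))
  }
  ramp <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  clean <- signal + cfg$background_level + cfg$background_gradient * ramp
  img <- if (cfg$noise_poisson) {
    matrix(stats::rpois(nr * nc, clean), nr, nc)
  } else clean
  if (cfg$noise_gaussian_sd > 0) {
    img <- img + matrix(stats::rnorm(nr * nc, 0, cfg$noise_gaussian_sd),
                        nr, nc)
  }
  img <- matrix(as.integer(round(pmin(pmax(img, 0), 65535))), nr, nc)
  list(image = img, labels = labels, cells = cells, n_placed = placed)
}

#' Simulate a replicated multi-condition imaging experiment
#'
#' Renders `n_replicates` independent fields per condition. Field seeds are
#' derived deterministically from the master seed, and a per-field
#' log-normal jitter of `intensity_scale` (CV `replicate_cv`) emulates
#' replicate-to-replicate variation.
#'
#' @param config An [imaging_sim_config()].
#' @param condition_folds Named numeric vector of per-condition intensity
#'   fold factors, e.g. `c("1x" = 1, "5x" = 2.3)`.
#' @return Named list (one entry per condition) of lists of
#'   [render_field()] results; each field also records `applied_scale`, the
#'   jittered intensity scale it was rendered with.
#' @export
simulate_imaging_experiment <- function(config,
                                        condition_folds = c("1x" = 1,
                                                            "5x" = 2.3)) {
  cfg <- config
  stopifnot(inherits(cfg, "imaging_sim_config"),
            length(condition_folds) >= 1, !is.null(names(condition_folds)),
            all(condition_folds > 0))
  sdrep <- sqrt(log(1 + cfg$replicate_cv^2))
  out <- list()
  for (j in seq_along(condition_folds)) {
    fields <- vector("list", cfg$n_replicates)
    for (k in seq_len(cfg$n_replicates)) {
      field_seed <- (cfg$seed + 7919L * j + 104729L * k) %% .Machine$integer.max
      set.seed(field_seed)
      jitter <- if (cfg$replicate_cv > 0) {
        stats::rlnorm(1, -sdrep^2 / 2, sdrep)
      } else 1
      fcfg <- cfg
      fcfg$intensity_scale <- cfg$intensity_scale * jitter
      f <- render_field(fcfg, condition_fold = condition_folds[[j]],
                        seed = field_seed + 1L)
      f$applied_scale <- fcfg$intensity_scale
      f$condition <- names(condition_folds)[j]
      f$replicate <- k
      fields[[k]] <- f
    }
    out[[names(condition_folds)[j]]] <- fields
  }
  out
}

#' Write a field image or label mask as a 16-bit TIFF
#'
#' @param image Integer matrix in \[0, 65535\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF files")
  }
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a single-channel 8/16-bit TIFF as an intensity matrix
#'
#' @param path TIFF path.
#' @return Numeric matrix on the original integer scale.
#' @export
read_field_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF files")
  }
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}
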