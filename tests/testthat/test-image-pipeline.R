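# Background subtraction, bandpass segmentation, particle filtering and
# the Welch amplification test, checked against analytic oracles and the
# generator's ground truth.

test_that("rolling-ball subtraction zeroes a constant image and preserves small features", {
  const <- matrix(100, 96, 96)
  expect_equal(subtract_background(const, 20), matrix(0, 96, 96))
  # bright disk of radius 5 on a plateau: the radius-20 ball cannot enter
  # it, so its amplitude survives within 2%
  img <- const
  ctr <- 48
  for (i in 1:96) for (j in 1:96) {
    if ((i - ctr)^2 + (j - ctr)^2 <= 25) img[i, j] <- 150
  }
  out <- subtract_background(img, 20)
  expect_equal(max(out), 50, tolerance = 0.02 * 50)
  expect_lt(max(out[img == 100]), 1e-9)
  expect_error(subtract_background(const, 48), "half")
  expect_error(subtract_background(const, 0), ">= 1")
})

test_that("rolling-ball subtraction flattens a linear ramp background", {
  nr <- 256
  ramp <- matrix(rep(seq(0, 100, length.out = nr), each = nr), nr, nr)
  img <- ramp
  for (ctr in list(c(30, 40), c(90, 80))) {
    for (i in 1:nr) for (j in 1:nr) {
      if ((i - ctr[1])^2 + (j - ctr[2])^2 <= 36) img[i, j] <- img[i, j] + 200
    }
  }
  out <- subtract_background(img, 20)
  spots <- img - ramp > 0
  expect_lt(max(out[!spots]), 5) # residual background < 5% of ramp amplitude
  expect_gt(max(out[spots]), 190)
})

test_that("bandpass mask is DC-invariant, deterministic, and empty on flat input", {
  cfg <- small_imaging_config(seed = 31L)
  f <- render_field(cfg, condition_fold = 2)
  img <- subtract_background(f$image, 20)
  m1 <- bandpass_mask(img)
  m2 <- bandpass_mask(img + 500)
  expect_identical(m1, m2)
  expect_warning(m0 <- bandpass_mask(matrix(7, 96, 96)), "flat")
  expect_false(any(m0))
})

test_that("segmentation recovers ground-truth cells and their intensities", {
  cfg <- imaging_sim_config(seed = 32L)
  f <- render_field(cfg, condition_fold = 1.5)
  bgsub <- subtract_background(f$image, 20)
  mask <- bandpass_mask(bgsub)
  p <- analyze_particles(mask, bgsub, cfg$pixel_size_um)
  # match each ground-truth cell to the particle covering it
  seg_labels <- splitFPquant:::label_components_cpp(mask, 8L)
  ious <- vapply(seq_len(f$n_placed), function(l) {
    gt <- f$labels == l
    cand <- seg_labels[gt]
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    sl <- as.integer(names(which.max(table(cand))))
    sm <- seg_labels == sl
    sum(sm & gt) / sum(sm | gt)
  }, numeric(1))
  expect_gte(mean(ious >= 0.5), 0.9)
  # intensity fidelity on matched cells
  m <- vapply(seq_len(nrow(p)), function(i) {
    which.min((f$cells$row - p$centroid_row[i])^2 +
              (f$cells$col - p$centroid_col[i])^2)
  }, integer(1))
  expect_gte(stats::cor(p$median_intensity, f$cells$intensity[m]), 0.95)
})

test_that("particle filters apply the printed bounds inclusively", {
  ps <- 0.65
  px_area <- ps^2
  nr <- 96
  place_blob <- function(mask, r0, c0, n_px, width) {
    rows <- r0 + seq_len(ceiling(n_px / width)) - 1L
    k <- 0L
    for (r in rows) for (cc in c0 + seq_len(width) - 1L) {
      if (k < n_px) { mask[r, cc] <- TRUE; k <- k + 1L }
    }
    mask
  }
  mask <- matrix(FALSE, nr, nr)
  n_below <- floor(80 / px_area)        # 189 px -> 79.85 um^2: below bound
  n_at <- ceiling(80 / px_area)         # 190 px -> 80.28 um^2: inside
  mask <- place_blob(mask, 5, 5, n_below, 14L)
  mask <- place_blob(mask, 40, 40, n_at, 14L)
  intens <- matrix(1, nr, nr)
  p <- analyze_particles(mask, intens, ps)
  expect_equal(nrow(p), 1L)
  expect_gte(p$area_um2, 80)
  # a disk well inside both filters is retained with circularity near 1
  dm <- disk_mask(20L)
  big <- matrix(FALSE, nr, nr)
  big[10 + seq_len(nrow(dm)), 10 + seq_len(ncol(dm))] <- dm
  pd <- analyze_particles(big, matrix(3, nr, nr), ps)
  expect_equal(nrow(pd), 1L)
  expect_equal(pd$area_um2, sum(dm) * px_area, tolerance = 1e-9)
  expect_gt(pd$circularity, 0.9)
  expect_equal(pd$median_intensity, 3)
  # a thin plus-shaped skeleton (in the size range, circularity ~0.05) is
  # discarded by the circularity filter
  plus <- matrix(FALSE, nr, nr)
  plus[30:32, 3:94] <- TRUE
  plus[3:94, 45:47] <- TRUE # 543 px = 229 um^2, perimeter-dominated
  p_plus <- analyze_particles(plus, intens, ps)
  expect_equal(nrow(p_plus), 0L)
  expect_error(analyze_particles(big, matrix(3, nr, nr)), "pixel_size_um")
})

test_that("condition summaries average normalized histograms across replicates", {
  mk <- function(v) {
    data.frame(label = seq_along(v), area_um2 = rep(100, length(v)),
               circularity = rep(0.9, length(v)), median_intensity = v,
               centroid_row = rep(1, length(v)),
               centroid_col = rep(1, length(v)))
  }
  same <- list(mk(c(1, 2, 3, 4, 5)), mk(c(1, 2, 3, 4, 5)))
  s <- summarize_condition(same, bin_edges = seq(0, 6, by = 1))
  expect_equal(s$hist_sd, rep(0, 6))
  expect_equal(unname(s$field_medians), c(3, 3))
  # pooled and averaged histograms differ when replicates differ
  diffr <- list(mk(c(1, 1, 1, 5)), mk(c(5, 5, 5, 1, 3)))
  sd2 <- summarize_condition(diffr, bin_edges = seq(0, 6, by = 1))
  pooled <- graphics::hist(c(1, 1, 1, 5, 5, 5, 5, 1, 3),
                           breaks = seq(0, 6, by = 1), plot = FALSE)
  pooled_norm <- pooled$counts / sum(pooled$counts)
  expect_false(isTRUE(all.equal(sd2$hist_mean, pooled_norm)))
  expect_warning(summarize_condition(list(mk(1:3), mk(numeric(0)))),
                 "zero particles")
})

test_that("Welch test matches the closed form and orients the alternative", {
  res <- welch_one_sided(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t_statistic, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$degrees_of_freedom, 4, tolerance = 1e-10)
  expect_equal(res$p_value, stats::pt(-sqrt(3 / 2), 4), tolerance = 1e-10)
  expect_equal(res$fold_change, 3 / 2, tolerance = 1e-12)
  # closed-form oracle over random small samples
  set.seed(99)
  for (i in 1:1000) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    x <- stats::rnorm(n1, 5, 2)
    y <- stats::rnorm(n2, 6, 1)
    r <- welch_one_sided(x, y)
    se2 <- stats::var(x) / n1 + stats::var(y) / n2
    t_ref <- (mean(x) - mean(y)) / sqrt(se2)
    df_ref <- se2^2 / ((stats::var(x) / n1)^2 / (n1 - 1) +
                       (stats::var(y) / n2)^2 / (n2 - 1))
    expect_equal(r$t_statistic, t_ref, tolerance = 1e-10)
    expect_equal(r$degrees_of_freedom, df_ref, tolerance = 1e-10)
    expect_equal(r$p_value, stats::pt(t_ref, df_ref), tolerance = 1e-10)
  }
  # identical samples: t = 0, p = 0.5; large shifts drive p to the limits
  same <- welch_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 0.5)
  expect_lt(welch_one_sided(c(1, 2, 3), c(1001, 1002, 1003))$p_value, 1e-6)
  expect_gt(welch_one_sided(c(1001, 1002, 1003), c(1, 2, 3))$p_value, 1 - 1e-6)
  deg <- welch_one_sided(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0.5)
  expect_error(welch_one_sided(c(2, 2), c(3, 3)), "undefined")
})

test_that("every particle reported by the full pipeline satisfies both filters", {
  cfg <- small_imaging_config(seed = 41L)
  ex <- simulate_imaging_experiment(cfg, c("1x" = 1, "5x" = 2))
  rep <- run_image_analysis(ex, pixel_size_um = cfg$pixel_size_um)
  all_p <- do.call(rbind, unlist(rep$particles, recursive = FALSE))
  expect_gt(nrow(all_p), 0)
  expect_true(all(all_p$area_um2 >= 80 & all_p$area_um2 <= 2000))
  expect_true(all(all_p$circularity >= 0.1 & all_p$circularity <= 1.0))
  expect_s3_class(rep$amplification, "amplification_result")
})
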