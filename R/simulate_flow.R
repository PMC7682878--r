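#' Configuration for the transfection flow-cytometry simulator
#'
#' Describes a transiently co-transfected cell population as seen by a flow
#' cytometer. FP_11 expression B is log-normal across cells (transient
#' transfection spans decades); FP_1-10 expression A is log-normal with the
#' same log-scale spread, median `expression_ratio` times that of B, and
#' correlation `rho` with log B (cells taking up more of one plasmid tend to
#' take up more of the other). Fluorescence channels carry additive Gaussian
#' autofluorescence; all channels clip at `saturation_value`. A
#' `doublet_fraction` of events are two cells in one droplet and a
#' `1 - transfected_fraction` share of cells carry no plasmid.
#'
#' With `rho = 1` the fragments are produced in strict proportion
#' (A = expression_ratio x B), the regime the equilibrium slope model
#' assumes; lower `rho` decouples the fragments and attenuates the
#' weak-binding slope limit from 2 toward `1 + rho` -- the
#' transfection-efficiency effect on the estimated gradient.
#'
#' @param n_events Number of events to generate.
#' @param log10_b_mean,log10_b_sd Location and scale of log10 FP_11
#'   expression (default sd 1: a ~4-decade population).
#' @param expression_ratio Median A/B ratio (default 2, mirroring the 2:1
#'   plasmid mass ratio used for co-transfection).
#' @param rho Correlation of log A and log B across cells, in \[0, 1\].
#' @param kd Effective dissociation constant, same arbitrary units as B.
#' @param green_gain,blue_gain Fluorescence per unit concentration. `NULL`
#'   (default) auto-scales each gain so the 99.5th percentile of the
#'   noiseless signal sits at 25% of `saturation_value`, as an operator
#'   does when setting detector voltages; log-log slopes are invariant to
#'   this choice.
#' @param autofluor_green_mean,autofluor_green_sd Additive green-channel
#'   autofluorescence (Gaussian, clipped at 0).
#' @param autofluor_blue_mean,autofluor_blue_sd Additive blue-channel
#'   autofluorescence.
#' @param transfected_fraction Fraction of cells carrying the plasmids.
#' @param doublet_fraction Fraction of events that are doublets.
#' @param saturation_value Channel ceiling (default `2^18 - 1`, a typical
#'   18-bit ADC).
#' @param seed Random seed; identical config + seed gives a bit-identical
#'   event table.
#' @return A validated `flow_sim_config` list.
#' @export
flow_sim_config <- function(n_events = 20000L,
                            log10_b_mean = 0,
                            log10_b_sd = 1,
                            expression_ratio = 2,
                            rho = 0.7,
                            kd = 1,
                            green_gain = NULL,
                            blue_gain = NULL,
                            autofluor_green_mean = 150,
                            autofluor_green_sd = 40,
                            autofluor_blue_mean = 150,
                            autofluor_blue_sd = 40,
                            transfected_fraction = 0.8,
                            doublet_fraction = 0.05,
                            saturation_value = 2^18 - 1,
                            seed = 1L) {
  cfg <- list(n_events = as.integer(n_events), log10_b_mean = log10_b_mean,
              log10_b_sd = log10_b_sd, expression_ratio = expression_ratio,
              rho = rho, kd = kd, green_gain = green_gain,
              blue_gain = blue_gain,
              autofluor_green_mean = autofluor_green_mean,
              autofluor_green_sd = autofluor_green_sd,
              autofluor_blue_mean = autofluor_blue_mean,
              autofluor_blue_sd = autofluor_blue_sd,
              transfected_fraction = transfected_fraction,
              doublet_fraction = doublet_fraction,
              saturation_value = saturation_value, seed = as.integer(seed))
  validate_flow_sim_config(cfg)
}

validate_flow_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_events >= 0, log10_b_sd >= 0, expression_ratio > 0,
              rho >= 0, rho <= 1, kd >= 0,
              autofluor_green_sd >= 0, autofluor_blue_sd >= 0,
              transfected_fraction >= 0, transfected_fraction <= 1,
              doublet_fraction >= 0, doublet_fraction <= 1,
              saturation_value > autofluor_green_mean,
              saturation_value > autofluor_blue_mean)
    if (!is.null(green_gain)) stopifnot(green_gain > 0)
    if (!is.null(blue_gain)) stopifnot(blue_gain > 0)
  })
  structure(cfg, class = "flow_sim_config")
}

# scatter-channel model shared by every simulated cell population:
# correlated log-normal FSC-A/SSC-A with FSC-H slightly below FSC-A
scatter_singlets <- function(n) {
  lfsc <- stats::rnorm(n, 5.0, 0.15)
  lssc <- 4.5 + 0.8 * (lfsc - 5.0) + stats::rnorm(n, 0, 0.12)
  ratio <- exp(stats::rnorm(n, log(1.03), 0.04)) # FSC-A / FSC-H
  data.frame(fsc_a = 10^lfsc, ssc_a = 10^lssc, fsc_h = 10^lfsc / ratio)
}

#' Simulate a flow-cytometry experiment on a co-transfected population
#'
#' Draws singlet cells (transfected and untransfected), computes the
#' complemented concentration C from the equilibrium model for each
#' transfected cell, converts concentrations to fluorescence through
#' channel gains plus autofluorescence, forms doublets as sums of two
#' singlets (pulse height FSC-H takes the larger of the pair -- heights do
#' not add), and clips every channel at the saturation ceiling. Ground
#' truth (per-event A, B, C, population label, doublet and saturation
#' flags, applied gains) is attached as an attribute.
#'
#' @param config A [flow_sim_config()].
#' @param mode `"split"` (green reports complemented C), `"full_length"`
#'   (green directly proportional to B: the unsplit P2A control) or
#'   `"untransfected"` (autofluorescence only).
#' @return A [flow_events()] table with attributes `ground_truth` (data
#'   frame) and `gains` (named vector of the gains actually applied).
#' @export
simulate_flow_experiment <- function(config,
                                     mode = c("split", "full_length",
                                              "untransfected")) {
  mode <- match.arg(mode)
  cfg <- validate_flow_sim_config(unclass(config))
  set.seed(cfg$seed)
  n <- cfg$n_events
  empty <- data.frame(fsc_a = numeric(0), ssc_a = numeric(0),
                      fsc_h = numeric(0), green = numeric(0),
                      blue = numeric(0))
  if (n == 0L) {
    return(structure(flow_events(empty, cfg$saturation_value),
                     ground_truth = data.frame(), gains = c(green = 1, blue = 1)))
  }
  n_dbl <- round(n * cfg$doublet_fraction)
  n_single <- n - n_dbl
  n_pool <- n_single + 2L * n_dbl # singlet draws; last 2*n_dbl get paired

  tf <- if (mode == "untransfected") 0 else cfg$transfected_fraction
  transfected <- stats::runif(n_pool) < tf
  a <- b <- cc <- numeric(n_pool)
  nt <- sum(transfected)
  if (nt > 0) {
    z1 <- stats::rnorm(nt)
    z2 <- stats::rnorm(nt)
    lb <- cfg$log10_b_mean + cfg$log10_b_sd * z1
    la <- cfg$log10_b_mean + log10(cfg$expression_ratio) +
      cfg$log10_b_sd * (cfg$rho * z1 + sqrt(1 - cfg$rho^2) * z2)
    b[transfected] <- 10^lb
    a[transfected] <- 10^la
    cc[transfected] <- complemented_concentration(a[transfected],
                                                  b[transfected], cfg$kd)
  }
  green_sig <- if (mode == "full_length") b else cc
  gains <- c(
    green = auto_gain(cfg$green_gain, green_sig[transfected],
                      cfg$saturation_value),
    blue = auto_gain(cfg$blue_gain, b[transfected], cfg$saturation_value)
  )
  sc <- scatter_singlets(n_pool)
  green <- gains[["green"]] * green_sig +
    stats::rnorm(n_pool, cfg$autofluor_green_mean, cfg$autofluor_green_sd)
  blue <- gains[["blue"]] * b +
    stats::rnorm(n_pool, cfg$autofluor_blue_mean, cfg$autofluor_blue_sd)
  pool <- cbind(sc, green = pmax(green, 0), blue = pmax(blue, 0))

  keep <- seq_len(n_single)
  ev <- pool[keep, , drop = FALSE]
  gt <- data.frame(population = ifelse(transfected[keep], "transfected",
                                       "untransfected"),
                   a = a[keep], b = b[keep], c_complemented = cc[keep],
                   is_doublet = FALSE)
  if (n_dbl > 0L) {
    i1 <- n_single + seq_len(n_dbl)
    i2 <- n_single + n_dbl + seq_len(n_dbl)
    dbl <- data.frame(
      fsc_a = pool$fsc_a[i1] + pool$fsc_a[i2],
      ssc_a = pool$ssc_a[i1] + pool$ssc_a[i2],
      fsc_h = pmax(pool$fsc_h[i1], pool$fsc_h[i2]),
      green = pool$green[i1] + pool$green[i2],
      blue = pool$blue[i1] + pool$blue[i2])
    ev <- rbind(ev, dbl)
    gt <- rbind(gt, data.frame(population = "doublet",
                               a = a[i1] + a[i2], b = b[i1] + b[i2],
                               c_complemented = cc[i1] + cc[i2],
                               is_doublet = TRUE))
  }
  sat <- Reduce(`|`, lapply(ev, function(v) v >= cfg$saturation_value))
  ev[] <- lapply(ev, function(v) pmin(v, cfg$saturation_value))
  gt$saturated <- sat
  rownames(ev) <- rownames(gt) <- NULL
  structure(flow_events(ev, cfg$saturation_value),
            ground_truth = gt, gains = gains)
}

# Auto-scaled detector gain: place the 90th percentile of the noiseless
# signal at 25% of the ADC ceiling. With expression spanning ~4 decades the
# top tail then saturates -- as real transient transfections do, which is
# why saturation filtering is the first processing stage -- while the bulk
# of the population sits well above autofluorescence.
auto_gain <- function(gain, signal, saturation_value) {
  if (!is.null(gain)) return(unname(gain))
  signal <- signal[signal > 0]
  if (!length(signal)) return(1)
  q <- stats::quantile(signal, 0.90, names = FALSE)
  if (q <= 0) 1 else 0.25 * saturation_value / q
}

#' Simulate the full-length (P2A) control sample
#'
#' Identical population, noise, doublet and saturation machinery as
#' [simulate_flow_experiment()], but the green channel reports B directly
#' (no binding step): the unsplit FP and the blue reporter are produced in
#' fixed proportion from one transcript, so the log-log slope is 1 up to
#' noise.
#'
#' @param config A [flow_sim_config()].
#' @return A [flow_events()] table with ground truth.
#' @export
simulate_full_length_control <- function(config) {
  simulate_flow_experiment(config, mode = "full_length")
}

#' Simulate an untransfected (autofluorescence-only) control
#'
#' @param config A [flow_sim_config()].
#' @return A [flow_events()] table with ground truth.
#' @export
simulate_untransfected <- function(config) {
  simulate_flow_experiment(config, mode = "untransfected")
}
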