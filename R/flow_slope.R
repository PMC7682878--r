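#' Slope fits of log10 green versus log10 blue
#'
#' The complemented green signal is regressed on the blue expression
#' reporter on log10 axes. The raw slope confounds complementation with
#' instrument settings (different lasers, detector gains per channel), so a
#' paired full-length control -- the unsplit FP fused to the reporter
#' through a self-cleaving P2A site, giving strictly proportional green and
#' blue production -- is fitted first, and sample slopes are divided by the
#' control slope so that a 1:1 green/blue relationship reads as slope 1.
#' The rescaled slope lies near 2 when the effective K_D is far above
#' cellular fragment concentrations and near 1 when complementation is
#' saturated.
#'
#' @name slope_fit
NULL

new_slope_fit <- function(raw_slope, raw_intercept, control_slope,
                          rescaled_slope, n_events_fit, reliable,
                          in_model_range = NA) {
  structure(list(raw_slope = raw_slope, raw_intercept = raw_intercept,
                 control_slope = control_slope,
                 rescaled_slope = rescaled_slope,
                 n_events_fit = n_events_fit, reliable = reliable,
                 in_model_range = in_model_range,
                 channels = c(response = "green", regressor = "blue")),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat("<slope_fit> raw slope ", signif(x$raw_slope, 4),
      ", control slope ", signif(x$control_slope, 4),
      ", rescaled slope ", signif(x$rescaled_slope, 4),
      " (n = ", x$n_events_fit,
      if (!x$reliable) ", UNRELIABLE" else "", ")\n", sep = "")
  invisible(x)
}

ols_log_slope <- function(events) {
  fit <- stats::lm.fit(cbind(1, events$blue), events$green)
  stats::setNames(stats::coef(fit), c("intercept", "slope"))
}

#' Fit the full-length control slope
#'
#' Ordinary least squares of log10 green on log10 blue for the gated,
#' thresholded full-length control. The fitted slope becomes the
#' denominator that rescales sample slopes; for a well-behaved P2A control
#' it is close to 1.
#'
#' @param control A `log_events` table (gated, log-transformed,
#'   above-threshold events of the full-length control).
#' @param min_events Minimum events for the fit to be flagged reliable.
#' @return A `slope_fit`; `control_slope` equals its own raw slope.
#' @export
fit_control_slope <- function(control, min_events = 100L) {
  stopifnot(inherits(control, "log_events"))
  if (nrow(control) < 2L) stop("too few control events to fit")
  cf <- ols_log_slope(control)
  new_slope_fit(raw_slope = unname(cf["slope"]),
                raw_intercept = unname(cf["intercept"]),
                control_slope = unname(cf["slope"]),
                rescaled_slope = 1,
                n_events_fit = nrow(control),
                reliable = nrow(control) >= min_events)
}

#' Fit and rescale the slope of a split-FP sample
#'
#' @param sample A `log_events` table (gated, log-transformed,
#'   above-threshold events of the split-FP sample).
#' @param control_fit The [fit_control_slope()] result for the paired
#'   full-length control.
#' @param min_events Minimum events for the fit to be flagged reliable.
#' @return A `slope_fit` with `rescaled_slope = raw_slope / control_slope`.
#'   `in_model_range` flags whether the rescaled slope lies in the
#'   equilibrium-model band [0.95, 2.05]; values outside are flagged, not
#'   rejected.
#' @export
fit_split_slope <- function(sample, control_fit, min_events = 100L) {
  stopifnot(inherits(sample, "log_events"), inherits(control_fit, "slope_fit"))
  if (!isTRUE(control_fit$reliable)) {
    stop("control fit is unreliable; cannot rescale")
  }
  if (control_fit$control_slope <= 0) {
    stop("control slope must be positive for rescaling")
  }
  if (nrow(sample) < 2L) stop("too few sample events to fit")
  cf <- ols_log_slope(sample)
  rescaled <- unname(cf["slope"]) / control_fit$control_slope
  new_slope_fit(raw_slope = unname(cf["slope"]),
                raw_intercept = unname(cf["intercept"]),
                control_slope = control_fit$control_slope,
                rescaled_slope = rescaled,
                n_events_fit = nrow(sample),
                reliable = nrow(sample) >= min_events,
                in_model_range = rescaled >= 0.95 && rescaled <= 2.05)
}

#' Run the full flow-cytometry analysis
#'
#' Applies the processing chain in fixed order -- saturation filter,
#' density scatter gate, singlet gate, log10 transform, untransfected
#' thresholding -- then fits the full-length control and rescales each
#' split-FP sample slope by the control slope. By default the median
#' autofluorescence of the gated untransfected control is subtracted from
#' each fluorescence channel before the log transform, so that the fitted
#' log axes measure signal above background; without this the
#' autofluorescence floor flattens the low-expression end of every fit.
#'
#' @param samples Named list of [flow_events()] tables. Must contain the
#'   two control roles named by `untransfected` and `control`; every other
#'   entry is treated as a split-FP sample.
#' @param untransfected,control Names of the untransfected and full-length
#'   control samples within `samples`.
#' @param retain_fraction Scatter-gate retained fraction (see
#'   [scatter_gate()]).
#' @param singlet_band FSC-A/FSC-H band (see [singlet_gate()]).
#' @param threshold_quantile Untransfected quantile (see
#'   [fit_thresholds()]).
#' @param subtract_autofluorescence Subtract the untransfected control's
#'   median per-channel autofluorescence before the log transform
#'   (default `TRUE`).
#' @param min_events Minimum events per reliable fit.
#' @return A `flow_report`: list with `thresholds`, `control_fit`, `fits`
#'   (one `slope_fit` per split sample), `retention` (per-sample stage
#'   counts), and `events` (per-sample thresholded `log_events`).
#' @export
run_flow_analysis <- function(samples,
                              untransfected = "untransfected",
                              control = "full_length",
                              retain_fraction = 0.5,
                              singlet_band = c(0.8, 1.3),
                              threshold_quantile = 0.999,
                              subtract_autofluorescence = TRUE,
                              min_events = 100L) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  for (role in c(untransfected, control)) {
    if (!role %in% names(samples)) {
      stop("missing required control sample: '", role, "'")
    }
  }
  gate_pop <- function(ev) {
    singlet_gate(
      scatter_gate(filter_saturated(ev), retain_fraction = retain_fraction),
      band = singlet_band)
  }
  pops <- lapply(samples, gate_pop)
  background <- NULL
  if (subtract_autofluorescence) {
    u_ev <- gated_events(pops[[untransfected]])
    background <- c(green = stats::median(u_ev$green),
                    blue = stats::median(u_ev$blue))
  }
  gated <- lapply(pops, function(pop) {
    logtab <- log_transform(pop, background = background)
    ret <- retention_counts(pop)
    ret <- rbind(ret, data.frame(stage = "log_transform",
                                 retained = nrow(logtab)))
    list(logtab = logtab, retention = ret)
  })
  thresholds <- fit_thresholds(gated[[untransfected]]$logtab,
                               quantile = threshold_quantile)
  thresholded <- lapply(gated, function(g) {
    apply_thresholds(g$logtab, thresholds)
  })
  control_fit <- fit_control_slope(thresholded[[control]],
                                   min_events = min_events)
  split_names <- setdiff(names(samples), c(untransfected, control))
  fits <- lapply(thresholded[split_names], fit_split_slope,
                 control_fit = control_fit, min_events = min_events)
  retention <- do.call(rbind, lapply(names(gated), function(nm) {
    ret <- gated[[nm]]$retention
    ret <- rbind(ret, data.frame(stage = "threshold",
                                 retained = nrow(thresholded[[nm]])))
    cbind(sample = nm, ret)
  }))
  structure(list(thresholds = thresholds, control_fit = control_fit,
                 fits = fits, retention = retention, events = thresholded,
                 background = background,
                 settings = list(retain_fraction = retain_fraction,
                                 singlet_band = singlet_band,
                                 threshold_quantile = threshold_quantile,
                                 subtract_autofluorescence =
                                   subtract_autofluorescence,
                                 min_events = min_events)),
            class = "flow_report")
}

#' @export
print.flow_report <- function(x, ...) {
  cat("<flow_report>\n")
  cat("thresholds (log10): green ", signif(x$thresholds[["green"]], 4),
      ", blue ", signif(x$thresholds[["blue"]], 4), "\n", sep = "")
  cat("control raw slope: ", signif(x$control_fit$raw_slope, 4), "\n", sep = "")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-16s rescaled slope %.3f (raw %.3f, n = %d)\n",
                nm, f$rescaled_slope, f$raw_slope, f$n_events_fit))
  }
  invisible(x)
}

#' Scatter plot of a fitted sample with its regression line
#'
#' @param events A `log_events` table used in a fit.
#' @param fit The corresponding `slope_fit`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_slope_fit <- function(events, fit, title = NULL) {
  df <- as.data.frame(events)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$blue, y = .data$green)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_abline(slope = fit$raw_slope, intercept = fit$raw_intercept,
                         colour = "red") +
    ggplot2::labs(x = "log10 blue (expression reporter)",
                  y = "log10 green (complemented FP)",
                  title = title,
                  subtitle = sprintf("raw slope %.3f, rescaled %.3f, n = %d",
                                     fit$raw_slope, fit$rescaled_slope,
                                     fit$n_events_fit)) +
    ggplot2::theme_minimal()
}
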