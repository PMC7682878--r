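#' Gated population: an event table plus per-stage survivor masks
#'
#' Gating proceeds through named, ordered stages (`saturation`, `scatter`,
#' `singlet`); each stage records a boolean mask over the *original* event
#' table so the provenance of every filtering step is retained. Masks are
#' nested: a stage can only remove events that survived all earlier stages,
#' so retained counts are monotone non-increasing. Re-applying a stage that
#' is already the last recorded stage recomputes it from the same input and
#' is therefore the identity.
#'
#' @name gated_population
NULL

new_gated_population <- function(source, masks) {
  stopifnot(inherits(source, "flow_events"))
  structure(list(source = source, masks = masks),
            class = "gated_population")
}

#' Logical survivor mask / surviving events of a gated population
#'
#' @param pop A `gated_population`.
#' @return `survivors()`: logical vector over the source events;
#'   `gated_events()`: the surviving rows as a [flow_events()] table.
#' @export
survivors <- function(pop) {
  stopifnot(inherits(pop, "gated_population"))
  Reduce(`&`, pop$masks, rep(TRUE, nrow(pop$source)))
}

#' @rdname survivors
#' @export
gated_events <- function(pop) {
  ev <- pop$source[survivors(pop), , drop = FALSE]
  flow_events(ev, attr(pop$source, "ceilings"))
}

#' Per-stage retention counts
#'
#' @param pop A `gated_population`.
#' @return Data frame of stage names and events retained after each stage.
#' @export
retention_counts <- function(pop) {
  n <- nrow(pop$source)
  cum <- rep(TRUE, n)
  rows <- data.frame(stage = "input", retained = n)
  for (nm in names(pop$masks)) {
    cum <- cum & pop$masks[[nm]]
    rows <- rbind(rows, data.frame(stage = nm, retained = sum(cum)))
  }
  rows
}

#' @export
print.gated_population <- function(x, ...) {
  cat("<gated_population>\n")
  print(retention_counts(x))
  invisible(x)
}

# Truncate masks at (and including) stage `name` so the stage can be
# recomputed from the same input it saw the first time (idempotence).
masks_before <- function(pop, name) {
  ms <- pop$masks
  i <- match(name, names(ms))
  if (!is.na(i)) ms <- ms[seq_len(i - 1L)]
  ms
}

#' Remove events that saturated any recorded channel
#'
#' Drops every event with any channel value at or above that channel's
#' ceiling. This is the first gating stage: saturated values are clipped by
#' the instrument ADC and would distort every downstream fit.
#'
#' @param events A [flow_events()] table with ceiling metadata.
#' @return A [gated_population] with a `saturation` mask.
#' @export
filter_saturated <- function(events) {
  stopifnot(inherits(events, "flow_events"))
  ceil <- attr(events, "ceilings")
  if (is.null(ceil) || anyNA(ceil)) {
    stop("per-channel ceilings are unknown; supply them at ingestion")
  }
  hit <- Reduce(`|`, lapply(flow_channels(),
                            function(ch) events[[ch]] >= ceil[[ch]]))
  new_gated_population(events, list(saturation = !hit))
}

#' Density-quantile scatter gate
#'
#' Retains the events lying in the highest-density region of the
#' (log10 FSC-A, log10 SSC-A) plane containing `retain_fraction` of the
#' surviving events, removing debris, dying cells and other outliers that
#' sit in low-density regions. Density is a bivariate normal kernel
#' estimate with Scott's-rule bandwidth, so the gate is deterministic.
#'
#' @param pop A [gated_population].
#' @param retain_fraction Fraction of surviving events to retain, in (0, 1].
#' @param min_events Minimum events required to estimate the density.
#' @return The population with a `scatter` mask appended.
#' @export
scatter_gate <- function(pop, retain_fraction = 0.5, min_events = 50L) {
  stopifnot(inherits(pop, "gated_population"),
            retain_fraction > 0, retain_fraction <= 1)
  ms <- masks_before(pop, "scatter")
  surv <- Reduce(`&`, ms, rep(TRUE, nrow(pop$source)))
  if (retain_fraction == 1) {
    return(new_gated_population(pop$source, c(ms, list(scatter = surv))))
  }
  x <- log10(pop$source$fsc_a[surv])
  y <- log10(pop$source$ssc_a[surv])
  if (length(x) < min_events) {
    stop("scatter gate needs at least ", min_events, " events")
  }
  n <- length(x)
  # Scott's rule per axis; kde2d's `h` is 4x the kernel sd
  h <- 4 * c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
  lims <- c(range(x) + c(-1, 1) * h[1], range(y) + c(-1, 1) * h[2])
  dens <- MASS::kde2d(x, y, h = h, n = 128L, lims = lims)
  d_at <- bilinear_at(dens, x, y)
  thr <- stats::quantile(d_at, 1 - retain_fraction, names = FALSE)
  keep <- logical(nrow(pop$source))
  keep[which(surv)] <- d_at >= thr
  new_gated_population(pop$source, c(ms, list(scatter = keep)))
}

# bilinear interpolation of a kde2d grid at query points
bilinear_at <- function(dens, x, y) {
  gx <- dens$x; gy <- dens$y; z <- dens$z
  ix <- pmin(pmax(findInterval(x, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(y, gy), 1L), length(gy) - 1L)
  fx <- (x - gx[ix]) / (gx[ix + 1L] - gx[ix])
  fy <- (y - gy[iy]) / (gy[iy + 1L] - gy[iy])
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  z[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    z[cbind(ix + 1L, iy)] * fx * (1 - fy) +
    z[cbind(ix, iy + 1L)] * (1 - fx) * fy +
    z[cbind(ix + 1L, iy + 1L)] * fx * fy
}

#' Singlet gate on the FSC-A/FSC-H ratio
#'
#' A droplet containing two cells roughly doubles the area-type forward
#' scatter signal (FSC-A) while the pulse height (FSC-H) stays near that of
#' one cell, so doublets show FSC-A/FSC-H far above 1. Events whose ratio
#' falls outside `band` are removed.
#'
#' @param pop A [gated_population].
#' @param band Length-2 increasing interval of acceptable FSC-A/FSC-H
#'   ratios (default `c(0.8, 1.3)`).
#' @return The population with a `singlet` mask appended.
#' @export
singlet_gate <- function(pop, band = c(0.8, 1.3)) {
  stopifnot(inherits(pop, "gated_population"))
  if (length(band) != 2L || band[2] <= band[1]) {
    stop("`band` must be a strictly increasing length-2 interval")
  }
  ms <- masks_before(pop, "singlet")
  surv <- Reduce(`&`, ms, rep(TRUE, nrow(pop$source)))
  ratio <- pop$source$fsc_a / pop$source$fsc_h
  keep <- surv & ratio >= band[1] & ratio <= band[2]
  new_gated_population(pop$source, c(ms, list(singlet = keep)))
}

#' Log10-transform the fluorescence channels of the surviving events
#'
#' Returns the surviving events with `green` and `blue` replaced by their
#' log10 values, optionally after subtracting a per-channel
#' autofluorescence background (typically the median of the gated
#' untransfected control), so that the log axis reflects signal above
#' background rather than signal plus a floor. Events with a non-positive
#' (background-subtracted) fluorescence value cannot be log-transformed;
#' they are dropped and counted (attribute `n_dropped_nonpositive`), never
#' imputed.
#'
#' @param pop A [gated_population] (or a [flow_events()] table).
#' @param background Optional named numeric `c(green = , blue = )`
#'   subtracted from the fluorescence channels before the log transform.
#' @return A `log_events` data frame with columns `green` and `blue` on the
#'   log10 axis (scatter channels carried through unchanged).
#' @export
log_transform <- function(pop, background = NULL) {
  ev <- if (inherits(pop, "gated_population")) gated_events(pop) else pop
  stopifnot(inherits(ev, "flow_events"))
  ev <- as.data.frame(ev)
  if (!is.null(background)) {
    stopifnot(all(c("green", "blue") %in% names(background)))
    ev$green <- ev$green - background[["green"]]
    ev$blue <- ev$blue - background[["blue"]]
  }
  ok <- ev$green > 0 & ev$blue > 0
  out <- ev[ok, , drop = FALSE]
  out$green <- log10(out$green)
  out$blue <- log10(out$blue)
  structure(out, n_dropped_nonpositive = sum(!ok),
            class = c("log_events", "data.frame"))
}

#' Fluorescence thresholds from an untransfected control
#'
#' Transfected cells are identified as those whose fluorescence exceeds what
#' untransfected (autofluorescence-only) cells show. The threshold for each
#' fluorescence channel is an upper empirical quantile of the gated,
#' log10-transformed untransfected control.
#'
#' @param control A `log_events` table from the untransfected control,
#'   processed through the same gates as the samples.
#' @param quantile Quantile used as the threshold (default 0.999).
#' @return Named numeric vector `c(green = , blue = )` on the log10 axis.
#' @export
fit_thresholds <- function(control, quantile = 0.999) {
  stopifnot(inherits(control, "log_events"),
            quantile > 0, quantile < 1)
  if (nrow(control) == 0L) stop("untransfected control is empty")
  c(green = stats::quantile(control$green, quantile, names = FALSE),
    blue = stats::quantile(control$blue, quantile, names = FALSE))
}

#' Keep events above the untransfected thresholds
#'
#' @param events A `log_events` table.
#' @param thresholds Named thresholds from [fit_thresholds()].
#' @return The subset of events strictly above threshold in both
#'   fluorescence channels.
#' @export
apply_thresholds <- function(events, thresholds) {
  stopifnot(inherits(events, "log_events"),
            all(c("green", "blue") %in% names(thresholds)))
  keep <- events$green > thresholds[["green"]] &
    events$blue > thresholds[["blue"]]
  out <- events[keep, , drop = FALSE]
  attr(out, "n_dropped_nonpositive") <- attr(events, "n_dropped_nonpositive")
  out
}
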