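#' Equilibrium model of split fluorescent protein complementation
#'
#' A split FP system consists of a large FP_1-10 fragment (total cellular
#' concentration `a_total`) and a small FP_11 peptide fused to a target
#' (total concentration `b_total`). The fragments associate reversibly with
#' effective dissociation constant `kd`; only the bound complex is
#' fluorescent. At equilibrium the complemented concentration C is the
#' smaller root of
#' \deqn{(A - C)(B - C) = K_D C}
#' which lies in \eqn{[0, \min(A, B)]}.
#'
#' When \eqn{K_D} greatly exceeds both fragment concentrations,
#' \eqn{C \approx AB/K_D}, so with A proportional to B the complemented
#' signal grows as the square of expression (log-log slope 2). When
#' \eqn{K_D} is far below the concentrations, complementation saturates at
#' \eqn{C = \min(A, B)} and the slope is 1. The slope measured between those
#' limits therefore reports the effective \eqn{K_D} relative to cellular
#' expression.
#'
#' @param a_total Total FP_1-10 concentration (arbitrary units, >= 0).
#' @param b_total Total FP_11 concentration (same units, >= 0).
#' @param kd Effective dissociation constant (same units, >= 0).
#' @return Complemented (bound) concentration, same length as the inputs.
#'   Never exceeds `min(a_total, b_total)`; equals it when `kd = 0`.
#' @examples
#' complemented_concentration(2, 1, 1)   # ~0.586
#' complemented_concentration(1, 1, 0)   # 1: zero-KD limit
#' @export
complemented_concentration <- function(a_total, b_total, kd) {
  k <- check_conc(a_total = a_total, b_total = b_total, kd = kd)
  a <- k$a_total; b <- k$b_total; kd <- k$kd
  s <- a + b + kd
  disc <- s^2 - 4 * a * b
  disc[disc < 0] <- 0 # guard FP rounding; exact disc >= (a-b)^2 + kd terms
  # smaller quadratic root in the catastrophic-cancellation-free form
  # 2ab / (s + sqrt(disc)); s = 0 only when a = b = kd = 0, where C = 0
  denom <- s + sqrt(disc)
  out <- ifelse(denom > 0, 2 * a * b / denom, 0)
  unname(pmin(out, pmin(a, b))) # clamp FP noise at the physical bound
}

#' Predicted log-log slope of complemented signal versus expression
#'
#' Evaluates the equilibrium model over a log-spaced grid of FP_11
#' concentrations `b_range` with FP_1-10 held at a fixed expression ratio
#' A/B, and returns the ordinary-least-squares slope of
#' `log10 C` on `log10 B`. This mirrors how the slope is estimated from
#' scattered single-cell data rather than as a point derivative. The slope
#' lies in (1, 2) for finite positive `kd`, approaching 2 when `kd` is far
#' above the concentration grid and 1 when far below.
#'
#' @param kd Effective dissociation constant (>= 0).
#' @param expression_ratio Ratio A/B held fixed while B varies (> 0).
#' @param b_range Length-2 positive increasing interval of B values over
#'   which the slope is evaluated.
#' @param n_grid Number of log-spaced grid points (default 50).
#' @return The fitted slope (scalar).
#' @examples
#' predicted_slope(1e6, 2, c(1e-2, 1e2))  # -> 2
#' predicted_slope(1e-8, 2, c(1e-2, 1e2)) # -> 1
#' @export
predicted_slope <- function(kd, expression_ratio = 2, b_range = c(1e-2, 1e2),
                            n_grid = 50L) {
  stopifnot(length(kd) == 1L, is.finite(kd), kd >= 0,
            length(expression_ratio) == 1L, is.finite(expression_ratio),
            expression_ratio > 0, n_grid >= 2L)
  if (length(b_range) != 2L || any(!is.finite(b_range)) ||
      any(b_range <= 0) || b_range[2] <= b_range[1]) {
    stop("`b_range` must be a positive, strictly increasing length-2 interval")
  }
  lb <- seq(log10(b_range[1]), log10(b_range[2]), length.out = n_grid)
  b <- 10^lb
  cc <- complemented_concentration(expression_ratio * b, b, kd)
  if (any(cc <= 0)) stop("complemented concentration vanished on the grid")
  unname(stats::coef(stats::lm.fit(cbind(1, lb), log10(cc)))[2])
}

#' Free FP_1-10 concentration with tandem FP_11 tags
#'
#' Tandem tagging fuses `n_repeats` FP_11 copies to each target molecule;
#' every copy can recruit an FP_1-10 from a shared free pool. Sites are
#' modelled as independent and identical (per-site dissociation constant
#' `kd`, no cooperativity), so the free fragment concentration `a` solves
#' the mass balance
#' \deqn{a + n \, b_{tags} \frac{a}{a + K_D} = A}
#' i.e. the positive root of
#' \eqn{a^2 + a (K_D + n b_{tags} - A) - A K_D = 0}.
#'
#' @param n_repeats Integer number of FP_11 copies per tagged molecule (>= 1).
#' @param a_total Total FP_1-10 concentration (>= 0).
#' @param b_tags Concentration of tagged molecules (>= 0).
#' @param kd Per-site dissociation constant (>= 0).
#' @return Free FP_1-10 concentration. With `kd = 0` and
#'   `a_total <= n_repeats * b_tags` all fragment is bound and 0 is returned.
#' @export
tandem_free_fragment <- function(n_repeats, a_total, b_tags, kd) {
  check_conc(a_total = a_total, b_tags = b_tags, kd = kd)
  stopifnot(all(n_repeats >= 1), all(n_repeats == as.integer(n_repeats)))
  p <- kd + n_repeats * b_tags - a_total
  disc <- sqrt(p^2 + 4 * a_total * kd)
  # stable branch: avoid -p + disc cancellation when p > 0
  a <- ifelse(p > 0,
              ifelse(a_total * kd > 0, 2 * a_total * kd / (p + disc), 0),
              (disc - p) / 2)
  unname(pmin(a, a_total))
}

#' Expected fluorophores per tandem-tagged molecule
#'
#' Per-site occupancy is \eqn{\theta = a / (a + K_D)} with `a` the free
#' FP_1-10 concentration from [tandem_free_fragment()]; each tagged molecule
#' then carries `n_repeats * theta` complemented fluorophores on average,
#' bounded by `n_repeats`.
#'
#' @inheritParams tandem_free_fragment
#' @return Expected complemented fluorophores per tagged molecule.
#' @export
tandem_signal <- function(n_repeats, a_total, b_tags, kd) {
  a <- tandem_free_fragment(n_repeats, a_total, b_tags, kd)
  theta <- ifelse(a + kd > 0,
                  a / (a + kd),
                  # kd = 0 with the pool exhausted: all fragment bound,
                  # occupancy = bound sites / total sites
                  ifelse(n_repeats * b_tags > 0,
                         pmin(a_total / (n_repeats * b_tags), 1), 1))
  unname(n_repeats * theta)
}

#' Signal amplification from tandem tagging
#'
#' Ratio of per-molecule signal with an `n`-repeat tag to a single tag, at
#' identical total FP_1-10, tag concentration and per-site `kd`. Because the
#' n sites compete for a shared finite FP_1-10 pool the fold is strictly
#' below `n` whenever `a_total` is finite -- the model's explanation for
#' sub-linear amplification of 5x tandem tags.
#'
#' @param n_repeats Integer tandem copy number (>= 1).
#' @inheritParams tandem_free_fragment
#' @return Amplification fold in `[1, n_repeats]`.
#' @export
amplification_fold <- function(n_repeats, a_total, b_tags, kd) {
  s1 <- tandem_signal(1L, a_total, b_tags, kd)
  if (any(s1 == 0)) stop("single-tag signal is zero; fold undefined")
  tandem_signal(n_repeats, a_total, b_tags, kd) / s1
}

# shared non-negativity / finiteness validation for concentration arguments
check_conc <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("`", nm, "` must be finite and non-negative")
    }
  }
  invisible(args)
}
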