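# Shared fixtures: simulation configs and a minimal FCS 3.0 writer used to
# exercise the reader round-trip.

# Low-autofluorescence, proportional-expression conditions under which the
# equilibrium slope model's assumptions hold (rho = 1: fragments produced
# in strict proportion). Used for slope-recovery checks.
recovery_config <- function(kd, seed, n_events = 20000L) {
  flow_sim_config(n_events = n_events, kd = kd, seed = seed, rho = 1,
                  doublet_fraction = 0, transfected_fraction = 1,
                  autofluor_green_mean = 5, autofluor_green_sd = 1,
                  autofluor_blue_mean = 5, autofluor_blue_sd = 1)
}

# Simulate the three samples of one experiment and run the full pipeline.
run_recovery_pipeline <- function(kd, seed, n_events = 20000L) {
  cfg <- recovery_config(kd, seed, n_events)
  ucfg <- cfg
  ucfg$transfected_fraction <- 0
  split <- simulate_flow_experiment(cfg)
  report <- run_flow_analysis(list(
    untransfected = simulate_untransfected(ucfg),
    full_length = simulate_full_length_control(cfg),
    split = split))
  list(report = report, split = split,
       gains = attr(split, "gains"), truth = attr(split, "ground_truth"))
}

# B-window actually entering the fit, recovered from the fitted events'
# blue values through the applied blue gain.
fitted_b_window <- function(run) {
  ev <- run$report$events$split
  unname(10^stats::quantile(ev$blue, c(0.005, 0.995)) / run$gains[["blue"]])
}

small_imaging_config <- function(seed = 1L, ...) {
  imaging_sim_config(field_shape = c(128L, 128L), n_cells = 12L,
                     cell_radius_px_mean = 10, cell_radius_px_sd = 1,
                     seed = seed, ...)
}

# Minimal FCS 3.0 writer (float32 little-endian) for reader round-trips.
write_minimal_fcs <- function(path, data, ranges) {
  stopifnot(is.data.frame(data), all(names(data) %in% names(ranges)))
  n_par <- ncol(data)
  n_tot <- nrow(data)
  kw <- c("$PAR", n_par, "$TOT", n_tot, "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$MODE", "L")
  for (i in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dN", i), names(data)[i],
            sprintf("$P%dB", i), 32L,
            sprintf("$P%dR", i), format(ranges[[names(data)[i]]],
                                        scientific = FALSE))
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  header_len <- 58L
  text_start <- header_len
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_par * n_tot - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  stopifnot(nchar(header) == header_len)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(as.matrix(data))), con, size = 4L,
           endian = "little")
  invisible(path)
}

# Rasterized disk mask, used as a geometry oracle.
disk_mask <- function(radius, pad = 4L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- (i - ctr)^2 + (seq_len(n) - ctr)^2 <= radius^2
  }
  m
}
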