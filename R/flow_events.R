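#' Construct a flow-cytometry event table
#'
#' A `flow_events` object is a data frame with one row per detected event
#' and canonical channel columns `fsc_a`, `ssc_a`, `fsc_h` (scatter) and
#' `green`, `blue` (fluorescence), plus per-channel saturation ceilings
#' stored as an attribute. The ceilings are required by
#' [filter_saturated()]; they come from instrument metadata ($PnR for FCS
#' files) or from configuration.
#'
#' @param x Data frame containing the canonical channel columns.
#' @param ceilings Named numeric vector of per-channel saturation ceilings;
#'   either one value per channel or a single value recycled to all.
#' @return A `flow_events` data frame.
#' @export
flow_events <- function(x, ceilings) {
  chans <- flow_channels()
  missing <- setdiff(chans, names(x))
  if (length(missing)) {
    stop("missing channel column(s): ", paste(missing, collapse = ", "))
  }
  x <- as.data.frame(x)[chans]
  if (anyNA(x)) stop("event table contains missing values")
  if (any(vapply(x, function(v) any(v < 0), logical(1)))) {
    stop("channel values must be non-negative")
  }
  if (length(ceilings) == 1L && is.null(names(ceilings))) {
    ceilings <- stats::setNames(rep(ceilings, length(chans)), chans)
  }
  if (!all(chans %in% names(ceilings))) {
    stop("`ceilings` must name every channel: ", paste(chans, collapse = ", "))
  }
  ceilings <- ceilings[chans]
  over <- vapply(chans, function(ch) any(x[[ch]] > ceilings[[ch]]), logical(1))
  if (any(over)) {
    stop("channel value(s) above their ceiling in: ",
         paste(chans[over], collapse = ", "))
  }
  structure(x, ceilings = ceilings, class = c("flow_events", "data.frame"))
}

flow_channels <- function() c("fsc_a", "ssc_a", "fsc_h", "green", "blue")

#' @export
print.flow_events <- function(x, ...) {
  cat("<flow_events> ", nrow(x), " events\n", sep = "")
  cat("ceilings:", paste(names(attr(x, "ceilings")),
                         signif(attr(x, "ceilings"), 4),
                         sep = "=", collapse = " "), "\n")
  NextMethod()
}

default_channel_map <- function() {
  c(fsc_a = "FSC-A", ssc_a = "SSC-A", fsc_h = "FSC-H",
    green = "green", blue = "blue")
}

#' Read an event table from FCS or CSV
#'
#' Reads a flow-cytometry event table from an FCS 3.0/3.1 file or a CSV in
#' the dialect written by [write_events_csv()], mapping instrument channel
#' names to the canonical names via `channel_map`. Per-channel ceilings are
#' taken from the FCS `$PnR` keywords when available, otherwise from the
#' `ceilings` argument.
#'
#' @param path Path to an `.fcs` or `.csv` file.
#' @param channel_map Named character vector mapping canonical channel names
#'   (`fsc_a`, `ssc_a`, `fsc_h`, `green`, `blue`) to the names used in the
#'   file. Defaults to `FSC-A`, `SSC-A`, `FSC-H`, `green`, `blue`.
#' @param ceilings Per-channel saturation ceilings (see [flow_events()]);
#'   required for CSV input, optional override for FCS input.
#' @return A [flow_events()] table.
#' @export
ingest_events <- function(path, channel_map = default_channel_map(),
                          ceilings = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  map <- default_channel_map()
  map[names(channel_map)] <- channel_map
  is_fcs <- grepl("\\.fcs$", path, ignore.case = TRUE) ||
    identical(substr(readChar(path, 3L, useBytes = TRUE), 1, 3), "FCS")
  if (is_fcs) {
    fcs <- read_fcs(path)
    tab <- fcs$data
    if (is.null(ceilings)) ceilings <- fcs$ranges[map]
    if (anyNA(ceilings)) stop("no $PnR ceiling for mapped channel(s); ",
                              "supply `ceilings`")
    names(ceilings) <- names(map)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    if (is.null(ceilings)) {
      stop("`ceilings` must be given for CSV input (no instrument metadata)")
    }
  }
  missing <- map[!map %in% names(tab)]
  if (length(missing)) {
    stop("channel(s) not found in file: ", paste(missing, collapse = ", "),
         "; available: ", paste(names(tab), collapse = ", "))
  }
  out <- stats::setNames(tab[map], names(map))
  flow_events(out, ceilings)
}

#' Write an event table (and optional ground truth) as CSV
#'
#' Writes the canonical channels under the instrument-style column names
#' `FSC-A`, `SSC-A`, `FSC-H`, `green`, `blue`. Ground truth attached by the
#' simulators can be written to a sidecar CSV.
#'
#' @param events A [flow_events()] table.
#' @param path Output CSV path.
#' @param ground_truth_path Optional sidecar path for the simulator ground
#'   truth (`attr(events, "ground_truth")`).
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, ground_truth_path = NULL) {
  map <- default_channel_map()
  out <- stats::setNames(as.data.frame(events)[names(map)], unname(map))
  utils::write.csv(out, path, row.names = FALSE)
  gt <- attr(events, "ground_truth")
  if (!is.null(ground_truth_path)) {
    if (is.null(gt)) stop("events carry no ground truth")
    utils::write.csv(gt, ground_truth_path, row.names = FALSE)
  }
  invisible(path)
}

# Minimal FCS 3.0/3.1 reader: HEADER offsets, TEXT keyword segment, and an
# uncompressed DATA segment in list mode. Supports $DATATYPE F/D/I and
# little/big endian $BYTEORD, which covers files from mainstream cytometers.
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version: ", version)
  }
  off <- function(i, j) as.numeric(trimws(substr(header, i, j)))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(parts[seq(1, length(parts), 2)]))
  need <- function(k) {
    if (!k %in% names(kw)) stop("FCS file lacks required keyword ", k)
    kw[[k]]
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (grepl("^1", byteord)) "little" else "big"
  if (data_start == 0) {
    data_start <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  names_p <- vapply(seq_len(n_par),
                    function(i) need(sprintf("$P%dN", i)), character(1))
  bits <- vapply(seq_len(n_par),
                 function(i) as.integer(need(sprintf("$P%dB", i))), integer(1))
  ranges <- vapply(seq_len(n_par), function(i) {
    k <- sprintf("$P%dR", i)
    if (k %in% names(kw)) as.numeric(kw[[k]]) else NA_real_
  }, numeric(1))
  seek(con, data_start)
  n_val <- n_par * n_tot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n_val, size = 4L, endian = endian),
    D = readBin(con, "numeric", n_val, size = 8L, endian = endian),
    I = {
      if (length(unique(bits)) != 1L) {
        stop("mixed $PnB widths for integer data are not supported")
      }
      readBin(con, "integer", n_val, size = bits[1] / 8L,
              signed = bits[1] / 8L > 2L, endian = endian)
    },
    stop("unsupported $DATATYPE: ", dtype))
  if (length(vals) < n_val) stop("truncated FCS data segment")
  mat <- matrix(vals, ncol = n_par, byrow = TRUE)
  data <- stats::setNames(as.data.frame(mat), names_p)
  list(data = data, ranges = stats::setNames(ranges, names_p),
       keywords = kw, version = version)
}
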