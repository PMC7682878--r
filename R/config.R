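#' Load and validate a project configuration
#'
#' The configuration is one flat YAML file with per-module sections:
#' `seed`, `output_dir`, `flow_sim` (see [flow_sim_config()]),
#' `imaging_sim` (see [imaging_sim_config()]), `flow_pipeline` (gate and
#' threshold parameters), `image_pipeline` (filter parameters) and
#' `samples`, a manifest mapping sample names to `path` and `role`
#' (`split`, `full_length` or `untransfected`). Defaults are filled for
#' every omitted key; unknown keys are rejected by name. When a sample
#' manifest is present it must reference exactly one untransfected control
#' and exactly one full-length control, validated before any file is read.
#'
#' @param path Path to the YAML configuration file.
#' @return A validated `project_config` list with all defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  normalize_config(raw)
}

default_config <- function() {
  list(
    seed = 1L,
    output_dir = "results",
    log_level = "info",
    flow_sim = unclass(flow_sim_config()),
    imaging_sim = unclass(imaging_sim_config()),
    flow_pipeline = list(retain_fraction = 0.5, singlet_band = c(0.8, 1.3),
                         threshold_quantile = 0.999, min_events = 100L),
    image_pipeline = list(ball_radius_px = 20L, small_px = 3, large_px = 40,
                          size_range_um2 = c(80, 2000),
                          circularity_range = c(0.1, 1.0),
                          pixel_size_um = 0.65,
                          condition_folds = c("1x" = 1, "5x" = 2.3)),
    samples = list()
  )
}

normalize_config <- function(raw) {
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- def
  for (top in names(raw)) {
    if (top == "samples") {
      cfg$samples <- raw$samples
      next
    }
    if (is.list(def[[top]])) {
      sub_unknown <- setdiff(names(raw[[top]]), names(def[[top]]))
      if (length(sub_unknown)) {
        stop("unknown key(s) in '", top, "': ",
             paste(sub_unknown, collapse = ", "))
      }
      cfg[[top]][names(raw[[top]])] <- raw[[top]]
    } else {
      cfg[[top]] <- raw[[top]]
    }
  }
  # YAML maps come back as lists; the fold table is a named numeric vector
  cfg$image_pipeline$condition_folds <-
    unlist(cfg$image_pipeline$condition_folds)
  # seed propagates to simulator blocks unless they set their own
  if (!("seed" %in% names(raw$flow_sim))) cfg$flow_sim$seed <- cfg$seed
  if (!("seed" %in% names(raw$imaging_sim))) cfg$imaging_sim$seed <- cfg$seed
  validate_flow_sim_config(cfg$flow_sim)
  do.call(imaging_sim_config, cfg$imaging_sim)
  fp <- cfg$flow_pipeline
  if (fp$retain_fraction <= 0 || fp$retain_fraction > 1) {
    stop("flow_pipeline: retain_fraction must be in (0, 1]")
  }
  if (fp$threshold_quantile <= 0 || fp$threshold_quantile >= 1) {
    stop("flow_pipeline: threshold_quantile must be in (0, 1)")
  }
  if (length(fp$singlet_band) != 2L || fp$singlet_band[2] <= fp$singlet_band[1]) {
    stop("flow_pipeline: singlet_band must be a strictly increasing interval")
  }
  ip <- cfg$image_pipeline
  if (ip$pixel_size_um <= 0) stop("image_pipeline: pixel_size_um must be > 0")
  if (ip$ball_radius_px < 1) stop("image_pipeline: ball_radius_px must be >= 1")
  if (length(cfg$samples)) validate_manifest(cfg$samples)
  structure(cfg, class = "project_config")
}

validate_manifest <- function(samples) {
  roles <- vapply(samples, function(s) {
    if (!is.list(s) || is.null(s$role) || is.null(s$path)) {
      stop("each samples entry needs 'path' and 'role'")
    }
    match.arg(s$role, c("split", "full_length", "untransfected"))
  }, character(1))
  if (sum(roles == "untransfected") != 1L) {
    stop("samples manifest must name exactly one 'untransfected' control")
  }
  if (sum(roles == "full_length") != 1L) {
    stop("samples manifest must name exactly one 'full_length' control")
  }
  invisible(roles)
}

#' Write a normalized configuration back to YAML
#'
#' @param config A `project_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "project_config"))
  out <- unclass(config)
  # named vectors lose their names in YAML; store the fold table as a map
  out$image_pipeline$condition_folds <-
    as.list(out$image_pipeline$condition_folds)
  yaml::write_yaml(out, path)
  invisible(path)
}
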