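#' Default end-to-end run configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]. By default
#' the run simulates its own input stack: an annular phantom stained
#' according to the exact saturation model, sampled along a horizontal ray
#' from the background into the wall centre.
#'
#' @param input `"simulate"` (default) or a path to a TIFF stack written by
#'   [write_stack()].
#' @param phantom Named list overriding [phantom_config()] defaults
#'   (simulate mode only).
#' @param model Named list overriding [exact_model_params()] defaults
#'   (simulate mode only).
#' @param ray `NULL` for the default transmural ray, or a list with 0-based
#'   pixel coordinates `start = c(x, y)`, `end = c(x, y)` and optional
#'   `width_px`.
#' @param edge List with `sigma_px`, `drop_fraction` and `reference_time`
#'   (`"last"`, `"first"` or a 1-based timepoint index): the timepoint whose
#'   profile the edge is detected on and reused for all timepoints.
#' @param segments List with `seg_len` (mm) and `n_segments`.
#' @param levels Saturation levels, sorted, all in (0, 1).
#' @param seed Integer seed for all simulated randomness.
#'
#' @return An object of class `run_config`.
#' @export
default_run_config <- function(input = "simulate",
                               phantom = list(),
                               model = list(),
                               ray = NULL,
                               edge = list(),
                               segments = list(),
                               levels = c(0.90, 0.95, 0.99),
                               seed = 1L) {
  edge_def <- list(sigma_px = 1.5, drop_fraction = 0.5, reference_time = "last")
  seg_def <- list(seg_len = 0.1, n_segments = 20L)
  edge <- utils::modifyList(edge_def, edge)
  segments <- utils::modifyList(seg_def, segments)
  structure(list(input = input,
                 phantom = phantom,
                 model = model,
                 ray = ray,
                 edge = edge,
                 segments = segments,
                 levels = levels,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Accepts a YAML file whose top-level keys match the arguments of
#' [default_run_config()]; missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stop(sprintf("config file '%s' is not a YAML mapping", path))
  args <- y[intersect(names(y), names(formals(default_run_config)))]
  if (!is.null(args$ray)) {
    args$ray$start <- as.numeric(args$ray$start)
    args$ray$end <- as.numeric(args$ray$end)
  }
  do.call(default_run_config, args)
}

#' Validate a run configuration
#'
#' Checks a configuration without running anything and returns one finding
#' per violation, each with a machine-readable code. An empty data frame
#' means the configuration is valid.
#'
#' @param cfg A `run_config`.
#' @return A data frame with columns `code` and `message` (zero rows if
#'   valid).
#' @export
#' @examples
#' validate_config(default_run_config())
validate_config <- function(cfg) {
  findings <- list()
  add <- function(code, message)
    findings[[length(findings) + 1]] <<- data.frame(code = code, message = message)
  if (!inherits(cfg, "run_config")) {
    add("not_a_run_config", "object is not a run_config")
    return(do.call(rbind, findings))
  }
  if (any(cfg$levels <= 0 | cfg$levels >= 1))
    add("level_out_of_range",
        "saturation levels must lie strictly between 0 and 1")
  if (is.unsorted(cfg$levels, strictly = TRUE))
    add("levels_unsorted", "saturation levels must be strictly increasing")
  if (cfg$segments$seg_len <= 0 || cfg$segments$n_segments < 1)
    add("segments_invalid", "seg_len must be > 0 and n_segments >= 1")
  if (cfg$edge$sigma_px <= 0)
    add("sigma_invalid", "edge$sigma_px must be > 0")
  if (cfg$edge$drop_fraction <= 0 || cfg$edge$drop_fraction >= 1)
    add("drop_fraction_invalid", "edge$drop_fraction must be in (0, 1)")
  if (identical(cfg$input, "simulate")) {
    ph <- tryCatch(do.call(phantom_config, cfg$phantom), error = function(e) e)
    if (inherits(ph, "error")) {
      add("phantom_invalid", conditionMessage(ph))
    } else {
      if (cfg$segments$n_segments * cfg$segments$seg_len > ph$wall_thickness)
        add("segments_exceed_wall",
            sprintf("analysis window %.3g mm exceeds wall thickness %.3g mm",
                    cfg$segments$n_segments * cfg$segments$seg_len,
                    ph$wall_thickness))
      if (length(ph$times) < 4L)
        add("times_too_few",
            "at least 4 staining timepoints (including 0 h) are required")
    }
    md <- tryCatch(do.call(exact_model_params, cfg$model), error = function(e) e)
    if (inherits(md, "error")) add("model_invalid", conditionMessage(md))
  } else {
    if (!file.exists(cfg$input))
      add("input_missing", sprintf("input stack '%s' not found", cfg$input))
    else if (!file.exists(sidecar_path(cfg$input)))
      add("sidecar_missing",
          sprintf("metadata sidecar '%s' not found", sidecar_path(cfg$input)))
  }
  if (!is.null(cfg$ray)) {
    ok <- is.list(cfg$ray) &&
      is.numeric(cfg$ray$start) && length(cfg$ray$start) == 2L &&
      is.numeric(cfg$ray$end) && length(cfg$ray$end) == 2L
    if (!ok) add("ray_invalid", "ray must supply numeric start and end (x, y) pairs")
  }
  if (length(findings) == 0)
    data.frame(code = character(0), message = character(0))
  else do.call(rbind, findings)
}
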