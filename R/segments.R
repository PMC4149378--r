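#' Discretize a line profile into fixed-length depth segments
#'
#' Starting at the detected epicardial edge, the profile is cut into
#' `n_segments` half-open depth bins `[k * seg_len, (k + 1) * seg_len)`,
#' `k = 0, ..., n_segments - 1`, measured along the ray. Each segment is
#' assigned the arithmetic mean of the samples whose position falls in its
#' bin; membership uses sample centres and every covered sample belongs to
#' exactly one segment.
#'
#' @param p A [line_profile()].
#' @param edge An [detect_epicardial_edge()] result for `p`.
#' @param seg_len Segment length in mm, default 0.1.
#' @param n_segments Number of segments, default 20 (a 2 mm analysis window).
#'
#' @return A data frame with one row per segment: `depth` (mm, segment start
#'   measured from the edge), `mean_intensity` (counts), `n_samples`.
#' @export
discretize_profile <- function(p, edge, seg_len = 0.1, n_segments = 20L) {
  stopifnot(inherits(p, "line_profile"), inherits(edge, "edge_result"))
  if (seg_len <= 0) stop("seg_len must be > 0")
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  required <- n_segments * seg_len
  available <- p$positions[length(p$positions)] - edge$edge_position
  if (available < required - 1e-9)
    stop(sprintf("profile too short beyond the edge: %.3g mm required, %.3g mm available",
                 required, available))
  step <- if (length(p$positions) >= 2) p$positions[2] - p$positions[1] else seg_len
  # integer sample offsets from the edge keep bin assignment exact
  offs <- seq_along(p$positions) - edge$edge_index
  rel <- offs * step
  bin <- floor(rel / seg_len + 1e-9)
  keep <- bin >= 0 & bin < n_segments
  means <- tapply(p$intensities[keep], factor(bin[keep], levels = 0:(n_segments - 1)),
                  mean)
  counts <- tapply(rep(1L, sum(keep)), factor(bin[keep], levels = 0:(n_segments - 1)),
                   sum)
  counts[is.na(counts)] <- 0L
  if (any(counts == 0))
    stop("some depth segments contain no samples; segment length below sample spacing?")
  data.frame(depth = (0:(n_segments - 1)) * seg_len,
             mean_intensity = as.numeric(means),
             n_samples = as.integer(counts))
}
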