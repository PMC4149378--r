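#' Write a slice time series to a multi-page TIFF
#'
#' One TIFF page per staining timepoint, 16-bit unsigned (typical micro-CT
#' depth); intensities are clamped to `[0, 65535]` and rounded, so the round
#' trip through [read_stack()] is exact for integer counts in that range.
#' Acquisition metadata (staining times, voxel size, seed) goes to a JSON
#' sidecar next to the TIFF, named `<stem>.json`.
#'
#' @param images List of [slice_image()]s with identical dimensions.
#' @param times Staining durations in hours, one per image; defaults to the
#'   images' own `time_h` fields.
#' @param path Output TIFF path.
#' @param seed Optional integer recorded in the sidecar for provenance.
#'
#' @return `path`, invisibly.
#' @export
write_stack <- function(images, times = NULL, path, seed = NA_integer_) {
  stopifnot(is.list(images), length(images) >= 1L)
  if (!all(vapply(images, inherits, logical(1), "slice_image")))
    stop("images must be a list of slice_image objects")
  if (is.null(times)) times <- vapply(images, `[[`, numeric(1), "time_h")
  if (length(times) != length(images))
    stop(sprintf("length mismatch: %d images but %d times",
                 length(images), length(times)))
  dims <- vapply(images, function(im) dim(im$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all images must have identical dimensions")
  pages <- lapply(images, function(im) {
    q <- round(pmin(pmax(im$pixels, 0), 65535))
    q / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- sidecar_path(path)
  jsonlite::write_json(
    list(times_h = as.numeric(times),
         voxel_size_um = images[[1]]$voxel_size_um,
         seed = seed),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a slice time series written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar `<stem>.json` must be present.
#'
#' @return A list with elements `images` (list of [slice_image()]s, intensities
#'   in counts) and `times` (hours), plus `voxel_size_um` and `seed`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read stack: '%s' not found", path))
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar))
    stop(sprintf("metadata sidecar '%s' is missing", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("times_h", "voxel_size_um"))
    if (is.null(meta[[f]]))
      stop(sprintf("metadata sidecar '%s' lacks field '%s'", sidecar, f))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$times_h))
    stop(sprintf("stack has %d pages but sidecar lists %d times",
                 length(pages), length(meta$times_h)))
  images <- mapply(function(pg, t) {
    slice_image(round(pg * 65535), meta$voxel_size_um, t)
  }, pages, meta$times_h, SIMPLIFY = FALSE)
  list(images = images, times = as.numeric(meta$times_h),
       voxel_size_um = meta$voxel_size_um,
       seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}
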