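#' Two-channel 3D image stack
#'
#' Container for one field of view: a DAPI channel and a foci channel, both
#' 3D voxel arrays indexed `(z, y, x)`, with the axial spacing carried as
#' metadata. Fluorescence microscopes in this workflow acquire 5 (probe mode)
#' or 7 (gamma-H2AX mode) z-planes at 0.3 um spacing; other depths are
#' accepted with a warning.
#'
#' @param dapi,foci Numeric 3D arrays of identical dimension `(z, y, x)`,
#'   non-negative intensities.
#' @param z_spacing_um Axial spacing between z-planes, in micrometres.
#' @param pixel_size_um Lateral pixel size in micrometres (metadata only;
#'   sizes are reported in voxels throughout).
#' @param meta Named list of free-form provenance (seed, condition, ...).
#'
#' @return An object of class `image_stack`: a list with elements `channels`
#'   (named list `dapi`, `foci`), `dim`, `z_spacing_um`, `pixel_size_um`,
#'   `meta`.
#' @export
image_stack <- function(dapi, foci, z_spacing_um = 0.3, pixel_size_um = 0.11,
                        meta = list()) {
  if (!is.array(dapi) || length(dim(dapi)) != 3L ||
      !is.array(foci) || length(dim(foci)) != 3L) {
    abort("`dapi` and `foci` must be 3D arrays indexed (z, y, x).",
          class = "g4quant_error")
  }
  if (!identical(dim(dapi), dim(foci))) {
    abort("All channels must share one shape.", class = "g4quant_error")
  }
  if (min(dapi) < 0 || min(foci) < 0) {
    abort("Intensities must be non-negative.", class = "g4quant_error")
  }
  check_positive_number(z_spacing_um, "z_spacing_um")
  nz <- dim(dapi)[1L]
  if (!nz %in% c(5L, 7L)) {
    warn(sprintf(
      "Stack has %d z-planes; the reference acquisition uses 5 or 7.", nz))
  }
  structure(
    list(
      channels = list(dapi = dapi, foci = foci),
      dim = dim(dapi),
      z_spacing_um = z_spacing_um,
      pixel_size_um = pixel_size_um,
      meta = meta
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- x$dim
  cat(sprintf(
    "<image_stack> %d z x %d y x %d x voxels, z-spacing %.2f um, channels: %s\n",
    d[1], d[2], d[3], x$z_spacing_um, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Single-cell region of interest
#'
#' One outlined cell, as a logical voxel mask covering the z-planes used for
#' quantification. In the reference workflow cells are outlined manually;
#' the synthetic generator supplies masks with `provenance = "synthetic"`.
#'
#' @param mask Logical 3D array, same shape as the stack it applies to.
#' @param roi_id Identifier (character or integer).
#' @param provenance `"manual"` or `"synthetic"`.
#'
#' @return An object of class `cell_roi`.
#' @export
cell_roi <- function(mask, roi_id = "cell_1",
                     provenance = c("synthetic", "manual")) {
  provenance <- match.arg(provenance)
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    abort("`mask` must be a logical 3D array.", class = "g4quant_error")
  }
  if (!any(mask)) {
    abort("ROI mask is empty.", class = "g4quant_error")
  }
  structure(list(mask = mask, roi_id = roi_id, provenance = provenance),
            class = "cell_roi")
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Each channel is written as one multi-page 32-bit float TIFF (one page per
#' z-plane, intensities rescaled to `[0, 1]` by the recorded `scale`); a JSON
#' sidecar records axis order, z-spacing, the intensity scale and any
#' metadata, so a round trip reproduces the stack.
#'
#' @param stack An [image_stack].
#' @param path Base path without extension; files `<path>_dapi.tif`,
#'   `<path>_foci.tif` and `<path>.json` are created.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns an
#'   [image_stack].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(1, vapply(stack$channels, max, numeric(1)))
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]] / scale
    pages <- lapply(seq_len(dim(a)[1L]), function(z) a[z, , , drop = TRUE])
    tiff::writeTIFF(pages, paste0(path, "_", ch, ".tif"),
                    bits.per.sample = 32L)
  }
  sidecar <- list(
    axis_order = "z,y,x",
    z_spacing_um = stack$z_spacing_um,
    pixel_size_um = stack$pixel_size_um,
    intensity_scale = scale,
    channels = names(stack$channels),
    meta = stack$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scale <- sidecar$intensity_scale
  chans <- lapply(sidecar$channels, function(ch) {
    pages <- tiff::readTIFF(paste0(path, "_", ch, ".tif"), all = TRUE)
    a <- array(0, dim = c(length(pages), dim(pages[[1L]])))
    for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
    a * scale
  })
  names(chans) <- sidecar$channels
  meta <- sidecar$meta
  if (is.null(meta)) meta <- list()
  image_stack(chans$dapi, chans$foci,
              z_spacing_um = sidecar$z_spacing_um,
              pixel_size_um = sidecar$pixel_size_um,
              meta = as.list(meta))
}
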