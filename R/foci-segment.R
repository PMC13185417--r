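#' Label 3D connected components
#'
#' Labels the foreground of a logical voxel mask by connected components
#' under 6-, 18- or 26-connectivity (26 is the default, matching the common
#' 3D object-counter convention). Labels are assigned in array scan order
#' (the component containing the smallest linear index gets label 1), so the
#' labelling is deterministic.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  if (is.null(dm) || length(dm) != 3L) {
    abort("`mask` must be a 3D array.", class = "g4quant_error")
  }
  lab <- array(0L, dm)
  idx <- which(mask != 0)
  n <- length(idx)
  if (n == 0L) return(lab)
  co <- arrayInd(idx, dm)
  offs <- neighbor_offsets(connectivity, half = TRUE)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[i, ], "+")
    ok <- in_bounds(nb, dm)
    if (!any(ok)) next
    m <- match(linear_index(nb[ok, , drop = FALSE], dm), idx)
    hit <- which(!is.na(m))
    if (length(hit)) edges[[i]] <- cbind(which(ok)[hit], m[hit])
  }
  e <- do.call(rbind, edges)
  if (is.null(e) || nrow(e) == 0L) {
    lab[idx] <- seq_len(n)
    return(lab)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)$membership
  relab <- integer(max(comp))
  firsts <- comp[!duplicated(comp)]
  relab[firsts] <- seq_along(firsts)
  lab[idx] <- relab[comp]
  lab
}

#' Subtract the background floor of the foci channel
#'
#' Estimates the background as the mean foci-channel intensity over a
#' cell-free region (or takes a supplied constant), subtracts it from the
#' foci channel and floors at zero. The estimate is recorded in
#' `stack$meta$background_estimate`.
#'
#' @param stack An [image_stack].
#' @param background_region Logical array (cell-free region, caller's
#'   responsibility) or a single non-negative constant.
#' @return The stack with the foci channel background-subtracted.
#' @export
subtract_background <- function(stack, background_region) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.numeric(background_region) && length(background_region) == 1L) {
    if (background_region < 0) {
      abort("Constant background must be non-negative.", class = "g4quant_error")
    }
    est <- background_region
  } else {
    if (!is.array(background_region) ||
        !identical(dim(background_region), stack$dim)) {
      abort("`background_region` must be a mask of the stack's shape or a constant.",
            class = "g4quant_error")
    }
    if (!any(background_region)) {
      abort("Background region is empty.", class = "g4quant_error")
    }
    est <- mean(stack$channels$foci[background_region != 0])
  }
  stack$channels$foci <- pmax(stack$channels$foci - est, 0)
  stack$meta$background_estimate <- est
  stack
}

#' Clear all signal outside a cell ROI
#'
#' Sets every voxel outside the ROI mask to zero in every channel, so that
#' only the outlined cell contributes to quantification.
#'
#' @param stack An [image_stack].
#' @param roi A [cell_roi] whose mask intersects the stack.
#' @return The masked stack.
#' @export
clear_outside_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "cell_roi"))
  if (!identical(dim(roi$mask), stack$dim)) {
    abort("ROI mask shape does not match the stack.", class = "g4quant_error")
  }
  if (!any(roi$mask)) {
    abort("ROI lies entirely outside the stack.", class = "g4quant_error")
  }
  for (ch in names(stack$channels)) {
    stack$channels[[ch]][!roi$mask] <- 0
  }
  stack$meta$roi_id <- roi$roi_id
  stack
}

#' Segment the nucleus from the DAPI channel
#'
#' Otsu-thresholds the DAPI intensities within the ROI, fills holes slice by
#' slice, and keeps the largest connected component as the nucleus.
#'
#' @param stack An [image_stack] (typically already ROI-masked).
#' @param roi A [cell_roi]; thresholding is computed from voxels inside it.
#' @param fill_holes Fill 2D holes per z-slice (default `TRUE`).
#' @param connectivity Connectivity for the largest-component rule.
#' @return Logical array: the nucleus mask.
#' @export
segment_nucleus <- function(stack, roi, fill_holes = TRUE, connectivity = 26) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "cell_roi"))
  if (!identical(dim(roi$mask), stack$dim)) {
    abort("ROI mask shape does not match the stack.", class = "g4quant_error")
  }
  vals <- stack$channels$dapi[roi$mask]
  rng <- range(vals)
  if (diff(rng) == 0) {
    abort("DAPI channel is constant within the ROI; cannot segment a nucleus.",
          class = "g4quant_error")
  }
  sc <- (vals - rng[1L]) / diff(rng)
  th <- EBImage::otsu(matrix(sc, ncol = 1L), range = c(0, 1))
  bin <- array(FALSE, stack$dim)
  bin[roi$mask] <- sc > th
  if (!any(bin)) {
    abort("No above-threshold DAPI voxels within the ROI.",
          class = "g4quant_error")
  }
  if (fill_holes) {
    for (z in seq_len(stack$dim[1L])) {
      bin[z, , ] <- as.logical(EBImage::fillHull(bin[z, , ] * 1))
    }
  }
  lab <- label_components(bin, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Frozen foci-segmentation parameters
#'
#' The foci channel is thresholded at `background_mean + k * background_sd`
#' and labelled by 3D connected components. The reference protocol demands
#' the *same parameters throughout all conditions from a given experiment*;
#' a `foci_params` object therefore carries the experiment it was frozen for,
#' and [segment_foci()] refuses to apply it to another experiment unless
#' explicitly overridden.
#'
#' `estimate_foci_params()` freezes the threshold from cell-free regions of
#' untreated (NT) fields of one experiment.
#'
#' @param background_mean,background_sd Background statistics of the foci
#'   channel (post-subtraction: use 0 and the residual SD).
#' @param k Threshold multiplier (default 3): threshold is mean + k * SD.
#' @param threshold Absolute threshold; defaults to
#'   `background_mean + k * background_sd` and must not fall below
#'   `background_mean`.
#' @param connectivity 6, 18 or 26.
#' @param experiment_id Experiment the parameters are frozen for.
#' @return An object of class `foci_params`.
#' @export
foci_params <- function(background_mean, background_sd, k = 3,
                        threshold = background_mean + k * background_sd,
                        connectivity = 26, experiment_id = NULL) {
  if (threshold < background_mean) {
    abort("Threshold below the background mean would segment noise as foci.",
          class = "g4quant_error")
  }
  structure(
    list(background_mean = background_mean, background_sd = background_sd,
         k = k, threshold = threshold,
         connectivity = as.integer(connectivity),
         experiment_id = experiment_id),
    class = "foci_params"
  )
}

#' @rdname foci_params
#' @param stacks List of [image_stack]s from NT fields of one experiment.
#' @param regions List of logical arrays (cell-free region per stack).
#' @export
estimate_foci_params <- function(stacks, regions, k = 3, connectivity = 26,
                                 experiment_id = NULL) {
  stopifnot(length(stacks) == length(regions), length(stacks) >= 1L)
  vals <- unlist(purrr::map2(stacks, regions, function(s, r) {
    if (!any(r)) abort("Background region is empty.", class = "g4quant_error")
    s$channels$foci[r != 0]
  }))
  foci_params(background_mean = mean(vals), background_sd = stats::sd(vals),
              k = k, connectivity = connectivity, experiment_id = experiment_id)
}

#' Segment foci by thresholding and 3D connected components
#'
#' @param stack An [image_stack] (ROI-masked; background subtraction optional
#'   provided the threshold is on the same scale).
#' @param params A [foci_params] object, frozen once per experiment.
#' @param experiment_id Experiment of the stack being segmented; checked
#'   against `params$experiment_id`.
#' @param override Set `TRUE` to knowingly reuse parameters across
#'   experiments (breaks the frozen-parameters rule; logged in the result).
#' @return Integer label array (see [label_components()]) with the applied
#'   parameters attached as attribute `"params"`.
#' @export
segment_foci <- function(stack, params, experiment_id = NULL, override = FALSE) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "foci_params"))
  if (!is.null(params$experiment_id) && !is.null(experiment_id) &&
      !identical(params$experiment_id, experiment_id) && !override) {
    abort(sprintf(
      "Segmentation parameters were frozen for experiment '%s' but applied to '%s'. The protocol requires the same parameters throughout one experiment; pass `override = TRUE` only if you mean to break it.",
      params$experiment_id, experiment_id),
      class = "g4quant_frozen_params_error")
  }
  lab <- label_components(stack$channels$foci > params$threshold,
                          params$connectivity)
  attr(lab, "params") <- params
  lab
}
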