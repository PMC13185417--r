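#' Classify segmented components and apply voxel-size filters
#'
#' Applies the compartment and size rules of the quantification protocol.
#' In probe (`tasq`) mode, a component with any voxel overlapping the nucleus
#' mask is on the nuclear side; nuclear-side components larger than 100
#' voxels are the morphologically defined nucleoli and are removed from the
#' nuclear counts; nuclear foci are kept at 3-100 voxels and cytoplasmic foci
#' at 20-100 voxels (smaller ones are indistinguishable from background,
#' larger ones cannot be separated). In `gh2ax` mode only nucleus-overlapping
#' components of at least `min_gh2ax_voxels` are retained. Nothing is
#' silently dropped: every component appears in the output with its final
#' `compartment` (`"nuclear"`, `"cytoplasmic"`, `"nucleolar"` or
#' `"discarded"`) and, when discarded, a `reason`.
#'
#' @param components Integer label array from [segment_foci()].
#' @param nucleus_mask Logical array, same shape.
#' @param mode `"tasq"` or `"gh2ax"`.
#' @param foci_channel Optional intensity array for per-focus intensity sums.
#' @param nuclear_size,cyto_size Inclusive size windows (voxels).
#' @param min_gh2ax_voxels Minimum size in gh2ax mode (default 2).
#' @return Tibble with one row per component: `label`, `voxel_count`,
#'   `nucleus_overlap`, `side`, `compartment`, `kept`, `reason`,
#'   `total_intensity`, `mean_intensity`, centroid and bounding-box columns.
#' @export
classify_and_filter <- function(components, nucleus_mask,
                                mode = c("tasq", "gh2ax"),
                                foci_channel = NULL,
                                nuclear_size = c(3L, 100L),
                                cyto_size = c(20L, 100L),
                                min_gh2ax_voxels = 2L) {
  mode <- match.arg(mode)
  dm <- dim(components)
  if (!identical(dm, dim(nucleus_mask))) {
    abort("`components` and `nucleus_mask` must share one shape.",
          class = "g4quant_error")
  }
  empty <- tibble::tibble(
    label = integer(), voxel_count = integer(), nucleus_overlap = integer(),
    side = character(), compartment = character(), kept = logical(),
    reason = character(), total_intensity = double(),
    mean_intensity = double(),
    centroid_z = double(), centroid_y = double(), centroid_x = double(),
    zmin = integer(), zmax = integer(), ymin = integer(), ymax = integer(),
    xmin = integer(), xmax = integer()
  )
  idx <- which(components > 0L)
  if (!length(idx)) return(empty)

  co <- arrayInd(idx, dm)
  vox <- tibble::tibble(
    label = components[idx],
    z = co[, 1L], y = co[, 2L], x = co[, 3L],
    in_nucleus = nucleus_mask[idx],
    intensity = if (is.null(foci_channel)) NA_real_ else foci_channel[idx]
  )
  per <- vox |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      voxel_count = dplyr::n(),
      nucleus_overlap = sum(.data$in_nucleus),
      total_intensity = sum(.data$intensity),
      mean_intensity = mean(.data$intensity),
      centroid_z = mean(.data$z), centroid_y = mean(.data$y),
      centroid_x = mean(.data$x),
      zmin = min(.data$z), zmax = max(.data$z),
      ymin = min(.data$y), ymax = max(.data$y),
      xmin = min(.data$x), xmax = max(.data$x),
      .groups = "drop"
    ) |>
    dplyr::mutate(side = ifelse(.data$nucleus_overlap > 0L, "nuclear",
                                "cytoplasmic"))

  per <- if (mode == "tasq") {
    dplyr::mutate(per,
      compartment = dplyr::case_when(
        side == "nuclear" & voxel_count > 100L ~ "nucleolar",
        side == "nuclear" & voxel_count >= nuclear_size[1L] &
          voxel_count <= nuclear_size[2L] ~ "nuclear",
        side == "cytoplasmic" & voxel_count >= cyto_size[1L] &
          voxel_count <= cyto_size[2L] ~ "cytoplasmic",
        .default = "discarded"
      ),
      reason = dplyr::case_when(
        compartment != "discarded" ~ NA_character_,
        side == "nuclear" ~ sprintf("nuclear component below %d voxels",
                                    nuclear_size[1L]),
        voxel_count < cyto_size[1L] ~ sprintf(
          "cytoplasmic component below %d voxels", cyto_size[1L]),
        .default = sprintf("cytoplasmic component above %d voxels",
                           cyto_size[2L])
      )
    )
  } else {
    dplyr::mutate(per,
      compartment = dplyr::case_when(
        side == "nuclear" & voxel_count >= min_gh2ax_voxels ~ "nuclear",
        .default = "discarded"
      ),
      reason = dplyr::case_when(
        compartment != "discarded" ~ NA_character_,
        side != "nuclear" ~ "no overlap with the nucleus",
        .default = sprintf("below %d voxels", min_gh2ax_voxels)
      )
    )
  }
  per |>
    dplyr::mutate(kept = .data$compartment != "discarded") |>
    dplyr::select(dplyr::all_of(names(empty))) |>
    dplyr::arrange(.data$label)
}

#' Quantify one cell
#'
#' Runs the full per-cell pipeline: optional background subtraction, clearing
#' outside the ROI, nucleus segmentation from DAPI, foci segmentation with
#' the experiment's frozen parameters, and compartment/size classification.
#'
#' @param stack An [image_stack] (whole field or pre-cropped).
#' @param roi The cell's [cell_roi].
#' @param params Frozen [foci_params] of the experiment.
#' @param mode `"tasq"` or `"gh2ax"`.
#' @param background Optional cell-free mask or constant for
#'   [subtract_background()]; when supplied, `params` must be on the
#'   subtracted scale (background mean 0). Omit if already subtracted or if
#'   the threshold is on the raw scale.
#' @param experiment_id,override Passed to [segment_foci()].
#' @param ... Passed to [classify_and_filter()] (size windows, gh2ax minimum).
#' @return An object of class `cell_quant`: list with `roi_id`, `mode`,
#'   `nucleus_mask`, `nucleolus_mask`, `foci` (the classification tibble) and
#'   `summary`, a one-row tibble of per-compartment counts, volumes and
#'   intensity sums plus DAPI QC metrics. `as_tibble()` returns the summary
#'   row.
#' @export
quantify_cell <- function(stack, roi, params, mode = c("tasq", "gh2ax"),
                          background = NULL, experiment_id = NULL,
                          override = FALSE, ...) {
  mode <- match.arg(mode)
  roi_id <- roi$roi_id
  res <- withCallingHandlers(
    {
      if (!is.null(background)) stack <- subtract_background(stack, background)
      masked <- clear_outside_roi(stack, roi)
      nucleus <- segment_nucleus(masked, roi)
      labs <- segment_foci(masked, params, experiment_id = experiment_id,
                           override = override)
      foci <- classify_and_filter(labs, nucleus, mode = mode,
                                  foci_channel = masked$channels$foci, ...)
      list(masked = masked, nucleus = nucleus, labs = labs, foci = foci)
    },
    error = function(e) {
      abort(sprintf("While quantifying ROI '%s': %s", roi_id,
                    conditionMessage(e)),
            class = "g4quant_cell_error", parent = e)
    }
  )
  foci <- res$foci
  nucleolus_mask <- array(FALSE, stack$dim)
  nucleolar_labels <- foci$label[foci$compartment == "nucleolar"]
  if (length(nucleolar_labels)) {
    nucleolus_mask[res$labs %in% nucleolar_labels] <- TRUE
  }
  count_of <- function(comp) sum(foci$compartment == comp)
  vol_of <- function(comp) sum(foci$voxel_count[foci$compartment == comp])
  int_of <- function(comp) sum(foci$total_intensity[foci$compartment == comp])
  summary <- tibble::tibble(
    roi_id = roi_id,
    mode = mode,
    n_nuclear = count_of("nuclear"),
    n_cytoplasmic = count_of("cytoplasmic"),
    n_nucleolar = count_of("nucleolar"),
    n_discarded = count_of("discarded"),
    n_components = nrow(foci),
    vol_nuclear = vol_of("nuclear"),
    vol_cytoplasmic = vol_of("cytoplasmic"),
    vol_nucleolar = vol_of("nucleolar"),
    int_nuclear = int_of("nuclear"),
    int_cytoplasmic = int_of("cytoplasmic"),
    int_nucleolar = int_of("nucleolar"),
    dapi_volume = sum(res$nucleus),
    dapi_intensity = sum(res$masked$channels$dapi[res$nucleus]),
    qc_flags = "",
    excluded = FALSE
  )
  structure(
    list(roi_id = roi_id, mode = mode, nucleus_mask = res$nucleus,
         nucleolus_mask = nucleolus_mask, foci = foci, summary = summary),
    class = "cell_quant"
  )
}

#' @export
print.cell_quant <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cell_quant> %s (%s): %d nuclear, %d cytoplasmic, %d nucleolar, %d discarded\n",
    x$roi_id, x$mode, s$n_nuclear, s$n_cytoplasmic, s$n_nucleolar,
    s$n_discarded))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.cell_quant <- function(x, ...) x$summary

#' Flag outlier cells
#'
#' Marks cells whose DAPI nuclear volume or integrated DAPI intensity has a
#' robust z-score (median/MAD) beyond `z_cutoff`, cells with zero DAPI
#' intensity ("DAPI missing"), and -- in probe mode -- cells without any
#' segmented nucleolus. Flagged cells are marked `excluded = TRUE` but kept
#' in the table. Statistics are computed within `condition` x `experiment`
#' groups when those columns are present; groups of fewer than 5 cells are
#' returned unflagged with a warning.
#'
#' @param cells Tibble of per-cell summary rows (see [quantify_cell()]),
#'   optionally with `condition` / `experiment` columns.
#' @param z_cutoff Robust z-score cutoff (default 3).
#' @return The tibble with `qc_flags` (semicolon-separated) and `excluded`
#'   filled in.
#' @export
flag_outliers <- function(cells, z_cutoff = 3) {
  stopifnot(is.data.frame(cells))
  grp <- intersect(c("condition", "experiment"), names(cells))
  flag_group <- function(df) {
    if (nrow(df) < 5L) {
      warn(sprintf(
        "Only %d cells in a group; outlier flagging needs at least 5 and was skipped.",
        nrow(df)))
      df$qc_flags <- ""
      df$excluded <- FALSE
      return(df)
    }
    zv <- robust_z(df$dapi_volume)
    zi <- robust_z(df$dapi_intensity)
    flags <- purrr::pmap_chr(
      list(zv, zi, df$dapi_intensity, df$n_nucleolar, df$mode),
      function(zv1, zi1, di, nn, mode) {
        f <- character()
        if (di == 0) f <- c(f, "DAPI missing")
        if (is.infinite(zv1) || abs(zv1) > z_cutoff) f <- c(f, "DAPI volume outlier")
        if (di > 0 && (is.infinite(zi1) || abs(zi1) > z_cutoff)) {
          f <- c(f, "DAPI intensity outlier")
        }
        if (identical(mode, "tasq") && nn == 0L) f <- c(f, "no nucleolus segmented")
        paste(f, collapse = "; ")
      })
    df$qc_flags <- flags
    df$excluded <- flags != ""
    df
  }
  if (length(grp)) {
    cells |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::group_modify(~ flag_group(.x)) |>
      dplyr::ungroup()
  } else {
    flag_group(cells)
  }
}

#' Summarise foci counts by condition
#'
#' Per-experiment means first, then across-experiment mean and SD -- matching
#' a design where each independent experiment contributes one dot. The fold
#' change of each condition is its across-experiment mean divided by the
#' untreated (NT) mean; the delta is the difference (the NT-corrected value
#' used for gamma-H2AX foci/nucleus).
#'
#' @param cells Per-cell tibble with `condition`, `experiment` and count
#'   columns; excluded cells are dropped.
#' @param nt_label Label of the untreated condition (default `"NT"`).
#' @param metric `"nuclear"`, `"cytoplasmic"`, `"whole_cell"` (nuclear +
#'   cytoplasmic) or `"per_nucleus"` (gamma-H2AX foci/nucleus, i.e. the
#'   nuclear count).
#' @return Tibble: `condition`, `metric`, `n_experiments`, `n_cells`,
#'   `mean`, `sd`, `fold_change`, `delta`. `fold_change` is `NA` (with a
#'   warning) if the NT mean is exactly 0.
#' @export
summarize_condition <- function(cells, nt_label = "NT",
                                metric = c("nuclear", "cytoplasmic",
                                           "whole_cell", "per_nucleus")) {
  metric <- match.arg(metric)
  stopifnot(all(c("condition", "experiment") %in% names(cells)))
  if (!nt_label %in% cells$condition) {
    abort(sprintf("NT condition '%s' not present.", nt_label),
          class = "g4quant_error")
  }
  if ("excluded" %in% names(cells)) {
    cells <- dplyr::filter(cells, !.data$excluded)
  }
  value <- switch(metric,
    nuclear = cells$n_nuclear,
    cytoplasmic = cells$n_cytoplasmic,
    whole_cell = cells$n_nuclear + cells$n_cytoplasmic,
    per_nucleus = cells$n_nuclear
  )
  per_exp <- cells |>
    dplyr::mutate(.value = value) |>
    dplyr::group_by(.data$condition, .data$experiment) |>
    dplyr::summarise(exp_mean = mean(.data$.value), n_cells = dplyr::n(),
                     .groups = "drop")
  out <- per_exp |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      metric = metric,
      n_experiments = dplyr::n(),
      n_cells = sum(.data$n_cells),
      mean = mean(.data$exp_mean),
      sd = stats::sd(.data$exp_mean),
      .groups = "drop"
    )
  nt_mean <- out$mean[out$condition == nt_label]
  if (nt_mean == 0) {
    warn("NT mean is exactly 0; fold changes are undefined and reported as NA.")
    out$fold_change <- NA_real_
  } else {
    out$fold_change <- out$mean / nt_mean
  }
  out$delta <- out$mean - nt_mean
  dplyr::arrange(out, .data$condition != nt_label, .data$condition)
}
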