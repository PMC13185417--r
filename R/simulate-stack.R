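#' Configuration for the single-cell stack simulator
#'
#' Defines the geometry, focus statistics and intensity model of one
#' synthetic cell: an ellipsoidal nucleus inside an ellipsoidal cell
#' footprint, 2-4 bright intranuclear nucleoli (each well above the 100-voxel
#' nucleolus cutoff), and punctate foci planted in the nucleus and cytoplasm
#' over a Gaussian background floor. Counts are Poisson; a `fold_change`
#' multiplier scales both compartments' means to emulate treated conditions.
#'
#' Defaults emulate the reference acquisition: 5 z-planes at 0.3 um, nuclear
#' foci small (default 3-12 voxels), cytoplasmic foci 20-40 voxels, focus
#' amplitude 15x the background SD so detection at a mean + 3 SD threshold is
#' unambiguous.
#'
#' @param dim Grid shape `c(z, y, x)`; z should be 5 or 7.
#' @param z_spacing_um Axial spacing (um).
#' @param pixel_size_um Lateral pixel size (um; metadata only).
#' @param nucleus_semiaxes,cell_semiaxes Ellipsoid semi-axes `c(z, y, x)` in
#'   voxels; the nucleus must fit inside the cell, the cell inside the grid.
#' @param n_nucleoli Integer range `c(min, max)` of nucleoli per nucleus.
#' @param nucleolus_size_range Voxel-count range for nucleoli (> 100).
#' @param nuclear_foci_mean,cyto_foci_mean Poisson means for focus counts.
#' @param nuclear_size_range,cyto_size_range Voxel-count ranges (uniform) for
#'   planted foci.
#' @param nuclear_foci_n,cyto_foci_n Exact focus counts; override the Poisson
#'   draw when set (deterministic designs, boundary-size checks).
#' @param nuclear_sizes,cyto_sizes Explicit voxel counts, one per focus;
#'   override both the count and size distributions when set.
#' @param fold_change Dimensionless multiplier (> 0) applied to both focus
#'   count means; emulates treatment-induced increases.
#' @param focus_amplitude,nucleolus_amplitude Peak intensity added by a
#'   focus / nucleolus in the foci channel.
#' @param background_mean,background_sd Gaussian background floor of the foci
#'   channel (additive camera-noise model, floored at 0).
#' @param dapi_nucleus,dapi_cytoplasm,dapi_background,dapi_sd DAPI channel
#'   levels and noise.
#' @param z_anisotropy Weight applied to z-distances when shaping blobs
#'   (axial extent compressed relative to lateral, as under a widefield PSF).
#' @param separable If `TRUE` (default) planted objects keep a >= 1 voxel gap
#'   from each other, so segmentation can never merge them.
#' @param max_attempts Placement retries per object before the grid is
#'   rejected as too crowded.
#' @param seed Integer; fixes all randomness of [simulate_cell_stack()].
#'
#' @return An object of class `sim_config` (validated named list).
#' @export
sim_config <- function(dim = c(z = 5L, y = 64L, x = 64L),
                       z_spacing_um = 0.3,
                       pixel_size_um = 0.11,
                       nucleus_semiaxes = c(z = 2.4, y = 18, x = 18),
                       cell_semiaxes = c(z = 2.8, y = 26, x = 26),
                       n_nucleoli = c(2L, 3L),
                       nucleolus_size_range = c(110L, 160L),
                       nuclear_foci_mean = 4,
                       cyto_foci_mean = 1.5,
                       nuclear_size_range = c(3L, 12L),
                       cyto_size_range = c(20L, 40L),
                       nuclear_foci_n = NULL,
                       cyto_foci_n = NULL,
                       nuclear_sizes = NULL,
                       cyto_sizes = NULL,
                       fold_change = 1,
                       focus_amplitude = 120,
                       nucleolus_amplitude = 160,
                       background_mean = 100,
                       background_sd = 8,
                       dapi_nucleus = 180,
                       dapi_cytoplasm = 60,
                       dapi_background = 10,
                       dapi_sd = 5,
                       z_anisotropy = 2,
                       separable = TRUE,
                       max_attempts = 500L,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$dim <- as.integer(dim)
  if (length(cfg$dim) != 3L || any(cfg$dim < 1L)) {
    abort("`dim` must be three positive integers (z, y, x).",
          class = "g4quant_error")
  }
  if (!cfg$dim[1L] %in% c(5L, 7L)) {
    warn(sprintf("z depth %d; the reference acquisition uses 5 or 7 planes.",
                 cfg$dim[1L]))
  }
  amts <- c(nuclear_foci_mean, cyto_foci_mean, focus_amplitude,
            nucleolus_amplitude, background_mean, background_sd,
            dapi_nucleus, dapi_cytoplasm, dapi_background, dapi_sd)
  if (any(!is.finite(amts)) || any(amts < 0)) {
    abort("All means and amplitudes must be finite and >= 0.",
          class = "g4quant_error")
  }
  check_positive_number(fold_change, "fold_change")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer.", class = "g4quant_error")
  }
  cfg$seed <- as.integer(seed)
  # the cell ellipsoid (plus a 1-voxel margin laterally) must fit in the grid
  if (2 * cell_semiaxes[2L] + 2 > cfg$dim[2L] ||
      2 * cell_semiaxes[3L] + 2 > cfg$dim[3L]) {
    abort("Grid too small for the cell ellipsoid plus a cytoplasmic margin.",
          class = "g4quant_error")
  }
  if (any(nucleus_semiaxes[2:3] >= cell_semiaxes[2:3])) {
    abort("Nucleus semi-axes must be smaller than the cell's.",
          class = "g4quant_error")
  }
  if (nucleolus_size_range[1L] <= 100L) {
    abort("Nucleoli must exceed 100 voxels.", class = "g4quant_error")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate one two-channel cell stack with exact ground truth
#'
#' Draws Poisson focus counts for nucleus and cytoplasm (means scaled by
#' `fold_change`), places each focus as a compact connected voxel blob of an
#' exactly known size, places 2-4 bright nucleoli (> 100 voxels) inside the
#' nucleus, then renders the DAPI channel (bright nucleus on dim cytoplasm)
#' and the foci channel (background noise + nucleolus blobs + planted foci).
#' Blob intensity falls off as a Gaussian of distance from the blob centre
#' but never below 60% of the amplitude, so every planted voxel clears a
#' background mean + 3 SD threshold by a wide margin.
#'
#' All randomness is governed by `config$seed`: the same config yields
#' bit-identical output on every call.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cell` with elements:
#'   * `stack`: the [image_stack] (channels `dapi`, `foci`);
#'   * `truth`: class `image_truth` -- `nucleus_mask`, `nucleolus_mask`,
#'     `cell_mask` (logical arrays), `foci` (tibble with `compartment`,
#'     `voxel_count`, `centroid_z/y/x` and a `voxels` list-column of
#'     coordinate matrices), `background_level`;
#'   * `roi`: the [cell_roi] (the cell footprint, provenance `"synthetic"`).
#' @export
simulate_cell_stack <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cell_stack_impl(config))
}

simulate_cell_stack_impl <- function(cfg) {
  dm <- cfg$dim
  proto <- array(0, dm)
  zz <- slice.index(proto, 1L)
  yy <- slice.index(proto, 2L)
  xx <- slice.index(proto, 3L)
  ctr <- (dm + 1) / 2

  ell <- function(semi) {
    ((zz - ctr[1L]) / semi[1L])^2 + ((yy - ctr[2L]) / semi[2L])^2 +
      ((xx - ctr[3L]) / semi[3L])^2 <= 1
  }
  nucleus <- ell(cfg$nucleus_semiaxes)
  cell <- ell(cfg$cell_semiaxes)

  blocked <- array(FALSE, dm)
  signal <- array(0, dm)
  nucleolus <- array(FALSE, dm)

  place <- function(v, allowed) {
    # compact blob of exactly v voxels around a random centre, grown by
    # anisotropic distance within `allowed`, kept only if connected
    cand <- which(allowed & !blocked)
    if (length(cand) < v) return(NULL)
    co_all <- arrayInd(cand, dm)
    for (i in seq_len(cfg$max_attempts)) {
      j <- if (length(cand) == 1L) 1L else sample.int(length(cand), 1L)
      cz <- co_all[j, 1L]; cy <- co_all[j, 2L]; cx <- co_all[j, 3L]
      d2 <- ((co_all[, 1L] - cz) * cfg$z_anisotropy)^2 +
        (co_all[, 2L] - cy)^2 + (co_all[, 3L] - cx)^2
      ord <- order(d2, cand)
      pick <- ord[seq_len(v)]
      blob <- co_all[pick, , drop = FALSE]
      # reject fragmented picks (possible near mask boundaries)
      sub <- array(FALSE, dm)
      sub[linear_index(blob, dm)] <- TRUE
      if (max(label_components(sub, 26)) == 1L) {
        return(blob)
      }
    }
    NULL
  }

  paint <- function(blob, amplitude) {
    cz <- mean(blob[, 1L]); cy <- mean(blob[, 2L]); cx <- mean(blob[, 3L])
    d2 <- ((blob[, 1L] - cz) * cfg$z_anisotropy)^2 +
      (blob[, 2L] - cy)^2 + (blob[, 3L] - cx)^2
    s2 <- max(max(d2), 1) / 4
    w <- 0.6 + 0.4 * exp(-d2 / (2 * s2))
    idx <- linear_index(blob, dm)
    signal[idx] <<- signal[idx] + amplitude * w
    blocked[dilate_coords(blob, dm)] <<- TRUE
  }

  reject <- function(what) {
    abort(sprintf(
      "Could not place %s without violating compartment constraints after %d attempts; the grid is too crowded.",
      what, cfg$max_attempts), class = "g4quant_placement_error")
  }

  # nucleoli first: bright, > 100 voxels, strictly intranuclear
  # sample() on a length-1 vector would draw from 1:x; always index the pool
  draw_from <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]
  n_nucl <- draw_from(seq(cfg$n_nucleoli[1L], cfg$n_nucleoli[2L]), 1L)
  for (k in seq_len(n_nucl)) {
    v <- draw_from(seq(cfg$nucleolus_size_range[1L], cfg$nucleolus_size_range[2L]), 1L)
    blob <- place(v, nucleus)
    if (is.null(blob)) reject(sprintf("nucleolus %d (%d voxels)", k, v))
    nucleolus[linear_index(blob, dm)] <- TRUE
    paint(blob, cfg$nucleolus_amplitude)
  }

  draw_sizes <- function(n, rng) {
    if (n == 0L) return(integer())
    draw_from(seq(rng[1L], rng[2L]), n)
  }
  sizes_nuc <- if (!is.null(cfg$nuclear_sizes)) {
    as.integer(cfg$nuclear_sizes)
  } else {
    n <- cfg$nuclear_foci_n %||%
      rpois(1L, cfg$nuclear_foci_mean * cfg$fold_change)
    draw_sizes(n, cfg$nuclear_size_range)
  }
  sizes_cyt <- if (!is.null(cfg$cyto_sizes)) {
    as.integer(cfg$cyto_sizes)
  } else {
    n <- cfg$cyto_foci_n %||% rpois(1L, cfg$cyto_foci_mean * cfg$fold_change)
    draw_sizes(n, cfg$cyto_size_range)
  }

  foci <- list()
  add_focus <- function(v, compartment, allowed) {
    blob <- place(v, allowed)
    if (is.null(blob)) reject(sprintf("a %s focus of %d voxels", compartment, v))
    paint(blob, cfg$focus_amplitude)
    foci[[length(foci) + 1L]] <<- tibble::tibble(
      compartment = compartment,
      voxel_count = as.integer(v),
      centroid_z = mean(blob[, 1L]),
      centroid_y = mean(blob[, 2L]),
      centroid_x = mean(blob[, 3L]),
      voxels = list(blob)
    )
  }
  for (v in sizes_nuc) add_focus(v, "nuclear", nucleus & !nucleolus)
  for (v in sizes_cyt) add_focus(v, "cytoplasmic", cell & !nucleus)

  foci_tbl <- if (length(foci)) dplyr::bind_rows(foci) else
    tibble::tibble(compartment = character(), voxel_count = integer(),
                   centroid_z = double(), centroid_y = double(),
                   centroid_x = double(), voxels = list())

  bg <- if (cfg$background_sd > 0) {
    pmax(array(rnorm(prod(dm), cfg$background_mean, cfg$background_sd), dm), 0)
  } else {
    array(cfg$background_mean, dm)
  }
  foci_channel <- bg + signal

  dapi <- array(cfg$dapi_background, dm)
  dapi[cell] <- cfg$dapi_cytoplasm
  dapi[nucleus] <- cfg$dapi_nucleus
  if (cfg$dapi_sd > 0) {
    dapi <- pmax(dapi + array(rnorm(prod(dm), 0, cfg$dapi_sd), dm), 0)
  }

  stack <- image_stack(
    dapi, foci_channel,
    z_spacing_um = cfg$z_spacing_um,
    pixel_size_um = cfg$pixel_size_um,
    meta = list(seed = cfg$seed, fold_change = cfg$fold_change,
                generator = "simulate_cell_stack")
  )
  truth <- structure(
    list(nucleus_mask = nucleus, nucleolus_mask = nucleolus, cell_mask = cell,
         foci = foci_tbl, background_level = cfg$background_mean),
    class = "image_truth"
  )
  structure(list(stack = stack, truth = truth,
                 roi = cell_roi(cell, roi_id = sprintf("cell_seed%d", cfg$seed))),
            class = "sim_cell")
}
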