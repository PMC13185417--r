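#' Normalize a FRET-melting curve to 0-100%
#'
#' Min-max normalization of the FAM emission over the heating ramp: the
#' observed minimum maps to 0% and the maximum to 100%, making the curve
#' invariant to positive affine rescaling of the raw signal. When the table
#' carries several replicate `series`, their normalized curves are averaged
#' point-wise.
#'
#' @param melt Tibble with `temperature_C` and `emission`; optional `ramp`
#'   (only `"heating"` rows are used), `series` and `protocol` columns.
#' @return Object of class `melt_result`: tibble `temperature_C`,
#'   `emission_norm` (percent) with the protocol tag as attribute.
#' @export
normalize_melt <- function(melt) {
  stopifnot(is.data.frame(melt),
            all(c("temperature_C", "emission") %in% names(melt)))
  if ("ramp" %in% names(melt)) {
    melt <- dplyr::filter(melt, .data$ramp == "heating")
  }
  if (!"series" %in% names(melt)) melt$series <- 1L
  if (dplyr::n_distinct(melt$temperature_C) < 20L) {
    abort("A melt curve needs at least 20 temperature points.",
          class = "g4quant_error")
  }
  norm_one <- function(df) {
    df <- dplyr::arrange(df, .data$temperature_C)
    rng <- range(df$emission)
    if (diff(rng) == 0) {
      abort("Emission is constant; no melting transition to normalize.",
            class = "g4quant_error")
    }
    df$emission_norm <- 100 * (df$emission - rng[1L]) / diff(rng)
    df
  }
  out <- melt |>
    dplyr::group_by(.data$series) |>
    dplyr::group_modify(~ norm_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(emission_norm = mean(.data$emission_norm),
                     .groups = "drop")
  structure(out,
            class = c("melt_result", class(out)),
            protocol = if ("protocol" %in% names(melt))
              melt$protocol[1L] else "classical")
}

#' Half-transition temperature of a normalized melt curve
#'
#' T1/2 is the temperature at which the normalized emission first crosses
#' 50% on the way up, located by linear interpolation between the two
#' bracketing points. A 3-point running-median smooth (on by default) guards
#' the first-crossing rule against isolated noisy points; on a monotone
#' curve it is the identity.
#'
#' @param curve A `melt_result` (or tibble with `temperature_C`,
#'   `emission_norm`).
#' @param smooth Apply the 3-point median smooth (default `TRUE`).
#' @return T1/2 in degC.
#' @export
compute_t_half <- function(curve, smooth = TRUE) {
  stopifnot(all(c("temperature_C", "emission_norm") %in% names(curve)))
  curve <- dplyr::arrange(tibble::as_tibble(curve), .data$temperature_C)
  tt <- curve$temperature_C
  y <- curve$emission_norm
  if (smooth && length(y) >= 3L) y <- stats::runmed(y, 3L)
  if (y[1L] >= 50) {
    # already above 50% at the start: first upward crossing undefined
    abort("Curve starts at or above 50%; transition outside range.",
          class = "g4quant_error")
  }
  below <- y[-length(y)] < 50 & y[-1L] >= 50
  i <- which(below)[1L]
  if (is.na(i)) {
    abort("Curve never crosses 50%; transition outside range.",
          class = "g4quant_error")
  }
  tt[i] + (50 - y[i]) / (y[i + 1L] - y[i]) * (tt[i + 1L] - tt[i])
}

#' Ligand-induced melting-temperature shifts
#'
#' `delta_t_half()` is T1/2(DNA + ligand) - T1/2(DNA alone);
#' `delta_delta_t_half()` is the change of that shift in the presence of a
#' competitor, Delta(with competitor) - Delta(without). Both curves of a
#' pair must come from the same temperature grid and protocol
#' (classical competition vs sequential pre-fold).
#'
#' @param curve_with_ligand,curve_dna_alone Normalized `melt_result` curves.
#' @param ... Passed to [compute_t_half()].
#' @return `delta_t_half()`: one-row tibble of class `melt_comparison` with
#'   `t_half_ligand`, `t_half_alone`, `delta_t_half`, `protocol`.
#' @export
delta_t_half <- function(curve_with_ligand, curve_dna_alone, ...) {
  if (!isTRUE(all.equal(curve_with_ligand$temperature_C,
                        curve_dna_alone$temperature_C))) {
    abort("Curves were measured on different temperature grids.",
          class = "g4quant_error")
  }
  p1 <- attr(curve_with_ligand, "protocol") %||% "classical"
  p2 <- attr(curve_dna_alone, "protocol") %||% "classical"
  if (!identical(p1, p2)) {
    abort(sprintf("Protocol mismatch: '%s' vs '%s'.", p1, p2),
          class = "g4quant_error")
  }
  t1 <- compute_t_half(curve_with_ligand, ...)
  t0 <- compute_t_half(curve_dna_alone, ...)
  out <- tibble::tibble(t_half_ligand = t1, t_half_alone = t0,
                        delta_t_half = t1 - t0, protocol = p1)
  class(out) <- c("melt_comparison", class(out))
  out
}

#' @rdname delta_t_half
#' @param pair_with_competitor,pair_without `melt_comparison` rows from
#'   [delta_t_half()], measured with and without the competitor.
#' @return `delta_delta_t_half()`: one-row tibble with both deltas and
#'   `delta_delta_t_half` (degC).
#' @export
delta_delta_t_half <- function(pair_with_competitor, pair_without) {
  stopifnot(inherits(pair_with_competitor, "melt_comparison"),
            inherits(pair_without, "melt_comparison"))
  tibble::tibble(
    delta_with_competitor = pair_with_competitor$delta_t_half,
    delta_without = pair_without$delta_t_half,
    delta_delta_t_half = pair_with_competitor$delta_t_half -
      pair_without$delta_t_half,
    protocol = pair_with_competitor$protocol
  )
}
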