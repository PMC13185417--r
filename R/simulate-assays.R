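# Four-parameter logistic closed form used by the generators and by fit_4pl.
# direction "descending": response falls from `top` to `bottom` as dose rises.
fourpl <- function(dose, bottom, top, mid, hill,
                   direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  r <- if (direction == "descending") (dose / mid)^hill else (mid / dose)^hill
  bottom + (top - bottom) / (1 + r)
}

mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  pmax(x * (1 + rnorm(length(x), 0, cv)), 0)
}

#' Simulate a dose-response plate table
#'
#' Draws well-level readouts from a four-parameter logistic (4PL) curve with
#' multiplicative Gaussian noise (coefficient of variation `noise_cv`),
#' emulating an SRB viability plate or a fluorescence-quenching titration
#' (classical: ligand titrated against fixed labelled oligonucleotide;
#' reverse: oligonucleotide titrated against fixed ligand). Untreated (NT,
#' dose 0) wells are always included.
#'
#' @param curve_kind `"srb_viability"`, `"fqa_classical"` or `"fqa_reverse"`.
#' @param true_params List with `bottom`, `top`, `mid`, `hill` of the planted
#'   4PL (response scale: percent viability for SRB, fraction of T0
#'   fluorescence for FQA). Missing entries take kind-specific defaults
#'   (SRB: 0/100/hill 1; FQA: 0.15/1/hill 1).
#' @param doses Strictly positive dose vector, at least 5 distinct levels.
#' @param noise_cv Multiplicative noise CV (>= 0).
#' @param replicates Wells per dose.
#' @param n_nt Number of untreated wells.
#' @param dose_unit Unit string carried in the table (`"nM"`, `"uM"`, ...).
#' @param gain SRB only: absorbance of a fully viable well.
#' @param f0 FQA only: mean T0 fluorescence (arbitrary units).
#' @param ligand_conc FQA reverse only: fixed ligand concentration recorded in
#'   a `ligand` column (uM).
#' @param seed Integer seed; fixes all randomness.
#'
#' @return A tibble. SRB: `well, condition, dose, unit, absorbance`.
#'   FQA: `well, condition, dose, unit, F_T0, F_T60` (+ `ligand` in reverse
#'   mode). Attribute `true_params` carries the planted curve.
#' @export
simulate_plate <- function(curve_kind = c("srb_viability", "fqa_classical",
                                          "fqa_reverse"),
                           true_params = list(),
                           doses = 10^seq(-2, 2, length.out = 12),
                           noise_cv = 0, replicates = 3, n_nt = 6,
                           dose_unit = if (curve_kind == "srb_viability") "nM" else "uM",
                           gain = 0.8, f0 = 30000, ligand_conc = 0.2,
                           seed = 1L) {
  curve_kind <- match.arg(curve_kind)
  if (any(doses <= 0) || length(unique(doses)) < 5L) {
    abort("`doses` must be strictly positive with at least 5 distinct levels.",
          class = "g4quant_error")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.", class = "g4quant_error")
  defaults <- if (curve_kind == "srb_viability") {
    list(bottom = 0, top = 100, mid = stats::median(doses), hill = 1)
  } else {
    list(bottom = 0.15, top = 1, mid = stats::median(doses), hill = 1)
  }
  p <- utils::modifyList(defaults, true_params)

  withr::with_seed(seed, {
    dose <- rep(sort(doses), each = replicates)
    resp <- fourpl(dose, p$bottom, p$top, p$mid, p$hill, "descending")
    if (curve_kind == "srb_viability") {
      nt_abs <- mult_noise(rep(gain, n_nt), noise_cv)
      tbl <- tibble::tibble(
        well = sprintf("W%02d", seq_len(n_nt + length(dose))),
        condition = c(rep("NT", n_nt), rep("treated", length(dose))),
        dose = c(rep(0, n_nt), dose),
        unit = dose_unit,
        absorbance = c(nt_abs, mult_noise(gain * resp / 100, noise_cv))
      )
    } else {
      n <- length(dose) + n_nt
      t0 <- mult_noise(rep(f0, n), noise_cv)
      frac <- c(rep(p$top, n_nt), resp)
      tbl <- tibble::tibble(
        well = sprintf("W%02d", seq_len(n)),
        condition = c(rep("NT", n_nt), rep("treated", length(dose))),
        dose = c(rep(0, n_nt), dose),
        unit = dose_unit,
        F_T0 = t0,
        F_T60 = mult_noise(t0 * frac, noise_cv)
      )
      if (curve_kind == "fqa_reverse") tbl$ligand <- ligand_conc
    }
    attr(tbl, "true_params") <- p
    attr(tbl, "curve_kind") <- curve_kind
    tbl
  })
}

#' Simulate a FRET-melting table
#'
#' Emits a FAM-emission melting curve on a stepwise heating ramp (default
#' 25-90 degC in 1 degC steps): a logistic rise centred at `t_half_true` with
#' width `slope` (degC), plus additive Gaussian noise per point.
#'
#' @param t_half_true Planted half-transition temperature (degC); must lie
#'   inside the temperature range.
#' @param slope Logistic width (degC); smaller is steeper. As `slope` tends
#'   to 0 the curve tends to a step at `t_half_true`.
#' @param temperatures Heating-ramp temperatures (degC).
#' @param noise_sd Additive noise SD, on the emission scale (`top - bottom`
#'   is 1 by default, so 0.01 is 1% of the range).
#' @param bottom,top Raw emission levels before and after the transition.
#' @param n_series Number of replicate series.
#' @param protocol Protocol tag carried into downstream comparisons
#'   (`"classical"` or `"sequential"` pre-fold competition).
#' @param seed Integer seed.
#'
#' @return Tibble `series, ramp, protocol, temperature_C, emission`.
#' @export
simulate_melt <- function(t_half_true, slope = 2,
                          temperatures = seq(25, 90, by = 1),
                          noise_sd = 0, bottom = 0, top = 1, n_series = 1,
                          protocol = c("classical", "sequential"),
                          seed = 1L) {
  protocol <- match.arg(protocol)
  if (t_half_true < min(temperatures) || t_half_true > max(temperatures)) {
    abort("`t_half_true` must lie inside the temperature range.",
          class = "g4quant_error")
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_series), function(s) {
      mu <- bottom + (top - bottom) * plogis((temperatures - t_half_true) / slope)
      tibble::tibble(
        series = s, ramp = "heating", protocol = protocol,
        temperature_C = temperatures,
        emission = mu + if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0
      )
    })
  })
}

#' Simulate a drug-pair viability matrix with a planted Bliss excess
#'
#' Builds a full dose grid (including the zero-dose monotherapy margins),
#' computes each agent's inhibition from its own 4PL curve, sets the
#' combination inhibition to the Bliss-independence expectation plus
#' `planted_excess` percentage points (clipped to `[0, 1]` before noise), and
#' converts to percent viability with multiplicative noise per replicate.
#'
#' Default dose grids mirror a combination screen of a G4 ligand
#' (0.04-40 nM) against a PARP inhibitor (0.78-50 uM); default midpoints are
#' those ligands' measured IC50s (3.3 nM, 51.9 uM). With those defaults the
#' highest-dose pairs approach full inhibition, where a positive planted
#' excess is necessarily clipped; choose midpoints near the top of the grids
#' for an unclipped recovery study.
#'
#' @param params_a,params_b Lists `list(ic50 = , hill = 1)` for drugs A and B.
#' @param planted_excess Percentage points added to the Bliss expectation of
#'   every combination cell; in `[-100, 100]`.
#' @param doses_a,doses_b Positive dose grids (zero margins are added).
#' @param unit_a,unit_b Dose unit strings.
#' @param noise_cv Multiplicative viability noise CV.
#' @param replicates Replicates per dose pair.
#' @param seed Integer seed.
#'
#' @return Long tibble `dose_a, unit_a, dose_b, unit_b, replicate,
#'   viability_pct` with attribute `planted_excess`.
#' @export
simulate_synergy_matrix <- function(params_a = list(ic50 = 3.3, hill = 1),
                                    params_b = list(ic50 = 51.9, hill = 1),
                                    planted_excess = 0,
                                    doses_a = c(0.04, 0.16, 0.31, 1.25, 5, 10, 20, 40),
                                    doses_b = c(0.78, 1.56, 3.12, 6.25, 12.5, 25, 50),
                                    unit_a = "nM", unit_b = "uM",
                                    noise_cv = 0, replicates = 3, seed = 1L) {
  if (planted_excess < -100 || planted_excess > 100) {
    abort("`planted_excess` must be in [-100, 100].", class = "g4quant_error")
  }
  if (any(doses_a <= 0) || any(doses_b <= 0)) {
    abort("Dose grids must be strictly positive; zero margins are added automatically.",
          class = "g4quant_error")
  }
  inh <- function(d, p) {
    ifelse(d == 0, 0, 1 - fourpl(d, 0, 1, p$ic50, p$hill %||% 1, "descending"))
  }
  grid <- tidyr::expand_grid(
    dose_a = c(0, sort(unique(doses_a))),
    dose_b = c(0, sort(unique(doses_b))),
    replicate = seq_len(replicates)
  )
  withr::with_seed(seed, {
    fa <- inh(grid$dose_a, params_a)
    fb <- inh(grid$dose_b, params_b)
    combo <- bliss_expected(fa, fb)
    combo <- ifelse(grid$dose_a > 0 & grid$dose_b > 0,
                    pmin(pmax(combo + planted_excess / 100, 0), 1), combo)
    out <- tibble::tibble(
      dose_a = grid$dose_a, unit_a = unit_a,
      dose_b = grid$dose_b, unit_b = unit_b,
      replicate = grid$replicate,
      viability_pct = mult_noise(100 * (1 - combo), noise_cv)
    )
    attr(out, "planted_excess") <- planted_excess
    out
  })
}
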