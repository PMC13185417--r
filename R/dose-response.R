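#' Normalize SRB absorbance to percent viability
#'
#' Viability is 100 x absorbance / mean absorbance of the untreated (NT)
#' wells, so the NT mean is 100% by construction.
#'
#' @param plate Tibble with columns `condition`, `dose` and `absorbance`
#'   (one reduced value per well, e.g. the 490-540 nm mean).
#' @param nt_label Label of the untreated condition.
#' @return The tibble with a `viability` column (percent).
#' @export
normalize_viability <- function(plate, nt_label = "NT") {
  stopifnot(is.data.frame(plate), "absorbance" %in% names(plate))
  nt <- plate$absorbance[plate$condition == nt_label | plate$dose == 0]
  if (length(nt) < 2L) {
    abort("At least 2 NT wells are required for normalization.",
          class = "g4quant_error")
  }
  m <- mean(nt)
  if (m <= 0) {
    abort("NT mean absorbance must be positive.", class = "g4quant_error")
  }
  dplyr::mutate(plate, viability = 100 * .data$absorbance / m)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `response = bottom + (top - bottom) / (1 +
#' (dose/mid)^hill)` (descending; the ascending form swaps `dose/mid` for
#' `mid/dose`), with the midpoint fitted on the log10-dose scale. The fitted
#' midpoint is the relative IC50 in viability mode or the apparent KD in
#' binding mode. Starting values take `bottom`/`top` from the response
#' extremes, the midpoint from the dose whose mean response is nearest
#' half-range and a Hill slope of 1; bounds are one decade beyond the dose
#' range for the midpoint and 0.1 to 10 for the Hill slope.
#'
#' @param data Data frame with dose and response columns.
#' @param dose,response Column names (tidy-eval) of the positive doses and
#'   the responses.
#' @param direction `"descending"` (viability, quenching) or `"ascending"`.
#' @param mode `"ic50"` or `"kd"`: how the midpoint is reported.
#' @param unit Concentration unit carried into the result.
#' @return Object of class `dr_fit`: coefficients with standard errors
#'   (tibble, via [tidy()]), `mid`, `hill_slope`, `top`, `bottom`,
#'   `converged`, `n_points`, and the underlying data. Non-convergence is a
#'   warning, not an error, and is flagged in the result.
#' @export
fit_4pl <- function(data, dose = dose, response = response,
                    direction = c("descending", "ascending"),
                    mode = c("ic50", "kd"), unit = NA_character_) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  d <- dplyr::pull(data, {{ dose }})
  y <- dplyr::pull(data, {{ response }})
  keep <- d > 0 & is.finite(y)
  d <- d[keep]; y <- y[keep]
  if (length(unique(d)) < 5L) {
    abort("A 4PL fit needs at least 5 distinct positive doses.",
          class = "g4quant_error")
  }
  if (diff(range(y)) == 0) {
    abort("All responses are equal: no dose dependence to fit.",
          class = "g4quant_error")
  }
  ld <- log10(d)
  # start: extremes for the asymptotes, half-range dose for the midpoint
  half <- (max(y) + min(y)) / 2
  dose_means <- tapply(y, ld, mean)
  start_logmid <- as.numeric(names(dose_means))[
    which.min(abs(dose_means - half))]
  lower <- c(bottom = -Inf, top = -Inf, logmid = min(ld) - 1, hill = 0.1)
  upper <- c(bottom = Inf, top = Inf, logmid = max(ld) + 1, hill = 10)
  sgn <- if (direction == "descending") 1 else -1
  # steep or edge-midpoint curves can make the Jacobian singular at one
  # start; sweep a small grid of Hill/midpoint starts until one converges
  starts <- expand.grid(hill = c(1, 2, 0.5, 5),
                        logmid = unique(c(start_logmid, stats::median(ld))))
  fit <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(sgn * hill * (ld - logmid))),
        start = list(bottom = min(y), top = max(y),
                     logmid = starts$logmid[s], hill = starts$hill[s]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) e
    )
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    abort(sprintf("4PL fit failed: %s", conditionMessage(fit)),
          class = "g4quant_fit_error")
  }
  converged <- isTRUE(fit$convInfo$isConv)
  if (!converged) {
    warn("4PL fit did not converge; parameters of the best iterate returned.")
  }
  cf <- summary(fit)$coefficients
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  mid <- 10^est[["logmid"]]
  mid_se <- mid * log(10) * se[["logmid"]]
  coefs <- tibble::tibble(
    term = c("bottom", "top", "mid", "hill"),
    estimate = c(est[["bottom"]], est[["top"]], mid, est[["hill"]]),
    std.error = c(se[["bottom"]], se[["top"]], mid_se, se[["hill"]])
  )
  structure(
    list(
      coefficients = coefs,
      mid = mid,
      hill_slope = if (direction == "descending") -est[["hill"]] else est[["hill"]],
      top = max(est[["top"]], est[["bottom"]]),
      bottom = min(est[["top"]], est[["bottom"]]),
      direction = direction, mode = mode, unit = unit,
      converged = converged,
      n_points = length(y), n_doses = length(unique(d)),
      sigma = summary(fit)$sigma,
      data = tibble::tibble(dose = d, response = y),
      fit = fit
    ),
    class = "dr_fit"
  )
}

#' @export
print.dr_fit <- function(x, ...) {
  label <- if (x$mode == "ic50") "IC50" else "appKD"
  cat(sprintf(
    "<dr_fit> 4PL (%s): %s = %.4g %s, hill = %.3g, top = %.4g, bottom = %.4g%s\n",
    x$direction, label, x$mid, ifelse(is.na(x$unit), "", x$unit),
    x$hill_slope, x$top, x$bottom,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dr_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.dr_fit <- function(x, ...) {
  tibble::tibble(
    mid = x$mid, hill_slope = x$hill_slope, top = x$top, bottom = x$bottom,
    mode = x$mode, unit = x$unit, converged = x$converged,
    sigma = x$sigma, n_points = x$n_points, n_doses = x$n_doses
  )
}

#' Fit a fluorescence-quenching titration
#'
#' The per-well response is the fraction of the pre-incubation fluorescence
#' remaining after 60 min, `F_T60 / F_T0` (self-referenced per well, so
#' well-to-well loading differences cancel). The 4PL midpoint of that
#' response against the titrated concentration is reported as the apparent
#' dissociation constant. In classical mode the ligand is titrated against a
#' fixed labelled oligonucleotide; in reverse mode (for intrinsically
#' fluorescent ligands) the labelled oligonucleotide is titrated against a
#' fixed ligand and the table must carry the fixed `ligand` concentration.
#'
#' @param titration Tibble with `dose`, `F_T0`, `F_T60` (+ `ligand` in
#'   reverse mode). Zero-dose rows are ignored by the fit.
#' @param mode `"classical"` or `"reverse"`.
#' @param direction Passed to [fit_4pl()] (default `"descending"`:
#'   fluorescence quenched with increasing titrant).
#' @param unit Concentration unit.
#' @return A `dr_fit` with `mode = "kd"`.
#' @export
fit_fqa <- function(titration, mode = c("classical", "reverse"),
                    direction = "descending", unit = "uM") {
  mode <- match.arg(mode)
  need <- c("dose", "F_T0", "F_T60")
  if (mode == "reverse") need <- c(need, "ligand")
  missing_cols <- setdiff(need, names(titration))
  if (length(missing_cols)) {
    abort(sprintf("FQA table (%s mode) is missing column(s): %s.",
                  mode, paste(missing_cols, collapse = ", ")),
          class = "g4quant_schema_error")
  }
  if (any(titration$F_T0 <= 0)) {
    abort("F_T0 must be positive in every well.", class = "g4quant_error")
  }
  titration <- dplyr::mutate(titration,
                             fraction_remaining = .data$F_T60 / .data$F_T0)
  fit_4pl(dplyr::filter(titration, .data$dose > 0),
          dose = dose, response = fraction_remaining,
          direction = direction, mode = "kd", unit = unit)
}
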