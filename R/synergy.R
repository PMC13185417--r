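#' Bliss-independence expected combined inhibition
#'
#' Under Bliss independence two agents act as independent events, so the
#' expected combined inhibition of fractions `fa` and `fb` is
#' `fa + fb - fa * fb`.
#'
#' @param fa,fb Inhibition fractions in `[0, 1]` (vectorized; values within
#'   1e-9 of the bounds are clipped).
#' @return Expected combined inhibition fraction(s).
#' @export
bliss_expected <- function(fa, fb) {
  tol <- 1e-9
  clip <- function(f, name) {
    if (any(f < -tol | f > 1 + tol, na.rm = TRUE)) {
      abort(sprintf("`%s` must be an inhibition fraction in [0, 1].", name),
            class = "g4quant_error")
    }
    pmin(pmax(f, 0), 1)
  }
  fa <- clip(fa, "fa")
  fb <- clip(fb, "fb")
  fa + fb - fa * fb
}

#' Score a drug-pair viability matrix against Bliss independence
#'
#' Replicates are averaged per dose pair, viability is clipped to
#' `[0, 100]`%, and each combination cell is scored as
#' `100 x (observed inhibition - Bliss expectation from the monotherapy
#' margins)` -- percentage points of excess kill over independence. Pairs
#' scoring above `threshold` (default 10) are flagged synergistic. The
#' matrix mean averages combination cells only; the zero-dose margins define
#' the null and are excluded.
#'
#' @param matrix_long Long tibble `dose_a, dose_b, viability_pct` with
#'   optional `replicate`, `unit_a`, `unit_b`; must contain both zero-dose
#'   margins (monotherapies).
#' @param threshold Synergy call threshold in score points.
#' @return Object of class `synergy_matrix`: list with `scores` (tibble of
#'   combination cells: doses, mean viability, observed and expected
#'   inhibition, `score`, `synergistic`), `monotherapy_a`, `monotherapy_b`,
#'   `mean_score`, `n_synergistic`, `n_clipped`, `replicates`, `threshold`.
#' @export
bliss_score_matrix <- function(matrix_long, threshold = 10) {
  need <- c("dose_a", "dose_b", "viability_pct")
  if (!all(need %in% names(matrix_long))) {
    abort(sprintf("Matrix table must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "g4quant_schema_error")
  }
  if (!any(matrix_long$dose_a == 0) || !any(matrix_long$dose_b == 0)) {
    abort("Monotherapy margins (dose 0 rows for both drugs) are required.",
          class = "g4quant_error")
  }
  n_rep <- if ("replicate" %in% names(matrix_long)) {
    dplyr::n_distinct(matrix_long$replicate)
  } else 1L
  n_clipped <- sum(matrix_long$viability_pct < 0 |
                     matrix_long$viability_pct > 100)
  cells <- matrix_long |>
    dplyr::group_by(.data$dose_a, .data$dose_b) |>
    dplyr::summarise(viability = mean(.data$viability_pct), .groups = "drop") |>
    dplyr::mutate(viability = pmin(pmax(.data$viability, 0), 100),
                  inhibition = 1 - .data$viability / 100)
  mono_a <- cells |>
    dplyr::filter(.data$dose_b == 0, .data$dose_a > 0) |>
    dplyr::select("dose_a", fa = "inhibition")
  mono_b <- cells |>
    dplyr::filter(.data$dose_a == 0, .data$dose_b > 0) |>
    dplyr::select("dose_b", fb = "inhibition")
  combo <- cells |>
    dplyr::filter(.data$dose_a > 0, .data$dose_b > 0) |>
    dplyr::inner_join(mono_a, by = "dose_a") |>
    dplyr::inner_join(mono_b, by = "dose_b")
  if (nrow(combo) == 0L) {
    abort("No combination cells found.", class = "g4quant_error")
  }
  scores <- combo |>
    dplyr::mutate(
      expected = bliss_expected(.data$fa, .data$fb),
      score = 100 * (.data$inhibition - .data$expected),
      synergistic = .data$score > threshold
    ) |>
    dplyr::arrange(.data$dose_a, .data$dose_b)
  structure(
    list(
      scores = scores,
      monotherapy_a = mono_a, monotherapy_b = mono_b,
      mean_score = mean(scores$score),
      n_synergistic = sum(scores$synergistic),
      n_clipped = n_clipped,
      replicates = n_rep,
      threshold = threshold
    ),
    class = "synergy_matrix"
  )
}

#' @export
print.synergy_matrix <- function(x, ...) {
  cat(sprintf(
    "<synergy_matrix> %d combination cells (%d replicates): mean score %.2f, %d pairs > %g\n",
    nrow(x$scores), x$replicates, x$mean_score, x$n_synergistic, x$threshold))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.synergy_matrix <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.synergy_matrix <- function(x, ...) {
  tibble::tibble(
    mean_score = x$mean_score,
    n_pairs = nrow(x$scores),
    n_synergistic = x$n_synergistic,
    n_over_20 = sum(x$scores$score > 20),
    best_score = max(x$scores$score),
    n_clipped = x$n_clipped,
    replicates = x$replicates,
    threshold = x$threshold
  )
}

#' Additional lethality of a viability value
#'
#' Percentage points of killing relative to the untreated condition:
#' `100 - viability`, floored at 0 (stimulated wells count as 0 additional
#' lethality; the number of floored values is reported as an attribute).
#'
#' @param viability_pct Percent viability (vector or column).
#' @return Additional lethality in percentage points, same shape.
#' @export
additional_lethality <- function(viability_pct) {
  stopifnot(is.numeric(viability_pct), all(is.finite(viability_pct)))
  out <- pmax(100 - viability_pct, 0)
  attr(out, "n_clipped") <- sum(viability_pct > 100)
  out
}

#' Compare a combination's foci increase with the additive expectation
#'
#' For NT-corrected mean foci-per-nucleus deltas of two single agents and
#' their combination, the theoretical additive effect is `delta_a + delta_b`
#' and the fold beyond additive is `delta_combo / (delta_a + delta_b)`; a
#' fold of 1 is purely additive, above 1 indicates synergy between the two
#' drugs' activities. Undefined (returned as `NA` with a warning) when the
#' additive expectation is not positive.
#'
#' @param delta_combo,delta_a,delta_b NT-corrected mean foci/nucleus deltas.
#' @return One-row tibble: the three deltas, `additive_expectation`,
#'   `fold_beyond_additive`, `classification` (`"beyond additive"`,
#'   `"additive or less"` or `NA`).
#' @export
foci_additive_comparison <- function(delta_combo, delta_a, delta_b) {
  additive <- delta_a + delta_b
  if (additive <= 0) {
    warn("Additive expectation is not positive; fold beyond additive is undefined.")
    fold <- NA_real_
    cls <- NA_character_
  } else {
    fold <- delta_combo / additive
    cls <- if (fold > 1) "beyond additive" else "additive or less"
  }
  tibble::tibble(
    delta_a = delta_a, delta_b = delta_b, delta_combo = delta_combo,
    additive_expectation = additive,
    fold_beyond_additive = fold,
    classification = cls
  )
}

#' Write a synergy report
#'
#' Writes the scored matrix as a wide CSV heatmap table (rows = drug A
#' doses, columns = drug B doses) and a JSON summary with the matrix mean,
#' synergistic-pair counts, the best pair and a provenance block. Output is
#' deterministic: regenerating from the same inputs yields byte-identical
#' files.
#'
#' @param mat A [bliss_score_matrix()] result.
#' @param foci Optional [foci_additive_comparison()] row to embed.
#' @param out_dir Output directory (created if needed).
#' @param provenance Named list (seeds, parameters) recorded verbatim.
#' @return Invisibly, the paths written.
#' @export
synergy_report <- function(mat, foci = NULL, out_dir,
                           provenance = list()) {
  stopifnot(inherits(mat, "synergy_matrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wide <- mat$scores |>
    dplyr::select("dose_a", "dose_b", "score") |>
    tidyr::pivot_wider(names_from = "dose_b", values_from = "score",
                       names_prefix = "dose_b_")
  csv_path <- file.path(out_dir, "bliss_scores.csv")
  readr::write_csv(wide, csv_path)
  best <- mat$scores[which.max(mat$scores$score), ]
  summary <- list(
    best_pair = list(dose_a = best$dose_a, dose_b = best$dose_b,
                     score = best$score),
    foci_comparison = if (!is.null(foci)) as.list(foci),
    mean_score = mat$mean_score,
    n_clipped_wells = mat$n_clipped,
    n_pairs = nrow(mat$scores),
    n_score_over_10 = sum(mat$scores$score > 10),
    n_score_over_20 = sum(mat$scores$score > 20),
    provenance = provenance,
    replicates = mat$replicates,
    threshold = mat$threshold
  )
  summary <- summary[order(names(summary))]
  json_path <- file.path(out_dir, "synergy_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(csv = csv_path, json = json_path))
}
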