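#' Run the full synthetic demonstration study
#'
#' Mirrors the design of the imaging study: a two-ligand x with/without
#' modulator arm structure over several independent experiments, with planted
#' nuclear-foci fold changes per condition. For each experiment the untreated
#' (NT) cells are generated first and the foci-segmentation threshold is
#' frozen from their cell-free regions (background mean + 3 SD); every
#' condition of that experiment is then quantified with those frozen
#' parameters. Cells are QC-flagged, condition summaries (per-experiment
#' means, then across-experiment mean, SD, fold change and NT-corrected
#' delta) are computed, and a synthetic drug-pair viability matrix is scored
#' against Bliss independence.
#'
#' @param seed Integer; fixes all randomness end to end.
#' @param n_experiments Independent experiments (default 3).
#' @param cells_per_condition Cells per condition per experiment (default 30).
#' @param conditions Named numeric vector of planted nuclear-foci fold
#'   changes; must include `NT = 1`.
#' @param base_config [sim_config()] template; per-cell seed and fold change
#'   are filled in per condition.
#' @param synergy_excess Planted Bliss excess (percentage points) of the demo
#'   synergy matrix.
#' @param synergy_noise_cv Viability noise CV of the demo synergy matrix.
#' @param out_dir Optional directory: results are written via
#'   [write_outputs()].
#' @return List of class `g4_demo`: `cells` (per-cell tibble), `summaries`
#'   (nuclear + cytoplasmic condition summaries), `synergy`
#'   (a [bliss_score_matrix()] result), `params` (frozen per-experiment
#'   segmentation parameters), `planted` (the condition folds), `seed`.
#' @export
run_demo <- function(seed = 1L,
                     n_experiments = 3L,
                     cells_per_condition = 30L,
                     conditions = c(NT = 1, PhpC = 1.5, PDS = 3.8,
                                    `QN-302` = 4.5, `PDS+PhpC` = 1.5,
                                    `QN-302+PhpC` = 1.5),
                     base_config = sim_config(),
                     synergy_excess = 15,
                     synergy_noise_cv = 0.05,
                     out_dir = NULL) {
  if (!"NT" %in% names(conditions) || conditions[["NT"]] != 1) {
    abort("`conditions` must include NT = 1.", class = "g4quant_error")
  }
  seed <- as.integer(seed)
  # NT must be generated first within each experiment: its fields freeze the
  # segmentation threshold and its seeds are the first block
  cond_names <- c("NT", setdiff(names(conditions), "NT"))
  n_cells_total <- n_experiments * length(conditions) * cells_per_condition
  cells <- withr::with_seed(seed, {
    cell_seeds <- matrix(
      sample.int(.Machine$integer.max - 1L, n_cells_total),
      nrow = n_experiments
    )
    rows <- list()
    params_by_exp <- list()
    k <- 0L
    for (e in seq_len(n_experiments)) {
      exp_id <- sprintf("exp%d", e)
      offset <- 0L
      # NT first: the experiment's threshold is frozen from these fields
      nt_sims <- purrr::map(seq_len(cells_per_condition), function(i) {
        cfg <- base_config
        cfg$fold_change <- 1
        cfg$seed <- cell_seeds[e, offset + i]
        simulate_cell_stack(cfg)
      })
      params <- estimate_foci_params(
        purrr::map(nt_sims, ~ .x$stack),
        purrr::map(nt_sims, ~ !.x$truth$cell_mask),
        k = 3, connectivity = 26, experiment_id = exp_id
      )
      params_by_exp[[exp_id]] <- params
      for (cond in cond_names) {
        sims <- if (cond == "NT") nt_sims else {
          purrr::map(seq_len(cells_per_condition), function(i) {
            cfg <- base_config
            cfg$fold_change <- conditions[[cond]]
            cfg$seed <- cell_seeds[e, offset + i]
            simulate_cell_stack(cfg)
          })
        }
        offset <- offset + cells_per_condition
        quants <- purrr::map(sims, function(s) {
          cq <- quantify_cell(s$stack, s$roi, params, mode = "tasq",
                              experiment_id = exp_id)
          dplyr::mutate(tibble::as_tibble(cq), condition = cond,
                        experiment = exp_id, .before = 1L)
        })
        k <- k + 1L
        rows[[k]] <- dplyr::bind_rows(quants)
      }
    }
    attr(rows, "params") <- params_by_exp
    rows
  })
  params_by_exp <- attr(cells, "params")
  cell_tbl <- flag_outliers(dplyr::bind_rows(cells))
  summaries <- dplyr::bind_rows(
    summarize_condition(cell_tbl, metric = "nuclear"),
    summarize_condition(cell_tbl, metric = "cytoplasmic")
  )
  syn_tbl <- simulate_synergy_matrix(
    planted_excess = synergy_excess, noise_cv = synergy_noise_cv,
    replicates = 3, seed = seed + 1L
  )
  synergy <- bliss_score_matrix(syn_tbl)
  out <- structure(
    list(cells = cell_tbl, summaries = summaries, synergy = synergy,
         params = params_by_exp, planted = conditions, seed = seed),
    class = "g4_demo"
  )
  if (!is.null(out_dir)) {
    write_outputs(
      list(cells = cell_tbl,
           condition_summaries = summaries,
           bliss_scores = synergy$scores),
      out_dir,
      parameters = list(seed = seed, n_experiments = n_experiments,
                        cells_per_condition = cells_per_condition,
                        conditions = as.list(conditions),
                        synergy_excess = synergy_excess,
                        synergy_noise_cv = synergy_noise_cv)
    )
    synergy_report(synergy, out_dir = file.path(out_dir, "synergy"),
                   provenance = list(seed = seed + 1L,
                                     planted_excess = synergy_excess))
  }
  out
}

#' @export
print.g4_demo <- function(x, ...) {
  cat(sprintf("<g4_demo> seed %d: %d cells, %d conditions\n",
              x$seed, nrow(x$cells), length(x$planted)))
  print(dplyr::filter(x$summaries, .data$metric == "nuclear"))
  invisible(x)
}

#' Validate a run configuration file
#'
#' Reads a YAML (or JSON) run configuration, checks its schema -- known keys
#' only, a valid mode, integer seed, recognized concentration units -- and
#' enforces the frozen-parameters rule: a segmentation-parameter id may not
#' be shared across experiments unless `allow_shared_params` is set.
#'
#' @param path Path to a YAML/JSON file, or an equivalent named list.
#' @return The validated configuration (class `run_config`).
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) {
    abort("Configuration must parse to a named list.",
          class = "g4quant_config_error")
  }
  allowed <- c("mode", "seed", "input_dir", "output_dir", "experiments",
               "conditions", "units", "segmentation_params",
               "allow_shared_params", "n_experiments", "cells_per_condition",
               "synergy_excess", "synergy_noise_cv")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "g4quant_config_error")
  }
  modes <- c("tasq", "gh2ax", "srb", "fqa", "melt", "synergy", "demo")
  if (is.null(cfg$mode) || !cfg$mode %in% modes) {
    abort(sprintf("`mode` must be one of: %s.", paste(modes, collapse = ", ")),
          class = "g4quant_config_error")
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) ||
      cfg$seed != as.integer(cfg$seed)) {
    abort("`seed` must be an integer.", class = "g4quant_config_error")
  }
  ok_units <- c("nM", "uM", "µM", "mM", "M", "°C", "C", "%")
  if (!is.null(cfg$units)) {
    bad <- setdiff(unlist(cfg$units), ok_units)
    if (length(bad)) {
      abort(sprintf("Unrecognized unit(s): %s.", paste(bad, collapse = ", ")),
            class = "g4quant_config_error")
    }
  }
  for (p in c("input_dir")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      abort(sprintf("Referenced path does not exist: %s", cfg[[p]]),
            class = "g4quant_config_error")
    }
  }
  if (!is.null(cfg$segmentation_params) && !isTRUE(cfg$allow_shared_params)) {
    ids <- unlist(cfg$segmentation_params, use.names = FALSE)
    if (anyDuplicated(ids)) {
      abort(
        "The same segmentation-params id is used in more than one experiment; parameters are frozen per experiment (set allow_shared_params to override knowingly).",
        class = "g4quant_config_error")
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write result tables with a run manifest
#'
#' Writes each result data frame as CSV (atomically: to a temporary file in
#' the target directory, then renamed) and a `manifest.json` recording the
#' package version, parameter snapshot, SHA-like MD5 hashes of any input
#' files, per-table row counts and hashes, warnings, and timings. Re-running
#' with identical inputs reproduces identical result files (the manifest's
#' `timings` field is the only part that may differ).
#'
#' @param results Named list of data frames (empty frames are written with
#'   headers only).
#' @param out_dir Output directory.
#' @param parameters Named list snapshot of run parameters.
#' @param input_paths Character vector of input files to hash.
#' @param warnings Character vector of warnings to record.
#' @return Invisibly, the manifest as a list.
#' @export
write_outputs <- function(results, out_dir, parameters = list(),
                          input_paths = character(), warnings = character()) {
  stopifnot(is.list(results), all(nzchar(names(results))))
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Cannot create output directory '%s'.", out_dir),
          class = "g4quant_error")
  }
  tables <- list()
  for (nm in names(results)) {
    df <- results[[nm]]
    stopifnot(is.data.frame(df))
    path <- file.path(out_dir, paste0(nm, ".csv"))
    tmp <- tempfile(tmpdir = out_dir, fileext = ".csv")
    readr::write_csv(df, tmp)
    file.rename(tmp, path)
    tables[[nm]] <- list(rows = nrow(df),
                         md5 = unname(tools::md5sum(path)))
  }
  manifest <- list(
    package = "g4quant",
    version = as.character(packageVersion("g4quant")),
    parameters = parameters,
    inputs = if (length(input_paths)) {
      lapply(stats::setNames(input_paths, input_paths),
             function(p) unname(tools::md5sum(p)))
    } else list(),
    tables = tables,
    warnings = as.list(warnings),
    timings = list(elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  )
  tmp <- tempfile(tmpdir = out_dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
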