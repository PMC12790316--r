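#' End-to-end screening pipeline
#'
#' Orchestrates the two-round screening workflow: SMILES parsing and
#' pattern checks, conformer search, round-1 properties at the screening
#' level, the HOMO-energy filter, round-2 properties at the affinity level
#' for survivors only, descriptor extraction, and MLR prediction. The
#' two-round economy is structural: the affinity-level backend is invoked
#' exclusively for filter survivors. Failures are sandboxed per
#' nucleophile — one bad structure never aborts the batch.
#'
#' @name co2screen-pipeline
#' @keywords internal
NULL

#' Assemble a validated pipeline configuration
#'
#' @param input path to the SMILES input file.
#' @param backend a `qm_backend` (default [mock_backend()]).
#' @param model an `mlr_model`, or NULL to train from `training_table`.
#' @param training_table descriptor table (data.frame or CSV path) with a
#'   `co2a` response, used when `model` is NULL.
#' @param model_features feature columns used when training (default the
#'   three-descriptor Boltzmann set).
#' @param homo_threshold screening threshold, Hartree (default -0.140).
#' @param homo_aggregation which ensemble value feeds the filter: `"lowE"`
#'   (default) or `"boltz"`.
#' @param temperature Kelvin (default 298.15).
#' @param n_confs,energy_window,rmsd_threshold conformer-search settings.
#' @param buried_radius,angular_step steric descriptor settings.
#' @param screening_settings,affinity_settings `qm_settings` presets for
#'   the two rounds.
#' @param seed master seed; all stage seeds derive from it.
#' @param cache_dir optional persistent backend cache directory.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(input, backend = mock_backend(), model = NULL,
                            training_table = NULL,
                            model_features = c("homo_boltz",
                                               "site_dipole_boltz",
                                               "buried_b1_boltz"),
                            homo_threshold = -0.140,
                            homo_aggregation = c("lowE", "boltz"),
                            temperature = 298.15, n_confs = 50,
                            energy_window = 6, rmsd_threshold = 0.25,
                            buried_radius = 5.5, angular_step = 1,
                            screening_settings = qm_preset("screening"),
                            affinity_settings = qm_preset("affinity"),
                            seed = 42, cache_dir = NULL) {
  if (!file.exists(input)) {
    abort_co2(sprintf("input file does not exist: %s", input), "input_error")
  }
  if (is.null(model) && is.null(training_table)) {
    abort_co2("either a model or a training table is required",
              "input_error")
  }
  if (is.character(training_table)) {
    training_table <- read_descriptor_table(training_table)
  }
  stopifnot(is.finite(homo_threshold))
  structure(
    list(input = input, backend = backend, model = model,
         training_table = training_table, model_features = model_features,
         homo_threshold = homo_threshold,
         homo_aggregation = match.arg(homo_aggregation),
         temperature = temperature, n_confs = n_confs,
         energy_window = energy_window, rmsd_threshold = rmsd_threshold,
         buried_radius = buried_radius, angular_step = angular_step,
         screening_settings = screening_settings,
         affinity_settings = affinity_settings,
         seed = seed, cache_dir = cache_dir),
    class = "pipeline_config")
}

config_hash <- function(config) {
  rlang::hash(list(
    readLines(config$input, warn = FALSE), config$model_features,
    config$homo_threshold, config$homo_aggregation, config$temperature,
    config$n_confs, config$energy_window, config$rmsd_threshold,
    config$buried_radius, config$angular_step,
    unclass(config$screening_settings), unclass(config$affinity_settings),
    config$seed, config$backend$name))
}

#' Run the screening workflow
#'
#' @param config a `pipeline_config`.
#' @return a `screening_report`: `predictions` (one row per pattern-valid
#'   nucleophile, with the screening HOMO energy, filter outcome, predicted
#'   affinity and stability call, plus the descriptor row for survivors),
#'   `rejects`, `summary` counts, and a provenance block.
#' @export
run_screening <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- config$model
  if (is.null(model)) {
    model <- fit_mlr(config$training_table, config$model_features, "co2a")
  }
  parsed <- parse_smiles_input(config$input)
  records <- parsed$records
  rejects <- parsed$rejects
  pred_rows <- list()
  desc_rows <- list()
  for (id in names(records)) {
    rec <- records[[id]]
    row <- tryCatch({
      ens <- embed_ensemble(rec, n_confs = config$n_confs,
                            seed = derive_seed(config$seed,
                                               1000L + match(id, names(records))),
                            energy_window = config$energy_window,
                            rmsd_threshold = config$rmsd_threshold)
      els <- rec$molecule$elements
      ## round 1: screening level on every conformer
      qr1 <- lapply(seq_along(ens$conformers), function(k)
        run_backend(els, ens$conformers[[k]]$coordinates,
                    config$screening_settings, config$backend,
                    label = sprintf("%s_r1_c%d", id, k),
                    cache_dir = config$cache_dir))
      e1 <- vapply(qr1, function(q) q$electronic_energy, numeric(1))
      homos <- vapply(qr1, function(q) q$homo_energy, numeric(1))
      eps <- if (config$homo_aggregation == "lowE") homos[which.min(e1)]
             else sum(boltzmann_weights(e1, config$temperature) * homos)
      if (!homo_filter(eps, config$homo_threshold)) {
        prediction_row(id, eps, NA_real_, config$homo_threshold)
      } else {
        ## round 2: affinity level, survivors only
        qr2 <- lapply(seq_along(ens$conformers), function(k)
          run_backend(els, ens$conformers[[k]]$coordinates,
                      config$affinity_settings, config$backend,
                      label = sprintf("%s_r2_c%d", id, k),
                      cache_dir = config$cache_dir))
        dtab <- build_descriptor_table(
          stats::setNames(list(rec), id), stats::setNames(list(ens), id),
          stats::setNames(list(qr2), id),
          temperature = config$temperature,
          buried_radius = config$buried_radius,
          angular_step = config$angular_step)
        missing <- setdiff(model$feature_names, names(dtab))
        if (length(missing)) {
          abort_co2(sprintf("descriptor table lacks model feature(s): %s",
                            paste(missing, collapse = ", ")),
                    "feature_error")
        }
        desc_rows[[id]] <- dtab
        prediction_row(id, eps, predict(model, dtab), config$homo_threshold)
      }
    }, co2screen_error = function(e) e)
    if (inherits(row, "data.frame")) {
      pred_rows[[id]] <- row
    } else {
      rejects <- rbind(rejects, data.frame(
        id = id, line = NA_integer_, input = rec$smiles,
        reason = reject_reason(row)))
    }
  }
  predictions <- if (length(pred_rows)) do.call(rbind, pred_rows)
                 else data.frame(id = character(), epsilon_homo = numeric(),
                                 passed_homo_filter = logical(),
                                 co2a_pred = numeric(),
                                 stability_call = character())
  rownames(predictions) <- NULL
  descriptors <- if (length(desc_rows)) {
    d <- do.call(rbind, desc_rows); rownames(d) <- NULL; d
  } else NULL
  report <- structure(
    list(predictions = predictions, rejects = rejects,
         descriptors = descriptors,
         summary = list(
           n_input = nrow(predictions) + nrow(rejects),
           n_pattern_valid = nrow(predictions),
           n_passed_filter = sum(predictions$passed_homo_filter),
           n_predicted_stable = sum(predictions$stability_call == "stable"),
           n_rejected = nrow(rejects)),
         provenance = list(
           config_hash = config_hash(config), seed = config$seed,
           backend = config$backend$name,
           model_features = model$feature_names,
           homo_threshold = config$homo_threshold,
           homo_aggregation = config$homo_aggregation,
           package_version = as.character(utils::packageVersion("co2screen"))),
         status = if (nrow(predictions) == 0) "empty" else "ok"),
    class = "screening_report")
  report
}

#' @export
print.screening_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<screening_report: %d input, %d pattern-valid, %d passed filter, %d predicted stable, %d rejected>\n",
    s$n_input, s$n_pattern_valid, s$n_passed_filter, s$n_predicted_stable,
    s$n_rejected))
  invisible(x)
}

#' Render a screening report to files
#'
#' Writes `predictions.csv`, `rejects.csv`, `summary.json`, the plot data
#' layers (`ranking_data.csv`, `descriptor_map_data.csv`, byte-stable), and
#' two vector-graphic figures: a predicted-affinity ranking bar chart and a
#' HOMO-energy versus site-dipole map with marker size encoding the buried
#' B1 and color the predicted affinity.
#'
#' @param report a `screening_report`.
#' @param outdir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
render_report <- function(report, outdir) {
  stopifnot(inherits(report, "screening_report"))
  ok <- tryCatch({dir.create(outdir, recursive = TRUE, showWarnings = FALSE);
                  file.access(outdir, 2) == 0},
                 error = function(e) FALSE)
  if (!ok) abort_co2(sprintf("cannot write to %s", outdir), "io_error")
  paths <- c(pred = file.path(outdir, "predictions.csv"),
             rej = file.path(outdir, "rejects.csv"),
             sum = file.path(outdir, "summary.json"),
             rankdat = file.path(outdir, "ranking_data.csv"),
             mapdat = file.path(outdir, "descriptor_map_data.csv"),
             rank = file.path(outdir, "affinity_ranking.pdf"),
             map = file.path(outdir, "descriptor_map.pdf"))
  utils::write.csv(report$predictions, paths["pred"], row.names = FALSE)
  utils::write.csv(report$rejects, paths["rej"], row.names = FALSE)
  jsonlite::write_json(c(report$summary, report$provenance,
                         list(status = report$status)),
                       paths["sum"], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  ranked <- report$predictions[report$predictions$passed_homo_filter, ,
                               drop = FALSE]
  ranked <- ranked[order(-ranked$co2a_pred), , drop = FALSE]
  utils::write.csv(ranked, paths["rankdat"], row.names = FALSE)
  if (nrow(ranked) > 0) {
    p1 <- ggplot2::ggplot(ranked,
            ggplot2::aes(x = stats::reorder(id, co2a_pred), y = co2a_pred,
                         fill = co2a_pred > 0)) +
      ggplot2::geom_col(show.legend = FALSE) +
      ggplot2::coord_flip() +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "#b2182b")) +
      ggplot2::labs(x = NULL, y = "predicted CO2 affinity (kcal/mol)",
                    title = "Predicted adduct stability ranking") +
      ggplot2::theme_minimal()
    suppressMessages(ggplot2::ggsave(paths["rank"], p1, width = 6,
                                     height = 0.6 + 0.35 * nrow(ranked)))
  }
  if (!is.null(report$descriptors)) {
    mp <- merge(report$descriptors, report$predictions, by = "id")
    utils::write.csv(mp, paths["mapdat"], row.names = FALSE)
    p2 <- ggplot2::ggplot(mp,
            ggplot2::aes(x = homo_boltz, y = site_dipole_boltz,
                         size = buried_b1_boltz, color = co2a_pred)) +
      ggplot2::geom_point(alpha = 0.85) +
      ggplot2::scale_color_gradient2(low = "#b2182b", mid = "grey85",
                                     high = "#2166ac", midpoint = 0,
                                     name = "CO2A (kcal/mol)") +
      ggplot2::scale_size_continuous(name = "buried B1 (A)") +
      ggplot2::labs(x = "HOMO energy, Boltzmann avg (Hartree)",
                    y = "Hirshfeld site dipole, Boltzmann avg (au)",
                    title = "Electronic descriptors; size = steric bulk") +
      ggplot2::theme_minimal()
    suppressMessages(ggplot2::ggsave(paths["map"], p2, width = 7,
                                     height = 5))
  }
  invisible(paths)
}
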