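#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Stage
#' toggles are dependency-checked: a stage cannot be enabled if a stage
#' whose outputs it needs is disabled (unless those inputs are supplied
#' directly via `traces` / `input_dir`).
#'
#' @param preset_file Optional YAML preset file (default: shipped presets).
#' @param n_cells_per_group Cells per group (default 11).
#' @param seed Integer master seed, recorded in every output.
#' @param cv Per-cell lognormal variability (default 0.3).
#' @param interpolation_mode `"as_printed"` or `"endpoint_exact"` for the
#'   tonic prediction.
#' @param out_dir Output directory for CSVs and the manifest; `NULL` keeps
#'   results in memory only.
#' @param stages Character vector of stages to run, a subset of
#'   `c("generate", "fit", "decompose", "predict", "spikes", "summarize")`.
#' @param traces Optional traces tibble (as produced by
#'   [generate_cohort()]`$traces`) used when `"generate"` is toggled off.
#' @param input_dir Optional directory of trace CSV/JSON files used when
#'   `"generate"` is toggled off and `traces` is `NULL`.
#' @param write_traces Also write every generated trace to `out_dir`
#'   (default `FALSE`; trace files are large).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset_file = NULL,
                            n_cells_per_group = 11,
                            seed = 1,
                            cv = 0.3,
                            interpolation_mode = c("as_printed",
                                                   "endpoint_exact"),
                            out_dir = NULL,
                            stages = c("generate", "fit", "decompose",
                                       "predict", "spikes", "summarize"),
                            traces = NULL,
                            input_dir = NULL,
                            write_traces = FALSE) {
  interpolation_mode <- rlang::arg_match(interpolation_mode)
  all_stages <- c("generate", "fit", "decompose", "predict", "spikes",
                  "summarize")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  have_traces <- "generate" %in% stages || !is.null(traces) ||
    !is.null(input_dir)
  deps <- list(fit = "traces", decompose = "traces", spikes = "traces",
               predict = c("fit", "decompose"),
               summarize = "decompose")
  for (st in intersect(names(deps), stages)) {
    for (d in deps[[st]]) {
      ok <- if (d == "traces") have_traces else d %in% stages
      if (!ok) {
        rlang::abort(sprintf("stage '%s' needs '%s', which is not available.",
                             st, d),
                     class = "synaptrain_error_config")
      }
    }
  }
  structure(list(preset_file = preset_file,
                 n_cells_per_group = n_cells_per_group,
                 seed = seed, cv = cv,
                 interpolation_mode = interpolation_mode,
                 out_dir = out_dir, stages = stages, traces = traces,
                 input_dir = input_dir, write_traces = write_traces),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> fit -> decompose -> predict -> spikes ->
#' summarize on a synthetic cohort (or on supplied traces). Produces, per
#' enabled stage:
#'
#' * `fits`: first- and last-IPSC biexponential parameters per cell and
#'   condition;
#' * `decompositions`: per-stimulus phasic/tonic tables, plus per-cell mean
#'   tonic (stimuli 5-10);
#' * `prediction`: measured vs predicted tonic current per stimulus and its
#'   per-group means (the predicted-vs-measured table);
#' * `spiking`: per-cell spontaneous rate, AP half-width, rebound percent
#'   change per condition, and the per-group paired mGluR rebound component;
#' * `summaries`: group mean ± SEM tables, and the per-group mGluR tonic
#'   difference.
#'
#' With `out_dir` set, each table is written as CSV together with a JSON
#' manifest (package version, seed, configuration hash, cell counts); runs
#' with identical configuration and seed produce identical files.
#'
#' @param config A [pipeline_config()].
#' @return A list (the run report) with the elements above, plus `cells`,
#'   `manifest`, and `warnings` (cells rejected by a stage, with reasons).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  report <- list(manifest = NULL, warnings = character())
  note <- function(msg) {
    report$warnings <<- c(report$warnings, msg)
    rlang::inform(msg)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "synaptrain_error_stage", parent = e)
    })
  }

  presets <- group_presets(config$preset_file)

  traces <- NULL
  cells <- NULL
  if ("generate" %in% stages) {
    run_stage("generate", {
      coh <- generate_cohort(presets, config$n_cells_per_group,
                             seed = config$seed, cv = config$cv)
      traces <- coh$traces
      cells <- coh$cells
    })
  } else if (!is.null(config$traces)) {
    traces <- config$traces
  } else if (!is.null(config$input_dir)) {
    run_stage("load", {
      files <- list.files(config$input_dir, pattern = "\\.csv$",
                          full.names = TRUE)
      rows <- purrr::map(files, function(f) {
        tr <- read_trace(f)
        m <- trace_meta(tr)
        tibble::tibble(cell_id = m$cell_id %||% basename(f),
                       group = m$group %||% NA_character_,
                       sex = m$sex %||% NA_character_,
                       genotype = m$genotype %||% NA_character_,
                       condition = m$condition %||% "control",
                       modality = m$modality %||%
                         (if (trace_mode(tr) == "voltage_clamp") "ipsc"
                          else "rebound"),
                       trace = list(tr))
      })
      traces <- dplyr::bind_rows(rows)
    })
  }
  report$cells <- cells

  ipsc <- if (!is.null(traces)) {
    dplyr::filter(traces, .data$modality == "ipsc")
  } else NULL

  if ("fit" %in% stages) {
    run_stage("fit", {
      report$fits <- purrr::pmap_dfr(
        list(ipsc$cell_id, ipsc$condition, ipsc$trace,
             ipsc$group, ipsc$sex, ipsc$genotype),
        function(id, cond, tr, grp, sex, gen) {
          fits <- tryCatch(fit_train_kinetics(tr), error = function(e) {
            note(sprintf("fit: cell %s (%s) rejected: %s", id, cond,
                         conditionMessage(e)))
            NULL
          })
          if (is.null(fits)) return(tibble::tibble())
          purrr::map_dfr(c("first", "last"), function(wh) {
            f <- fits[[wh]]
            dplyr::bind_cols(
              tibble::tibble(cell_id = id, group = grp, sex = sex,
                             genotype = gen, condition = cond, which = wh),
              glance(f),
              tibble::tibble(tau_fast_ms = f$tau_fast_ms,
                             tau_slow_ms = f$tau_slow_ms,
                             frac_fast = f$frac_fast))
          })
        })
    })
  }

  if ("decompose" %in% stages) {
    run_stage("decompose", {
      decomps <- purrr::pmap_dfr(
        list(ipsc$cell_id, ipsc$condition, ipsc$trace,
             ipsc$group, ipsc$sex, ipsc$genotype),
        function(id, cond, tr, grp, sex, gen) {
          d <- tryCatch(measure_train(tr), error = function(e) {
            note(sprintf("decompose: cell %s (%s) rejected: %s", id, cond,
                         conditionMessage(e)))
            NULL
          })
          if (is.null(d)) return(tibble::tibble())
          dplyr::mutate(tibble::as_tibble(d), cell_id = id, group = grp,
                        sex = sex, genotype = gen, condition = cond,
                        .before = 1)
        })
      report$decompositions <- decomps
      report$tonic_5_10 <- decomps |>
        dplyr::group_by(.data$cell_id, .data$group, .data$sex,
                        .data$genotype, .data$condition) |>
        dplyr::summarise(mean_tonic_5_10_pct = mean(.data$tonic_pct[5:10]),
                         .groups = "drop")
    })
  }

  if ("predict" %in% stages) {
    run_stage("predict", {
      ctl <- dplyr::filter(report$decompositions,
                           .data$condition == "control")
      fits <- dplyr::filter(report$fits, .data$condition == "control")
      per_cell <- ctl |>
        dplyr::group_by(.data$cell_id, .data$group, .data$sex,
                        .data$genotype) |>
        dplyr::group_map(function(d, key) {
          ff <- dplyr::filter(fits, .data$cell_id == key$cell_id)
          f1 <- dplyr::filter(ff, .data$which == "first")
          fl <- dplyr::filter(ff, .data$which == "last")
          if (nrow(f1) != 1 || nrow(fl) != 1) {
            note(sprintf("predict: cell %s skipped (missing fits).",
                         key$cell_id))
            return(tibble::tibble())
          }
          pr <- predict_tonic(d$phasic_pct, as.list(f1), as.list(fl),
                              mode = config$interpolation_mode)
          tibble::tibble(cell_id = key$cell_id, group = key$group,
                         sex = key$sex, genotype = key$genotype,
                         stimulus = d$stimulus,
                         tonic_measured_pct = d$tonic_pct,
                         tonic_predicted_pct = pr$tonic_pred)
        }) |>
        dplyr::bind_rows()
      report$prediction <- per_cell
      report$prediction_by_group <- per_cell |>
        dplyr::group_by(.data$group, .data$sex, .data$genotype,
                        .data$stimulus) |>
        dplyr::summarise(
          measured_mean = mean(.data$tonic_measured_pct),
          measured_sem = sem(.data$tonic_measured_pct),
          predicted_mean = mean(.data$tonic_predicted_pct),
          predicted_sem = sem(.data$tonic_predicted_pct),
          n = dplyr::n(), .groups = "drop")
    })
  }

  if ("spikes" %in% stages) {
    run_stage("spikes", {
      spont <- dplyr::filter(traces, .data$modality == "spontaneous")
      spont_tbl <- purrr::pmap_dfr(
        list(spont$cell_id, spont$group, spont$sex, spont$genotype,
             spont$trace),
        function(id, grp, sex, gen, tr) {
          sp <- detect_spikes(tr)
          w <- c(max(min(tr$time_ms), 200), max(tr$time_ms))
          rate <- tryCatch(spontaneous_rate(sp, w), error = function(e) {
            note(sprintf("spikes: cell %s rate rejected: %s", id,
                         conditionMessage(e)))
            NA_real_
          })
          hw <- tryCatch(ap_half_width(tr, sp), error = function(e) {
            note(sprintf("spikes: cell %s half-width rejected: %s", id,
                         conditionMessage(e)))
            NA_real_
          })
          tibble::tibble(cell_id = id, group = grp, sex = sex,
                         genotype = gen, spontaneous_rate_Hz = rate,
                         ap_half_width_ms = hw)
        })
      report$spontaneous <- spont_tbl

      reb <- dplyr::filter(traces, .data$modality == "rebound")
      reb_tbl <- purrr::pmap_dfr(
        list(reb$cell_id, reb$group, reb$sex, reb$genotype, reb$condition,
             reb$trace),
        function(id, grp, sex, gen, cond, tr) {
          r <- tryCatch(rebound_percent_change(tr), error = function(e) {
            note(sprintf("spikes: cell %s (%s) rebound rejected: %s", id,
                         cond, conditionMessage(e)))
            return(NULL)
          })
          if (is.null(r)) return(tibble::tibble())
          dplyr::mutate(r, cell_id = id, group = grp, sex = sex,
                        genotype = gen, condition = cond, .before = 1)
        })
      report$rebound <- reb_tbl
      if (nrow(reb_tbl)) {
        wide <- tidyr::pivot_wider(
          reb_tbl[, c("cell_id", "group", "sex", "genotype", "condition",
                      "percent_change")],
          names_from = "condition", values_from = "percent_change")
        report$rebound_component <- wide |>
          dplyr::filter(!is.na(.data$control) & !is.na(.data$drug)) |>
          dplyr::group_by(.data$group, .data$sex, .data$genotype) |>
          dplyr::group_map(function(d, key) {
            comp <- mglur_rebound_component(d$control, d$drug, d$cell_id)
            dplyr::bind_cols(key, comp[, c("mean_component",
                                           "sem_component", "n")])
          }) |>
          dplyr::bind_rows()
      }
    })
  }

  if ("summarize" %in% stages) {
    run_stage("summarize", {
      summaries <- list()
      if (!is.null(report$fits)) {
        first <- dplyr::filter(report$fits, .data$which == "first")
        summaries$weighted_tau_first <-
          group_summary(first, "weighted_tau_ms")
      }
      if (!is.null(report$tonic_5_10)) {
        summaries$mean_tonic_5_10 <-
          group_summary(report$tonic_5_10, "mean_tonic_5_10_pct")
        summaries$mglur_tonic_difference <- report$tonic_5_10 |>
          dplyr::group_by(.data$group, .data$sex, .data$genotype) |>
          dplyr::group_map(function(d, key) {
            ctl <- d$mean_tonic_5_10_pct[d$condition == "control"]
            drg <- d$mean_tonic_5_10_pct[d$condition == "drug"]
            if (length(ctl) < 2 || length(drg) < 2) return(tibble::tibble())
            dplyr::bind_cols(key, mglur_tonic_difference(ctl, drg))
          }) |>
          dplyr::bind_rows()
      }
      if (!is.null(report$spontaneous)) {
        summaries$spontaneous_rate <-
          group_summary(report$spontaneous, "spontaneous_rate_Hz")
        summaries$ap_half_width <-
          group_summary(report$spontaneous, "ap_half_width_ms")
      }
      report$summaries <- summaries
    })
  }

  report$manifest <- list(
    package = "synaptrain",
    version = as.character(utils::packageVersion("synaptrain")),
    seed = config$seed,
    n_cells_per_group = config$n_cells_per_group,
    cv = config$cv,
    interpolation_mode = config$interpolation_mode,
    stages = stages,
    config_hash = rlang::hash(config[c("preset_file", "n_cells_per_group",
                                       "seed", "cv", "interpolation_mode",
                                       "stages")]),
    n_traces = if (!is.null(traces)) nrow(traces) else 0L,
    n_cells = if (!is.null(cells)) nrow(cells) else NA_integer_
  )

  if (!is.null(config$out_dir)) {
    run_stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(x, name) {
        if (!is.null(x) && nrow(x)) {
          utils::write.csv(as.data.frame(x),
                           file.path(config$out_dir,
                                     paste0(name, ".csv")),
                           row.names = FALSE)
        }
      }
      wr(report$cells, "cells")
      wr(report$fits, "fits")
      wr(report$decompositions, "decompositions")
      wr(report$tonic_5_10, "tonic_5_10")
      wr(report$prediction, "predicted_vs_measured")
      wr(report$prediction_by_group, "predicted_vs_measured_by_group")
      wr(report$spontaneous, "spontaneous_metrics")
      wr(report$rebound, "rebound_metrics")
      wr(report$rebound_component, "rebound_component")
      for (nm in names(report$summaries %||% list())) {
        wr(report$summaries[[nm]], paste0("summary_", nm))
      }
      if (isTRUE(config$write_traces) && !is.null(traces)) {
        tdir <- file.path(config$out_dir, "traces")
        dir.create(tdir, showWarnings = FALSE)
        purrr::pwalk(list(traces$cell_id, traces$condition,
                          traces$modality, traces$trace),
                     function(id, cond, mod, tr) {
                       write_trace(tr, file.path(
                         tdir, sprintf("%s_%s_%s.csv", id, mod, cond)))
                     })
      }
      jsonlite::write_json(report$manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  invisible(report)
}
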