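#' Configure an end-to-end pipeline run
#'
#' Collects every tunable of the discover -> triage -> (COXEN) -> train ->
#' predict -> evaluate pipeline. Defaults mirror the published thresholds:
#' discovery q <= 0.01, COXEN per-probe p < 0.001, 3 principal components,
#' equal LDA priors, Youden-optimal cutoffs.
#'
#' @param train_cell_type Name of the training cell type within the cohort.
#' @param q_threshold Discovery q-value cutoff (inclusive).
#' @param allowed_categories Function categories kept at triage.
#' @param use_coxen Also build a per-test-set COXEN panel.
#' @param coxen_alpha Strict per-probe concordance threshold.
#' @param priors LDA priors (low, high).
#' @param output_dir Optional directory for stage artifacts (TSVs + model
#'   JSONs + report).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(train_cell_type = "monocyte",
                            q_threshold = 0.01,
                            allowed_categories = atherosclerosis_categories(),
                            use_coxen = TRUE,
                            coxen_alpha = 0.001,
                            priors = c(0.5, 0.5),
                            output_dir = NULL) {
  stopifnot(q_threshold > 0, q_threshold <= 1, coxen_alpha > 0, coxen_alpha <= 1)
  structure(list(train_cell_type = train_cell_type, q_threshold = q_threshold,
                 allowed_categories = allowed_categories, use_coxen = use_coxen,
                 coxen_alpha = coxen_alpha, priors = priors,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full atherogenic-risk pipeline on a cohort
#'
#' Executes every stage on an in-memory cohort (from [simulate_cohort()] or
#' [read_cohort()]): per-probe discovery on the training cell type,
#' functional triage to the universal panel, an optional COXEN sub-panel per
#' test cell type, predictor training, posterior scoring of each test set,
#' and ROC/Youden confusion metrics — producing a report with one row per
#' test set and panel. Stage progress (probe counts in/out) is logged via
#' `message()`; when `config$output_dir` is set, per-stage TSV/JSON
#' artifacts are written.
#'
#' @param cohort List with `expression` (named list of [expr_matrix]),
#'   `metadata`, `annotations`.
#' @param config A [pipeline_config()].
#' @return A `pipeline_run` list: `discovery`, `panel`, `predictors`,
#'   `scores`, `report` (tibble: `dataset`, `cell_type`, `panel_source`,
#'   `n_genes`, `t_test_p`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `youden`, `optimal_cutoff`).
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  expr <- cohort$expression
  if (!config$train_cell_type %in% names(expr)) {
    stop("pipeline: training cell type '", config$train_cell_type,
         "' not in cohort", call. = FALSE)
  }
  train <- expr[[config$train_cell_type]]
  tests <- expr[setdiff(names(expr), config$train_cell_type)]
  meta <- cohort$metadata

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  de <- stage("discovery",
              discover_biomarkers(train, meta, q_threshold = config$q_threshold))
  message(sprintf("[discovery] %d probes tested, %d flagged at q <= %g",
                  nrow(de), sum(de$flagged), config$q_threshold))

  panel <- stage("triage",
                 filter_by_function(de, cohort$annotations,
                                    allowed_categories = config$allowed_categories,
                                    training_dataset_id = attr(train, "dataset_id")))
  message(sprintf("[triage] universal panel: %d probes", length(panel)))

  predictors <- list(universal = stage("train",
    train_risk_predictor(train, meta, panel, priors = config$priors)))

  scores <- list()
  report <- list()
  for (ct in names(tests)) {
    test <- tests[[ct]]
    panels_ct <- list(universal = panel)
    if (config$use_coxen) {
      # no concordant probes at the strict threshold is a legitimate outcome
      # for one test set; keep the universal row and move on
      cp <- tryCatch(
        select_coxen_panel(train, test, panel, alpha = config$coxen_alpha),
        error = function(e) {
          if (grepl("no probes", conditionMessage(e))) {
            warning(sprintf("[coxen:%s] %s; COXEN predictor skipped for this set",
                            ct, conditionMessage(e)), call. = FALSE)
            NULL
          } else {
            stop(sprintf("pipeline stage 'coxen:%s': %s", ct,
                         conditionMessage(e)), call. = FALSE)
          }
        })
      if (!is.null(cp) && length(cp) < 3) {
        warning(sprintf("[coxen:%s] only %d concordant probe(s), fewer than the 3 a PCA needs; COXEN predictor skipped for this set",
                        ct, length(cp)), call. = FALSE)
        cp <- NULL
      }
      if (!is.null(cp)) {
        message(sprintf("[coxen:%s] %d of %d probes concordant at p < %g",
                        ct, length(cp), length(panel), config$coxen_alpha))
        panels_ct$coxen <- cp
        key <- paste0("coxen_", ct)
        predictors[[key]] <- stage(paste0("train:", key),
          train_risk_predictor(train, meta, cp, priors = config$priors))
      }
    }
    for (src in names(panels_ct)) {
      fit <- if (src == "universal") predictors$universal else predictors[[paste0("coxen_", ct)]]
      common <- intersect_probes(train, test)
      sc <- stage(paste0("predict:", ct, ":", src), predict(fit, common$b))
      scores[[paste(ct, src, sep = ":")]] <- sc
      tt <- score_group_ttest(sc, meta)
      roc <- roc_with_youden(sc, meta)
      cm <- confusion_at_cutoff(sc, meta, attr(roc, "optimal_cutoff"))
      report[[paste(ct, src, sep = ":")]] <- tibble::tibble(
        dataset = attr(test, "dataset_id"), cell_type = ct, panel_source = src,
        n_genes = length(fit$panel), t_test_p = tt$p_value,
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        ppv = cm$ppv, npv = cm$npv, youden = cm$youden,
        optimal_cutoff = attr(roc, "optimal_cutoff")
      )
    }
  }
  report <- dplyr::bind_rows(report)

  run <- structure(list(discovery = de, panel = panel, predictors = predictors,
                        scores = scores, report = report, config = config),
                   class = "pipeline_run")
  if (!is.null(config$output_dir)) write_run_artifacts(run, cohort, config$output_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> universal panel %d probes; %d evaluation row(s)\n",
              length(x$panel), nrow(x$report)))
  print(format_report(x$report))
  invisible(x)
}

#' Format an evaluation report in the published table style
#'
#' Rates as percentages to one decimal, Youden to two decimals.
#'
#' @param report The `report` tibble of a [run_pipeline()] result.
#' @return A tibble with formatted character columns.
#' @export
format_report <- function(report) {
  pct <- function(v) sprintf("%.1f", 100 * v)
  tibble::tibble(
    dataset = report$dataset, panel = report$panel_source,
    n_genes = report$n_genes,
    t_test_p = signif(report$t_test_p, 2),
    `sensitivity_%` = pct(report$sensitivity),
    `specificity_%` = pct(report$specificity),
    `ppv_%` = pct(report$ppv), `npv_%` = pct(report$npv),
    youden = sprintf("%.2f", report$youden)
  )
}

write_run_artifacts <- function(run, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  de_out <- dplyr::left_join(run$discovery,
                             cohort$annotations[c("probe_id", "gene_symbol")],
                             by = "probe_id")
  wt(de_out[c("probe_id", "gene_symbol", "p_value", "q_value", "fold_change",
              "flagged")], "discovery.tsv")
  wt(data.frame(probe_id = run$panel$probe_ids), "panel_universal.tsv")
  for (key in names(run$predictors)) {
    write_predictor(run$predictors[[key]],
                    file.path(dir, paste0("predictor_", key, ".json")))
  }
  for (key in names(run$scores)) {
    wt(run$scores[[key]], paste0("scores_", gsub(":", "_", key), ".tsv"))
  }
  wt(run$report, "report.tsv")
  manifest <- list(stages = c("discovery", "triage",
                              if (run$config$use_coxen) "coxen",
                              "train", "predict", "evaluate"),
                   q_threshold = run$config$q_threshold,
                   coxen_alpha = run$config$coxen_alpha,
                   panel_sizes = lapply(run$predictors, function(p) length(p$panel)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
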