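#' Pipeline configuration
#'
#' Collects every knob of the analysis workflow in one serializable
#' object. A run's effective config is always written next to its outputs.
#'
#' @param input Path to a dataset bundle directory (see
#'   [write_dataset_bundle()]), or NULL when a dataset object is passed to
#'   [run_pipeline()] directly.
#' @param control_group Control group label (required for fold changes,
#'   saturation and differential statistics).
#' @param case_groups Case group labels to compare against the control;
#'   default: every other group in the data.
#' @param filter A `filter_params` object.
#' @param paired Use the paired test variants, pairing by `replicate_id`.
#' @param aggregate `"none"` or `"experiment"` (tests on per-experiment
#'   means).
#' @param test `"auto"` or a forced test id.
#' @param scale_stats `"percent"` (default; statistics on percent-of-total
#'   values) or `"raw"` (raw concentrations).
#' @param saturation_pools Pools to profile (subset of TG, CE,
#'   phospholipids).
#' @param out_dir Output directory; NULL disables writing.
#' @param seed Seed recorded for provenance (used by `simulate` paths).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, control_group = NULL,
                            case_groups = NULL,
                            filter = filter_params(), paired = FALSE,
                            aggregate = c("none", "experiment"),
                            test = "auto",
                            scale_stats = c("percent", "raw"),
                            saturation_pools = c("TG", "CE",
                                                 "phospholipids"),
                            out_dir = NULL, seed = NULL) {
  aggregate <- match.arg(aggregate)
  scale_stats <- match.arg(scale_stats)
  structure(list(input = input, control_group = control_group,
                 case_groups = case_groups, filter = filter,
                 paired = paired, aggregate = aggregate, test = test,
                 scale_stats = scale_stats,
                 saturation_pools = saturation_pools,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' validate -> blank filter -> class quantification -> saturation profiles
#' -> differential statistics (class and species families) -> PCA. Artifacts
#' are written as CSV/JSON when `config$out_dir` is set, together with the
#' effective config and a machine-readable stage log. The run is
#' deterministic given fixed inputs and config.
#'
#' @param config A `pipeline_config`.
#' @param dataset Optional `lipidomics_dataset` (otherwise read from
#'   `config$input`).
#' @return List of class `pipeline_result`: `validation`, `filter_report`,
#'   `dataset` (filtered), `class_profile`, `class_zscores`, `fold_changes`
#'   (per case group), `saturation` (per pool), `differential` (per case
#'   group: `class` and `species` results), `pca`, `log`.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(); t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    v <- force(expr)
    log[[length(log) + 1]] <<- list(stage = name,
                                    seconds = round(proc.time()[["elapsed"]] - ts, 3))
    v
  }

  if (is.null(dataset)) {
    if (is.null(config$input)) {
      lt_stop("config_error", "config has no input and no dataset was given")
    }
    dataset <- stage("read", read_dataset_bundle(config$input))
  }

  groups <- unique(stats::na.omit(dataset$samples$group))
  ctrl <- config$control_group
  if (!is.null(ctrl) && !ctrl %in% groups) {
    lt_stop("config_error",
            sprintf("control group '%s' not present in dataset", ctrl))
  }
  cases <- config$case_groups %||% setdiff(groups, ctrl)

  validation <- stage("validate",
                      validate_dataset(dataset$concentrations,
                                       dataset$samples))
  if (!validation$ok) {
    lt_stop("validation_error", paste(
      "validation failed:", paste(validation$failures, collapse = "; ")))
  }

  fil <- stage("filter", apply_blank_filter(dataset, config$filter))
  ds <- fil$dataset

  profile <- stage("quantify", class_totals(ds))
  zs <- stage("zscore", zscore_rows(profile$percent))
  species_pct <- percent_of_total(ds$concentrations, profile$total_lipid)
  grp <- sample_groups(ds)

  fold_changes <- NULL
  saturation <- NULL
  differential <- NULL
  if (!is.null(ctrl)) {
    fold_changes <- stage("fold_change", lapply(
      stats::setNames(cases, cases), function(g) {
        list(class = log2_fold_change(profile$percent, grp, ctrl,
                                      "per-group", case_group = g),
             species = log2_fold_change(
               species_pct[, names(grp), drop = FALSE], grp, ctrl,
               "per-group", case_group = g))
      }))
    saturation <- stage("saturation", lapply(
      stats::setNames(config$saturation_pools, config$saturation_pools),
      function(p) double_bond_profile(ds, p, ctrl)))
    rid <- stats::setNames(ds$samples$replicate_id, ds$samples$sample_id)
    stat_mat <- if (config$scale_stats == "percent") species_pct else
      ds$concentrations
    stat_cls <- if (config$scale_stats == "percent") profile$percent else
      profile$totals
    differential <- stage("stats", lapply(
      stats::setNames(cases, cases), function(g) {
        list(
          class = differential_test(
            stat_cls[, names(grp), drop = FALSE], grp, g, ctrl,
            paired = config$paired, replicate_id = rid,
            aggregate = config$aggregate, test = config$test,
            family = "class"),
          species = differential_test(
            stat_mat[, names(grp), drop = FALSE], grp, g, ctrl,
            paired = config$paired, replicate_id = rid,
            aggregate = config$aggregate, test = config$test,
            family = "species"))
      }))
  }

  pca <- stage("pca", tryCatch(
    pca_lipotypes(species_pct[, names(grp), drop = FALSE]),
    lipotyper_error = function(e) NULL))

  result <- structure(
    list(validation = validation, filter_report = fil$report, dataset = ds,
         class_profile = profile, class_zscores = zs,
         fold_changes = fold_changes, saturation = saturation,
         differential = differential, pca = pca,
         log = c(log, list(list(stage = "total",
                                seconds = round(proc.time()[["elapsed"]] - t0,
                                                3))))),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_result(result, config)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$filter_report)
  print(x$class_profile)
  if (!is.null(x$differential)) {
    for (g in names(x$differential)) print(x$differential[[g]]$class)
  }
  invisible(x)
}

write_pipeline_result <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f))
  write_filter_report(result$filter_report,
                      file.path(dir, "filter_report.csv"),
                      file.path(dir, "filter_summary.json"))
  wcsv(result$class_profile$totals, "class_totals.csv")
  wcsv(result$class_profile$percent, "class_percent.csv")
  wcsv(result$class_zscores, "class_zscores.csv")
  if (!is.null(result$fold_changes)) {
    for (g in names(result$fold_changes)) {
      wcsv(cbind(class = as.matrix(result$fold_changes[[g]]$class)),
           sprintf("log2fc_class_%s.csv", g))
      wcsv(cbind(species = as.matrix(result$fold_changes[[g]]$species)),
           sprintf("log2fc_species_%s.csv", g))
    }
  }
  if (!is.null(result$saturation)) {
    for (p in names(result$saturation)) {
      write_saturation_profile(result$saturation[[p]],
                               file.path(dir, sprintf("saturation_%s.csv", p)))
    }
  }
  if (!is.null(result$differential)) {
    for (g in names(result$differential)) {
      utils::write.csv(as.data.frame(result$differential[[g]]$class),
                       file.path(dir, sprintf("differential_class_%s.csv", g)),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(result$differential[[g]]$species),
                       file.path(dir, sprintf("differential_species_%s.csv", g)),
                       row.names = FALSE)
    }
  }
  if (!is.null(result$pca)) {
    wcsv(result$pca$scores, "pca_scores.csv")
    wcsv(result$pca$loadings, "pca_loadings.csv")
    utils::write.csv(
      data.frame(component = seq_along(result$pca$variance_explained),
                 variance_explained = result$pca$variance_explained),
      file.path(dir, "pca_variance.csv"), row.names = FALSE)
  }
  cfg <- unclass(config)
  cfg$filter <- unclass(cfg$filter)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  jsonlite::write_json(result$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Markdown run report
#'
#' Self-contained markdown summary of a pipeline result (filter totals,
#' class composition, significant features), for the `report` CLI
#' subcommand.
#'
#' @param result A `pipeline_result`.
#' @param path Output markdown path.
#' @return `path`, invisibly.
#' @export
report_markdown <- function(result, path) {
  tot <- attr(result$filter_report, "totals")
  lines <- c(
    "# Lipidomics pipeline report", "",
    "## Blank filtering", "",
    sprintf("- retained: %d", tot["retained"]),
    sprintf("- reintroduced: %d", tot["reintroduced"]),
    sprintf("- removed: %d", tot["removed"]), "",
    "## Class composition (mean percent of total)", "",
    "| class | mean % |", "|---|---|")
  mp <- sort(rowMeans(result$class_profile$percent), decreasing = TRUE)
  lines <- c(lines, sprintf("| %s | %.2f |", names(mp), mp), "")
  if (!is.null(result$differential)) {
    for (g in names(result$differential)) {
      dc <- result$differential[[g]]$class
      sig <- dc[!is.na(dc$q) & dc$q < 0.05, ]
      lines <- c(lines, sprintf("## Differential classes: %s", g), "",
                 if (nrow(sig) == 0) "none significant (q < 0.05)" else
                   sprintf("- %s: log2FC %.2f, q = %.3g (%s)",
                           sig$feature, sig$log2fc, sig$q, sig$test_used),
                 "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
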