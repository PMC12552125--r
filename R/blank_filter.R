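#' Blank-filter parameters
#'
#' Defaults reproduce the published rule exactly: a species must reach at
#' least `blank_fold` (2) times the blank background in at least
#' `global_fraction` (80%) of all biological samples; a species failing
#' globally is reintroduced if it reaches that intensity in at least
#' `group_fraction` (60%) of the samples within one experimental group
#' (groups formed by concatenating all grouping variables).
#'
#' @param blank_fold Positive multiplier on the blank background (default 2).
#' @param global_fraction Fraction of all biological samples required
#'   (default 0.8); the "at least" boundary is closed.
#' @param group_fraction Within-group fraction for reintroduction
#'   (default 0.6); closed boundary.
#' @param blank_statistic Summary over blank samples: `"mean"` (default,
#'   robust) or `"max"` (stringent).
#' @return List of class `filter_params`.
#' @export
filter_params <- function(blank_fold = 2, global_fraction = 0.8,
                          group_fraction = 0.6,
                          blank_statistic = c("mean", "max")) {
  blank_statistic <- match.arg(blank_statistic)
  stopifnot(is.numeric(blank_fold), blank_fold > 0,
            global_fraction >= 0, global_fraction <= 1,
            group_fraction >= 0, group_fraction <= 1)
  structure(list(blank_fold = blank_fold,
                 global_fraction = global_fraction,
                 group_fraction = group_fraction,
                 blank_statistic = blank_statistic),
            class = "filter_params")
}

#' Per-species blank threshold
#'
#' `blank_fold` times the blank summary statistic per species. Missing blank
#' values count as 0, so a species entirely absent from the blanks gets
#' threshold 0 and passes everywhere it was measured.
#'
#' @param ds A `lipidomics_dataset` with at least one blank sample.
#' @param params A `filter_params`.
#' @return Named numeric vector, one threshold per species.
#' @export
blank_threshold <- function(ds, params = filter_params()) {
  blanks <- blank_ids(ds)
  if (length(blanks) == 0L) {
    lt_stop("no_blank_error", "no blank samples: cannot compute thresholds")
  }
  bm <- ds$concentrations[, blanks, drop = FALSE]
  bm[is.na(bm)] <- 0
  stat <- switch(params$blank_statistic,
                 mean = rowMeans(bm),
                 max = apply(bm, 1, max))
  params$blank_fold * stat
}

#' Apply the blank filter
#'
#' A species "passes" in a biological sample iff its value is non-missing and
#' `>=` its blank threshold. Verdicts:
#' * `retained` — global pass fraction `>= global_fraction`;
#' * `reintroduced` — not retained, but pass fraction `>= group_fraction`
#'   within at least one experimental group;
#' * `removed` — otherwise.
#'
#' Fractions are computed over biological samples only (blanks cannot contain
#' species by definition; QCs are pools). The filtered dataset keeps retained
#' and reintroduced species; missing values are left missing — no imputation.
#'
#' @param ds A validated `lipidomics_dataset`.
#' @param params A `filter_params`.
#' @return List with elements `dataset` (filtered `lipidomics_dataset`) and
#'   `report` (a `filter_report` data.frame: species, threshold,
#'   global_fraction, max_group_fraction, best_group, verdict, plus per-group
#'   fraction columns and verdict totals in attributes).
#' @export
apply_blank_filter <- function(ds, params = filter_params()) {
  bio <- biological_ids(ds)
  if (length(bio) == 0L) {
    lt_stop("empty_design_error", "no biological samples in dataset")
  }
  thr <- blank_threshold(ds, params)
  x <- ds$concentrations[, bio, drop = FALSE]
  pass <- !is.na(x) & x >= thr  # thr recycles down columns (per species)
  global_frac <- rowMeans(pass)

  groups <- sample_groups(ds)[bio]
  glev <- unique(groups)
  gfrac <- vapply(glev, function(g) {
    rowMeans(pass[, groups == g, drop = FALSE])
  }, numeric(nrow(x)))
  if (is.null(dim(gfrac))) gfrac <- matrix(gfrac, nrow = nrow(x),
                                           dimnames = list(rownames(x), glev))
  max_gf <- apply(gfrac, 1, max)
  best_group <- glev[apply(gfrac, 1, which.max)]

  verdict <- ifelse(global_frac >= params$global_fraction, "retained",
                    ifelse(max_gf >= params$group_fraction,
                           "reintroduced", "removed"))

  report <- data.frame(species = rownames(x), threshold = unname(thr),
                       global_fraction = unname(global_frac),
                       max_group_fraction = unname(max_gf),
                       best_group = best_group, verdict = verdict,
                       stringsAsFactors = FALSE, row.names = NULL)
  gcols <- as.data.frame(gfrac)
  names(gcols) <- paste0("frac:", glev)
  report <- cbind(report, gcols)
  attr(report, "totals") <- c(retained = sum(verdict == "retained"),
                              reintroduced = sum(verdict == "reintroduced"),
                              removed = sum(verdict == "removed"))
  attr(report, "params") <- params
  class(report) <- c("filter_report", "data.frame")

  keep <- verdict != "removed"
  out <- ds
  out$concentrations <- ds$concentrations[keep, , drop = FALSE]
  out$species <- ds$species[keep, , drop = FALSE]
  list(dataset = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf(
    "<filter_report> %d species: %d retained, %d reintroduced, %d removed\n",
    nrow(x), tot["retained"], tot["reintroduced"], tot["removed"]))
  invisible(x)
}

#' Export a filter report
#'
#' Writes the per-species CSV and a JSON summary (verdict totals and the
#' parameters used).
#'
#' @param report A `filter_report`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the totals vector.
#' @export
write_filter_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    p <- attr(report, "params")
    jsonlite::write_json(
      list(totals = as.list(attr(report, "totals")),
           params = unclass(p)),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(attr(report, "totals"))
}
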