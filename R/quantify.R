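#' Class totals and percent-of-total composition
#'
#' Sums species concentrations within each lipid class per sample. Missing
#' species values are treated as absent (0) for sums — they stay missing for
#' species-level statistics; no imputation happens here. Every registry class
#' is kept in the output even when no member species survived filtering.
#'
#' @param ds A (typically blank-filtered) `lipidomics_dataset`.
#' @param classes Class codes to report; defaults to the full registry.
#' @return Object of class `class_profile`: list with `totals` (class x
#'   sample matrix), `percent` (same shape, percent of total lipid),
#'   `total_lipid` (named per-sample vector, sum over all species).
#' @export
class_totals <- function(ds, classes = lipid_class_registry()$code) {
  mat <- ds$concentrations
  ann <- ds$species
  if (!all(rownames(mat) %in% ann$canonical)) {
    lt_stop("annotation_error", "species without annotation in dataset")
  }
  cls <- ann$class[match(rownames(mat), ann$canonical)]
  m0 <- mat
  m0[is.na(m0)] <- 0
  totals <- matrix(0, length(classes), ncol(mat),
                   dimnames = list(classes, colnames(mat)))
  for (cl in intersect(classes, unique(cls))) {
    totals[cl, ] <- colSums(m0[cls == cl, , drop = FALSE])
  }
  total_lipid <- colSums(m0)
  pct <- percent_of_total(totals, total_lipid)
  structure(list(totals = totals, percent = pct, total_lipid = total_lipid),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf("<class_profile> %d classes x %d samples\n",
              nrow(x$totals), ncol(x$totals)))
  top <- sort(rowMeans(x$percent), decreasing = TRUE)[1:3]
  cat("  top classes (mean %):",
      paste(sprintf("%s=%.1f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Percent-of-total normalization
#'
#' Divides each column by the sample's total lipid and scales to percent.
#' Species-level and class-level matrices must share one total — the sum of
#' all retained species — so class percents equal the sum of their member
#' species percents.
#'
#' @param mat Feature x sample matrix (class totals or species values).
#' @param total_lipid Optional named per-sample totals; when omitted, column
#'   sums of `mat` (missing treated as 0) are used.
#' @return Matrix of the same shape, values in percent.
#' @export
percent_of_total <- function(mat, total_lipid = NULL) {
  if (is.null(total_lipid)) {
    m0 <- mat
    m0[is.na(m0)] <- 0
    total_lipid <- colSums(m0)
  }
  zero <- names(total_lipid)[total_lipid <= 0]
  if (length(zero) == 0 && any(total_lipid <= 0)) zero <- which(total_lipid <= 0)
  if (any(total_lipid <= 0)) {
    lt_stop("zero_total_error", sprintf(
      "zero total lipid in sample(s): %s", paste(zero, collapse = ", ")))
  }
  sweep(mat, 2, total_lipid, "/") * 100
}

#' Row-wise z-scores
#'
#' Centers and scales each feature across samples using the sample (n - 1)
#' standard deviation. Constant rows (sd = 0) become all zeros and are
#' recorded in the `"constant_features"` attribute.
#'
#' @param mat Feature x sample matrix, >= 2 samples.
#' @return Z-scored matrix with attribute `constant_features`.
#' @export
zscore_rows <- function(mat) {
  if (ncol(mat) < 2L) lt_stop("domain_error", "z-scoring needs >= 2 samples")
  mu <- rowMeans(mat, na.rm = TRUE)
  sd <- apply(mat, 1, stats::sd, na.rm = TRUE)
  flat <- !is.na(sd) & sd == 0
  sd[flat] <- 1
  z <- sweep(sweep(mat, 1, mu, "-"), 1, sd, "/")
  z[flat, ] <- 0
  attr(z, "constant_features") <- rownames(mat)[flat]
  z
}

#' Log2 fold changes against a control group
#'
#' Per-sample mode divides each sample by the mean of the control samples,
#' feature-wise (the per-individual heat-map payload); per-group mode uses
#' the case-group mean. Inputs are expected on the percent-of-total scale.
#' Features whose control mean is 0 get `NA` and are listed in the
#' `"undefined_features"` attribute; no pseudocount is applied unless
#' `epsilon > 0`.
#'
#' @param mat Feature x sample matrix (percent-of-total).
#' @param groups Named group label per column of `mat`.
#' @param control_group Control group label.
#' @param comparison `"per-sample"` or `"per-group"`.
#' @param case_group Required for `"per-group"`.
#' @param epsilon Optional pseudocount added to numerator and denominator.
#' @return Per-sample: feature x non-control-sample matrix of log2 fold
#'   changes. Per-group: named per-feature vector.
#' @export
log2_fold_change <- function(mat, groups, control_group,
                             comparison = c("per-sample", "per-group"),
                             case_group = NULL, epsilon = 0) {
  comparison <- match.arg(comparison)
  groups <- groups[colnames(mat)]
  ctrl <- colnames(mat)[!is.na(groups) & groups == control_group]
  if (length(ctrl) == 0L) {
    lt_stop("domain_error",
            sprintf("control group '%s' is empty", control_group))
  }
  ctrl_mean <- rowMeans(mat[, ctrl, drop = FALSE], na.rm = TRUE)
  denom <- ctrl_mean + epsilon
  undef <- rownames(mat)[denom <= 0 | is.na(denom)]

  if (comparison == "per-sample") {
    cases <- setdiff(colnames(mat), ctrl)
    fc <- log2(sweep(mat[, cases, drop = FALSE] + epsilon, 1, denom, "/"))
    fc[undef, ] <- NA_real_
  } else {
    if (is.null(case_group)) {
      lt_stop("domain_error", "case_group required for per-group comparison")
    }
    case <- colnames(mat)[!is.na(groups) & groups == case_group]
    if (length(case) == 0L) {
      lt_stop("domain_error", sprintf("case group '%s' is empty", case_group))
    }
    case_mean <- rowMeans(mat[, case, drop = FALSE], na.rm = TRUE)
    fc <- log2((case_mean + epsilon) / denom)
    fc[rownames(mat) %in% undef] <- NA_real_
    names(fc) <- rownames(mat)
  }
  attr(fc, "undefined_features") <- undef
  fc
}
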