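#' Double-bond (unsaturation) profile for a lipid pool
#'
#' For the TG class, the CE class, or the pooled glycerophospholipid classes
#' ([phospholipid_classes()]), species concentrations are summed per number
#' of double bonds in the sum composition, normalized over each sample's
#' total lipid concentration, and expressed as fold change over the mean of
#' the control samples.
#'
#' Double-bond bins with zero abundance in every sample are omitted. Bins
#' with zero mean in the controls keep their normalized values but have
#' undefined (missing) fold changes. Missing species values count as absent
#' (0) in the sums.
#'
#' @param ds A blank-filtered `lipidomics_dataset`.
#' @param pool `"TG"`, `"CE"` or `"phospholipids"`.
#' @param control_group Control group label (biological samples only).
#' @param include_sm If TRUE, sphingomyelin joins the phospholipid pool
#'   (off by default: SM is not a glycerophospholipid).
#' @return Object of class `saturation_profile`: list with `pool`,
#'   `double_bonds` (sorted integer vector of bins), `summed`, `normalized`,
#'   `fold_change` (bin x biological-sample matrices), `pool_total`
#'   (per-sample summed pool concentration) and `control_samples`.
#' @export
double_bond_profile <- function(ds, pool = c("TG", "CE", "phospholipids"),
                                control_group, include_sm = FALSE) {
  pool <- match.arg(pool)
  pool_classes <- switch(pool,
    TG = "TG", CE = "CE",
    phospholipids = c(phospholipid_classes(), if (include_sm) "SM"))
  member <- ds$species$class %in% pool_classes
  if (!any(member)) {
    lt_stop("empty_pool_error",
            sprintf("no species left in pool '%s' after filtering", pool))
  }
  bio <- biological_ids(ds)
  groups <- sample_groups(ds)
  if (!any(groups == control_group)) {
    lt_stop("domain_error",
            sprintf("control group '%s' is empty", control_group))
  }

  x <- ds$concentrations[member, bio, drop = FALSE]
  x[is.na(x)] <- 0
  db <- ds$species$total_double_bonds[member]

  m0 <- ds$concentrations[, bio, drop = FALSE]
  m0[is.na(m0)] <- 0
  total_lipid <- colSums(m0)

  bins <- sort(unique(db))
  summed <- t(vapply(bins, function(d) {
    colSums(x[db == d, , drop = FALSE])
  }, numeric(length(bio))))
  dimnames(summed) <- list(bins, bio)
  summed <- summed[rowSums(summed) > 0, , drop = FALSE]
  bins <- as.integer(rownames(summed))

  normalized <- sweep(summed, 2, total_lipid, "/")
  ctrl <- bio[groups[bio] == control_group]
  ctrl_mean <- rowMeans(normalized[, ctrl, drop = FALSE])
  fold_change <- sweep(normalized, 1, ctrl_mean, "/")
  fold_change[ctrl_mean == 0, ] <- NA_real_

  structure(list(pool = pool, double_bonds = bins, summed = summed,
                 normalized = normalized, fold_change = fold_change,
                 pool_total = colSums(summed), control_samples = ctrl),
            class = "saturation_profile")
}

#' @export
print.saturation_profile <- function(x, ...) {
  cat(sprintf(
    "<saturation_profile> pool %s: %d double-bond bins x %d samples (%d controls)\n",
    x$pool, length(x$double_bonds), ncol(x$summed),
    length(x$control_samples)))
  invisible(x)
}

#' Export a saturation profile as long-format CSV
#'
#' Columns: pool, double_bonds, sample, summed, normalized, fold_change.
#'
#' @param profile A `saturation_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_saturation_profile <- function(profile, path) {
  long <- data.frame(
    pool = profile$pool,
    double_bonds = rep(profile$double_bonds, times = ncol(profile$summed)),
    sample = rep(colnames(profile$summed), each = nrow(profile$summed)),
    summed = as.vector(profile$summed),
    normalized = as.vector(profile$normalized),
    fold_change = as.vector(profile$fold_change))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
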