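#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-implemented step-up: with order statistics \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, with
#' the original order restored. Equivalent to rejecting, at level
#' \eqn{\alpha}, all hypotheses up to the largest \eqn{k} with
#' \eqn{p_{(k)} \le k\alpha/m}.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`s are passed through
#'   and do not count toward `m`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  x <- p[ok]
  if (any(x < 0 | x > 1)) {
    lt_stop("domain_error", "p-values must lie in [0, 1]")
  }
  m <- length(x)
  out <- rep(NA_real_, length(p))
  if (m > 0L) {
    o <- order(x)
    q <- (m / seq_len(m)) * x[o]  # m/j first: q equals p exactly at j = m
    q <- rev(cummin(rev(q)))       # min over j >= i
    q <- pmin(q, 1)
    adj <- numeric(m)
    adj[o] <- q
    out[ok] <- adj
  }
  out
}

#' Choose between the t-test and the rank test
#'
#' Normality gate: Shapiro-Wilk at `alpha` on each group (unpaired) or on the
#' paired differences. Any rejection — or a degenerate (constant) input on
#' which Shapiro-Wilk is undefined — selects the rank test (Mann-Whitney U,
#' or signed-rank Wilcoxon when paired); otherwise the t-test.
#'
#' @param a,b Numeric value vectors (aligned pairs when `paired`).
#' @param paired Logical.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return `"t"`, `"mwu"`, `"paired-t"` or `"wilcoxon"`.
#' @export
select_test <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (paired && length(a) != length(b)) {
    lt_stop("domain_error", "paired groups must have equal length")
  }
  if (min(length(a), length(b)) < 3L) {
    lt_stop("insufficient_replicates_error",
            "need >= 3 values per group to select a test")
  }
  shapiro_rejects <- function(v) {
    if (length(unique(v)) < 3L) return(TRUE)  # degenerate: be conservative
    stats::shapiro.test(v)$p.value < alpha
  }
  if (paired) {
    d <- a - b
    if (shapiro_rejects(d)) "wilcoxon" else "paired-t"
  } else {
    if (shapiro_rejects(a) || shapiro_rejects(b)) "mwu" else "t"
  }
}

# Run one two-sided test; returns p. Welch t by default. Mann-Whitney uses
# the exact distribution for n <= 8 per group without ties, the
# tie-corrected normal approximation with continuity correction otherwise.
run_test <- function(a, b, test) {
  p <- switch(test,
    "t" = stats::t.test(a, b, var.equal = FALSE)$p.value,
    "paired-t" = stats::t.test(a, b, paired = TRUE)$p.value,
    "mwu" = {
      ties <- anyDuplicated(c(a, b)) > 0
      exact <- !ties && length(a) <= 8 && length(b) <= 8
      suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    },
    "wilcoxon" = {
      d <- a - b
      ties <- anyDuplicated(abs(d[d != 0])) > 0
      exact <- !ties && !any(d == 0) && length(d) <= 8
      suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE, exact = exact,
                           correct = TRUE)$p.value)
    },
    lt_stop("domain_error", sprintf("unknown test id '%s'", test)))
  p
}

#' Differential abundance testing with BH correction
#'
#' Tests each feature (lipid class or species) between two groups on the
#' percent-of-total scale, selecting the t-test or rank test per feature via
#' [select_test()] (or a forced override), and applies Benjamini-Hochberg
#' correction within the family. A paired design matches samples across
#' groups by `replicate_id`. When several wells share a `replicate_id`
#' within a group, `aggregate = "experiment"` first averages them, so tests
#' run on per-experiment means (the figure-legend convention).
#'
#' Missing values are dropped pairwise per feature; in paired mode a pair
#' with a missing member is dropped. Features with fewer than 3 usable
#' values (or pairs) per group are skipped and reported with `NA` p-values.
#'
#' @param mat Feature x sample matrix, percent-of-total values.
#' @param groups Named group label per column of `mat`.
#' @param group_a,group_b The two group labels; `group_b` is the
#'   control/reference for the log2 fold change.
#' @param paired Logical; pairs keyed by `replicate_id`.
#' @param replicate_id Named per-column experiment key (required for
#'   `paired` or `aggregate = "experiment"`).
#' @param aggregate `"none"` or `"experiment"`.
#' @param test `"auto"` (default) or a forced test id.
#' @param family Label recorded in the result (`"class"` or `"species"`);
#'   BH is applied within this call, i.e. within one family.
#' @return A `differential_result` data.frame: `feature`, `mean_a`, `mean_b`,
#'   `log2fc`, `test_used`, `p`, `q`, `n_a`, `n_b`, `skipped`.
#' @export
differential_test <- function(mat, groups, group_a, group_b,
                              paired = FALSE, replicate_id = NULL,
                              aggregate = c("none", "experiment"),
                              test = "auto",
                              family = c("species", "class")) {
  aggregate <- match.arg(aggregate)
  family <- match.arg(family)
  groups <- groups[colnames(mat)]
  if (!any(groups == group_a, na.rm = TRUE) ||
      !any(groups == group_b, na.rm = TRUE)) {
    lt_stop("domain_error", "both comparison groups must be non-empty")
  }

  if (aggregate == "experiment" || paired) {
    if (is.null(replicate_id)) {
      lt_stop("domain_error",
              "replicate_id required for paired/experiment-aggregated tests")
    }
    replicate_id <- replicate_id[colnames(mat)]
  }
  if (aggregate == "experiment") {
    key <- paste(groups, replicate_id, sep = "\r")
    agg <- t(apply(mat, 1, function(v) {
      tapply(v, key, mean, na.rm = TRUE)
    }))
    ukey <- colnames(agg)
    groups <- sub("\r.*$", "", ukey)
    replicate_id <- sub("^.*\r", "", ukey)
    colnames(agg) <- make.unique(replicate_id, sep = "#")
    names(groups) <- names(replicate_id) <- colnames(agg)
    mat <- agg
    mat[is.nan(mat)] <- NA_real_
  }

  ca <- colnames(mat)[!is.na(groups) & groups == group_a]
  cb <- colnames(mat)[!is.na(groups) & groups == group_b]
  if (paired) {
    ra <- replicate_id[ca]; rb <- replicate_id[cb]
    common <- intersect(ra, rb)
    ca <- ca[match(common, ra)]
    cb <- cb[match(common, rb)]
    if (length(common) == 0L) {
      lt_stop("domain_error", "no replicate_id pairs shared between groups")
    }
  }

  res <- lapply(rownames(mat), function(f) {
    a <- mat[f, ca]; b <- mat[f, cb]
    if (paired) {
      keep <- !is.na(a) & !is.na(b)
      a <- a[keep]; b <- b[keep]
      n_a <- n_b <- sum(keep)
    } else {
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      n_a <- length(a); n_b <- length(b)
    }
    mean_a <- if (n_a) mean(a) else NA_real_
    mean_b <- if (n_b) mean(b) else NA_real_
    l2fc <- if (isTRUE(mean_b > 0) && isTRUE(mean_a > 0)) {
      log2(mean_a / mean_b)
    } else if (isTRUE(mean_a == mean_b)) 0 else NA_real_
    if (min(n_a, n_b) < 3L) {
      return(data.frame(feature = f, mean_a = mean_a, mean_b = mean_b,
                        log2fc = l2fc, test_used = NA_character_,
                        p = NA_real_, n_a = n_a, n_b = n_b, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    tid <- if (identical(test, "auto")) select_test(a, b, paired = paired)
           else test
    identical_groups <- length(a) == length(b) && all(a == b)
    p <- if (identical_groups) 1 else run_test(a, b, tid)
    if (is.nan(p)) p <- 1  # zero-variance identical groups under t
    data.frame(feature = f, mean_a = mean_a, mean_b = mean_b, log2fc = l2fc,
               test_used = tid, p = p, n_a = n_a, n_b = n_b, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out <- out[, c("feature", "mean_a", "mean_b", "log2fc", "test_used",
                 "p", "q", "n_a", "n_b", "skipped")]
  attr(out, "family") <- family
  attr(out, "comparison") <- c(a = group_a, b = group_b)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' @export
`[.differential_result` <- function(x, ...) {
  y <- NextMethod()
  if (is.data.frame(y)) class(y) <- "data.frame"
  y
}

#' @export
print.differential_result <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat(sprintf(
    "<differential_result> %s vs %s, %d %s features (%d tested, %d with q < 0.05)\n",
    cmp["a"], cmp["b"], nrow(x), attr(x, "family"),
    sum(!x$skipped), sum(x$q < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' PCA of sample lipotypes
#'
#' Principal component analysis of samples on species percent-of-total
#' values. Features with any missing value are excluded (no imputation), as
#' are zero-variance features when `scale` is set. The sign of each
#' component is fixed so that its largest-|loading| feature has a positive
#' loading, making scores reproducible across platforms.
#'
#' @param mat Feature x sample matrix (percent-of-total values).
#' @param scale Unit-scale features (default FALSE; they share a scale
#'   already).
#' @param n_components Number of components to keep (default all).
#' @return Object of class `pca_result`: `scores` (sample x component),
#'   `loadings` (feature x component), `variance_explained` (fractions).
#' @export
pca_lipotypes <- function(mat, scale = FALSE, n_components = NULL) {
  if (ncol(mat) < 3L) {
    lt_stop("insufficient_samples_error", "PCA needs >= 3 samples")
  }
  keep <- rowSums(is.na(mat)) == 0
  x <- t(mat[keep, , drop = FALSE])  # samples x features
  if (scale) {
    v <- apply(x, 2, stats::sd)
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) {
    lt_stop("domain_error", "PCA needs >= 2 usable features")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale)
  k <- min(n_components %||% ncol(pr$x), ncol(pr$x))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # deterministic sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve[seq_len(k)]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$variance_explained[1],
              100 * (x$variance_explained[2] %||% NA)))
  invisible(x)
}

#' Mean silhouette width of a labeled embedding
#'
#' Small self-contained silhouette (Euclidean distance) used to quantify
#' cluster separation of PCA lipotype scores.
#'
#' @param x Sample x coordinate matrix.
#' @param labels Cluster label per row.
#' @return Mean silhouette width over all samples.
#' @export
silhouette_score <- function(x, labels) {
  labels <- as.character(labels)
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(unique(labels[!own]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    if (sum(own) == 1L) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
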