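# Brute-force BH: reject the largest k with p_(k) <= k * alpha / m; the
# adjusted value of a hypothesis is the smallest alpha at which it is
# rejected. Used as the independent oracle for bh_adjust().
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- max(c(0, which(p[o] <= seq_len(m) * alpha / m)))
  rejected <- logical(m)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

test_that("bh_adjust matches the worked example and caps at 1", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.9, 0.95)), c(0.95, 0.95))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "domain_error")
  # NAs pass through without counting toward m
  expect_equal(bh_adjust(c(0.01, NA, 0.02, 0.04)),
               c(0.03, NA, 0.03, 0.04))
})

test_that("bh_adjust equals the reject-set definition and p.adjust", {
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"))
    for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
      expect_identical(q <= alpha, bh_reject(p, alpha),
                       label = sprintf("case %d alpha %.2f", i, alpha))
    }
    # monotone: sorting by raw p sorts adjusted p non-decreasingly
    expect_true(!is.unsorted(q[order(p)]))
    expect_true(all(q >= p & q <= 1))
  }
})

test_that("select_test gates on Shapiro-Wilk normality", {
  expect_equal(select_test(c(1, 2, 3, 4), c(2, 3, 4, 6)), "t")
  expect_equal(select_test(c(1, 1, 1, 100), c(2, 3, 4, 6)), "mwu")
  # paired, distinct symmetric differences -> paired t
  expect_equal(select_test(c(1, 2, 3, 4.5), c(2.1, 3.3, 4.2, 6),
                           paired = TRUE), "paired-t")
  expect_error(select_test(c(1, 2), c(1, 2, 3)),
               class = "insufficient_replicates_error")
})

test_that("paired t matches the closed form", {
  # a - b = [-1,-1,-2,-2]: t = 1.5 / (sd/2) = 5.196, df = 3
  a <- c(1, 2, 3, 4); b <- c(2, 3, 5, 6)
  d <- a - b
  t_stat <- abs(mean(d)) / (sd(d) / sqrt(length(d)))
  p_expected <- 2 * pt(-t_stat, df = length(d) - 1)
  expect_equal(t_stat, 5.196152, tolerance = 1e-6)
  expect_equal(p_expected, 0.0138, tolerance = 1e-2)

  m <- rbind(f = c(a, b))
  colnames(m) <- paste0("s", 1:8)
  grp <- setNames(rep(c("A", "B"), each = 4), colnames(m))
  rid <- setNames(rep(paste0("e", 1:4), 2), colnames(m))
  res <- differential_test(m, grp, "A", "B", paired = TRUE,
                           replicate_id = rid, test = "paired-t")
  expect_equal(res$p, p_expected, tolerance = 1e-12)
  expect_equal(res$test_used, "paired-t")
})

test_that("differential_test handles identical groups, families and skips", {
  m <- rbind(same = c(1, 2, 3, 4, 1, 2, 3, 4),
             gap = c(1, 1.2, 0.9, 1.1, 4, 4.4, 3.8, 4.1),
             sparse = c(1, NA, NA, NA, 2, 2, 2, 2))
  colnames(m) <- paste0("s", 1:8)
  grp <- setNames(rep(c("A", "B"), each = 4), colnames(m))
  res <- differential_test(m, grp, "A", "B", family = "class")
  same <- res[res$feature == "same", ]
  expect_equal(same$p, 1)
  expect_equal(same$log2fc, 0)
  expect_true(res$skipped[res$feature == "sparse"])
  expect_true(is.na(res$p[res$feature == "sparse"]))
  expect_equal(res$q, bh_adjust(res$p))
  expect_true(res$q[res$feature == "gap"] < 0.05)

  # group-label swap: identical p, negated log2FC
  swapped <- differential_test(m, grp, "B", "A", family = "class")
  expect_equal(swapped$p, res$p)
  expect_equal(swapped$log2fc[1:2], -res$log2fc[1:2])
})

test_that("experiment aggregation averages wells before testing", {
  # 2 wells per experiment; effect visible on experiment means
  m <- rbind(f = c(1, 1.2, 2, 2.2, 3, 3.1, 4, 4.1, 5, 5.2, 6, 6.1))
  colnames(m) <- paste0("s", 1:12)
  grp <- setNames(rep(c("A", "B"), each = 6), colnames(m))
  rid <- setNames(rep(paste0("e", 1:6), each = 2), colnames(m))
  res <- differential_test(m, grp, "A", "B", aggregate = "experiment",
                           replicate_id = rid, test = "t")
  expect_equal(res$n_a, 3L)  # 3 experiments per group
  expect_equal(res$mean_a, mean(c(1.1, 2.1, 3.05)))
  # paired across experiments requires shared replicate ids
  rid2 <- setNames(rep(paste0("e", 1:3), 4), colnames(m))
  res2 <- differential_test(m, grp, "A", "B", paired = TRUE,
                            replicate_id = rid2, aggregate = "experiment",
                            test = "paired-t")
  expect_false(res2$skipped)
})

test_that("PCA separates constructed clusters with fixed signs", {
  set.seed(42)
  n <- 6
  base <- matrix(rnorm(40 * 2 * n, sd = 0.1), 40)
  base[1, ] <- base[1, ] + rep(c(0, 10), each = n)  # offset along feature 1
  colnames(base) <- paste0("s", seq_len(2 * n))
  rownames(base) <- paste0("f", 1:40)
  res <- pca_lipotypes(base)
  expect_true(res$variance_explained[1] > res$variance_explained[2])
  expect_true(!is.unsorted(rev(res$variance_explained)))
  expect_lte(sum(res$variance_explained), 1 + 1e-12)
  # PC1 separates the clusters
  cl <- rep(c("a", "b"), each = n)
  expect_true(min(res$scores[cl == "b", 1]) > max(res$scores[cl == "a", 1]) ||
              min(res$scores[cl == "a", 1]) > max(res$scores[cl == "b", 1]))
  # sign convention: largest-|loading| feature positive
  for (j in 1:2) {
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  # duplicated sample -> identical scores
  dup <- cbind(base, dup = base[, 1])
  res2 <- pca_lipotypes(dup)
  expect_equal(res2$scores["dup", ], res2$scores["s1", ], tolerance = 1e-9)

  # variance fractions match a direct covariance eigendecomposition
  ev <- eigen(cov(t(base)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(res$variance_explained, (ev / sum(ev))[seq_along(res$variance_explained)],
               tolerance = 1e-9)

  expect_error(pca_lipotypes(base[, 1:2]),
               class = "insufficient_samples_error")
  # features with missing values are excluded, not imputed
  base_na <- base
  base_na[2, 3] <- NA
  res3 <- pca_lipotypes(base_na)
  expect_false("f2" %in% rownames(res3$loadings))
})

test_that("silhouette_score behaves on separated vs mixed labels", {
  set.seed(7)
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 5, 0.1), 10))
  lab <- rep(c("a", "b"), each = 10)
  expect_gt(silhouette_score(x, lab), 0.9)
  expect_lt(silhouette_score(x, sample(lab)), 0.5)
})
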