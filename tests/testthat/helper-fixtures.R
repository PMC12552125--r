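# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no data files.

# A pool of valid species names to draw random small datasets from.
fixture_species_pool <- function() {
  c("CE 16:0", "CE 18:1", "CE 20:4", "TG 48:1", "TG 52:3", "TG 54:6",
    "PC 32:1", "PC 34:2", "PC 36:4", "PE 34:1", "PE 36:2", "PS 38:4",
    "PI 38:4", "PG 34:1", "SM 34:1", "SM 42:2", "CER 16:0", "CER 24:1",
    "DCER 18:0", "HCER 16:0", "LCER 24:1", "DG 34:1", "FFA 18:1",
    "FFA 22:6", "LPC 16:0", "LPE 18:1")
}

# Assemble a lipidomics_dataset from a plain matrix and per-sample roles.
make_fixture_dataset <- function(mat, sample_type, group = NULL,
                                 replicate_id = NULL, unit = "uM") {
  meta <- data.frame(sample_id = colnames(mat), sample_type = sample_type,
                     stringsAsFactors = FALSE)
  if (!is.null(replicate_id)) meta$replicate_id <- replicate_id
  gv <- character()
  if (!is.null(group)) {
    meta$condition <- group
    gv <- "condition"
  }
  lipidomics_dataset(mat, build_sample_annotations(meta, group_vars = gv),
                     unit = unit)
}

# A small deterministic 6-biological + 2-blank dataset exercising all three
# filter verdicts.
tiny_dataset <- function() {
  species <- c("CE 18:1", "TG 52:3", "PC 34:2", "SM 34:1", "FFA 18:1")
  samples <- c(paste0("s", 1:6), "b1", "b2")
  mat <- rbind(
    "CE 18:1" = c(10, 12, 9, 11, 10, 10, 1, 1),     # clearly retained
    "TG 52:3" = c(1, 1, 1, 1, 9, 9, 1, 1),          # group-specific (B)
    "PC 34:2" = c(1, 1, 1, 1, 1, 1, 1, 1),          # at blank: removed
    "SM 34:1" = c(40, 38, NA, 41, 39, 40, 2, 2),    # retained despite NA
    "FFA 18:1" = c(8, 8, 8, 8, 8, 8, 0, 0))         # absent from blanks
  colnames(mat) <- samples
  make_fixture_dataset(mat,
                       sample_type = c(rep("sample", 6), "blank", "blank"),
                       group = c(rep("A", 4), rep("B", 2), NA, NA))
}

# Independent brute-force coding of the blank-filter rule, written directly
# from its verbal definition with explicit loops (the oracle for the
# vectorized implementation).
brute_force_filter <- function(mat, sample_type, group, blank_fold = 2,
                               global_fraction = 0.8, group_fraction = 0.6,
                               blank_statistic = "mean") {
  bio <- which(sample_type == "biological" | sample_type == "sample")
  blanks <- which(sample_type == "blank")
  verdict <- character(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    bvals <- mat[i, blanks]
    bvals[is.na(bvals)] <- 0
    thr <- blank_fold * (if (blank_statistic == "mean") mean(bvals)
                         else max(bvals))
    passes <- logical(length(bio))
    for (k in seq_along(bio)) {
      v <- mat[i, bio[k]]
      passes[k] <- !is.na(v) && v >= thr
    }
    if (sum(passes) / length(bio) >= global_fraction) {
      verdict[i] <- "retained"
      next
    }
    reintro <- FALSE
    for (g in unique(group[bio])) {
      idx <- which(group[bio] == g)
      if (sum(passes[idx]) / length(idx) >= group_fraction) reintro <- TRUE
    }
    verdict[i] <- if (reintro) "reintroduced" else "removed"
  }
  stats::setNames(verdict, rownames(mat))
}

# Random small dataset (<= 12 species x <= 10 biological samples,
# <= 3 groups) for filter oracle-equivalence tests. Values are drawn around
# the blank level so all verdicts occur.
random_small_dataset <- function(seed) {
  set.seed(seed)
  ns <- sample(3:12, 1)
  nb <- sample(4:10, 1)
  ng <- sample(1:3, 1)
  species <- sample(fixture_species_pool(), ns)
  group <- sort(sample(paste0("g", seq_len(ng)), nb, replace = TRUE))
  mat <- matrix(stats::rlnorm(ns * (nb + 2), meanlog = log(2), sdlog = 1.2),
                ns, nb + 2,
                dimnames = list(species, c(paste0("s", seq_len(nb)),
                                           "b1", "b2")))
  mat[stats::runif(length(mat)) < 0.08] <- NA
  mat[, c("b1", "b2")][is.na(mat[, c("b1", "b2")])] <- 0.5
  list(mat = mat,
       sample_type = c(rep("sample", nb), "blank", "blank"),
       group = c(group, NA, NA))
}

fixture_dataset_from_random <- function(r) {
  make_fixture_dataset(r$mat, sample_type = r$sample_type, group = r$group)
}

# Fast small-template simulation for repeated studies.
fast_template <- function(cell = "iAstrocyte", species_per_class = 8, ...) {
  make_templates(species_per_class = species_per_class, ...)[[cell]]
}
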