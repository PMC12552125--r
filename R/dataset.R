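#' Read a wide concentration table
#'
#' Reads a CSV/TSV species-by-sample concentration table. Empty cells, `"NA"`
#' and `"NaN"` become missing; `"0"` is a measured zero, not missing (SLA
#' reports below-detection values as zeros and the blank filter relies on
#' them). Numbers are parsed locale-independently with a dot decimal.
#'
#' @param path Path to a CSV or TSV file. The delimiter is taken from the
#'   extension (`.tsv`/`.txt` = tab, otherwise comma).
#' @param orientation `"species_rows"` (default: first column species names)
#'   or `"species_cols"` (first row species names, first column sample ids).
#' @param dialect Shorthand dialect for canonicalization checks.
#' @return Numeric matrix, rows = canonical species names, cols = sample ids.
#' @export
read_concentration_table <- function(path,
                                     orientation = c("species_rows",
                                                     "species_cols"),
                                     dialect = "lipidyzer") {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"),
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) lt_stop("parse_error", "table needs >= 2 columns")
  keys <- df[[1]]
  cells <- df[, -1, drop = FALSE]
  num <- matrix(NA_real_, nrow(cells), ncol(cells),
                dimnames = list(keys, colnames(cells)))
  for (j in seq_len(ncol(cells))) {
    v <- cells[[j]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad)) {
      lt_stop("parse_error", sprintf(
        "non-numeric cell '%s' at row %d, column '%s' of %s",
        v[bad[1]], bad[1], colnames(cells)[j], path))
    }
    num[, j] <- parsed
  }
  if (orientation == "species_cols") num <- t(num)
  canonicalize_matrix(num, dialect = dialect)
}

# Rename rows to canonical species names; error on collisions.
canonicalize_matrix <- function(mat, dialect = "lipidyzer") {
  canon <- vapply(rownames(mat),
                  function(s) parse_species(s, dialect)$canonical,
                  character(1))
  if (anyDuplicated(canon)) {
    dup <- unique(canon[duplicated(canon)])
    collisions <- vapply(dup, function(d) {
      paste(rownames(mat)[canon == d], collapse = " / ")
    }, character(1))
    lt_stop("duplicate_species_error", sprintf(
      "species collide after canonicalization: %s",
      paste(sprintf("%s <- {%s}", dup, collisions), collapse = "; ")),
      collisions = collisions)
  }
  rownames(mat) <- unname(canon)
  mat[order(rownames(mat)), , drop = FALSE]
}

#' Read a sample metadata sheet
#'
#' One row per sample. Required fields: a sample id column and a sample type
#' column (case-insensitive header match on `sample_id`/`sample`/`id` and
#' `sample_type`/`type`). `sample_type` tokens `sample` and `biological` both
#' normalize to `"biological"`; `blank` and `qc` as written. An optional
#' `replicate_id` column keys experiment nesting for paired designs. All
#' remaining columns are grouping variables unless `group_vars` names a
#' subset explicitly; columns not used as grouping variables are preserved as
#' pass-through annotations.
#'
#' @param path CSV/TSV path.
#' @param group_vars Optional character vector naming the grouping columns.
#' @return A data.frame of class `sample_annotations` with columns
#'   `sample_id`, `sample_type`, `replicate_id`, one column per grouping
#'   variable, a `group` column (grouping values concatenated with `"|"`, or
#'   `"all"` when there are none), and any pass-through columns.
#' @export
read_metadata <- function(path, group_vars = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("", "NA"), colClasses = "character",
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  build_sample_annotations(df, group_vars = group_vars)
}

#' Build sample annotations from a data.frame
#'
#' The programmatic twin of [read_metadata()]; see there for the contract.
#'
#' @param df data.frame, one row per sample.
#' @param group_vars Optional character vector of grouping column names.
#' @return A `sample_annotations` data.frame.
#' @export
build_sample_annotations <- function(df, group_vars = NULL) {
  lownames <- tolower(names(df))
  id_col <- match(TRUE, lownames %in% c("sample_id", "sample", "id"))
  type_col <- match(TRUE, lownames %in% c("sample_type", "type"))
  if (is.na(type_col)) {
    lt_stop("metadata_error", "metadata has no sample-type field")
  }
  if (is.na(id_col)) {
    lt_stop("metadata_error", "metadata has no sample-id field")
  }
  sample_id <- as.character(df[[id_col]])
  if (anyDuplicated(sample_id)) {
    lt_stop("metadata_error", sprintf(
      "duplicate sample ids: %s",
      paste(unique(sample_id[duplicated(sample_id)]), collapse = ", ")))
  }
  type_raw <- tolower(trimws(as.character(df[[type_col]])))
  type_map <- c(sample = "biological", biological = "biological",
                blank = "blank", qc = "qc")
  sample_type <- unname(type_map[type_raw])
  if (anyNA(sample_type)) {
    lt_stop("metadata_error", sprintf(
      "unknown sample_type token(s): %s",
      paste(unique(type_raw[is.na(sample_type)]), collapse = ", ")))
  }
  rep_col <- match(TRUE, lownames == "replicate_id")
  replicate_id <- if (is.na(rep_col)) NA_character_ else
    as.character(df[[rep_col]])

  reserved <- stats::na.omit(c(id_col, type_col, rep_col))
  other <- setdiff(names(df), names(df)[reserved])
  if (is.null(group_vars)) group_vars <- other
  missing_gv <- setdiff(group_vars, names(df))
  if (length(missing_gv)) {
    lt_stop("metadata_error", sprintf(
      "declared grouping variable(s) absent from metadata: %s",
      paste(missing_gv, collapse = ", ")))
  }

  out <- data.frame(sample_id = sample_id, sample_type = sample_type,
                    replicate_id = replicate_id, stringsAsFactors = FALSE)
  for (gv in union(group_vars, other)) out[[gv]] <- as.character(df[[gv]])

  bio <- out$sample_type == "biological"
  if (length(group_vars)) {
    gvals <- out[group_vars]
    incomplete <- bio & Reduce(`|`, lapply(gvals, is.na))
    if (any(incomplete)) {
      lt_stop("metadata_error", sprintf(
        "biological sample(s) with missing grouping values: %s",
        paste(out$sample_id[incomplete], collapse = ", ")))
    }
    # group label = grouping values concatenated in declared order
    out$group <- ifelse(bio, do.call(paste, c(gvals, sep = "|")),
                        NA_character_)
  } else {
    out$group <- ifelse(bio, "all", NA_character_)
  }
  attr(out, "group_vars") <- group_vars
  class(out) <- c("sample_annotations", "data.frame")
  out
}

#' Validate a concentration matrix against sample annotations
#'
#' Mechanical QC: cross-checks sample ids, parses species names, scans for
#' negative values, and counts blanks and per-group biological samples.
#' Hard failures (id mismatches, unparseable species, negative values) block
#' dataset assembly; warnings (no blanks, no QC) do not.
#'
#' @param mat Species-by-sample numeric matrix.
#' @param samples A `sample_annotations` data.frame.
#' @return List of class `validation_report`: `failures` and `warnings`
#'   (character vectors), `n_blank`, `n_qc`, `group_sizes` (named counts of
#'   biological samples per group), and `ok` (TRUE iff no failures).
#' @export
validate_dataset <- function(mat, samples) {
  failures <- character()
  warnings <- character()

  missing_meta <- setdiff(colnames(mat), samples$sample_id)
  if (length(missing_meta)) {
    failures <- c(failures, sprintf(
      "sample(s) in matrix but not metadata: %s",
      paste(missing_meta, collapse = ", ")))
  }
  missing_mat <- setdiff(samples$sample_id, colnames(mat))
  if (length(missing_mat)) {
    failures <- c(failures, sprintf(
      "sample(s) in metadata but not matrix: %s",
      paste(missing_mat, collapse = ", ")))
  }
  bad_species <- rownames(mat)[vapply(rownames(mat), function(s) {
    inherits(tryCatch(parse_species(s), error = identity), "error")
  }, logical(1))]
  if (length(bad_species)) {
    failures <- c(failures, sprintf(
      "species failing shorthand parsing: %s",
      paste(bad_species, collapse = ", ")))
  }
  neg <- which(!is.na(mat) & mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    failures <- c(failures, sprintf(
      "negative concentration(s), e.g. %s / %s",
      rownames(mat)[neg[1, 1]], colnames(mat)[neg[1, 2]]))
  }

  n_blank <- sum(samples$sample_type == "blank")
  n_qc <- sum(samples$sample_type == "qc")
  if (n_blank == 0L) {
    warnings <- c(warnings, "no blank samples: blank filtering unavailable")
  }
  if (n_qc == 0L) warnings <- c(warnings, "no QC samples")
  bio <- samples[samples$sample_type == "biological", ]
  group_sizes <- if (nrow(bio)) table(bio$group) else table(character())

  structure(list(failures = failures, warnings = warnings,
                 n_blank = n_blank, n_qc = n_qc,
                 group_sizes = group_sizes,
                 ok = length(failures) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$ok) "OK" else "FAILED", "\n")
  for (f in x$failures) cat("  failure:", f, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  cat(sprintf("  blanks: %d, QCs: %d\n", x$n_blank, x$n_qc))
  if (length(x$group_sizes)) {
    cat("  biological samples per group:",
        paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble a validated lipidomics dataset
#'
#' Joins a species-by-sample concentration matrix to sample and species
#' annotations after validation. Columns are reordered to metadata order and
#' rows to canonical species order, so assembly is invariant to input
#' shuffling.
#'
#' @param mat Species-by-sample numeric matrix (canonical or raw names).
#' @param samples A `sample_annotations` data.frame (or plain data.frame
#'   accepted by [build_sample_annotations()]).
#' @param unit Concentration unit label, e.g. `"uM"` or
#'   `"pmol/500k cells"`. Purely descriptive.
#' @param dialect Shorthand dialect.
#' @return Object of class `lipidomics_dataset`: list with `concentrations`
#'   (matrix), `species` (annotation data.frame from [annotate_species()]),
#'   `samples`, `unit`.
#' @export
lipidomics_dataset <- function(mat, samples, unit = "uM",
                               dialect = "lipidyzer") {
  if (!inherits(samples, "sample_annotations")) {
    samples <- build_sample_annotations(samples)
  }
  mat <- canonicalize_matrix(mat, dialect = dialect)
  rep <- validate_dataset(mat, samples)
  if (!rep$ok) {
    lt_stop("validation_error", paste(
      "dataset validation failed:", paste(rep$failures, collapse = "; ")))
  }
  mat <- mat[, samples$sample_id, drop = FALSE]
  species <- annotate_species(rownames(mat), dialect = dialect)
  structure(list(concentrations = mat, species = species,
                 samples = samples, unit = unit),
            class = "lipidomics_dataset")
}

#' @export
print.lipidomics_dataset <- function(x, ...) {
  st <- table(x$samples$sample_type)
  cat(sprintf(
    "<lipidomics_dataset> %d species x %d samples [%s]\n",
    nrow(x$concentrations), ncol(x$concentrations), x$unit))
  cat("  sample types:",
      paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  cat("  classes:", length(unique(x$species$class)), "| missing values:",
      sum(is.na(x$concentrations)), "\n")
  invisible(x)
}

# Convenience selectors -------------------------------------------------------

biological_ids <- function(ds) {
  ds$samples$sample_id[ds$samples$sample_type == "biological"]
}

blank_ids <- function(ds) {
  ds$samples$sample_id[ds$samples$sample_type == "blank"]
}

sample_groups <- function(ds) {
  ids <- biological_ids(ds)
  stats::setNames(ds$samples$group[match(ids, ds$samples$sample_id)], ids)
}

#' Write a canonical dataset bundle
#'
#' Writes the matrix CSV, species and sample annotation CSVs, a long "tidy"
#' export (species, sample, concentration), and a JSON manifest carrying the
#' unit, package version and a content hash. Fixed column order and fixed
#' float formatting (`%.10g`) make the bundle byte-stable.
#'
#' @param ds A `lipidomics_dataset`.
#' @param dir Output directory (created if needed).
#' @param extra Optional named list merged into the manifest (e.g. the
#'   generation manifest of a synthetic dataset).
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(ds, dir, extra = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- ds$concentrations
  wide <- data.frame(species = rownames(mat),
                     apply(mat, 2, function(v) sprintf("%.10g", v)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  wide[wide == "NA"] <- ""
  utils::write.csv(wide, file.path(dir, "concentrations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$species, file.path(dir, "species_annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ds$samples),
                   file.path(dir, "sample_annotations.csv"),
                   row.names = FALSE)
  long <- data.frame(
    species = rep(rownames(mat), times = ncol(mat)),
    sample = rep(colnames(mat), each = nrow(mat)),
    concentration = as.vector(mat))
  long <- long[!is.na(long$concentration), ]
  utils::write.csv(long, file.path(dir, "concentrations_long.csv"),
                   row.names = FALSE)
  manifest <- c(list(
    unit = ds$unit,
    n_species = nrow(mat), n_samples = ncol(mat),
    package = "lipotyper",
    version = as.character(utils::packageVersion("lipotyper")),
    content_hash = dataset_hash(ds)), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# Deterministic content hash over the formatted matrix (no external deps).
dataset_hash <- function(ds) {
  txt <- paste(c(rownames(ds$concentrations), colnames(ds$concentrations),
                 sprintf("%.10g", ds$concentrations)), collapse = "\n")
  # FNV-1a 32-bit over UTF-8 bytes
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes %% 256) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Read a dataset bundle written by [write_dataset_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `lipidomics_dataset`.
#' @export
read_dataset_bundle <- function(dir) {
  mat <- read_concentration_table(file.path(dir, "concentrations.csv"))
  samples <- read_metadata(file.path(dir, "sample_annotations.csv"),
                           group_vars = character())
  # grouping columns are everything beyond the reserved + group columns
  meta <- utils::read.csv(file.path(dir, "sample_annotations.csv"),
                          colClasses = "character", check.names = FALSE)
  gv <- setdiff(names(meta),
                c("sample_id", "sample_type", "replicate_id", "group"))
  samples <- build_sample_annotations(
    meta[, setdiff(names(meta), "group"), drop = FALSE], group_vars = gv)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lipidomics_dataset(mat, samples, unit = manifest$unit %||% "uM")
}
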