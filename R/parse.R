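#' Parse a lipid species name in shorthand notation
#'
#' Decomposes a LipidMaps-style shorthand name (e.g. `"PC 16:0/18:1"`,
#' `"TG 16:0_18:1_18:2"`, `"CE 18:1"`) into its class, acyl chains and sum
#' composition. The separator `"_"` marks unknown sn-positions, `"/"` known
#' positions; both are accepted but may not be mixed within one name. Class
#' tokens are case-insensitive and common dialect synonyms (TAG, DAG, FA,
#' HexCER, LacCER, dhCER) are mapped onto the 16-code registry.
#'
#' Ether/oxygen modifiers (`O-`, `P-`) are rejected: the DMS panel this
#' pipeline targets does not report them.
#'
#' @param name Species name, non-empty string.
#' @param dialect Input dialect, `"lipidyzer"` or `"lipidmaps-2020"`. The two
#'   currently share one grammar; the argument pins the contract for future
#'   divergence and is validated.
#' @return An object of class `parsed_lipid`: a list with elements
#'   `lipid_class` (registry code), `chains` (two-column integer matrix,
#'   `carbons` and `double_bonds`, one row per chain), `chain_level`
#'   (`"sum-only"` or `"molecular-species"`), `sep` (`"_"` or `"/"`), and
#'   `canonical` (canonical string form).
#' @examples
#' parse_species("TG 16:0_18:1_18:2")
#' parse_species("LacCER 24:1")$lipid_class  # "LCER"
#' @export
parse_species <- function(name, dialect = c("lipidyzer", "lipidmaps-2020")) {
  dialect <- match.arg(dialect)
  # memoized: species names recur thousands of times across a pipeline run
  if (is.character(name) && length(name) == 1L && !is.na(name)) {
    key <- paste0(dialect, "\r", name)
    hit <- .parse_cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- parse_species_impl(name, dialect)
    .parse_cache[[key]] <- val
    return(val)
  }
  parse_species_impl(name, dialect)
}

.parse_cache <- new.env(parent = emptyenv())

parse_species_impl <- function(name, dialect) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name))) {
    lt_stop("parse_error", "species name must be a non-empty string")
  }
  raw <- trimws(name)
  if (grepl("\\b[OP]-", raw)) {
    lt_stop("parse_error", sprintf(
      "ether/oxygen-modified species are not supported: '%s'", raw))
  }

  # class token = leading run of letters; remainder = chain spec
  m <- regexpr("^[A-Za-z]+", raw)
  if (m == -1L) {
    lt_stop("parse_error",
            sprintf("no class token at position 1 in '%s'", raw))
  }
  token <- regmatches(raw, m)
  rest <- trimws(substring(raw, attr(m, "match.length") + 1L))

  cls <- resolve_class(token)
  if (is.na(cls)) {
    lt_stop("unknown_class_error",
            sprintf("unknown lipid class token '%s' in '%s'", token, raw),
            token = token)
  }

  if (!nzchar(rest)) {
    lt_stop("parse_error",
            sprintf("missing chain specification in '%s' (position %d)",
                    raw, nchar(raw) + 1L))
  }
  has_slash <- grepl("/", rest, fixed = TRUE)
  has_under <- grepl("_", rest, fixed = TRUE)
  if (has_slash && has_under) {
    lt_stop("parse_error", sprintf(
      "mixed chain separators '/' and '_' in '%s'", raw))
  }
  sep <- if (has_slash) "/" else "_"
  parts <- trimws(strsplit(rest, sep, fixed = TRUE)[[1]])
  chains <- matrix(NA_integer_, nrow = length(parts), ncol = 2L,
                   dimnames = list(NULL, c("carbons", "double_bonds")))
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (!grepl("^[0-9]+:[0-9]+$", p)) {
      pos <- regexpr(p, raw, fixed = TRUE)
      lt_stop("parse_error", sprintf(
        "malformed chain '%s' in '%s' (position %d): expected carbons:double_bonds",
        p, raw, max(pos, 1L)))
    }
    cd <- as.integer(strsplit(p, ":", fixed = TRUE)[[1]])
    chains[i, ] <- cd
  }

  chain_level <- if (nrow(chains) > 1L) "molecular-species" else "sum-only"
  p <- structure(
    list(lipid_class = cls, chains = chains, chain_level = chain_level,
         sep = sep, canonical = NA_character_),
    class = "parsed_lipid")
  p$canonical <- canonical_name(p)
  p
}

#' Sum composition of a parsed lipid
#'
#' Total carbons and total double bonds over all acyl chains. For sum-only
#' species this is the single stated pair.
#'
#' @param p A `parsed_lipid`.
#' @return Named integer vector `c(total_carbons =, total_double_bonds =)`.
#' @examples
#' sum_composition(parse_species("PC 16:0/20:4"))  # 36, 4
#' @export
sum_composition <- function(p) {
  stopifnot(inherits(p, "parsed_lipid"))
  c(total_carbons = sum(p$chains[, "carbons"]),
    total_double_bonds = sum(p$chains[, "double_bonds"]))
}

#' Canonical name of a parsed lipid
#'
#' Deterministic form: upper-case class code, one space, chains sorted
#' ascending by (carbons, double bonds), joined by the original separator
#' (`"_"` when sn-positions are unknown). Parsing a canonical name yields an
#' equal object, so canonical names are safe join keys across input files.
#'
#' @param p A `parsed_lipid`.
#' @return Canonical name string.
#' @export
canonical_name <- function(p) {
  stopifnot(inherits(p, "parsed_lipid"))
  ch <- p$chains[order(p$chains[, "carbons"], p$chains[, "double_bonds"]), ,
                 drop = FALSE]
  paste0(p$lipid_class, " ",
         paste(sprintf("%d:%d", ch[, "carbons"], ch[, "double_bonds"]),
               collapse = p$sep))
}

#' @export
print.parsed_lipid <- function(x, ...) {
  sc <- sum_composition(x)
  cat(sprintf("<parsed_lipid> %s  [class %s, %s, sum %d:%d]\n",
              x$canonical, x$lipid_class, x$chain_level,
              sc["total_carbons"], sc["total_double_bonds"]))
  invisible(x)
}

#' @export
format.parsed_lipid <- function(x, ...) x$canonical

all.equal.parsed_lipid <- function(target, current, ...) {
  # equality up to chain ordering (canonical forms sort chains)
  if (target$canonical == current$canonical) TRUE else
    sprintf("canonical forms differ: '%s' vs '%s'",
            target$canonical, current$canonical)
}

#' Annotate a vector of species names
#'
#' Parses each name and returns the per-species annotation table used by the
#' aggregation and saturation stages.
#'
#' @param species Character vector of shorthand names.
#' @param dialect Passed to [parse_species()].
#' @return data.frame with columns `species` (input), `canonical`, `class`,
#'   `total_carbons`, `total_double_bonds`, `chain_level`.
#' @export
annotate_species <- function(species, dialect = "lipidyzer") {
  parsed <- lapply(species, parse_species, dialect = dialect)
  sums <- vapply(parsed, sum_composition, integer(2))
  data.frame(
    species = species,
    canonical = vapply(parsed, `[[`, character(1), "canonical"),
    class = vapply(parsed, `[[`, character(1), "lipid_class"),
    total_carbons = sums["total_carbons", ],
    total_double_bonds = sums["total_double_bonds", ],
    chain_level = vapply(parsed, `[[`, character(1), "chain_level"),
    stringsAsFactors = FALSE
  )
}

#' Write a species annotation table to CSV
#'
#' @param annotations Output of [annotate_species()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(
    annotations[, c("species", "class", "total_carbons",
                    "total_double_bonds", "canonical")],
    path, row.names = FALSE)
  invisible(path)
}
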