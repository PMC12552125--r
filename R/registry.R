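#' The default lipid class registry
#'
#' The quantitative shotgun (Lipidyzer/SLA-style) panel this package targets
#' reports species across 16 lipid classes. The registry fixes the canonical
#' class codes, human-readable display names, and a coarse category used for
#' pooling (notably the glycerophospholipid pool of the saturation analysis).
#'
#' Categories are one of `"neutral/storage"`, `"phospholipid"`,
#' `"lysophospholipid"`, `"sphingolipid"`, `"fatty acid"`.
#'
#' @return A data.frame with columns `code`, `display_name`, `category`,
#'   one row per class, 16 rows.
#' @examples
#' lipid_class_registry()
#' @export
lipid_class_registry <- function() {
  reg <- data.frame(
    code = c("CE", "CER", "DCER", "HCER", "LCER", "DG", "FFA", "LPC",
             "LPE", "PC", "PE", "PG", "PI", "PS", "SM", "TG"),
    display_name = c("CE", "CER", "dhCER", "HexCER", "LacCER", "DAG", "FFA",
                     "LPC", "LPE", "PC", "PE", "PG", "PI", "PS", "SM", "TAG"),
    category = c("neutral/storage", "sphingolipid", "sphingolipid",
                 "sphingolipid", "sphingolipid", "neutral/storage",
                 "fatty acid", "lysophospholipid", "lysophospholipid",
                 "phospholipid", "phospholipid", "phospholipid",
                 "phospholipid", "phospholipid", "sphingolipid",
                 "neutral/storage"),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(reg$code), nrow(reg) == 16L)
  reg
}

# Dialect synonyms, mapped case-insensitively onto registry codes.
.class_synonyms <- c(
  TAG = "TG", DAG = "DG", FA = "FFA", HEXCER = "HCER", LACCER = "LCER",
  DHCER = "DCER", LYSOPC = "LPC", LYSOPE = "LPE"
)

#' Classes forming the glycerophospholipid saturation pool
#'
#' The pooled "phospholipids" of the double-bond saturation analysis:
#' the five diacyl glycerophospholipid classes plus the two
#' lysophospholipids. Sphingomyelin is excluded (not a glycerophospholipid);
#' see the methods vignette for the rationale and the switch.
#'
#' @return Character vector of class codes.
#' @export
phospholipid_classes <- function() {
  c("PC", "PE", "PG", "PI", "PS", "LPC", "LPE")
}

# Resolve a (possibly synonym, possibly lower-case) class token to a registry
# code, or NA if unknown.
resolve_class <- function(token) {
  up <- toupper(trimws(token))
  reg <- lipid_class_registry()$code
  out <- ifelse(up %in% reg, up, unname(.class_synonyms[up]))
  out
}
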