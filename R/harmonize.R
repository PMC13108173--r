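#' Harmonize miRNA identifiers to a shared base form
#'
#' Expression matrices, methylation annotations, validation panels and
#' target databases each spell miRNA names differently
#' (`hsa-miR-129-2-3p`, `MIR129-2`, `mir-129-2`, ...). To join records
#' across platforms, identifiers are reduced to a common base form by
#' applying, in order: lowercasing; stripping a leading species prefix
#' (a three-letter token followed by a hyphen, e.g. `hsa-`, `mmu-`);
#' stripping one terminal mature-arm annotation (`-5p` or `-3p`); and
#' removing all remaining hyphens. Trailing locus numbers (`...-1`,
#' `...-2`) are preserved as digits, so distinct genomic loci of the same
#' mature miRNA stay distinct (`hsa-miR-486-1` -> `mir4861`,
#' `hsa-miR-486-2` -> `mir4862`).
#'
#' Only a *terminal* arm token is stripped, never an interior `-5p`-like
#' substring, so `hsa-miR-129-2-3p` keeps the locus digit and becomes
#' `mir1292`. A leading `mir-`/`let-`/`lin-` token is a miRNA stem, not a
#' species prefix, and is never stripped.
#'
#' @param raw_id character vector of platform-specific miRNA identifiers.
#' @return character vector of base identifiers, same length as `raw_id`.
#'   The map is idempotent: `harmonize_mirna_id(harmonize_mirna_id(x))`
#'   equals `harmonize_mirna_id(x)`.
#' @examples
#' harmonize_mirna_id("hsa-miR-129-2-3p")  # "mir1292"
#' harmonize_mirna_id("hsa-let-7a-5p")     # "let7a"
#' @export
harmonize_mirna_id <- function(raw_id) {
  if (length(raw_id) == 0L) return(character(0))
  stopifnot(is.character(raw_id))
  if (anyNA(raw_id) || any(!nzchar(raw_id))) {
    stop("miRNA identifiers must be non-empty strings")
  }
  x <- tolower(raw_id)
  # species prefix: three letters + hyphen, but never the miRNA stem itself
  has_prefix <- grepl("^[a-z]{3}-", x) &
    !grepl("^(mir|let|lin)-", x)
  x[has_prefix] <- sub("^[a-z]{3}-", "", x[has_prefix])
  # one terminal mature-arm token only
  x <- sub("-[53]p$", "", x)
  x <- gsub("-", "", x, fixed = TRUE)
  bad <- !nzchar(x)
  if (any(bad)) {
    stop("harmonization left an empty identifier for input(s): ",
         paste(sQuote(raw_id[bad]), collapse = ", "))
  }
  x
}

#' Group raw miRNA identifiers by their harmonized base id
#'
#' Builds the join index used during integration: every raw identifier is
#' assigned to exactly one base id, and identifiers that collapse to the
#' same base (for example the -5p and -3p arms of one locus) are grouped
#' rather than dropped.
#'
#' @param ids character vector of raw miRNA identifiers.
#' @return named list; names are base ids, elements are character vectors
#'   of the raw ids mapping to that base.
#' @examples
#' build_join_index(c("hsa-miR-7-2", "hsa-miR-7-2-3p"))
#' @export
build_join_index <- function(ids) {
  if (length(ids) == 0L) return(structure(list(), names = character(0)))
  base <- harmonize_mirna_id(ids)
  split(ids, base)
}
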