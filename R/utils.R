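`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical SMILES. Strings that do not parse
#' to a valid molecule are returned as `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' \donttest{
#' canonical_smiles(c("c1ccccc1C(=O)N", "NC(=O)c1ccccc1"))  # identical output
#' }
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# SMILES vector -> SDFset, dropping invalid entries (returns index map)
smiles_to_sdfset <- function(smiles, names = NULL) {
  names <- names %||% paste0("CMP", seq_along(smiles))
  ok <- !is.na(canonical_smiles(smiles))
  if (!any(ok)) stop_arg("no valid structures to convert")
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles[ok], names[ok]))
  attr(sdf, "source_index") <- which(ok)
  sdf
}

# Count SMARTS matches per molecule of an SDFset
smarts_match <- function(sdfset, smarts) {
  as.integer(ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = FALSE)) > 0
}

# Euclidean distance matrix between two coordinate matrices (n x 3, m x 3)
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
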