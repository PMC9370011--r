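# Protein sequence records with offset (reported) residue numbering.

#' Construct a protein record
#'
#' A `protein_record` carries an uppercase amino-acid sequence together with
#' a numbering offset so that positions can be reported in the numbering of
#' the full-length protein even when only a domain is analyzed: the reported
#' position of residue `i` (1-based index into `residues`) is `i + offset`.
#' For the core domain of p53 (residues 94-297) the offset is 93.
#'
#' @param residues amino-acid sequence (one string); lowercase is accepted
#'   and uppercased.
#' @param id record identifier.
#' @param offset integer added to 1-based indices to obtain reported
#'   positions.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(residues, id = "protein", offset = 0L) {
  if (!is.character(residues) || length(residues) != 1L || nchar(residues) == 0L)
    stop("'residues' must be a single non-empty string")
  residues <- toupper(residues)
  offset <- as.integer(offset)
  if (is.na(offset)) stop("'offset' must be an integer")
  structure(
    list(id = as.character(id), residues = residues, offset = offset),
    class = "protein_record"
  )
}

#' @export
length.protein_record <- function(x) nchar(x$residues)

# Reported (offset) position -> 1-based internal index, with bounds check.
pos_to_index <- function(protein, position) {
  idx <- as.integer(position) - protein$offset
  n <- nchar(protein$residues)
  if (any(idx < 1L) || any(idx > n))
    stop("position ", paste(position[idx < 1L | idx > n], collapse = ", "),
         " outside record '", protein$id, "' (",
         protein$offset + 1L, "-", protein$offset + n, ")")
  idx
}

index_to_pos <- function(protein, index) as.integer(index) + protein$offset

# Substring in reported numbering, inclusive on both ends.
protein_segment <- function(protein, from, to) {
  i <- pos_to_index(protein, from)
  j <- pos_to_index(protein, to)
  substr(protein$residues, i, j)
}

#' @export
print.protein_record <- function(x, ...) {
  n <- nchar(x$residues)
  cat("Protein record:", x$id, "\n")
  cat("  ", n, " residues, numbered ", x$offset + 1L, "-", x$offset + n, "\n",
      sep = "")
  seq_show <- if (n > 60L) paste0(substr(x$residues, 1L, 57L), "...") else x$residues
  cat("  ", seq_show, "\n", sep = "")
  invisible(x)
}
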