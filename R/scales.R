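# Hydrophobicity scales: named per-residue free-energy-of-transfer values.

# Fauchere & Pliska (1983) octanol/water side-chain transfer values (pi),
# glycine as the zero reference. Units: scale units; 0.45 units ~ 1 kT.
.FAUCHERE_PLISKA <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22
)

.SCALE_REGISTRY <- list("fauchere-pliska" = .FAUCHERE_PLISKA)

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a hydrophobicity scale
#'
#' A `hydro_scale` maps each of the 20 standard amino-acid one-letter codes
#' to a unitless free-energy-of-transfer value \eqn{h_k}. The conversion
#' factor `kT_conversion` (default 0.45 scale units per kT, with an error
#' margin of about 0.1 kT per conversion) turns summed window
#' hydrophobicities into thermal energy units.
#'
#' @param values named numeric vector with exactly the 20 standard residues.
#' @param name scale identifier.
#' @param kT_conversion scale units equivalent to one kT; must be positive.
#' @param unit_margin_kT stated error margin of one conversion, in kT.
#' @return An object of class `hydro_scale`.
#' @seealso [load_scale()] for the built-in registry, [read_hydro_scale()]
#'   for custom two-column files.
#' @export
hydro_scale <- function(values, name = "custom", kT_conversion = 0.45,
                        unit_margin_kT = 0.1) {
  if (is.null(names(values)) || anyNA(values) || !is.numeric(values))
    stop("'values' must be a named numeric vector without NA")
  names(values) <- toupper(names(values))
  missing <- setdiff(.AA20, names(values))
  extra <- setdiff(names(values), .AA20)
  if (length(missing) > 0L)
    stop("scale is missing standard residues: ", paste(missing, collapse = ", "))
  if (length(extra) > 0L)
    stop("scale has non-standard residue letters: ", paste(extra, collapse = ", "))
  if (!is.numeric(kT_conversion) || length(kT_conversion) != 1L || kT_conversion <= 0)
    stop("'kT_conversion' must be a single positive number")
  structure(
    list(name = name, values = values[.AA20],
         kT_conversion = kT_conversion, unit_margin_kT = unit_margin_kT),
    class = "hydro_scale"
  )
}

#' Load a registered hydrophobicity scale by name
#'
#' The built-in registry contains `"fauchere-pliska"`, the experimental
#' octanol/water side-chain transfer scale used to score early hydrophobic
#' contacts.
#'
#' @param name registered scale identifier.
#' @return A [hydro_scale()] object.
#' @examples
#' sc <- load_scale("fauchere-pliska")
#' sc$values[["W"]]  # tryptophan, the most hydrophobic residue
#' @export
load_scale <- function(name = "fauchere-pliska") {
  if (!is.character(name) || length(name) != 1L || !(name %in% names(.SCALE_REGISTRY)))
    stop("unknown scale '", name, "'; registered scales: ",
         paste(names(.SCALE_REGISTRY), collapse = ", "))
  hydro_scale(.SCALE_REGISTRY[[name]], name = name)
}

#' Read a custom hydrophobicity scale from a two-column text file
#'
#' The file holds one residue per line: a one-letter code and a numeric
#' value, whitespace- or comma-separated. All 20 standard residues must be
#' present.
#'
#' @param path file path.
#' @param name identifier for the resulting scale.
#' @param kT_conversion scale units per kT.
#' @return A [hydro_scale()] object.
#' @export
read_hydro_scale <- function(path, name = basename(path), kT_conversion = 0.45) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("letter", "value"),
                           colClasses = c("character", "numeric"),
                           comment.char = "#")
  values <- stats::setNames(tab$value, tab$letter)
  hydro_scale(values, name = name, kT_conversion = kT_conversion)
}

# Per-residue lookup with a policy for non-standard letters (X, U, B, Z, ...):
# "error" aborts; "zero" assigns h = 0 with a warning (silent zeros would
# bias the contact free energy, so the default is the hard error).
scale_lookup <- function(scale, letters, nonstandard = c("error", "zero")) {
  nonstandard <- match.arg(nonstandard)
  h <- unname(scale$values[letters])
  bad <- is.na(h)
  if (any(bad)) {
    letters_bad <- unique(letters[bad])
    if (nonstandard == "error")
      stop("non-standard residue letter(s): ", paste(letters_bad, collapse = ", "),
           "; use nonstandard = \"zero\" to assign h = 0")
    warning("assigning h = 0 to non-standard residue letter(s): ",
            paste(letters_bad, collapse = ", "))
    h[bad] <- 0
  }
  h
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat("Hydrophobicity scale:", x$name, "\n")
  cat("  ", length(x$values), "residues;", x$kT_conversion,
      "scale units per kT (margin ~", x$unit_margin_kT, "kT)\n")
  print(round(x$values, 2))
  invisible(x)
}
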