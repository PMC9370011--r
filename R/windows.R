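# Windowed segment hydrophobicities: the h_{i,w} sums that enter the
# contact free energy.

# Window extent around a center, in internal index space. Odd widths are
# centered (center +/- (w-1)/2). Even widths are accepted as a special case
# with the center sitting just left of the midpoint (e.g. w = 4 covers
# center-1 ... center+2); documented, not padded.
window_bounds <- function(center_idx, width) {
  start <- center_idx - (width - 1L) %/% 2L
  c(start = start, end = start + width - 1L)
}

#' Segment hydrophobicity of one window
#'
#' Sums per-residue hydrophobicity values over a contact window of `width`
#' residues centered at `center` (reported numbering), giving the segment
#' hydrophobicity \eqn{h_{i,w}} in scale units. Windows overhanging either
#' terminus are an error (they are skipped, not padded, during a scan).
#'
#' @param protein a [protein_record()].
#' @param center window center in reported (offset) numbering.
#' @param width window size in residues (default 5). Odd widths are
#'   centered; width 4 is accepted left-anchored.
#' @param scale a [hydro_scale()].
#' @param nonstandard policy for non-standard residue letters: `"error"`
#'   (default) or `"zero"` (assign 0 with a warning).
#' @return A `segment_window`: list with `center`, `width`, `sequence`,
#'   `span` (reported start/end) and `h_sum`.
#' @examples
#' p53 <- p53_core_fixture()
#' fp <- load_scale("fauchere-pliska")
#' window_hydrophobicity(p53, center = 253, width = 5, scale = fp)$h_sum # 7.36
#' @export
window_hydrophobicity <- function(protein, center, width = 5L,
                                  scale = load_scale(),
                                  nonstandard = c("error", "zero")) {
  stopifnot(inherits(protein, "protein_record"), inherits(scale, "hydro_scale"))
  width <- as.integer(width)
  if (width < 1L) stop("'width' must be >= 1")
  ci <- pos_to_index(protein, center)
  b <- window_bounds(ci, width)
  n <- nchar(protein$residues)
  if (b["start"] < 1L || b["end"] > n)
    stop("window of width ", width, " at center ", center,
         " overhangs a terminus of '", protein$id, "'")
  seq_w <- substr(protein$residues, b["start"], b["end"])
  h <- scale_lookup(scale, strsplit(seq_w, "")[[1]], nonstandard = nonstandard)
  structure(
    list(center = as.integer(center), width = width, sequence = seq_w,
         span = c(index_to_pos(protein, b["start"]),
                  index_to_pos(protein, b["end"])),
         h_sum = sum(h)),
    class = "segment_window"
  )
}

#' Sliding-window hydrophobicity profile
#'
#' Computes \eqn{h_{i,w}} for every admissible window center, in position
#' order. A sequence of length `n` yields `n - width + 1` windows.
#'
#' @inheritParams window_hydrophobicity
#' @return A data frame with one row per window: `center` (reported
#'   numbering), `start`, `end`, `sequence`, `h_sum`.
#' @export
hydrophobicity_profile <- function(protein, width = 5L, scale = load_scale(),
                                   nonstandard = c("error", "zero")) {
  stopifnot(inherits(protein, "protein_record"), inherits(scale, "hydro_scale"))
  width <- as.integer(width)
  n <- nchar(protein$residues)
  if (n < width)
    stop("sequence of length ", n, " is shorter than window width ", width)
  letters <- strsplit(protein$residues, "")[[1]]
  h <- scale_lookup(scale, letters, nonstandard = nonstandard)
  # direct left-to-right summation per window (not a cumsum difference), so
  # equal windows give bitwise-equal sums regardless of position
  starts <- seq_len(n - width + 1L)
  h_sum <- vapply(starts, function(s) sum(h[s:(s + width - 1L)]), numeric(1))
  centers_idx <- starts + (width - 1L) %/% 2L
  data.frame(
    center = index_to_pos(protein, centers_idx),
    start = index_to_pos(protein, starts),
    end = index_to_pos(protein, starts + width - 1L),
    sequence = substring(protein$residues, starts, starts + width - 1L),
    h_sum = h_sum,
    stringsAsFactors = FALSE
  )
}
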