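# Primary-contact scan: score all admissible non-local window pairs and
# select the distinct candidate primary contacts.

#' Scan configuration
#'
#' Parameters of the primary-contact scan. The defaults encode the model's
#' operating regime: 5-residue contact windows, loop separations between the
#' optimal minimal loop (`min_separation` = 65 residues, below which early
#' loop closure is entropically disfavored) and the maximum viable primary
#' loop (`max_separation` = 100), a reporting cutoff of 3 kT below the best
#' contact, a side-chain ordering cost of 1.09 kT per contact residue, and a
#' loop-entropy exponent of 3/2 (`dG_loop = 1.5 ln n_ij` kT).
#'
#' @param width window size per segment, residues.
#' @param min_separation minimum center-to-center separation, residues.
#' @param max_separation maximum center-to-center separation, residues.
#' @param cutoff_kT contacts more than this much less stable than the best
#'   one are dropped from the report.
#' @param sidechain_cost_per_residue side-chain entropic cost, kT per
#'   contact residue; the contact involves `2 * width` residues, so the
#'   default pair cost is 1.09 * 10 = 10.9 kT at width 5.
#' @param loop_exponent coefficient of `ln(n_ij)` in the loop term.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(width = 5L, min_separation = 65L, max_separation = 100L,
                        cutoff_kT = 3.0, sidechain_cost_per_residue = 1.09,
                        loop_exponent = 1.5) {
  width <- as.integer(width)
  min_separation <- as.integer(min_separation)
  max_separation <- as.integer(max_separation)
  if (width < 1L) stop("'width' must be >= 1")
  if (min_separation < 1L || min_separation > max_separation)
    stop("need 0 < min_separation <= max_separation")
  if (cutoff_kT < 0) stop("'cutoff_kT' must be >= 0")
  structure(
    list(width = width, min_separation = min_separation,
         max_separation = max_separation, cutoff_kT = cutoff_kT,
         sidechain_cost_per_residue = sidechain_cost_per_residue,
         loop_exponent = loop_exponent),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat("Primary-contact scan configuration\n")
  cat("  window width:        ", x$width, "residues\n")
  cat("  separation n_ij:     ", x$min_separation, "-", x$max_separation,
      "residues (inclusive)\n")
  cat("  reporting cutoff:    ", x$cutoff_kT, "kT below best contact\n")
  cat("  side-chain cost:     ", x$sidechain_cost_per_residue, "kT/residue (",
      x$sidechain_cost_per_residue * 2 * x$width, "kT per contact )\n")
  cat("  loop-entropy term:   ", x$loop_exponent, "* ln(n_ij) kT\n")
  invisible(x)
}

# Vectorized free-energy decomposition. All terms in kT:
#   dG_hyd       = -(h_a + h_b) / kT_conversion     (stabilizing, <= 0 for
#                                                    hydrophobic segments)
#   dG_loop      = loop_exponent * ln(n_ij)         (loop-closure entropy)
#   dG_sidechain = cost_per_residue * 2 * width     (side-chain ordering)
contact_energy_terms <- function(h_a, h_b, n_ij, config, kT_conversion = 0.45) {
  if (any(n_ij < 1)) stop("'n_ij' must be >= 1")
  dG_hyd <- -(h_a + h_b) / kT_conversion
  dG_loop <- config$loop_exponent * log(n_ij)
  dG_sidechain <- rep_len(config$sidechain_cost_per_residue * 2 * config$width,
                          length(dG_loop))
  data.frame(dG_hyd = dG_hyd, dG_loop = dG_loop, dG_sidechain = dG_sidechain,
             dG_total = dG_hyd + dG_loop + dG_sidechain)
}

#' Contact free energy of a segment pair
#'
#' Evaluates the contact free energy (in kT) of two hydrophobic windows with
#' summed hydrophobicities `h_a` and `h_b` separated by `n_ij` residues:
#' \deqn{\Delta G_{cont} = -\frac{h_a + h_b}{0.45} +
#'       \frac{3}{2}\ln n_{ij} + 1.09\,(2w)}
#' Negative values are stabilizing; the reported "stability" is the
#' magnitude of a negative total. The constant side-chain term (10.9 kT at
#' the default width 5) is generated from the per-residue cost, never
#' hard-coded. Vectorized over its numeric arguments.
#'
#' @param h_a,h_b segment hydrophobicities in scale units.
#' @param n_ij center-to-center separation in residues (>= 1).
#' @param config a [scan_config()].
#' @param kT_conversion scale units per kT (the scale's conversion factor).
#' @return Numeric vector of total free energies in kT, with the three
#'   components attached as a data frame in attribute `"components"`.
#' @examples
#' # the dominant core-p53 contact: AMAIY (4.61) on ILTII (7.36), n_ij = 92
#' contact_free_energy(4.61, 7.36, 92)  # about -8.9 kT
#' @export
contact_free_energy <- function(h_a, h_b, n_ij, config = scan_config(),
                                kT_conversion = 0.45) {
  terms <- contact_energy_terms(h_a, h_b, n_ij, config, kT_conversion)
  structure(terms$dG_total, components = terms)
}

#' Enumerate and score all admissible window pairs
#'
#' Scores every ordered pair of window centers `(a, b)` with
#' `min_separation <= b - a <= max_separation`, each pair exactly once.
#' Centers too close to a terminus for a full window are skipped.
#'
#' @param protein a [protein_record()].
#' @param scale a [hydro_scale()].
#' @param config a [scan_config()].
#' @param nonstandard policy for non-standard residue letters.
#' @return A data frame (the scored grid), one row per pair: window spans
#'   and sequences, `n_ij`, the three energy components, `dG_total` and
#'   `stability_kT = -dG_total`. Zero rows (with a warning) when no pair is
#'   admissible.
#' @export
enumerate_candidates <- function(protein, scale = load_scale(),
                                 config = scan_config(),
                                 nonstandard = c("error", "zero")) {
  stopifnot(inherits(protein, "protein_record"), inherits(config, "scan_config"))
  prof <- hydrophobicity_profile(protein, width = config$width, scale = scale,
                                 nonstandard = nonstandard)
  nc <- nrow(prof)
  sep <- outer(prof$center, prof$center, function(a, b) b - a)
  ok <- which(sep >= config$min_separation & sep <= config$max_separation,
              arr.ind = TRUE)
  if (nrow(ok) == 0L) {
    warning("no admissible window pair for '", protein$id,
            "' (length ", nchar(protein$residues), ", separation ",
            config$min_separation, "-", config$max_separation, ")")
    return(empty_grid())
  }
  ia <- ok[, 1L]
  ib <- ok[, 2L]
  n_ij <- prof$center[ib] - prof$center[ia]
  terms <- contact_energy_terms(prof$h_sum[ia], prof$h_sum[ib], n_ij, config,
                                kT_conversion = scale$kT_conversion)
  grid <- data.frame(
    center_a = prof$center[ia], center_b = prof$center[ib],
    seg_a_start = prof$start[ia], seg_a_end = prof$end[ia],
    seg_a_seq = prof$sequence[ia],
    seg_b_start = prof$start[ib], seg_b_end = prof$end[ib],
    seg_b_seq = prof$sequence[ib],
    n_ij = n_ij, h_a = prof$h_sum[ia], h_b = prof$h_sum[ib],
    terms,
    stability_kT = -terms$dG_total,
    stringsAsFactors = FALSE
  )
  grid[order_candidates(grid), , drop = FALSE]
}

empty_grid <- function() {
  data.frame(center_a = integer(), center_b = integer(),
             seg_a_start = integer(), seg_a_end = integer(),
             seg_a_seq = character(),
             seg_b_start = integer(), seg_b_end = integer(),
             seg_b_seq = character(),
             n_ij = integer(), h_a = numeric(), h_b = numeric(),
             dG_hyd = numeric(), dG_loop = numeric(),
             dG_sidechain = numeric(), dG_total = numeric(),
             stability_kT = numeric(), stringsAsFactors = FALSE)
}

# Deterministic ranking: lower dG_total first, then smaller n_ij, then
# smaller a-center, then smaller b-center.
order_candidates <- function(grid) {
  order(grid$dG_total, grid$n_ij, grid$center_a, grid$center_b)
}

intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' Select the distinct primary contacts from a scored grid
#'
#' Applies non-maximum suppression and a stability cutoff. A candidate is
#' retained only if no better-scoring candidate exists whose N-terminal AND
#' C-terminal windows both overlap its own — so shifted variants of one
#' contact collapse to their local optimum, while candidates sharing only
#' one segment remain distinct contacts. Retained candidates within
#' `cutoff_kT` of the best are ranked most stable first and labelled C1,
#' C2, ...
#'
#' @param grid scored candidate grid from [enumerate_candidates()].
#' @param config the [scan_config()] used to build the grid.
#' @param protein_id identifier recorded in the result.
#' @return An object of class `contact_set`: list with `contacts` (ranked
#'   data frame with `label` and `rank` columns), `config`, `protein_id`.
#' @export
select_primary_contacts <- function(grid, config = scan_config(),
                                    protein_id = "protein") {
  if (nrow(grid) == 0L) {
    return(structure(list(contacts = cbind(label = character(), rank = integer(),
                                           empty_grid()),
                          config = config, protein_id = protein_id),
                     class = "contact_set"))
  }
  grid <- grid[order_candidates(grid), , drop = FALSE]
  best <- grid$dG_total[1L]
  # every candidate that can either survive the cutoff or suppress one lies
  # within the cutoff itself (a suppressor is more stable than its victim)
  pool <- grid[grid$dG_total <= best + config$cutoff_kT, , drop = FALSE]
  keep <- rep(TRUE, nrow(pool))
  if (nrow(pool) > 1L) {
    for (i in 2L:nrow(pool)) {
      better <- seq_len(i - 1L)  # pool is in ranking order
      keep[i] <- !any(
        intervals_overlap(pool$seg_a_start[i], pool$seg_a_end[i],
                          pool$seg_a_start[better], pool$seg_a_end[better]) &
        intervals_overlap(pool$seg_b_start[i], pool$seg_b_end[i],
                          pool$seg_b_start[better], pool$seg_b_end[better])
      )
    }
  }
  contacts <- pool[keep, , drop = FALSE]
  rownames(contacts) <- NULL
  contacts <- cbind(label = paste0("C", seq_len(nrow(contacts))),
                    rank = seq_len(nrow(contacts)), contacts,
                    stringsAsFactors = FALSE)
  structure(list(contacts = contacts, config = config, protein_id = protein_id),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("Primary contacts for", x$protein_id, "\n")
  if (nrow(x$contacts) == 0L) {
    cat("  (none)\n")
    return(invisible(x))
  }
  print(format_contact_table(x$contacts), row.names = FALSE)
  invisible(x)
}

# Contact-table display: spans, n_ij, stability to 1 decimal.
format_contact_table <- function(contacts) {
  data.frame(
    contact = contacts$label,
    segment_a = sprintf("%d-%d %s", contacts$seg_a_start, contacts$seg_a_end,
                        contacts$seg_a_seq),
    segment_b = sprintf("%d-%d %s", contacts$seg_b_start, contacts$seg_b_end,
                        contacts$seg_b_seq),
    n_ij = contacts$n_ij,
    stability_kT = sprintf("%.1f", contacts$stability_kT),
    stringsAsFactors = FALSE
  )
}
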