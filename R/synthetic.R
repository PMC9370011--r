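# Synthetic sequence generation (controlled composition, planted
# hydrophobic segment pairs), an independent brute-force scoring oracle,
# and the embedded core-p53 worked example.

#' Specification for a synthetic protein sequence
#'
#' Describes an i.i.d. random background sequence with optional planted
#' segments that overwrite the background at fixed positions — the device
#' used to construct sequences with known best contacts (a pair of strongly
#' hydrophobic 5-mers at a chosen separation in a polar background).
#'
#' @param length sequence length in residues.
#' @param composition named sampling probabilities over residue letters;
#'   default uniform over the 20 standard residues. Must sum to 1.
#' @param seed integer seed; generation is deterministic given the spec.
#' @param plants list of `list(sequence, start)` insertions (1-based start);
#'   plants must fit inside the sequence and must not overlap one another.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(length, composition = NULL, seed = 1L,
                           plants = list()) {
  length <- as.integer(length)
  if (length < 1L) stop("'length' must be >= 1")
  if (is.null(composition))
    composition <- stats::setNames(rep(1 / 20, 20), .AA20)
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition probabilities must sum to 1")
  if (is.null(names(composition)))
    stop("'composition' must be named by residue letter")
  spans <- lapply(plants, function(p) {
    s <- as.integer(p$start)
    e <- s + nchar(p$sequence) - 1L
    if (s < 1L || e > length)
      stop("plant '", p$sequence, "' at ", s, " does not fit in length ", length)
    c(s, e)
  })
  if (length(spans) > 1L) {
    for (i in 2L:length(spans)) for (j in 1L:(i - 1L)) {
      if (spans[[i]][1] <= spans[[j]][2] && spans[[j]][1] <= spans[[i]][2])
        stop("planted segments ", i, " and ", j, " overlap")
    }
  }
  structure(
    list(length = length, composition = composition,
         seed = as.integer(seed), plants = plants),
    class = "generator_spec"
  )
}

#' Generate a synthetic protein sequence
#'
#' Draws the background i.i.d. from the spec's composition under the spec's
#' seed (the caller's RNG state is preserved), then overwrites the planted
#' segments at their stated positions.
#'
#' @param spec a [generator_spec()].
#' @param id identifier for the resulting record.
#' @return A [protein_record()] with offset 0.
#' @export
generate_sequence <- function(spec, id = sprintf("synthetic_seed%d", spec$seed)) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  letters <- sample(names(spec$composition), spec$length, replace = TRUE,
                    prob = spec$composition)
  for (p in spec$plants) {
    s <- as.integer(p$start)
    letters[s:(s + nchar(p$sequence) - 1L)] <- strsplit(toupper(p$sequence), "")[[1]]
  }
  protein_record(paste(letters, collapse = ""), id = id, offset = 0L)
}

#' Brute-force scoring oracle
#'
#' Re-scores every admissible window pair with an independently coded
#' evaluation of the contact free energy — explicit per-residue summation
#' and a plain double loop over centers, sharing no code with
#' [enumerate_candidates()]. Exists purely as a verification oracle: on any
#' input the two grids must agree pair for pair.
#'
#' @inheritParams enumerate_candidates
#' @return A data frame with columns `center_a`, `center_b`, `n_ij`,
#'   `dG_total`, ordered by the same deterministic ranking as the scan.
#' @export
oracle_scan <- function(protein, scale = load_scale(), config = scan_config()) {
  stopifnot(inherits(protein, "protein_record"))
  res <- strsplit(protein$residues, "")[[1]]
  n <- length(res)
  w <- config$width
  half <- (w - 1L) %/% 2L
  first_center <- 1L + half
  last_center <- n - (w - 1L - half)
  if (last_center < first_center)
    stop("sequence of length ", n, " is shorter than window width ", w)
  win_sum <- function(center_idx) {
    total <- 0
    for (k in (center_idx - half):(center_idx - half + w - 1L)) {
      h <- scale$values[[res[k]]]
      if (is.null(h)) stop("non-standard residue letter: ", res[k])
      total <- total + h
    }
    total
  }
  rows <- list()
  for (ia in first_center:last_center) {
    for (ib in first_center:last_center) {
      d <- ib - ia
      if (d < config$min_separation || d > config$max_separation) next
      dg <- -(win_sum(ia) + win_sum(ib)) / scale$kT_conversion +
        config$loop_exponent * log(d) +
        config$sidechain_cost_per_residue * 2 * w
      rows[[length(rows) + 1L]] <- c(ia, ib, d, dg)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(center_a = integer(), center_b = integer(),
                      n_ij = integer(), dG_total = numeric()))
  m <- do.call(rbind, rows)
  out <- data.frame(center_a = as.integer(m[, 1]) + protein$offset,
                    center_b = as.integer(m[, 2]) + protein$offset,
                    n_ij = as.integer(m[, 3]), dG_total = m[, 4])
  out <- out[order(out$dG_total, out$n_ij, out$center_a, out$center_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Core domain (DNA-binding domain) of canonical human p53, residues 94-297.
.P53_CORE <- paste0(
  "SSSVPSQKTYQGSYGFRLGFLHSGTAKSVTCTYSPALNKMFCQLAKTCPVQLWVDSTPPP",
  "GTRVRAMAIYKQSQHMTEVVRRCPHHERCSDSDGLAPPQHLIRVEGNLRVEYLDDRNTFR",
  "HSVVVPYEPPEVGSDCTTIHYNYMCNSSCMGGMNRRPILTIITLEDSSGNLLGRNSFEVR",
  "VCACPGRDRRTEEENLRKKGEPHH"
)

#' The core-p53 worked example
#'
#' Returns the 204-residue DNA-binding core domain of human p53 (residues
#' 94-297 of the canonical sequence) with the numbering offset set so that
#' positions report in full-length p53 numbering. Before returning, the
#' record is checked against the segment spans the analysis depends on
#' (AMAIY at 159-163, ILTII at 251-255, VQLWV at 143-147, VVVPY at 216-220,
#' YNYMC at 234-238, MFCQL at 133-137, PILTIITL at 250-257), so any
#' transcription error in the embedded constant fails loudly.
#'
#' @return A [protein_record()] with id `"core_p53"` and offset 93.
#' @examples
#' p53 <- p53_core_fixture()
#' length(p53)  # 204
#' @export
p53_core_fixture <- function() {
  rec <- protein_record(.P53_CORE, id = "core_p53", offset = 93L)
  checks <- list(
    c(159, 163, "AMAIY"), c(251, 255, "ILTII"), c(143, 147, "VQLWV"),
    c(216, 220, "VVVPY"), c(234, 238, "YNYMC"), c(133, 137, "MFCQL"),
    c(250, 257, "PILTIITL")
  )
  for (ck in checks) {
    got <- protein_segment(rec, as.integer(ck[1]), as.integer(ck[2]))
    if (got != ck[3])
      stop("core-p53 fixture integrity failure at ", ck[1], "-", ck[2],
           ": expected ", ck[3], ", got ", got)
  }
  if (nchar(rec$residues) != 204L)
    stop("core-p53 fixture integrity failure: length ", nchar(rec$residues))
  rec
}
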