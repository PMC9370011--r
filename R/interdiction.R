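# Folding-interdiction analysis: map an exogenous peptide onto the primary
# contacts it can block, score its attachment, and model how blocked
# folding flux redistributes among the surviving channels.

#' FIP/FITR designations of a contact
#'
#' A primary contact between segments A and B yields two interdiction
#' designs: either segment can serve as the template of the folding
#' interdicting peptide (FIP) while the other is the folding interdiction
#' target region (FITR) that the peptide competes for.
#'
#' @param contact one row of a selected-contacts data frame (or an
#'   `scm_scan` fit plus a `label`).
#' @param label when `contact` is an `scm_scan` fit, the contact label to
#'   use (default the top-ranked contact).
#' @return A list of two `fitr_designation` objects, each with
#'   `contact_label`, `fip_template` (sequence + span) and `fitr`
#'   (sequence + span).
#' @examples
#' fit <- scm_scan(p53_core_fixture())
#' fitr_pairs(fit, "C1")  # ILTII targeting AMAIY, and the converse
#' @export
fitr_pairs <- function(contact, label = NULL) {
  if (inherits(contact, "scm_scan")) {
    ct <- contact$contacts$contacts
    if (is.null(label)) label <- ct$label[1L]
    contact <- ct[ct$label == label, , drop = FALSE]
    if (nrow(contact) == 0L) stop("no contact labelled '", label, "'")
  }
  stopifnot(is.data.frame(contact), nrow(contact) == 1L)
  seg <- function(which) {
    list(sequence = contact[[paste0("seg_", which, "_seq")]],
         span = c(contact[[paste0("seg_", which, "_start")]],
                  contact[[paste0("seg_", which, "_end")]]))
  }
  a <- seg("a")
  b <- seg("b")
  mk <- function(fip, fitr) structure(
    list(contact_label = contact$label, fip_template = fip, fitr = fitr),
    class = "fitr_designation"
  )
  list(mk(a, b), mk(b, a))
}

#' @export
print.fitr_designation <- function(x, ...) {
  cat("Contact ", x$contact_label, ": FIP template ", x$fip_template$sequence,
      " (", x$fip_template$span[1], "-", x$fip_template$span[2],
      ") targeting FITR ", x$fitr$sequence,
      " (", x$fitr$span[1], "-", x$fitr$span[2], ")\n", sep = "")
  invisible(x)
}

#' Map a peptide onto the primary contacts it can interdict
#'
#' A peptide is assigned to a contact when it covers one of the contact's
#' segments as an exact substring alignment against the native sequence
#' with at least `min_overlap` matching residues. Each match is reported in
#' both interdiction modes: `"partner"` (the peptide mimics the matched
#' segment and competes for the contact's other segment) and `"mask"` (the
#' peptide binds the matched segment itself, masking it). Which mode
#' dominates is an open experimental question, so both are listed.
#'
#' @param peptide peptide sequence (string).
#' @param fit an `scm_scan` fit (supplies the protein and contact set).
#' @param min_overlap minimum number of peptide residues that must align
#'   with a contact segment (default 5).
#' @param max_mismatch allowed mismatches in the alignment (default 0,
#'   exact matching).
#' @param seed logical flag marking the assignment as arising from
#'   polymeric peptide seeds rather than monomer; recorded, not modeled.
#' @return A data frame of assignments, zero rows when the peptide matches
#'   nothing: `peptide`, `contact_label`, `matched_segment` (`"a"` or
#'   `"b"`), `segment_seq`, `segment_span`, `mode`, `overlap_length`,
#'   `attachment_score_kT`, `seed`.
#' @examples
#' fit <- scm_scan(p53_core_fixture())
#' map_peptide_to_contacts("PILTIITL", fit)  # covers ILTII, interdicts C1
#' @export
map_peptide_to_contacts <- function(peptide, fit, min_overlap = 5L,
                                    max_mismatch = 0L, seed = FALSE) {
  stopifnot(inherits(fit, "scm_scan"))
  peptide <- toupper(peptide)
  if (nchar(peptide) == 0L) stop("'peptide' must be non-empty")
  ct <- fit$contacts$contacts
  out <- list()
  for (i in seq_len(nrow(ct))) {
    for (which in c("a", "b")) {
      seg_seq <- ct[[paste0("seg_", which, "_seq")]][i]
      span <- c(ct[[paste0("seg_", which, "_start")]][i],
                ct[[paste0("seg_", which, "_end")]][i])
      ov <- best_overlap(peptide, seg_seq, max_mismatch)
      if (ov < min_overlap) next
      partner <- if (which == "a") "b" else "a"
      att <- attachment_pair_score(fit, ct[i, ], which)
      for (mode in c("partner", "mask")) {
        out[[length(out) + 1L]] <- data.frame(
          peptide = peptide, contact_label = ct$label[i],
          matched_segment = which, segment_seq = seg_seq,
          segment_span = sprintf("%d-%d", span[1], span[2]),
          mode = mode, overlap_length = ov,
          attachment_score_kT = att, seed = seed,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(peptide = character(), contact_label = character(),
                      matched_segment = character(), segment_seq = character(),
                      segment_span = character(), mode = character(),
                      overlap_length = integer(),
                      attachment_score_kT = numeric(), seed = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Longest run of residues of `segment` matched inside `peptide` allowing up
# to max_mismatch substitutions; with the default 0 this is plain substring
# containment of the (full) segment, else the best windowed alignment.
best_overlap <- function(peptide, segment, max_mismatch = 0L) {
  np <- nchar(peptide)
  ns <- nchar(segment)
  if (np < ns) return(0L)
  pep <- strsplit(peptide, "")[[1]]
  seg <- strsplit(segment, "")[[1]]
  best <- 0L
  for (s in seq_len(np - ns + 1L)) {
    mism <- sum(pep[s:(s + ns - 1L)] != seg)
    if (mism <= max_mismatch) best <- max(best, ns - mism)
  }
  best
}

# Attachment of the peptide (modelled by the matched segment's own window)
# to the contact's partner segment.
attachment_pair_score <- function(fit, contact_row, matched) {
  partner <- if (matched == "a") "b" else "a"
  h_m <- if (matched == "a") contact_row$h_a else contact_row$h_b
  h_p <- if (partner == "a") contact_row$h_a else contact_row$h_b
  attachment_energy(h_m, h_p, fit$config, fit$scale$kT_conversion)
}

attachment_energy <- function(h_pep, h_target, config, kT_conversion = 0.45) {
  -(h_pep + h_target) / kT_conversion +
    config$sidechain_cost_per_residue * 2 * config$width
}

#' Intermolecular attachment score of two segment windows
#'
#' Scores the attachment of a peptide window to a target window with the
#' contact free energy minus the loop term: an intermolecular contact
#' closes no loop, so only the hydrophobic stabilization and the side-chain
#' ordering cost remain. This is a model extension beyond the intramolecular
#' scan (no intermolecular formula is part of the scan itself) and is
#' flagged as such in reports.
#'
#' @param peptide_window,target_window `segment_window` objects of equal
#'   width (from [window_hydrophobicity()]).
#' @param config a [scan_config()].
#' @param kT_conversion scale units per kT.
#' @return Attachment free energy in kT (negative = favorable). Always at
#'   least as favorable as the corresponding intramolecular contact, since
#'   the dropped loop term is non-negative.
#' @export
attachment_score <- function(peptide_window, target_window,
                             config = scan_config(), kT_conversion = 0.45) {
  if (peptide_window$width != target_window$width)
    stop("windows must have equal width (",
         peptide_window$width, " vs ", target_window$width, ")")
  attachment_energy(peptide_window$h_sum, target_window$h_sum, config,
                    kT_conversion)
}

#' Redistribute channel populations after interdiction
#'
#' Models interdiction of one folding channel with efficiency `efficiency`
#' (the fraction of that channel's nucleation events that are blocked): the
#' blocked channel's population is scaled by `1 - efficiency` and the
#' removed mass is reassigned to the other channels in proportion to their
#' baseline Boltzmann weights, then renormalized. How blocked flux actually
#' partitions among surviving channels (or misfolds directly) is unknown;
#' proportional redistribution is a stated modeling assumption.
#'
#' @param baseline a `channel_populations` object.
#' @param blocked_label label of the interdicted channel.
#' @param efficiency blocking fraction in `[0, 1]`.
#' @return An object of class `redistributed_populations`: list with
#'   `baseline`, `blocked_label`, `efficiency` and `result` (a
#'   `channel_populations` over the same labels).
#' @examples
#' pops <- boltzmann_populations(c(8.9, 8.2, 7.8, 7.8))
#' redistribute_populations(pops, "C1", efficiency = 1)
#' @export
redistribute_populations <- function(baseline, blocked_label, efficiency) {
  stopifnot(inherits(baseline, "channel_populations"))
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency < 0 || efficiency > 1)
    stop("'efficiency' must be a single value in [0, 1]")
  k <- match(blocked_label, baseline$labels)
  if (is.na(k))
    stop("unknown channel label '", blocked_label, "'; available: ",
         paste(baseline$labels, collapse = ", "))
  p <- baseline$fractions
  removed <- efficiency * p[k]
  q <- p
  q[k] <- p[k] - removed
  if (length(p) > 1L) {
    others <- setdiff(seq_along(p), k)
    q[others] <- p[others] + removed * p[others] / sum(p[others])
  }
  q <- q / sum(q)
  result <- baseline
  result$fractions <- q
  structure(
    list(baseline = baseline, blocked_label = blocked_label,
         efficiency = efficiency, result = result),
    class = "redistributed_populations"
  )
}

#' @export
print.redistributed_populations <- function(x, ...) {
  cat("Interdiction of channel ", x$blocked_label,
      " at efficiency ", x$efficiency, "\n", sep = "")
  print(data.frame(channel = x$result$labels,
                   baseline = sprintf("%.4f", x$baseline$fractions),
                   redistributed = sprintf("%.4f", x$result$fractions),
                   stringsAsFactors = FALSE),
        row.names = FALSE)
  cat("(proportional redistribution of blocked flux: modeling assumption)\n")
  invisible(x)
}

#' Full interdiction report for one peptide
#'
#' Combines the peptide-to-contact assignments, the baseline channel
#' populations of the fit, and the redistributed populations for each
#' requested interdiction efficiency applied to every contact the peptide
#' is assigned to.
#'
#' @param fit an `scm_scan` fit.
#' @param peptide peptide sequence.
#' @param efficiencies numeric vector of interdiction efficiencies.
#' @param min_overlap,max_mismatch,seed passed to
#'   [map_peptide_to_contacts()].
#' @return An object of class `interdiction_report`: list with `peptide`,
#'   `assignments`, `baseline`, and `redistributions` (one
#'   `redistributed_populations` per assigned contact x efficiency), plus
#'   an `assumptions` character vector labelling the model extensions.
#' @export
interdiction_report <- function(fit, peptide, efficiencies = c(0.5, 1),
                                min_overlap = 5L, max_mismatch = 0L,
                                seed = FALSE) {
  stopifnot(inherits(fit, "scm_scan"))
  assignments <- map_peptide_to_contacts(peptide, fit,
                                         min_overlap = min_overlap,
                                         max_mismatch = max_mismatch,
                                         seed = seed)
  baseline <- boltzmann_populations(fit)
  targets <- unique(assignments$contact_label)
  redis <- list()
  for (lab in targets) {
    for (eps in efficiencies) {
      redis[[sprintf("%s@%g", lab, eps)]] <-
        redistribute_populations(baseline, lab, eps)
    }
  }
  structure(
    list(peptide = toupper(peptide), protein_id = fit$protein$id,
         assignments = assignments, baseline = baseline,
         redistributions = redis,
         assumptions = c(
           "attachment score is the contact energy without the loop term (model extension)",
           "blocked flux redistributes proportionally to baseline Boltzmann weights (modeling assumption)",
           "interdiction efficiency is a free input, not an estimated binding constant")),
    class = "interdiction_report"
  )
}

#' @export
print.interdiction_report <- function(x, ...) {
  cat("Folding-interdiction report: peptide ", x$peptide, " vs ",
      x$protein_id, "\n", sep = "")
  if (nrow(x$assignments) == 0L) {
    cat("  no contact segment matched\n")
    return(invisible(x))
  }
  print(x$assignments, row.names = FALSE)
  cat("\nBaseline populations:\n")
  print(x$baseline)
  for (r in x$redistributions) {
    cat("\n")
    print(r)
  }
  cat("\nModel assumptions:\n")
  for (a in x$assumptions) cat("  -", a, "\n")
  invisible(x)
}
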