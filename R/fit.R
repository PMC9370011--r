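# scm_scan(): the model-fitting entry point. Runs the full primary-contact
# analysis on one sequence and returns a classed object carrying the
# profile, the scored grid and the selected contact set.

#' Scan a protein for candidate primary folding contacts
#'
#' Fits the sequential collapse model's primary-contact scan to a protein
#' sequence: computes the sliding-window hydrophobicity profile, scores
#' every admissible non-local window pair (contact free energy = hydrophobic
#' stabilization + loop-closure entropy + side-chain ordering cost), and
#' selects the distinct locally-optimal contacts within the stability
#' cutoff. The selected contacts are the predicted parallel nucleation
#' sites of the folding pathway; their relative Boltzmann populations are
#' available through [boltzmann_populations()] and [summary.scm_scan()].
#'
#' @param protein a [protein_record()], or a plain sequence string (an
#'   offset of 0 is assumed).
#' @param scale a [hydro_scale()]; default the Fauchere-Pliska scale.
#' @param config a [scan_config()].
#' @param nonstandard policy for non-standard residue letters: `"error"`
#'   (default) or `"zero"`.
#' @return An object of class `scm_scan` with components `protein`,
#'   `scale`, `config`, `profile` (per-window hydrophobicities), `grid`
#'   (all scored candidates, ranked), and `contacts` (the selected
#'   `contact_set`).
#' @examples
#' fit <- scm_scan(p53_core_fixture())
#' fit                      # Table of selected contacts
#' coef(fit)                # named stability magnitudes in kT
#' summary(fit)             # adds Boltzmann channel populations
#' @seealso [boltzmann_populations()], [map_peptide_to_contacts()]
#' @export
scm_scan <- function(protein, scale = load_scale(), config = scan_config(),
                     nonstandard = c("error", "zero")) {
  if (is.character(protein)) protein <- protein_record(protein)
  stopifnot(inherits(protein, "protein_record"))
  nonstandard <- match.arg(nonstandard)
  profile <- hydrophobicity_profile(protein, width = config$width,
                                    scale = scale, nonstandard = nonstandard)
  grid <- enumerate_candidates(protein, scale = scale, config = config,
                               nonstandard = nonstandard)
  contacts <- select_primary_contacts(grid, config = config,
                                      protein_id = protein$id)
  structure(
    list(protein = protein, scale = scale, config = config,
         profile = profile, grid = grid, contacts = contacts,
         call = match.call()),
    class = "scm_scan"
  )
}

#' @export
print.scm_scan <- function(x, ...) {
  cat("Sequential-collapse primary-contact scan\n")
  cat("Protein: ", x$protein$id, " (", nchar(x$protein$residues),
      " residues, numbered ", x$protein$offset + 1L, "-",
      x$protein$offset + nchar(x$protein$residues), ")\n", sep = "")
  cat("Scale: ", x$scale$name, "; window ", x$config$width,
      "; separation ", x$config$min_separation, "-", x$config$max_separation,
      "; cutoff ", x$config$cutoff_kT, " kT\n", sep = "")
  cat(nrow(x$grid), "candidate pairs scored;",
      nrow(x$contacts$contacts), "distinct contacts selected\n\n")
  print(x$contacts)
  invisible(x)
}

#' Extract contact stabilities
#'
#' @param object an `scm_scan` fit.
#' @param ... unused.
#' @return Named numeric vector of stability magnitudes (kT), most stable
#'   first, named by contact label.
#' @export
coef.scm_scan <- function(object, ...) {
  ct <- object$contacts$contacts
  stats::setNames(ct$stability_kT, ct$label)
}

#' @export
as.data.frame.scm_scan <- function(x, ...) x$contacts$contacts

#' Summarize a primary-contact scan
#'
#' Augments the selected contacts with their Boltzmann channel populations
#' and, when per-contact stability uncertainties are supplied, the
#' one-at-a-time perturbation intervals of each population.
#'
#' @param object an `scm_scan` fit.
#' @param uncertainties optional numeric vector of one-standard-deviation
#'   stability uncertainties (kT), one per selected contact.
#' @param merge_tolerance_kT contacts whose stabilities differ by at most
#'   this are merged into one apparent kinetic channel.
#' @param ... unused.
#' @return An object of class `summary.scm_scan`.
#' @export
summary.scm_scan <- function(object, uncertainties = NULL,
                             merge_tolerance_kT = 0, ...) {
  ct <- object$contacts$contacts
  pops <- if (nrow(ct) > 0L)
    boltzmann_populations(ct$stability_kT, labels = ct$label)
  else NULL
  intervals <- if (!is.null(uncertainties) && nrow(ct) > 0L)
    perturbation_intervals(ct$stability_kT, uncertainties, labels = ct$label)
  else NULL
  channels <- if (!is.null(pops))
    merge_channels(pops, tolerance_kT = merge_tolerance_kT)
  else NULL
  structure(list(fit = object, populations = pops, intervals = intervals,
                 channels = channels),
            class = "summary.scm_scan")
}

#' @export
print.summary.scm_scan <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$populations)) {
    cat("\nChannel populations (Boltzmann weighting of stabilities):\n")
    tab <- data.frame(
      contact = x$populations$labels,
      stability_kT = sprintf("%.1f", x$populations$stabilities),
      population = sprintf("%d%%", percent_int(x$populations$fractions)),
      stringsAsFactors = FALSE
    )
    if (!is.null(x$intervals)) {
      tab$interval_pp <- sprintf("[%+d, %+d]",
                                 percent_int(x$intervals$shift_down_pp / 100),
                                 percent_int(x$intervals$shift_up_pp / 100))
    }
    print(tab, row.names = FALSE)
  }
  if (!is.null(x$channels) && length(x$channels) < length(x$populations$labels)) {
    cat("\nApparent kinetic channels (merged):\n")
    for (ch in x$channels)
      cat("  ", paste(ch$member_labels, collapse = "+"), ": ",
          percent_int(ch$combined_fraction), "%\n", sep = "")
  }
  invisible(x)
}

#' Plot a primary-contact scan
#'
#' Draws the sliding-window hydrophobicity profile with the selected
#' contacts' windows shaded and arcs joining each contact's two segments,
#' labelled by contact and stability.
#'
#' @param x an `scm_scan` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scm_scan <- function(x, ...) {
  prof <- x$profile
  ct <- x$contacts$contacts
  ymax <- max(prof$h_sum) + 0.35 * diff(range(prof$h_sum)) * max(1, nrow(ct))
  graphics::plot(prof$center, prof$h_sum, type = "l",
                 xlab = "window center (residue)",
                 ylab = sprintf("segment hydrophobicity h (width %d)",
                                x$config$width),
                 ylim = c(min(prof$h_sum), ymax),
                 main = paste("Primary-contact scan:", x$protein$id), ...)
  if (nrow(ct) == 0L) return(invisible(x))
  y0 <- max(prof$h_sum)
  step <- 0.3 * diff(range(prof$h_sum))
  for (i in seq_len(nrow(ct))) {
    graphics::rect(ct$seg_a_start[i], min(prof$h_sum), ct$seg_a_end[i], y0,
                   col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
    graphics::rect(ct$seg_b_start[i], min(prof$h_sum), ct$seg_b_end[i], y0,
                   col = grDevices::adjustcolor("tomato", 0.25), border = NA)
    y <- y0 + step * i
    graphics::segments(ct$center_a[i], y, ct$center_b[i], y, lty = 2)
    graphics::text((ct$center_a[i] + ct$center_b[i]) / 2, y,
                   sprintf("%s: %.1f kT", ct$label[i], ct$stability_kT[i]),
                   pos = 3, cex = 0.8)
  }
  invisible(x)
}
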