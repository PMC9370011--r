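# Folding-channel populations: Boltzmann weighting of contact stabilities,
# one-at-a-time perturbation intervals, and merged kinetic channels.

# Round half away from zero (5.5 -> 6, -5.5 -> -6); matches how the printed
# integer percentages are presented.
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

percent_int <- function(fraction) as.integer(round_half_away(100 * fraction))

#' Boltzmann channel populations from contact stabilities
#'
#' Converts stability magnitudes \eqn{s_k} (kT) into the relative population
#' of each folding channel, \eqn{p_k = e^{s_k} / \sum_m e^{s_m}}
#' (equivalently \eqn{e^{-\Delta G_k/kT}} normalized). The maximum stability
#' is subtracted before exponentiation for numerical stability, which leaves
#' the fractions unchanged.
#'
#' @param stabilities numeric vector of stability magnitudes in kT (positive
#'   = more stable), or an `scm_scan` fit whose selected contacts are used.
#' @param labels optional channel identifiers; default `C1`, `C2`, ...
#' @return An object of class `channel_populations`: list with
#'   `stabilities`, `fractions` (summing to 1) and `labels`.
#' @examples
#' boltzmann_populations(c(8.9, 8.2, 7.8, 7.8))  # 46% / 23% / 15% / 15%
#' @export
boltzmann_populations <- function(stabilities, labels = NULL) {
  if (inherits(stabilities, "scm_scan")) {
    s <- coef(stabilities)
    return(boltzmann_populations(unname(s), labels = names(s)))
  }
  if (length(stabilities) == 0L)
    stop("'stabilities' must contain at least one value")
  if (!is.numeric(stabilities) || any(!is.finite(stabilities)))
    stop("'stabilities' must be finite numeric")
  if (is.null(labels)) labels <- paste0("C", seq_along(stabilities))
  if (length(labels) != length(stabilities))
    stop("'labels' must match 'stabilities' in length")
  w <- exp(stabilities - max(stabilities))
  structure(
    list(stabilities = as.numeric(stabilities), fractions = w / sum(w),
         labels = as.character(labels)),
    class = "channel_populations"
  )
}

#' @export
print.channel_populations <- function(x, ...) {
  cat("Folding-channel populations\n")
  print(data.frame(channel = x$labels,
                   stability_kT = sprintf("%.1f", x$stabilities),
                   fraction = sprintf("%.4f", x$fractions),
                   population = sprintf("%d%%", percent_int(x$fractions)),
                   stringsAsFactors = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' One-at-a-time perturbation intervals of channel populations
#'
#' For each contact `k`, recomputes the populations with that contact's own
#' stability raised (then lowered) by its one-standard-deviation uncertainty
#' `u_k`, all other stabilities held at their nominal values, and reports
#' the signed change of `p_k` in percentage points. This single-contact
#' perturbation is what produces the asymmetric confidence shifts of the
#' populations (the Boltzmann map is logistic, not linear, in the
#' stability).
#'
#' @param stabilities numeric vector of stability magnitudes (kT).
#' @param uncertainties numeric vector of the same length, in kT.
#' @param labels optional channel identifiers.
#' @return A data frame with columns `label`, `shift_up_pp` (change when
#'   raised; >= 0) and `shift_down_pp` (change when lowered; <= 0), full
#'   precision.
#' @examples
#' perturbation_intervals(c(8.9, 8.2, 7.8, 7.8), c(0.3, 0.4, 0.4, 0.4))
#' @export
perturbation_intervals <- function(stabilities, uncertainties, labels = NULL) {
  if (length(stabilities) != length(uncertainties))
    stop("'stabilities' and 'uncertainties' must have equal length")
  if (any(uncertainties < 0)) stop("'uncertainties' must be >= 0")
  base <- boltzmann_populations(stabilities, labels = labels)
  shift <- function(k, delta) {
    s <- stabilities
    s[k] <- s[k] + delta
    p <- boltzmann_populations(s)$fractions
    100 * (p[k] - base$fractions[k])
  }
  n <- length(stabilities)
  data.frame(
    label = base$labels,
    shift_up_pp = vapply(seq_len(n), function(k) shift(k, uncertainties[k]),
                         numeric(1)),
    shift_down_pp = vapply(seq_len(n), function(k) shift(k, -uncertainties[k]),
                           numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Merge contacts of indistinguishable stability into kinetic channels
#'
#' Contacts whose stabilities differ by at most `tolerance_kT` are grouped
#' transitively: they are expected to break up on similar time scales, so a
#' low-resolution kinetic experiment would see them as one channel carrying
#' their combined population.
#'
#' @param populations a `channel_populations` object.
#' @param tolerance_kT non-negative merge tolerance in kT.
#' @return A list of `kinetic_channel` objects, each a list with
#'   `member_labels` and `combined_fraction`, ordered by decreasing combined
#'   stability of members.
#' @examples
#' pops <- boltzmann_populations(c(8.9, 8.2, 7.8, 7.8))
#' merge_channels(pops, tolerance_kT = 0)  # C3+C4 merge at ~31%
#' @export
merge_channels <- function(populations, tolerance_kT = 0) {
  stopifnot(inherits(populations, "channel_populations"))
  if (tolerance_kT < 0) stop("'tolerance_kT' must be >= 0")
  ord <- order(populations$stabilities, decreasing = TRUE)
  s <- populations$stabilities[ord]
  # transitive chaining: consecutive gaps <= tolerance join one group
  group <- cumsum(c(1, diff(-s) > tolerance_kT))
  lapply(split(ord, group), function(members) {
    structure(
      list(member_labels = populations$labels[members],
           combined_fraction = sum(populations$fractions[members])),
      class = "kinetic_channel"
    )
  })
}

#' @export
print.kinetic_channel <- function(x, ...) {
  cat("Kinetic channel ", paste(x$member_labels, collapse = "+"), ": ",
      sprintf("%.4f", x$combined_fraction), " (",
      percent_int(x$combined_fraction), "%)\n", sep = "")
  invisible(x)
}
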