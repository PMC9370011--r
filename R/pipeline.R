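# FASTA I/O, run configuration, and the end-to-end pipeline that ties the
# scan, population and interdiction stages together.

#' Read protein records from a FASTA file
#'
#' Multi-record files and wrapped sequence lines are accepted. Sequences
#' are uppercased; trailing stop characters (`*`) are stripped with a
#' warning; duplicate ids are suffixed `.2`, `.3`, ... with a warning.
#'
#' @param path FASTA file path.
#' @param offset numbering offset applied to every record (reported
#'   position = index + offset); recycled if one value.
#' @return A list of [protein_record()] objects.
#' @export
read_fasta <- function(path, offset = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  ids[is.na(ids) | ids == ""] <- sprintf("record_%d", which(is.na(ids) | ids == ""))
  if (anyDuplicated(ids)) {
    warning("duplicate record ids in ", path, "; suffixing")
    ids <- make.unique(ids, sep = ".")
  }
  seqs <- toupper(as.character(aa))
  if (any(grepl("\\*", seqs))) {
    warning("stripping '*' stop characters from ", sum(grepl("\\*", seqs)),
            " record(s)")
    seqs <- gsub("\\*", "", seqs)
  }
  offset <- rep_len(as.integer(offset), length(seqs))
  mapply(function(s, id, off) protein_record(s, id = id, offset = off),
         seqs, ids, offset, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records a [protein_record()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  aa <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "residues"))
  names(aa) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every tunable of a pipeline run. Serializable to and from a
#' plain-text JSON file with [write_run_config()] / [read_run_config()];
#' command-line flags override file values in the bundled CLI.
#'
#' @param scan a [scan_config()].
#' @param scale_name registered hydrophobicity scale name.
#' @param offset numbering offset applied to input records.
#' @param output_format `"tsv"` or `"json"`.
#' @param uncertainties optional per-contact stability uncertainties (kT)
#'   for perturbation intervals.
#' @param merge_tolerance_kT kinetic-channel merge tolerance.
#' @param nonstandard residue-letter policy, `"error"` or `"zero"`.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scan = scan_config(), scale_name = "fauchere-pliska",
                       offset = 0L, output_format = c("tsv", "json"),
                       uncertainties = NULL, merge_tolerance_kT = 0,
                       nonstandard = c("error", "zero"),
                       log_level = c("info", "quiet")) {
  structure(
    list(scan = scan, scale_name = scale_name, offset = as.integer(offset),
         output_format = match.arg(output_format),
         uncertainties = uncertainties,
         merge_tolerance_kT = merge_tolerance_kT,
         nonstandard = match.arg(nonstandard),
         log_level = match.arg(log_level)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a `run_config` to serialize.
#' @param path plain-text JSON path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$scan <- unclass(x$scan)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    scan = do.call(scan_config, x$scan),
    scale_name = x$scale_name, offset = x$offset,
    output_format = x$output_format,
    uncertainties = x$uncertainties,
    merge_tolerance_kT = x$merge_tolerance_kT,
    nonstandard = if (is.null(x$nonstandard)) "error" else x$nonstandard,
    log_level = x$log_level
  )
}

pipeline_log <- function(config, ...) {
  if (config$log_level != "quiet") message(...)
}

#' Run the full primary-contact pipeline on a FASTA file
#'
#' For every record: scans for primary contacts, computes Boltzmann channel
#' populations (with perturbation intervals when uncertainties are
#' configured) and merged kinetic channels, and — when a peptide is given —
#' the folding-interdiction report. Records too short to scan are skipped
#' with a warning.
#'
#' @param fasta_path input FASTA file.
#' @param config a [run_config()].
#' @param peptide optional interdiction peptide sequence.
#' @param efficiencies interdiction efficiencies evaluated when `peptide`
#'   is given.
#' @return An object of class `scm_report`: a list with one bundle per
#'   scannable record, each holding `fit`, `summary` and optionally
#'   `interdiction`.
#' @export
run_pipeline <- function(fasta_path, config = run_config(), peptide = NULL,
                         efficiencies = c(0.5, 1)) {
  stopifnot(inherits(config, "run_config"))
  records <- read_fasta(fasta_path, offset = config$offset)
  scale <- load_scale(config$scale_name)
  bundles <- list()
  for (rec in records) {
    fit <- tryCatch(
      scm_scan(rec, scale = scale, config = config$scan,
               nonstandard = config$nonstandard),
      error = function(e) {
        warning("skipping record '", rec$id, "': ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    unc <- config$uncertainties
    if (!is.null(unc) && length(unc) != nrow(fit$contacts$contacts)) {
      warning("record '", rec$id, "': ", length(unc), " uncertainties for ",
              nrow(fit$contacts$contacts), " contacts; intervals skipped")
      unc <- NULL
    }
    bundle <- list(
      fit = fit,
      summary = summary(fit, uncertainties = unc,
                        merge_tolerance_kT = config$merge_tolerance_kT)
    )
    if (!is.null(peptide) && nrow(fit$contacts$contacts) > 0L)
      bundle$interdiction <- interdiction_report(fit, peptide,
                                                 efficiencies = efficiencies)
    bundles[[rec$id]] <- bundle
    pipeline_log(config, "record '", rec$id, "': ",
                 nrow(fit$contacts$contacts), " contact(s) selected")
  }
  structure(bundles, class = "scm_report")
}

#' @export
print.scm_report <- function(x, ...) {
  for (id in names(x)) {
    print(summary_or_fit <- x[[id]]$summary)
    if (!is.null(x[[id]]$interdiction)) {
      cat("\n")
      print(x[[id]]$interdiction)
    }
    cat("\n")
  }
  invisible(x)
}

# One flat table per record: contacts + populations (+ intervals).
report_table <- function(bundle) {
  ct <- bundle$fit$contacts$contacts
  if (nrow(ct) == 0L) return(NULL)
  tab <- data.frame(
    rank = ct$rank,
    seg_a_span = sprintf("%d-%d", ct$seg_a_start, ct$seg_a_end),
    seg_a_seq = ct$seg_a_seq,
    seg_b_span = sprintf("%d-%d", ct$seg_b_start, ct$seg_b_end),
    seg_b_seq = ct$seg_b_seq,
    n_ij = ct$n_ij,
    dG_hyd_kT = ct$dG_hyd, dG_loop_kT = ct$dG_loop,
    dG_sidechain_kT = ct$dG_sidechain,
    stability_kT = ct$stability_kT,
    stringsAsFactors = FALSE
  )
  pops <- bundle$summary$populations
  tab$population_pct <- percent_int(pops$fractions)
  tab$population_frac <- pops$fractions
  iv <- bundle$summary$intervals
  if (!is.null(iv)) {
    tab$pop_shift_up_pp <- iv$shift_up_pp
    tab$pop_shift_down_pp <- iv$shift_down_pp
  }
  tab
}

#' Write a pipeline report
#'
#' `write_report_tsv()` emits one deterministic TSV per run (records
#' separated by their id on a comment line; energies at 4 decimals,
#' stability at 1 decimal as in the contact table display).
#' `write_report_json()` mirrors the same fields at full precision; a
#' report written and re-read round-trips every numeric field exactly.
#'
#' @param report an `scm_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(report)) {
    tab <- report_table(report[[id]])
    if (is.null(tab)) next
    writeLines(paste0("# record: ", id), con)
    fmt <- tab
    for (col in c("dG_hyd_kT", "dG_loop_kT", "dG_sidechain_kT",
                  "population_frac", "pop_shift_up_pp", "pop_shift_down_pp"))
      if (col %in% names(fmt)) fmt[[col]] <- sprintf("%.4f", fmt[[col]])
    fmt$stability_kT <- sprintf("%.1f", tab$stability_kT)
    utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path) {
  out <- lapply(report, function(bundle) {
    x <- list(protein_id = bundle$fit$protein$id,
              contacts = report_table(bundle))
    ch <- bundle$summary$channels
    if (!is.null(ch))
      x$channels <- lapply(unname(ch), function(k)
        list(members = k$member_labels, combined_fraction = k$combined_fraction))
    if (!is.null(bundle$interdiction)) {
      ir <- bundle$interdiction
      x$interdiction <- list(
        peptide = ir$peptide,
        assignments = ir$assignments,
        redistributed = lapply(unname(ir$redistributions), function(r)
          list(blocked = r$blocked_label, efficiency = r$efficiency,
               labels = r$result$labels, fractions = r$result$fractions)),
        assumptions = ir$assumptions)
    }
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
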