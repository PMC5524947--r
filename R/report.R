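# Serialisation of validation results: per-particle score tables (CSV and
# STAR), a JSON run summary, and optional pruned particle tables.

#' Write a validation report to disk
#'
#' Writes \code{<prefix>_scores.csv} and \code{<prefix>_scores.star}
#' (per-particle alpha, chi, q_p, q_a, flags), \code{<prefix>_summary.json}
#' (Q, percentage precise/accurate, all run parameters and the seed) and,
#' when \code{records} and \code{prune_tau} are given,
#' \code{<prefix>_pruned.star} with the passing subset.
#'
#' @param report A \code{ValidationReport} from [validate_particles()].
#' @param out_prefix Output path prefix.
#' @param records Optional particle records aligned with the report rows,
#'   required for STAR outputs.
#' @param prune_tau Optional threshold for writing the pruned STAR.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, out_prefix, records = NULL, prune_tau = NULL) {
  if (!inherits(report, "ValidationReport")) stop("invalid input: not a ValidationReport")
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character()

  csv <- paste0(out_prefix, "_scores.csv")
  utils::write.csv(report$scores, csv, row.names = FALSE, quote = FALSE)
  files <- c(files, csv)

  if (!is.null(records)) {
    if (nrow(records) != nrow(report$scores))
      stop("invalid input: records and report rows are not aligned")
    star <- paste0(out_prefix, "_scores.star")
    sc <- report$scores
    write_particles_star(records, star,
                         extra_cols = data.frame(cvAlpha = sc$alpha,
                                                 cvChi = ifelse(is.na(sc$chi), -999, sc$chi),
                                                 cvScorePrecision = ifelse(is.na(sc$q_p), -999, sc$q_p),
                                                 cvScoreAccuracy = ifelse(is.na(sc$q_a), -999, sc$q_a)))
    files <- c(files, star)
    if (!is.null(prune_tau)) {
      keep <- prune(report, prune_tau)
      pruned <- paste0(out_prefix, "_pruned.star")
      write_particles_star(records[keep, , drop = FALSE], pruned)
      files <- c(files, pruned)
    }
  }

  js <- paste0(out_prefix, "_summary.json")
  jsonlite::write_json(list(
    n_particles = nrow(report$scores),
    Q = report$Q,
    percent_precise = report$frac_precise,
    percent_accurate = report$frac_accurate,
    mean_q_p = report$mean_q_p,
    alpha_noise = report$alpha_noise,
    parameters = report$params
  ), js, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, js)
  invisible(files)
}
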