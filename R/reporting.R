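#' Render a QC report as text and TSV
#'
#' Fixed row order (total, sex/unplaced, call rate, HWE, MAF, retained) with
#' thousands separators in the text rendering and display percentages from
#' [qc_percentages()]. The TSV carries the raw counts so a re-parse
#' reproduces the report exactly.
#'
#' @param report a [qc_report()].
#' @param tsv_path optional path; when given, a TSV is written alongside.
#' @return Character vector of report lines (invisibly when writing).
#' @export
render_qc_table <- function(report, tsv_path = NULL) {
  stopifnot(inherits(report, "qc_report"))
  if (is.null(report$pct)) report <- qc_percentages(report)
  pc <- report$pct
  rows <- list(
    c("Total number of markers", report$total_markers, NA),
    c("Markers on sex chromosomes (X, Y) or unplaced (0)",
      report$removed_sexchrom, pc$categories[["sexchrom"]]),
    c("SNP detection rate < threshold", report$removed_snp_callrate,
      pc$categories[["snp_callrate"]]),
    c("Hardy-Weinberg exact test failures", report$removed_hwe,
      pc$categories[["hwe"]]),
    c("Minor allele frequency < threshold", report$removed_maf,
      pc$categories[["maf"]]),
    c("Markers passing quality control", report$retained_markers,
      pc$retained)
  )
  lines <- vapply(rows, function(r) {
    pct <- if (is.na(r[3])) "" else sprintf(" (%s%%)", r[3])
    sprintf("%-50s %10s%s", r[1], format_count(as.integer(r[2])), pct)
  }, character(1))
  if (report$removed_samples > 0) {
    lines <- c(lines, sprintf("%-50s %10s", "Individuals removed (call rate)",
                              format_count(report$removed_samples)))
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(
      field = c("total_markers", "removed_sexchrom", "removed_snp_callrate",
                "removed_hwe", "removed_maf", "removed_samples",
                "retained_markers"),
      count = c(report$total_markers, report$removed_sexchrom,
                report$removed_snp_callrate, report$removed_hwe,
                report$removed_maf, report$removed_samples,
                report$retained_markers))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(lines))
  }
  lines
}

#' Re-parse a QC report TSV
#'
#' @param tsv_path path written by [render_qc_table()].
#' @return The reconstructed [qc_report()] (percentages populated).
#' @export
parse_qc_table <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  v <- stats::setNames(df$count, df$field)
  qc_percentages(qc_report(
    total_markers = v[["total_markers"]],
    removed_sexchrom = v[["removed_sexchrom"]],
    removed_snp_callrate = v[["removed_snp_callrate"]],
    removed_hwe = v[["removed_hwe"]],
    removed_maf = v[["removed_maf"]],
    removed_samples = v[["removed_samples"]]
  ))
}

#' Render the family table
#'
#' One row per family and sex (bulls, then cows), with member ids, plus the
#' final `Other` row of unassigned cows.
#'
#' @param fa a [assign_families()] result.
#' @param tsv_path optional TSV output path.
#' @return data.frame with `family`, `sex`, `count`, `ids`.
#' @export
render_family_table <- function(fa, tsv_path = NULL) {
  stopifnot(inherits(fa, "family_assignment"))
  rows <- list()
  for (k in seq_along(fa$families)) {
    f <- fa$families[[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      family = paste("Family", k), sex = "male",
      count = length(f$bulls), ids = paste(f$bulls, collapse = ","),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      family = paste("Family", k), sex = "female",
      count = length(f$cows), ids = paste(f$cows, collapse = ","),
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    family = "Other", sex = "female", count = length(fa$other_cows),
    ids = paste(fa$other_cows, collapse = ","), stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  if (!is.null(tsv_path)) {
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tab
}

#' Percentage of individuals below a total-ROH-length threshold
#'
#' The class-arithmetic helper behind statements like "32 of 60 individuals
#' carry less than 100 Mb of ROH (53.33%)".
#'
#' @param summary a [roh_summaries()] result.
#' @param threshold_mb total-length threshold in Mb.
#' @param digits display decimals.
#' @return List with `count`, `n`, `pct` (floored at `digits`).
#' @export
roh_pct_below <- function(summary, threshold_mb = 100, digits = 2L) {
  stopifnot(inherits(summary, "roh_summary"))
  below <- sum(summary$per_individual$total_mb < threshold_mb)
  n <- nrow(summary$per_individual)
  list(count = below, n = n, pct = pct_floor(below, n, digits))
}
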