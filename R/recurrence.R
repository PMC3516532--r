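# Clinical-recurrence categorization and rare-vs-frequent feature comparisons.

#' Categorize fusions by registry report count
#'
#' Rare = reported exactly once; frequent = reported more than once.
#' Zero-report entries are rejected (a registry entry implies at least one
#' report).
#'
#' @param ids Identifier vector (fusion or gene ids).
#' @param report_counts Integer vector of report counts (>= 1), matched to
#'   `ids`.
#' @return data.frame: id, report_count, category ("rare"/"frequent").
#' @export
categorize_by_reports <- function(ids, report_counts) {
  if (length(ids) != length(report_counts)) stop("ids and counts must match")
  if (any(report_counts < 1)) stop("report counts must be >= 1")
  data.frame(id = ids, report_count = report_counts,
             category = ifelse(report_counts > 1, "frequent", "rare"),
             stringsAsFactors = FALSE)
}

#' Attach registry report counts to a translocation table
#'
#' Joins a Mitelman-like report-count table by gene pair. Pairs absent from
#' the table default to one report, with a warning: the registry counts
#' entries, so absence does not mean zero.
#'
#' @param tloc Translocation data.frame.
#' @param report_counts data.frame with five_gene, three_gene, n_reports.
#' @return `tloc` with an `n_reports` column.
#' @export
attach_report_counts <- function(tloc, report_counts) {
  key <- paste(tloc$five_gene, tloc$three_gene, sep = "\r")
  rkey <- paste(report_counts$five_gene, report_counts$three_gene, sep = "\r")
  n <- report_counts$n_reports[match(key, rkey)]
  if (anyNA(n)) {
    warning(sum(is.na(n)), " pair(s) absent from the report-count table; defaulting to 1")
    n[is.na(n)] <- 1
  }
  tloc$n_reports <- n
  tloc
}

#' Compare a feature between rare and frequent fusions
#'
#' Two-sided Mann-Whitney U test of the feature values in the rare versus the
#' frequent category, with per-category medians and direction. An empty
#' category skips the test with a flag; a single-member category runs it but
#' flags the wide-variance caveat.
#'
#' @param categories data.frame from [categorize_by_reports()].
#' @param feature_values data.frame with columns `id` and `value`.
#' @param feature_name Label carried into the output.
#' @return One-row data.frame: feature, n_rare, n_frequent, median_rare,
#'   median_frequent, direction, U, p_value, flag.
#' @export
compare_rare_frequent <- function(categories, feature_values, feature_name) {
  v <- feature_values$value[match(categories$id, feature_values$id)]
  keep <- !is.na(v)
  v <- v[keep]; cat <- categories$category[keep]
  rare <- v[cat == "rare"]; freq <- v[cat == "frequent"]
  out <- data.frame(feature = feature_name,
                    n_rare = length(rare), n_frequent = length(freq),
                    median_rare = stats::median(rare),
                    median_frequent = stats::median(freq),
                    direction = NA_character_, U = NA_real_,
                    p_value = NA_real_, flag = "", stringsAsFactors = FALSE)
  if (length(rare) == 0 || length(freq) == 0) {
    out$flag <- "skipped: empty category"
    return(out)
  }
  if (min(length(rare), length(freq)) == 1) out$flag <- "wide-variance: category of size 1"
  wt <- suppressWarnings(stats::wilcox.test(freq, rare))
  out$U <- unname(wt$statistic)
  out$p_value <- wt$p.value
  out$direction <- if (out$median_frequent >= out$median_rare) "frequent_higher" else "rare_higher"
  out
}
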