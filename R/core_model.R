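# Shared domain types and on-disk formats.
#
# Coordinate conventions used throughout:
#   * genomic intervals are 0-based half-open (BED convention);
#   * transcript and protein coordinates are 1-based inclusive
#     (annotation convention).

STRANDS    <- c("+", "-")
LINEAGES   <- c("HEM-L", "HEM-M", "both")
CATEGORIES <- c("D", "P", "H", "K", "O")
# N encodes "no retained domain"; used in co-occurrence analyses
CATEGORIES_N <- c(CATEGORIES, "N")

read_tsv_checked <- function(path, required, numeric_cols = character()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  for (cc in intersect(numeric_cols, names(df))) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df
}

write_tsv_stable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

#' Validate a gene-model table
#'
#' Columns: `gene_id`, `chrom`, `strand` (+/-), `tx_start` < `tx_end`
#' (0-based half-open), `cds_start_nt` (1-based first coding position in
#' transcript coordinates), and optional `utr3_start`/`utr3_end` (0-based
#' half-open, NA when the gene has no annotated 3'-UTR). The 3'-UTR, when
#' present, must lie inside the gene span.
#'
#' @param genes data.frame of gene models.
#' @return The validated data.frame (invisibly the same object).
#' @export
validate_gene_models <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "tx_start", "tx_end", "cds_start_nt")
  missing <- setdiff(req, names(genes))
  if (length(missing)) stop("gene models: missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("gene models: duplicated gene_id")
  if (!all(genes$strand %in% STRANDS)) stop("gene models: strand must be + or -")
  if (!all(genes$tx_start < genes$tx_end)) stop("gene models: tx_start must be < tx_end")
  if (!all(genes$cds_start_nt >= 1)) stop("gene models: cds_start_nt must be >= 1")
  has_utr <- !is.na(genes$utr3_start) & !is.na(genes$utr3_end)
  if (any(has_utr)) {
    u <- genes[has_utr, ]
    ok <- u$utr3_start < u$utr3_end & u$utr3_start >= u$tx_start & u$utr3_end <= u$tx_end
    if (!all(ok)) stop("gene models: 3'-UTR must be a non-empty interval inside the gene span")
  }
  genes
}

#' Read a gene-model table (TSV)
#' @param path Path to a TSV with a header naming all gene-model fields.
#' @return Validated data.frame.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_checked(path,
    required = c("gene_id", "chrom", "strand", "tx_start", "tx_end", "cds_start_nt"),
    numeric_cols = c("tx_start", "tx_end", "cds_start_nt", "utr3_start", "utr3_end"))
  if (!"utr3_start" %in% names(df)) df$utr3_start <- NA_real_
  if (!"utr3_end" %in% names(df)) df$utr3_end <- NA_real_
  validate_gene_models(df)
}

#' Write a gene-model table (TSV, byte-stable: sorted by gene_id)
#' @param genes Validated gene-model data.frame.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  genes <- validate_gene_models(genes)
  cols <- c("gene_id", "chrom", "strand", "tx_start", "tx_end", "cds_start_nt",
            "utr3_start", "utr3_end")
  write_tsv_stable(genes[order(genes$gene_id), cols], path)
}

#' Strand-resolved transcription start site
#'
#' For a + strand gene the TSS is `tx_start`; for a - strand gene it is
#' `tx_end` (under the half-open convention `tx_end` is the coordinate of the
#' first base of a minus-strand transcript when read 5' to 3').
#'
#' @param genes Gene-model data.frame (vectorized).
#' @return Integer vector of TSS coordinates.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
}

# ---- translocations --------------------------------------------------------

#' Validate a translocation table
#'
#' Columns: `fusion_id`, `five_gene`, `three_gene`, `five_bp_nt`,
#' `three_bp_nt` (1-based breakpoint positions in transcript coordinates),
#' `lineage` (HEM-L / HEM-M / both), `report_count` (>= 0). An optional
#' logical `self_fusion` column permits five_gene == three_gene.
#'
#' @param tloc data.frame of translocations.
#' @return Validated data.frame.
#' @export
validate_translocations <- function(tloc) {
  req <- c("fusion_id", "five_gene", "three_gene", "five_bp_nt", "three_bp_nt",
           "lineage", "report_count")
  missing <- setdiff(req, names(tloc))
  if (length(missing)) stop("translocations: missing column(s): ", paste(missing, collapse = ", "))
  if (!"self_fusion" %in% names(tloc)) tloc$self_fusion <- rep(FALSE, nrow(tloc))
  tloc$self_fusion[is.na(tloc$self_fusion)] <- FALSE
  if (anyDuplicated(tloc$fusion_id)) stop("translocations: duplicated fusion_id")
  if (!all(tloc$lineage %in% LINEAGES)) {
    bad <- setdiff(unique(tloc$lineage), LINEAGES)
    stop("translocations: unknown lineage code(s): ", paste(bad, collapse = ", "))
  }
  if (!all(tloc$five_bp_nt >= 1 & tloc$three_bp_nt >= 1)) {
    stop("translocations: breakpoints must be >= 1")
  }
  if (!all(tloc$report_count >= 0)) stop("translocations: report_count must be >= 0")
  same <- tloc$five_gene == tloc$three_gene & !tloc$self_fusion
  if (any(same)) stop("translocations: five_gene == three_gene without self_fusion flag")
  tloc
}

#' Read a translocation table (TSV)
#' @param path Path to a TSV with header naming all translocation fields.
#' @return Validated data.frame.
#' @export
read_translocations <- function(path) {
  df <- read_tsv_checked(path,
    required = c("fusion_id", "five_gene", "three_gene", "five_bp_nt",
                 "three_bp_nt", "lineage", "report_count"),
    numeric_cols = c("five_bp_nt", "three_bp_nt", "report_count"))
  validate_translocations(df)
}

#' Write a translocation table (TSV, sorted by fusion_id)
#' @param tloc Validated translocation data.frame.
#' @param path Output path.
#' @export
write_translocations <- function(tloc, path) {
  tloc <- validate_translocations(tloc)
  cols <- c("fusion_id", "five_gene", "three_gene", "five_bp_nt", "three_bp_nt",
            "lineage", "report_count", "self_fusion")
  write_tsv_stable(tloc[order(tloc$fusion_id), cols], path)
}

#' Deduplicate translocations
#'
#' Three modes mirroring the analysis-specific uniqueness rules:
#' * `"pairs"` — unique (five_gene, three_gene) pairs (genome-organization
#'   analyses); first occurrence kept.
#' * `"gene_instances"` — unique gene instances per side (expression
#'   analyses); returns a data.frame of (gene_id, side).
#' * `"domain_composition"` — pairs unique by gene pair plus retained-domain
#'   functional profile (domain co-occurrence analyses); requires `profiles`,
#'   a data.frame keyed by fusion_id with a `profile_key` column.
#'
#' All modes are idempotent and order-independent (records are ranked by
#' fusion_id before first-occurrence selection).
#'
#' @param tloc Translocation data.frame.
#' @param mode One of "pairs", "gene_instances", "domain_composition".
#' @param profiles Required for mode "domain_composition": data.frame with
#'   columns fusion_id and profile_key.
#' @return Deduplicated data.frame (see modes).
#' @export
dedup_translocations <- function(tloc,
                                 mode = c("pairs", "gene_instances", "domain_composition"),
                                 profiles = NULL) {
  mode <- match.arg(mode)
  tloc <- tloc[order(tloc$fusion_id), , drop = FALSE]
  if (mode == "pairs") {
    key <- paste(tloc$five_gene, tloc$three_gene, sep = "\r")
    return(tloc[!duplicated(key), , drop = FALSE])
  }
  if (mode == "gene_instances") {
    inst <- rbind(
      data.frame(gene_id = tloc$five_gene, side = "five_prime", stringsAsFactors = FALSE),
      data.frame(gene_id = tloc$three_gene, side = "three_prime", stringsAsFactors = FALSE))
    inst <- inst[order(inst$side, inst$gene_id), ]
    rownames(inst) <- NULL
    return(inst[!duplicated(paste(inst$gene_id, inst$side, sep = "\r")), , drop = FALSE])
  }
  if (is.null(profiles) || !all(c("fusion_id", "profile_key") %in% names(profiles))) {
    stop("mode 'domain_composition' needs profiles with fusion_id and profile_key")
  }
  pk <- profiles$profile_key[match(tloc$fusion_id, profiles$fusion_id)]
  if (anyNA(pk)) stop("profiles missing for some fusion_ids")
  key <- paste(tloc$five_gene, tloc$three_gene, pk, sep = "\r")
  tloc[!duplicated(key), , drop = FALSE]
}

# ---- domain annotations and category map -----------------------------------

#' Validate domain / interaction-interface annotations
#'
#' Columns: `gene_id`, `feature_id`, `aa_start` <= `aa_end` (1-based inclusive
#' amino-acid coordinates), `is_pii` (logical), `partners` (comma-separated
#' gene ids; non-empty only for PII records).
#'
#' @param dom data.frame of annotations.
#' @return Validated data.frame.
#' @export
validate_domains <- function(dom) {
  req <- c("gene_id", "feature_id", "aa_start", "aa_end", "is_pii", "partners")
  missing <- setdiff(req, names(dom))
  if (length(missing)) stop("domains: missing column(s): ", paste(missing, collapse = ", "))
  if (!all(dom$aa_start <= dom$aa_end)) stop("domains: aa_start must be <= aa_end")
  if (!all(dom$aa_start >= 1)) stop("domains: aa coordinates are 1-based")
  dom$partners[is.na(dom$partners)] <- ""
  if (any(!dom$is_pii & nzchar(dom$partners))) {
    stop("domains: partners must be empty when is_pii is FALSE")
  }
  dom
}

#' Read domain annotations (TSV)
#' @param path Input path.
#' @return Validated data.frame.
#' @export
read_domains <- function(path) {
  df <- read_tsv_checked(path,
    required = c("gene_id", "feature_id", "aa_start", "aa_end", "is_pii", "partners"),
    numeric_cols = c("aa_start", "aa_end"))
  df$is_pii <- as.logical(df$is_pii)
  df$partners <- as.character(df$partners)
  df$partners[is.na(df$partners)] <- ""
  validate_domains(df)
}

#' Write domain annotations (TSV, sorted by gene_id then feature then start)
#' @param dom Validated annotation data.frame.
#' @param path Output path.
#' @export
write_domains <- function(dom, path) {
  dom <- validate_domains(dom)
  cols <- c("gene_id", "feature_id", "aa_start", "aa_end", "is_pii", "partners")
  ord <- order(dom$gene_id, dom$feature_id, dom$aa_start)
  write_tsv_stable(dom[ord, cols], path)
}

#' Read a functional category map (TSV: feature_id, category)
#'
#' Categories are the five broad functional classes: D (DNA binding),
#' P (protein interaction), H (histone modification), K (kinase), O (other).
#'
#' @param path Input path.
#' @return Named character vector mapping feature_id to category.
#' @export
read_category_map <- function(path) {
  df <- read_tsv_checked(path, required = c("feature_id", "category"))
  if (!all(df$category %in% CATEGORIES)) {
    bad <- setdiff(unique(df$category), CATEGORIES)
    stop("category map: unknown category code(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$feature_id)) stop("category map: duplicated feature_id")
  stats::setNames(df$category, df$feature_id)
}

#' Write a functional category map (TSV, sorted by feature_id)
#' @param cmap Named character vector (feature_id -> category).
#' @param path Output path.
#' @export
write_category_map <- function(cmap, path) {
  df <- data.frame(feature_id = names(cmap), category = unname(cmap),
                   stringsAsFactors = FALSE)
  write_tsv_stable(df[order(df$feature_id), ], path)
}

# ---- BED tracks and bedGraph signal profiles --------------------------------

#' Parse one BED record
#'
#' @param line A tab-separated BED line (>= 3 fields).
#' @param line_number Line number used in error messages.
#' @return List with chrom, start, end and optional name, score
#'   (0-based half-open interval).
#' @export
parse_bed_record <- function(line, line_number = NA_integer_) {
  where <- if (is.na(line_number)) "" else sprintf(" at line %d", line_number)
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 3) stop(sprintf("BED format error%s: fewer than 3 fields", where))
  start <- suppressWarnings(as.numeric(fields[2]))
  end <- suppressWarnings(as.numeric(fields[3]))
  if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end)) {
    stop(sprintf("BED format error%s: non-integer coordinates", where))
  }
  if (start >= end) stop(sprintf("BED format error%s: start >= end", where))
  rec <- list(chrom = fields[1], start = start, end = end,
              name = NA_character_, score = NA_real_)
  if (length(fields) >= 4) rec$name <- fields[4]
  if (length(fields) >= 5) rec$score <- suppressWarnings(as.numeric(fields[5]))
  rec
}

#' Read a BED (3-6 column) track
#' @param path Input path (no header).
#' @return data.frame with chrom, start, end, name, score; class
#'   `interval_track`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(interval_track(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), name = character(),
                                     score = numeric(), stringsAsFactors = FALSE)))
  }
  recs <- lapply(seq_along(lines), function(i) parse_bed_record(lines[i], i))
  interval_track(data.frame(
    chrom = vapply(recs, `[[`, "", "chrom"),
    start = vapply(recs, `[[`, 0, "start"),
    end = vapply(recs, `[[`, 0, "end"),
    name = vapply(recs, `[[`, "", "name"),
    score = vapply(recs, `[[`, 0, "score"),
    stringsAsFactors = FALSE))
}

#' Construct / validate an interval track (0-based half-open records)
#' @param df data.frame with at least chrom, start, end.
#' @return The data.frame with class `interval_track`.
#' @export
interval_track <- function(df) {
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop("interval track needs chrom, start, end")
  }
  if (!"name" %in% names(df)) df$name <- rep(NA_character_, nrow(df))
  if (!"score" %in% names(df)) df$score <- rep(NA_real_, nrow(df))
  if (any(df$start >= df$end)) stop("interval track: start must be < end")
  class(df) <- c("interval_track", "data.frame")
  df
}

#' Write a BED track (sorted by chrom, start, end; byte-stable)
#' @param track interval_track data.frame.
#' @param path Output path.
#' @export
write_bed <- function(track, path) {
  track <- track[order(track$chrom, track$start, track$end), , drop = FALSE]
  has_name <- !all(is.na(track$name))
  has_score <- !all(is.na(track$score))
  cols <- c("chrom", "start", "end",
            if (has_name || has_score) "name",
            if (has_score) "score")
  out <- as.data.frame(track)[, cols, drop = FALSE]
  if ("name" %in% cols) out$name[is.na(out$name)] <- "."
  if ("score" %in% cols) out$score[is.na(out$score)] <- 0
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal / replication-timing profile
#'
#' Each interval's value is assigned to the interval midpoint
#' `floor((start + end) / 2)`; the original intervals are retained so the
#' profile round-trips. Positions must be strictly increasing within each
#' chromosome.
#'
#' @param path Input path (chrom, start, end, value; no header).
#' @param semantics "signal" or "replication_timing".
#' @return data.frame (chrom, start, end, position, value) of class
#'   `signal_profile`, sorted by chrom then position, with attribute
#'   `semantics`.
#' @export
read_bedgraph <- function(path, semantics = c("signal", "replication_timing")) {
  semantics <- match.arg(semantics)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  signal_profile(df, semantics)
}

#' Construct / validate a signal profile
#' @param df data.frame with chrom, start, end, value.
#' @param semantics "signal" or "replication_timing".
#' @return `signal_profile` data.frame.
#' @export
signal_profile <- function(df, semantics = c("signal", "replication_timing")) {
  semantics <- match.arg(semantics)
  if (any(df$start >= df$end)) stop("signal profile: start must be < end")
  df$position <- floor((df$start + df$end) / 2)
  df <- df[order(df$chrom, df$position), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    pos <- df$position[df$chrom == ch]
    if (any(diff(pos) <= 0)) {
      stop(sprintf("signal profile: positions not strictly increasing on %s", ch))
    }
  }
  attr(df, "semantics") <- semantics
  class(df) <- c("signal_profile", "data.frame")
  df
}

#' Write a signal profile back to bedGraph (sorted; byte-stable)
#' @param profile `signal_profile` data.frame.
#' @param path Output path.
#' @export
write_bedgraph <- function(profile, path) {
  out <- as.data.frame(profile)[order(profile$chrom, profile$start),
                                c("chrom", "start", "end", "value")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- contact matrices ------------------------------------------------------

#' Construct a binned contact matrix
#'
#' @param bins data.frame with bin_id (0-based, genome-ordered), chrom, start,
#'   end (0-based half-open, tiling each chromosome without overlap).
#' @param values Symmetric numeric matrix (n_bins x n_bins) of non-negative
#'   normalized contact frequencies.
#' @return List of class `contact_matrix` with elements `bins` and `values`.
#' @export
contact_matrix <- function(bins, values) {
  req <- c("bin_id", "chrom", "start", "end")
  if (!all(req %in% names(bins))) stop("bins need bin_id, chrom, start, end")
  n <- nrow(bins)
  if (!isTRUE(all.equal(sort(as.numeric(bins$bin_id)), as.numeric(0:(n - 1))))) {
    stop("bin ids must be 0..n-1")
  }
  bins$bin_id <- as.integer(bins$bin_id)
  bins <- bins[order(bins$bin_id), , drop = FALSE]
  rownames(bins) <- NULL
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    b <- b[order(b$start), ]
    if (any(b$start >= b$end)) stop("bins: start must be < end")
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("bins must tile each chromosome without overlap")
    }
  }
  values <- as.matrix(values)
  if (!all(dim(values) == c(n, n))) stop("value grid must be n_bins x n_bins")
  if (any(values < 0)) stop("contact values must be >= 0")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-10))) {
    stop("contact matrix must be symmetric")
  }
  structure(list(bins = bins, values = values), class = "contact_matrix")
}

#' Load a contact matrix from a bin table and COO triplets
#'
#' Triplets are (bin_i, bin_j, value); unlisted pairs are zero; the loaded
#' grid is symmetrized from either triangle. Duplicate (i, j) triplets
#' (including a duplicate given as its transpose) are an error, as silent
#' summation would hide upstream corruption.
#'
#' @param bins_path TSV with bin_id, chrom, start, end.
#' @param triplets_path TSV with bin_i, bin_j, value.
#' @return `contact_matrix`.
#' @export
load_contact_matrix <- function(bins_path, triplets_path) {
  bins <- read_tsv_checked(bins_path, required = c("bin_id", "chrom", "start", "end"),
                           numeric_cols = c("bin_id", "start", "end"))
  trip <- read_tsv_checked(triplets_path, required = c("bin_i", "bin_j", "value"),
                           numeric_cols = c("bin_i", "bin_j", "value"))
  n <- nrow(bins)
  if (nrow(trip) > 0) {
    if (any(!trip$bin_i %in% bins$bin_id) || any(!trip$bin_j %in% bins$bin_id)) {
      stop("unknown bin id in triplets")
    }
    if (any(trip$value < 0)) stop("negative contact value")
    key <- paste(pmin(trip$bin_i, trip$bin_j), pmax(trip$bin_i, trip$bin_j))
    if (anyDuplicated(key)) stop("duplicate (i,j) triplet")
  }
  values <- matrix(0, n, n)
  if (nrow(trip) > 0) {
    values[cbind(trip$bin_i + 1L, trip$bin_j + 1L)] <- trip$value
    values[cbind(trip$bin_j + 1L, trip$bin_i + 1L)] <- trip$value
  }
  contact_matrix(bins, values)
}

#' Write a contact matrix as a bin table plus COO triplets
#'
#' Emits the upper triangle (including the diagonal) of non-zero entries,
#' sorted by (bin_i, bin_j), so output is byte-stable for identical input.
#'
#' @param cm `contact_matrix`.
#' @param bins_path Output path for the bin table.
#' @param triplets_path Output path for the triplets.
#' @export
write_contact_matrix <- function(cm, bins_path, triplets_path) {
  write_tsv_stable(cm$bins[order(cm$bins$bin_id),
                           c("bin_id", "chrom", "start", "end")], bins_path)
  idx <- which(upper.tri(cm$values, diag = TRUE) & cm$values != 0, arr.ind = TRUE)
  trip <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                     value = cm$values[idx])
  trip <- trip[order(trip$bin_i, trip$bin_j), , drop = FALSE]
  write_tsv_stable(trip, triplets_path)
  invisible(NULL)
}

# ---- expression matrix and sample metadata ---------------------------------

#' Read an expression table and its sample metadata
#'
#' @param expr_path TSV: first column gene_id, remaining columns one per
#'   sample.
#' @param samples_path TSV with sample_id, tissue, lineage_group (EPI / HEM /
#'   MES or a cell-line tag).
#' @return List of class `expression_table` with `values` (gene x sample
#'   matrix) and `samples` (metadata data.frame).
#' @export
read_expression <- function(expr_path, samples_path) {
  df <- utils::read.delim(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("expression: first column must be gene_id")
  samples <- read_tsv_checked(samples_path,
                              required = c("sample_id", "tissue", "lineage_group"))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  expression_table(values, samples)
}

#' Construct / validate an expression table
#' @param values Gene x sample numeric matrix with dimnames.
#' @param samples Sample metadata data.frame.
#' @return `expression_table` list.
#' @export
expression_table <- function(values, samples) {
  if (anyDuplicated(rownames(values))) stop("expression: duplicated gene ids")
  if (anyDuplicated(colnames(values))) stop("expression: duplicated sample ids")
  if (anyDuplicated(samples$sample_id)) stop("expression: duplicated sample metadata")
  missing <- setdiff(colnames(values), samples$sample_id)
  if (length(missing)) {
    stop("expression: samples without metadata: ", paste(missing, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expression_table")
}

#' Write an expression table and metadata (sorted, byte-stable)
#' @param expr `expression_table`.
#' @param expr_path Output path for the matrix.
#' @param samples_path Output path for the metadata.
#' @export
write_expression <- function(expr, expr_path, samples_path) {
  v <- expr$values[order(rownames(expr$values)), order(colnames(expr$values)), drop = FALSE]
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_stable(df, expr_path)
  s <- expr$samples[order(expr$samples$sample_id),
                    c("sample_id", "tissue", "lineage_group")]
  write_tsv_stable(s, samples_path)
  invisible(NULL)
}

# ---- report counts ---------------------------------------------------------

#' Read a registry report-count table (TSV: five_gene, three_gene, n_reports)
#' @param path Input path.
#' @return data.frame.
#' @export
read_report_counts <- function(path) {
  df <- read_tsv_checked(path, required = c("five_gene", "three_gene", "n_reports"),
                         numeric_cols = "n_reports")
  if (any(df$n_reports < 0)) stop("report counts must be >= 0")
  df
}

#' Write a report-count table (sorted by gene pair)
#' @param counts data.frame with five_gene, three_gene, n_reports.
#' @param path Output path.
#' @export
write_report_counts <- function(counts, path) {
  write_tsv_stable(counts[order(counts$five_gene, counts$three_gene),
                          c("five_gene", "three_gene", "n_reports")], path)
}
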