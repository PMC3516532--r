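# Expression aggregation and regulatory-feature computation for TPGs:
# tissue/lineage means, paired 5'-3' differences, promoter Pol2 peak
# frequency, H3K4me3 meta-profiles, and 3'-UTR features.

#' Aggregate an expression table by tissue and lineage group
#'
#' Per-gene tissue means average only that tissue's donor samples; lineage
#' group means (EPI / HEM / MES) are the mean of the tissue means within the
#' group, so every tissue carries equal weight regardless of donor count.
#' Samples whose lineage_group is a cell-line tag contribute a tissue mean
#' but no group mean.
#'
#' @param expr `expression_table`.
#' @return List of class `tissue_summary`: tissue_means (gene x tissue
#'   matrix), group_means (gene x group matrix), tissue_groups (named
#'   character vector tissue -> lineage_group).
#' @export
aggregate_by_tissue <- function(expr) {
  samples <- expr$samples
  tissues <- unique(samples$tissue)
  tissue_means <- sapply(tissues, function(ts) {
    cols <- samples$sample_id[samples$tissue == ts]
    if (length(cols) == 0) stop("tissue with zero samples: ", ts)
    rowMeans(expr$values[, cols, drop = FALSE])
  })
  tissue_groups <- vapply(tissues, function(ts) {
    unique(samples$lineage_group[samples$tissue == ts])[1]
  }, character(1))
  groups <- intersect(c("EPI", "HEM", "MES"), tissue_groups)
  group_means <- sapply(groups, function(g) {
    rowMeans(tissue_means[, tissue_groups == g, drop = FALSE])
  })
  structure(list(tissue_means = tissue_means, group_means = group_means,
                 tissue_groups = tissue_groups),
            class = "tissue_summary")
}

#' Paired 5'-3' partner difference with signed-rank test
#'
#' Differences `a - b` per matched translocation, the median difference, and
#' a two-sided Wilcoxon signed-rank p-value. When every pair is tied (all
#' differences zero) the test is undefined and is reported as p = 1 with a
#' flag.
#'
#' @param values_a,values_b Equal-length numeric vectors matched by
#'   translocation.
#' @return List: differences, median_diff, p_value, flag.
#' @export
paired_partner_difference <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("length mismatch between sides")
  if (length(values_a) == 0) stop("need at least one pair")
  d <- values_a - values_b
  if (all(d == 0)) {
    return(list(differences = d, median_diff = 0, p_value = 1,
                flag = "degenerate: all pairs tied"))
  }
  p <- suppressWarnings(stats::wilcox.test(values_a, values_b, paired = TRUE)$p.value)
  list(differences = d, median_diff = stats::median(d), p_value = p, flag = "")
}

#' Promoter windows around strand-resolved TSSs
#'
#' `[TSS - flank, TSS + flank)`, clipped at the chromosome start.
#'
#' @param genes Gene-model data.frame.
#' @param flank Flank in bp (default 3000, the -3 kb/+3 kb window).
#' @return data.frame: gene_id, chrom, start, end, strand.
#' @export
promoter_window <- function(genes, flank = 3000) {
  tss <- gene_tss(genes)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, tss - flank), end = tss + flank,
             strand = genes$strand, stringsAsFactors = FALSE)
}

track_to_granges <- function(track) {
  # half-open 0-based -> 1-based closed
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(start = track$start + 1, end = track$end))
}

#' Pol2 peak frequency in promoters, per cell-line group
#'
#' Per gene, the proportion of cell lines in a group whose Pol2 peak track
#' overlaps (>= 1 bp) the promoter window, then z-normalized over all genes
#' separately within each group.
#'
#' @param genes Gene-model data.frame.
#' @param peak_tracks Named list of groups (e.g. `hematopoietic`,
#'   `non_hematopoietic`), each a list of `interval_track`s, one per cell
#'   line.
#' @param flank Promoter flank in bp.
#' @return data.frame of class `promoter_features`: gene_id, then per group
#'   `prop_<group>` and `z_<group>`.
#' @export
pol2_peak_frequency <- function(genes, peak_tracks, flank = 3000) {
  prom <- promoter_window(genes, flank)
  prom_gr <- track_to_granges(prom)
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (grp in names(peak_tracks)) {
    tracks <- peak_tracks[[grp]]
    if (length(tracks) == 0) stop("empty cell-line group: ", grp)
    hits <- vapply(tracks, function(tr) {
      if (nrow(tr) == 0) return(rep(0L, nrow(genes)))
      as.integer(GenomicRanges::countOverlaps(prom_gr, track_to_granges(tr)) > 0)
    }, integer(nrow(genes)))
    prop <- rowMeans(hits)
    out[[paste0("prop_", grp)]] <- prop
    out[[paste0("z_", grp)]] <- zscore_normalize(prop)
  }
  class(out) <- c("promoter_features", "data.frame")
  out
}

#' Averaged strand-oriented signal meta-profile around promoters
#'
#' Splits each promoter window into `n_bins` equal bins (bin 1 is upstream of
#' the TSS; minus-strand windows contribute mirror-ordered bins), averages
#' `log2(signal + 1)` of the profile points falling in each bin, averages
#' across genes, and normalizes by the profile maximum.
#'
#' @param profile `signal_profile`.
#' @param genes Gene-model data.frame.
#' @param flank Promoter flank in bp.
#' @param n_bins Number of bins (>= 1).
#' @return Numeric vector of length `n_bins`, maximum 1.
#' @export
signal_metaprofile <- function(profile, genes, flank = 3000, n_bins = 50) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  prom <- promoter_window(genes, flank)
  acc <- matrix(NA_real_, nrow(genes), n_bins)
  for (i in seq_len(nrow(prom))) {
    p <- profile[profile$chrom == prom$chrom[i] &
                   profile$position >= prom$start[i] &
                   profile$position < prom$end[i], , drop = FALSE]
    if (nrow(p) == 0) next
    width <- (prom$end[i] - prom$start[i]) / n_bins
    bin <- pmin(n_bins, floor((p$position - prom$start[i]) / width) + 1)
    if (prom$strand[i] == "-") bin <- n_bins + 1 - bin
    acc[i, ] <- vapply(seq_len(n_bins), function(b) {
      v <- p$value[bin == b]
      if (length(v) == 0) NA_real_ else mean(log2(v + 1))
    }, numeric(1))
  }
  if (all(is.na(acc))) stop("no gene promoter overlaps the signal profile")
  prof <- colMeans(acc, na.rm = TRUE)
  prof / max(prof, na.rm = TRUE)
}

#' 3'-UTR length and regulatory-element counts
#'
#' Per gene with an annotated 3'-UTR: length in bp and the number of
#' conserved-element and microRNA-target-site track records overlapping the
#' UTR by at least 1 bp. Genes without a UTR are flagged absent (NA) and
#' excluded downstream.
#'
#' @param genes Gene-model data.frame.
#' @param conserved_track,mirna_track `interval_track`s.
#' @return data.frame of class `utr3_features`: gene_id, utr_length,
#'   n_conserved, n_mirna_sites, has_utr.
#' @export
utr3_features <- function(genes, conserved_track, mirna_track) {
  has_utr <- !is.na(genes$utr3_start) & !is.na(genes$utr3_end)
  out <- data.frame(gene_id = genes$gene_id,
                    utr_length = ifelse(has_utr, genes$utr3_end - genes$utr3_start, NA_real_),
                    n_conserved = NA_real_, n_mirna_sites = NA_real_,
                    has_utr = has_utr, stringsAsFactors = FALSE)
  if (any(has_utr)) {
    utr_gr <- GenomicRanges::GRanges(
      genes$chrom[has_utr],
      IRanges::IRanges(start = genes$utr3_start[has_utr] + 1,
                       end = genes$utr3_end[has_utr]))
    count_track <- function(track) {
      if (nrow(track) == 0) return(rep(0, sum(has_utr)))
      GenomicRanges::countOverlaps(utr_gr, track_to_granges(track))
    }
    out$n_conserved[has_utr] <- count_track(conserved_track)
    out$n_mirna_sites[has_utr] <- count_track(mirna_track)
  }
  class(out) <- c("utr3_features", "data.frame")
  out
}

#' Per-fusion expression / promoter / 3'-UTR gain statistics by partner type
#'
#' Emits the three gain statistics per translocation:
#' * transcription gain: Pol2 occupancy (unnormalized hematopoietic peak
#'   proportion) of the 5' promoter minus that of the 3' promoter,
#'   compared between fusions whose 5' partner is type 1 vs type 2;
#' * 3'-UTR stability gain: log2(5' UTR length / 3' UTR length), compared by
#'   the 3' partner type (fusions with a zero or missing UTR length excluded
#'   with a warning);
#' * expression increase: (5' expression / 3' expression) - 1 in the
#'   hematopoietic group means, compared by 5' partner type.
#'
#' Each comparison is a two-tailed t-test between the type-1 and type-2
#' groups.
#'
#' @param profiles Profile data.frame from [fusion_profiles()].
#' @param promoter_features From [pol2_peak_frequency()]; the hematopoietic
#'   proportion column is `prop_hematopoietic`.
#' @param utr_features From [utr3_features()].
#' @param hem_expression Named numeric vector of hematopoietic-group mean
#'   expression per gene.
#' @return List: per_fusion (data.frame with the three statistics and the
#'   type labels), tests (data.frame statistic, n_type1, n_type2, mean_type1,
#'   mean_type2, p_value).
#' @export
fusion_gain_stats <- function(profiles, promoter_features, utr_features,
                              hem_expression) {
  pf <- promoter_features
  prop <- stats::setNames(pf$prop_hematopoietic, pf$gene_id)
  ulen <- stats::setNames(utr_features$utr_length, utr_features$gene_id)
  per <- data.frame(fusion_id = profiles$fusion_id,
                    five_type = profiles$five_type,
                    three_type = profiles$three_type,
                    stringsAsFactors = FALSE)
  per$pol2_gain <- unname(prop[profiles$five_gene] - prop[profiles$three_gene])
  l5 <- unname(ulen[profiles$five_gene]); l3 <- unname(ulen[profiles$three_gene])
  bad_utr <- is.na(l5) | is.na(l3) | l5 == 0 | l3 == 0
  if (any(bad_utr)) {
    warning(sum(bad_utr), " fusion(s) excluded from the UTR ratio (zero or missing UTR)")
  }
  per$utr_log2_ratio <- ifelse(bad_utr, NA_real_, log2(l5 / l3))
  e5 <- unname(hem_expression[profiles$five_gene])
  e3 <- unname(hem_expression[profiles$three_gene])
  per$expr_increase <- e5 / e3 - 1

  one_test <- function(stat, values, type) {
    g1 <- values[type == 1 & !is.na(values)]
    g2 <- values[type == 2 & !is.na(values)]
    p <- if (length(g1) >= 2 && length(g2) >= 2) {
      stats::t.test(g1, g2)$p.value
    } else NA_real_
    data.frame(statistic = stat, n_type1 = length(g1), n_type2 = length(g2),
               mean_type1 = mean(g1), mean_type2 = mean(g2), p_value = p,
               stringsAsFactors = FALSE)
  }
  tests <- rbind(
    one_test("pol2_gain", per$pol2_gain, per$five_type),
    one_test("utr_log2_ratio", per$utr_log2_ratio, per$three_type),
    one_test("expr_increase", per$expr_increase, per$five_type))
  list(per_fusion = per, tests = tests)
}
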