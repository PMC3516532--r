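# Hi-C trans-contact pair-proximity statistics, permutation nulls, and the
# central/peripheral nuclear partition. "Distance" is reported as contact
# frequency throughout (higher = closer); only interchromosomal (trans)
# values enter any statistic.

#' Map genes to contact-matrix bins
#'
#' A gene maps to the bin containing its anchor point: the gene-body midpoint
#' `floor((tx_start + tx_end) / 2)` by default, or the strand-resolved TSS.
#' Bins are half-open, so an anchor exactly on a boundary belongs to the bin
#' starting there.
#'
#' @param genes Gene-model data.frame.
#' @param cm `contact_matrix`.
#' @param anchor "midpoint" (default) or "tss".
#' @return Integer vector of bin ids (0-based), named by gene_id.
#' @export
gene_bin_index <- function(genes, cm, anchor = c("midpoint", "tss")) {
  anchor <- match.arg(anchor)
  pos <- if (anchor == "midpoint") {
    floor((genes$tx_start + genes$tx_end) / 2)
  } else {
    gene_tss(genes)
  }
  out <- rep(NA_integer_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    b <- cm$bins[cm$bins$chrom == ch, , drop = FALSE]
    sel <- genes$chrom == ch
    if (nrow(b) == 0) {
      stop(sprintf("chromosome %s absent from bin table", ch))
    }
    b <- b[order(b$start), ]
    idx <- findInterval(pos[sel], b$start)
    bad <- idx == 0 | pos[sel] >= b$end[pmax(idx, 1L)]
    if (any(bad)) {
      stop(sprintf("gene anchor outside binned region on %s (e.g. %s)",
                   ch, genes$gene_id[sel][bad][1]))
    }
    out[sel] <- b$bin_id[idx]
  }
  names(out) <- genes$gene_id
  out
}

#' Trans contact frequency between two genes
#'
#' Returns the matrix value at the genes' bins. Same-chromosome pairs return
#' `NA` (the excluded-pair marker): cis values never enter pair statistics.
#'
#' @param cm `contact_matrix`.
#' @param gene_a,gene_b Single-row gene-model data.frames (or ids resolvable
#'   via `genes`).
#' @param genes Optional gene-model table when ids are passed.
#' @return Contact value, or `NA` for a same-chromosome pair.
#' @export
pair_contact_frequency <- function(cm, gene_a, gene_b, genes = NULL) {
  resolve <- function(g) {
    if (is.character(g)) {
      if (is.null(genes)) stop("gene ids need a gene table")
      g <- genes[genes$gene_id == g, , drop = FALSE]
      if (nrow(g) == 0) stop("unmapped gene")
    }
    g
  }
  a <- resolve(gene_a); b <- resolve(gene_b)
  if (a$chrom == b$chrom) return(NA_real_)
  ba <- gene_bin_index(a, cm); bb <- gene_bin_index(b, cm)
  cm$values[ba + 1L, bb + 1L]
}

# vectorized helpers used by the permutation schemes -------------------------

# draw m universe indices whose chromosome differs from chrom_other
draw_trans <- function(m, universe_idx, universe_chrom, chrom_other) {
  out <- universe_idx[sample.int(length(universe_idx), m, replace = TRUE)]
  repeat {
    clash <- universe_chrom[out] == chrom_other
    if (!any(clash)) return(out)
    out[clash] <- universe_idx[sample.int(length(universe_idx), sum(clash), replace = TRUE)]
  }
}

#' Pair-proximity permutation test for TPG pairs
#'
#' The observed statistic is the mean trans contact frequency over mapped
#' interchromosomal TPG pairs. Four null schemes are compared against it:
#'
#' * `shuffle` — permute the 3' genes across pairs (both gene multisets
#'   preserved); same-chromosome combinations arising in a permutation are
#'   excluded from that permutation's mean;
#' * `replace5` / `replace3` — substitute one side with uniform draws from the
#'   gene universe, redrawing same-chromosome combinations so the pair count
#'   stays constant;
#' * `random` — both sides drawn from the universe (same-chromosome draws
#'   redrawn).
#'
#' Each scheme's p-value is the add-one empirical probability that a permuted
#' mean is at least the observed mean (i.e. that random pairs are as close or
#' closer).
#'
#' @param pairs data.frame with five_gene, three_gene.
#' @param cm `contact_matrix`.
#' @param genes Gene-model data.frame (must cover pairs and universe).
#' @param universe Character vector of gene ids forming the background
#'   universe (defaults to all genes).
#' @param n_perm Permutations per scheme (the full-scale analysis uses 10^5).
#' @param seed Integer seed.
#' @param anchor Bin-anchor mode passed to [gene_bin_index()].
#' @return List of class `pair_proximity_result`: observed_mean, n_pairs, and
#'   per-scheme data.frame (scheme, null_mean, null_sd, p_value), plus the
#'   null mean vectors.
#' @export
tpg_pair_proximity_test <- function(pairs, cm, genes, universe = genes$gene_id,
                                    n_perm = 1e5, seed = 1,
                                    anchor = c("midpoint", "tss")) {
  anchor <- match.arg(anchor)
  if (nrow(pairs) < 2) stop("need at least two pairs")
  bin_of <- gene_bin_index(genes, cm, anchor)
  chrom_of <- stats::setNames(genes$chrom, genes$gene_id)
  miss <- setdiff(unique(c(pairs$five_gene, pairs$three_gene, universe)),
                  genes$gene_id)
  if (length(miss)) stop("genes absent from gene table: ", paste(miss, collapse = ", "))

  b5 <- unname(bin_of[pairs$five_gene]); c5 <- unname(chrom_of[pairs$five_gene])
  b3 <- unname(bin_of[pairs$three_gene]); c3 <- unname(chrom_of[pairs$three_gene])
  trans <- c5 != c3
  if (!any(trans)) stop("no interchromosomal pairs")
  V <- cm$values
  observed <- mean(V[cbind(b5[trans] + 1L, b3[trans] + 1L)])
  n_used <- sum(trans)

  ub <- unname(bin_of[universe]); uc <- unname(chrom_of[universe])
  if (length(universe) < nrow(pairs)) stop("universe smaller than the pair list")
  uidx <- seq_along(universe)

  # permuted means operate on the trans-mapped pairs only, keeping the
  # statistic a mean over n_used pairs (except shuffle, which drops clashes)
  tb5 <- b5[trans]; tc5 <- c5[trans]; tb3 <- b3[trans]; tc3 <- c3[trans]
  m <- n_used
  set.seed(seed)
  nulls <- list(
    shuffle = vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(m)
      keep <- tc5 != tc3[idx]
      if (!any(keep)) return(NA_real_)
      mean(V[cbind(tb5[keep] + 1L, tb3[idx][keep] + 1L)])
    }, numeric(1)),
    replace5 = vapply(seq_len(n_perm), function(b) {
      r <- draw_trans(m, uidx, uc, tc3)
      mean(V[cbind(ub[r] + 1L, tb3 + 1L)])
    }, numeric(1)),
    replace3 = vapply(seq_len(n_perm), function(b) {
      r <- draw_trans(m, uidx, uc, tc5)
      mean(V[cbind(tb5 + 1L, ub[r] + 1L)])
    }, numeric(1)),
    random = vapply(seq_len(n_perm), function(b) {
      r5 <- uidx[sample.int(length(uidx), m, replace = TRUE)]
      r3 <- draw_trans(m, uidx, uc, uc[r5])
      mean(V[cbind(ub[r5] + 1L, ub[r3] + 1L)])
    }, numeric(1))
  )
  nulls <- lapply(nulls, function(v) v[!is.na(v)])
  schemes <- data.frame(
    scheme = names(nulls),
    null_mean = vapply(nulls, mean, numeric(1)),
    null_sd = vapply(nulls, stats::sd, numeric(1)),
    p_value = vapply(nulls, function(v) empirical_pvalue(observed, v, "ge"),
                     numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(observed_mean = observed, n_pairs = n_used,
                 schemes = schemes, null_values = nulls),
            class = "pair_proximity_result")
}

#' Partition bins into central and peripheral clusters by k-means
#'
#' Clusters bins on their trans-only contact profiles (each bin's row of the
#' matrix with cis entries masked; masked entries are imputed with the row's
#' mean trans contact, since k-means needs complete rows). The cluster with
#' the higher mean trans contact is labelled central. Multiple restarts; best
#' within-cluster sum of squares; deterministic given seed.
#'
#' @param cm `contact_matrix`.
#' @param k Number of clusters (default 2: central / peripheral).
#' @param seed Integer seed.
#' @param restarts k-means restarts (default 10).
#' @return List of class `compartment_partition`: labels (character vector
#'   per bin: "central"/"peripheral" for k = 2, otherwise "cluster<i>"),
#'   cluster_mean_trans, centrality (per-bin mean trans contact), cluster
#'   (integer assignments).
#' @export
partition_contact_clusters <- function(cm, k = 2, seed = 1, restarts = 10) {
  n <- nrow(cm$bins)
  if (k > n) stop("k cannot exceed the number of bins")
  same_chrom <- outer(cm$bins$chrom, cm$bins$chrom, `==`)
  x <- cm$values
  trans_mean <- rowSums(x * !same_chrom) / rowSums(!same_chrom)
  x[same_chrom] <- trans_mean[row(x)[same_chrom]]
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100)
  cl_mean <- vapply(seq_len(k), function(i) mean(trans_mean[km$cluster == i]),
                    numeric(1))
  labels <- if (k == 2) {
    ifelse(km$cluster == which.max(cl_mean), "central", "peripheral")
  } else {
    paste0("cluster", rank(-cl_mean)[km$cluster])
  }
  structure(list(labels = labels, cluster_mean_trans = cl_mean,
                 centrality = trans_mean, cluster = km$cluster),
            class = "compartment_partition")
}

#' Locus centrality: mean trans contact of a gene's bin
#'
#' Mean of the gene's matrix row over bins on other chromosomes; entirely
#' independent of cis values.
#'
#' @param cm `contact_matrix`.
#' @param genes Gene-model data.frame (vectorized).
#' @param anchor Bin-anchor mode.
#' @return Numeric vector named by gene_id.
#' @export
locus_centrality <- function(cm, genes, anchor = c("midpoint", "tss")) {
  anchor <- match.arg(anchor)
  bins <- gene_bin_index(genes, cm, anchor)
  out <- numeric(length(bins))
  for (i in seq_along(bins)) {
    ch <- cm$bins$chrom[bins[i] + 1L]
    trans_cols <- cm$bins$chrom != ch
    out[i] <- mean(cm$values[bins[i] + 1L, trans_cols])
  }
  names(out) <- genes$gene_id
  out
}

#' Lineage comparison of pair contacts between two cell-line matrices
#'
#' Per pair: `log2(a + eps) - log2(b + eps)` of the two matrices' trans
#' contact values. Within each lineage subset a two-sided Wilcoxon
#' signed-rank test asks whether the paired difference is centred at zero;
#' a Mann-Whitney test compares the two lineages' difference distributions;
#' the Spearman correlation relates the two matrices over all used pairs.
#' Pairs unmapped in either matrix (or cis) are dropped with a warning.
#'
#' @param pairs data.frame with five_gene, three_gene, lineage.
#' @param cm_a,cm_b `contact_matrix` for the two cell lines.
#' @param genes Gene-model data.frame.
#' @param eps Pseudocount added before log2 (default 1).
#' @param lineages Two lineage labels to compare (default HEM-L vs HEM-M).
#' @return List: per_pair (data.frame fusion row, value_a, value_b, diff,
#'   lineage), wilcoxon_p (named per lineage), mann_whitney_p, spearman_r.
#' @export
lineage_contact_difference <- function(pairs, cm_a, cm_b, genes, eps = 1,
                                       lineages = c("HEM-L", "HEM-M")) {
  val <- function(cm) {
    b5 <- gene_bin_index(genes, cm)[pairs$five_gene]
    b3 <- gene_bin_index(genes, cm)[pairs$three_gene]
    c5 <- genes$chrom[match(pairs$five_gene, genes$gene_id)]
    c3 <- genes$chrom[match(pairs$three_gene, genes$gene_id)]
    v <- cm$values[cbind(b5 + 1L, b3 + 1L)]
    v[c5 == c3] <- NA_real_
    v
  }
  va <- val(cm_a); vb <- val(cm_b)
  keep <- !is.na(va) & !is.na(vb)
  if (any(!keep)) warning(sum(!keep), " pair(s) dropped (cis or unmapped)")
  per_pair <- data.frame(pairs[keep, , drop = FALSE],
                         value_a = va[keep], value_b = vb[keep],
                         diff = log2(va[keep] + eps) - log2(vb[keep] + eps),
                         stringsAsFactors = FALSE)
  wilcox_p <- vapply(lineages, function(l) {
    d <- per_pair$diff[per_pair$lineage == l]
    if (length(d) == 0 || all(d == 0)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(d)$p.value)
  }, numeric(1))
  da <- per_pair$diff[per_pair$lineage == lineages[1]]
  db <- per_pair$diff[per_pair$lineage == lineages[2]]
  mw_p <- if (length(da) && length(db)) {
    suppressWarnings(stats::wilcox.test(da, db)$p.value)
  } else NA_real_
  rho <- suppressWarnings(stats::cor(per_pair$value_a, per_pair$value_b,
                                     method = "spearman"))
  list(per_pair = per_pair, wilcoxon_p = wilcox_p, mann_whitney_p = mw_p,
       spearman_r = rho)
}

#' Closeness of a chromosome pair from its trans contact distribution
#'
#' Returns all bin-pair trans contact values between two different
#' chromosomes, with median and IQR; two chromosome pairs can then be
#' compared by a Mann-Whitney test on these distributions.
#'
#' @param cm `contact_matrix`.
#' @param chrom_a,chrom_b Distinct chromosome names present in the bin table.
#' @return List: values, median, iqr, n.
#' @export
chromosome_pair_closeness <- function(cm, chrom_a, chrom_b) {
  if (chrom_a == chrom_b) stop("chromosome pair must be two different chromosomes")
  ia <- which(cm$bins$chrom == chrom_a)
  ib <- which(cm$bins$chrom == chrom_b)
  if (length(ia) == 0) stop("chromosome absent: ", chrom_a)
  if (length(ib) == 0) stop("chromosome absent: ", chrom_b)
  vals <- as.vector(cm$values[ia, ib, drop = FALSE])
  list(values = vals, median = stats::median(vals),
       iqr = stats::IQR(vals), n = length(vals))
}
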