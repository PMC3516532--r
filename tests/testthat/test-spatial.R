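# Hi-C pair proximity, permutation schemes, partitioning and centrality.

test_that("genes map to bins by midpoint under the half-open rule", {
  cm <- uniform_contact_matrix(nb = 4)
  g <- data.frame(gene_id = c("a", "b", "c"), chrom = c("chr1", "chr1", "chr2"),
                  strand = "+", tx_start = c(2.4e6, 1.9e6, 0),
                  tx_end = c(2.6e6, 2.1e6, 2e5), cds_start_nt = 1,
                  utr3_start = NA, utr3_end = NA)
  idx <- gene_bin_index(g, cm)
  expect_equal(unname(idx["a"]), 2L)   # midpoint 2.5e6 -> third bin of chr1
  expect_equal(unname(idx["b"]), 2L)   # midpoint exactly at 2e6 -> right bin
  expect_equal(unname(idx["c"]), 4L)   # first bin of chr2
  bad <- data.frame(gene_id = "z", chrom = "chrX", strand = "+",
                    tx_start = 0, tx_end = 10, cds_start_nt = 1,
                    utr3_start = NA, utr3_end = NA)
  expect_error(gene_bin_index(bad, cm), "absent")
})

test_that("pair contact frequency is symmetric and excludes cis pairs", {
  cm <- uniform_contact_matrix(nb = 3, trans = 5)
  g <- data.frame(gene_id = c("a", "b", "c"),
                  chrom = c("chr1", "chr2", "chr1"), strand = "+",
                  tx_start = c(0, 0, 1.2e6), tx_end = c(2e5, 2e5, 1.4e6),
                  cds_start_nt = 1, utr3_start = NA, utr3_end = NA)
  expect_equal(pair_contact_frequency(cm, g[1, ], g[2, ]), 5)
  expect_equal(pair_contact_frequency(cm, g[2, ], g[1, ]), 5)
  expect_true(is.na(pair_contact_frequency(cm, g[1, ], g[3, ])))
  expect_error(pair_contact_frequency(cm, "a", "nope", genes = g), "unmapped")
})

test_that("an exchangeable flat matrix gives high p for every scheme", {
  cm <- uniform_contact_matrix(nb = 6, trans = 2)
  set.seed(15)
  g <- data.frame(gene_id = paste0("g", 1:40),
                  chrom = sample(c("chr1", "chr2"), 40, TRUE), strand = "+",
                  tx_start = sample(seq(0, 5.5e6, 5e5), 40, TRUE),
                  cds_start_nt = 1, utr3_start = NA, utr3_end = NA)
  g$tx_end <- g$tx_start + 1e5
  pairs <- data.frame(five_gene = paste0("g", 1:15),
                      three_gene = paste0("g", 26:40))
  pt <- tpg_pair_proximity_test(pairs, cm, g, n_perm = 1000, seed = 3)
  expect_equal(pt$observed_mean, 2)
  expect_true(all(pt$schemes$p_value >= 0.3))
})

test_that("pair statistics are invariant to pair order and within-pair bookkeeping", {
  cfg <- simulation_config(seed = 16, n_genes = 150, n_chrom = 4,
                           chrom_length = 2e7, n_transloc = 40)
  cat_ <- simulate_genome(cfg)
  hic <- simulate_contact_matrix(cfg, cat_)
  tl <- simulate_translocation_set(cfg, cat_)
  pairs <- dedup_translocations(tl, "pairs")[, c("five_gene", "three_gene")]
  a <- tpg_pair_proximity_test(pairs, hic$matrix, cat_$genes,
                               n_perm = 200, seed = 2)
  b <- tpg_pair_proximity_test(pairs[sample.int(nrow(pairs)), ], hic$matrix,
                               cat_$genes, n_perm = 200, seed = 2)
  expect_equal(a$observed_mean, b$observed_mean)
  expect_equal(a$n_pairs, b$n_pairs)
})

test_that("permutation schemes preserve their stated marginals", {
  cm <- uniform_contact_matrix(nb = 3)
  g <- data.frame(gene_id = paste0("g", 1:8),
                  chrom = rep(c("chr1", "chr2"), 4), strand = "+",
                  tx_start = rep(c(0, 1e6, 2e6, 0), 2), cds_start_nt = 1,
                  utr3_start = NA, utr3_end = NA)
  g$tx_end <- g$tx_start + 5e5
  # shuffle keeps both gene multisets: verified through the mean over a
  # matrix where each bin pair value is unique, so any change of multiset
  # would change the attainable set of means
  vals <- matrix(seq_len(36), 6, 6)
  vals <- (vals + t(vals)) / 2
  same <- outer(cm$bins$chrom, cm$bins$chrom, `==`)
  vals[same] <- 0
  cm2 <- contact_matrix(cm$bins, vals)
  pairs <- data.frame(five_gene = c("g1", "g3"), three_gene = c("g2", "g4"))
  pt <- tpg_pair_proximity_test(pairs, cm2, g, n_perm = 50, seed = 1)
  b5 <- gene_bin_index(g, cm2)[pairs$five_gene]
  b3 <- gene_bin_index(g, cm2)[pairs$three_gene]
  attainable <- c(mean(vals[cbind(b5 + 1, b3 + 1)]),
                  mean(vals[cbind(b5 + 1, rev(b3) + 1)]))
  expect_true(all(pt$null_values$shuffle %in% attainable))
})

test_that("planted two-block matrices are partitioned exactly", {
  bins <- data.frame(bin_id = 0:9, chrom = rep(c("chr1", "chr2"), each = 5),
                     start = rep(seq(0, 4e6, 1e6), 2),
                     end = rep(seq(1e6, 5e6, 1e6), 2))
  central <- c(TRUE, TRUE, FALSE, FALSE, FALSE,
               TRUE, TRUE, FALSE, FALSE, FALSE)
  vals <- matrix(0.5, 10, 10)
  vals[central, central] <- 10
  vals[!central, !central] <- 1
  same <- outer(bins$chrom, bins$chrom, `==`)
  vals[same] <- 20
  vals <- (vals + t(vals)) / 2
  cm <- contact_matrix(bins, vals)
  part <- partition_contact_clusters(cm, k = 2, seed = 1)
  expect_equal(part$labels == "central", central)
  # labels invariant to bin permutation (up to relabeling)
  ord <- c(2, 1, 4, 3, 5, 7, 6, 9, 8, 10)
  bins2 <- bins; bins2$start <- bins$start[order(ord)]  # keep tiling valid
  cm2 <- contact_matrix(bins, vals[ord, ord])
  part2 <- partition_contact_clusters(cm2, k = 2, seed = 1)
  expect_equal(part2$labels, part$labels[ord])
})

test_that("partition recovers planted central bins with boost and low noise", {
  cfg <- simulation_config(seed = 18, contact_boost = 5, contact_noise_sd = 0.1)
  cat_ <- simulate_genome(cfg)
  hic <- simulate_contact_matrix(cfg, cat_)
  part <- partition_contact_clusters(hic$matrix, k = 2, seed = 2)
  recovery <- sum(part$labels == "central" & hic$central) / sum(hic$central)
  expect_gte(recovery, 0.95)
  expect_gte(part$cluster_mean_trans[which.max(part$cluster_mean_trans)],
             part$cluster_mean_trans[which.min(part$cluster_mean_trans)])
})

test_that("boost-free matrices split into clusters of similar mean contact", {
  cfg <- simulation_config(seed = 19, n_genes = 200, n_chrom = 4,
                           chrom_length = 2.5e7, contact_boost = 0)
  hic <- simulate_contact_matrix(cfg, simulate_genome(cfg))
  part <- partition_contact_clusters(hic$matrix, k = 2, seed = 2)
  m <- sort(part$cluster_mean_trans)
  expect_lt((m[2] - m[1]) / m[2], 0.10)
})

test_that("locus centrality averages trans contact only", {
  cm <- uniform_contact_matrix(nb = 4, trans = 3, cis = 50)
  g <- data.frame(gene_id = "a", chrom = "chr1", strand = "+",
                  tx_start = 0, tx_end = 2e5, cds_start_nt = 1,
                  utr3_start = NA, utr3_end = NA)
  expect_equal(unname(locus_centrality(cm, g)), 3)
  # changing cis values does not change centrality
  v2 <- cm$values
  same <- outer(cm$bins$chrom, cm$bins$chrom, `==`)
  v2[same] <- 999
  expect_equal(unname(locus_centrality(contact_matrix(cm$bins, v2), g)), 3)
})

test_that("lineage contact differences and correlations behave at the fixed points", {
  cfg <- simulation_config(seed = 22, n_genes = 200, n_chrom = 4,
                           chrom_length = 2e7, n_transloc = 60)
  cat_ <- simulate_genome(cfg)
  hic <- simulate_contact_matrix(cfg, cat_)
  tl <- simulate_translocation_set(cfg, cat_)
  pairs <- tl[tl$lineage %in% c("HEM-L", "HEM-M"), ]
  same <- suppressWarnings(
    lineage_contact_difference(pairs, hic$matrix, hic$matrix, cat_$genes))
  expect_true(all(same$per_pair$diff == 0))
  expect_equal(same$spearman_r, 1)

  # independently generated matrices: low correlation
  hic_b <- simulate_contact_matrix(
    simulation_config(seed = 23, n_genes = 200, n_chrom = 4,
                      chrom_length = 2e7, contact_boost = 0), cat_)
  ind <- suppressWarnings(
    lineage_contact_difference(pairs, hic$matrix, hic_b$matrix, cat_$genes))
  expect_lt(abs(ind$spearman_r), 0.35)
  expect_equal(log2(8 + 1) - log2(2 + 1),
               with(list(a = 8, b = 2), log2(a + 1) - log2(b + 1)))
})

test_that("chromosome-pair closeness returns the full trans block", {
  cm <- uniform_contact_matrix(nb = 3, trans = 2)
  cp <- chromosome_pair_closeness(cm, "chr1", "chr2")
  expect_equal(cp$n, 9)
  expect_equal(cp$median, 2)
  expect_error(chromosome_pair_closeness(cm, "chr1", "chr1"), "different")
  expect_error(chromosome_pair_closeness(cm, "chr1", "chr9"), "absent")
})

test_that("a planted chromosome-pair boost is detectable by Mann-Whitney", {
  cfg <- simulation_config(seed = 24)
  cat_ <- simulate_genome(cfg)
  hic <- simulate_contact_matrix(cfg, cat_)
  v <- hic$matrix$values
  i1 <- cm_rows <- which(hic$matrix$bins$chrom == "chr1")
  i2 <- which(hic$matrix$bins$chrom == "chr2")
  v[i1, i2] <- v[i1, i2] * 1.5
  v[i2, i1] <- t(v[i1, i2])
  cmb <- contact_matrix(hic$matrix$bins, v)
  boosted <- chromosome_pair_closeness(cmb, "chr1", "chr2")
  plain <- chromosome_pair_closeness(cmb, "chr3", "chr4")
  expect_gt(boosted$median, plain$median)
  expect_lt(wilcox.test(boosted$values, plain$values)$p.value, 0.01)
})
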