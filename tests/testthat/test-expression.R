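# Expression aggregation, paired comparisons, promoter and 3'-UTR features.

test_that("tissue and lineage-group aggregation averages at the right levels", {
  vals <- rbind(g1 = c(4, 6, 5, 7, 9), g2 = c(1, 1, 2, 2, 3))
  colnames(vals) <- paste0("s", 1:5)
  samples <- data.frame(sample_id = paste0("s", 1:5),
                        tissue = c("t1", "t1", "t2", "t2", "t3"),
                        lineage_group = c("HEM", "HEM", "HEM", "HEM", "EPI"),
                        stringsAsFactors = FALSE)
  ts <- aggregate_by_tissue(expression_table(vals, samples))
  expect_equal(ts$tissue_means["g1", "t1"], 5)       # (4+6)/2
  expect_equal(ts$tissue_means["g1", "t3"], 9)       # single sample
  expect_equal(ts$group_means["g1", "HEM"], (5 + 6) / 2)  # mean of tissue means
  expect_equal(ts$group_means["g2", "EPI"], 3)
})

test_that("paired partner differences handle signal, ties and degenerate input", {
  pd <- paired_partner_difference(c(8, 10), c(6, 7))
  expect_equal(pd$differences, c(2, 3))

  tie <- paired_partner_difference(c(3, 3), c(3, 3))
  expect_equal(tie$p_value, 1)
  expect_match(tie$flag, "tied")

  set.seed(2)
  b <- rnorm(100, 5)
  a <- b + rnorm(100, 1, 0.1)
  expect_lt(paired_partner_difference(a, b)$p_value, 0.001)
  expect_error(paired_partner_difference(1:3, 1:2), "length mismatch")
})

test_that("promoter windows are strand-resolved and clipped", {
  g <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                  strand = c("+", "-", "+"),
                  tx_start = c(10000, 20000, 1000), tx_end = c(15000, 50000, 5000),
                  cds_start_nt = 1, utr3_start = NA, utr3_end = NA)
  w <- promoter_window(g, flank = 3000)
  expect_equal(unlist(w[1, c("start", "end")], use.names = FALSE), c(7000, 13000))
  expect_equal(unlist(w[2, c("start", "end")], use.names = FALSE), c(47000, 53000))
  expect_equal(unlist(w[3, c("start", "end")], use.names = FALSE), c(0, 4000))
})

test_that("Pol2 peak frequency counts cell lines with an overlapping peak", {
  g <- data.frame(gene_id = "a", chrom = "chr1", strand = "+",
                  tx_start = 10000, tx_end = 15000, cds_start_nt = 1,
                  utr3_start = NA, utr3_end = NA)
  g <- rbind(g, within(g, { gene_id <- "b"; tx_start <- 50000; tx_end <- 60000 }))
  # promoter of a: [7000, 13000)
  hit <- interval_track(data.frame(chrom = "chr1", start = 12000, end = 12500))
  edge <- interval_track(data.frame(chrom = "chr1", start = 6500, end = 7000))
  miss <- interval_track(data.frame(chrom = "chr1", start = 100, end = 200))
  pf <- pol2_peak_frequency(g, list(
    hematopoietic = list(hit, hit, edge, miss),
    non_hematopoietic = list(hit, miss)))
  expect_equal(pf$prop_hematopoietic, c(0.5, 0))  # edge-touching peak: no overlap
  expect_equal(pf$prop_non_hematopoietic, c(0.5, 0))
  expect_equal(mean(pf$z_hematopoietic), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(pf$z_hematopoietic^2)), 1, tolerance = 1e-12)
  expect_error(pol2_peak_frequency(g, list(hematopoietic = list())), "empty")
})

test_that("peak frequency is invariant to cell-line order and track splitting", {
  cfg <- simulation_config(seed = 13, n_genes = 120, n_chrom = 3,
                           chrom_length = 2e7, n_transloc = 30)
  cat_ <- simulate_genome(cfg)
  tl <- simulate_translocation_set(cfg, cat_)
  reg <- simulate_expression_and_tracks(cfg, cat_, tl)
  tracks <- reg$pol2_tracks$hematopoietic
  a <- pol2_peak_frequency(cat_$genes, list(hematopoietic = tracks))
  b <- pol2_peak_frequency(cat_$genes, list(hematopoietic = rev(tracks)))
  expect_equal(a$prop_hematopoietic, b$prop_hematopoietic)
  # splitting one cell line's BED into two files must not change the
  # per-cell-line indicator when both halves are still that cell line
  tr <- tracks[[1]]
  half1 <- interval_track(tr[seq(1, nrow(tr), 2), ])
  half2 <- interval_track(tr[seq(2, nrow(tr), 2), ])
  merged_hits <- GenomicRanges::countOverlaps(
    tpghallmarks:::track_to_granges(promoter_window(cat_$genes)),
    tpghallmarks:::track_to_granges(tr)) > 0
  split_hits <- (GenomicRanges::countOverlaps(
    tpghallmarks:::track_to_granges(promoter_window(cat_$genes)),
    tpghallmarks:::track_to_granges(half1)) +
      GenomicRanges::countOverlaps(
        tpghallmarks:::track_to_granges(promoter_window(cat_$genes)),
        tpghallmarks:::track_to_granges(half2))) > 0
  expect_equal(merged_hits, split_hits)
})

test_that("signal metaprofile normalizes, mirrors minus-strand genes and peaks upstream", {
  g <- data.frame(gene_id = "a", chrom = "chr1", strand = "+",
                  tx_start = 10000, tx_end = 15000, cds_start_nt = 1,
                  utr3_start = NA, utr3_end = NA)
  const <- signal_profile(data.frame(chrom = "chr1",
                                     start = seq(6000, 13900, 100),
                                     end = seq(6100, 14000, 100), value = 3),
                          "signal")
  prof <- signal_metaprofile(const, g, flank = 3000, n_bins = 10)
  expect_equal(prof, rep(1, 10))

  # signal only upstream of the TSS
  up <- signal_profile(data.frame(chrom = "chr1",
                                  start = seq(7000, 9900, 100),
                                  end = seq(7100, 10000, 100), value = 10),
                       "signal")
  pu <- signal_metaprofile(up, g, flank = 3000, n_bins = 10)
  expect_gt(max(pu[1:5], na.rm = TRUE), max(pu[6:10], 0, na.rm = TRUE))

  # a minus-strand gene with the same windows contributes mirrored bins
  gm <- g; gm$strand <- "-"; gm$tx_start <- 5000; gm$tx_end <- 10000
  pm <- signal_metaprofile(up, gm, flank = 3000, n_bins = 10)
  expect_equal(pm, rev(pu))
  expect_error(signal_metaprofile(up, within(g, chrom <- "chrX"), 3000, 10),
               "no gene promoter")
})

test_that("metaprofile of strand-randomized genes over symmetric signal is flat", {
  set.seed(14)
  tss <- seq(2e5, 2e6, 1e5)
  g <- data.frame(gene_id = paste0("g", seq_along(tss)), chrom = "chr1",
                  strand = sample(c("+", "-"), length(tss), TRUE),
                  tx_start = tss, tx_end = tss + 1000, cds_start_nt = 1,
                  utr3_start = NA, utr3_end = NA)
  g$tx_start[g$strand == "-"] <- tss[g$strand == "-"] - 1000
  g$tx_end[g$strand == "-"] <- tss[g$strand == "-"]
  sig <- signal_profile(data.frame(chrom = "chr1",
                                   start = seq(0, 2.1e6, 500),
                                   end = seq(500, 2.1e6 + 500, 500),
                                   value = 4), "signal")
  prof <- signal_metaprofile(sig, g, flank = 3000, n_bins = 12)
  expect_lt(diff(range(prof)), 0.01)
})

test_that("3'-UTR features count >=1 bp overlaps under the half-open rule", {
  g <- data.frame(gene_id = c("a", "b"), chrom = "chr1", strand = "+",
                  tx_start = c(0, 0), tx_end = c(1000, 1000), cds_start_nt = 1,
                  utr3_start = c(100, NA), utr3_end = c(400, NA))
  cons <- interval_track(data.frame(chrom = "chr1",
                                    start = c(150, 390, 400),
                                    end = c(160, 410, 420)))
  mir <- interval_track(data.frame(chrom = "chr1", start = 1, end = 2))
  u <- utr3_features(g, cons, mir)
  expect_equal(u$utr_length[1], 300)
  expect_equal(u$n_conserved[1], 2)   # [400,420) does not overlap [100,400)
  expect_equal(u$n_mirna_sites[1], 0)
  expect_false(u$has_utr[2])
  expect_true(is.na(u$utr_length[2]))
  empty <- interval_track(data.frame(chrom = character(), start = numeric(),
                                     end = numeric()))
  expect_equal(utr3_features(g, empty, empty)$n_conserved[1], 0)
})

test_that("fusion gain statistics emit the three formulas", {
  profiles <- data.frame(fusion_id = c("T1", "T2"),
                         five_gene = c("a", "c"), three_gene = c("b", "d"),
                         five_type = c(1L, 2L), three_type = c(2L, 1L))
  pf <- data.frame(gene_id = c("a", "b", "c", "d"),
                   prop_hematopoietic = c(0.8, 0.3, 0.5, 0.5))
  utr <- data.frame(gene_id = c("a", "b", "c", "d"),
                    utr_length = c(2000, 500, 1000, 1000))
  hem <- c(a = 6, b = 3, c = 4, d = 4)
  gs <- fusion_gain_stats(profiles, pf, utr, hem)
  expect_equal(gs$per_fusion$pol2_gain[1], 0.5)
  expect_equal(gs$per_fusion$utr_log2_ratio[1], 2.0)
  expect_equal(gs$per_fusion$expr_increase[1], 1.0)
  expect_equal(gs$tests$statistic,
               c("pol2_gain", "utr_log2_ratio", "expr_increase"))
})

test_that("the planted HEM shift is recovered from lineage-group contrasts", {
  devs <- numeric(6)
  for (s in 1:6) {
    cfg <- simulation_config(seed = 30 + s, n_transloc = 200)
    cat_ <- simulate_genome(cfg)
    tl <- simulate_translocation_set(cfg, cat_)
    reg <- simulate_expression_and_tracks(cfg, cat_, tl)
    gm <- aggregate_by_tissue(reg$expression)$group_means
    five <- rownames(gm) %in% tl$five_gene
    contrast <- gm[five, "HEM"] - (gm[five, "EPI"] + gm[five, "MES"]) / 2
    devs[s] <- median(contrast)
  }
  # each seed carries a random tissue-effect offset; the mean over seeds
  # must centre on the planted shift
  expect_lt(abs(mean(devs) - 1.0), 0.2)
})
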