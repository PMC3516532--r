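# Breakpoint conversion, retention accounting, categorization, co-occurrence
# counting and the permutation test.

test_that("breakpoint nucleotide-to-amino-acid conversion clamps upstream hits", {
  expect_equal(breakpoint_nt_to_aa(100, 100)$aa, 1L)
  expect_equal(breakpoint_nt_to_aa(103, 100)$aa, 2L)
  up <- breakpoint_nt_to_aa(50, 100)
  expect_equal(up$aa, 0L)
  expect_true(up$upstream)
  expect_error(breakpoint_nt_to_aa(0, 100), "1-based")
})

test_that("retention keeps only features entirely on one side of the breakpoint", {
  dom <- data.frame(gene_id = "g", feature_id = paste0("f", 1:4),
                    aa_start = c(10, 150, 280, 400),
                    aa_end = c(100, 290, 350, 500),
                    is_pii = FALSE, partners = "", stringsAsFactors = FALSE)
  r5 <- retained_and_lost(dom, 300, "five_prime")
  expect_equal(nrow(r5$retained), 2)   # (10-100), (150-290)
  expect_equal(nrow(r5$lost), 2)       # spanning (280-350) and downstream
  r3 <- retained_and_lost(dom, 300, "three_prime")
  expect_equal(r3$retained$feature_id, "f4")
  expect_equal(nrow(r3$lost), 3)
  # clamped breakpoint 0 on the 3' side retains everything
  r0 <- retained_and_lost(dom, 0, "three_prime")
  expect_equal(nrow(r0$retained), 4)
  # accounting identity
  expect_equal(nrow(r5$retained) + nrow(r5$lost), nrow(dom))
})

test_that("category sets map retained domains and type flags correctly", {
  dom <- data.frame(gene_id = "g", feature_id = c("F_D", "F_O", "PII_x"),
                    aa_start = c(1, 10, 20), aa_end = c(5, 15, 30),
                    is_pii = c(FALSE, FALSE, TRUE),
                    partners = c("", "", "gZ"), stringsAsFactors = FALSE)
  cmap <- c(F_D = "D", F_O = "O")
  r <- retained_and_lost(dom, 100, "five_prime")
  cs <- partner_category_set(r, cmap)
  expect_setequal(cs$categories, c("D", "O"))
  expect_equal(cs$type, 1L)

  r_none <- retained_and_lost(dom, 1, "five_prime")
  cs_none <- partner_category_set(r_none, cmap)
  expect_equal(cs_none$categories, "N")
  expect_equal(cs_none$type, 2L)

  only_o <- retained_and_lost(dom[2, ], 100, "five_prime")
  expect_equal(partner_category_set(only_o, cmap)$type, 2L)

  bad <- retained_and_lost(within(dom, feature_id[1] <- "F_UNKNOWN"),
                           100, "five_prime")
  expect_error(partner_category_set(bad, cmap), "unmapped")
})

test_that("co-occurrence counts follow the set-product rule with N for empty sets", {
  profiles <- data.frame(
    five_cats = c("D", "D,P", "N"),
    three_cats = c("P", "P", "K"), stringsAsFactors = FALSE)
  cnt <- cooccurrence_counts(profiles)
  expect_equal(cnt["D", "P"], 2L)
  expect_equal(cnt["P", "P"], 1L)
  expect_equal(cnt["N", "K"], 1L)
  expect_equal(sum(cnt), 4L)

  single <- data.frame(five_cats = "N", three_cats = "N")
  cs <- cooccurrence_counts(single)
  expect_equal(cs["N", "N"], 1L)
  expect_equal(sum(cs), 1L)

  # margin identity: row sums >= number of translocations carrying that
  # 5' category, with equality when all 3' sets are singletons
  expect_equal(sum(cnt["D", ]), 2L)
})

test_that("fusion profile extraction preserves the retention accounting identity", {
  cfg <- simulation_config(seed = 17, n_genes = 150, n_chrom = 3,
                           chrom_length = 2e7, n_transloc = 60)
  cat_ <- simulate_genome(cfg)
  tl <- simulate_translocation_set(cfg, cat_)
  fp <- fusion_profiles(tl, cat_$genes, cat_$domains, cat_$cmap)
  dom_counts <- table(cat_$domains$gene_id)
  for (fid in tl$fusion_id[1:20]) {
    ret <- fp$retentions[[fid]]
    g5 <- tl$five_gene[tl$fusion_id == fid]
    n5 <- if (g5 %in% names(dom_counts)) dom_counts[[g5]] else 0L
    expect_equal(nrow(ret$five$retained) + nrow(ret$five$lost), n5)
    g3 <- tl$three_gene[tl$fusion_id == fid]
    n3 <- if (g3 %in% names(dom_counts)) dom_counts[[g3]] else 0L
    expect_equal(nrow(ret$three$retained) + nrow(ret$three$lost), n3)
  }
  # a side with all-zero bits is exactly the N encoding
  bits3 <- as.matrix(fp$profiles[, paste0("three_", c("D", "P", "H", "K", "O"))])
  expect_equal(rowSums(bits3) == 0, fp$profiles$three_cats == "N")
})

test_that("permutation test matches exhaustive enumeration on tiny inputs", {
  profiles <- data.frame(
    five_cats = c("D", "O", "N", "D,P"),
    three_cats = c("K", "K", "P", "N"), stringsAsFactors = FALSE)
  exact <- enumerate_cooccurrence_p(profiles)
  mc <- cooccurrence_permutation_test(profiles, n_perm = 2e4, seed = 5)
  for (a in 1:6) for (b in 1:6) {
    if (!mc$tested[a, b]) next
    se <- sqrt(exact$p_two[a, b] * (1 - exact$p_two[a, b]) / 2e4)
    expect_lt(abs(mc$p_values[a, b] - exact$p_two[a, b]),
              2 * (3 * se) + 1e-3)
    expect_lt(abs(mc$null_mean[a, b] - exact$null_mean[a, b]),
              4 * sqrt(max(exact$null_mean[a, b], 0.05) / 2e4) + 0.02)
  }
})

test_that("a single translocation yields p = 1 everywhere", {
  one <- data.frame(five_cats = "D", three_cats = "K")
  r <- cooccurrence_permutation_test(one, n_perm = 100, seed = 1)
  expect_true(all(r$p_values[r$tested] == 1))
})

test_that("fold is exactly 1 for a category present in every 3' set", {
  profiles <- data.frame(five_cats = c("D", "O", "N"),
                         three_cats = c("K", "K", "K"), stringsAsFactors = FALSE)
  r <- cooccurrence_permutation_test(profiles, n_perm = 500, seed = 2)
  # every permutation reproduces the same (x, K) counts
  expect_equal(r$fold["D", "K"], 1)
  expect_equal(r$fold["O", "K"], 1)
  expect_equal(r$fold["N", "K"], 1)
})

test_that("the permutation null preserves both marginal category-set multisets", {
  profiles <- data.frame(
    five_cats = c("D", "O,P", "N", "K"),
    three_cats = c("K", "P", "D,H", "N"), stringsAsFactors = FALSE)
  m5 <- tpghallmarks:::category_membership(profiles$five_cats)
  m3 <- tpghallmarks:::category_membership(profiles$three_cats)
  key <- function(m) sort(apply(m, 1, paste, collapse = ""))
  set.seed(3)
  for (r in 1:25) {
    p <- sample.int(4)
    # 5' sets untouched, 3' multiset preserved under the shuffle
    expect_identical(key(m3[p, , drop = FALSE]), key(m3))
    # per-category totals on both sides are therefore invariant
    expect_equal(colSums(m3[p, , drop = FALSE]), colSums(m3))
    expect_equal(colSums(m5), colSums(m5))
  }
})

test_that("type dependency test builds the 2x2 table and permutation fold", {
  profiles <- data.frame(five_type = c(1, 1, 2, 2), three_type = c(1, 2, 1, 2))
  td <- type_dependency_test(profiles, n_perm = 500, seed = 4)
  expect_equal(as.vector(td$table), rep(1L, 4))
  expect_equal(td$fisher_p, 1.0)
  expect_equal(td$t2t2_fraction, 0.25)

  all1 <- data.frame(five_type = rep(1, 10), three_type = rep(1, 10))
  td1 <- type_dependency_test(all1, n_perm = 100, seed = 4)
  expect_true(td1$fisher_skipped)
  expect_equal(td1$t2t2_fraction, 0)

  sym <- data.frame(five_type = rep(c(1, 1, 2, 2), 2),
                    three_type = rep(c(1, 2, 1, 2), 2))
  expect_equal(type_dependency_test(sym, n_perm = 100, seed = 1)$fisher_p, 1.0)
})

test_that("planted type dependence is detected by the Fisher test", {
  f <- matrix(1, 6, 6, dimnames = list(tpghallmarks:::CATEGORIES_N,
                                       tpghallmarks:::CATEGORIES_N))
  # 5' type-1 categories pair preferentially with 3' type-2 categories
  f[c("D", "P"), c("O", "N")] <- 1.5
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(seed = 500 + s, cooccurrence_fold = f)
    cat_ <- simulate_genome(cfg)
    tl <- simulate_translocation_set(cfg, cat_)
    fp <- fusion_profiles(tl, cat_$genes, cat_$domains, cat_$cmap)
    td <- type_dependency_test(fp$profiles, n_perm = 200, seed = s)
    hits <- hits + (!td$fisher_skipped && td$fisher_p < 0.05)
  }
  expect_gte(hits, ceiling(0.8 * n_seeds))
})

test_that("interactor networks follow retained interfaces with multiplicity", {
  cat_ <- tiny_catalog()
  tl <- data.frame(fusion_id = c("T1", "T2"),
                   five_gene = c("gA", "gC"), three_gene = c("gB", "gB"),
                   five_bp_nt = c(1000, 500),
                   three_bp_nt = c(200 + 3 * 350, 200 + 3 * 350),
                   lineage = "both", report_count = 1,
                   stringsAsFactors = FALSE)
  fp <- fusion_profiles(tl, cat_$genes, cat_$domains, cat_$cmap)
  # gB breakpoint at aa 351 < PII start 400 -> PII retained on the 3' side
  net <- build_interactor_network(fp$retentions, "three_prime")
  expect_setequal(unique(net$edges$partner), c("gC", "gD"))
  expect_equal(nrow(net$edges), 4)  # both fusions retain the same PII
  # one TPG (gB) -> multiset counts each distinct TPG-partner link once
  expect_equal(sort(net$partner_multiset), c("gC", "gD"))

  # PII lost to the breakpoint -> no edges
  tl_lost <- tl
  tl_lost$three_bp_nt <- 200 + 3 * 520   # aa 521 > PII end 500
  fp2 <- fusion_profiles(tl_lost, cat_$genes, cat_$domains, cat_$cmap)
  expect_equal(nrow(build_interactor_network(fp2$retentions, "three_prime")$edges), 0)
})
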