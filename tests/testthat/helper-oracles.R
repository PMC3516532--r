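# Independent oracles and small fixture builders used across the suite.

# all permutations of 1..n (n <= 7), one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

# exact per-cell two-sided p-values for the co-occurrence statistic by
# enumerating every pairing of 3' category sets (tiny n only)
enumerate_cooccurrence_p <- function(profiles) {
  m5 <- tpghallmarks:::category_membership(profiles$five_cats)
  m3 <- tpghallmarks:::category_membership(profiles$three_cats)
  observed <- crossprod(m5, m3)
  perms <- all_perms(nrow(profiles))
  n_ge <- matrix(0, 6, 6); n_le <- matrix(0, 6, 6); acc <- matrix(0, 6, 6)
  for (r in seq_len(nrow(perms))) {
    cnt <- crossprod(m5, m3[perms[r, ], , drop = FALSE])
    n_ge <- n_ge + (cnt >= observed)
    n_le <- n_le + (cnt <= observed)
    acc <- acc + cnt
  }
  n_all <- nrow(perms)
  p_ge <- matrix(n_ge / n_all, 6, 6, dimnames = dimnames(observed))
  p_le <- matrix(n_le / n_all, 6, 6, dimnames = dimnames(observed))
  p_two <- matrix(pmin(1, 2 * pmin(p_ge, p_le)), 6, 6,
                  dimnames = dimnames(observed))
  list(p_two = p_two, p_ge = p_ge, p_le = p_le,
       null_mean = acc / n_all, observed = observed)
}

# brute-force two-sided Fisher p for a 2x2 table by full enumeration of
# tables with the observed margins, using only choose()
fisher_bruteforce <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  k_min <- max(0, cs[1] - r[2]); k_max <- min(r[1], cs[1])
  prob_a <- function(a) {
    choose(r[1], a) * choose(r[2], cs[1] - a) / choose(n, cs[1])
  }
  probs <- vapply(k_min:k_max, prob_a, numeric(1))
  p_obs <- prob_a(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact upper/lower binomial tail using only choose()
binom_tail_bruteforce <- function(k, n, p0, upper = TRUE) {
  xs <- if (upper) k:n else 0:k
  sum(vapply(xs, function(x) choose(n, x) * p0^x * (1 - p0)^(n - x), numeric(1)))
}

# small deterministic gene/domain fixture: 4 genes, mixed strands, one
# missing UTR; domains spanning known categories
tiny_catalog <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "-", "+", "-"),
    tx_start = c(10000, 50000, 2000, 70000),
    tx_end = c(30000, 80000, 20000, 95000),
    cds_start_nt = c(100, 200, 150, 120),
    utr3_start = c(28000, 50000, NA, 70000),
    utr3_end = c(30000, 51000, NA, 70500),
    stringsAsFactors = FALSE)
  domains <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gD"),
    feature_id = c("F_D", "F_O", "F_K", "PII_gB_1", "F_P", "F_H"),
    aa_start = c(10, 150, 280, 400, 5, 50),
    aa_end = c(100, 290, 350, 500, 60, 120),
    is_pii = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    partners = c("", "", "", "gC,gD", "", ""),
    stringsAsFactors = FALSE)
  cmap <- c(F_D = "D", F_O = "O", F_K = "K", F_P = "P", F_H = "H")
  list(genes = validate_gene_models(genes),
       domains = validate_domains(domains), cmap = cmap)
}

# a small contact matrix: two chromosomes, nb bins each, constant trans value
uniform_contact_matrix <- function(nb = 4, trans = 2, cis = 10) {
  bins <- data.frame(bin_id = 0:(2 * nb - 1),
                     chrom = rep(c("chr1", "chr2"), each = nb),
                     start = rep(seq(0, by = 1e6, length.out = nb), 2),
                     end = rep(seq(1e6, by = 1e6, length.out = nb), 2),
                     stringsAsFactors = FALSE)
  vals <- matrix(trans, 2 * nb, 2 * nb)
  same <- outer(bins$chrom, bins$chrom, `==`)
  vals[same] <- cis
  contact_matrix(bins, vals)
}
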