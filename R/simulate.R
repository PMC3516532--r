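# Synthetic-data generator: emits every pipeline input with known planted
# structure (expression shifts, UTR shortening, domain-category co-occurrence,
# a central nuclear compartment, RT-centrality coupling, Zipf report counts)
# so each analysis stage can be verified against ground truth.

#' Simulation configuration
#'
#' Defaults define the reference synthetic study: 1,000 genes on 10
#' chromosomes of 50 Mb (1 Mb bins, 500 bins), 300 translocations, a 3-fold
#' planted (O, K) domain-category co-occurrence, a +1 log2 hematopoietic
#' expression shift for 5' TPGs, 3' TPG 3'-UTRs halved, a central compartment
#' of 30% of bins with a 5-fold trans-contact boost at log-normal noise
#' sd 0.2, RT-centrality correlation 0.9, and Zipf(1.5) report counts.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_chrom,chrom_length,n_genes,bin_size,n_transloc Genome shape.
#' @param cooccurrence_fold 6x6 matrix (categories D/P/H/K/O/N; rows = 5',
#'   columns = 3') of planted fold factors relative to independence.
#' @param expr_shift Planted log2 expression shift of 5' TPGs in HEM samples.
#' @param utr_ratio 3' TPG UTR length ratio relative to its original length.
#' @param contact_decay Cis distance-decay exponent.
#' @param central_frac Fraction of bins in the central compartment.
#' @param contact_boost Trans-contact boost between two central bins.
#' @param contact_noise_sd Log-normal noise sd on contact values.
#' @param rt_cor RT-centrality correlation parameter in [0, 1).
#' @param zipf_exponent Report-count Zipf exponent.
#' @param lineage_probs Sampling weights for HEM-L / HEM-M / both.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_chrom = 10, chrom_length = 5e7,
                              n_genes = 1000, bin_size = 1e6, n_transloc = 300,
                              cooccurrence_fold = default_fold_matrix(),
                              expr_shift = 1.0, utr_ratio = 0.5,
                              contact_decay = 1.0, central_frac = 0.3,
                              contact_boost = 5, contact_noise_sd = 0.2,
                              rt_cor = 0.9, zipf_exponent = 1.5,
                              lineage_probs = c("HEM-L" = 0.23, "HEM-M" = 0.26,
                                                "both" = 0.51)) {
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              chrom_length = chrom_length, n_genes = n_genes,
              bin_size = bin_size, n_transloc = n_transloc,
              cooccurrence_fold = cooccurrence_fold, expr_shift = expr_shift,
              utr_ratio = utr_ratio, contact_decay = contact_decay,
              central_frac = central_frac, contact_boost = contact_boost,
              contact_noise_sd = contact_noise_sd, rt_cor = rt_cor,
              zipf_exponent = zipf_exponent, lineage_probs = lineage_probs)
  stopifnot(cfg$n_chrom > 0, cfg$n_genes > 0, cfg$n_transloc > 0,
            cfg$bin_size > 0, cfg$chrom_length > 0,
            cfg$central_frac > 0, cfg$central_frac < 1,
            cfg$utr_ratio > 0, cfg$utr_ratio <= 1,
            cfg$contact_boost >= 0, cfg$contact_noise_sd >= 0,
            cfg$rt_cor >= 0, cfg$rt_cor < 1)
  if (!all(dim(cfg$cooccurrence_fold) == c(6, 6)) ||
      any(cfg$cooccurrence_fold <= 0)) {
    stop("cooccurrence_fold must be a 6x6 matrix of positive folds")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Default planted co-occurrence fold matrix: all 1 except 3-fold on (O, K)
#' @return 6x6 matrix over categories D/P/H/K/O/N.
#' @export
default_fold_matrix <- function() {
  f <- matrix(1, 6, 6, dimnames = list(CATEGORIES_N, CATEGORIES_N))
  f["O", "K"] <- 3
  f
}

# protein length implied by a gene model: coding nt between CDS start and the
# 3'-UTR, floored to whole codons, at least 30 aa
gene_protein_length <- function(genes) {
  tx_len <- genes$tx_end - genes$tx_start
  utr_len <- ifelse(is.na(genes$utr3_start), 0, genes$utr3_end - genes$utr3_start)
  pmax(30, floor((tx_len - genes$cds_start_nt + 1 - utr_len) / 3))
}

#' Simulate a gene catalog, domain annotations and category map
#'
#' Genes are tiled on chromosomes with random strands, CDS starts and 3'-UTRs
#' (about 10% of genes lack a UTR; each UTR lies at the transcript 3' end).
#' Domains are drawn from a pool of 150 features with fixed functional
#' categories; about 40% of genes carry 1-2 protein interaction interfaces
#' with 1-3 partner genes each. Deterministic given the config seed.
#'
#' @param config `simulation_config`.
#' @return List: genes, domains, cmap.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  if (n * 5e3 > config$n_chrom * config$chrom_length / 2) {
    stop("genome too small for requested gene count")
  }
  chroms <- paste0("chr", seq_len(config$n_chrom))
  # one gene per chromosome first so every chromosome is non-empty
  chrom <- c(chroms, sample(chroms, n - config$n_chrom, replace = TRUE))
  tx_len <- round(stats::runif(n, 2e4, 2e5))
  tx_start <- vapply(seq_len(n), function(i) {
    round(stats::runif(1, 0, config$chrom_length - tx_len[i]))
  }, numeric(1))
  strand <- sample(STRANDS, n, replace = TRUE)
  cds_start_nt <- sample(50:500, n, replace = TRUE)
  has_utr <- stats::runif(n) > 0.1
  utr_len <- ifelse(has_utr, pmin(round(stats::runif(n, 300, 4000)),
                                  floor(tx_len * 0.3)), NA)
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n)),
                      chrom = chrom, strand = strand,
                      tx_start = tx_start, tx_end = tx_start + tx_len,
                      cds_start_nt = cds_start_nt, stringsAsFactors = FALSE)
  genes$utr3_start <- ifelse(has_utr,
                             ifelse(strand == "+", genes$tx_end - utr_len, genes$tx_start),
                             NA_real_)
  genes$utr3_end <- ifelse(has_utr,
                           ifelse(strand == "+", genes$tx_end, genes$tx_start + utr_len),
                           NA_real_)
  genes <- validate_gene_models(genes)

  # feature pool with fixed categories
  n_feat <- 150
  feat_ids <- sprintf("IPR%05d", seq_len(n_feat))
  cmap <- stats::setNames(sample(CATEGORIES, n_feat, replace = TRUE,
                                 prob = c(0.25, 0.25, 0.10, 0.10, 0.30)),
                          feat_ids)
  aa_len <- gene_protein_length(genes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    n_dom <- sample(0:4, 1, prob = c(0.15, 0.30, 0.25, 0.20, 0.10))
    recs <- NULL
    if (n_dom > 0) {
      a_start <- sample.int(max(1, aa_len[i] - 15), n_dom, replace = TRUE)
      a_end <- pmin(aa_len[i], a_start + sample(10:100, n_dom, replace = TRUE))
      recs <- data.frame(gene_id = genes$gene_id[i],
                         feature_id = sample(feat_ids, n_dom, replace = TRUE),
                         aa_start = a_start, aa_end = a_end,
                         is_pii = FALSE, partners = "", stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < 0.4) {
      n_pii <- sample(1:2, 1)
      a_start <- sample.int(max(1, aa_len[i] - 15), n_pii, replace = TRUE)
      a_end <- pmin(aa_len[i], a_start + sample(10:60, n_pii, replace = TRUE))
      partners <- vapply(seq_len(n_pii), function(j) {
        paste(sample(genes$gene_id[-i], sample(1:3, 1)), collapse = ",")
      }, character(1))
      recs <- rbind(recs, data.frame(
        gene_id = genes$gene_id[i],
        feature_id = sprintf("PII_%s_%d", genes$gene_id[i], seq_len(n_pii)),
        aa_start = a_start, aa_end = a_end,
        is_pii = TRUE, partners = partners, stringsAsFactors = FALSE))
    }
    rows[[i]] <- recs
  }
  domains <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(domains) <- NULL
  list(genes = genes, domains = validate_domains(domains), cmap = cmap)
}

# retained category set of one side of a candidate junction
candidate_category_set <- function(dom, bp_aa, side, cmap) {
  partner_category_set(retained_and_lost(dom, bp_aa, side), cmap)$categories
}

#' Simulate a translocation set with planted category co-occurrence
#'
#' Candidate 5' sides draw a gene from the first half of the catalog and
#' candidate 3' sides from the second half (disjoint partner pools, so
#' per-side planted effects stay identifiable), each with a CDS-internal
#' breakpoint placed uniformly; the retained category sets of both sides are
#' computed with the analysis retention rule. The two candidate lists are
#' then matched by Metropolis swap sampling with pair weight equal to the
#' planted fold of the strongest-deviating realized (5' category,
#' 3' category) cell. Because both marginal category-set multisets are fixed
#' by construction, the planted fold is expressed as dependence between the
#' sides — exactly the quantity the marginal-preserving permutation null
#' measures — rather than being partly absorbed into the marginals.
#' Lineages are drawn from the configured weights; report counts are
#' Zipf-distributed.
#'
#' @param config `simulation_config`.
#' @param catalog Output of [simulate_genome()].
#' @return Translocation data.frame.
#' @export
simulate_translocation_set <- function(config, catalog) {
  set.seed(config$seed + 1L)
  genes <- catalog$genes
  fold <- config$cooccurrence_fold
  aa_len <- gene_protein_length(genes)
  dom_by_gene <- split(catalog$domains, catalog$domains$gene_id)
  empty_dom <- catalog$domains[0, , drop = FALSE]
  n <- config$n_transloc
  pool5 <- seq_len(floor(nrow(genes) / 2))
  pool3 <- setdiff(seq_len(nrow(genes)), pool5)

  draw_side <- function(pool, side) {
    g <- pool[sample.int(length(pool), n, replace = TRUE)]
    bp <- genes$cds_start_nt[g] + 3L * vapply(aa_len[g], function(m) {
      sample.int(m, 1)
    }, integer(1)) - 1L
    aa <- breakpoint_nt_to_aa(bp, genes$cds_start_nt[g])$aa
    member <- matrix(0L, n, 6, dimnames = list(NULL, CATEGORIES_N))
    for (i in seq_len(n)) {
      d <- dom_by_gene[[genes$gene_id[g[i]]]]
      if (is.null(d)) d <- empty_dom
      member[i, candidate_category_set(d, aa[i], side, catalog$cmap)] <- 1L
    }
    list(gene = g, bp = bp, member = member)
  }
  side5 <- draw_side(pool5, "five_prime")
  side3 <- draw_side(pool3, "three_prime")

  # feasibility: a planted over-count cannot exceed either marginal count;
  # targets mildly above the attainable bound (the marginals are random) are
  # clipped to it, grossly infeasible targets are a config error
  logf <- log(fold)
  c5 <- colSums(side5$member); c3 <- colSums(side3$member)
  for (a in CATEGORIES_N) for (b in CATEGORIES_N) {
    if (fold[a, b] > 1 &&
        fold[a, b] * c5[a] * c3[b] / n > 1.5 * min(c5[a], c3[b])) {
      stop(sprintf("planted fold matrix incompatible with marginals: cell (%s,%s)", a, b))
    }
  }

  # Start from a uniform random matching of the two sides, then drive each
  # deviating cell (a, b) to its target count fold x (a b / n) by random
  # swaps of 3'-side assignments between an eligible and a non-eligible
  # 5' row (stochastic rounding keeps targets unbiased). Cells are processed
  # in increasing |log fold| so the strongest-deviating cell is planted last
  # and is not disturbed; with the all-ones fold matrix the matching stays
  # exactly uniform.
  perm <- sample.int(n)
  dev_cells <- which(logf != 0, arr.ind = TRUE)
  if (nrow(dev_cells) > 0) {
    for (r in order(abs(logf[dev_cells]))) {
      a <- dev_cells[r, 1]; b <- dev_cells[r, 2]
      target <- fold[a, b] * c5[a] * c3[b] / n
      if (target > min(c5[a], c3[b])) {
        warning(sprintf("planted count for cell (%s,%s) clipped to the attainable bound",
                        CATEGORIES_N[a], CATEGORIES_N[b]))
        target <- min(c5[a], c3[b])
      }
      target_n <- floor(target) +
        (stats::runif(1) < target - floor(target))
      in5 <- side5$member[, a] == 1L
      in3 <- side3$member[perm, b] == 1L
      x <- sum(in5 & in3)
      while (x != target_n) {
        if (x < target_n) {
          i_pool <- which(in5 & !in3); j_pool <- which(!in5 & in3)
        } else {
          i_pool <- which(in5 & in3); j_pool <- which(!in5 & !in3)
        }
        if (!length(i_pool) || !length(j_pool)) break
        i <- i_pool[sample.int(length(i_pool), 1)]
        j <- j_pool[sample.int(length(j_pool), 1)]
        tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
        tmp <- in3[i]; in3[i] <- in3[j]; in3[j] <- tmp
        x <- x + if (x < target_n) 1L else -1L
      }
    }
  }

  tloc <- data.frame(fusion_id = sprintf("T%04d", seq_len(n)),
                     five_gene = genes$gene_id[side5$gene],
                     three_gene = genes$gene_id[side3$gene[perm]],
                     five_bp_nt = side5$bp, three_bp_nt = side3$bp[perm],
                     stringsAsFactors = FALSE)
  tloc$lineage <- sample(names(config$lineage_probs), n, replace = TRUE,
                         prob = config$lineage_probs)
  k_max <- 100
  zipf_p <- (1:k_max)^(-config$zipf_exponent)
  tloc$report_count <- sample.int(k_max, n, replace = TRUE, prob = zipf_p)
  tloc$self_fusion <- FALSE
  validate_translocations(tloc)
}

#' Simulate a binned trans-contact matrix with a planted central compartment
#'
#' Bins tile each chromosome at `bin_size`. A fraction `central_frac` of bins
#' is central; trans values are
#' `base * (1 + boost * central_i * central_j) * exp(N(0, sd))`, cis values
#' follow a distance-decay curve (they are present but excluded from all
#' downstream pair statistics). The truth labels are returned for recovery
#' tests.
#'
#' @param config `simulation_config`.
#' @param catalog Output of [simulate_genome()].
#' @param central Optional logical vector reusing existing truth labels (for
#'   a second cell-line matrix over the same genome).
#' @param seed_offset Offset added to the config seed (default 2).
#' @return List: matrix (`contact_matrix`), central (logical truth labels).
#' @export
simulate_contact_matrix <- function(config, catalog, central = NULL,
                                    seed_offset = 2L) {
  set.seed(config$seed + seed_offset)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  per_chrom <- ceiling(config$chrom_length / config$bin_size)
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    st <- seq(0, by = config$bin_size, length.out = per_chrom)
    data.frame(chrom = ch, start = st,
               end = pmin(st + config$bin_size, config$chrom_length),
               stringsAsFactors = FALSE)
  }))
  bins$bin_id <- seq_len(nrow(bins)) - 1L
  bins <- bins[, c("bin_id", "chrom", "start", "end")]
  n <- nrow(bins)
  if (is.null(central)) {
    central <- stats::runif(n) < config$central_frac
  }
  base <- 1
  cvec <- as.numeric(central)
  mu <- base * (1 + config$contact_boost * outer(cvec, cvec))
  # cis blocks: distance decay, scaled up as cis contacts dominate trans
  same <- outer(bins$chrom, bins$chrom, `==`)
  d <- abs(outer(bins$start, bins$start, `-`)) / config$bin_size
  mu[same] <- 20 * base * (1 + d[same])^(-config$contact_decay)
  noise <- matrix(exp(stats::rnorm(n * n, 0, config$contact_noise_sd)), n, n)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  vals <- mu * noise
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  list(matrix = contact_matrix(bins, vals), central = central)
}

#' Simulate a replication-timing profile coupled to nuclear centrality
#'
#' Per-bin raw RT is `rho * z(central) + sqrt(1 - rho^2) * N(0, 1)`, laid out
#' as a bedGraph-like profile of `bin_size / 5` windows, then linearly
#' rescaled so the gene-level RT distribution spans about [-1.5, 1.5]
#' (1st/99th percentiles of the gene-midpoint values mapped to the ends).
#'
#' @param config `simulation_config`.
#' @param catalog Output of [simulate_genome()].
#' @param central_labels Logical truth labels from [simulate_contact_matrix()].
#' @return `signal_profile` with replication_timing semantics.
#' @export
simulate_rt_profile <- function(config, catalog, central_labels) {
  set.seed(config$seed + 3L)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  per_chrom <- ceiling(config$chrom_length / config$bin_size)
  rho <- config$rt_cor
  cz <- as.numeric(central_labels)
  cz <- if (stats::sd(cz) > 0) (cz - mean(cz)) / stats::sd(cz) else cz * 0
  bin_rt <- rho * cz + sqrt(1 - rho^2) * stats::rnorm(length(cz))
  step <- config$bin_size / 5
  rows <- lapply(seq_along(chroms), function(ci) {
    st <- seq(0, config$chrom_length - step, by = step)
    bin_idx <- (ci - 1L) * per_chrom + floor(st / config$bin_size) + 1L
    val <- bin_rt[bin_idx] + stats::rnorm(length(st), 0, 0.05)
    # narrow edge intervals so interpolation covers the whole chromosome
    data.frame(chrom = chroms[ci],
               start = c(0, st, config$chrom_length - 2),
               end = c(2, st + step, config$chrom_length),
               value = c(val[1], val, val[length(val)]),
               stringsAsFactors = FALSE)
  })
  prof <- signal_profile(do.call(rbind, rows), "replication_timing")
  # rescale on the gene-level distribution
  gvals <- gene_rt_value(prof, catalog$genes)$rt
  qs <- stats::quantile(gvals, c(0.01, 0.99), names = FALSE)
  prof$value <- -1.5 + 3 * (prof$value - qs[1]) / (qs[2] - qs[1])
  prof
}

#' Simulate expression and regulatory tracks with planted TPG effects
#'
#' Plants: a log2 `expr_shift` for 5' TPGs in HEM samples (and
#' lineage-matched shifts in the GM128/K562 cell-line columns), elevated Pol2
#' peak probability for 5' TPG promoters in hematopoietic cell lines, a
#' stronger promoter H3K4me3 bump for 5' TPGs, and 3' TPG 3'-UTRs shortened
#' to `utr_ratio` of their length with proportionally fewer conserved
#' elements and microRNA sites (element counts are Poisson in UTR length).
#'
#' @param config `simulation_config`.
#' @param catalog Output of [simulate_genome()].
#' @param tloc Translocation data.frame.
#' @return List: expression (`expression_table`), pol2_tracks (list of
#'   cell-line groups, each a named list of `interval_track`s), h3k4me3
#'   (`signal_profile`), conserved, mirna (`interval_track`s), catalog (gene
#'   models with the shortened 3' TPG UTRs).
#' @export
simulate_expression_and_tracks <- function(config, catalog, tloc) {
  set.seed(config$seed + 4L)
  genes <- catalog$genes
  five_set <- unique(tloc$five_gene)
  three_set <- unique(tloc$three_gene)
  is5 <- genes$gene_id %in% five_set

  # shorten 3' TPG UTRs, keeping the transcript 3' end anchored
  shrink <- genes$gene_id %in% three_set & !is.na(genes$utr3_start)
  new_len <- pmax(50, round((genes$utr3_end - genes$utr3_start) * config$utr_ratio))
  genes$utr3_start[shrink & genes$strand == "+"] <-
    (genes$utr3_end - new_len)[shrink & genes$strand == "+"]
  genes$utr3_end[shrink & genes$strand == "-"] <-
    (genes$utr3_start + new_len)[shrink & genes$strand == "-"]
  genes <- validate_gene_models(genes)

  # samples: 3 lineage groups x 4 tissues x 3 donors, plus 2 cell lines
  groups <- c("EPI", "HEM", "MES")
  samples <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(1:4, function(t) {
      data.frame(sample_id = sprintf("%s_t%d_d%d", g, t, 1:3),
                 tissue = sprintf("%s_tissue%d", g, t), lineage_group = g,
                 stringsAsFactors = FALSE)
    }))
  }))
  samples <- rbind(samples,
                   data.frame(sample_id = c("GM128", "K562"),
                              tissue = c("GM128", "K562"),
                              lineage_group = c("CELL", "CELL"),
                              stringsAsFactors = FALSE))
  n_g <- nrow(genes); n_s <- nrow(samples)
  baseline <- stats::rnorm(n_g, 8, 1.5)
  vals <- matrix(stats::rnorm(n_g * n_s, 0, 0.4), n_g, n_s) + baseline
  tissue_effect <- stats::rnorm(length(unique(samples$tissue)), 0, 0.3)
  names(tissue_effect) <- unique(samples$tissue)
  vals <- vals + matrix(tissue_effect[samples$tissue], n_g, n_s, byrow = TRUE)
  vals[is5, samples$lineage_group == "HEM"] <-
    vals[is5, samples$lineage_group == "HEM"] + config$expr_shift
  # lineage-specific cell-line shifts for 5' TPGs
  hem_l_5 <- genes$gene_id %in% unique(tloc$five_gene[tloc$lineage == "HEM-L"])
  hem_m_5 <- genes$gene_id %in% unique(tloc$five_gene[tloc$lineage == "HEM-M"])
  vals[hem_l_5, samples$sample_id == "GM128"] <-
    vals[hem_l_5, samples$sample_id == "GM128"] + config$expr_shift
  vals[hem_m_5, samples$sample_id == "K562"] <-
    vals[hem_m_5, samples$sample_id == "K562"] + config$expr_shift
  rownames(vals) <- genes$gene_id
  colnames(vals) <- samples$sample_id
  expr <- expression_table(vals, samples)

  # Pol2 peaks: 4 hematopoietic + 4 non-hematopoietic cell lines
  prom <- promoter_window(genes)
  make_track <- function(p_peak) {
    hit <- stats::runif(n_g) < p_peak
    if (!any(hit)) return(interval_track(prom[0, c("chrom", "start", "end")]))
    w <- prom[hit, , drop = FALSE]
    pk_start <- w$start + floor(stats::runif(nrow(w)) * (w$end - w$start - 500))
    interval_track(data.frame(chrom = w$chrom, start = pk_start,
                              end = pk_start + 500,
                              name = paste0("peak_", w$gene_id),
                              stringsAsFactors = FALSE))
  }
  pol2_tracks <- list(
    hematopoietic = lapply(1:4, function(i) make_track(ifelse(is5, 0.8, 0.3))),
    non_hematopoietic = lapply(1:4, function(i) make_track(rep(0.3, n_g))))
  names(pol2_tracks$hematopoietic) <- paste0("hem_cl", 1:4)
  names(pol2_tracks$non_hematopoietic) <- paste0("nonhem_cl", 1:4)

  # H3K4me3: gaussian bump over each promoter, stronger for 5' TPGs
  tss <- gene_tss(genes)
  amp <- ifelse(is5, 6, 3)
  h3_rows <- lapply(seq_len(n_g), function(i) {
    st <- seq(tss[i] - 3000, tss[i] + 2750, by = 250)
    st <- st[st >= 0]
    mid <- st + 125
    data.frame(chrom = genes$chrom[i], start = st, end = st + 250,
               value = 1 + amp[i] * exp(-((mid - tss[i]) / 1200)^2) +
                 abs(stats::rnorm(length(st), 0, 0.2)),
               stringsAsFactors = FALSE)
  })
  h3 <- do.call(rbind, h3_rows)
  h3$position <- floor((h3$start + h3$end) / 2)
  h3 <- h3[!duplicated(h3[, c("chrom", "position")]), ]
  h3 <- signal_profile(h3[, c("chrom", "start", "end", "value")], "signal")

  # conserved elements and miRNA sites: Poisson in UTR length
  utr_track <- function(rate_per_bp) {
    rows <- list()
    for (i in which(!is.na(genes$utr3_start))) {
      len <- genes$utr3_end[i] - genes$utr3_start[i]
      k <- stats::rpois(1, len * rate_per_bp)
      if (k == 0) next
      st <- genes$utr3_start[i] + floor(stats::runif(k) * (len - 20))
      rows[[length(rows) + 1L]] <- data.frame(chrom = genes$chrom[i],
                                              start = st, end = st + 20,
                                              stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
      return(interval_track(data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), stringsAsFactors = FALSE)))
    }
    interval_track(do.call(rbind, rows))
  }
  conserved <- utr_track(1 / 400)
  mirna <- utr_track(1 / 600)

  list(expression = expr, pol2_tracks = pol2_tracks, h3k4me3 = h3,
       conserved = conserved, mirna = mirna,
       catalog = list(genes = genes, domains = catalog$domains,
                      cmap = catalog$cmap))
}

#' Generate and write the full synthetic input bundle
#'
#' Runs every generator stage and writes the bundle in the package's on-disk
#' formats (gene models, translocations, domains, category map, expression +
#' metadata, report counts, bin table + two contact-matrix triplet files for
#' the two cell lines, RT and H3K4me3 bedGraphs, Pol2/conserved/miRNA BED
#' tracks) plus `truth.json` recording the planted parameters and central-bin
#' truth labels. Identical seeds give identical bytes.
#'
#' @param config `simulation_config`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the in-memory bundle (list).
#' @export
simulate_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  catalog <- simulate_genome(config)
  tloc <- simulate_translocation_set(config, catalog)
  hic_a <- simulate_contact_matrix(config, catalog, seed_offset = 2L)
  hic_b <- simulate_contact_matrix(config, catalog, central = hic_a$central,
                                   seed_offset = 5L)
  rt <- simulate_rt_profile(config, catalog, hic_a$central)
  reg <- simulate_expression_and_tracks(config, catalog, tloc)
  genes <- reg$catalog$genes

  p <- function(f) file.path(outdir, f)
  write_gene_models(genes, p("genes.tsv"))
  write_translocations(tloc, p("translocations.tsv"))
  write_domains(catalog$domains, p("domains.tsv"))
  write_category_map(catalog$cmap, p("category_map.tsv"))
  write_expression(reg$expression, p("expression.tsv"), p("samples.tsv"))
  counts <- unique(tloc[, c("five_gene", "three_gene", "report_count")])
  names(counts)[3] <- "n_reports"
  write_report_counts(counts, p("report_counts.tsv"))
  write_contact_matrix(hic_a$matrix, p("bins.tsv"), p("contacts_gm.tsv"))
  write_contact_matrix(hic_b$matrix, p("bins.tsv"), p("contacts_k562.tsv"))
  write_bedgraph(rt, p("rt.bedgraph"))
  write_bedgraph(reg$h3k4me3, p("h3k4me3.bedgraph"))
  for (grp in names(reg$pol2_tracks)) {
    for (cl in names(reg$pol2_tracks[[grp]])) {
      write_bed(reg$pol2_tracks[[grp]][[cl]], p(sprintf("pol2_%s.bed", cl)))
    }
  }
  write_bed(reg$conserved, p("conserved.bed"))
  write_bed(reg$mirna, p("mirna.bed"))
  truth <- list(seed = config$seed, expr_shift = config$expr_shift,
                utr_ratio = config$utr_ratio,
                contact_boost = config$contact_boost,
                central_frac = config$central_frac, rt_cor = config$rt_cor,
                cooccurrence_fold = config$cooccurrence_fold,
                central_bins = which(hic_a$central) - 1L)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(config = config, catalog = reg$catalog, translocations = tloc,
                 hic_gm = hic_a, hic_k562 = hic_b, rt = rt, regulation = reg))
}
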