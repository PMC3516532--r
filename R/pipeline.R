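# Pipeline orchestration: run every analysis stage over an on-disk bundle
# (synthetic or user-supplied) and emit per-stage TSV tables plus a
# machine-readable summary.

#' Pipeline configuration
#'
#' @param bundle_dir Directory holding the input bundle (the layout written
#'   by [simulate_bundle()]).
#' @param outdir Output directory.
#' @param seed Integer seed governing all stage randomness.
#' @param stages Character vector of stages to run, a subset of
#'   expression, domains, spatial, rt, recurrence.
#' @param n_perm_domains Permutations for the co-occurrence test (the
#'   full-scale analysis uses 10^6).
#' @param n_perm_spatial Permutations per spatial scheme (full scale 10^5).
#' @param q BH FDR level (default 0.10).
#' @param rt_early Early-replication RT cutoff (default 0.5).
#' @param rt_span LOESS span for RT smoothing (default 0.05, sized so the
#'   local window covers roughly the replication-domain scale of a few Mb at
#'   the bundle's profile density; a window much wider than the domain scale
#'   averages early and late domains away).
#' @param flank Promoter flank in bp (default 3000).
#' @param max_k Cluster-count cap for profile clustering.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(bundle_dir, outdir, seed = 1,
                            stages = c("expression", "domains", "spatial",
                                       "rt", "recurrence"),
                            n_perm_domains = 1e6, n_perm_spatial = 1e5,
                            q = 0.10, rt_early = 0.5, rt_span = 0.05,
                            flank = 3000, max_k = 8) {
  known <- c("expression", "domains", "spatial", "rt", "recurrence")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  structure(list(bundle_dir = bundle_dir, outdir = outdir,
                 seed = as.integer(seed), stages = stages,
                 n_perm_domains = n_perm_domains,
                 n_perm_spatial = n_perm_spatial, q = q, rt_early = rt_early,
                 rt_span = rt_span, flank = flank, max_k = max_k),
            class = "pipeline_config")
}

stage_files <- function() {
  common <- c("genes.tsv", "translocations.tsv")
  list(
    expression = c(common, "expression.tsv", "samples.tsv", "h3k4me3.bedgraph",
                   "conserved.bed", "mirna.bed", "domains.tsv",
                   "category_map.tsv"),
    domains = c(common, "domains.tsv", "category_map.tsv"),
    spatial = c(common, "bins.tsv", "contacts_gm.tsv", "contacts_k562.tsv"),
    rt = c(common, "rt.bedgraph"),
    recurrence = c(common, "report_counts.tsv", "bins.tsv", "contacts_gm.tsv",
                   "rt.bedgraph", "domains.tsv", "expression.tsv",
                   "samples.tsv"))
}

#' Load an on-disk input bundle
#' @param bundle_dir Directory written by [simulate_bundle()] (or assembled
#'   by the user in the same layout).
#' @param need Character vector of file names that must be present.
#' @return List of loaded inputs (only the files present are loaded).
#' @export
load_bundle <- function(bundle_dir, need = NULL) {
  p <- function(f) file.path(bundle_dir, f)
  if (!is.null(need)) {
    missing <- need[!file.exists(p(need))]
    if (length(missing)) {
      stop("bundle is missing required input(s): ", paste(missing, collapse = ", "))
    }
  }
  b <- list()
  if (file.exists(p("genes.tsv"))) b$genes <- read_gene_models(p("genes.tsv"))
  if (file.exists(p("translocations.tsv"))) {
    b$translocations <- read_translocations(p("translocations.tsv"))
  }
  if (file.exists(p("domains.tsv"))) b$domains <- read_domains(p("domains.tsv"))
  if (file.exists(p("category_map.tsv"))) b$cmap <- read_category_map(p("category_map.tsv"))
  if (file.exists(p("expression.tsv")) && file.exists(p("samples.tsv"))) {
    b$expression <- read_expression(p("expression.tsv"), p("samples.tsv"))
  }
  if (file.exists(p("report_counts.tsv"))) {
    b$report_counts <- read_report_counts(p("report_counts.tsv"))
  }
  if (file.exists(p("bins.tsv"))) {
    if (file.exists(p("contacts_gm.tsv"))) {
      b$hic_gm <- load_contact_matrix(p("bins.tsv"), p("contacts_gm.tsv"))
    }
    if (file.exists(p("contacts_k562.tsv"))) {
      b$hic_k562 <- load_contact_matrix(p("bins.tsv"), p("contacts_k562.tsv"))
    }
  }
  if (file.exists(p("rt.bedgraph"))) {
    b$rt <- read_bedgraph(p("rt.bedgraph"), "replication_timing")
  }
  if (file.exists(p("h3k4me3.bedgraph"))) {
    b$h3k4me3 <- read_bedgraph(p("h3k4me3.bedgraph"), "signal")
  }
  if (file.exists(p("conserved.bed"))) b$conserved <- read_bed(p("conserved.bed"))
  if (file.exists(p("mirna.bed"))) b$mirna <- read_bed(p("mirna.bed"))
  pol2_files <- list.files(bundle_dir, pattern = "^pol2_.*\\.bed$")
  if (length(pol2_files)) {
    tracks <- lapply(pol2_files, function(f) read_bed(p(f)))
    names(tracks) <- sub("^pol2_(.*)\\.bed$", "\\1", pol2_files)
    hem <- grepl("^hem", names(tracks))
    b$pol2_tracks <- list(hematopoietic = tracks[hem],
                          non_hematopoietic = tracks[!hem])
  }
  b
}

#' Run the analysis pipeline over a bundle
#'
#' Runs the enabled stages in order (expression -> domains -> spatial -> rt ->
#' recurrence), writes per-stage TSV tables under `config$outdir`, and a
#' `summary.json` of headline statistics. A missing input file for any
#' enabled stage raises a named error before any stage runs; a rerun with the
#' same config writes byte-identical outputs.
#'
#' @param config `pipeline_config`.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  req <- unique(unlist(stage_files()[config$stages]))
  b <- load_bundle(config$bundle_dir, need = req)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  summary <- list(seed = config$seed, stages = as.list(config$stages))

  profiles <- NULL
  retentions <- NULL
  if (any(c("expression", "domains", "recurrence") %in% config$stages)) {
    fp <- fusion_profiles(b$translocations, b$genes, b$domains, b$cmap)
    profiles <- fp$profiles
    retentions <- fp$retentions
  }

  if ("expression" %in% config$stages) {
    t0 <- proc.time()[3]
    ts <- aggregate_by_tissue(b$expression)
    hem <- ts$group_means[, "HEM"]
    pairs <- dedup_translocations(b$translocations, "pairs")
    pd <- paired_partner_difference(unname(hem[pairs$five_gene]),
                                    unname(hem[pairs$three_gene]))
    pf <- pol2_peak_frequency(b$genes, b$pol2_tracks, config$flank)
    meta5 <- signal_metaprofile(b$h3k4me3,
                                b$genes[b$genes$gene_id %in% pairs$five_gene, ],
                                config$flank)
    utr <- utr3_features(b$genes, b$conserved, b$mirna)
    gains <- fusion_gain_stats(profiles, pf, utr, hem)
    write_tsv_stable(data.frame(gene_id = rownames(ts$group_means),
                                ts$group_means, check.names = FALSE),
                     out("expression_group_means.tsv"))
    write_tsv_stable(as.data.frame(pf), out("promoter_features.tsv"))
    write_tsv_stable(as.data.frame(utr), out("utr3_features.tsv"))
    write_tsv_stable(gains$per_fusion, out("fusion_gains.tsv"))
    write_tsv_stable(gains$tests, out("fusion_gain_tests.tsv"))
    summary$expression <- list(
      paired_median_diff = pd$median_diff, paired_p = pd$p_value,
      n_pairs = nrow(pairs), metaprofile_peak_bin = which.max(meta5),
      gain_tests = stats::setNames(as.list(gains$tests$p_value),
                                   gains$tests$statistic))
    message(sprintf("expression stage done in %.1fs", proc.time()[3] - t0))
  }

  if ("domains" %in% config$stages) {
    t0 <- proc.time()[3]
    uniq <- dedup_translocations(b$translocations, "domain_composition",
                                 profiles = profiles)
    up <- profiles[match(uniq$fusion_id, profiles$fusion_id), ]
    co <- cooccurrence_permutation_test(up, n_perm = config$n_perm_domains,
                                        q = config$q, seed = config$seed)
    td <- type_dependency_test(up, n_perm = min(config$n_perm_domains, 1e4),
                               seed = config$seed)
    cl <- cluster_functional_profiles(up, seed = config$seed,
                                      max_k = config$max_k)
    net <- build_interactor_network(retentions, "three_prime")
    cells <- expand.grid(five = CATEGORIES_N, three = CATEGORIES_N,
                         stringsAsFactors = FALSE)
    co_tab <- data.frame(cells,
                         observed = co$observed[as.matrix(cells)],
                         null_mean = co$null_mean[as.matrix(cells)],
                         fold = co$fold[as.matrix(cells)],
                         p_value = co$p_values[as.matrix(cells)],
                         q_value = co$q_values[as.matrix(cells)],
                         direction = co$direction[as.matrix(cells)],
                         significant = co$reject[as.matrix(cells)])
    write_tsv_stable(co_tab[order(co_tab$five, co_tab$three), ],
                     out("cooccurrence.tsv"))
    write_tsv_stable(data.frame(fusion_id = up$fusion_id,
                                cluster = cl$assignments),
                     out("cluster_assignments.tsv"))
    write_tsv_stable(data.frame(cluster = seq_len(cl$k), cl$cluster_probs),
                     out("cluster_probs.tsv"))
    fusion_edges <- data.frame(source = up$five_gene, target = up$three_gene,
                               cluster = cl$assignments,
                               weight = as.integer(table(paste(
                                 b$translocations$five_gene,
                                 b$translocations$three_gene))[
                                   paste(up$five_gene, up$three_gene)]))
    write_tsv_stable(fusion_edges, out("fusion_network_edges.tsv"))
    write_tsv_stable(net$edges, out("interactor_edges.tsv"))
    sig <- co$reject & !is.na(co$reject)
    summary$domains <- list(
      n_unique_profiles = nrow(up),
      n_over = sum(sig & co$fold > 1), n_under = sum(sig & co$fold < 1),
      fisher_p = td$fisher_p, t2t2_fraction = td$t2t2_fraction,
      t2t2_fold = td$t2t2_fold, t2t2_p = td$t2t2_p,
      n_clusters = cl$k, n_interactor_edges = nrow(net$edges))
    message(sprintf("domains stage done in %.1fs", proc.time()[3] - t0))
  }

  if ("spatial" %in% config$stages) {
    t0 <- proc.time()[3]
    pairs <- dedup_translocations(b$translocations, "pairs")
    prox <- tpg_pair_proximity_test(pairs, b$hic_gm, b$genes,
                                    n_perm = config$n_perm_spatial,
                                    seed = config$seed)
    part <- partition_contact_clusters(b$hic_gm, k = 2, seed = config$seed)
    cent5 <- locus_centrality(b$hic_gm,
                              b$genes[b$genes$gene_id %in% pairs$five_gene, ])
    lin <- lineage_contact_difference(pairs[pairs$lineage %in% c("HEM-L", "HEM-M"), ],
                                      b$hic_gm, b$hic_k562, b$genes)
    write_tsv_stable(prox$schemes, out("proximity_test.tsv"))
    part_bed <- interval_track(data.frame(chrom = b$hic_gm$bins$chrom,
                                          start = b$hic_gm$bins$start,
                                          end = b$hic_gm$bins$end,
                                          name = part$labels,
                                          stringsAsFactors = FALSE))
    write_bed(part_bed, out("partition.bed"))
    write_tsv_stable(data.frame(gene_id = names(cent5), centrality = cent5),
                     out("centrality_5tpg.tsv"))
    write_tsv_stable(lin$per_pair, out("lineage_differences.tsv"))
    summary$spatial <- list(
      observed_mean = prox$observed_mean, n_pairs = prox$n_pairs,
      p_values = stats::setNames(as.list(prox$schemes$p_value),
                                 prox$schemes$scheme),
      n_central_bins = sum(part$labels == "central"),
      lineage_spearman = lin$spearman_r, lineage_mw_p = lin$mann_whitney_p)
    message(sprintf("spatial stage done in %.1fs", proc.time()[3] - t0))
  }

  if ("rt" %in% config$stages) {
    t0 <- proc.time()[3]
    sm <- loess_smooth(b$rt, span = config$rt_span)
    rtv <- gene_rt_value(sm, b$genes)
    pairs <- dedup_translocations(b$translocations, "pairs")
    enr5 <- early_late_enrichment(unique(pairs$five_gene), b$genes$gene_id, rtv)
    enr3 <- early_late_enrichment(unique(pairs$three_gene), b$genes$gene_id, rtv)
    write_bedgraph(sm, out("rt_smoothed.bedgraph"))
    write_tsv_stable(rtv, out("gene_rt.tsv"))
    write_tsv_stable(data.frame(
      set = c("five_prime", "three_prime"),
      percent_early = c(enr5$percent_early, enr3$percent_early),
      fold = c(enr5$fold, enr3$fold),
      p_value = c(enr5$p_value, enr3$p_value)), out("rt_enrichment.tsv"))
    summary$rt <- list(pct_early_5 = enr5$percent_early, fold_5 = enr5$fold,
                       p_5 = enr5$p_value, pct_early_3 = enr3$percent_early,
                       fold_3 = enr3$fold, p_3 = enr3$p_value)
    message(sprintf("rt stage done in %.1fs", proc.time()[3] - t0))
  }

  if ("recurrence" %in% config$stages) {
    t0 <- proc.time()[3]
    tl <- attach_report_counts(b$translocations, b$report_counts)
    pairs <- dedup_translocations(tl, "pairs")
    cats <- categorize_by_reports(pairs$fusion_id, pairs$n_reports)
    feats <- list()
    contact <- vapply(seq_len(nrow(pairs)), function(i) {
      pair_contact_frequency(b$hic_gm, pairs$five_gene[i], pairs$three_gene[i],
                             genes = b$genes)
    }, numeric(1))
    feats$pair_contact <- data.frame(id = pairs$fusion_id, value = contact)
    ts <- aggregate_by_tissue(b$expression)
    hem <- ts$group_means[, "HEM"]
    feats$expression_5 <- data.frame(id = pairs$fusion_id,
                                     value = unname(hem[pairs$five_gene]))
    pii_n <- table(b$domains$gene_id[b$domains$is_pii])
    feats$pii_count_3 <- data.frame(
      id = pairs$fusion_id,
      value = as.numeric(ifelse(pairs$three_gene %in% names(pii_n),
                                pii_n[pairs$three_gene], 0)))
    sm <- loess_smooth(b$rt, span = config$rt_span)
    rtv <- gene_rt_value(sm, b$genes)
    rt_of <- stats::setNames(rtv$rt, rtv$gene_id)
    feats$rt_5 <- data.frame(id = pairs$fusion_id,
                             value = unname(rt_of[pairs$five_gene]))
    cent <- locus_centrality(b$hic_gm, b$genes)
    feats$centrality_5 <- data.frame(id = pairs$fusion_id,
                                     value = unname(cent[pairs$five_gene]))
    cmp <- do.call(rbind, lapply(names(feats), function(nm) {
      compare_rare_frequent(cats, feats[[nm]], nm)
    }))
    write_tsv_stable(cmp, out("recurrence_tests.tsv"))
    summary$recurrence <- list(
      n_rare = sum(cats$category == "rare"),
      n_frequent = sum(cats$category == "frequent"),
      p_values = stats::setNames(as.list(cmp$p_value), cmp$feature))
    message(sprintf("recurrence stage done in %.1fs", proc.time()[3] - t0))
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
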