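# Breakpoint-relative domain retention, functional categorization and the
# domain-category co-occurrence permutation test.

#' Convert a transcript-coordinate breakpoint to an amino-acid position
#'
#' `aa = floor((bp_nt - cds_start_nt) / 3) + 1`. Breakpoints upstream of the
#' CDS (aa < 1) clamp to 0 and are flagged; a 0 breakpoint means the 5' part
#' contributes no coding sequence, and for a 3' gene that every domain lies
#' downstream of the junction.
#'
#' @param bp_nt 1-based breakpoint position(s) in transcript coordinates.
#' @param cds_start_nt 1-based first coding position(s) of the transcript.
#' @return List with `aa` (integer vector, 0 = clamped) and `upstream`
#'   (logical flag vector).
#' @export
breakpoint_nt_to_aa <- function(bp_nt, cds_start_nt) {
  if (any(bp_nt < 1)) stop("breakpoints are 1-based, must be >= 1")
  aa <- floor((bp_nt - cds_start_nt) / 3) + 1
  upstream <- aa < 1
  aa[upstream] <- 0
  list(aa = as.integer(aa), upstream = upstream)
}

#' Split a gene's annotations into retained and lost at a breakpoint
#'
#' A feature is retained by the 5' part only when it lies entirely upstream of
#' the breakpoint (`aa_end < breakpoint_aa`) and by the 3' part only when it
#' lies entirely downstream (`aa_start > breakpoint_aa`). Everything else,
#' including breakpoint-spanning features, is lost, so retained and lost
#' always partition the gene's annotations.
#'
#' @param annotations Domain-annotation data.frame for one gene.
#' @param breakpoint_aa 1-based amino-acid breakpoint (0 = upstream-clamped).
#' @param side "five_prime" or "three_prime".
#' @return List of class `retention_record`: side, breakpoint_aa, retained,
#'   lost (both data.frames).
#' @export
retained_and_lost <- function(annotations, breakpoint_aa, side = c("five_prime", "three_prime")) {
  side <- match.arg(side)
  keep <- if (side == "five_prime") {
    annotations$aa_end < breakpoint_aa
  } else {
    annotations$aa_start > breakpoint_aa
  }
  structure(list(side = side, breakpoint_aa = breakpoint_aa,
                 retained = annotations[keep, , drop = FALSE],
                 lost = annotations[!keep, , drop = FALSE]),
            class = "retention_record")
}

#' Functional category set and partner type of a retained-domain set
#'
#' Maps retained InterPro-like domains (PIIs are excluded from
#' categorization) to the five functional categories; an empty set encodes as
#' `{N}`. Type 1 partners retain at least one D/P/H/K domain; type 2 partners
#' retain only O, or nothing (N).
#'
#' @param retention `retention_record`.
#' @param cmap Named character vector (feature_id -> category).
#' @return List with `categories` (character vector) and `type` (1 or 2).
#' @export
partner_category_set <- function(retention, cmap) {
  dom <- retention$retained
  dom <- dom[!dom$is_pii, , drop = FALSE]
  if (nrow(dom) == 0) {
    return(list(categories = "N", type = 2L))
  }
  unmapped <- setdiff(dom$feature_id, names(cmap))
  if (length(unmapped)) {
    stop("unmapped feature_id(s): ", paste(unmapped, collapse = ", "))
  }
  cats <- sort(unique(unname(cmap[dom$feature_id])))
  type <- if (length(intersect(cats, c("D", "P", "H", "K")))) 1L else 2L
  list(categories = cats, type = type)
}

#' Per-fusion domain retention, category sets and functional profiles
#'
#' For every translocation, converts both breakpoints to amino-acid
#' coordinates, computes the retained/lost split on both sides, the retained
#' category sets, partner types, and the 10-bit functional profile (per side,
#' one indicator per category D/P/H/K/O; a side with no retained domain has
#' all five bits 0, the `N` encoding).
#'
#' @param tloc Translocation data.frame.
#' @param genes Gene-model data.frame (provides cds_start_nt).
#' @param domains Domain-annotation data.frame.
#' @param cmap Category map (feature_id -> category).
#' @return List with `profiles` (one row per fusion: category-set strings,
#'   types, upstream-clamp flags, bit columns `five_D` ... `three_O`,
#'   `profile_key`) and `retentions` (named list of per-side
#'   `retention_record`s).
#' @export
fusion_profiles <- function(tloc, genes, domains, cmap) {
  gidx <- match(tloc$five_gene, genes$gene_id)
  gidx3 <- match(tloc$three_gene, genes$gene_id)
  if (anyNA(gidx) || anyNA(gidx3)) stop("translocation gene absent from gene models")
  bp5 <- breakpoint_nt_to_aa(tloc$five_bp_nt, genes$cds_start_nt[gidx])
  bp3 <- breakpoint_nt_to_aa(tloc$three_bp_nt, genes$cds_start_nt[gidx3])
  dom_by_gene <- split(domains, domains$gene_id)
  empty_dom <- domains[0, , drop = FALSE]

  n <- nrow(tloc)
  bits <- matrix(0L, n, 10,
                 dimnames = list(NULL, c(paste0("five_", CATEGORIES),
                                         paste0("three_", CATEGORIES))))
  five_cats <- character(n); three_cats <- character(n)
  five_type <- integer(n); three_type <- integer(n)
  retentions <- vector("list", n)
  names(retentions) <- tloc$fusion_id
  for (i in seq_len(n)) {
    d5 <- dom_by_gene[[tloc$five_gene[i]]]
    if (is.null(d5)) d5 <- empty_dom
    d3 <- dom_by_gene[[tloc$three_gene[i]]]
    if (is.null(d3)) d3 <- empty_dom
    r5 <- retained_and_lost(d5, bp5$aa[i], "five_prime")
    r3 <- retained_and_lost(d3, bp3$aa[i], "three_prime")
    c5 <- partner_category_set(r5, cmap)
    c3 <- partner_category_set(r3, cmap)
    five_cats[i] <- paste(c5$categories, collapse = ",")
    three_cats[i] <- paste(c3$categories, collapse = ",")
    five_type[i] <- c5$type; three_type[i] <- c3$type
    on5 <- intersect(c5$categories, CATEGORIES)
    on3 <- intersect(c3$categories, CATEGORIES)
    if (length(on5)) bits[i, paste0("five_", on5)] <- 1L
    if (length(on3)) bits[i, paste0("three_", on3)] <- 1L
    retentions[[i]] <- list(five = r5, three = r3)
  }
  profiles <- data.frame(fusion_id = tloc$fusion_id,
                         five_gene = tloc$five_gene, three_gene = tloc$three_gene,
                         five_bp_aa = bp5$aa, three_bp_aa = bp3$aa,
                         five_upstream = bp5$upstream, three_upstream = bp3$upstream,
                         five_cats = five_cats, three_cats = three_cats,
                         five_type = five_type, three_type = three_type,
                         stringsAsFactors = FALSE)
  profiles <- cbind(profiles, as.data.frame(bits))
  profiles$profile_key <- apply(bits, 1, paste, collapse = "")
  list(profiles = profiles, retentions = retentions)
}

# membership matrices over the six category codes, one row per fusion
category_membership <- function(cat_strings) {
  m <- matrix(0L, length(cat_strings), length(CATEGORIES_N),
              dimnames = list(NULL, CATEGORIES_N))
  sets <- strsplit(cat_strings, ",", fixed = TRUE)
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  m
}

#' Observed 6x6 domain-category co-occurrence counts
#'
#' Cell (c5, c3) counts translocations whose 5' retained category set contains
#' c5 and whose 3' set contains c3; a translocation with |set5| x |set3|
#' category combinations contributes that many cells. Empty sets count as N.
#'
#' @param profiles Profile data.frame from [fusion_profiles()] (or any
#'   data.frame with `five_cats` / `three_cats` comma-separated strings).
#' @return 6x6 integer matrix (rows = 5' category, columns = 3' category).
#' @export
cooccurrence_counts <- function(profiles) {
  m5 <- category_membership(profiles$five_cats)
  m3 <- category_membership(profiles$three_cats)
  counts <- crossprod(m5, m3)
  storage.mode(counts) <- "integer"
  counts
}

#' Permutation test for domain-category co-occurrence
#'
#' The null model randomly permutes the 3' category sets across translocations
#' while keeping the 5' sets fixed, preserving both marginal category-set
#' multisets. Per cell: fold = observed / mean permuted count, two-sided
#' empirical p-value (add-one convention, doubled smaller tail), and BH
#' q-values across all cells with observed or expected support (cells with
#' observed = 0 and permuted mean = 0 carry an undefined fold and are
#' excluded from FDR).
#'
#' @param profiles Profile data.frame (deduplicated to pairs unique by domain
#'   composition by the caller).
#' @param n_perm Number of permutations (the full-scale analysis uses 10^6).
#' @param q BH FDR level (default 0.10).
#' @param seed Integer seed for the permutation stream.
#' @return List: observed, null_mean, fold, p_values, q_values, reject
#'   (6x6 matrices; q/reject NA for cells excluded from FDR), tested (logical
#'   matrix), n_perm.
#' @export
cooccurrence_permutation_test <- function(profiles, n_perm = 1e6, q = 0.10, seed = 1) {
  if (nrow(profiles) < 1) stop("need at least one translocation")
  m5 <- category_membership(profiles$five_cats)
  m3 <- category_membership(profiles$three_cats)
  observed <- crossprod(m5, m3)
  n <- nrow(profiles)
  set.seed(seed)
  sum_null <- matrix(0, 6, 6)
  n_ge <- matrix(0L, 6, 6)
  n_le <- matrix(0L, 6, 6)
  for (b in seq_len(n_perm)) {
    perm_counts <- crossprod(m5, m3[sample.int(n), , drop = FALSE])
    sum_null <- sum_null + perm_counts
    n_ge <- n_ge + (perm_counts >= observed)
    n_le <- n_le + (perm_counts <= observed)
  }
  null_mean <- sum_null / n_perm
  p_ge <- (1 + n_ge) / (n_perm + 1)
  p_le <- (1 + n_le) / (n_perm + 1)
  p_values <- matrix(pmin(1, 2 * pmin(p_ge, p_le)), 6, 6)
  fold <- ifelse(null_mean > 0, observed / null_mean, NA_real_)
  tested <- !(observed == 0 & null_mean == 0)
  q_values <- matrix(NA_real_, 6, 6, dimnames = dimnames(observed))
  reject <- matrix(NA, 6, 6, dimnames = dimnames(observed))
  if (any(tested)) {
    bh <- benjamini_hochberg(p_values[tested], q)
    q_values[tested] <- bh$q_values
    reject[tested] <- bh$reject
  }
  dimnames(p_values) <- dimnames(fold) <- dimnames(null_mean) <- dimnames(observed)
  direction <- ifelse(!is.na(fold) & fold < 1, "under", "over")
  list(observed = observed, null_mean = null_mean, fold = fold,
       p_values = p_values, q_values = q_values, reject = reject,
       direction = direction, tested = tested, n_perm = n_perm)
}

#' Dependence between 5' and 3' partner domain types
#'
#' Builds the 2x2 table of partner types (rows = 5' type 1/2, columns = 3'
#' type 1/2), tests dependence with the two-sided Fisher exact test, and
#' reports the fraction of fusions in which both partners are type 2 along
#' with its fold against the permutation null that shuffles 3' types across
#' translocations.
#'
#' @param profiles Profile data.frame with `five_type`, `three_type`.
#' @param n_perm Permutations for the type2-type2 fold and empirical p.
#' @param seed Integer seed.
#' @return List: table, fisher_p (NA when a margin is zero, with
#'   `fisher_skipped` flag), t2t2_fraction, t2t2_fold, t2t2_p.
#' @export
type_dependency_test <- function(profiles, n_perm = 1e4, seed = 1) {
  t5 <- profiles$five_type
  t3 <- profiles$three_type
  tab <- matrix(c(sum(t5 == 1 & t3 == 1), sum(t5 == 1 & t3 == 2),
                  sum(t5 == 2 & t3 == 1), sum(t5 == 2 & t3 == 2)),
                2, 2, byrow = TRUE,
                dimnames = list(five = c("type1", "type2"),
                                three = c("type1", "type2")))
  skipped <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  fisher_p <- if (skipped) NA_real_ else fisher_exact_2x2(tab)$p_value
  n <- length(t5)
  obs_t2t2 <- tab["type2", "type2"]
  set.seed(seed)
  null_t2t2 <- vapply(seq_len(n_perm),
                      function(b) sum(t5 == 2 & t3[sample.int(n)] == 2),
                      numeric(1))
  null_mean <- mean(null_t2t2)
  list(table = tab, fisher_p = fisher_p, fisher_skipped = skipped,
       t2t2_fraction = obs_t2t2 / n,
       t2t2_fold = if (null_mean > 0) obs_t2t2 / null_mean else NA_real_,
       t2t2_p = empirical_pvalue(obs_t2t2, null_t2t2, "two_sided"))
}

#' Interaction-partner network through retained interaction interfaces
#'
#' For each fusion, edges run from the chosen side's TPG to every partner of
#' every retained protein interaction interface (PII). A partner interacting
#' with several TPGs appears once per TPG in the partner multiset, preserving
#' multiplicity.
#'
#' @param retentions Named list from [fusion_profiles()].
#' @param side "three_prime" (default) or "five_prime".
#' @return List: `edges` (data.frame fusion_id, tpg, feature_id, partner) and
#'   `partner_multiset` (character vector with one entry per TPG-partner
#'   link).
#' @export
build_interactor_network <- function(retentions, side = c("three_prime", "five_prime")) {
  side <- match.arg(side)
  slot <- if (side == "three_prime") "three" else "five"
  rows <- list()
  for (fid in names(retentions)) {
    ret <- retentions[[fid]][[slot]]$retained
    piis <- ret[ret$is_pii & nzchar(ret$partners), , drop = FALSE]
    if (nrow(piis) == 0) next
    for (j in seq_len(nrow(piis))) {
      partners <- strsplit(piis$partners[j], ",", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        fusion_id = fid, tpg = piis$gene_id[j], feature_id = piis$feature_id[j],
        partner = partners, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fusion_id = character(), tpg = character(),
               feature_id = character(), partner = character(),
               stringsAsFactors = FALSE)
  # multiplicity is per distinct TPG-partner link, counted once per TPG
  link <- unique(edges[, c("tpg", "partner")])
  list(edges = edges, partner_multiset = link$partner)
}
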