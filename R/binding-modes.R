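# Gene-proximal peak assignment, four-way binding-mode classification,
# enrichment statistics over the TGF-beta-independent background, and
# composite per-gene occupancy profiles.

MODE_LEVELS <- 1:4
CATEGORY_LEVELS <- c("identical", "mixed", "mutually_exclusive",
                     "a_only", "b_only", "unbound")

#' Assign peak matches to gene-proximal windows
#'
#' A match (shared pair or condition-unique peak, represented by the union
#' interval of its peaks) is assigned to every gene whose gene-proximal
#' window it touches. The default rule is >= 1 bp interval overlap;
#' `rule = "containment"` requires the match interval to lie entirely
#' inside the window.
#'
#' @param windows gene-proximal windows from [derive_gene_proximal()].
#' @param matches match table from [match_peaks()].
#' @param rule `"overlap"` (default) or `"containment"`.
#' @return Data.frame `gene_id`, `match_id`, `status`; a match may appear
#'   under several genes.
#' @export
assign_proximal_peaks <- function(windows, matches,
                                  rule = c("overlap", "containment")) {
  rule <- match.arg(rule)
  pairs <- overlap_pairs(
    data.frame(chrom = windows$chrom, start = windows$start,
               end = windows$end, stringsAsFactors = FALSE),
    data.frame(chrom = matches$chrom, start = matches$start,
               end = matches$end, stringsAsFactors = FALSE))
  if (rule == "containment" && nrow(pairs) > 0) {
    keep <- matches$start[pairs$j] >= windows$start[pairs$i] &
      matches$end[pairs$j] <= windows$end[pairs$i]
    pairs <- pairs[keep, , drop = FALSE]
  }
  out <- data.frame(gene_id = windows$gene_id[pairs$i],
                    match_id = matches$match_id[pairs$j],
                    status = matches$status[pairs$j],
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$match_id), , drop = FALSE]
}

#' Per-gene binding profiles: counts, mode, occupancy category
#'
#' Counts gene-proximal matches by status and derives the four-way binding
#' mode -- bound in A only (1), in B only (2), in both (3), in neither (4),
#' where "present in A" means at least one A-unique or shared match -- and
#' the occupancy category refining mode 3 into `identical` (shared matches
#' only), `mixed` (shared plus condition-unique) and `mutually_exclusive`
#' (unique matches on both sides, none shared); modes 1, 2 and 4 map to
#' `a_only`, `b_only` and `unbound`.
#'
#' @param gene_ids the full gene universe (genes without any assigned
#'   match get zero counts, mode 4, `unbound`).
#' @param assignments output of [assign_proximal_peaks()].
#' @return Data.frame `gene_id`, `n_unique_a`, `n_unique_b`, `n_shared`,
#'   `mode`, `category`.
#' @export
gene_binding_profiles <- function(gene_ids, assignments) {
  gene_ids <- as.character(gene_ids)
  cnt <- function(status) {
    t <- table(factor(assignments$gene_id[assignments$status == status],
                      levels = gene_ids))
    as.integer(t)
  }
  n_ua <- cnt("unique_a")
  n_ub <- cnt("unique_b")
  n_sh <- cnt("shared")
  present_a <- n_ua > 0 | n_sh > 0
  present_b <- n_ub > 0 | n_sh > 0
  mode <- ifelse(present_a & present_b, 3L,
                 ifelse(present_a, 1L, ifelse(present_b, 2L, 4L)))
  category <- ifelse(
    n_sh > 0 & n_ua == 0 & n_ub == 0, "identical",
    ifelse(n_sh > 0, "mixed",
           ifelse(n_ua > 0 & n_ub > 0, "mutually_exclusive",
                  ifelse(n_ua > 0, "a_only",
                         ifelse(n_ub > 0, "b_only", "unbound")))))
  data.frame(gene_id = gene_ids, n_unique_a = n_ua, n_unique_b = n_ub,
             n_shared = n_sh, mode = mode, category = category,
             stringsAsFactors = FALSE)
}

chisq_2x2 <- function(tab) {
  # Pearson chi-square without continuity correction, df = 1; a table
  # with an empty margin carries no evidence (statistic 0, p 1)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = c("X-squared" = 0), p.value = 1,
                expected = tab))
  }
  suppressWarnings(stats::chisq.test(tab, correct = FALSE))
}

#' Enrichment of gene-proximal binding among responsive genes
#'
#' 2x2 chi-square test (bound/unbound x responsive/background, without
#' continuity correction) of whether responsive genes are enriched for
#' gene-proximal TF binding relative to the TGF-beta-independent
#' background; "bound" means binding mode 1, 2 or 3.
#'
#' @param responsive_ids,background_ids disjoint gene id sets.
#' @param profiles profile table from [gene_binding_profiles()].
#' @return One-row data.frame: counts, `fold` (fraction bound in the
#'   responsive set over fraction bound in the background), `chisq`, `p`,
#'   and `low_expected` flagging any expected cell below 5.
#' @export
bound_fraction_enrichment <- function(responsive_ids, background_ids,
                                      profiles) {
  if (length(intersect(responsive_ids, background_ids)) > 0) {
    stop("responsive and background sets must be disjoint", call. = FALSE)
  }
  bound <- profiles$gene_id[profiles$mode != 4]
  rb <- sum(responsive_ids %in% bound)
  bb <- sum(background_ids %in% bound)
  tab <- matrix(c(rb, length(responsive_ids) - rb,
                  bb, length(background_ids) - bb),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("responsive", "background"),
                                c("bound", "unbound")))
  ct <- chisq_2x2(tab)
  data.frame(n_responsive = length(responsive_ids),
             n_background = length(background_ids),
             responsive_bound = rb, background_bound = bb,
             fold = (rb / length(responsive_ids)) /
               (bb / length(background_ids)),
             chisq = unname(ct$statistic), p = ct$p.value,
             low_expected = any(ct$expected < 5))
}

#' Binding-mode enrichment of a gene set over the background
#'
#' For each of the four binding modes, tests a 2x2 table (in-mode /
#' not-in-mode x set / background) by chi-square without continuity
#' correction; fold enrichment is the set's mode fraction over the
#' background's; FDR is Benjamini-Hochberg across the four modes.
#'
#' @param set_ids non-empty gene id set (e.g. responsive genes at one time
#'   point); must be disjoint from `background_ids`.
#' @param background_ids TGF-beta-independent background gene ids.
#' @param profiles profile table from [gene_binding_profiles()].
#' @param set_label label stored on the result rows.
#' @return Four-row data.frame: `set_label`, `mode`, `n_set_in_mode`,
#'   `n_background_in_mode`, `fold`, `chisq`, `p`, `fdr`, `low_expected`.
#' @export
mode_enrichment <- function(set_ids, background_ids, profiles,
                            set_label = "set") {
  if (length(set_ids) == 0) stop("empty gene set", call. = FALSE)
  if (length(intersect(set_ids, background_ids)) > 0) {
    stop("set and background must be disjoint", call. = FALSE)
  }
  mode_of <- profiles$mode[match(c(set_ids, background_ids),
                                 profiles$gene_id)]
  if (anyNA(mode_of)) stop("gene missing from profiles", call. = FALSE)
  m_set <- mode_of[seq_along(set_ids)]
  m_bg <- mode_of[-seq_along(set_ids)]
  rows <- lapply(MODE_LEVELS, function(m) {
    a <- sum(m_set == m); b <- length(m_set) - a
    c_ <- sum(m_bg == m); d <- length(m_bg) - c_
    tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
    ct <- chisq_2x2(tab)
    data.frame(set_label = set_label, mode = m,
               n_set_in_mode = a, n_background_in_mode = c_,
               fold = (a / length(m_set)) / (c_ / length(m_bg)),
               chisq = unname(ct$statistic), p = ct$p.value,
               low_expected = any(ct$expected < 5))
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("set_label", "mode", "n_set_in_mode", "n_background_in_mode",
          "fold", "chisq", "p", "fdr", "low_expected")]
}

#' Composite occupancy profile table for a gene set
#'
#' Orders a gene set by occupancy category (identical, mixed,
#' mutually_exclusive, a_only, b_only, unbound) for composite-profile
#' reporting, with per-category counts.
#'
#' @param profiles profile table from [gene_binding_profiles()].
#' @param gene_ids gene set to report (default: all profiled genes).
#' @return List with `table` (profiles ordered by category then gene id)
#'   and `counts` (named integer vector over all six categories, summing
#'   to `length(gene_ids)`).
#' @export
composite_profile_table <- function(profiles, gene_ids = profiles$gene_id) {
  sub <- profiles[profiles$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(sub) != length(unique(gene_ids))) {
    stop("gene missing from profiles", call. = FALSE)
  }
  f <- factor(sub$category, levels = CATEGORY_LEVELS)
  sub <- sub[order(f, sub$gene_id), , drop = FALSE]
  rownames(sub) <- NULL
  list(table = sub,
       counts = stats::setNames(as.integer(table(f)), CATEGORY_LEVELS))
}
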