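# The four-way gene taxonomy: every context-specific responsive gene is
# labeled by whether its context is coupled to differential TF binding,
# a permissive epigenetic difference, both, or neither.
#
#   epigenome_assisted : in smad3_high AND in (open_chromatin_high OR
#                        hypo_methylation) of its own context condition --
#                        differential TF binding assisted by a permissive
#                        epigenetic configuration;
#   epigenome_directed : NOT in smad3_high but in at least one epigenetic
#                        set -- equivalent TF binding, specificity tracking
#                        the epigenome;
#   smad3_only         : in smad3_high, in neither epigenetic set;
#   unexplained        : in none of the three sets.

CONTEXT_LABELS <- c("epigenome_assisted", "epigenome_directed",
                    "smad3_only", "unexplained")

#' Classify context-specific responsive genes
#'
#' @param context_sets named list with `a` and `b`: the condition-unique
#'   responsive gene ids for each condition (e.g. the `a_unique` /
#'   `b_unique` sets of [partition_context_sets()] at one time point).
#'   The two sets must be disjoint.
#' @param epigenome_sets an `epigenome_gene_sets` object from
#'   [build_epigenome_sets()].
#' @return Data.frame `gene_id`, `context` ("a" or "b"), `in_smad3_high`,
#'   `in_open_chromatin_high`, `in_hypo_methylation`, `label`.
#' @export
classify_context_genes <- function(context_sets, epigenome_sets) {
  both <- intersect(context_sets$a, context_sets$b)
  if (length(both) > 0) {
    stop("gene(s) present in both contexts: ",
         paste(utils::head(both, 3), collapse = ", "), call. = FALSE)
  }
  one <- function(ids, ctx) {
    es <- epigenome_sets[[ctx]]
    s3 <- ids %in% es$smad3_high
    oc <- ids %in% es$open_chromatin_high
    hm <- ids %in% es$hypo_methylation
    epi <- oc | hm
    label <- ifelse(s3 & epi, "epigenome_assisted",
                    ifelse(!s3 & epi, "epigenome_directed",
                           ifelse(s3, "smad3_only", "unexplained")))
    data.frame(gene_id = ids, context = rep(ctx, length(ids)),
               in_smad3_high = s3,
               in_open_chromatin_high = oc, in_hypo_methylation = hm,
               label = label, stringsAsFactors = FALSE)
  }
  out <- rbind(one(context_sets$a, "a"), one(context_sets$b, "b"))
  rownames(out) <- NULL
  out
}

#' Summary of classification labels per context
#'
#' @param classification output of [classify_context_genes()].
#' @return Data.frame of counts, one row per (context, label), all four
#'   labels reported.
#' @export
classification_summary <- function(classification) {
  tab <- table(factor(classification$context, levels = c("a", "b")),
               factor(classification$label, levels = CONTEXT_LABELS))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("context", "label", "n")
  out
}

#' Three-set overlap report within a context gene set
#'
#' Counts the 8 membership regions (in/out of each of three gene sets,
#' Venn style) restricted to one context gene set; counts sum to the
#' context-set size.
#'
#' @param context_ids gene ids of one context set.
#' @param sets named list of exactly three gene id sets (e.g. smad3_high,
#'   open_chromatin_high, hypo_methylation for the matching condition).
#' @return Data.frame with one logical column per set plus `n`.
#' @export
set_overlap_report <- function(context_ids, sets) {
  stopifnot(length(sets) == 3, !is.null(names(sets)))
  context_ids <- unique(context_ids)
  mem <- vapply(sets, function(s) context_ids %in% s,
                logical(length(context_ids)))
  if (length(context_ids) == 1) mem <- matrix(mem, nrow = 1)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 3))
  names(grid) <- names(sets)
  grid$n <- vapply(seq_len(nrow(grid)), function(i) {
    sum(colSums(t(mem) == unlist(grid[i, 1:3])) == 3)
  }, numeric(1))
  grid
}
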