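# Per-window differential signal analysis between the two conditions for
# each factor (TF, open-chromatin marks, repressive marks, DNA
# methylation), the derived epigenome gene sets, and hypergeometric
# gene-set enrichment.

OPEN_CHROMATIN_FACTORS <- c("H3K4me3", "H3K27ac", "POL2")

#' Validate a count table against a window set
#'
#' Pass-through validation: every requested window must have a row in the
#' count table; rows are returned in window order.
#'
#' @param windows window table (needs `gene_id`) or character vector of
#'   window ids.
#' @param ct a [count_table()].
#' @return The count table restricted to the windows, in window order.
#' @export
quantify_window_counts <- function(windows, ct) {
  ids <- if (is.data.frame(windows)) windows$gene_id else as.character(windows)
  miss <- setdiff(ids, rownames(ct$counts))
  if (length(miss) > 0) {
    stop("windows missing from count table: ",
         paste(utils::head(miss, 3), collapse = ", "),
         if (length(miss) > 3) ", ..." else "", call. = FALSE)
  }
  count_table(ct$counts[ids, , drop = FALSE], ct$lib_sizes)
}

#' Differential window-signal test between two conditions
#'
#' Counts are normalized to counts per million by genome-wide library
#' size; the log2 fold change is
#' `log2((mean CPM A + 0.5) / (mean CPM B + 0.5))`. With replicates on
#' both sides the per-window test is edgeR's negative-binomial exact test
#' with empirical dispersion estimation (`method = "edger"`, the
#' field-standard differential-binding test; a plain Welch t on
#' `log2(CPM + 0.5)` remains available as `method = "welch"`); with a
#' single column per side it is the classic two-library exact binomial
#' conditional test of countA against countA + countB with success
#' probability `libA / (libA + libB)` (`method = "binomial"`). P values
#' are BH-adjusted across windows, and a window is called `higher_a` when
#' `fdr < alpha` and `log2fc >= min_lfc` (symmetrically `higher_b`),
#' otherwise `ns`.
#'
#' @param ct a [count_table()].
#' @param side character vector, one entry per column, with exactly two
#'   distinct values; the first value sorted is condition A unless `a`
#'   is given.
#' @param a the side label to treat as condition A.
#' @param alpha FDR threshold (default 0.05).
#' @param min_lfc minimum absolute log2 fold change (default 1),
#'   emulating a stringent "most pronounced differences" call.
#' @param method `"auto"` (default; edger when both sides have >= 2
#'   columns, binomial otherwise), `"edger"`, `"welch"` or `"binomial"`.
#' @param factor_label label stored on the result rows.
#' @return Data.frame `window_id`, `factor`, `log2fc`, `p`, `fdr`,
#'   `direction`.
#' @export
differential_test <- function(ct, side, a = sort(unique(side))[1],
                              alpha = 0.05, min_lfc = 1,
                              method = c("auto", "edger", "welch",
                                         "binomial"),
                              factor_label = NA_character_) {
  method <- match.arg(method)
  side <- as.character(side)
  stopifnot(length(side) == ncol(ct$counts))
  lv <- unique(side)
  if (length(lv) != 2 || !a %in% lv) {
    stop("side must take exactly two values including '", a, "'",
         call. = FALSE)
  }
  ia <- which(side == a)
  ib <- which(side != a)
  if (method == "auto") {
    method <- if (length(ia) >= 2 && length(ib) >= 2) "edger" else "binomial"
  }
  if (any(ct$lib_sizes <= 0)) stop("zero library size", call. = FALSE)
  cpm <- sweep(ct$counts, 2, ct$lib_sizes / 1e6, "/")
  mean_a <- rowMeans(cpm[, ia, drop = FALSE])
  mean_b <- rowMeans(cpm[, ib, drop = FALSE])
  log2fc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  if (method %in% c("edger", "welch")) {
    if (length(ia) < 2 || length(ib) < 2) {
      stop(method, " method needs >= 2 columns per side", call. = FALSE)
    }
    if (method == "welch") {
      w <- row_welch_test(log2(cpm[, ia, drop = FALSE] + 0.5),
                          log2(cpm[, ib, drop = FALSE] + 0.5))
      p <- w$p
    } else {
      grp <- base::factor(ifelse(seq_along(side) %in% ia, "A", "B"),
                          levels = c("B", "A"))
      y <- edgeR::DGEList(counts = ct$counts, group = grp,
                          lib.size = unname(ct$lib_sizes))
      # noise-free or near-constant replicates make the empirical-Bayes
      # dispersion fit warn or fail; both collapse to the Poisson limit
      y <- tryCatch(suppressWarnings(suppressMessages(
        edgeR::estimateDisp(y))), error = function(e) y)
      if (is.null(y$common.dispersion) ||
          !is.finite(y$common.dispersion)) {
        # degenerate (e.g. noise-free) replicates: Poisson limit
        y$common.dispersion <- 1e-6
        y$tagwise.dispersion <- NULL
        y$trended.dispersion <- NULL
      }
      p <- edgeR::exactTest(y, pair = c("B", "A"))$table$PValue
    }
  } else {
    if (length(ia) != 1 || length(ib) != 1) {
      stop("binomial method needs exactly one column per side", call. = FALSE)
    }
    la <- ct$lib_sizes[ia]
    lb <- ct$lib_sizes[ib]
    p0 <- la / (la + lb)
    ka <- ct$counts[, ia]
    n <- ka + ct$counts[, ib]
    p <- vapply(seq_along(ka), function(i) {
      if (n[i] == 0) return(1)
      stats::binom.test(ka[i], n[i], p = p0)$p.value
    }, numeric(1))
  }
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(fdr < alpha & log2fc >= min_lfc, "higher_a",
                      ifelse(fdr < alpha & log2fc <= -min_lfc, "higher_b",
                             "ns"))
  data.frame(window_id = rownames(ct$counts), factor = factor_label,
             log2fc = log2fc, p = p, fdr = fdr, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build SMAD3-high, open-chromatin-high and hypo-methylation gene sets
#'
#' For each condition X: `smad3_high` holds genes with differentially
#' higher TF signal in X; `open_chromatin_high` is the union over the
#' open-chromatin factors (H3K4me3, H3K27ac, Pol II) of genes higher in X;
#' `hypo_methylation` holds genes with differentially *lower* TSS
#' methylation in X (i.e. methylation higher in the opposing condition).
#' Methylation calls must have been computed over TSS-proximal windows,
#' all other factors over gene-proximal windows.
#'
#' @param calls named list of [differential_test()] results; names must
#'   include `smad3_factor`, every `open_factors` entry, and
#'   `meth_factor`.
#' @param smad3_factor,open_factors,meth_factor factor names.
#' @return An `epigenome_gene_sets` list with elements `a` and `b`, each
#'   holding `smad3_high`, `open_chromatin_high`, `hypo_methylation` id
#'   vectors.
#' @export
build_epigenome_sets <- function(calls, smad3_factor = "SMAD3",
                                 open_factors = OPEN_CHROMATIN_FACTORS,
                                 meth_factor = "METH") {
  need <- c(smad3_factor, open_factors, meth_factor)
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0) {
    stop("missing differential calls for factor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  higher <- function(f, dir) calls[[f]]$window_id[calls[[f]]$direction == dir]
  sets_for <- function(own, other) {
    list(smad3_high = higher(smad3_factor, own),
         open_chromatin_high =
           sort(unique(unlist(lapply(open_factors, higher, dir = own)))),
         hypo_methylation = higher(meth_factor, other))
  }
  structure(list(a = sets_for("higher_a", "higher_b"),
                 b = sets_for("higher_b", "higher_a")),
            class = "epigenome_gene_sets")
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided over-representation p of a differential gene set within a
#' context gene set: `P(X >= overlap)` with
#' `X ~ Hypergeometric(universe, differential set, context set)`, plus the
#' sample odds ratio of the 2x2 membership table.
#'
#' @param diff_set,context_set gene id sets, both subsets of `universe`.
#' @param universe the tested-gene universe.
#' @return One-row data.frame: sizes, `overlap`, `expected`, `odds_ratio`,
#'   `p`.
#' @export
gene_set_enrichment <- function(diff_set, context_set, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  diff_set <- unique(diff_set)
  context_set <- unique(context_set)
  if (!all(diff_set %in% universe) || !all(context_set %in% universe)) {
    stop("sets must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(diff_set, context_set))
  m <- length(diff_set)
  n <- length(universe) - m
  s <- length(context_set)
  p <- stats::phyper(k - 1, m, n, s, lower.tail = FALSE)
  a <- k
  b <- m - k
  c_ <- s - k
  d <- n - (s - k)
  data.frame(n_universe = length(universe), n_diff = m, n_context = s,
             overlap = k, expected = m * s / length(universe),
             odds_ratio = (a * d) / (b * c_),
             p = p)
}
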