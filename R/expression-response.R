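# Responsive-gene calling per condition and time point, and the partition
# of the tested-gene universe into context-specific and shared sets.

#' Row-wise Welch two-sample t-test
#'
#' Vectorised Welch (unequal-variance) t-test across the rows of two
#' matrices. When both groups have zero variance the p value is 1 for a
#' zero mean difference and 0 otherwise (the noise-free limit).
#'
#' @param x,y numeric matrices with matching rows, >= 2 columns each.
#' @return Data.frame with `diff` (rowMeans(x) - rowMeans(y)), `t`, `df`,
#'   `p`.
#' @export
row_welch_test <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y),
            ncol(x) >= 2, ncol(y) >= 2)
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  diff <- mx - my
  tt <- ifelse(se2 > 0, diff / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df),
              ifelse(diff == 0, 1, 0))
  data.frame(diff = diff, t = tt, df = df, p = p)
}

#' Call TGF-beta-responsive genes at one time point
#'
#' Per-gene two-sided test of treated vs control log2 expression at the
#' given time point in the given condition, Benjamini-Hochberg adjusted
#' across all tested genes; a gene is responsive at `fdr < threshold`
#' (default 0.1). The default test is Welch's t; `method = "moderated"`
#' uses limma's moderated t (empirical-Bayes variance pooling) instead.
#'
#' @param expr an [expression_matrix()].
#' @param condition condition label to test.
#' @param time time point in hours (one of the matrix's time points).
#' @param fdr responsiveness threshold on the BH-adjusted p value.
#' @param method `"moderated"` (default; limma's empirical-Bayes
#'   moderated t, appropriate for the few-replicate arrays this emulates)
#'   or `"welch"` (plain Welch t).
#' @return Data.frame with `gene_id`, `condition`, `time`, `log2fc`
#'   (treated - control), `p`, `fdr`, `responsive`.
#' @export
call_responsive <- function(expr, condition, time, fdr = 0.1,
                            method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "expression_matrix"))
  s <- expr$samples
  sel_t <- s$condition == condition & s$time == time &
    s$treatment == "treated"
  sel_c <- s$condition == condition & s$time == time &
    s$treatment == "control"
  if (sum(sel_t) < 2 || sum(sel_c) < 2) {
    stop("need >= 2 replicates per group (condition ", condition,
         ", time ", time, ")", call. = FALSE)
  }
  x <- expr$values[, sel_t, drop = FALSE]
  y <- expr$values[, sel_c, drop = FALSE]
  if (method == "welch") {
    w <- row_welch_test(x, y)
    lfc <- w$diff
    p <- w$p
  } else {
    mat <- cbind(x, y)
    design <- cbind(Intercept = 1,
                    treated = rep(c(1, 0), c(ncol(x), ncol(y))))
    fit <- limma::lmFit(mat, design)
    if (max(fit$sigma) == 0) {
      # noise-free limit: no residual variance to moderate
      lfc <- fit$coefficients[, "treated"]
      p <- ifelse(lfc == 0, 1, 0)
    } else {
      fit <- limma::eBayes(fit)
      lfc <- fit$coefficients[, "treated"]
      p <- fit$p.value[, "treated"]
    }
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(expr$values), condition = condition,
             time = time, log2fc = lfc, p = p, fdr = q,
             responsive = q < fdr, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Call responsive genes for all (condition, time) cells
#'
#' @inheritParams call_responsive
#' @return One long data.frame of [call_responsive()] results.
#' @export
call_responsive_all <- function(expr, fdr = 0.1,
                                method = c("moderated", "welch")) {
  method <- match.arg(method)
  s <- expr$samples
  cells <- unique(s[, c("condition", "time")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    call_responsive(expr, cells$condition[i], cells$time[i], fdr, method)
  })
  do.call(rbind, out)
}

#' Partition the gene universe into context-specific and shared sets
#'
#' At each time point, genes responsive in A but not B are `a_unique`,
#' responsive in B but not A are `b_unique`, responsive in both `shared`,
#' and the remainder `independent`; the four sets partition the universe.
#' The global TGF-beta-independent background set contains genes responsive
#' in neither condition at any time point.
#'
#' @param calls_a,calls_b responsive-gene call tables for the two
#'   conditions (from [call_responsive_all()] or equivalent), covering the
#'   same gene universe and time points. Only `gene_id`, `time`,
#'   `responsive` are used, so externally computed calls can be supplied.
#' @return A `context_gene_sets` list: `$by_time` (named by time point,
#'   each with `a_unique`, `b_unique`, `shared`, `independent` id vectors),
#'   `$background` (global), `$universe`, and `$conditions`.
#' @export
partition_context_sets <- function(calls_a, calls_b) {
  universe <- sort(unique(calls_a$gene_id))
  if (!setequal(universe, unique(calls_b$gene_id))) {
    stop("conditions were tested on different gene universes", call. = FALSE)
  }
  times <- sort(unique(calls_a$time))
  if (!setequal(times, unique(calls_b$time))) {
    stop("conditions were tested at different time points", call. = FALSE)
  }
  resp <- function(calls, t) {
    unique(calls$gene_id[calls$time == t & calls$responsive])
  }
  by_time <- lapply(times, function(t) {
    ra <- resp(calls_a, t)
    rb <- resp(calls_b, t)
    list(a_unique = setdiff(ra, rb),
         b_unique = setdiff(rb, ra),
         shared = intersect(ra, rb),
         independent = setdiff(universe, union(ra, rb)))
  })
  names(by_time) <- as.character(times)
  ever <- unique(c(calls_a$gene_id[calls_a$responsive],
                   calls_b$gene_id[calls_b$responsive]))
  conds <- c(unique(calls_a$condition), unique(calls_b$condition))
  structure(list(by_time = by_time,
                 background = setdiff(universe, ever),
                 universe = universe,
                 conditions = conds),
            class = "context_gene_sets")
}

#' Tabulate context classes per gene and time point
#'
#' @param sets a `context_gene_sets` object.
#' @return Long data.frame `gene_id`, `time`, `class`.
#' @export
context_class_table <- function(sets) {
  out <- lapply(names(sets$by_time), function(t) {
    st <- sets$by_time[[t]]
    cls <- rep("independent", length(sets$universe))
    names(cls) <- sets$universe
    cls[st$a_unique] <- "a_unique"
    cls[st$b_unique] <- "b_unique"
    cls[st$shared] <- "shared"
    data.frame(gene_id = sets$universe, time = as.numeric(t),
               class = unname(cls), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
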