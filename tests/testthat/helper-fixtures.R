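# Fixture builders shared across test files. Everything is generated in
# code; no stored binary fixtures.

make_peaks <- function(chrom, start, end, summit = NULL, ids = NULL,
                       condition = NA_character_) {
  n <- length(start)
  if (is.null(summit)) summit <- floor((start + end) / 2)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(n))
  data.frame(peak_id = ids, chrom = rep_len(chrom, n), start = start,
             end = end, name = ids, score = rep(1, n), strand = ".",
             summit_offset = summit - start, summit = summit,
             factor = "SMAD3", condition = condition,
             stringsAsFactors = FALSE)
}

random_peak_set <- function(n, chrom_len = 50000, width_range = c(50, 500),
                            chroms = c("chr1", "chr2"), prefix = "p") {
  chrom <- sample(chroms, n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  start <- sample.int(chrom_len - max(width_range), n, replace = TRUE)
  make_peaks(chrom, start, start + w,
             summit = start + floor(w / 2),
             ids = sprintf("%s%04d", prefix, seq_len(n)))
}

# O(n*m) brute-force reimplementation of the shared/unique matching rule:
# candidate pairs by summit-in-interval symmetric closure, greedy
# resolution by smallest summit distance (ties by row order).
brute_force_match <- function(pa, pb) {
  cand <- list()
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      if (pa$chrom[i] != pb$chrom[j]) next
      sa_in <- pa$summit[i] >= pb$start[j] && pa$summit[i] < pb$end[j]
      sb_in <- pb$summit[j] >= pa$start[i] && pb$summit[j] < pa$end[i]
      if (sa_in || sb_in) {
        cand[[length(cand) + 1]] <-
          c(i = i, j = j, d = abs(pa$summit[i] - pb$summit[j]))
      }
    }
  }
  pairs <- matrix(numeric(0), ncol = 2)
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    ord <- order(cand[, "d"], cand[, "i"], cand[, "j"])
    used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
    for (k in ord) {
      i <- cand[k, "i"]; j <- cand[k, "j"]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  list(pairs = data.frame(peak_a = pa$peak_id[pairs[, 1]],
                          peak_b = pb$peak_id[pairs[, 2]],
                          stringsAsFactors = FALSE),
       unique_a = setdiff(pa$peak_id, pa$peak_id[pairs[, 1]]),
       unique_b = setdiff(pb$peak_id, pb$peak_id[pairs[, 2]]))
}

# Tiny two-condition dataset with fully hand-controlled planting, used by
# the archetype and zero-noise tests. Genes sit on one chromosome, one
# 20-kb slot each, all + strand.
hand_dataset <- function(genes_spec, expr_spec, count_spec,
                         time_points = c(6, 24), reps = 3) {
  n <- nrow(genes_spec)
  layout <- genome_layout("chr1", n * 20000 + 10000)
  start <- (seq_len(n) - 1) * 20000 + 6000
  genes <- gene_model(genes_spec$gene_id, "chr1", start, start + 4000, "+")
  peaks_a <- list(); peaks_b <- list()
  for (i in seq_len(n)) {
    ka <- genes_spec$peaks_a[i]; kb <- genes_spec$peaks_b[i]
    sh <- genes_spec$peaks_shared[i]
    base <- start[i]
    mk <- function(cond, k, offset) {
      if (k == 0) return(NULL)
      s <- base + offset + (seq_len(k) - 1) * 600
      make_peaks("chr1", s, s + 300,
                 ids = sprintf("%s_%s_%d", cond, genes_spec$gene_id[i],
                               seq_len(k)), condition = cond)
    }
    peaks_a[[i]] <- rbind(mk("a", sh, 0), mk("a", ka, 2000))
    peaks_b[[i]] <- rbind(mk("b", sh, 0), mk("b", kb, 3200))
  }
  peaks_a <- do.call(rbind, peaks_a)
  peaks_b <- do.call(rbind, peaks_b)
  samples <- expand.grid(rep = seq_len(reps),
                         treatment = c("control", "treated"),
                         time = time_points, condition = c("a", "b"),
                         stringsAsFactors = FALSE)
  cn <- sprintf("%s.%s.t%d.r%d", samples$condition, samples$treatment,
                samples$time, samples$rep)
  vals <- matrix(8, n, nrow(samples),
                 dimnames = list(genes_spec$gene_id, cn))
  for (i in seq_len(n)) {
    on <- samples$treatment == "treated" &
      samples$condition %in% strsplit(expr_spec$responsive_in[i], "")[[1]]
    vals[i, on] <- 8 + expr_spec$log2fc[i]
  }
  expr <- expression_matrix(vals)
  counts <- list()
  for (f in names(count_spec)) {
    hi <- count_spec[[f]]  # n x 2 matrix of "high"/"low"
    mu <- ifelse(hi == "high", 200, 50)
    mat <- cbind(matrix(rep(mu[, 1], reps), n), matrix(rep(mu[, 2], reps), n))
    mat <- matrix(as.integer(mat), n)
    colnames(mat) <- c(sprintf("a.rep%d", seq_len(reps)),
                       sprintf("b.rep%d", seq_len(reps)))
    rownames(mat) <- genes_spec$gene_id
    counts[[f]] <- list(ct = count_table(mat, rep(1e6, 2 * reps)),
                        side = rep(c("a", "b"), each = reps))
  }
  list(layout = layout, genes = genes,
       peaks = list(a = peaks_a, b = peaks_b),
       counts = counts, expression = expr)
}
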