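# Seeded synthetic-data generator. Emits a toy genome, gene annotation,
# per-condition TF peak files, per-factor window count tables, a
# time-course expression matrix, and a ground-truth table encoding every
# planted label (responsive class per time point, binding mode, occupancy
# category, per-factor chromatin states, context label) that the pipeline
# is expected to recover.
#
# RNG streams: one stream per output family, derived from the master seed
# (structure/truth: seed; peaks: seed + 1; counts: seed + 2; expression:
# seed + 3; all via set.seed on R's default Mersenne-Twister), so adding
# or regenerating one family never perturbs the draws of another.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is validated under:
#' 1,000 genes, planted expression effect |log2FC| = 2 with Gaussian noise
#' sigma = 0.5 and 3 replicates per cell, 4-fold chromatin count
#' differences (NB means 200 vs 50, size 20, 3 replicates per condition),
#' and shared-peak coordinate jitter up to 50 bp.
#'
#' @param seed master seed (mandatory).
#' @param n_genes number of genes.
#' @param n_chrom chromosomes the genes are spread over.
#' @param gene_slot bp of genome reserved per gene (windows of neighbours
#'   never touch).
#' @param gene_offset gene start offset within its slot (leaves room for
#'   the 1,500 bp upstream margin).
#' @param gene_length_range min/max gene body length (bp).
#' @param time_points expression time points (hours).
#' @param class_fractions named fractions (a_unique, b_unique, shared,
#'   independent) summing to 1.
#' @param p_early probability a responsive gene responds from the 6-hr
#'   time point (otherwise from 24 hr).
#' @param expr_log2fc,expr_sigma,expr_reps planted absolute expression
#'   log2 fold change, Gaussian noise sd, replicates per
#'   (condition, treatment, time) cell.
#' @param expr_baseline_range range of per-gene baseline log2 expression.
#' @param label_fractions_early,label_fractions_late named fractions
#'   (assisted, directed, smad3_only, unexplained) over context-specific
#'   genes by onset, each summing to 1.
#' @param unexplained_mode_probs probabilities that an unexplained context
#'   gene carries identical shared binding (mode 3) vs no binding (mode 4).
#' @param mode_probs_shared,mode_probs_independent binding-mode (1..4)
#'   probabilities for shared-responsive and independent genes.
#' @param mode3_category_probs probabilities (identical, mixed,
#'   mutually_exclusive) for non-context mode-3 genes.
#' @param epi_route_probs for epigenetically coupled context genes, the
#'   probabilities that the planted difference is open chromatin, TSS
#'   methylation, or both.
#' @param p_k27me3_flip probability an epigenetically coupled gene also
#'   gets the repressive H3K27me3 mark planted high in the opposing
#'   condition.
#' @param p_background_high probability a non-differential gene x factor
#'   is high in both conditions (otherwise low in both).
#' @param peak_width_mean,peak_width_sd,peak_width_min TF peak width
#'   distribution (bp).
#' @param peaks_per_gene_max planted TF peaks per bound gene drawn
#'   uniformly from 1..max (per side where applicable).
#' @param jitter maximum absolute shift (bp) applied to the condition-B
#'   copy of a shared peak.
#' @param peak_fp_rate,peak_fn_rate per-gene-per-condition spurious-peak
#'   probability; per-peak-copy drop probability.
#' @param count_reps replicates per condition in each factor count table.
#' @param nb_mean_low,nb_mean_high,nb_size negative-binomial window-count
#'   means for low/high chromatin states and dispersion size.
#' @param count_noise when FALSE counts equal their means exactly (the
#'   noise-free limit used by identity checks).
#' @param lib_size genome-wide library size per sample.
#' @param factors factor names; must include SMAD3, the open-chromatin
#'   trio and METH.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 42,
    n_genes = 1000,
    n_chrom = 2,
    gene_slot = 20000,
    gene_offset = 6000,
    gene_length_range = c(2000, 8000),
    time_points = c(1, 3, 6, 24),
    class_fractions = c(a_unique = 0.15, b_unique = 0.15, shared = 0.10,
                        independent = 0.60),
    p_early = 0.4,
    expr_log2fc = 2,
    expr_sigma = 0.5,
    expr_reps = 3,
    expr_baseline_range = c(6, 10),
    label_fractions_early = c(assisted = 0.20, directed = 0.50,
                              smad3_only = 0.05, unexplained = 0.25),
    label_fractions_late = c(assisted = 0.50, directed = 0.25,
                             smad3_only = 0.05, unexplained = 0.20),
    unexplained_mode_probs = c(mode3 = 0.5, mode4 = 0.5),
    mode_probs_shared = c(0.10, 0.10, 0.60, 0.20),
    mode_probs_independent = c(0.15, 0.15, 0.25, 0.45),
    mode3_category_probs = c(identical = 0.5, mixed = 0.3,
                             mutually_exclusive = 0.2),
    epi_route_probs = c(open = 0.4, meth = 0.3, both = 0.3),
    p_k27me3_flip = 0.5,
    p_background_high = 0.3,
    peak_width_mean = 300,
    peak_width_sd = 50,
    peak_width_min = 150,
    peaks_per_gene_max = 3,
    jitter = 50,
    peak_fp_rate = 0,
    peak_fn_rate = 0,
    count_reps = 3,
    nb_mean_low = 50,
    nb_mean_high = 200,
    nb_size = 20,
    count_noise = TRUE,
    lib_size = 1e6,
    factors = c("SMAD3", "H3K4me3", "H3K27ac", "POL2", "H3K27me3", "METH")) {
  cfg <- as.list(environment())
  check_frac <- function(x, nm) {
    if (abs(sum(x) - 1) > 1e-8 || any(x < 0)) {
      stop(nm, " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  check_frac(cfg$class_fractions, "class_fractions")
  check_frac(cfg$label_fractions_early, "label_fractions_early")
  check_frac(cfg$label_fractions_late, "label_fractions_late")
  check_frac(cfg$unexplained_mode_probs, "unexplained_mode_probs")
  check_frac(cfg$mode_probs_shared, "mode_probs_shared")
  check_frac(cfg$mode_probs_independent, "mode_probs_independent")
  check_frac(cfg$mode3_category_probs, "mode3_category_probs")
  check_frac(cfg$epi_route_probs, "epi_route_probs")
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("seed is mandatory",
                                                 call. = FALSE)
  stopifnot(cfg$n_genes >= 1, cfg$expr_reps >= 2, cfg$jitter >= 0,
            cfg$peak_fp_rate >= 0, cfg$peak_fp_rate <= 1,
            cfg$peak_fn_rate >= 0, cfg$peak_fn_rate <= 1)
  class(cfg) <- "simulation_config"
  cfg
}

#' Load a simulation configuration from YAML
#'
#' Any field of [simulation_config()] may be set; unset fields keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(simulation_config, raw)
}

sample_classes <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Plant peak composition counts (n_shared, n_unique_a, n_unique_b) for a
# gene given its mode and (for mode 3) category.
plan_peak_counts <- function(mode, category, kmax) {
  k <- function() sample.int(kmax, 1)
  if (mode == 1) return(c(sh = 0, ua = k(), ub = 0))
  if (mode == 2) return(c(sh = 0, ua = 0, ub = k()))
  if (mode == 4) return(c(sh = 0, ua = 0, ub = 0))
  switch(category,
         identical = c(sh = k(), ua = 0, ub = 0),
         mixed = {
           sides <- sample.int(3, 1)  # 1 = A, 2 = B, 3 = both
           c(sh = k(),
             ua = if (sides %in% c(1, 3)) k() else 0,
             ub = if (sides %in% c(2, 3)) k() else 0)
         },
         mutually_exclusive = c(sh = 0, ua = k(), ub = k()))
}

#' Generate a complete synthetic two-condition experiment
#'
#' Produces, deterministically given the config seed: the genome layout
#' and gene annotation; TF (SMAD3) peak tables for both conditions where
#' planted shared peaks sit at identical coordinates up to the configured
#' jitter and condition-unique peaks appear only in their own condition's
#' gene-proximal window; per-factor window count tables drawn
#' NB(state mean, size) over gene-proximal windows (TSS-proximal for
#' methylation); a treated-vs-control expression time course; and the
#' ground-truth table.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, all files are written
#'   there in their external formats (narrowPeak, TSV) plus `truth.tsv`.
#' @return A `synthetic_experiment` list: `config`, `layout`, `genes`,
#'   `windows` (gene_proximal, tss_proximal), `peaks` (list `a`, `b`),
#'   `counts` (per factor: `ct` and `side`), `expression`, `truth`.
#' @export
simulate_experiment <- function(config = simulation_config(),
                                out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config

  ## ---- structure & truth (stream: seed) -------------------------------
  set.seed(cfg$seed)
  n <- cfg$n_genes
  per_chr <- ceiling(n / cfg$n_chrom)
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chrom))
  gene_chrom <- chrom_names[ceiling(seq_len(n) / per_chr)]
  slot_in_chr <- (seq_len(n) - 1) %% per_chr
  gene_len <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                     n, replace = TRUE)
  gene_start <- slot_in_chr * cfg$gene_slot + cfg$gene_offset
  strand <- sample(c("+", "-"), n, replace = TRUE)
  layout <- genome_layout(chrom_names,
                          rep(per_chr * cfg$gene_slot + 10000, cfg$n_chrom))
  genes <- gene_model(sprintf("gene_%04d", seq_len(n)), gene_chrom,
                      gene_start, gene_start + gene_len, strand)
  gp <- derive_gene_proximal(genes, layout)
  tp <- derive_tss_proximal(genes, layout)

  cls <- sample_classes(n, cfg$class_fractions)
  responsive <- cls != "independent"
  onset <- ifelse(responsive,
                  ifelse(stats::runif(n) < cfg$p_early, 6, 24), NA)
  sign <- sample(c(-1, 1), n, replace = TRUE)

  label <- rep(NA_character_, n)
  ctx <- cls %in% c("a_unique", "b_unique")
  early <- !is.na(onset) & onset == 6
  label[ctx & early] <- sample_classes(sum(ctx & early),
                                       cfg$label_fractions_early)
  label[ctx & !early] <- sample_classes(sum(ctx & !early),
                                        cfg$label_fractions_late)

  mode <- integer(n)
  category <- character(n)
  for (i in seq_len(n)) {
    if (ctx[i]) {
      own <- if (cls[i] == "a_unique") 1L else 2L
      mode[i] <- switch(label[i],
                        assisted = own,
                        smad3_only = own,
                        directed = 3L,
                        unexplained = if (sample_classes(
                          1, cfg$unexplained_mode_probs) == "mode3") 3L
                        else 4L)
      category[i] <- if (mode[i] == 3) "identical" else
        c("a_only", "b_only", "", "unbound")[mode[i]]
    } else {
      probs <- if (cls[i] == "shared") cfg$mode_probs_shared
      else cfg$mode_probs_independent
      mode[i] <- sample.int(4, 1, prob = probs)
      category[i] <- switch(mode[i], "a_only", "b_only",
                            sample_classes(1, cfg$mode3_category_probs),
                            "unbound")
    }
  }

  route <- rep(NA_character_, n)
  epi_coupled <- ctx & label %in% c("assisted", "directed")
  route[epi_coupled] <- sample_classes(sum(epi_coupled),
                                       cfg$epi_route_probs)

  # chromatin states: "high"/"low" per factor x condition
  states <- list()
  for (f in cfg$factors) {
    states[[f]] <- matrix("low", n, 2, dimnames = list(genes$gene_id,
                                                       c("a", "b")))
  }
  # SMAD3 counts reflect binding
  states$SMAD3[mode %in% c(1, 3), "a"] <- "high"
  states$SMAD3[mode %in% c(2, 3), "b"] <- "high"
  # non-differential background states for marks and methylation
  for (f in setdiff(cfg$factors, "SMAD3")) {
    hi <- stats::runif(n) < cfg$p_background_high
    states[[f]][hi, ] <- "high"
  }
  own_col <- ifelse(cls == "a_unique", 1L, 2L)  # meaningful for ctx genes
  open_factor <- rep(NA_character_, n)
  open_set <- setdiff(intersect(cfg$factors, OPEN_CHROMATIN_FACTORS),
                      character(0))
  for (i in which(epi_coupled)) {
    oc <- own_col[i]; other <- 3L - oc
    if (route[i] %in% c("open", "both")) {
      open_factor[i] <- sample(open_set, 1)
      states[[open_factor[i]]][i, oc] <- "high"
      states[[open_factor[i]]][i, other] <- "low"
    }
    if (route[i] %in% c("meth", "both")) {
      states$METH[i, other] <- "high"
      states$METH[i, oc] <- "low"
    }
    if ("H3K27me3" %in% cfg$factors &&
        stats::runif(1) < cfg$p_k27me3_flip) {
      states$H3K27me3[i, other] <- "high"
      states$H3K27me3[i, oc] <- "low"
    }
  }
  # smad3_only genes must carry no planted epigenetic difference: force
  # their mark/methylation states equal across conditions (both low)
  for (i in which(ctx & label == "smad3_only")) {
    for (f in setdiff(cfg$factors, "SMAD3")) {
      states[[f]][i, ] <- states[[f]][i, 1]
    }
  }

  ## ---- TF peaks (stream: seed + 1) ------------------------------------
  set.seed(cfg$seed + 1)
  peaks <- generate_peaks(cfg, genes, gp, mode, category)

  ## ---- counts (stream: seed + 2) --------------------------------------
  set.seed(cfg$seed + 2)
  counts <- list()
  for (f in cfg$factors) {
    mu <- matrix(ifelse(states[[f]] == "high", cfg$nb_mean_high,
                        cfg$nb_mean_low), n, 2)
    cols <- as.vector(outer(sprintf("rep%d", seq_len(cfg$count_reps)),
                            c("a", "b"), function(r, s) paste(s, r, sep = ".")))
    side <- rep(c("a", "b"), each = cfg$count_reps)
    mat <- matrix(0L, n, length(cols),
                  dimnames = list(genes$gene_id, cols))
    for (j in seq_along(cols)) {
      m <- mu[, ifelse(side[j] == "a", 1, 2)]
      mat[, j] <- if (cfg$count_noise) {
        stats::rnbinom(n, mu = m, size = cfg$nb_size)
      } else {
        as.integer(round(m))
      }
    }
    counts[[f]] <- list(ct = count_table(mat, rep(cfg$lib_size,
                                                  length(cols))),
                        side = side)
  }

  ## ---- expression (stream: seed + 3) ----------------------------------
  set.seed(cfg$seed + 3)
  baseline <- stats::runif(n, cfg$expr_baseline_range[1],
                           cfg$expr_baseline_range[2])
  samples <- expand.grid(rep = seq_len(cfg$expr_reps),
                         treatment = c("control", "treated"),
                         time = cfg$time_points,
                         condition = c("a", "b"),
                         stringsAsFactors = FALSE)
  colnames_tok <- sprintf("%s.%s.t%d.r%d", samples$condition,
                          samples$treatment, samples$time, samples$rep)
  vals <- matrix(0, n, nrow(samples),
                 dimnames = list(genes$gene_id, colnames_tok))
  resp_in <- function(cond, t) {
    in_cond <- if (cond == "a") cls %in% c("a_unique", "shared")
    else cls %in% c("b_unique", "shared")
    in_cond & !is.na(onset) & t >= onset
  }
  for (j in seq_len(nrow(samples))) {
    mu <- baseline
    if (samples$treatment[j] == "treated") {
      on <- resp_in(samples$condition[j], samples$time[j])
      mu <- mu + ifelse(on, sign * cfg$expr_log2fc, 0)
    }
    noise <- if (cfg$expr_sigma > 0) {
      stats::rnorm(n, 0, cfg$expr_sigma)
    } else 0
    vals[, j] <- mu + noise
  }
  expr <- expression_matrix(vals)

  ## ---- truth table ----------------------------------------------------
  truth <- data.frame(gene_id = genes$gene_id, class = cls, onset = onset,
                      expr_sign = ifelse(responsive, sign, NA),
                      mode = mode, category = category,
                      context_label = label, epi_route = route,
                      stringsAsFactors = FALSE)
  for (t in cfg$time_points) {
    ra <- resp_in("a", t)
    rb <- resp_in("b", t)
    truth[[sprintf("class_t%d", t)]] <-
      ifelse(ra & rb, "shared",
             ifelse(ra, "a_unique", ifelse(rb, "b_unique", "independent")))
  }
  for (f in cfg$factors) {
    truth[[paste0(tolower(f), "_a")]] <- states[[f]][, "a"]
    truth[[paste0(tolower(f), "_b")]] <- states[[f]][, "b"]
  }

  out <- structure(list(config = cfg, layout = layout, genes = genes,
                        windows = list(gene_proximal = gp,
                                       tss_proximal = tp),
                        peaks = peaks, counts = counts, expression = expr,
                        truth = truth),
                   class = "synthetic_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

# Peak placement. The gene-proximal window is split into equal bins, one
# per planted peak, each peak centred in its own bin with a margin wide
# enough that jittered copies stay separated; mutually exclusive unique
# peaks therefore never overlap across conditions.
generate_peaks <- function(cfg, genes, gp, mode, category) {
  rows_a <- list()
  rows_b <- list()
  margin <- cfg$jitter + 10
  for (i in seq_len(nrow(genes))) {
    counts <- plan_peak_counts(mode[i], category[i], cfg$peaks_per_gene_max)
    k <- sum(counts)
    extra_a <- stats::runif(1) < cfg$peak_fp_rate
    extra_b <- stats::runif(1) < cfg$peak_fp_rate
    k_all <- k + extra_a + extra_b
    if (k_all == 0) next
    w0 <- gp$start[i]
    w1 <- gp$end[i]
    bin <- floor((w1 - w0) / k_all)
    if (bin < cfg$peak_width_min + 2 * margin) {
      stop("gene '", genes$gene_id[i],
           "': gene-proximal window too small for ", k_all, " peaks",
           call. = FALSE)
    }
    kinds <- sample(c(rep("sh", counts["sh"]), rep("ua", counts["ua"]),
                      rep("ub", counts["ub"]),
                      if (extra_a) "fpa", if (extra_b) "fpb"))
    for (b in seq_len(k_all)) {
      b0 <- w0 + (b - 1) * bin
      wmax <- bin - 2 * margin
      w <- round(min(max(stats::rnorm(1, cfg$peak_width_mean,
                                      cfg$peak_width_sd),
                         cfg$peak_width_min), wmax))
      s <- b0 + margin + sample.int(max(wmax - w, 0) + 1, 1) - 1
      id <- sprintf("%s_p%d", genes$gene_id[i], b)
      kind <- kinds[b]
      rec <- function(cond, start) {
        data.frame(peak_id = paste0(cond, "_", id),
                   chrom = genes$chrom[i], start = start, end = start + w,
                   name = paste0(cond, "_", id),
                   score = round(stats::runif(1, 5, 50), 2), strand = ".",
                   summit_offset = floor(w / 2),
                   summit = start + floor(w / 2),
                   factor = "SMAD3", condition = cond,
                   stringsAsFactors = FALSE)
      }
      drop_a <- stats::runif(1) < cfg$peak_fn_rate
      drop_b <- stats::runif(1) < cfg$peak_fn_rate
      if (kind == "sh") {
        shift <- if (cfg$jitter > 0) {
          sample.int(2 * cfg$jitter + 1, 1) - cfg$jitter - 1
        } else 0
        if (!drop_a) rows_a[[length(rows_a) + 1]] <- rec("a", s)
        if (!drop_b) rows_b[[length(rows_b) + 1]] <- rec("b", s + shift)
      } else if (kind %in% c("ua", "fpa")) {
        if (!drop_a) rows_a[[length(rows_a) + 1]] <- rec("a", s)
      } else {
        if (!drop_b) rows_b[[length(rows_b) + 1]] <- rec("b", s)
      }
    }
  }
  empty <- data.frame(peak_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      name = character(0), score = numeric(0),
                      strand = character(0), summit_offset = numeric(0),
                      summit = numeric(0), factor = character(0),
                      condition = character(0), stringsAsFactors = FALSE)
  list(a = if (length(rows_a)) do.call(rbind, rows_a) else empty,
       b = if (length(rows_b)) do.call(rbind, rows_b) else empty)
}

#' Write a synthetic experiment to disk
#'
#' Emits `genes.bed` (BED6), `chrom.sizes`, per-condition narrowPeak
#' files, per-factor count and library-size TSVs, `expression.tsv` and
#' `truth.tsv`, all in the package's external formats.
#'
#' @param exp a `synthetic_experiment`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- exp$genes
  writeLines(sprintf("%s\t%s\t%s\t%s\t0\t%s", g$chrom, num_fmt(g$start),
                     num_fmt(g$end), g$gene_id, g$strand),
             file.path(dir, "genes.bed"))
  writeLines(sprintf("%s\t%s", exp$layout$chrom,
                     num_fmt(exp$layout$length)),
             file.path(dir, "chrom.sizes"))
  write_peaks(exp$peaks$a, file.path(dir, "smad3_condA.narrowPeak"))
  write_peaks(exp$peaks$b, file.path(dir, "smad3_condB.narrowPeak"))
  for (f in names(exp$counts)) {
    write_counts(exp$counts[[f]]$ct,
                 file.path(dir, sprintf("counts_%s.tsv", f)),
                 file.path(dir, sprintf("libsizes_%s.tsv", f)))
  }
  write_expression(exp$expression, file.path(dir, "expression.tsv"))
  write_gene_table(exp$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
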