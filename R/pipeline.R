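# End-to-end orchestration: expression response -> TF binding modes ->
# differential chromatin -> context classification, with table output and
# a reproducibility manifest.

#' Analysis parameters
#'
#' @param fdr_expr responsiveness FDR threshold (0.1).
#' @param de_method expression test, `"welch"` or `"moderated"`.
#' @param match_criterion peak sharedness criterion, see [match_peaks()].
#' @param assign_rule proximal-assignment rule, see
#'   [assign_proximal_peaks()].
#' @param alpha,min_lfc differential chromatin thresholds, see
#'   [differential_test()].
#' @param count_method differential count test, see [differential_test()].
#' @param enrich_times time points (hours) at which binding-mode
#'   enrichment is computed (6 and 24: early and late responders).
#' @param classify_time time point whose context-specific sets are
#'   classified (24).
#' @return A named list of parameters.
#' @export
analysis_params <- function(fdr_expr = 0.1,
                            de_method = "moderated",
                            match_criterion = "summit",
                            assign_rule = "overlap",
                            alpha = 0.05, min_lfc = 1,
                            count_method = "auto",
                            enrich_times = c(6, 24),
                            classify_time = 24) {
  as.list(environment())
}

#' Run the full analysis on a two-condition dataset
#'
#' Takes a dataset shaped like a [simulate_experiment()] result (fields
#' `layout`, `genes`, `peaks$a`, `peaks$b`, `counts` per factor,
#' `expression`) -- synthetic or loaded from files via
#' [load_experiment()] -- and runs: responsive-gene calling per condition
#' and time point; context-set partition; peak matching and gene-proximal
#' assignment; binding-mode profiles; bound-fraction and mode enrichment
#' over the TGF-beta-independent background; per-factor differential
#' window-signal tests (methylation over TSS-proximal windows, all other
#' factors over gene-proximal windows); epigenome gene sets; and the
#' context classification.
#'
#' @param data the dataset.
#' @param params an [analysis_params()] list.
#' @return An `analysis_results` list (calls, context_sets, matches,
#'   assignments, profiles, bound_fraction, mode_enrichment,
#'   differential, epigenome_sets, classification, overlap_report,
#'   composite, params).
#' @export
analyze_experiment <- function(data, params = analysis_params()) {
  gp <- derive_gene_proximal(data$genes, data$layout)
  tp <- derive_tss_proximal(data$genes, data$layout)

  calls_a <- call_responsive_all_cond(data$expression, "a", params)
  calls_b <- call_responsive_all_cond(data$expression, "b", params)
  context_sets <- partition_context_sets(calls_a, calls_b)

  matches <- match_peaks(data$peaks$a, data$peaks$b,
                         criterion = params$match_criterion)
  assignments <- assign_proximal_peaks(gp, matches,
                                       rule = params$assign_rule)
  profiles <- gene_binding_profiles(data$genes$gene_id, assignments)

  background <- context_sets$background
  bound_fraction <- list()
  enrich <- list()
  for (t in names(context_sets$by_time)) {
    st <- context_sets$by_time[[t]]
    for (cond in c("a", "b")) {
      resp <- union(st[[paste0(cond, "_unique")]], st$shared)
      if (length(resp) > 0) {
        row <- bound_fraction_enrichment(resp, background, profiles)
        row <- cbind(data.frame(condition = cond, time = as.numeric(t)),
                     row)
        bound_fraction[[length(bound_fraction) + 1]] <- row
      }
    }
    if (as.numeric(t) %in% params$enrich_times) {
      for (set_name in c("a_unique", "b_unique", "shared")) {
        ids <- st[[set_name]]
        if (length(ids) > 0) {
          enrich[[length(enrich) + 1]] <-
            mode_enrichment(ids, background, profiles,
                            set_label = sprintf("%s_t%s", set_name, t))
        }
      }
    }
  }
  bound_fraction <- do.call(rbind, bound_fraction)
  enrich <- do.call(rbind, enrich)

  differential <- list()
  for (f in names(data$counts)) {
    windows <- if (f == "METH") tp else gp
    ct <- quantify_window_counts(windows, data$counts[[f]]$ct)
    differential[[f]] <- differential_test(
      ct, data$counts[[f]]$side, a = "a", alpha = params$alpha,
      min_lfc = params$min_lfc, method = params$count_method,
      factor_label = f)
  }
  epigenome_sets <- build_epigenome_sets(differential)

  st <- context_sets$by_time[[as.character(params$classify_time)]]
  if (is.null(st)) {
    stop("classify_time ", params$classify_time,
         " is not among the tested time points", call. = FALSE)
  }
  classification <- classify_context_genes(
    list(a = st$a_unique, b = st$b_unique), epigenome_sets)
  overlap_report <- list(
    a = set_overlap_report(st$a_unique, epigenome_sets$a),
    b = set_overlap_report(st$b_unique, epigenome_sets$b))
  composite <- list(
    a = composite_profile_table(profiles, st$a_unique),
    b = composite_profile_table(profiles, st$b_unique))

  structure(list(calls = rbind(calls_a, calls_b),
                 context_sets = context_sets, matches = matches,
                 assignments = assignments, profiles = profiles,
                 bound_fraction = bound_fraction,
                 mode_enrichment = enrich, differential = differential,
                 epigenome_sets = epigenome_sets,
                 classification = classification,
                 overlap_report = overlap_report, composite = composite,
                 params = params),
            class = "analysis_results")
}

call_responsive_all_cond <- function(expr, condition, params) {
  s <- expr$samples
  times <- sort(unique(s$time[s$condition == condition]))
  do.call(rbind, lapply(times, function(t) {
    call_responsive(expr, condition, t, fdr = params$fdr_expr,
                    method = params$de_method)
  }))
}

#' Load an experiment directory written by [write_experiment()]
#'
#' @param dir directory with `genes.bed`, `chrom.sizes`, the two
#'   narrowPeak files, per-factor `counts_*` / `libsizes_*` TSVs and
#'   `expression.tsv`.
#' @return A dataset list usable by [analyze_experiment()].
#' @export
load_experiment <- function(dir) {
  genes <- read_genes(file.path(dir, "genes.bed"), "bed6")
  layout <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  peaks <- list(
    a = read_peaks(file.path(dir, "smad3_condA.narrowPeak"), "narrowPeak",
                   factor = "SMAD3", condition = "a"),
    b = read_peaks(file.path(dir, "smad3_condB.narrowPeak"), "narrowPeak",
                   factor = "SMAD3", condition = "b"))
  count_files <- list.files(dir, pattern = "^counts_.*\\.tsv$")
  counts <- list()
  for (cf in count_files) {
    f <- sub("^counts_(.*)\\.tsv$", "\\1", cf)
    ct <- read_counts(file.path(dir, cf),
                      file.path(dir, sprintf("libsizes_%s.tsv", f)))
    counts[[f]] <- list(ct = ct,
                        side = vapply(strsplit(colnames(ct$counts),
                                               ".", fixed = TRUE),
                                      `[`, "", 1))
  }
  expression <- read_expression(file.path(dir, "expression.tsv"))
  list(layout = layout, genes = genes, peaks = peaks, counts = counts,
       expression = expression)
}

#' Run the pipeline end-to-end and write all result tables
#'
#' When `config` is a [simulation_config()] the inputs are simulated
#' first (and `truth.tsv` plus a truth-recovery report are written);
#' when `config` is a directory path the inputs are loaded from it.
#' Writes nine result tables (response calls, context sets, peak matches,
#' binding profiles, bound-fraction enrichment, mode enrichment,
#' differential calls, epigenome set membership, classification) plus
#' `manifest.yaml` recording the config hash, input checksums, seed,
#' package version and timestamp. Identical inputs reproduce identical
#' tables; only the manifest timestamp varies.
#'
#' @param config a `simulation_config` or an input directory path.
#' @param out_dir output directory.
#' @param params an [analysis_params()] list.
#' @return The `analysis_results`, invisibly (with `$report` attached
#'   when ground truth was available).
#' @export
run_pipeline <- function(config, out_dir, params = analysis_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (inherits(config, "simulation_config")) {
    message("[simulate] generating synthetic experiment (seed ",
            config$seed, ")")
    input_dir <- file.path(out_dir, "input")
    data <- simulate_experiment(config, out_dir = input_dir)
    truth <- data$truth
    seed <- config$seed
  } else if (is.character(config) && dir.exists(config)) {
    message("[load] reading experiment from ", config)
    input_dir <- config
    data <- load_experiment(config)
    seed <- NA
  } else {
    stop("config must be a simulation_config or an input directory",
         call. = FALSE)
  }
  message("[analyze] running analysis stages")
  res <- analyze_experiment(data, params)

  tbl <- function(x, name) write_gene_table(x, file.path(out_dir, name))
  tbl(res$calls, "response_calls.tsv")
  tbl(context_class_table(res$context_sets), "context_sets.tsv")
  tbl(res$matches, "peak_matches.tsv")
  tbl(res$profiles, "binding_profiles.tsv")
  tbl(res$bound_fraction, "bound_fraction.tsv")
  tbl(res$mode_enrichment, "mode_enrichment.tsv")
  tbl(do.call(rbind, res$differential), "differential_calls.tsv")
  es <- res$epigenome_sets
  memb <- do.call(rbind, lapply(c("a", "b"), function(cond) {
    do.call(rbind, lapply(names(es[[cond]]), function(s) {
      ids <- es[[cond]][[s]]
      if (length(ids) == 0) return(NULL)
      data.frame(condition = cond, set = s, gene_id = ids,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(memb)) {
    memb <- data.frame(condition = character(0), set = character(0),
                       gene_id = character(0))
  }
  tbl(memb, "epigenome_sets.tsv")
  tbl(res$classification, "classification.tsv")
  if (!is.null(truth)) {
    res$report <- truth_vs_result_report(truth, res)
  }

  inputs <- list.files(input_dir, full.names = TRUE)
  cfg_file <- tempfile(fileext = ".yaml")
  if (inherits(config, "simulation_config")) {
    yaml::write_yaml(unclass(config), cfg_file)
  } else {
    yaml::write_yaml(list(input_dir = config), cfg_file)
  }
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    input_checksums = as.list(tools::md5sum(inputs)),
    seed = seed,
    package_version = as.character(utils::packageVersion("smadcontext")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  unlink(cfg_file)
  message("[done] results in ", out_dir)
  invisible(res)
}
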