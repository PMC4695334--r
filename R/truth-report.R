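# Confusion matrices and recovery metrics of pipeline output against the
# generator's planted ground truth.

confusion <- function(truth, pred, levels) {
  table(truth = factor(truth, levels = levels),
        predicted = factor(pred, levels = unique(c(levels,
                                                   unique(pred)))))
}

set_metrics <- function(truth_ids, pred_ids) {
  tp <- length(intersect(truth_ids, pred_ids))
  c(sensitivity = if (length(truth_ids) > 0) tp / length(truth_ids)
    else NA_real_,
    precision = if (length(pred_ids) > 0) tp / length(pred_ids)
    else NA_real_,
    n_truth = length(truth_ids), n_pred = length(pred_ids))
}

truth_state_set <- function(truth, factors, cond) {
  other <- if (cond == "a") "b" else "a"
  hit <- rep(FALSE, nrow(truth))
  for (f in factors) {
    hit <- hit | (truth[[paste0(tolower(f), "_", cond)]] == "high" &
                    truth[[paste0(tolower(f), "_", other)]] == "low")
  }
  truth$gene_id[hit]
}

#' Compare pipeline results with the planted ground truth
#'
#' Builds confusion matrices and accuracies for every label family the
#' generator plants: responsive class per time point, binding mode,
#' occupancy category, the three epigenome gene sets per condition
#' (sensitivity/precision), and the context label. Context-label accuracy
#' is end-to-end: a truth context gene the pipeline failed to call
#' context-specific counts as an error (`missed`); the accuracy restricted
#' to genes the pipeline did classify is also reported.
#'
#' @param truth the generator's truth table.
#' @param results output of [analyze_experiment()].
#' @return A `truth_report` list of per-family confusion matrices and
#'   accuracy/sensitivity/precision figures.
#' @export
truth_vs_result_report <- function(truth, results) {
  if (!setequal(truth$gene_id, results$profiles$gene_id)) {
    stop("truth and results cover different genes", call. = FALSE)
  }
  ## responsive class per (gene, time point)
  cls_pred <- context_class_table(results$context_sets)
  cls_levels <- c("a_unique", "b_unique", "shared", "independent")
  cls_truth <- unlist(lapply(sort(unique(cls_pred$time)), function(t) {
    truth[[sprintf("class_t%d", t)]][match(
      cls_pred$gene_id[cls_pred$time == t], truth$gene_id)]
  }))
  resp_conf <- confusion(cls_truth, cls_pred$class, cls_levels)
  ## binding mode & occupancy category
  prof <- results$profiles[match(truth$gene_id,
                                 results$profiles$gene_id), ]
  mode_conf <- confusion(truth$mode, prof$mode, as.character(1:4))
  cat_conf <- confusion(truth$category, prof$category, CATEGORY_LEVELS)
  ## epigenome sets
  es <- results$epigenome_sets
  set_rows <- list()
  for (cond in c("a", "b")) {
    truth_sets <- list(
      smad3_high = truth_state_set(truth, "SMAD3", cond),
      open_chromatin_high = truth_state_set(truth,
                                            OPEN_CHROMATIN_FACTORS, cond),
      hypo_methylation = truth_state_set(
        truth, "METH", if (cond == "a") "b" else "a"))
    for (s in names(truth_sets)) {
      m <- set_metrics(truth_sets[[s]], es[[cond]][[s]])
      set_rows[[length(set_rows) + 1]] <-
        data.frame(condition = cond, set = s, t(m),
                   stringsAsFactors = FALSE)
    }
  }
  sets_df <- do.call(rbind, set_rows)
  ## context label (end-to-end)
  t_cls <- truth[[sprintf("class_t%d", results$params$classify_time)]]
  ctx_truth <- truth[t_cls %in% c("a_unique", "b_unique"), , drop = FALSE]
  label_map <- c(assisted = "epigenome_assisted",
                 directed = "epigenome_directed",
                 smad3_only = "smad3_only", unexplained = "unexplained")
  truth_lab <- unname(label_map[ctx_truth$context_label])
  pred_lab <- results$classification$label[
    match(ctx_truth$gene_id, results$classification$gene_id)]
  pred_lab[is.na(pred_lab)] <- "missed"
  ctx_conf <- confusion(truth_lab, pred_lab,
                        c(CONTEXT_LABELS, "missed"))
  classified <- pred_lab != "missed"
  structure(list(
    responsive_class = list(confusion = resp_conf,
                            accuracy = mean(cls_truth == cls_pred$class)),
    mode = list(confusion = mode_conf,
                accuracy = mean(truth$mode == prof$mode)),
    category = list(confusion = cat_conf,
                    accuracy = mean(truth$category == prof$category)),
    epigenome_sets = sets_df,
    context_label = list(
      confusion = ctx_conf,
      accuracy = mean(truth_lab == pred_lab),
      accuracy_classified = if (any(classified)) {
        mean(truth_lab[classified] == pred_lab[classified])
      } else NA_real_,
      n_context = nrow(ctx_truth))),
    class = "truth_report")
}
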