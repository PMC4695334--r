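# Two-condition peak comparison: shared / condition-unique classification
# and summit-centred occupancy matrices.

validate_peak_table <- function(peaks, label) {
  need <- c("peak_id", "chrom", "start", "end", "summit")
  if (!all(need %in% names(peaks))) {
    stop(label, ": peak table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(peaks$peak_id)) {
    stop(label, ": duplicate peak id '",
         peaks$peak_id[duplicated(peaks$peak_id)][1], "'", call. = FALSE)
  }
  if (any(peaks$end <= peaks$start)) {
    stop(label, ": end must be > start", call. = FALSE)
  }
  invisible(peaks)
}

overlap_pairs <- function(a, b) {
  # candidate index pairs (i in a, j in b) with >= 1 bp interval overlap,
  # chromosome-aware; 0-based half-open -> IRanges closed [start+1, end]
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  hits <- lapply(unique(a$chrom), function(ch) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (length(ia) == 0 || length(ib) == 0) {
      return(data.frame(i = integer(0), j = integer(0)))
    }
    ra <- IRanges::IRanges(start = a$start[ia] + 1, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1, end = b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    data.frame(i = ia[S4Vectors::queryHits(ov)],
               j = ib[S4Vectors::subjectHits(ov)])
  })
  do.call(rbind, hits)
}

#' Match peaks between two conditions
#'
#' A pair of peaks is a candidate shared pair when, under the default
#' `"summit"` criterion, the summit of either peak lies inside the other
#' peak's interval (symmetric closure; robust to width differences between
#' narrow and broad peak callers); under `"overlap"`, any >= 1 bp interval
#' overlap qualifies. Candidates are resolved to a one-to-one matching
#' greedily by smallest summit distance (ties broken by peak order).
#' Unmatched peaks are unique to their condition.
#'
#' @param peaks_a,peaks_b peak tables (see [read_peaks()]) for the two
#'   conditions. Missing summits must already be midpoint-resolved, as
#'   `read_peaks()` does.
#' @param criterion `"summit"` (default) or `"overlap"`.
#' @return Data.frame with one row per match: `match_id`, `peak_a`,
#'   `peak_b` (NA when absent), `status` in shared/unique_a/unique_b,
#'   `chrom`, `start`, `end` (the union interval of the matched peaks) and
#'   `summit` (mean of the matched summits, floored).
#' @export
match_peaks <- function(peaks_a, peaks_b,
                        criterion = c("summit", "overlap")) {
  criterion <- match.arg(criterion)
  validate_peak_table(peaks_a, "peaks_a")
  validate_peak_table(peaks_b, "peaks_b")
  cand <- overlap_pairs(peaks_a, peaks_b)
  if (criterion == "summit" && nrow(cand) > 0) {
    sa <- peaks_a$summit[cand$i]
    sb <- peaks_b$summit[cand$j]
    ok <- (sa >= peaks_b$start[cand$j] & sa < peaks_b$end[cand$j]) |
      (sb >= peaks_a$start[cand$i] & sb < peaks_a$end[cand$i])
    cand <- cand[ok, , drop = FALSE]
  }
  matched_a <- matched_b <- integer(0)
  pair_a <- pair_b <- integer(0)
  if (nrow(cand) > 0) {
    d <- abs(peaks_a$summit[cand$i] - peaks_b$summit[cand$j])
    ord <- order(d, cand$i, cand$j)
    used_a <- logical(nrow(peaks_a))
    used_b <- logical(nrow(peaks_b))
    for (k in ord) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE
        used_b[j] <- TRUE
        pair_a <- c(pair_a, i)
        pair_b <- c(pair_b, j)
      }
    }
  }
  shared <- data.frame(
    peak_a = peaks_a$peak_id[pair_a],
    peak_b = peaks_b$peak_id[pair_b],
    status = rep("shared", length(pair_a)),
    chrom = peaks_a$chrom[pair_a],
    start = pmin(peaks_a$start[pair_a], peaks_b$start[pair_b]),
    end = pmax(peaks_a$end[pair_a], peaks_b$end[pair_b]),
    summit = floor((peaks_a$summit[pair_a] + peaks_b$summit[pair_b]) / 2),
    stringsAsFactors = FALSE)
  rest_a <- setdiff(seq_len(nrow(peaks_a)), pair_a)
  rest_b <- setdiff(seq_len(nrow(peaks_b)), pair_b)
  uniq_a <- data.frame(
    peak_a = peaks_a$peak_id[rest_a],
    peak_b = rep(NA_character_, length(rest_a)),
    status = rep("unique_a", length(rest_a)),
    chrom = peaks_a$chrom[rest_a], start = peaks_a$start[rest_a],
    end = peaks_a$end[rest_a], summit = peaks_a$summit[rest_a],
    stringsAsFactors = FALSE)
  uniq_b <- data.frame(
    peak_a = rep(NA_character_, length(rest_b)),
    peak_b = peaks_b$peak_id[rest_b],
    status = rep("unique_b", length(rest_b)),
    chrom = peaks_b$chrom[rest_b], start = peaks_b$start[rest_b],
    end = peaks_b$end[rest_b], summit = peaks_b$summit[rest_b],
    stringsAsFactors = FALSE)
  out <- rbind(shared, uniq_a, uniq_b)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$match_id <- sprintf("m%04d", seq_len(nrow(out)))
  out[, c("match_id", "peak_a", "peak_b", "status", "chrom", "start",
          "end", "summit")]
}

#' Summit-centred binary occupancy matrix
#'
#' For each reference peak summit, a window of `window` bp centred on the
#' summit is scanned base-by-base; entry (i, j) is 1 when any query peak
#' covers reference summit i + (j - window/2 - 1) (columns run over offsets
#' -window/2 .. window/2 - 1). Rows are ordered shared-first (when the
#' reference table carries a `status` column) and then by position.
#'
#' @param ref_peaks reference peak table; optional `status` column is used
#'   for row ordering.
#' @param query_peaks query peak table.
#' @param window even positive window width in bp (default 5000, the 5-kb
#'   window around peak summits).
#' @return Binary integer matrix, rows named by reference `peak_id`.
#' @export
occupancy_matrix <- function(ref_peaks, query_peaks, window = 5000) {
  stopifnot(window > 0, window %% 2 == 0)
  validate_peak_table(ref_peaks, "ref_peaks")
  validate_peak_table(query_peaks, "query_peaks")
  ord <- if ("status" %in% names(ref_peaks)) {
    order(ref_peaks$status != "shared", ref_peaks$chrom, ref_peaks$start)
  } else {
    order(ref_peaks$chrom, ref_peaks$start)
  }
  ref_peaks <- ref_peaks[ord, , drop = FALSE]
  half <- window / 2
  mat <- matrix(0L, nrow = nrow(ref_peaks), ncol = window,
                dimnames = list(ref_peaks$peak_id,
                                as.character(seq(-half, half - 1))))
  for (i in seq_len(nrow(ref_peaks))) {
    qs <- query_peaks[query_peaks$chrom == ref_peaks$chrom[i], ,
                      drop = FALSE]
    if (nrow(qs) == 0) next
    s <- ref_peaks$summit[i]
    lo <- pmax(qs$start - s + half, 0)
    hi <- pmin(qs$end - s + half, window)
    for (k in which(lo < hi)) {
      mat[i, (lo[k] + 1):hi[k]] <- 1L
    }
  }
  mat
}
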