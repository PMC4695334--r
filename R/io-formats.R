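# Strict readers/writers for the external formats the pipeline touches.
# Readers reject malformed input with line numbers rather than coercing;
# writers are byte-stable (fixed column order, tab separator, no quoting,
# floats at 6 significant digits).

num_fmt <- function(x) {
  # 6 significant digits, no scientific notation surprises for integers
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15,
                format(x, scientific = FALSE, trim = TRUE),
                formatC(x, digits = 6, format = "g")))
}

parse_error <- function(path, lineno, msg) {
  stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
}

as_num_strict <- function(x, path, lineno, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    parse_error(path, lineno[is.na(out)][1],
                paste("non-numeric", what, ":", x[is.na(out)][1]))
  }
  out
}

#' Read a peak file (ENCODE narrowPeak, broadPeak, or BED6)
#'
#' Coordinates are kept 0-based half-open exactly as in the file. For
#' narrowPeak, column 10 is the summit offset from `start`; `-1` means the
#' summit was not called and is stored as `NA`. Peaks without a summit use
#' the interval midpoint `floor((start + end) / 2)` downstream; the `summit`
#' column always carries the resolved absolute summit position.
#'
#' @param path file path.
#' @param dialect one of `"narrowPeak"`, `"broadPeak"`, `"bed6"`.
#' @param factor,condition optional tags stored on every record.
#' @return Data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `summit_offset` (NA when absent), `summit`
#'   (absolute, midpoint fallback), `factor`, `condition`.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "broadPeak", "bed6"),
                       factor = NA_character_, condition = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  min_cols <- switch(dialect, narrowPeak = 10L, broadPeak = 9L, bed6 = 4L)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    parse_error(path, lineno[nf < min_cols][1],
                sprintf("expected >= %d tab-separated fields for %s, got %d",
                        min_cols, dialect, min(nf[nf < min_cols])))
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  chrom <- col(1)
  start <- as_num_strict(col(2), path, lineno, "start")
  end <- as_num_strict(col(3), path, lineno, "end")
  if (any(end <= start)) {
    parse_error(path, lineno[end <= start][1], "end must be > start")
  }
  name <- col(4)
  score_raw <- col(5, "0")
  score_raw[score_raw == "."] <- "0"
  score <- as_num_strict(score_raw, path, lineno, "score")
  strand <- col(6, ".")
  summit_offset <- rep(NA_real_, length(chrom))
  if (dialect == "narrowPeak") {
    so <- as_num_strict(col(10), path, lineno, "summit offset")
    bad <- so != -1 & (so < 0 | so >= end - start)
    if (any(bad)) {
      parse_error(path, lineno[bad][1],
                  "summit offset outside [0, peak width)")
    }
    summit_offset <- ifelse(so == -1, NA_real_, so)
  }
  summit <- ifelse(is.na(summit_offset),
                   floor((start + end) / 2), start + summit_offset)
  n <- length(chrom)
  if (anyDuplicated(name) && !all(name == name[1])) {
    # names repeat in the wild; synthesize unique ids but keep the name
    peak_id <- sprintf("%s_%d", name, seq_len(n))
  } else {
    peak_id <- if (n > 0 && !anyDuplicated(name)) name else
      sprintf("peak_%d", seq_len(n))
  }
  data.frame(peak_id = peak_id, chrom = chrom, start = start, end = end,
             name = name, score = score, strand = strand,
             summit_offset = summit_offset, summit = summit,
             factor = factor, condition = condition,
             stringsAsFactors = FALSE)
}

#' Write peaks as narrowPeak
#'
#' @param peaks a peak table from [read_peaks()] or the simulator.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  so <- ifelse(is.na(peaks$summit_offset), -1, peaks$summit_offset)
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t-1\t-1\t%s",
                   peaks$chrom, num_fmt(peaks$start), num_fmt(peaks$end),
                   peaks$name, num_fmt(peaks$score), peaks$strand,
                   num_fmt(peaks$score), num_fmt(so))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a generic gene-keyed result table (TSV)
#'
#' Tab-separated, header row mandatory, no quoting; numeric columns are
#' serialized at 6 significant digits so `read_gene_table(write_gene_table(x))`
#' round-trips exactly for values representable at that precision.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `write_gene_table` the path, invisibly; `read_gene_table` a
#'   data.frame with numeric columns restored.
#' @export
write_gene_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  cols <- lapply(x, function(col) {
    if (is.numeric(col)) num_fmt(col) else as.character(col)
  })
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(paste(names(x), collapse = "\t"), out), path)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns name, length (no header).
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop(path, ": expected two columns", call. = FALSE)
  genome_layout(tab[[1]], tab[[2]])
}

#' Read gene annotation from BED6 or GTF
#'
#' BED6: one record per gene. GTF: only `gene` features are used; the
#' `gene_id` attribute is required. GTF coordinates (1-based closed) are
#' converted to the package's 0-based half-open convention.
#'
#' @param path file path.
#' @param format `"bed6"` or `"gtf"`.
#' @return A [gene_model()] table.
#' @export
read_genes <- function(path, format = c("bed6", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "bed6") {
    nf <- lengths(fields)
    if (any(nf < 6)) {
      parse_error(path, lineno[nf < 6][1], "expected 6 BED fields")
    }
    gene_model(vapply(fields, `[`, "", 4),
               vapply(fields, `[`, "", 1),
               as_num_strict(vapply(fields, `[`, "", 2), path, lineno, "start"),
               as_num_strict(vapply(fields, `[`, "", 3), path, lineno, "end"),
               vapply(fields, `[`, "", 6))
  } else {
    nf <- lengths(fields)
    if (any(nf < 9)) {
      parse_error(path, lineno[nf < 9][1], "expected 9 GTF fields")
    }
    type <- vapply(fields, `[`, "", 3)
    sel <- type == "gene"
    if (!any(sel)) stop(path, ": no 'gene' features", call. = FALSE)
    fields <- fields[sel]
    lineno <- lineno[sel]
    attrs <- vapply(fields, `[`, "", 9)
    m <- regmatches(attrs, regexpr('gene_id "[^"]+"', attrs))
    if (length(m) != length(attrs)) {
      stop(path, ": gene feature without gene_id attribute", call. = FALSE)
    }
    ids <- sub('gene_id "([^"]+)"', "\\1", m)
    start1 <- as_num_strict(vapply(fields, `[`, "", 4), path, lineno, "start")
    end1 <- as_num_strict(vapply(fields, `[`, "", 5), path, lineno, "end")
    gene_model(ids, vapply(fields, `[`, "", 1), start1 - 1, end1,
               vapply(fields, `[`, "", 7))
  }
}

ALLOWED_TIME_POINTS <- c(1, 3, 6, 24)

parse_sample_tokens <- function(tokens, path) {
  parts <- strsplit(tokens, ".", fixed = TRUE)
  if (any(lengths(parts) != 4)) {
    stop(path, ": sample header tokens must be condition.treatment.time.rep",
         " (got '", tokens[lengths(parts) != 4][1], "')", call. = FALSE)
  }
  ann <- data.frame(
    sample = tokens,
    condition = vapply(parts, `[`, "", 1),
    treatment = vapply(parts, `[`, "", 2),
    time = suppressWarnings(as.numeric(sub("^t", "", vapply(parts, `[`, "", 3)))),
    replicate = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE)
  if (!all(ann$treatment %in% c("control", "treated"))) {
    stop(path, ": treatment must be 'control' or 'treated'", call. = FALSE)
  }
  if (anyNA(ann$time) || !all(ann$time %in% ALLOWED_TIME_POINTS)) {
    stop(path, ": unknown time point token (allowed: ",
         paste0("t", ALLOWED_TIME_POINTS, collapse = ", "), ")",
         call. = FALSE)
  }
  ann
}

#' Build an expression matrix object
#'
#' @param values numeric matrix of log2 expression, genes x samples; row
#'   names are gene ids, column names are `condition.treatment.tTIME.rep`
#'   tokens (time in hours, one of 1, 3, 6, 24).
#' @return An `expression_matrix` list with `values` and the parsed
#'   `samples` annotation data.frame.
#' @export
expression_matrix <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id in expression matrix", call. = FALSE)
  }
  samples <- parse_sample_tokens(colnames(values), "expression matrix")
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' Read an expression TSV
#'
#' First column `gene_id`; remaining column names encode sample annotations
#' as `condition.treatment.tTIME.rep` tokens. Every
#' (condition, treatment, time) cell must have at least 2 replicates.
#'
#' @param path file path.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  tab <- read_gene_table(path)
  if (names(tab)[1] != "gene_id") {
    stop(path, ": first column must be 'gene_id'", call. = FALSE)
  }
  if (anyDuplicated(tab$gene_id)) {
    stop(path, ": duplicate gene id '",
         tab$gene_id[duplicated(tab$gene_id)][1], "'", call. = FALSE)
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(as.matrix(tab[, -1])), nrow = nrow(tab)))) , arr.ind = TRUE)
    stop(sprintf("%s: non-numeric expression value at gene '%s', sample '%s'",
                 path, tab$gene_id[bad[1, 1]], names(tab)[-1][bad[1, 2]]),
         call. = FALSE)
  }
  rownames(vals) <- tab$gene_id
  em <- expression_matrix(vals)
  counts <- table(em$samples$condition, em$samples$treatment, em$samples$time)
  if (any(counts > 0 & counts < 2)) {
    stop(path, ": fewer than 2 replicates in at least one ",
         "(condition, treatment, time) cell", call. = FALSE)
  }
  em
}

#' @rdname read_expression
#' @param em an `expression_matrix`.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_gene_table(df, path)
}

#' Build a count table with library sizes
#'
#' @param counts non-negative integer matrix, windows (gene ids) x samples.
#' @param lib_sizes positive numeric vector, one per column (genome-wide
#'   library size; not required to be >= the column sum).
#' @return A `count_table` list with `counts` and `lib_sizes`.
#' @export
count_table <- function(counts, lib_sizes) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate window id in count table", call. = FALSE)
  }
  if (anyNA(counts)) stop("missing cells in count table", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(lib_sizes) != ncol(counts)) {
    stop("need one library size per column", call. = FALSE)
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  names(lib_sizes) <- colnames(counts)
  structure(list(counts = counts, lib_sizes = lib_sizes),
            class = "count_table")
}

#' Read / write window count tables
#'
#' The counts TSV has first column `window_id` and one column per sample;
#' library sizes come as a two-column TSV (sample, lib_size).
#'
#' @param path counts TSV path.
#' @param lib_path library-size TSV path.
#' @return A [count_table()].
#' @export
read_counts <- function(path, lib_path) {
  tab <- read_gene_table(path)
  if (names(tab)[1] != "window_id") {
    stop(path, ": first column must be 'window_id'", call. = FALSE)
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$window_id
  libs <- read_gene_table(lib_path)
  ls <- libs[[2]][match(colnames(mat), libs[[1]])]
  if (anyNA(ls)) {
    stop(lib_path, ": missing library size for sample '",
         colnames(mat)[is.na(ls)][1], "'", call. = FALSE)
  }
  count_table(mat, ls)
}

#' @rdname read_counts
#' @param ct a `count_table`.
#' @export
write_counts <- function(ct, path, lib_path) {
  df <- data.frame(window_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_gene_table(df, path)
  write_gene_table(data.frame(sample = names(ct$lib_sizes),
                              lib_size = unname(ct$lib_sizes)), lib_path)
  invisible(path)
}
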