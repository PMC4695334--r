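# Coordinate conventions used throughout the package:
#   * all intervals are 0-based half-open [start, end), BED style;
#   * the TSS of a + strand gene is `start`, of a - strand gene `end - 1`;
#   * the gene-proximal window runs from 1,500 bp upstream of the TSS
#     (on the strand's upstream side) to the end of the gene body;
#   * the TSS-proximal window is the symmetric 3,000 bp window around the
#     TSS base: [TSS - 1500, TSS + 1500) on +, [TSS - 1499, TSS + 1501) on -
#     (the one-base shift keeps the window symmetric about the TSS base on
#     either strand); used for promoter DNA methylation only.

#' Upstream margin of the gene-proximal window (bp)
#' @keywords internal
GENE_PROXIMAL_UPSTREAM <- 1500L

#' Half-width of the TSS-proximal window (bp)
#' @keywords internal
TSS_PROXIMAL_HALFWIDTH <- 1500L

#' Describe a toy or real genome as chromosome names and lengths
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths (bp), all >= 1.
#' @return A `genome_layout` data.frame with columns `chrom`, `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (length(chrom) != base::length(length)) {
    stop("chrom and length differ in length", call. = FALSE)
  }
  if (any(!is.finite(length)) || any(length < 1) ||
      any(length != floor(length))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, length = length,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Build a validated gene model table
#'
#' One row per gene: coordinates (0-based half-open), strand, and the
#' derived TSS (`start` on +, `end - 1` on -). Annotations with multiple
#' isoforms must be collapsed (see [collapse_gene_models()]) before use.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open gene body coordinates, `start < end`.
#' @param strand "+" or "-".
#' @return A `gene_model` data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`.
#' @examples
#' gene_model("g1", "chr1", 5000, 8000, "+")
#' @export
gene_model <- function(gene_id, chrom, start, end, strand) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  strand <- as.character(strand)
  n <- length(gene_id)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(strand) == 1) strand <- rep(strand, n)
  stopifnot(length(chrom) == n, length(start) == n,
            length(end) == n, length(strand) == n)
  if (anyDuplicated(gene_id)) {
    stop("gene ids must be unique within an annotation", call. = FALSE)
  }
  if (any(start >= end)) {
    bad <- gene_id[start >= end][1]
    stop("gene '", bad, "': start must be < end", call. = FALSE)
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  tss <- ifelse(strand == "+", start, end - 1)
  out <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                    end = end, strand = strand, tss = tss,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_model", "data.frame")
  out
}

check_genes_in_layout <- function(genes, layout) {
  idx <- match(genes$chrom, layout$chrom)
  if (anyNA(idx)) {
    stop("unknown chromosome in annotation: ",
         paste(unique(genes$chrom[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(genes$end > layout$length[idx])) {
    bad <- genes$gene_id[genes$end > layout$length[idx]][1]
    stop("gene '", bad, "' extends beyond its chromosome", call. = FALSE)
  }
  idx
}

#' Derive gene-proximal windows
#'
#' The gene-proximal window spans from 1,500 bp upstream of the TSS to the
#' end of the gene body: `[start - 1500, end)` for + strand genes,
#' `[start, end + 1500)` for - strand genes, clipped to chromosome bounds.
#' This is the window in which transcription-factor peaks are considered
#' gene-proximal.
#'
#' @param genes a [gene_model()] table.
#' @param layout a [genome_layout()].
#' @return Data.frame with `gene_id`, `kind`, `chrom`, `start`, `end`.
#' @examples
#' g <- gene_model("g1", "chr1", 5000, 8000, "+")
#' derive_gene_proximal(g, genome_layout("chr1", 1e5))
#' @export
derive_gene_proximal <- function(genes, layout) {
  idx <- check_genes_in_layout(genes, layout)
  plus <- genes$strand == "+"
  w_start <- ifelse(plus, genes$start - GENE_PROXIMAL_UPSTREAM, genes$start)
  w_end <- ifelse(plus, genes$end, genes$end + GENE_PROXIMAL_UPSTREAM)
  clip_windows(genes$gene_id, "gene_proximal", genes$chrom,
               w_start, w_end, layout$length[idx])
}

#' Derive TSS-proximal windows
#'
#' The symmetric 3,000 bp window around the TSS base:
#' `[TSS - 1500, TSS + 1500)` for + strand genes and
#' `[TSS - 1499, TSS + 1501)` for - strand genes (so the window is centred
#' on the TSS base under the 0-based half-open convention), clipped to
#' chromosome bounds. Used for promoter DNA methylation quantification.
#'
#' @inheritParams derive_gene_proximal
#' @return Data.frame with `gene_id`, `kind`, `chrom`, `start`, `end`.
#' @export
derive_tss_proximal <- function(genes, layout) {
  idx <- check_genes_in_layout(genes, layout)
  plus <- genes$strand == "+"
  w_start <- ifelse(plus, genes$tss - TSS_PROXIMAL_HALFWIDTH,
                    genes$tss - TSS_PROXIMAL_HALFWIDTH + 1)
  w_end <- ifelse(plus, genes$tss + TSS_PROXIMAL_HALFWIDTH,
                  genes$tss + TSS_PROXIMAL_HALFWIDTH + 1)
  clip_windows(genes$gene_id, "tss_proximal", genes$chrom,
               w_start, w_end, layout$length[idx])
}

clip_windows <- function(gene_id, kind, chrom, w_start, w_end, chrom_len) {
  w_start <- pmax(w_start, 0)
  w_end <- pmin(w_end, chrom_len)
  if (any(w_start >= w_end)) {
    stop("window empty after clipping for gene '",
         gene_id[w_start >= w_end][1], "'", call. = FALSE)
  }
  data.frame(gene_id = gene_id, kind = kind, chrom = chrom,
             start = w_start, end = w_end, stringsAsFactors = FALSE)
}

#' Collapse multi-isoform annotations to one model per gene
#'
#' Isoforms of one gene are merged to their union span; the strand must be
#' consistent. The resulting TSS is the most-upstream TSS by construction
#' (union start on +, union end - 1 on -).
#'
#' @param gene_id,chrom,start,end,strand per-transcript vectors; `gene_id`
#'   may repeat across isoforms.
#' @return A [gene_model()] table with one row per gene.
#' @export
collapse_gene_models <- function(gene_id, chrom, start, end, strand) {
  key <- as.character(gene_id)
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  ids <- unique(key)
  u_chrom <- u_start <- u_end <- u_strand <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sel <- key == ids[i]
    if (length(unique(chrom[sel])) > 1 || length(unique(strand[sel])) > 1) {
      stop("gene '", ids[i], "': isoforms disagree on chromosome or strand",
           call. = FALSE)
    }
    u_chrom[[i]] <- chrom[sel][1]
    u_strand[[i]] <- strand[sel][1]
    u_start[[i]] <- min(start[sel])
    u_end[[i]] <- max(end[sel])
  }
  gene_model(ids, unlist(u_chrom), unlist(u_start), unlist(u_end),
             unlist(u_strand))
}
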