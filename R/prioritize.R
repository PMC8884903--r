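#' Rank genes by sgRNA appearance frequency across compartments
#'
#' The primary ranking key is the number of qualifying samples (recurrent
#' tumors, blood, and organ metastases by default) in which the gene is
#' present; ties break by the summed reads of its threshold-passing sgRNAs in
#' those samples, then alphabetically, so the ordering is a reproducible total
#' order.
#'
#' @param presence A `presence_matrix`.
#' @param counts The sgRNA x sample count matrix the presence calls came from.
#' @param lib The `crispr_library`.
#' @param sheet A `sample_sheet`.
#' @param compartments Compartments whose samples qualify. Default
#'   `c("recurrent", "blood", "metastasis")`.
#' @return A `rank_table` data frame: `gene`, `frequency`, `total_reads`,
#'   `rank`.
#' @export
rank_by_frequency <- function(presence, counts, lib, sheet,
                              compartments = c("recurrent", "blood", "metastasis")) {
  stopifnot(inherits(sheet, "sample_sheet"), inherits(lib, "crispr_library"))
  compartments <- unique(compartments)
  if (length(compartments) == 0L) stop("empty compartment selection")
  bad <- setdiff(compartments, COMPARTMENTS)
  if (length(bad) > 0L) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  qual <- sheet$sample_id[sheet$compartment %in% compartments]
  cols <- intersect(colnames(presence), qual)

  freq <- as.integer(rowSums(presence[, cols, drop = FALSE]))
  names(freq) <- rownames(presence)

  # summed reads of threshold-passing sgRNAs in qualifying samples
  tau <- attr(presence, "tau")
  gene <- structure(lib$gene, names = lib$sgrna_id)[rownames(counts)]
  cc <- counts[, intersect(colnames(counts), cols), drop = FALSE]
  passing <- cc * (cc >= tau)
  per_gene <- rowsum(passing, group = gene, reorder = TRUE)
  reads <- structure(rep(0, length(freq)), names = names(freq))
  tot <- rowSums(per_gene)
  reads[names(tot)] <- tot

  ord <- order(-freq, -reads, names(freq), method = "radix")
  out <- data.frame(gene = names(freq)[ord],
                    frequency = freq[ord],
                    total_reads = as.numeric(reads[ord]),
                    rank = seq_along(ord),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Take the top N genes of a rank table
#'
#' @param rank A `rank_table`.
#' @param n Number of rows to keep (default 50). Fewer are returned when the
#'   table is shorter.
#' @return The first `min(n, nrow)` rows, order preserved.
#' @export
top_n_genes <- function(rank, n = 50L) {
  stopifnot(inherits(rank, "rank_table"))
  if (n < 1L) stop("n must be >= 1")
  out <- rank[seq_len(min(n, nrow(rank))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' OncoPrint-style binary presence matrix for selected genes
#'
#' Rows follow the given gene order (typically rank order); columns are
#' samples grouped by compartment, then organ, then sample id, so each
#' compartment/organ block is contiguous — the layout of a presence oncoplot.
#'
#' @param genes Character vector of genes (must all be presence rows).
#' @param presence A `presence_matrix`.
#' @param sheet A `sample_sheet`.
#' @return 0/1 integer matrix, genes x samples, with column ordering as above.
#' @export
oncoprint_matrix <- function(genes, presence, sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  miss <- setdiff(genes, rownames(presence))
  if (length(miss) > 0L) stop("genes not in presence matrix: ", paste(miss, collapse = ", "))
  sh <- sheet[sheet$sample_id %in% colnames(presence), , drop = FALSE]
  ord <- order(match(sh$compartment, COMPARTMENTS), sh$organ, sh$sample_id,
               method = "radix")
  cols <- sh$sample_id[ord]
  out <- presence[genes, cols, drop = FALSE] + 0L
  out
}

#' Annotate top-ranked genes with ubiquity and pan-organ flags
#'
#' Combines the frequency ranking with per-organ ubiquity: each top gene gets
#' its organ count `k`, a pan-organ flag (`k == K_observed`), and optionally a
#' flag for membership in a human candidate catalog. Also reports whether
#' exactly one gene is pan-organ — the signature of a single suppressor whose
#' knockout colonizes every organ.
#'
#' @param rank A `rank_table` (typically already cut to top N).
#' @param report A result of [organ_ubiquity()] or [gene_set_report()].
#' @param catalog Optional `candidate_catalog`; membership is tested after
#'   homolog mapping with `map`.
#' @param map Optional homolog table for the catalog comparison.
#' @return A `hit_report` data frame: `gene`, `frequency`, `total_reads`,
#'   `rank`, `k`, `pan_organ`, and `in_catalog` when a catalog is given; with
#'   attributes `pan_organ_genes` and `unique_pan_organ`.
#' @export
call_hits <- function(rank, report, catalog = NULL, map = NULL) {
  stopifnot(inherits(rank, "rank_table"))
  k <- report$ubiquity[rank$gene]
  k[is.na(k)] <- 0L
  out <- rank
  out$k <- as.integer(k)
  out$pan_organ <- rank$gene %in% report$pan_organ
  if (!is.null(catalog)) {
    hm <- map_homologs(rank$gene, map)
    human <- structure(hm$pairs$human, names = hm$pairs$mouse)[rank$gene]
    cand <- if (inherits(catalog, "candidate_catalog")) catalog$candidates
            else as.character(catalog)
    out$in_catalog <- !is.na(human) & human %in% cand
  }
  attr(out, "pan_organ_genes") <- report$pan_organ
  attr(out, "unique_pan_organ") <- length(report$pan_organ) == 1L
  class(out) <- c("hit_report", "data.frame")
  out
}
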