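#' Construct and validate a patient cohort
#'
#' Bundles a log-scale expression matrix over tumor and normal subjects with a
#' survival table for the tumor subjects. This is the input to the human
#' candidate-suppressor filter: genes under-expressed in tumors versus normal
#' tissue whose low expression also stratifies patients toward worse survival.
#'
#' @param expression Numeric gene x subject matrix (log scale), with rownames
#'   (genes) and colnames (subjects).
#' @param group Named character vector over all subjects, values `"tumor"` or
#'   `"normal"`; both groups must be non-empty.
#' @param survival Data frame with columns `subject_id`, `time` (> 0), `event`
#'   (0 censored / 1 death); every subject must be a tumor subject.
#' @return A `cohort_data` list.
#' @export
cohort_data <- function(expression, group, survival) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  subjects <- colnames(expression)
  if (!all(subjects %in% names(group))) stop("every subject needs a group label")
  group <- group[subjects]
  if (!all(group %in% c("tumor", "normal"))) {
    stop("group labels must be 'tumor' or 'normal'")
  }
  if (!any(group == "tumor") || !any(group == "normal")) {
    stop("both tumor and normal groups must be non-empty")
  }
  stopifnot(is.data.frame(survival),
            all(c("subject_id", "time", "event") %in% names(survival)))
  tumor_ids <- subjects[group == "tumor"]
  bad <- setdiff(survival$subject_id, tumor_ids)
  if (length(bad) > 0L) {
    stop("survival records for non-tumor subjects: ", paste(bad, collapse = ", "))
  }
  if (any(survival$time <= 0)) stop("survival times must be positive")
  if (!all(survival$event %in% c(0, 1))) stop("event must be 0 or 1")
  structure(list(expression = expression, group = group,
                 survival = survival), class = "cohort_data")
}

#' Build the candidate tumor-suppressor catalog
#'
#' Applies the two-step filter per gene: (i) low expression — tumor mean below
#' normal mean with a two-tailed t test p below `alpha`; (ii) poor survival —
#' tumor subjects split at the median of the gene's expression, and the
#' low-expression arm shows a significant excess of observed deaths by the
#' log-rank test. Candidates are exactly the intersection of the two sets.
#' Raw p-values drive selection (no multiple-testing adjustment, mirroring a
#' raw P < 0.05 double filter); Benjamini-Hochberg q-values are annotated for
#' reference only.
#'
#' @param cohort A `cohort_data`.
#' @param alpha Significance level for both tests. Default 0.05.
#' @param pooled_t Use pooled-variance Student's t (default) or Welch.
#' @return A `candidate_catalog` list: `low_expr`, `poor_surv`, `candidates`
#'   (sorted gene vectors), `sizes`, `table` (per-gene statistics), `skipped`
#'   (degenerate genes), and `alpha`.
#' @export
candidate_catalog <- function(cohort, alpha = 0.05, pooled_t = TRUE) {
  stopifnot(inherits(cohort, "cohort_data"))
  expr <- cohort$expression
  grp <- cohort$group
  tumor_ids <- names(grp)[grp == "tumor"]
  normal_ids <- names(grp)[grp == "normal"]
  if (length(tumor_ids) < 2L || length(normal_ids) < 2L) {
    stop("need at least 2 subjects per group")
  }
  surv <- cohort$survival
  surv <- surv[surv$subject_id %in% tumor_ids, , drop = FALSE]
  if (sum(surv$event) == 0) stop("no events in the survival table")
  surv_expr <- expr[, surv$subject_id, drop = FALSE]

  genes <- rownames(expr)
  n <- length(genes)
  t_p <- surv_p <- rep(NA_real_, n)
  mean_t <- mean_n <- rep(NA_real_, n)
  direction <- rep(NA_character_, n)
  skipped <- logical(n)

  for (i in seq_len(n)) {
    xt <- expr[i, tumor_ids]
    xn <- expr[i, normal_ids]
    if (stats::var(c(xt, xn)) == 0) { skipped[i] <- TRUE; next }
    tt <- two_sample_t(xt, xn, pooled = pooled_t)
    t_p[i] <- tt$p; mean_t[i] <- tt$mean_x; mean_n[i] <- tt$mean_y
    vals <- surv_expr[i, ]
    if (all(vals == vals[1L])) next  # no survival split possible
    arm <- median_split(vals)
    lo <- arm == "low"
    if (sum(lo) == 0L || sum(!lo) == 0L) next
    lr <- log_rank(surv$time[lo], surv$event[lo],
                   surv$time[!lo], surv$event[!lo])
    surv_p[i] <- lr$p
    direction[i] <- c(A = "low", B = "high", none = "none")[lr$direction]
  }

  low_expr <- !skipped & !is.na(t_p) & t_p < alpha & mean_t < mean_n
  poor_surv <- !skipped & !is.na(surv_p) & surv_p < alpha & direction == "low"
  poor_surv[is.na(poor_surv)] <- FALSE
  candidates <- low_expr & poor_surv

  tab <- data.frame(
    gene = genes, mean_tumor = mean_t, mean_normal = mean_n,
    expr_p = t_p, expr_q = stats::p.adjust(t_p, "BH"),
    logrank_p = surv_p, logrank_q = stats::p.adjust(surv_p, "BH"),
    worse_arm = direction,
    low_expr = low_expr, poor_surv = poor_surv, candidate = candidates,
    stringsAsFactors = FALSE)

  structure(list(
    low_expr = sort(genes[low_expr]),
    poor_surv = sort(genes[poor_surv]),
    candidates = sort(genes[candidates]),
    sizes = c(low_expr = sum(low_expr), poor_surv = sum(poor_surv),
              candidates = sum(candidates)),
    table = tab, skipped = genes[skipped], alpha = alpha),
    class = "candidate_catalog")
}

#' Map mouse gene symbols to human homologs
#'
#' Default rule: uppercase the mouse symbol (Atp11b -> ATP11B), the usual
#' mouse/human nomenclature correspondence. A user-supplied two-column table
#' (`mouse`, `human`) overrides the default for the symbols it lists; symbols
#' it maps to `NA` or `""` are reported as unmapped, never silently dropped.
#'
#' @param genes Character vector of mouse symbols.
#' @param map Optional data frame with columns `mouse`, `human`.
#' @return List with `human` (mapped symbols, sorted unique), `unmapped`
#'   (mouse symbols without a mapping), and `pairs` (mouse -> human table).
#' @export
map_homologs <- function(genes, map = NULL) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) {
    return(list(human = character(0), unmapped = character(0),
                pairs = data.frame(mouse = character(0), human = character(0))))
  }
  human <- toupper(genes)
  if (!is.null(map)) {
    stopifnot(is.data.frame(map), all(c("mouse", "human") %in% names(map)))
    if (anyDuplicated(map$mouse)) {
      dups <- unique(map$mouse[duplicated(map$mouse)])
      conflicting <- vapply(dups, function(m) {
        length(unique(map$human[map$mouse == m])) > 1L
      }, logical(1))
      if (any(conflicting)) {
        stop("conflicting homolog map rows for: ",
             paste(dups[conflicting], collapse = ", "))
      }
      map <- map[!duplicated(map$mouse), , drop = FALSE]
    }
    idx <- match(genes, map$mouse)
    override <- !is.na(idx)
    human[override] <- map$human[idx[override]]
  }
  unmapped <- genes[is.na(human) | human == ""]
  ok <- !(is.na(human) | human == "")
  list(human = sort(unique(human[ok])), unmapped = unmapped,
       pairs = data.frame(mouse = genes[ok], human = human[ok],
                          stringsAsFactors = FALSE))
}

#' Intersect screen hits with the human candidate catalog
#'
#' Maps the mouse screen genes to human symbols and intersects with the
#' catalog's candidate set — the step that narrows screen hits to genes that
#' are also under-expressed, survival-relevant human suppressors.
#'
#' @param screen_genes Character vector of mouse symbols from the screen.
#' @param catalog A `candidate_catalog` (or a character vector of human
#'   symbols).
#' @param map Optional homolog table passed to [map_homologs()].
#' @return List with `genes` (sorted human symbols in both), `n`, and
#'   `unmapped` mouse symbols.
#' @export
screen_vs_catalog <- function(screen_genes, catalog, map = NULL) {
  hm <- map_homologs(screen_genes, map)
  cand <- if (inherits(catalog, "candidate_catalog")) catalog$candidates
          else as.character(catalog)
  hits <- sort(intersect(hm$human, cand))
  list(genes = hits, n = length(hits), unmapped = hm$unmapped)
}

#' Read cohort files (expression TSV, group TSV, survival TSV)
#'
#' @param expr_path Genes x subjects TSV, first column `gene`.
#' @param group_path TSV with columns `subject_id`, `group`.
#' @param surv_path TSV with columns `subject_id`, `time`, `event`.
#' @return A `cohort_data`.
#' @export
read_cohort <- function(expr_path, group_path, surv_path) {
  ed <- utils::read.delim(expr_path, check.names = FALSE)
  if (names(ed)[1L] != "gene") stop("expression TSV must start with a gene column")
  expr <- as.matrix(ed[, -1L, drop = FALSE])
  rownames(expr) <- ed$gene
  gd <- utils::read.delim(group_path, stringsAsFactors = FALSE)
  group <- structure(gd$group, names = gd$subject_id)
  surv <- utils::read.delim(surv_path, stringsAsFactors = FALSE)
  cohort_data(expr, group, surv)
}

#' Write cohort files
#'
#' @param cohort A `cohort_data`.
#' @param expr_path,group_path,surv_path Output TSV paths.
#' @return Invisibly, the three paths.
#' @export
write_cohort <- function(cohort, expr_path, group_path, surv_path) {
  ed <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                   check.names = FALSE)
  utils::write.table(ed, expr_path, sep = "\t", row.names = FALSE, quote = FALSE)
  gd <- data.frame(subject_id = names(cohort$group), group = cohort$group)
  utils::write.table(gd, group_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$survival, surv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(expr_path, group_path, surv_path))
}
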