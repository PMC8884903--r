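#' Threshold sgRNA counts into per-sample gene presence calls
#'
#' A gene is called present in a sample when at least `m` of its sgRNAs reach
#' the read-count threshold `tau` in that sample. The screen's enrichment
#' filter is this hard cut (reads >= 10 by default) with no normalization or
#' smoothing; the filter operates at sgRNA level and is reported at gene level.
#'
#' @param counts sgRNA x sample integer matrix (rows must be library sgRNAs).
#' @param lib A `crispr_library` mapping sgRNAs to genes.
#' @param tau Read-count threshold, >= 1. Default 10.
#' @param m Minimum number of passing sgRNAs per gene, >= 1. Default 1.
#' @return A `presence_matrix`: logical gene x sample matrix with attributes
#'   `tau` and `m`.
#' @export
call_presence <- function(counts, lib, tau = 10L, m = 1L) {
  stopifnot(inherits(lib, "crispr_library"), is.matrix(counts))
  if (tau < 1L) stop("tau must be >= 1")
  if (m < 1L) stop("m must be >= 1")
  miss <- setdiff(rownames(counts), lib$sgrna_id)
  if (length(miss) > 0L) {
    stop("count rows absent from library: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  gene <- structure(lib$gene, names = lib$sgrna_id)[rownames(counts)]
  pass <- counts >= tau
  # per-gene count of passing sgRNAs, per sample
  npass <- rowsum(pass + 0L, group = gene, reorder = TRUE)
  pres <- npass >= m
  structure(pres, tau = as.integer(tau), m = as.integer(m),
            class = c("presence_matrix", class(pres)))
}

#' Compartment gene sets and the cross-compartment shared set
#'
#' A gene belongs to a compartment's set if it is present in at least one
#' sample of that compartment (union semantics: a gene "identified from" a
#' compartment). `shared_all` is the intersection of the compartment sets,
#' i.e. genes seen in every sampled compartment type. The preimplant
#' compartment (the library-infected cells before implantation) is by default
#' excluded from `shared_all`, since the screen compares post-implantation
#' compartments against it; set `include_preimplant = TRUE` to include it.
#'
#' @param presence A `presence_matrix` from [call_presence()].
#' @param sheet A `sample_sheet` covering every presence column.
#' @param include_preimplant Include preimplant in the `shared_all`
#'   intersection? Default `FALSE`.
#' @return List with `compartment_sets` (named list of sorted gene vectors),
#'   `all_samples` (union over every sample), and `shared_all`.
#' @export
compartment_sets <- function(presence, sheet, include_preimplant = FALSE) {
  stopifnot(inherits(sheet, "sample_sheet"))
  miss <- setdiff(colnames(presence), sheet$sample_id)
  if (length(miss) > 0L) {
    stop("presence columns absent from sample sheet: ", paste(miss, collapse = ", "))
  }
  comp_of <- structure(sheet$compartment, names = sheet$sample_id)
  comp <- comp_of[colnames(presence)]
  comps_here <- intersect(COMPARTMENTS, unique(comp))
  sets <- lapply(comps_here, function(cc) {
    cols <- which(comp == cc)
    sort(rownames(presence)[rowSums(presence[, cols, drop = FALSE]) > 0L])
  })
  names(sets) <- comps_here
  all_samples <- sort(rownames(presence)[rowSums(presence) > 0L])
  inter_over <- if (include_preimplant) comps_here else setdiff(comps_here, "preimplant")
  shared_all <- if (length(inter_over) == 0L) character(0) else
    Reduce(intersect, sets[inter_over])
  list(compartment_sets = sets, all_samples = all_samples,
       shared_all = sort(shared_all))
}

#' Per-organ gene sets, ubiquity scores, and pan-organ calls
#'
#' For each organ, the organ set is the union of genes present in at least one
#' metastasis sample from that organ (pooled across mice). A gene's ubiquity
#' `k` counts the distinct organs containing it; genes with `k` equal to the
#' number of organs observed in the sheet are pan-organ hits (the pattern of a
#' suppressor whose loss seeds every organ).
#'
#' @param presence A `presence_matrix`.
#' @param sheet A `sample_sheet` with at least one metastasis sample.
#' @return List with `organ_sets` (named list), `ubiquity` (named integer
#'   vector over all presence genes), `pan_organ` (gene vector), and
#'   `K_observed`.
#' @export
organ_ubiquity <- function(presence, sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  miss <- setdiff(colnames(presence), sheet$sample_id)
  if (length(miss) > 0L) {
    stop("presence columns absent from sample sheet: ", paste(miss, collapse = ", "))
  }
  met <- sheet[sheet$compartment == "metastasis" &
                 sheet$sample_id %in% colnames(presence), , drop = FALSE]
  if (nrow(met) == 0L) stop("no metastasis samples in sheet")
  organs <- sort(unique(met$organ))
  organ_sets <- lapply(organs, function(o) {
    cols <- met$sample_id[met$organ == o]
    sort(rownames(presence)[rowSums(presence[, cols, drop = FALSE]) > 0L])
  })
  names(organ_sets) <- organs
  genes <- rownames(presence)
  k <- integer(length(genes))
  names(k) <- genes
  for (o in organs) k[organ_sets[[o]]] <- k[organ_sets[[o]]] + 1L
  K <- length(organs)
  list(organ_sets = organ_sets, ubiquity = k,
       pan_organ = sort(genes[k == K]), K_observed = K)
}

#' Full gene-set report: compartments, shared set, organs, ubiquity
#'
#' Convenience wrapper combining [compartment_sets()] and [organ_ubiquity()],
#' with the thresholds recorded for provenance.
#'
#' @inheritParams compartment_sets
#' @return A `gene_set_report` list.
#' @export
gene_set_report <- function(presence, sheet, include_preimplant = FALSE) {
  cs <- compartment_sets(presence, sheet, include_preimplant)
  ou <- organ_ubiquity(presence, sheet)
  structure(c(cs, ou,
              list(tau = attr(presence, "tau"), m = attr(presence, "m"))),
            class = "gene_set_report")
}

#' Write a gene-set report as JSON
#'
#' @param report A `gene_set_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_gene_set_report <- function(report, path) {
  out <- list(
    tau = report$tau, m = report$m, K_observed = report$K_observed,
    compartment_sets = report$compartment_sets,
    all_samples = report$all_samples,
    shared_all = report$shared_all,
    organ_sets = report$organ_sets,
    ubiquity = as.list(report$ubiquity[report$ubiquity > 0L]),
    pan_organ = report$pan_organ)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
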