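#' Pipeline configuration
#'
#' Collects the file paths and parameters for a full screen analysis run:
#' enrichment filtering, compartment/organ intersection, frequency ranking,
#' hit calling, and (when cohort files are given) the human candidate catalog
#' and its intersection with the screen.
#'
#' @param library_path sgRNA library CSV.
#' @param counts_path sgRNA x sample counts TSV.
#' @param sheet_path Sample sheet TSV.
#' @param out_dir Output directory for all artifacts.
#' @param expr_path,group_path,surv_path Optional cohort TSVs.
#' @param homolog_path Optional mouse-to-human homolog TSV (columns `mouse`,
#'   `human`).
#' @param tau,m Presence thresholds (reads, min passing sgRNAs).
#' @param alpha Significance level for the catalog filters.
#' @param n_top Size of the frequency-ranked top list.
#' @param compartments Compartments that qualify for frequency ranking.
#' @param seed Seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed is provenance for upstream simulation).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(library_path, counts_path, sheet_path, out_dir,
                            expr_path = NULL, group_path = NULL,
                            surv_path = NULL, homolog_path = NULL,
                            tau = 10L, m = 1L, alpha = 0.05, n_top = 50L,
                            compartments = c("recurrent", "blood", "metastasis"),
                            seed = 1L) {
  cfg <- list(library_path = library_path, counts_path = counts_path,
              sheet_path = sheet_path, out_dir = out_dir,
              expr_path = expr_path, group_path = group_path,
              surv_path = surv_path, homolog_path = homolog_path,
              tau = as.integer(tau), m = as.integer(m), alpha = alpha,
              n_top = as.integer(n_top), compartments = compartments,
              seed = as.integer(seed))
  stopifnot(cfg$tau >= 1L, cfg$m >= 1L, cfg$alpha > 0, cfg$alpha < 1,
            cfg$n_top >= 1L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full screen-analysis pipeline
#'
#' Stages in order: read and validate inputs; presence calling; compartment
#' and organ gene sets; frequency ranking and top-N; OncoPrint matrix; hit
#' calling; optionally the cohort candidate catalog and the screen-vs-catalog
#' homolog intersection; the stage-ledger summary; and a manifest with input
#' and output checksums. Identical inputs and parameters give byte-identical
#' artifacts and manifest checksums. Missing input files are reported before
#' any stage runs.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list with the main in-memory results and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  inputs <- c(library = cfg$library_path, counts = cfg$counts_path,
              sheet = cfg$sheet_path, expr = cfg$expr_path,
              group = cfg$group_path, surv = cfg$surv_path,
              homolog = cfg$homolog_path)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  missing <- inputs[!file.exists(unlist(inputs))]
  if (length(missing) > 0L) {
    stop("missing input file(s): ",
         paste(names(missing), unlist(missing), sep = "=", collapse = ", "))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  lib <- run_stage("read_library", function() read_library(cfg$library_path))
  sheet <- run_stage("read_sheet", function() read_sample_sheet(cfg$sheet_path))
  counts <- run_stage("read_counts",
                      function() read_counts(cfg$counts_path, lib, sheet))

  presence <- run_stage("presence",
                        function() call_presence(counts, lib, cfg$tau, cfg$m))
  report <- run_stage("gene_sets", function() gene_set_report(presence, sheet))
  rank <- run_stage("rank", function() {
    rank_by_frequency(presence, counts, lib, sheet, cfg$compartments)
  })
  top <- top_n_genes(rank, cfg$n_top)
  onco <- run_stage("oncoprint",
                    function() oncoprint_matrix(top$gene, presence, sheet))

  hmap <- if (!is.null(cfg$homolog_path)) {
    utils::read.delim(cfg$homolog_path, stringsAsFactors = FALSE)
  } else NULL

  catalog <- NULL; screen_cat <- NULL
  if (!is.null(cfg$expr_path)) {
    catalog <- run_stage("catalog", function() {
      cohort <- read_cohort(cfg$expr_path, cfg$group_path, cfg$surv_path)
      candidate_catalog(cohort, alpha = cfg$alpha)
    })
    screen_cat <- run_stage("screen_vs_catalog", function() {
      screen_vs_catalog(report$all_samples, catalog, hmap)
    })
  }
  hits <- run_stage("hits",
                    function() call_hits(top, report, catalog, hmap))

  out <- function(f) file.path(cfg$out_dir, f)
  utils::write.table(data.frame(gene = rownames(presence), presence + 0L,
                                check.names = FALSE),
                     out("presence.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_gene_set_report(report, out("gene_sets.json"))
  utils::write.table(rank, out("rank.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(gene = rownames(onco), onco,
                                check.names = FALSE),
                     out("oncoprint.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  hits_out <- as.list(hits)
  attributes(hits_out) <- list(names = names(hits_out))
  jsonlite::write_json(
    list(hits = hits_out,
         pan_organ_genes = attr(hits, "pan_organ_genes"),
         unique_pan_organ = attr(hits, "unique_pan_organ")),
    out("hits.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(catalog)) {
    jsonlite::write_json(
      list(alpha = catalog$alpha, sizes = as.list(catalog$sizes),
           low_expr = catalog$low_expr, poor_surv = catalog$poor_surv,
           candidates = catalog$candidates, skipped = catalog$skipped,
           screen_intersection = screen_cat$genes,
           screen_intersection_n = screen_cat$n),
      out("catalog.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  write_report(hits, report, catalog, screen_cat, out("summary.json"))

  outputs <- c("presence.tsv", "gene_sets.json", "rank.tsv", "oncoprint.tsv",
               "hits.json", "summary.json")
  if (!is.null(catalog)) outputs <- c(outputs, "catalog.json")
  manifest <- list(
    parameters = list(tau = cfg$tau, m = cfg$m, alpha = cfg$alpha,
                      n_top = cfg$n_top, compartments = cfg$compartments,
                      seed = cfg$seed),
    version = as.character(utils::packageVersion("crisprmet")),
    input_checksums = {
      cs <- tools::md5sum(unlist(inputs)); names(cs) <- names(inputs)
      as.list(cs)
    },
    output_checksums = {
      cs <- tools::md5sum(vapply(outputs, out, character(1)))
      names(cs) <- outputs
      as.list(cs)
    })
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(presence = presence, report = report, rank = rank,
                 top = top, hits = hits, catalog = catalog,
                 screen_vs_catalog = screen_cat, manifest = manifest))
}

#' Write the stage-ledger summary
#'
#' A single human-readable JSON summary of the set sizes at every stage of
#' the analysis — the chain from genes detected anywhere, through per-
#' compartment and shared sets, organ ubiquity and pan-organ calls, down to
#' the catalog filter sizes and the screen/catalog homolog intersection.
#'
#' @param hits A `hit_report`.
#' @param report A `gene_set_report`.
#' @param catalog Optional `candidate_catalog`.
#' @param screen_cat Optional result of [screen_vs_catalog()].
#' @param path Output JSON path.
#' @return The summary list, invisibly.
#' @export
write_report <- function(hits, report, catalog = NULL, screen_cat = NULL,
                         path) {
  ledger <- list(
    genes_all_samples = length(report$all_samples),
    genes_per_compartment = lapply(report$compartment_sets, length),
    shared_all = length(report$shared_all),
    genes_per_organ = lapply(report$organ_sets, length),
    K_observed = report$K_observed,
    pan_organ = length(report$pan_organ),
    pan_organ_genes = report$pan_organ,
    unique_pan_organ = isTRUE(attr(hits, "unique_pan_organ")),
    top_genes = nrow(hits))
  if (!is.null(catalog)) {
    ledger$catalog <- as.list(catalog$sizes)
  }
  if (!is.null(screen_cat)) {
    ledger$screen_catalog_intersection = screen_cat$n
  }
  jsonlite::write_json(ledger, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(ledger)
}
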