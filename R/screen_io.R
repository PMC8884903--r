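#' Read an sgRNA library design table
#'
#' The library design maps each sgRNA to the gene it targets and records its
#' spacer (protospacer) sequence. Genome-wide knockout libraries of the GeCKO
#' type carry several guides per gene (typically 6), and the per-gene guide
#' count is what downstream presence calling thresholds against.
#'
#' @param path Path to a CSV file with header columns `sgrna_id`, `spacer`,
#'   `gene` (order free, extra columns ignored).
#' @param spacer_length Required spacer length in nucleotides. All spacers must
#'   have this exact length. Default 20, the GeCKOv2 spacer length.
#' @return A `crispr_library` data frame with columns `sgrna_id`, `spacer`,
#'   `gene`.
#' @export
read_library <- function(path, spacer_length = 20L) {
  if (!file.exists(path)) stop("library file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sgrna_id", "spacer", "gene")
  if (!all(need %in% names(df))) {
    stop("library CSV must have columns sgrna_id, spacer, gene; found: ",
         paste(names(df), collapse = ", "))
  }
  new_library(df[need], spacer_length = spacer_length)
}

#' Construct and validate a library design
#'
#' @param df Data frame with character columns `sgrna_id`, `spacer`, `gene`.
#' @param spacer_length Required spacer length (default 20).
#' @return A validated `crispr_library`.
#' @export
new_library <- function(df, spacer_length = 20L) {
  stopifnot(is.data.frame(df), all(c("sgrna_id", "spacer", "gene") %in% names(df)))
  df <- data.frame(sgrna_id = as.character(df$sgrna_id),
                   spacer   = toupper(as.character(df$spacer)),
                   gene     = as.character(df$gene),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("library is empty")
  dup <- df$sgrna_id[duplicated(df$sgrna_id)]
  if (length(dup) > 0L) {
    stop("duplicate sgrna_id in library: ", paste(unique(dup), collapse = ", "))
  }
  bad <- grep(sprintf("^[ACGT]{%d}$", spacer_length), df$spacer, invert = TRUE)
  if (length(bad) > 0L) {
    stop("invalid spacer (non-ACGT or wrong length, expected ", spacer_length,
         " nt) at row ", bad[1L], ": ", df$spacer[bad[1L]])
  }
  if (anyNA(df$gene) || any(df$gene == "")) stop("empty gene symbol in library")
  attr(df, "spacer_length") <- as.integer(spacer_length)
  class(df) <- c("crispr_library", "data.frame")
  df
}

#' Number of sgRNAs per gene in a library
#'
#' @param lib A `crispr_library`.
#' @return Named integer vector, one entry per gene.
#' @export
sgrnas_per_gene <- function(lib) {
  stopifnot(inherits(lib, "crispr_library"))
  tab <- table(lib$gene)
  structure(as.integer(tab), names = names(tab))
}

#' Write a library design to CSV
#'
#' Inverse of [read_library()]: `write_library()` then `read_library()`
#' reproduces the object, and a re-write is byte-identical.
#'
#' @param lib A `crispr_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "crispr_library"))
  utils::write.csv(as.data.frame(lib)[c("sgrna_id", "spacer", "gene")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

COMPARTMENTS <- c("preimplant", "primary", "recurrent", "blood", "metastasis")
ORGANS <- c("lung", "liver", "spleen", "brain", "kidney")

#' Read a sample sheet
#'
#' Each screen sample is annotated with a compartment (preimplant cells,
#' primary tumor, recurrent tumor, blood, or organ metastasis), the organ for
#' metastasis samples, the subject (mouse) it came from, and the week of
#' harvest.
#'
#' @param path TSV with header columns `sample_id`, `compartment`, `organ`,
#'   `subject_id`, `week`.
#' @return A validated `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("sample_id", "compartment", "organ", "subject_id", "week")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$week <- suppressWarnings(as.integer(df$week))
  new_sample_sheet(df)
}

#' Construct and validate a sample sheet
#'
#' Enforces the closed compartment vocabulary and the rule that `organ` is
#' present exactly when `compartment == "metastasis"`.
#'
#' @param df Data frame with columns `sample_id`, `compartment`, `organ`,
#'   `subject_id`, `week`.
#' @return A validated `sample_sheet`.
#' @export
new_sample_sheet <- function(df) {
  need <- c("sample_id", "compartment", "organ", "subject_id", "week")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- data.frame(sample_id   = as.character(df$sample_id),
                   compartment = as.character(df$compartment),
                   organ       = as.character(df$organ),
                   subject_id  = as.character(df$subject_id),
                   week        = as.integer(df$week),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad) > 0L) {
    stop("unknown compartment(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(COMPARTMENTS, collapse = ", "), ")")
  }
  df$organ[is.na(df$organ)] <- ""
  is_met <- df$compartment == "metastasis"
  if (any(is_met & df$organ == "")) {
    stop("metastasis sample without organ: ",
         paste(df$sample_id[is_met & df$organ == ""], collapse = ", "))
  }
  if (any(!is_met & df$organ != "")) {
    stop("organ given for non-metastasis sample: ",
         paste(df$sample_id[!is_met & df$organ != ""], collapse = ", "))
  }
  if (anyNA(df$week) || any(df$week < 0L)) stop("week must be a nonnegative integer")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet to TSV
#'
#' @param sheet A `sample_sheet`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "sample_sheet"))
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate an sgRNA-by-sample count matrix
#'
#' @param mat Nonnegative integer matrix, rownames are sgRNA ids, colnames are
#'   sample ids.
#' @param lib Optional `crispr_library`; if given, rownames must be a subset of
#'   its sgRNA ids.
#' @param sheet Optional `sample_sheet`; if given, colnames must be a subset of
#'   its sample ids.
#' @return The validated integer matrix.
#' @export
new_count_matrix <- function(mat, lib = NULL, sheet = NULL) {
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("count matrix needs sgRNA rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("duplicate row or column labels in count matrix")
  }
  storage.mode(mat) <- "integer"
  if (anyNA(mat) || any(mat < 0L)) stop("count matrix entries must be nonnegative integers")
  if (!is.null(lib)) {
    miss <- setdiff(rownames(mat), lib$sgrna_id)
    if (length(miss) > 0L) {
      stop("count rows absent from library: ", paste(utils::head(miss, 5L), collapse = ", "))
    }
  }
  if (!is.null(sheet)) {
    miss <- setdiff(colnames(mat), sheet$sample_id)
    if (length(miss) > 0L) {
      stop("count columns absent from sample sheet: ", paste(utils::head(miss, 5L), collapse = ", "))
    }
  }
  mat
}

#' Read a count matrix from TSV
#'
#' Dialect: first column `sgrna_id`, remaining columns one per sample, integer
#' cells, tab separated.
#'
#' @param path TSV path.
#' @param lib,sheet Optional library / sample sheet for label validation.
#' @return Integer matrix (sgRNA x sample).
#' @export
read_counts <- function(path, lib = NULL, sheet = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "sgrna_id") stop("counts TSV must start with an sgrna_id column")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$sgrna_id
  new_count_matrix(mat, lib = lib, sheet = sheet)
}

#' Write a count matrix to TSV
#'
#' @param mat Integer count matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path) {
  df <- data.frame(sgrna_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quantify sgRNA abundance in one FASTQ sample
#'
#' Each read is assigned to at most one sgRNA by the spacer-length substring at
#' a fixed offset: an exact spacer match wins; otherwise, when
#' `max_mismatch = 1`, the read is assigned to the unique sgRNA at Hamming
#' distance 1. Reads matching zero sgRNAs, matching two or more (including a
#' duplicated spacer, or a distance-1 tie), or too short to cover
#' `offset + spacer length` are tallied as unassigned. Assigned plus unassigned
#' always equals the number of reads.
#'
#' @param fastq Path to a FASTQ file (gzip accepted).
#' @param lib A `crispr_library`.
#' @param offset 0-based position of the spacer within the read. Default 0.
#' @param max_mismatch 0 (exact only) or 1 (unique single-mismatch rescue).
#' @return List with `counts` (named integer vector over all library sgRNAs),
#'   `unassigned` (integer), and `n_reads`.
#' @export
quantify_fastq <- function(fastq, lib, offset = 0L, max_mismatch = 0L) {
  stopifnot(inherits(lib, "crispr_library"))
  if (nrow(lib) == 0L) stop("library is empty")
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  offset <- as.integer(offset)
  if (offset < 0L) stop("offset must be nonnegative")
  L <- attr(lib, "spacer_length")

  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq")),
    error = function(e) stop("failed to parse FASTQ ", fastq, ": ",
                             conditionMessage(e), call. = FALSE))
  n_reads <- length(reads)
  counts <- structure(integer(nrow(lib)), names = lib$sgrna_id)
  if (n_reads == 0L) {
    return(list(counts = counts, unassigned = 0L, n_reads = 0L))
  }

  long_enough <- nchar(reads) >= offset + L
  kmers <- substr(reads[long_enough], offset + 1L, offset + L)

  # spacers may be duplicated in a library; an exact hit on a duplicated
  # spacer matches >=2 sgRNAs and is therefore unassigned
  spacer_n <- table(lib$spacer)
  unique_spacers <- names(spacer_n)[spacer_n == 1L]
  sg_of_spacer <- structure(lib$sgrna_id, names = lib$spacer)[unique_spacers]

  hit <- sg_of_spacer[kmers]           # NA where no unique exact match
  exact_dup <- kmers %in% names(spacer_n)[spacer_n > 1L]
  hit[exact_dup] <- NA_character_      # >=2 exact matches: unassigned
  unresolved <- is.na(hit) & !exact_dup

  if (max_mismatch == 1L && any(unresolved)) {
    idx <- which(unresolved)
    for (i in idx) {
      hit_i <- .hamming1_unique(kmers[i], lib, sg_of_spacer, spacer_n)
      if (!is.na(hit_i)) hit[i] <- hit_i
    }
  }

  assigned <- hit[!is.na(hit)]
  if (length(assigned) > 0L) {
    tab <- table(assigned)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  unassigned <- n_reads - length(assigned)
  list(counts = counts, unassigned = as.integer(unassigned),
       n_reads = as.integer(n_reads))
}

# unique sgRNA at Hamming distance exactly 1 from kmer, else NA.
# Enumerates the 3L single-substitution neighbours and looks each up in the
# spacer index; a neighbour landing on a duplicated spacer counts as 2 hits.
.hamming1_unique <- function(kmer, lib, sg_of_spacer, spacer_n) {
  L <- nchar(kmer)
  hits <- character(0)
  n_hits <- 0L
  for (pos in seq_len(L)) {
    base <- substr(kmer, pos, pos)
    for (nt in c("A", "C", "G", "T")) {
      if (nt == base) next
      cand <- kmer
      substr(cand, pos, pos) <- nt
      k <- spacer_n[cand]
      if (!is.na(k)) {
        if (k > 1L) return(NA_character_)  # tie within one duplicated spacer
        n_hits <- n_hits + 1L
        if (n_hits > 1L) return(NA_character_)
        hits <- sg_of_spacer[[cand]]
      }
    }
  }
  if (n_hits == 1L) hits else NA_character_
}

#' Write reads embedding library spacers as FASTQ
#'
#' Synthesizes one read per requested sgRNA draw: the spacer placed at `offset`
#' inside random flanking sequence. Used by the screen simulator's optional
#' FASTQ output and by tests.
#'
#' @param spacers Character vector of spacer sequences, one per read.
#' @param path Output FASTQ path.
#' @param offset 0-based spacer offset within the read.
#' @param read_length Total read length (default offset + spacer + 5).
#' @return `path`, invisibly.
#' @export
write_spacer_fastq <- function(spacers, path, offset = 0L,
                               read_length = NULL) {
  n <- length(spacers)
  L <- if (n > 0L) nchar(spacers[1L]) else 20L
  if (is.null(read_length)) read_length <- offset + L + 5L
  stopifnot(read_length >= offset + L)
  con <- file(path, "w")
  on.exit(close(con))
  if (n == 0L) return(invisible(path))
  rand_seq <- function(k, m) {
    if (k == 0L) return(rep("", m))
    apply(matrix(sample(c("A", "C", "G", "T"), k * m, replace = TRUE), m), 1L, paste0, collapse = "")
  }
  left <- rand_seq(offset, n)
  right <- rand_seq(read_length - offset - L, n)
  seqs <- paste0(left, spacers, right)
  qual <- strrep("I", read_length)
  writeLines(paste0("@read", seq_len(n), "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}
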