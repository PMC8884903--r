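# Fixture builders and independent brute-force oracles. Everything here is
# deliberately naive (loops, exhaustive scans) and independent of the package
# implementation paths it is used to check.

rand_spacer <- function(n, L = 20L) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

make_library <- function(n_genes = 5L, s = 3L, L = 20L) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  sp <- rand_spacer(n_genes * s, L)
  while (anyDuplicated(sp)) sp[duplicated(sp)] <- rand_spacer(sum(duplicated(sp)), L)
  new_library(data.frame(
    sgrna_id = paste0(rep(genes, each = s), "_", seq_len(s)),
    spacer = sp, gene = rep(genes, each = s)), spacer_length = L)
}

make_sheet <- function(n_mice = 2L, organs = c("lung", "liver")) {
  rows <- list(data.frame(sample_id = "pre", compartment = "preimplant",
                          organ = "", subject_id = "pool", week = 0L))
  for (m in seq_len(n_mice)) {
    id <- sprintf("m%d", m)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(id, c("_pri", "_rec", "_bld")),
      compartment = c("primary", "recurrent", "blood"),
      organ = "", subject_id = id, week = 8L)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(id, "_met_", organs),
      compartment = "metastasis", organ = organs, subject_id = id, week = 8L)
  }
  new_sample_sheet(do.call(rbind, rows))
}

rand_counts <- function(lib, sheet, max_count = 30L) {
  n <- nrow(lib) * nrow(sheet)
  mat <- matrix(sample(0:max_count, n, replace = TRUE), nrow(lib),
                dimnames = list(lib$sgrna_id, sheet$sample_id))
  new_count_matrix(mat, lib, sheet)
}

# per-cell brute-force presence evaluation
bf_presence <- function(counts, lib, tau, m) {
  genes <- sort(unique(lib$gene))
  out <- matrix(FALSE, length(genes), ncol(counts),
                dimnames = list(genes, colnames(counts)))
  for (g in genes) {
    sg <- lib$sgrna_id[lib$gene == g]
    sg <- intersect(sg, rownames(counts))
    for (s in colnames(counts)) {
      out[g, s] <- sum(counts[sg, s] >= tau) >= m
    }
  }
  out
}

# naive set unions/intersections from a presence matrix and sheet
bf_compartment_sets <- function(presence, sheet) {
  comps <- intersect(c("preimplant", "primary", "recurrent", "blood", "metastasis"),
                     unique(sheet$compartment))
  sets <- list()
  for (cc in comps) {
    ids <- sheet$sample_id[sheet$compartment == cc]
    genes <- character(0)
    for (s in intersect(ids, colnames(presence))) {
      genes <- union(genes, rownames(presence)[presence[, s]])
    }
    sets[[cc]] <- sort(genes)
  }
  sets
}

bf_organ_sets <- function(presence, sheet) {
  met <- sheet[sheet$compartment == "metastasis", ]
  sets <- list()
  for (o in sort(unique(met$organ))) {
    ids <- met$sample_id[met$organ == o]
    genes <- character(0)
    for (s in intersect(ids, colnames(presence))) {
      genes <- union(genes, rownames(presence)[presence[, s]])
    }
    sets[[o]] <- sort(genes)
  }
  sets
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive per-read assignment: exact match first, else unique distance-1
bf_assign_read <- function(read, lib, offset, max_mismatch) {
  L <- attr(lib, "spacer_length")
  if (nchar(read) < offset + L) return(NA_character_)
  kmer <- substr(read, offset + 1L, offset + L)
  d <- vapply(lib$spacer, hamming, integer(1), b = kmer)
  exact <- which(d == 0L)
  if (length(exact) == 1L) return(lib$sgrna_id[exact])
  if (length(exact) > 1L) return(NA_character_)
  if (max_mismatch == 1L) {
    one <- which(d == 1L)
    if (length(one) == 1L) return(lib$sgrna_id[one])
  }
  NA_character_
}

# event-table log-rank: O, E, V summed over distinct event times
bf_logrank <- function(tA, eA, tB, eB) {
  time <- c(tA, tB); event <- c(eA, eB)
  inA <- rep(c(TRUE, FALSE), c(length(tA), length(tB)))
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); nA <- sum(at_risk & inA)
    d <- sum(event == 1 & time == t)
    dA <- sum(event == 1 & time == t & inA)
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       O = O, E = E)
}

# vectorized exact-permutation two-sided p for the pooled two-sample t;
# with fixed group sizes |t| is monotone in |meanA - meanB|, so the
# permutation distribution of the mean difference is sufficient
perm_t_p <- function(x, y, B = 1e5) {
  z <- c(x, y); nx <- length(x); n <- length(z)
  obs <- abs(mean(x) - mean(y))
  diffs <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, nx)
    abs(mean(z[idx]) - mean(z[-idx]))
  }, numeric(1))
  (sum(diffs >= obs - 1e-12) + 1) / (B + 1)
}

small_screen_cfg <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 60L, sgrnas_per_gene = 3L, n_mice = 3L,
                   organs = c("lung", "liver", "brain"),
                   cells_implanted = 2e4, reads_per_sample = 2e5,
                   n_planted_pan = 3L, n_planted_single = 3L, seed = seed)
  do.call(screen_sim_config, utils::modifyList(defaults, list(...)))
}
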