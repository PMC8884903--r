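setup_ranked <- function(seed = 1L) {
  set.seed(seed)
  lib <- make_library(6, 2)
  sheet <- make_sheet(2, organs = c("lung", "liver"))
  counts <- rand_counts(lib, sheet, max_count = 40L)
  pres <- call_presence(counts, lib)
  list(lib = lib, sheet = sheet, counts = counts, pres = pres)
}

test_that("frequency ranking counts qualifying samples with stable tie-breaks", {
  s <- setup_ranked(5)
  rk <- rank_by_frequency(s$pres, s$counts, s$lib, s$sheet)
  qual <- s$sheet$sample_id[s$sheet$compartment %in%
                              c("recurrent", "blood", "metastasis")]
  # frequency equals a direct per-gene count over qualifying samples
  for (g in rk$gene) {
    expect_equal(rk$frequency[rk$gene == g],
                 sum(s$pres[g, intersect(colnames(s$pres), qual)]))
  }
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$frequency) <= 0))
  # within equal frequency, reads descend, then symbols ascend
  for (f in unique(rk$frequency)) {
    blk <- rk[rk$frequency == f, ]
    expect_true(all(diff(blk$total_reads) <= 0))
    for (r in unique(blk$total_reads)) {
      expect_false(is.unsorted(blk$gene[blk$total_reads == r]))
    }
  }
  # permuting sample order changes nothing
  perm <- sample(colnames(s$pres))
  pres_p <- s$pres[, perm]
  attr(pres_p, "tau") <- attr(s$pres, "tau")
  rk_p <- rank_by_frequency(pres_p, s$counts[, perm], s$lib, s$sheet)
  expect_equal(rk_p, rk)

  expect_error(rank_by_frequency(s$pres, s$counts, s$lib, s$sheet,
                                 compartments = character(0)), "empty")
})

test_that("primary-only genes score zero under default compartments", {
  lib <- make_library(2, 1)
  sheet <- make_sheet(1, organs = "lung")
  counts <- matrix(0L, nrow(lib), nrow(sheet),
                   dimnames = list(lib$sgrna_id, sheet$sample_id))
  counts["g01_1", "m1_pri"] <- 100L       # primary only
  counts["g02_1", "m1_met_lung"] <- 100L  # qualifying
  pres <- call_presence(counts, lib)
  rk <- rank_by_frequency(pres, counts, lib, sheet)
  expect_equal(rk$frequency[rk$gene == "g01"], 0L)
  expect_equal(rk$frequency[rk$gene == "g02"], 1L)
  expect_equal(rk$gene[1], "g02")
})

test_that("tie-breaking by read sum on a constructed fixture", {
  lib <- make_library(2, 1)
  sheet <- make_sheet(1, organs = "lung")
  counts <- matrix(0L, nrow(lib), nrow(sheet),
                   dimnames = list(lib$sgrna_id, sheet$sample_id))
  counts["g01_1", "m1_bld"] <- 10L   # same frequency, fewer reads
  counts["g02_1", "m1_bld"] <- 99L
  pres <- call_presence(counts, lib)
  rk <- rank_by_frequency(pres, counts, lib, sheet)
  expect_equal(rk$gene[1:2], c("g02", "g01"))
  # equal again -> alphabetical
  counts["g01_1", "m1_bld"] <- 99L
  rk2 <- rank_by_frequency(call_presence(counts, lib), counts, lib, sheet)
  expect_equal(rk2$gene[1:2], c("g01", "g02"))
})

test_that("top-n is a prefix-stable cut", {
  s <- setup_ranked(6)
  rk <- rank_by_frequency(s$pres, s$counts, s$lib, s$sheet)
  expect_equal(top_n_genes(rk, 1e6), rk)         # larger than table
  expect_equal(nrow(top_n_genes(rk, 1)), 1L)
  for (i in 1:10) {
    ab <- sort(sample(nrow(rk), 2, replace = TRUE))
    expect_equal(top_n_genes(rk, ab[1]),
                 top_n_genes(rk, ab[2])[seq_len(ab[1]), ],
                 ignore_attr = TRUE)
  }
})

test_that("oncoprint matrix restricts presence with grouped columns", {
  s <- setup_ranked(7)
  rk <- rank_by_frequency(s$pres, s$counts, s$lib, s$sheet)
  top <- top_n_genes(rk, 4)
  om <- oncoprint_matrix(top$gene, s$pres, s$sheet)
  expect_equal(rownames(om), top$gene)
  expect_setequal(colnames(om), colnames(s$pres))
  # cells equal the presence calls
  expect_equal(om, unclass(s$pres)[top$gene, colnames(om)] + 0L,
               ignore_attr = TRUE)
  # compartment blocks (and organ blocks within metastasis) are contiguous
  comp <- s$sheet$compartment[match(colnames(om), s$sheet$sample_id)]
  expect_equal(rle(comp)$values, unique(comp))
  org <- s$sheet$organ[match(colnames(om), s$sheet$sample_id)]
  met_org <- org[comp == "metastasis"]
  expect_equal(rle(met_org)$values, unique(met_org))

  expect_error(oncoprint_matrix("nope", s$pres, s$sheet), "not in presence")
})

test_that("hit calls annotate ubiquity and flag a unique pan-organ gene", {
  lib <- make_library(3, 1)
  sheet <- make_sheet(1, organs = c("lung", "liver", "brain"))
  counts <- matrix(0L, nrow(lib), nrow(sheet),
                   dimnames = list(lib$sgrna_id, sheet$sample_id))
  counts["g01_1", paste0("m1_met_", c("lung", "liver", "brain"))] <- 50L
  counts["g02_1", "m1_met_lung"] <- 50L
  pres <- call_presence(counts, lib)
  rep_ <- gene_set_report(pres, sheet)
  rk <- rank_by_frequency(pres, counts, lib, sheet)
  hits <- call_hits(rk, rep_)
  expect_equal(hits$k[hits$gene == "g01"], 3L)
  expect_true(hits$pan_organ[hits$gene == "g01"])
  expect_false(any(hits$pan_organ[hits$gene != "g01"]))
  expect_true(attr(hits, "unique_pan_organ"))

  # no gene reaches every organ -> empty pan-organ set
  counts["g01_1", "m1_met_brain"] <- 0L
  rep2 <- gene_set_report(call_presence(counts, lib), sheet)
  hits2 <- call_hits(rank_by_frequency(call_presence(counts, lib), counts, lib, sheet),
                     rep2)
  expect_false(any(hits2$pan_organ))
  expect_false(attr(hits2, "unique_pan_organ"))

  # catalog membership flag goes through homolog mapping
  hits3 <- call_hits(rk, rep_, catalog = c("G01"))
  expect_true(hits3$in_catalog[hits3$gene == "g01"])
  expect_false(any(hits3$in_catalog[hits3$gene != "g01"]))
})
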