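test_that("library reader validates, constructs, and round-trips", {
  set.seed(101)
  tmp <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("sgrna_id,spacer,gene",
               paste0("sg", 1:3, ",", rand_spacer(3), ",g1")), tmp)
  lib <- read_library(tmp)
  expect_s3_class(lib, "crispr_library")
  expect_equal(nrow(lib), 3L)
  expect_equal(unname(sgrnas_per_gene(lib)), 3L)

  # duplicate id names the offender
  writeLines(c("sgrna_id,spacer,gene",
               paste0("sgA,", rand_spacer(1), ",g1"),
               paste0("sgA,", rand_spacer(1), ",g1")), tmp)
  expect_error(read_library(tmp), "sgA")

  # non-ACGT spacer reported with its row
  writeLines(c("sgrna_id,spacer,gene",
               paste0("sg1,", rand_spacer(1), ",g1"),
               "sg2,ACGTNACGTNACGTNACGTN,g1"), tmp)
  expect_error(read_library(tmp), "row 2")

  # write(read(x)) is byte-identical for a simulator-emitted library
  sim <- simulate_screen(small_screen_cfg(seed = 7))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_library(sim$library, f1)
  write_library(read_library(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("sample sheet enforces vocabulary and organ conditionality", {
  df <- data.frame(sample_id = paste0("s", 1:5), compartment = "metastasis",
                   organ = c("lung", "liver", "spleen", "brain", "kidney"),
                   subject_id = "m1", week = 8L)
  sheet <- new_sample_sheet(df)
  expect_setequal(unique(sheet$organ),
                  c("lung", "liver", "spleen", "brain", "kidney"))

  bad <- df; bad$compartment[1] <- "spleen"
  expect_error(new_sample_sheet(bad), "unknown compartment")

  bad <- df; bad$compartment[2] <- "blood"  # blood row keeps organ=liver
  expect_error(new_sample_sheet(bad), "organ given for non-metastasis")

  bad <- df; bad$organ[3] <- ""
  expect_error(new_sample_sheet(bad), "without organ")

  # simulator sheet round-trips losslessly
  sim <- simulate_screen(small_screen_cfg(seed = 3))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_sample_sheet(sim$sheet, f1)
  write_sample_sheet(read_sample_sheet(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("count matrix validates labels and round-trips", {
  set.seed(5)
  lib <- make_library(3, 2)
  sheet <- make_sheet(1)
  counts <- rand_counts(lib, sheet)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(counts, f1)
  back <- read_counts(f1, lib, sheet)
  expect_identical(back, counts)

  rogue <- counts
  rownames(rogue)[1] <- "not_in_library"
  expect_error(new_count_matrix(rogue, lib), "absent from library")
  neg <- counts; neg[1, 1] <- -1L
  expect_error(new_count_matrix(neg), "nonnegative")
})

test_that("fastq quantification: exact matching, mismatch rescue, ties", {
  set.seed(42)
  lib <- make_library(4, 2)

  # five reads embedding sgRNA 1's spacer at offset 0
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_spacer_fastq(rep(lib$spacer[1], 5), fq, offset = 0L)
  q <- quantify_fastq(fq, lib, offset = 0L, max_mismatch = 0L)
  expect_equal(unname(q$counts[lib$sgrna_id[1]]), 5L)
  expect_equal(sum(q$counts), 5L)
  expect_equal(q$unassigned, 0L)

  # single substitution: unassigned at mm=0, rescued at mm=1 when unique;
  # regenerate the library if the random spacers made an accidental neighbour
  repeat {
    mut <- lib$spacer[1]
    substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(mut, 3, 3))[1]
    d <- vapply(lib$spacer, hamming, integer(1), b = mut)
    if (sum(d <= 1) == 1) break
    lib <- make_library(4, 2)
  }
  write_spacer_fastq(mut, fq, offset = 0L)
  q0 <- quantify_fastq(fq, lib, max_mismatch = 0L)
  expect_equal(sum(q0$counts), 0L)
  expect_equal(q0$unassigned, 1L)
  q1 <- quantify_fastq(fq, lib, max_mismatch = 1L)
  expect_equal(unname(q1$counts[lib$sgrna_id[1]]), 1L)

  # distance-1 tie between two sgRNAs -> unassigned
  base <- strrep("A", 20)
  tie_lib <- new_library(data.frame(
    sgrna_id = c("t1", "t2"),
    spacer = c(paste0("C", strrep("A", 19)), paste0("G", strrep("A", 19))),
    gene = "gT"))
  write_spacer_fastq(base, fq, offset = 0L)  # distance 1 from both
  qt <- quantify_fastq(fq, tie_lib, max_mismatch = 1L)
  expect_equal(sum(qt$counts), 0L)
  expect_equal(qt$unassigned, 1L)

  # offset handling and short-read accounting
  write_spacer_fastq(lib$spacer[3], fq, offset = 4L, read_length = 30L)
  qo <- quantify_fastq(fq, lib, offset = 4L)
  expect_equal(unname(qo$counts[lib$sgrna_id[3]]), 1L)
  qshort <- quantify_fastq(fq, lib, offset = 20L)  # 20+20 > 30: too short
  expect_equal(qshort$unassigned, 1L)
  expect_equal(sum(qshort$counts), 0L)
})

test_that("fastq quantification equals the exhaustive per-read oracle", {
  set.seed(77)
  for (rep_i in 1:20) {
    lib <- make_library(n_genes = 3L, s = 2L, L = 8L)
    n_reads <- 30L
    # mix: exact spacers, mutated spacers, random junk
    pick <- sample(lib$spacer, n_reads, replace = TRUE)
    mutate <- runif(n_reads) < 0.5
    for (i in which(mutate)) {
      p <- sample(8L, 1)
      substr(pick[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    junk <- runif(n_reads) < 0.2
    pick[junk] <- rand_spacer(sum(junk), 8L)
    fq <- withr::local_tempfile(fileext = ".fastq")
    write_spacer_fastq(pick, fq, offset = 2L, read_length = 14L)
    reads <- pick  # the embedded k-mer at offset 2 is exactly `pick`
    for (mm in c(0L, 1L)) {
      q <- quantify_fastq(fq, lib, offset = 2L, max_mismatch = mm)
      expected <- table(factor(
        vapply(paste0("NN", reads), bf_assign_read, character(1),
               lib = lib, offset = 2L, max_mismatch = mm),
        levels = lib$sgrna_id))
      expect_equal(unname(q$counts), as.integer(expected))
      expect_equal(q$unassigned + sum(q$counts), n_reads)
    }
  }
})
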