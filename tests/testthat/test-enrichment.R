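test_that("presence calls implement the hard read-count cut", {
  lib <- new_library(data.frame(sgrna_id = c("a1", "a2", "b1"),
                                spacer = rand_spacer(3),
                                gene = c("gA", "gA", "gB")))
  counts <- matrix(0L, 3, 2, dimnames = list(lib$sgrna_id, c("s1", "s2")))
  counts["a1", "s1"] <- 10L   # exactly at the cut
  counts["a2", "s2"] <- 9L    # one below
  pres <- call_presence(counts, lib, tau = 10L, m = 1L)
  expect_true(pres["gA", "s1"])
  expect_false(pres["gA", "s2"])
  expect_false(any(pres["gB", ]))

  # all-zero matrix: nothing present
  zero <- matrix(0L, 3, 2, dimnames = dimnames(counts))
  expect_false(any(call_presence(zero, lib)))

  expect_error(call_presence(counts, lib, tau = 0L), "tau")
  expect_error(call_presence(counts, lib, m = 0L), "m")

  # m > 1 requires that many passing guides
  counts2 <- counts; counts2["a2", "s1"] <- 50L
  p2 <- call_presence(counts2, lib, tau = 10L, m = 2L)
  expect_true(p2["gA", "s1"])
  expect_false(p2["gA", "s2"])
})

test_that("presence matches per-cell brute force on random matrices", {
  set.seed(202)
  for (i in 1:25) {
    lib <- make_library(n_genes = sample(3:8, 1), s = sample(2:6, 1))
    sheet <- make_sheet(2)
    counts <- rand_counts(lib, sheet, max_count = 15L)
    tau <- sample(1:12, 1); m <- sample(1:3, 1)
    pres <- call_presence(counts, lib, tau, m)
    bf <- bf_presence(counts, lib, tau, m)
    expect_equal(unclass(pres)[rownames(bf), colnames(bf)], bf)
  }
})

test_that("compartment sets follow union/intersection semantics", {
  lib <- make_library(4, 2)
  sheet <- make_sheet(2, organs = c("lung", "liver"))
  counts <- matrix(0L, nrow(lib), nrow(sheet),
                   dimnames = list(lib$sgrna_id, sheet$sample_id))
  # g01 present only in one blood sample
  counts["g01_1", "m1_bld"] <- 20L
  # g02 present in >=1 sample of every compartment
  for (s in c("pre", "m1_pri", "m2_rec", "m1_bld", "m2_met_lung")) {
    counts["g02_1", s] <- 20L
  }
  pres <- call_presence(counts, lib)
  cs <- compartment_sets(pres, sheet)
  expect_equal(cs$compartment_sets$blood, c("g01", "g02"))
  expect_false("g01" %in% cs$compartment_sets$primary)
  expect_equal(cs$shared_all, "g02")
  # preimplant doesn't gate shared_all by default, but can
  counts2 <- counts; counts2["g02_1", "pre"] <- 0L
  cs2 <- compartment_sets(call_presence(counts2, lib), sheet)
  expect_equal(cs2$shared_all, "g02")
  cs3 <- compartment_sets(call_presence(counts2, lib), sheet,
                          include_preimplant = TRUE)
  expect_equal(cs3$shared_all, character(0))

  orphan <- pres
  colnames(orphan)[1] <- "mystery_sample"
  expect_error(compartment_sets(orphan, sheet), "absent from sample sheet")
})

test_that("organ ubiquity and pan-organ calls match brute force", {
  set.seed(303)
  for (i in 1:25) {
    lib <- make_library(n_genes = sample(4:8, 1), s = 2L)
    sheet <- make_sheet(sample(2:3, 1),
                        organs = sample(c("lung", "liver", "spleen", "brain", "kidney"),
                                        sample(2:4, 1)))
    counts <- rand_counts(lib, sheet, max_count = 14L)
    pres <- call_presence(counts, lib)
    ou <- organ_ubiquity(pres, sheet)
    bf <- bf_organ_sets(pres, sheet)
    expect_equal(ou$organ_sets, bf)
    k_bf <- sapply(rownames(pres), function(g) sum(vapply(bf, function(s) g %in% s, logical(1))))
    expect_equal(ou$ubiquity, k_bf[names(ou$ubiquity)])
    expect_equal(ou$pan_organ,
                 sort(names(k_bf)[k_bf == length(bf)]))
    expect_true(all(ou$ubiquity >= 0 & ou$ubiquity <= ou$K_observed))
    for (o in names(bf)) expect_true(all(ou$pan_organ %in% bf[[o]]))
    cs <- compartment_sets(pres, sheet)
    bfc <- bf_compartment_sets(pres, sheet)
    expect_equal(cs$compartment_sets, bfc)
    for (cc in setdiff(names(bfc), "preimplant")) {
      expect_true(all(cs$shared_all %in% bfc[[cc]]))
    }
  }
  sheet_nomet <- new_sample_sheet(data.frame(
    sample_id = "s1", compartment = "primary", organ = "",
    subject_id = "m1", week = 8L))
  lib <- make_library(2, 2)
  pres <- call_presence(rand_counts(lib, sheet_nomet), lib)
  expect_error(organ_ubiquity(pres, sheet_nomet), "no metastasis samples")
})

test_that("raising thresholds or dropping samples never enlarges sets", {
  set.seed(404)
  for (i in 1:10) {
    lib <- make_library(6, 3)
    sheet <- make_sheet(2, organs = c("lung", "liver", "brain"))
    counts <- rand_counts(lib, sheet, max_count = 120L)
    p_lo <- call_presence(counts, lib, tau = 10L, m = 1L)
    p_hi <- call_presence(counts, lib, tau = 100L, m = 1L)
    p_m2 <- call_presence(counts, lib, tau = 10L, m = 2L)
    expect_true(all(p_hi <= p_lo))
    expect_true(all(p_m2 <= p_lo))
    for (p_strict in list(p_hi, p_m2)) {
      cs_lo <- compartment_sets(p_lo, sheet); cs_hi <- compartment_sets(p_strict, sheet)
      for (cc in names(cs_hi$compartment_sets)) {
        expect_true(all(cs_hi$compartment_sets[[cc]] %in% cs_lo$compartment_sets[[cc]]))
      }
      expect_true(all(cs_hi$shared_all %in% cs_lo$shared_all))
      ou_lo <- organ_ubiquity(p_lo, sheet); ou_hi <- organ_ubiquity(p_strict, sheet)
      expect_true(all(ou_hi$ubiquity <= ou_lo$ubiquity))
    }
    # deleting a sample can only shrink or preserve every derived set
    drop <- sample(colnames(p_lo), 1)
    keep <- setdiff(colnames(p_lo), drop)
    p_sub <- unclass(p_lo)[, keep]
    cs_full <- compartment_sets(p_lo, sheet)
    cs_sub <- compartment_sets(p_sub, sheet)
    for (cc in names(cs_sub$compartment_sets)) {
      expect_true(all(cs_sub$compartment_sets[[cc]] %in% cs_full$compartment_sets[[cc]]))
    }
  }
})
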