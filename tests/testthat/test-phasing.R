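test_that("fragments merge mates and define connectivity components", {
  het <- data.table::data.table(pos = c(10L, 50L, 200L),
                                ref = c("A", "C", "G"),
                                alt = c("T", "G", "A"))
  # read pair r1 spans sites 1 and 2 with one mate each; r2 covers site 3
  aln <- data.table::data.table(
    read_id = c("r1", "r1", "r2"),
    pos = c(0L, 40L, 180L),
    seq = c(paste0(strrep("A", 10), "T", strrep("A", 9)),   # alt at 10
            paste0(strrep("A", 10), "G", strrep("A", 9)),   # alt at 50
            paste0(strrep("A", 20), "G", strrep("A", 9))))  # ref at 200
  fb <- build_fragments(aln, het)
  expect_equal(fb$components, c(1L, 1L, 2L))
  expect_equal(unname(fb$fragments["r1", ]), c(1L, 1L, NA))
  # r2 covers one site only: uninformative, dropped
  expect_false("r2" %in% rownames(fb$fragments))
})

test_that("conflicting mate observations become gaps", {
  het <- data.table::data.table(pos = c(5L, 8L), ref = c("A", "A"),
                                alt = c("T", "T"))
  aln <- data.table::data.table(
    read_id = c("r1", "r1"),
    pos = c(0L, 0L),
    seq = c(paste0("AAAAA", "T", "AA", "T", "A"),    # alt at both
            paste0("AAAAA", "A", "AA", "T", "A")))   # ref at 5, alt at 8
  fb <- build_fragments(aln, het)
  # site 5 conflicts -> gap; one informative site left -> fragment dropped
  expect_equal(nrow(fb$fragments), 0L)
})

test_that("phase_block minimises MEC on canonical cases", {
  # ten concordant fragments over three sites
  F <- rbind(matrix(rep(c(0L, 0L, 0L), 5), ncol = 3, byrow = TRUE),
             matrix(rep(c(1L, 1L, 1L), 5), ncol = 3, byrow = TRUE))
  b <- phase_block(F)
  expect_equal(b$mec, 0L)
  expect_true(all(b$haplotype == 0L) || all(b$haplotype == 1L))
  # one discordant fragment costs exactly one correction
  F2 <- rbind(F, c(0L, 1L, 0L))
  expect_equal(phase_block(F2)$mec, 1L)
  # fewer than two sites: no block
  expect_null(phase_block(matrix(0L, 3, 1)))
})

test_that("heuristic phasing matches the exhaustive oracle", {
  set.seed(31)
  for (i in 1:60) {
    F <- random_fragments(n_sites = sample(4:10, 1),
                          n_frags = sample(8:30, 1))
    if (nrow(F) == 0) next
    exact <- phase_block(F, phasing_params())  # exhaustive path
    heur <- phase_block(F, phasing_params(exhaustive_site_limit = 2L))
    want <- oracle_mec(F)
    expect_equal(exact$mec, want)
    expect_equal(heur$mec, want)
  }
})

test_that("block filtering applies the MEC and concordance thresholds", {
  params <- phasing_params()
  mk <- function(hap, mec) list(haplotype = hap, mec = mec, n_fragments = 10L)
  # perfect reference concordance retained with A/B labels
  b <- filter_and_label(mk(rep(0L, 10), 0L), params)
  expect_equal(b$reference_concordance, 1)
  expect_equal(c(b$label_h1, b$label_h2), c("A", "B"))
  # complement orientation gets the mirrored labels
  b2 <- filter_and_label(mk(rep(1L, 10), 0L), params)
  expect_equal(c(b2$label_h1, b2$label_h2), c("B", "A"))
  # 8 of 10 reference alleles is below the 90% concordance filter
  expect_null(filter_and_label(mk(c(rep(0L, 8), 1L, 1L), 0L), params))
  # MEC 11 exceeds the cap even at perfect concordance
  expect_null(filter_and_label(mk(rep(0L, 10), 11L), params))
  # relaxed concordance with strict labelling: retained but unassigned
  loose <- phasing_params(min_reference_concordance = 0.6,
                          min_subgenome_match = 0.9)
  b3 <- filter_and_label(mk(c(rep(0L, 7), rep(1L, 3)), 0L), loose)
  expect_equal(b3$label_h1, "unassigned")
})

test_that("raising max_mec or lowering concordance never shrinks retention", {
  set.seed(32)
  blocks <- lapply(1:40, function(i) {
    F <- random_fragments(sample(4:8, 1), sample(6:20, 1), flip = 0.2)
    if (nrow(F) == 0) return(NULL)
    phase_block(F)
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  kept <- function(max_mec, conc) {
    p <- phasing_params(max_mec = max_mec,
                        min_reference_concordance = conc)
    which(!vapply(blocks, function(b) is.null(filter_and_label(b, p)),
                  logical(1)))
  }
  expect_true(all(kept(2, 0.9) %in% kept(10, 0.9)))
  expect_true(all(kept(5, 0.95) %in% kept(5, 0.8)))
})

test_that("sequence editing applies phased and fixed sites correctly", {
  ref <- strrep("A", 60)
  fixed <- data.table::data.table(pos = 5L, alt = "G")
  none <- edit_homoeolog_sequences(ref, data.table::data.table(), fixed)
  expect_equal(none$seq_a, none$seq_b)
  expect_equal(substring(none$seq_a, 6, 6), "G")

  blocks <- data.table::data.table(
    block = 1L,
    sites = list(c(10L, 20L)), ref = list(c("A", "A")),
    alt = list(c("T", "C")), haplotype = list(c(0L, 1L)),
    label_h1 = "A", label_h2 = "B")
  one <- edit_homoeolog_sequences(ref, blocks, fixed)
  # A carries the A-haplotype allele, B its complement, fixed in both
  expect_equal(substring(one$seq_a, 11, 11), "A")
  expect_equal(substring(one$seq_b, 11, 11), "T")
  expect_equal(substring(one$seq_a, 21, 21), "C")
  expect_equal(substring(one$seq_b, 21, 21), "A")
  expect_equal(substring(one$seq_a, 6, 6), "G")
  expect_equal(substring(one$seq_b, 6, 6), "G")
  # complementarity: differ exactly at phased sites
  da <- utf8ToInt(one$seq_a) != utf8ToInt(one$seq_b)
  expect_equal(which(da) - 1L, c(10L, 20L))
})

test_that("discontinuous blocks split the transcript into abutting pieces", {
  ref <- strrep("A", 100)
  blocks <- data.table::data.table(
    block = 1:2,
    sites = list(c(10L, 20L), c(70L, 80L)),
    ref = list(c("A", "A"), c("A", "A")),
    alt = list(c("T", "T"), c("C", "C")),
    haplotype = list(c(0L, 0L), c(0L, 0L)),
    label_h1 = c("A", "A"), label_h2 = c("B", "B"))
  pieces <- edit_homoeolog_sequences(ref, blocks, NULL)
  expect_equal(nrow(pieces), 2L)
  expect_equal(pieces$start, c(0L, 46L))
  expect_equal(pieces$end, c(46L, 100L))
  expect_equal(pieces$end[1], pieces$start[2])  # pieces abut
  expect_equal(sum(pieces$end - pieces$start), 100L)

  overlapping <- data.table::copy(blocks)
  overlapping$sites <- list(c(10L, 75L), c(70L, 80L))
  expect_error(edit_homoeolog_sequences(ref, overlapping, NULL),
               "overlapping")
})

test_that("phasing recovers simulator truth on error-free reads", {
  sim <- small_sim()
  aln1 <- small_reads()[[1]]
  calls1 <- small_calls()[[1]]
  rec <- reconstruct_homoeologs(aln1, calls1, sim$reference)
  expect_gt(nrow(rec$blocks), 0)
  expect_true(all(rec$blocks$mec == 0L))
  # focal-variety hemi alleles may sit on a phased haplotype, so concordance
  # is bounded by the filter threshold rather than exactly 1
  expect_true(all(rec$blocks$reference_concordance >= 0.9))
  expect_true(all(rec$blocks$label_h1 %in% c("A", "B")))
  v1 <- variety_sequences(sim, 1)
  for (i in seq_len(nrow(rec$blocks))) {
    b <- rec$blocks[i, ]
    sites <- b$sites[[1]]
    hap <- b$haplotype[[1]]
    h1 <- ifelse(hap == 0L, b$ref[[1]], b$alt[[1]])
    a_alleles <- if (b$label_h1 == "A") h1
    else ifelse(hap == 0L, b$alt[[1]], b$ref[[1]])
    truth <- substring(v1$A[[b$transcript]], sites + 1L, sites + 1L)
    expect_identical(a_alleles, truth)
  }
})
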