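test_that("hit acceptance is the stated three-way disjunction", {
  p <- qc_params()
  # 250 bp hit: short of both fractions but >= 200 bp absolute
  expect_true(accept_hit(250, 600, 2000, 100, p))
  # 150 bp hit covering 75% of its contig
  expect_true(accept_hit(150, 200, 1000, 100, p))
  # 150 bp hit failing all three conditions
  expect_false(accept_hit(150, 300, 1000, 100, p))
  # identity pre-filter
  expect_false(accept_hit(250, 600, 2000, 79, p))
  # monotone in hit length at fixed contig/gene lengths
  lens <- seq(10, 400, by = 10)
  acc <- accept_hit(lens, 1000, 1000, 100, p)
  expect_false(is.unsorted(acc))
})

test_that("gene reconstruction computes span and minimal contig cover", {
  p <- qc_params()
  one <- gene_reconstruction(
    data.table::data.table(contig = "c1", gstart = 0L, gend = 1000L,
                           identity = 99), 1000L, p)
  expect_equal(one$span_fraction, 1)
  expect_equal(one$contigs_needed, 1L)
  expect_true(one$reconstructed)

  two <- gene_reconstruction(
    data.table::data.table(contig = c("c1", "c2"),
                           gstart = c(0L, 500L), gend = c(500L, 1000L),
                           identity = c(99, 99)), 1000L, p)
  expect_equal(two$span_fraction, 1)
  expect_equal(two$contigs_needed, 2L)

  none <- gene_reconstruction(
    data.table::data.table(contig = character(), gstart = integer(),
                           gend = integer(), identity = numeric()), 1000L, p)
  expect_equal(none$span_fraction, 0)
  expect_false(none$reconstructed)

  expect_warning(gene_reconstruction(
    data.table::data.table(contig = "c1", gstart = -5L, gend = 1200L,
                           identity = 99), 1000L, p), "clipped")
})

test_that("greedy contig cover matches exhaustive search on small cases", {
  p <- qc_params()
  exhaustive_cover <- function(hits, gene_length) {
    contigs <- unique(hits$contig)
    target <- IRanges::reduce(IRanges::IRanges(hits$gstart + 1L, hits$gend))
    target_w <- sum(IRanges::width(target))
    for (k in seq_along(contigs)) {
      combos <- utils::combn(contigs, k, simplify = FALSE)
      for (cc in combos) {
        h <- hits[hits$contig %in% cc, ]
        w <- sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(h$gstart + 1L, h$gend))))
        if (w == target_w) return(k)
      }
    }
    0L
  }
  set.seed(41)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    gstart <- sample(0:800, n)
    glen <- sample(50:300, n, replace = TRUE)
    hits <- data.table::data.table(
      contig = paste0("c", sample(1:5, n, replace = TRUE)),
      gstart = gstart, gend = pmin(gstart + glen, 1000L),
      identity = runif(n, 90, 100))
    got <- gene_reconstruction(hits, 1000L, p)$contigs_needed
    expect_equal(got, exhaustive_cover(hits, 1000L))
  }
})

test_that("span is invariant to hit order and splitting", {
  p <- qc_params()
  hits <- data.table::data.table(
    contig = c("c1", "c1", "c2"),
    gstart = c(0L, 300L, 150L), gend = c(200L, 600L, 400L),
    identity = c(99, 99, 98))
  base <- gene_reconstruction(hits, 1000L, p)$span_fraction
  set.seed(42)
  expect_equal(gene_reconstruction(hits[sample(3), ], 1000L, p)$span_fraction,
               base)
  split <- data.table::data.table(
    contig = c("c1", "c1", "c1", "c2"),
    gstart = c(0L, 100L, 300L, 150L), gend = c(100L, 200L, 600L, 400L),
    identity = c(99, 99, 99, 98))
  expect_equal(gene_reconstruction(split, 1000L, p)$span_fraction, base)
})

test_that("copy estimation assigns hits by identity bands", {
  p <- qc_params()
  # full-length contigs for both homoeologs of a 97%-identity pair
  hits <- data.table::data.table(
    contig = c("cA", "cB"),
    gstart = c(0L, 0L), gend = c(1000L, 1000L),
    identity = c(99.8, 97.2))
  ce <- homoeolog_copy_estimate(hits, 1000L, paired_identity = 97, p)
  expect_equal(ce$coverage_A, 1)
  expect_equal(ce$coverage_B, 1)
  expect_equal(ce$category, "both")
  expect_false(ce$indeterminate)
  # only the A copy present
  ce1 <- homoeolog_copy_estimate(hits[1], 1000L, 97, p)
  expect_equal(ce1$category, "one")
  # a 90%-identity hit matches neither band: putative paralog
  par <- data.table::data.table(contig = "cP", gstart = 0L, gend = 1000L,
                                identity = 90)
  ce2 <- homoeolog_copy_estimate(par, 1000L, 97, p)
  expect_equal(ce2$category, "none")
  # overlapping bands flagged indeterminate
  expect_true(homoeolog_copy_estimate(hits, 1000L, 99.5, p)$indeterminate)
})

test_that("copy categories partition the coverage unit square", {
  p <- qc_params()
  classify_cov <- function(ca, cb) {
    hi <- max(ca, cb); lo <- min(ca, cb)
    if (hi >= 0.8 && lo >= 0.8) "both"
    else if (hi >= 0.8 && lo < 0.2) "one"
    else if (hi >= 0.8) "one_to_two"
    else if (hi >= 0.2) "less_than_one"
    else "none"
  }
  for (ca in seq(0, 1, by = 0.1)) {
    for (cb in seq(0, 1, by = 0.1)) {
      # build hits realising the target coverages exactly
      hits <- data.table::data.table(
        contig = c("cA", "cB"),
        gstart = c(0L, 0L),
        gend = c(as.integer(1000 * ca), as.integer(1000 * cb)),
        identity = c(99.5, 97))
      hits <- hits[hits$gend > 0, ]
      ce <- homoeolog_copy_estimate(hits, 1000L, 97, p)
      expect_equal(ce$category, classify_cov(ca, cb),
                   info = sprintf("ca=%.1f cb=%.1f", ca, cb))
    }
  }
})

test_that("the QC report chains acceptance, span and copy estimation", {
  p <- qc_params()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene1\tctgA\t99.9\t1000\t1\t0\t1\t1000\t1\t1000\t0.0\t1800",
    "gene1\tctgB\t97.1\t1000\t29\t0\t1\t1000\t1\t1000\t0.0\t1700",
    "gene1\tctgS\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-10\t150",
    "gene2\tctgC\t99.0\t500\t5\t0\t1\t500\t1\t500\t0.0\t900"
  ), path)
  hits <- read_alignment_table(path, "blast-tab-12")
  rep <- assembly_qc_report(
    hits,
    gene_lengths = c(gene1 = 1000L, gene2 = 1000L),
    contig_lengths = c(ctgA = 1100L, ctgB = 1050L, ctgS = 5000L,
                       ctgC = 520L),
    paired_identity = c(gene1 = 97),
    params = p)
  g1 <- rep[rep$gene == "gene1", ]
  expect_equal(g1$n_accepted, 2L)  # the 100 bp low-fraction hit fails all rules
  expect_equal(g1$span_fraction, 1)
  expect_true(g1$reconstructed)
  expect_equal(g1$category, "both")
  g2 <- rep[rep$gene == "gene2", ]
  expect_equal(g2$span_fraction, 0.5)
  expect_false(g2$reconstructed)
})
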