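test_that("identical exon structures give the empty event set", {
  a <- exons_df(c(1, 200, 400), c(100, 300, 500))
  expect_length(classify_event(a, a), 0L)
})

test_that("a skipped internal exon is labeled exon_skipping only", {
  a <- exons_df(c(1, 200, 400), c(100, 300, 500))
  b <- exons_df(c(1, 400), c(100, 500))
  expect_equal(classify_event(a, b), "exon_skipping")
  expect_equal(classify_event(b, a), "exon_skipping")  # symmetric
})

test_that("an intron inside the other's exon is intron_retention, strand-symmetric", {
  a <- exons_df(c(1, 200), c(100, 300))
  b <- exons_df(1, 300)
  expect_equal(classify_event(a, b), "intron_retention")
  expect_equal(classify_event(b, a), "intron_retention")
  am <- exons_df(c(1, 200), c(100, 300), strand = "-")
  bm <- exons_df(1, 300, strand = "-")
  expect_equal(classify_event(am, bm), "intron_retention")
})

test_that("shared acceptor with shifted donor is alt_donor, strand-aware", {
  ## plus strand: donor = left (5') end of the intron
  a <- exons_df(c(1, 200), c(100, 300))
  b <- exons_df(c(1, 200), c(130, 300))   # intron start shifts, end shared
  expect_equal(classify_event(a, b), "alt_donor")
  ## relabeling the strand flips donor and acceptor
  am <- exons_df(c(1, 200), c(100, 300), strand = "-")
  bm <- exons_df(c(1, 200), c(130, 300), strand = "-")
  expect_equal(classify_event(am, bm), "alt_acceptor")
  ## plus strand: acceptor = right (3') end of the intron
  c1 <- exons_df(c(1, 200), c(100, 300))
  c2 <- exons_df(c(1, 170), c(100, 300))  # intron end shifts, start shared
  expect_equal(classify_event(c1, c2), "alt_acceptor")
})

test_that("labels are invariant under coordinate translation", {
  a <- exons_df(c(1, 200, 400), c(100, 300, 500))
  b <- exons_df(c(1, 400), c(100, 500))
  k <- 10000
  expect_equal(classify_event(exons_df(c(1, 200, 400) + k,
                                       c(100, 300, 500) + k),
                              exons_df(c(1, 400) + k, c(100, 500) + k)),
               classify_event(a, b))
})

test_that("mirror-and-flip preserves labels (same molecule read from the other end)", {
  mirror <- function(ex, C = 10000) {
    out <- exons_df(C - ex$end, C - ex$start,
                    strand = ifelse(ex$strand[1] == "+", "-", "+"))
    out[order(out$start), ]
  }
  a <- exons_df(c(1, 200), c(100, 300))
  b <- exons_df(c(1, 200), c(130, 300))
  expect_equal(classify_event(a, b), "alt_donor")
  expect_equal(classify_event(mirror(a), mirror(b)), "alt_donor")
  sk_a <- exons_df(c(1, 200, 400), c(100, 300, 500))
  sk_b <- exons_df(c(1, 400), c(100, 500))
  expect_equal(classify_event(mirror(sk_a), mirror(sk_b)), "exon_skipping")
})

test_that("terminal-exon differences are 'other' and strand mixing is rejected", {
  a <- exons_df(c(1, 200), c(100, 300))
  b <- exons_df(c(50, 200), c(100, 300))  # alternative start, same introns
  expect_equal(classify_event(a, b), "other")
  bad <- exons_df(c(1, 200), c(100, 300), strand = "-")
  expect_error(classify_event(a, bad), "strand")
})

test_that("event tallies aggregate per pair and per gene with deduplication", {
  ## g1: single isoform; g2: a skipping pair; g3: a retention pair
  ex <- rbind(
    data.frame(gene_id = "g1", transcript_id = "g1.t1",
               exon_id = c("a", "b"), chrom = "2L",
               start = c(1, 200), end = c(100, 300), strand = "+"),
    data.frame(gene_id = "g2", transcript_id = "g2.t1",
               exon_id = c("c", "d", "e"), chrom = "2L",
               start = c(1000, 1200, 1400), end = c(1100, 1300, 1500),
               strand = "+"),
    data.frame(gene_id = "g2", transcript_id = "g2.t2",
               exon_id = c("c", "e"), chrom = "2L",
               start = c(1000, 1400), end = c(1100, 1500), strand = "+"),
    data.frame(gene_id = "g3", transcript_id = "g3.t1",
               exon_id = c("f", "g"), chrom = "2L",
               start = c(2000, 2200), end = c(2100, 2300), strand = "+"),
    data.frame(gene_id = "g3", transcript_id = "g3.t2",
               exon_id = "h", chrom = "2L",
               start = 2000, end = 2300, strand = "+"))
  ann <- annotation(ex)

  calls1 <- data.frame(gene_id = "g1")
  t1 <- summarize_events(calls1, ann)
  expect_true(all(t1$n_pairs == 0))

  calls <- data.frame(gene_id = c("g1", "g2", "g3"))
  t2 <- summarize_events(calls, ann)
  expect_equal(t2$n_pairs[t2$event == "exon_skipping"], 1L)
  expect_equal(t2$n_pairs[t2$event == "intron_retention"], 1L)
  expect_equal(t2$n_genes[t2$event == "exon_skipping"], 1L)
  expect_equal(sum(t2$n_pairs), 2L)

  ## duplicated call rows do not change the tallies
  t3 <- summarize_events(rbind(calls, calls), ann)
  expect_equal(t3, t2)
})
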