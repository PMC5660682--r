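make_tiny_counts <- function() {
  ann <- tiny_annotation()
  samples <- paste0("s", 1:4)
  tx <- matrix(c(20, 40, 10, 8,     # g1.t1
                 12, 8, 20, 4,      # g2.t1
                 8, 12, 0, 16),     # g2.t2
               nrow = 3, byrow = TRUE,
               dimnames = list(c("g1.t1", "g2.t1", "g2.t2"), samples))
  ex <- matrix(c(20, 40, 10, 8,     # g1.e1 (= transcript counts)
                 20, 40, 10, 8,     # g1.e2
                 5, 10, 4, 10,      # g2.e1 (shared)
                 12, 6, 18, 2,      # g2.e2 (t1 only)
                 6, 9, 0, 12),      # g2.e3 (t2 only)
               nrow = 5, byrow = TRUE,
               dimnames = list(c("g1.e1", "g1.e2", "g2.e1", "g2.e2",
                                 "g2.e3"), samples))
  list(ann = ann, tx = tx, ex = ex)
}

test_that("single-isoform gene with exon counts equal to transcript counts gives fraction 1", {
  d <- make_tiny_counts()
  ph <- exon_fraction(d$ex, d$tx, d$ann)
  expect_true(all(ph$values[c("g1.e1", "g1.e2"), ] == 1))
})

test_that("exon fractions match a by-hand oracle on the two-gene toy table", {
  d <- make_tiny_counts()
  ph <- exon_fraction(d$ex, d$tx, d$ann)
  ## g2 denominator in s1 = 12 + 8 = 20; g2.e1 count 5 -> 0.25
  expect_equal(ph$values["g2.e1", "s1"], 0.25)
  expect_equal(ph$values["g2.e2", "s1"], 12 / 20)
  expect_equal(ph$values["g2.e3", "s2"], 9 / 20)
  ## anchors point at the host gene midpoint
  expect_equal(ph$anchors$pos[ph$anchors$phenotype_id == "g2.e1"],
               round((5000 + 8300) / 2))
})

test_that("zero-denominator cells follow the zero policy and the missing filter", {
  d <- make_tiny_counts()
  d$tx["g2.t1", c("s1", "s2")] <- 0
  d$tx["g2.t2", c("s1", "s2")] <- 0
  d$ex[c("g2.e1", "g2.e2", "g2.e3"), c("s1", "s2")] <- 0
  ## 50% of samples undefined > max_missing_frac -> g2 phenotypes dropped
  ph <- exon_fraction(d$ex, d$tx, d$ann, zero_policy = "drop",
                      max_missing_frac = 0.2)
  expect_false(any(grepl("^g2", rownames(ph$values))))
  ## with a permissive filter they are kept as NA
  ph2 <- exon_fraction(d$ex, d$tx, d$ann, zero_policy = "drop",
                       max_missing_frac = 0.6)
  expect_true(all(is.na(ph2$values["g2.e1", c("s1", "s2")])))
  ## pseudocount mode defines every cell
  ph3 <- exon_fraction(d$ex, d$tx, d$ann, zero_policy = "pseudocount")
  expect_equal(ph3$values["g2.e1", "s1"], (0 + 1) / (0 + 1))
  expect_equal(ph3$values["g2.e1", "s3"], (4 + 1) / (20 + 1))
})

test_that("unknown exons are skipped with a warning and negative counts are fatal", {
  d <- make_tiny_counts()
  ex2 <- rbind(d$ex, orphan = c(1, 1, 1, 1))
  expect_warning(ph <- exon_fraction(ex2, d$tx, d$ann), "absent")
  expect_false("orphan" %in% rownames(ph$values))
  d$ex[1, 1] <- -1
  expect_error(exon_fraction(d$ex, d$tx, d$ann), "negative")
})

test_that("exon fractions conserve gene-level read totals", {
  s <- sim_small(seed = 13, n_rils = 15, n_genes = 8)
  ph <- exon_fraction(s$exon_counts, s$transcript_counts, s$annotation,
                      max_missing_frac = 1)
  tg <- transcript_genes(s$annotation)
  gene_tot <- rowsum(s$transcript_counts, tg[rownames(s$transcript_counts)])
  ## fraction * denominator restores the exon counts, summed per gene
  for (g in unique(ph$anchors$gene_id)) {
    rows <- ph$anchors$phenotype_id[ph$anchors$gene_id == g]
    back <- sweep(ph$values[rows, , drop = FALSE], 2, gene_tot[g, ], `*`)
    ex_tot <- colSums(s$exon_counts[rows, , drop = FALSE])
    ok <- !is.na(colSums(back))
    expect_equal(colSums(back)[ok], ex_tot[ok], tolerance = 1e-10)
  }
})

test_that("exon fractions are invariant to uniform per-sample count scaling", {
  d <- make_tiny_counts()
  ph1 <- exon_fraction(d$ex, d$tx, d$ann, zero_policy = "drop")
  ph2 <- exon_fraction(d$ex * 3L, d$tx * 3L, d$ann, zero_policy = "drop")
  expect_equal(ph1$values, ph2$values)
})

test_that("isoform grouping keeps only multi-isoform genes (regrouping oracle)", {
  ann <- make_annotation(10, isoforms_per_gene = c(`1` = 0.4, `2` = 0.3,
                                                   `4` = 0.3), seed = 77)
  tg <- transcript_genes(ann)
  txs <- names(tg)
  cnts <- matrix(10, length(txs), 4,
                 dimnames = list(txs, paste0("s", 1:4)))
  grps <- suppressMessages(isoform_groups(cnts, ann))
  ## brute-force regrouping of the annotation
  expected <- table(tg)
  expected <- expected[expected >= 2]
  expect_equal(length(grps), length(expected))
  for (gr in grps) {
    expect_equal(ncol(gr$Y), unname(expected[gr$gene_id]),
                 ignore_attr = TRUE)
    expect_setequal(gr$isoforms, txs[tg == gr$gene_id])
    expect_equal(rownames(gr$Y), paste0("s", 1:4))
  }
  ## sizes example: genes with 1, 2, 4 isoforms -> groups of 2 and 4 only
  expect_true(all(vapply(grps, function(g) ncol(g$Y), numeric(1)) >= 2))
  ## empty table -> empty list
  empty <- cnts[0, , drop = FALSE]
  expect_length(suppressMessages(isoform_groups(empty, ann)), 0L)
})

test_that("mutually exclusive exon-cluster combinatorics multiply out", {
  expect_equal(dscam_isoform_count(c(12, 48, 33, 2)), 38016)
  expect_equal(dscam_isoform_count(c(1)), 1)
  expect_equal(dscam_isoform_count(numeric(0)), 1)
  ## brute-force enumeration oracle
  expect_equal(dscam_isoform_count(c(3, 5, 7)),
               nrow(expand.grid(1:3, 1:5, 1:7)))
  expect_error(dscam_isoform_count(c(3, 0)), ">= 1")
})
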