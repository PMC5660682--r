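test_that("identical seed and config give byte-identical count tables", {
  a <- sim_small(seed = 5, n_rils = 10, n_genes = 6)
  b <- sim_small(seed = 5, n_rils = 10, n_genes = 6)
  expect_identical(a$exon_counts, b$exon_counts)
  expect_identical(a$transcript_counts, b$transcript_counts)
  d <- sim_small(seed = 6, n_rils = 10, n_genes = 6)
  expect_false(identical(a$transcript_counts, d$transcript_counts))
})

test_that("counts are non-negative integers and exons never exceed the gene total", {
  s <- sim_small(seed = 9, n_rils = 12, n_genes = 8)
  expect_true(all(s$exon_counts >= 0))
  expect_true(all(s$transcript_counts >= 0))
  expect_true(all(s$exon_counts == round(s$exon_counts)))
  tg <- transcript_genes(s$annotation)
  gene_tot <- rowsum(s$transcript_counts, tg[rownames(s$transcript_counts)])
  mem <- exon_membership(s$annotation)
  gene_of_exon <- mem$gene_id[match(rownames(s$exon_counts), mem$exon_id)]
  expect_true(all(s$exon_counts <= gene_tot[gene_of_exon, ]))
})

test_that("with no planted effects, founder-grouped contrasts are null (group-mean oracle)", {
  s <- sim_small(seed = 21, n_rils = 50, n_genes = 10, delta = 0)
  ph <- exon_fraction(s$exon_counts, s$transcript_counts, s$annotation)
  E <- s$E
  z <- vapply(seq_len(min(6, nrow(ph$values))), function(i) {
    y <- ph$values[i, ]
    G <- locus_design(s$genotypes, 3, s$samples$ril)
    dom <- G[, "A3"] > 0.5
    if (sum(dom) < 4 || stats::sd(y, na.rm = TRUE) == 0) return(0)
    con <- (mean(y[dom & E == 1], na.rm = TRUE) -
              mean(y[dom & E == 0], na.rm = TRUE)) -
      (mean(y[!dom & E == 1], na.rm = TRUE) -
         mean(y[!dom & E == 0], na.rm = TRUE))
    se <- stats::sd(y, na.rm = TRUE) *
      sqrt(2 / sum(dom & E == 1) + 2 / sum(!dom & E == 1))
    con / se
  }, numeric(1))
  expect_true(all(abs(z) < 4))
})

test_that("a planted cis GxE effect is recovered by the group-mean oracle", {
  delta <- 1.5
  s <- sim_small(seed = 31, n_rils = 100, n_genes = 10, delta = delta)
  eff <- s$truth$effects
  ph <- exon_fraction(s$exon_counts, s$transcript_counts, s$annotation)
  fr <- pmin(pmax(ph$values[eff$phenotype_id, ], 1e-4), 1 - 1e-4)
  lg <- stats::qlogis(fr)  # latent scale of the planted shift
  G <- locus_design(s$genotypes, eff$locus_index, s$samples$ril)
  dom <- G[, eff$founder] > 0.5
  E <- s$E
  gmeans <- c(mean(lg[dom & E == 1]), mean(lg[dom & E == 0]),
              mean(lg[!dom & E == 1]), mean(lg[!dom & E == 0]))
  con <- (gmeans[1] - gmeans[2]) - (gmeans[3] - gmeans[4])
  vars <- c(stats::var(lg[dom & E == 1]) / sum(dom & E == 1),
            stats::var(lg[dom & E == 0]) / sum(dom & E == 0),
            stats::var(lg[!dom & E == 1]) / sum(!dom & E == 1),
            stats::var(lg[!dom & E == 0]) / sum(!dom & E == 0))
  expect_lt(abs(con - delta), 3 * sqrt(sum(vars)))
})

test_that("misconfigured planted effects are rejected", {
  loci <- locus_grid(chroms = "2L", length_bp = 5e4, spacing = 1e4)
  g <- simulate_founder_mosaics(5, loci, seed = 1)
  ann <- make_annotation(3, seed = 2, chroms = "2L", chrom_length_bp = 5e4)
  ss <- make_sample_sheet(g$rils)
  base <- data.frame(kind = "cis_gxe", gene_id = ann$genes$gene_id[1],
                     target = "exon", locus_index = 1L, founder = "A3",
                     delta = 1, stringsAsFactors = FALSE)
  bad_gene <- transform(base, gene_id = "nope")
  expect_error(simulate_counts(g, ann, ss, sim_truth(bad_gene), seed = 3),
               "gene id")
  bad_locus <- transform(base, locus_index = 99L)
  expect_error(simulate_counts(g, ann, ss, sim_truth(bad_locus), seed = 3),
               "locus index")
  bad_founder <- transform(base, founder = "A9")
  expect_error(simulate_counts(g, ann, ss, sim_truth(bad_founder), seed = 3),
               "founder")
  expect_error(simulate_counts(g, ann, ss, sim_truth(base),
                               nb_dispersion = 0, seed = 3), "dispersion")
})

test_that("sample sheets are paired and the environment vector is 0/1", {
  ss <- make_sample_sheet(c("r1", "r2"))
  expect_equal(nrow(ss), 4L)
  expect_equal(sort(unique(ss$treatment)), c("control", "pb"))
  expect_equal(unname(table(ss$ril)), c(2L, 2L), ignore_attr = TRUE)
  expect_equal(environment_vector(ss), c(0L, 0L, 1L, 1L))
  expect_error(environment_vector(data.frame(treatment = c("control",
                                                           "control"))),
               "both environments")
})
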