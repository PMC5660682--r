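# Small balanced designs with known founder probabilities, for oracle
# comparisons.
toy_design <- function(n_rils = 12, n_founders = 3, seed = 1) {
  set.seed(seed)
  G1 <- matrix(rgamma(n_rils * n_founders, 2), n_rils)
  G1 <- G1 / rowSums(G1)
  G <- rbind(G1, G1)  # paired: same RILs in both environments
  colnames(G) <- paste0("A", seq_len(n_founders))
  E <- rep(c(0, 1), each = n_rils)
  list(G = G, E = E, n = 2 * n_rils)
}

test_that("a constant response gives F = 0 and p = 1 in both models", {
  d <- toy_design()
  f <- fit_exon_model(rep(2.5, d$n), d$G, d$E, ref_founder = "A3")
  expect_equal(f$record$F, 0)
  expect_equal(f$record$p, 1)
  grp <- structure(list(gene_id = "g", isoforms = c("t1", "t2"),
                        Y = matrix(1.0, d$n, 2,
                                   dimnames = list(NULL, c("t1", "t2"))),
                        anchor = list(chrom = "2L", pos = 1)),
                   class = "isoform_group")
  fi <- fit_isoform_model(grp, d$G, d$E, ref_founder = "A3")
  expect_equal(fi$record$F, 0)
  expect_equal(fi$record$p, 1)
})

test_that("the exon model agrees with the normal-equations oracle", {
  for (s in 1:6) {
    d <- toy_design(n_rils = 12, n_founders = 3, seed = s)
    set.seed(100 + s)
    y <- rnorm(d$n)
    f <- fit_exon_model(y, d$G, d$E, ref_founder = "A3")
    ## independent design construction + explicit normal equations
    Gd <- d$G[, c("A1", "A2")]
    X0 <- cbind(1, d$E)
    X1 <- cbind(1, d$E, Gd, Gd * d$E)
    o <- oracle_partial_f(X0, X1, y)
    expect_equal(f$record$F, o$F, tolerance = 1e-8)
    expect_equal(f$record$p, o$p, tolerance = 1e-8)
    expect_equal(f$record$df1, 4)
    expect_equal(f$record$df2, d$n - 6)
  }
})

test_that("the isoform model agrees with the oracle under both tested blocks", {
  for (s in 1:5) {
    d <- toy_design(n_rils = 8, n_founders = 2, seed = s)
    k <- 2
    set.seed(200 + s)
    Y <- matrix(rnorm(d$n * k), d$n, k, dimnames = list(NULL, c("t1", "t2")))
    grp <- structure(list(gene_id = "g", isoforms = c("t1", "t2"), Y = Y,
                          anchor = list(chrom = "2L", pos = 1)),
                     class = "isoform_group")
    ## oracle long-format designs, built independently
    y <- c(Y[, 1], Y[, 2])
    T2 <- rep(c(0, 1), each = d$n)
    El <- rep(d$E, k)
    g1 <- rep(d$G[, "A1"], k)
    X0p <- cbind(1 - T2, T2, El * (1 - T2), El * T2, g1)
    X1 <- cbind(X0p, g1 * T2, g1 * El * (1 - T2), g1 * El * T2)
    X0g <- cbind(X0p, g1 * T2)
    fp <- fit_isoform_model(grp, d$G, d$E, tested_block = "as_printed",
                            ref_founder = "A2")
    op <- oracle_partial_f(X0p, X1, y)
    expect_equal(fp$record$F, op$F, tolerance = 1e-8)
    expect_equal(fp$record$p, op$p, tolerance = 1e-8)
    fg <- fit_isoform_model(grp, d$G, d$E, tested_block = "gxe_only",
                            ref_founder = "A2")
    og <- oracle_partial_f(X0g, X1, y)
    expect_equal(fg$record$F, og$F, tolerance = 1e-8)
    expect_equal(fg$record$df1, 2)  # one founder x E x each of 2 isoforms
  }
})

test_that("the F statistic is invariant to the dropped founder column", {
  d <- toy_design(n_rils = 15, n_founders = 4, seed = 3)
  set.seed(33)
  y <- rnorm(d$n)
  Fs <- vapply(colnames(d$G), function(rf) {
    fit_exon_model(y, d$G, d$E, ref_founder = rf)$record$F
  }, numeric(1))
  expect_lt(max(Fs) - min(Fs), 1e-8)
  grp <- structure(list(gene_id = "g", isoforms = c("t1", "t2"),
                        Y = matrix(rnorm(d$n * 2), d$n, 2,
                                   dimnames = list(NULL, c("t1", "t2"))),
                        anchor = list(chrom = "2L", pos = 1)),
                   class = "isoform_group")
  Fi <- vapply(colnames(d$G), function(rf) {
    fit_isoform_model(grp, d$G, d$E, ref_founder = rf)$record$F
  }, numeric(1))
  expect_lt(max(Fi) - min(Fi), 1e-8)
})

test_that("zero-probability dummy founders do not change the F statistic", {
  d <- toy_design(n_rils = 10, n_founders = 3, seed = 5)
  set.seed(55)
  y <- rnorm(d$n)
  base <- fit_exon_model(y, d$G, d$E, ref_founder = "A3")
  Gplus <- cbind(d$G, A4 = 0, A5 = 0)
  aug <- fit_exon_model(y, Gplus, d$E, ref_founder = "A3")
  expect_equal(aug$record$F, base$record$F, tolerance = 1e-10)
  expect_false(aug$record$flagged)
})

test_that("rank-deficient and underdetermined fits are flagged with missing p", {
  d <- toy_design(n_rils = 3, n_founders = 8, seed = 6)
  set.seed(66)
  y <- rnorm(d$n)  # 6 obs, HA needs 16 params
  f <- fit_exon_model(y, d$G, d$E)
  expect_true(f$record$flagged)
  expect_true(is.na(f$record$p))
  ## duplicated founder column -> collinear beyond the reference drop
  d2 <- toy_design(n_rils = 12, n_founders = 3, seed = 7)
  G <- d2$G
  G[, "A2"] <- G[, "A1"]
  f2 <- fit_exon_model(rnorm(d2$n), G, d2$E, ref_founder = "A3")
  expect_true(f2$record$flagged)
  expect_true(is.na(f2$record$p))
})

test_that("missing phenotype values are removed pairwise", {
  d <- toy_design(n_rils = 14, n_founders = 3, seed = 8)
  set.seed(88)
  y <- rnorm(d$n)
  y[c(1, 5)] <- NA
  f <- fit_exon_model(y, d$G, d$E, ref_founder = "A3")
  keep <- !is.na(y)
  o <- oracle_partial_f(cbind(1, d$E[keep]),
                        cbind(1, d$E[keep], d$G[keep, 1:2],
                              d$G[keep, 1:2] * d$E[keep]), y[keep])
  expect_equal(f$record$F, o$F, tolerance = 1e-8)
})

test_that("null phenotypes give uniform p-values (KS check)", {
  d <- toy_design(n_rils = 30, n_founders = 4, seed = 9)
  set.seed(99)
  p <- replicate(400, fit_exon_model(rnorm(d$n), d$G, d$E,
                                     ref_founder = "A4")$record$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
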