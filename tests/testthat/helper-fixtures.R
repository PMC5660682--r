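# Shared in-code fixtures: tiny hand-built annotations and a standard small
# simulated data set. Everything is generated at test time; no files.

# Two genes: g1 has one isoform (two exons), g2 has two isoforms sharing
# exon e1 and differing by exon e2 (a skipping pair).
tiny_annotation <- function() {
  annotation(data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g2", "g2"),
    transcript_id = c("g1.t1", "g1.t1", "g2.t1", "g2.t1", "g2.t2", "g2.t2"),
    exon_id = c("g1.e1", "g1.e2", "g2.e1", "g2.e2", "g2.e1", "g2.e3"),
    chrom = "2L",
    start = c(100L, 500L, 5000L, 6000L, 5000L, 8000L),
    end = c(200L, 700L, 5400L, 6500L, 5400L, 8300L),
    strand = c("+", "+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE))
}

# Exon table constructor for splice-event fixtures.
exons_df <- function(starts, ends, strand = "+", chrom = "2L") {
  data.frame(chrom = chrom, start = starts, end = ends, strand = strand,
             stringsAsFactors = FALSE)
}

# One standard small simulated study: genotypes, annotation, samples, counts
# with an optional planted exon-target cis G x E effect.
sim_small <- function(seed, n_rils = 40, n_genes = 12, delta = 0,
                      target = "exon", chroms = "2L", length_bp = 2e5,
                      blur = 0.05) {
  loci <- locus_grid(chroms = chroms, length_bp = length_bp, spacing = 1e4)
  g <- simulate_founder_mosaics(n_rils, loci, breakpoint_rate = 0.05,
                                blur = blur, seed = seed)
  ann <- make_annotation(n_genes, seed = seed + 1000, chroms = chroms,
                         chrom_length_bp = length_bp)
  ss <- make_sample_sheet(g$rils)
  tg <- transcript_genes(ann)
  multi <- names(which(table(tg) >= 2))
  truth <- if (delta != 0) {
    sim_truth(data.frame(kind = "cis_gxe", gene_id = multi[1],
                         target = target,
                         locus_index = nearest_locus(g, ann, multi[1]),
                         founder = "A3", delta = delta,
                         stringsAsFactors = FALSE))
  } else {
    sim_truth()
  }
  cnt <- simulate_counts(g, ann, ss, truth, seed = seed + 2000)
  list(genotypes = g, annotation = ann, samples = ss,
       E = environment_vector(ss), exon_counts = cnt$exon_counts,
       transcript_counts = cnt$transcript_counts, truth = cnt$truth)
}

# Independent normal-equations least-squares oracle: RSS via explicit
# solve of X'X b = X'y (ridge-free; requires full-rank X).
oracle_rss <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% b)^2)
}

oracle_partial_f <- function(X0, X1, y) {
  r0 <- oracle_rss(X0, y)
  r1 <- oracle_rss(X1, y)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- length(y) - ncol(X1)
  f <- ((r0 - r1) / df1) / (r1 / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
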