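#!/usr/bin/env Rscript
# Stage 2 — build and normalize the two splicing phenotypes.
#
# Phenotype 1: the fraction of each gene's reads falling in each exon.
# Phenotype 2: per-gene isoform dosage (normalized transcript values for
# genes with >= 2 isoforms). Both are quantile-normalized across samples
# and cleaned of leading principal components (3 for fractions, 4 for
# transcript values), with the treatment contrast protected so the G x E
# signal tested later is not absorbed.

suppressMessages(library(sqtlgxe))
ann <- read_annotation("results/data/annotation.gtf")
samples <- read_sample_sheet("results/data/samples.tsv")
exon_counts <- read_counts("results/data/exon_counts.tsv")
tx_counts <- read_counts("results/data/transcript_counts.tsv")
E <- environment_vector(samples)

ph <- exon_fraction(exon_counts, tx_counts, ann)
cat(sprintf("exon-fraction phenotypes: %d (of %d exons; dropped those undefined in > 20%% of samples)\n",
            nrow(ph$values), nrow(exon_counts)))
phn <- normalize_phenotypes(ph, protect = E)
rep1 <- attr(phn, "report")
cat(sprintf("removed %d PCs from fractions (variance shares %s)\n",
            rep1$n_pc, paste(sprintf("%.2f", rep1$var_explained),
                             collapse = ", ")))
write_phenotypes(phn, "results/phenotypes_exon_fraction.tsv")

keep <- rowSums(tx_counts) > 0
txn <- normalize_phenotypes(log2(tx_counts[keep, , drop = FALSE] + 1),
                            n_pc = 4, protect = E)
tx_out <- phenotype_matrix(
  unclass(txn),
  data.frame(phenotype_id = rownames(txn),
             gene_id = unname(transcript_genes(ann)[rownames(txn)]),
             chrom = NA_character_, pos = NA_real_),
  "isoform_dosage")
write_phenotypes(tx_out, "results/phenotypes_transcript_normalized.tsv")
grps <- isoform_groups(unclass(txn), ann, min_total = -Inf)
cat(sprintf("isoform-dosage groups: %d genes with >= 2 expressed isoforms\n",
            length(grps)))
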