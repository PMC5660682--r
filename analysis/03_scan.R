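#!/usr/bin/env Rscript
# Stage 3 — the genome-wide G x E association scan.
#
# Every (phenotype, locus) pair is tested with a partial F-test between the
# nested models: the null carries only the treatment effect, the
# alternative adds founder-genotype main effects and founder x treatment
# interactions (one founder dropped as reference). Both splicing phenotypes
# are scanned against all loci.

suppressMessages(library(sqtlgxe))
genotypes <- read_genotype_probs("results/data/genotypes.tsv")
ann <- read_annotation("results/data/annotation.gtf")
samples <- read_sample_sheet("results/data/samples.tsv")
phn <- read_phenotypes("results/phenotypes_exon_fraction.tsv",
                       kind = "exon_fraction")
txn <- read_phenotypes("results/phenotypes_transcript_normalized.tsv")
grps <- isoform_groups(txn$values, ann, min_total = -Inf)

cfg <- scan_config(verbose = FALSE)
assoc_exon <- sqtl_scan(phn, genotypes, samples, cfg)
assoc_iso <- sqtl_scan(grps, genotypes, samples, cfg)

write_table_tsv(assoc_exon, "results/assoc_exon.tsv")
write_table_tsv(assoc_iso, "results/assoc_isoform.tsv")

n_loci <- nrow(genotypes$loci)
cat(sprintf("exon-fraction scan: %d phenotypes x %d loci = %d tests (expected %s)\n",
            nrow(phn$values), n_loci, nrow(assoc_exon),
            format(scan_size(nrow(phn$values), n_loci))))
cat(sprintf("isoform-dosage scan: %d genes x %d loci = %d tests\n",
            length(grps), n_loci, nrow(assoc_iso)))
cat(sprintf("flagged (rank-deficient) fits: %d exon, %d isoform\n",
            sum(assoc_exon$flagged), sum(assoc_iso$flagged)))
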