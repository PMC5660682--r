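#!/usr/bin/env Rscript
# Stage 1 — simulate the study.
#
# Generates a DSPR-like experiment: 60 recombinant inbred lines genotyped as
# eight-founder probability mosaics on three chromosomes, assayed once under
# control (NaAc) and once under lead (PbAc). The transcriptome carries two
# planted founder-specific cis G x E splicing effects (one exon-level, one
# isoform-level) and one trans hotspot locus on 3L that shifts isoform usage
# of 25 genes on the other chromosomes. All inputs for the later stages are
# written as plain text under results/data/.

suppressMessages(library(sqtlgxe))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260929

loci <- locus_grid(chroms = c("2L", "2R", "3L"), length_bp = 9e4,
                   spacing = 1e4)
genotypes <- simulate_founder_mosaics(60, loci, breakpoint_rate = 0.05,
                                      blur = 0.05, seed = seed)
ann <- make_annotation(120, isoforms_per_gene = c(`1` = 0.3, `2` = 0.5,
                                                  `3` = 0.2),
                       chroms = c("2L", "2R", "3L"), chrom_length_bp = 9e4,
                       seed = seed + 1)
samples <- make_sample_sheet(genotypes$rils)

tg <- transcript_genes(ann)
multi <- names(which(table(tg) >= 2))
gene_chrom <- ann$genes$chrom[match(multi, ann$genes$gene_id)]
cis_targets <- multi[1:2]
hot_locus <- which(genotypes$loci$chrom == "3L")[5]
hot_targets <- setdiff(multi[gene_chrom != "3L"], cis_targets)[1:25]

effects <- rbind(
  data.frame(kind = "cis_gxe", gene_id = cis_targets[1], target = "exon",
             locus_index = nearest_locus(genotypes, ann, cis_targets[1]),
             founder = "A3", delta = 1.5),
  data.frame(kind = "cis_gxe", gene_id = cis_targets[2],
             target = "isoform",
             locus_index = nearest_locus(genotypes, ann, cis_targets[2]),
             founder = "A3", delta = 2.0),
  data.frame(kind = "trans_hotspot", gene_id = hot_targets,
             target = "isoform", locus_index = hot_locus,
             founder = "A3", delta = 1.8))

cnt <- simulate_counts(genotypes, ann, samples, sim_truth(effects),
                       seed = seed + 2)

write_genotype_probs(genotypes, "results/data/genotypes.tsv")
write_annotation(ann, "results/data/annotation.gtf")
write_table_tsv(samples, "results/data/samples.tsv")
write_counts(cnt$exon_counts, "results/data/exon_counts.tsv", "exon")
write_counts(cnt$transcript_counts, "results/data/transcript_counts.tsv",
             "transcript")
write_table_tsv(cnt$truth$effects, "results/data/planted_truth.tsv")

cat(sprintf("simulated %d RILs x 2 treatments = %d samples\n",
            length(genotypes$rils), nrow(samples)))
cat(sprintf("%d loci on %s; %d genes, %d transcripts\n",
            nrow(genotypes$loci),
            paste(unique(genotypes$loci$chrom), collapse = "/"),
            nrow(ann$genes), length(tg)))
cat(sprintf("planted: 2 cis GxE effects (A3 x Pb) and 1 trans hotspot at 3L:%d driving %d genes\n",
            genotypes$loci$pos[hot_locus], length(hot_targets)))
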