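#' Options for an association scan
#'
#' @param tested_block isoform-model tested block (`"as_printed"` or
#'   `"gxe_only"`; see [fit_isoform_model()]).
#' @param ref_founder founder column dropped as reference.
#' @param min_founder_mass optional locus filter: loci where the total
#'   probability mass on non-dominant founders (summed over samples) is
#'   below this value are excluded (default 0 = no filtering).
#' @param window optional cis window in bp: when set, each phenotype is
#'   tested only against loci on its own chromosome within this distance of
#'   its anchor (default NULL = genome-wide).
#' @param verbose log progress per chromosome (default TRUE).
#' @return list of class `scan_config`.
#' @export
scan_config <- function(tested_block = "as_printed", ref_founder = "A8",
                        min_founder_mass = 0, window = NULL,
                        verbose = TRUE) {
  structure(list(tested_block = tested_block, ref_founder = ref_founder,
                 min_founder_mass = min_founder_mass, window = window,
                 verbose = verbose),
            class = "scan_config")
}

#' Number of association tests in a full scan
#'
#' The scan's metadata-level size contract: a genome-wide scan of
#' `n_phenotypes` splicing traits against `n_loci` genotyped positions
#' performs their product in tests (e.g. 106,681 exon/transcript traits by
#' 11,768 loci is 1,255,422,008 tests). The cross-product is never
#' materialized to compute this.
#'
#' @param n_phenotypes number of phenotypes.
#' @param n_loci number of loci.
#' @return the product, as a double.
#' @export
scan_size <- function(n_phenotypes, n_loci) {
  as.numeric(n_phenotypes) * as.numeric(n_loci)
}

#' Genome-wide splicing-QTL association scan
#'
#' Fits the nested G x E models at every (phenotype, locus) pair and
#' returns one association record per pair, ordered phenotype-major,
#' locus-minor. Works for both splicing traits: pass a
#' [phenotype_matrix()] (exon-fraction kind) or a list of isoform groups
#' ([isoform_groups()]).
#'
#' @param phenotypes a `phenotype_matrix` or list of `isoform_group`s,
#'   sample columns/rows aligned with `samples`.
#' @param genotypes a [genotype_tensor()].
#' @param samples sample sheet; `ril` links samples to genotypes and
#'   `treatment` defines the environment.
#' @param config a [scan_config()].
#' @return data.frame with columns `phenotype_id`, `gene_id`,
#'   `pheno_chrom`, `pheno_pos`, `locus_chrom`, `locus_pos`, `method`,
#'   `F`, `df1`, `df2`, `p`, `top_founder`, `flagged`.
#' @export
sqtl_scan <- function(phenotypes, genotypes, samples,
                      config = scan_config()) {
  is_pm <- inherits(phenotypes, "phenotype_matrix")
  sample_ids <- if (is_pm) colnames(phenotypes$values) else
    rownames(phenotypes[[1]]$Y)
  miss <- setdiff(sample_ids, samples$sample)
  extra <- setdiff(samples$sample, sample_ids)
  if (length(miss) || length(extra)) {
    stop("sample mismatch between phenotypes and sample sheet; ",
         "missing from sheet: [", paste(miss, collapse = ", "),
         "]; missing from phenotypes: [", paste(extra, collapse = ", "), "]",
         call. = FALSE)
  }
  samples <- samples[match(sample_ids, samples$sample), ]
  if (!all(samples$ril %in% genotypes$rils)) {
    stop("sample RIL(s) absent from genotypes: ",
         paste(setdiff(samples$ril, genotypes$rils), collapse = ", "),
         call. = FALSE)
  }
  E <- environment_vector(samples)
  loci <- genotypes$loci
  locus_idx <- seq_len(nrow(loci))

  ## optional informativeness filter
  if (config$min_founder_mass > 0) {
    keep <- vapply(locus_idx, function(j) {
      G <- locus_design(genotypes, j, samples$ril)
      mass <- colSums(G)
      sum(mass) - max(mass) >= config$min_founder_mass
    }, logical(1))
    locus_idx <- locus_idx[keep]
  }

  anchors <- if (is_pm) phenotypes$anchors else
    data.frame(phenotype_id = vapply(phenotypes, function(g)
                 paste0(g$gene_id, ":dosage"), character(1)),
               gene_id = vapply(phenotypes, function(g) g$gene_id,
                                character(1)),
               chrom = vapply(phenotypes, function(g) g$anchor$chrom,
                              character(1)),
               pos = vapply(phenotypes, function(g) g$anchor$pos,
                            numeric(1)),
               stringsAsFactors = FALSE)
  method <- if (is_pm) "exon_fraction" else "isoform_dosage"
  n_ph <- nrow(anchors)

  ## precompute per-locus sample-expanded founder designs
  G_list <- lapply(locus_idx, function(j)
    locus_design(genotypes, j, samples$ril))

  res <- vector("list", length(locus_idx))
  last_chrom <- ""
  for (jj in seq_along(locus_idx)) {
    j <- locus_idx[jj]
    if (config$verbose && loci$chrom[j] != last_chrom) {
      message("scanning chromosome ", loci$chrom[j], " (", method, ")")
      last_chrom <- loci$chrom[j]
    }
    G <- G_list[[jj]]
    recs <- vector("list", n_ph)
    for (i in seq_len(n_ph)) {
      if (!is.null(config$window)) {
        if (anchors$chrom[i] != loci$chrom[j] ||
            abs(anchors$pos[i] - loci$pos[j]) > config$window) next
      }
      fit <- if (is_pm) {
        fit_exon_model(phenotypes$values[i, ], G, E,
                       ref_founder = config$ref_founder)
      } else {
        fit_isoform_model(phenotypes[[i]], G, E,
                          tested_block = config$tested_block,
                          ref_founder = config$ref_founder)
      }
      recs[[i]] <- cbind(data.frame(phenotype_id = anchors$phenotype_id[i],
                                    gene_id = anchors$gene_id[i],
                                    pheno_chrom = anchors$chrom[i],
                                    pheno_pos = anchors$pos[i],
                                    locus_chrom = loci$chrom[j],
                                    locus_pos = loci$pos[j],
                                    method = method,
                                    stringsAsFactors = FALSE),
                         fit$record)
    }
    res[[jj]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty_assoc())
  out <- out[order(match(out$phenotype_id, anchors$phenotype_id),
                   match(paste(out$locus_chrom, out$locus_pos),
                         paste(loci$chrom, loci$pos))), ]
  rownames(out) <- NULL
  out
}

empty_assoc <- function() {
  data.frame(phenotype_id = character(), gene_id = character(),
             pheno_chrom = character(), pheno_pos = numeric(),
             locus_chrom = character(), locus_pos = numeric(),
             method = character(), F = numeric(), df1 = numeric(),
             df2 = numeric(), p = numeric(), top_founder = character(),
             flagged = logical(), stringsAsFactors = FALSE)
}
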