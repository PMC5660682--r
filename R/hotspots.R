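#' Detect trans-sQTL hotspots by permutation
#'
#' A trans-sQTL hotspot is a single locus associated with splicing changes
#' in unusually many genes genome-wide — a vertical band on the sQTL map.
#' Loci are binned along the genome and each bin scored by the number of
#' distinct target genes among the (trans) significant calls it carries
#' (the per-locus association-count profile). Because founder mosaics are
#' correlated along a chromosome, one gene's association typically spans
#' several linked loci; calls are first clumped to one unit per
#' (gene, bin), so the exchangeable unit is the gene's regional
#' association, not its LD-duplicated calls. The empirical null reassigns
#' every unit a locus drawn uniformly from the tested locus grid,
#' preserving the unit count while breaking any locus clustering.
#' (Permuting the observed locus column instead would preserve the
#' hotspot's own pile-up in every permutation and have no power against
#' exactly the alternative of interest.) Each bin's empirical p-value is
#' the fraction of null draws reaching its observed gene count, and bins
#' passing a Bonferroni-adjusted cutoff over the scored bins are reported
#' as hotspots.
#'
#' @param calls significance-call table (columns `gene_id`, `locus_chrom`,
#'   `locus_pos`; if a `cis_trans` column is present only `trans` rows are
#'   used).
#' @param bin_size bin width in bp (default 1e5).
#' @param n_perm number of null draws (default 1000; fewer than 100
#'   triggers a warning about an unstable null).
#' @param cutoff family-wise significance cutoff before Bonferroni
#'   (default 0.05).
#' @param loci the tested locus grid (data.frame `chrom`, `pos`), i.e. the
#'   loci of the association scan; when NULL, the distinct loci observed
#'   among the calls are used (adequate only when calls cover the grid).
#' @param seed integer RNG seed (required).
#' @return list with `hotspots` (data.frame: `chrom`, `start`, `end`,
#'   `n_genes`, `p_emp`, rows passing the cutoff) and `profile` (per-bin
#'   distinct-gene counts for all bins with any call, plus `p_emp`).
#' @export
find_hotspots <- function(calls, bin_size = 1e5, n_perm = 1000,
                          cutoff = 0.05, loci = NULL, seed) {
  if (n_perm < 100) warning("n_perm < 100: unstable permutation null",
                            call. = FALSE)
  if (!is.null(calls$cis_trans)) {
    calls <- calls[calls$cis_trans == "trans", , drop = FALSE]
  }
  empty <- list(hotspots = data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), n_genes = integer(),
                                      p_emp = numeric()),
                profile = data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), n_genes = integer(),
                                     p_emp = numeric()))
  if (nrow(calls) == 0L) return(empty)

  bin_start <- floor(calls$locus_pos / bin_size) * bin_size
  bin <- paste0(calls$locus_chrom, ":", bin_start)
  genes <- calls$gene_id
  ## clump LD-duplicated calls: one exchangeable unit per (gene, bin)
  unit <- !duplicated(paste(bin, genes, sep = "\r"))
  bin <- bin[unit]
  genes <- genes[unit]
  ## null draws are uniform over tested loci (then binned), so bins
  ## holding more grid loci correctly attract more null mass
  grid_bins <- if (is.null(loci)) {
    u <- unique(calls[, c("locus_chrom", "locus_pos")])
    paste0(u$locus_chrom, ":", floor(u$locus_pos / bin_size) * bin_size)
  } else {
    paste0(loci$chrom, ":", floor(loci$pos / bin_size) * bin_size)
  }

  count_bins <- function(bin_assign) {
    keep <- !duplicated(paste(bin_assign, genes, sep = "\r"))
    table(bin_assign[keep])
  }
  obs <- count_bins(bin)
  bins <- names(obs)

  exceed <- stats::setNames(numeric(length(obs)), bins)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      null_bin <- sample(grid_bins, length(bin), replace = TRUE)
      perm <- count_bins(null_bin)
      hit <- perm[bins]
      hit[is.na(hit)] <- 0
      exceed <- exceed + (hit >= obs)
    }
  })
  p_emp <- (1 + exceed) / (n_perm + 1)

  split_bin <- strsplit(bins, ":", fixed = TRUE)
  profile <- data.frame(chrom = vapply(split_bin, `[`, "", 1),
                        start = as.numeric(vapply(split_bin, `[`, "", 2)),
                        n_genes = as.integer(obs),
                        p_emp = as.numeric(p_emp),
                        stringsAsFactors = FALSE)
  profile$end <- profile$start + bin_size
  profile <- profile[order(profile$chrom, profile$start),
                     c("chrom", "start", "end", "n_genes", "p_emp")]
  rownames(profile) <- NULL
  hot <- profile[profile$p_emp <= cutoff / nrow(profile), , drop = FALSE]
  rownames(hot) <- NULL
  list(hotspots = hot, profile = profile)
}
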