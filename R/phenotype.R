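#' Splicing phenotype matrix
#'
#' Quantitative splicing traits across samples, with a genomic anchor per
#' phenotype (the midpoint of the host gene span) used for cis/trans
#' classification and the sQTL map axes.
#'
#' @param values numeric matrix, phenotypes x samples (rownames = phenotype
#'   ids, colnames = sample ids).
#' @param anchors data.frame with columns `phenotype_id`, `gene_id`,
#'   `chrom`, `pos`, aligned to the rows of `values`.
#' @param kind `"exon_fraction"` or `"isoform_dosage"`.
#' @return object of class `phenotype_matrix`.
#' @export
phenotype_matrix <- function(values, anchors, kind) {
  kind <- match.arg(kind, c("exon_fraction", "isoform_dosage"))
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (nrow(values) != nrow(anchors) ||
      !identical(rownames(values), anchors$phenotype_id)) {
    stop("`anchors` must align with rows of `values`", call. = FALSE)
  }
  if (anyDuplicated(anchors$phenotype_id)) {
    stop("duplicate phenotype ids", call. = FALSE)
  }
  structure(list(values = values, anchors = anchors, kind = kind),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotype_matrix (%s): %d phenotypes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Exon-fraction splicing phenotype
#'
#' The first splicing trait: the fraction of a gene's reads that fall in
#' each exon. For exon e of gene g in sample n the value is the exon's read
#' count divided by the summed read counts of all transcripts of g in that
#' sample (well-defined for exons shared between isoforms). With
#' `zero_policy = "drop"`, cells with a zero denominator are missing and
#' phenotypes missing in more than `max_missing_frac` of samples are
#' removed; with `"pseudocount"`, 1 is added to numerator and denominator.
#'
#' @param exon_counts integer matrix, exons x samples.
#' @param transcript_counts integer matrix, transcripts x samples (same
#'   sample columns).
#' @param annotation an [annotation()] resolving exons and transcripts to
#'   genes.
#' @param zero_policy `"drop"` (default) or `"pseudocount"`.
#' @param max_missing_frac drop phenotypes with more than this fraction of
#'   undefined cells (default 0.2; only relevant under `"drop"`).
#' @return a [phenotype_matrix()] of kind `exon_fraction`. Exons absent
#'   from the annotation are skipped with a warning giving their number.
#' @export
exon_fraction <- function(exon_counts, transcript_counts, annotation,
                          zero_policy = c("drop", "pseudocount"),
                          max_missing_frac = 0.2) {
  zero_policy <- match.arg(zero_policy)
  if (any(exon_counts < 0) || any(transcript_counts < 0)) {
    stop("negative counts", call. = FALSE)
  }
  if (!identical(colnames(exon_counts), colnames(transcript_counts))) {
    stop("exon and transcript tables must share sample columns",
         call. = FALSE)
  }
  mem <- exon_membership(annotation)
  known <- rownames(exon_counts) %in% mem$exon_id
  if (any(!known)) {
    warning(sum(!known), " exon id(s) absent from annotation; skipped",
            call. = FALSE)
    exon_counts <- exon_counts[known, , drop = FALSE]
  }
  mem <- mem[match(rownames(exon_counts), mem$exon_id), ]
  tx_gene <- transcript_genes(annotation)
  tx_in <- rownames(transcript_counts)
  ## per-gene denominator: summed reads of all the gene's transcripts
  gene_of_tx <- tx_gene[tx_in]
  gene_sum <- rowsum(transcript_counts, group = gene_of_tx)
  denom <- gene_sum[match(mem$gene_id, rownames(gene_sum)), , drop = FALSE]
  if (anyNA(denom)) {
    stop("gene(s) of some exons have no transcripts in the count table",
         call. = FALSE)
  }
  if (zero_policy == "pseudocount") {
    vals <- (as.matrix(exon_counts) + 1) / (denom + 1)
  } else {
    vals <- as.matrix(exon_counts) / denom
    vals[denom == 0] <- NA_real_
    keep <- rowMeans(is.na(vals)) <= max_missing_frac
    vals <- vals[keep, , drop = FALSE]
    mem <- mem[keep, , drop = FALSE]
  }
  gi <- match(mem$gene_id, annotation$genes$gene_id)
  anchors <- data.frame(phenotype_id = mem$exon_id,
                        gene_id = mem$gene_id,
                        chrom = annotation$genes$chrom[gi],
                        pos = annotation$genes$anchor_pos[gi],
                        stringsAsFactors = FALSE)
  rownames(vals) <- anchors$phenotype_id
  phenotype_matrix(vals, anchors, "exon_fraction")
}

#' Per-gene isoform-dosage groups
#'
#' The second splicing trait: for every gene with at least two isoforms
#' present in the (typically normalized) transcript matrix, the samples x
#' isoforms block of values, analysed jointly as a multivariate splicing
#' trait. Single-isoform genes are excluded.
#'
#' @param transcript_mat numeric matrix, transcripts x samples (raw counts
#'   or normalized values).
#' @param annotation an [annotation()].
#' @param min_total exclude transcripts whose row sum is <= this value
#'   (default 0: keep transcripts with any signal; set to `-Inf` to keep
#'   all rows, e.g. for already-normalized input).
#' @return list of `isoform_group` objects, each with `gene_id`,
#'   `isoforms`, `Y` (samples x isoforms) and `anchor` (chrom, pos). The
#'   number of groups is reported via a message.
#' @export
isoform_groups <- function(transcript_mat, annotation, min_total = 0) {
  tx_gene <- transcript_genes(annotation)
  ids <- rownames(transcript_mat)
  unknown <- !(ids %in% names(tx_gene))
  if (any(unknown)) {
    warning(sum(unknown), " transcript id(s) absent from annotation; skipped",
            call. = FALSE)
  }
  keep <- !unknown & rowSums(abs(transcript_mat), na.rm = TRUE) > min_total
  ids <- ids[keep]
  if (length(ids) == 0L) {
    message("isoform_groups: 0 groups")
    return(list())
  }
  by_gene <- split(ids, tx_gene[ids])
  by_gene <- by_gene[vapply(by_gene, length, integer(1)) >= 2L]
  groups <- lapply(names(by_gene), function(g) {
    gi <- match(g, annotation$genes$gene_id)
    structure(list(gene_id = g,
                   isoforms = sort(by_gene[[g]]),
                   Y = t(transcript_mat[sort(by_gene[[g]]), , drop = FALSE]),
                   anchor = list(chrom = annotation$genes$chrom[gi],
                                 pos = annotation$genes$anchor_pos[gi])),
              class = "isoform_group")
  })
  message("isoform_groups: ", length(groups), " groups (genes with >= 2 isoforms)")
  groups
}

#' Theoretical isoform count from mutually exclusive exon clusters
#'
#' Genes like Drosophila Dscam1 contain clusters of mutually exclusive
#' variant exons; exactly one exon per cluster is used in each mature
#' transcript, so the number of theoretically possible mRNAs is the product
#' of the cluster sizes. For Dscam1's clusters of 12, 48, 33 and 2
#' alternatives this gives 12 x 48 x 33 x 2 = 38,016.
#'
#' @param cluster_sizes integer vector of cluster sizes (all >= 1). The
#'   empty list yields 1 (empty product).
#' @return the product, as a double.
#' @export
dscam_isoform_count <- function(cluster_sizes) {
  if (length(cluster_sizes) == 0L) return(1)
  if (!is.numeric(cluster_sizes) || any(!is.finite(cluster_sizes)) ||
      any(cluster_sizes < 1) || any(cluster_sizes != round(cluster_sizes))) {
    stop("`cluster_sizes` must be integers >= 1", call. = FALSE)
  }
  prod(as.numeric(cluster_sizes))
}
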