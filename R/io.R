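## Readers and writers for the pipeline's plain-text formats. All tables
## are TSV with headers; annotation is GTF (1-based closed, gene_id /
## transcript_id attributes); significant-call locus intervals can also be
## emitted as BED (0-based half-open).

#' Read a founder-probability genotype file
#'
#' Expects TSV columns `ril`, `chrom`, `pos`, then one probability column
#' per founder (`A1`..`A8` by default). Every RIL must cover the same
#' locus grid; rows whose probabilities do not sum to 1 within 1e-6 are
#' rejected with their line numbers.
#'
#' @param path file path.
#' @return a [genotype_tensor()].
#' @export
read_genotype_probs <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("ril", "chrom", "pos") %in% names(d))) {
    stop("genotype file must have columns ril, chrom, pos", call. = FALSE)
  }
  founders <- setdiff(names(d), c("ril", "chrom", "pos"))
  if (length(founders) < 2L) {
    stop("missing founder probability columns", call. = FALSE)
  }
  pm <- as.matrix(d[, founders])
  bad <- which(abs(rowSums(pm) - 1) > 1e-6)
  if (length(bad)) {
    stop("founder probabilities do not sum to 1 on line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  }
  rils <- unique(d$ril)
  loci <- unique(d[, c("chrom", "pos")])
  loci <- validate_loci(loci)   # errors on unsorted loci
  key_all <- paste(d$chrom, d$pos, sep = "\r")
  key_loci <- paste(loci$chrom, loci$pos, sep = "\r")
  probs <- array(NA_real_, dim = c(length(rils), nrow(loci),
                                   length(founders)))
  ri <- match(d$ril, rils)
  li <- match(key_all, key_loci)
  for (f in seq_along(founders)) {
    probs[cbind(ri, li, f)] <- pm[, f]
  }
  if (anyNA(probs)) stop("incomplete genotype grid (missing ril x locus rows)",
                         call. = FALSE)
  genotype_tensor(probs, loci, rils = rils, founders = founders)
}

#' Write a founder-probability genotype file
#' @param genotypes a [genotype_tensor()].
#' @param path output path (TSV).
#' @export
write_genotype_probs <- function(genotypes, path) {
  n_r <- length(genotypes$rils); n_l <- nrow(genotypes$loci)
  d <- data.frame(ril = rep(genotypes$rils, each = n_l),
                  chrom = rep(genotypes$loci$chrom, n_r),
                  pos = rep(genotypes$loci$pos, n_r),
                  stringsAsFactors = FALSE)
  for (f in seq_along(genotypes$founders)) {
    d[[genotypes$founders[f]]] <-
      as.vector(t(genotypes$probs[, , f]))
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GTF annotation
#'
#' Imports exon records (1-based closed coordinates, `gene_id` /
#' `transcript_id` attributes) into an [annotation()]. An optional
#' `exon_id` attribute is honored; otherwise exon ids are derived from
#' coordinates within the gene, so shared exons keep a stable id.
#'
#' @param path GTF file path.
#' @return an [annotation()].
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in GTF", call. = FALSE)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    bad <- which(is.na(gr$transcript_id))
    stop("exon record(s) without transcript_id (record ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  ex <- data.frame(gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  ex$exon_id <- if (!is.null(gr$exon_id) && !anyNA(gr$exon_id)) {
    as.character(gr$exon_id)
  } else {
    paste0(ex$gene_id, ":", ex$start, "-", ex$end)
  }
  annotation(ex)
}

#' Write an annotation as GTF
#' @param ann an [annotation()].
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  ex <- ann$exons
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; exon_id "%s";',
                   ex$gene_id, ex$transcript_id, ex$exon_id)
  lines <- sprintf("%s\tsqtlgxe\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, ex$start, ex$end, ex$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a counts table (features x samples TSV)
#' @param path file path; first column = feature id, header = sample ids.
#' @return integer matrix.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                         stringsAsFactors = FALSE)
  as.matrix(d)
}

#' Write a counts (or any feature x sample) table as TSV
#' @param mat matrix with row and column names.
#' @param path output path.
#' @param id_col name of the feature-id column (default `"feature"`).
#' @export
write_counts <- function(mat, path, id_col = "feature") {
  d <- data.frame(rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (TSV: sample, ril, treatment)
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "ril", "treatment") %in% names(d))) {
    stop("sample sheet must have columns sample, ril, treatment",
         call. = FALSE)
  }
  if (!all(d$treatment %in% c("control", "pb"))) {
    stop("treatment must be 'control' or 'pb'", call. = FALSE)
  }
  d
}

#' Write a phenotype matrix as TSV
#'
#' Columns: `phenotype_id`, `gene_id`, `chrom`, `pos`, then one column per
#' sample.
#' @param pheno a [phenotype_matrix()].
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  d <- cbind(pheno$anchors,
             as.data.frame(pheno$values, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV written by [write_phenotypes()]
#' @param path file path.
#' @param kind phenotype kind.
#' @return a [phenotype_matrix()].
#' @export
read_phenotypes <- function(path, kind = "exon_fraction") {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta <- c("phenotype_id", "gene_id", "chrom", "pos")
  vals <- as.matrix(d[, setdiff(names(d), meta), drop = FALSE])
  rownames(vals) <- d$phenotype_id
  phenotype_matrix(vals, d[, meta], kind)
}

#' Write a generic result table as TSV
#' @param d data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write significant-call locus intervals as BED
#'
#' Emits one BED interval per call, 0-based half-open, centred on the
#' locus (a point interval of 1 bp), named by the target phenotype.
#' @param calls significance-call table.
#' @param path output path.
#' @export
write_calls_bed <- function(calls, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s",
                   calls$locus_chrom,
                   as.integer(calls$locus_pos) - 1L,
                   as.integer(calls$locus_pos),
                   calls$phenotype_id,
                   format(calls$p, digits = 4))
  writeLines(lines, path)
  invisible(path)
}
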