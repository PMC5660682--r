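#' Gene/transcript/exon annotation
#'
#' Container for the exon structure of a transcriptome: genes own one or
#' more transcripts, transcripts own ordered, non-overlapping exons.
#' Coordinates are 1-based closed intervals (the GTF convention). Exons
#' drawn from a shared per-gene pool keep a stable `exon_id`, so an exon
#' shared by several isoforms of a gene is represented once per transcript
#' under the same id — this is the exon-to-transcript membership map.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`,
#'   `exon_id`, `chrom`, `start`, `end`, `strand`.
#' @return an object of class `annotation` with elements `exons` (as given,
#'   sorted) and `genes` (one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `anchor_pos` = midpoint of the gene span, used as the
#'   genomic anchor of the gene's phenotypes).
#' @export
annotation <- function(exons) {
  need <- c("gene_id", "transcript_id", "exon_id", "chrom", "start", "end",
            "strand")
  if (!is.data.frame(exons) || !all(need %in% names(exons))) {
    stop("`exons` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start),
                 need]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) {
    stop("exon end < start", call. = FALSE)
  }
  ## transcripts belong to exactly one gene
  tx_gene <- unique(exons[, c("transcript_id", "gene_id")])
  if (anyDuplicated(tx_gene$transcript_id)) {
    stop("a transcript maps to more than one gene", call. = FALSE)
  }
  ## exons within a transcript non-overlapping and ordered
  by_tx <- split(exons, exons$transcript_id)
  for (tx in by_tx) {
    if (nrow(tx) > 1L && any(tx$start[-1] <= tx$end[-nrow(tx)])) {
      stop("overlapping exons within transcript ", tx$transcript_id[1],
           call. = FALSE)
    }
    if (length(unique(tx$strand)) != 1L || length(unique(tx$chrom)) != 1L) {
      stop("mixed strand/chromosome within transcript ", tx$transcript_id[1],
           call. = FALSE)
    }
  }
  g_start <- tapply(exons$start, exons$gene_id, min)
  g_end <- tapply(exons$end, exons$gene_id, max)
  g_chrom <- tapply(exons$chrom, exons$gene_id, function(x) x[1])
  g_strand <- tapply(exons$strand, exons$gene_id, function(x) x[1])
  gid <- sort(unique(exons$gene_id))
  genes <- data.frame(gene_id = gid,
                      chrom = as.character(g_chrom[gid]),
                      start = as.integer(g_start[gid]),
                      end = as.integer(g_end[gid]),
                      strand = as.character(g_strand[gid]),
                      stringsAsFactors = FALSE)
  genes$anchor_pos <- as.integer(round((genes$start + genes$end) / 2))
  rownames(genes) <- NULL
  structure(list(exons = exons, genes = genes), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("annotation: %d genes, %d transcripts, %d exon records\n",
              nrow(x$genes), length(unique(x$exons$transcript_id)),
              nrow(x$exons)))
  invisible(x)
}

#' Map transcript ids to gene ids
#' @param ann an [annotation()].
#' @return named character vector (names = transcript ids).
#' @export
transcript_genes <- function(ann) {
  m <- unique(ann$exons[, c("transcript_id", "gene_id")])
  stats::setNames(m$gene_id, m$transcript_id)
}

#' Unique exons with their member transcripts
#' @param ann an [annotation()].
#' @return data.frame, one row per (gene, exon), with a list-column
#'   `transcripts` of member transcript ids.
#' @export
exon_membership <- function(ann) {
  key <- paste(ann$exons$gene_id, ann$exons$exon_id, sep = "\r")
  first <- !duplicated(key)
  out <- ann$exons[first, c("gene_id", "exon_id", "chrom", "start", "end",
                            "strand")]
  out$transcripts <- unname(split(ann$exons$transcript_id, key)[key[first]])
  rownames(out) <- NULL
  out
}

#' Exon structure of one transcript
#' @param ann an [annotation()].
#' @param transcript_id transcript identifier.
#' @return data.frame of the transcript's exons, sorted by coordinate.
#' @export
transcript_model <- function(ann, transcript_id) {
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript: ", transcript_id,
                           call. = FALSE)
  ex[order(ex$start), ]
}

#' Simulate a compact gene/transcript/exon annotation
#'
#' Generates genes laid out along the given chromosomes, each with a pool of
#' non-overlapping exons; every isoform of a gene uses an ordered subset of
#' the pool, so isoforms of multi-isoform genes naturally differ by skipped
#' exons and shared flanks. Both single- and multi-isoform genes are
#' produced (the isoform-count distribution defaults to roughly the split
#' seen in compact animal transcriptomes).
#'
#' @param n_genes number of genes (>= 1).
#' @param isoforms_per_gene named probability vector: names are isoform
#'   counts, values their probabilities.
#' @param exons_per_transcript named probability vector for the number of
#'   exons in each transcript.
#' @param chroms chromosomes to place genes on.
#' @param chrom_length_bp chromosome length in bp (recycled over `chroms`).
#' @param retention_prob probability that an isoform of a multi-isoform
#'   gene retains one of its introns, i.e. fuses an adjacent exon pair
#'   into a single exon spanning the intron (default 0.15; intron
#'   retention is among the most common alternative-splicing events).
#' @param seed integer RNG seed (required).
#' @return an [annotation()]; deterministic given `seed`.
#' @export
make_annotation <- function(n_genes,
                            isoforms_per_gene = c(`1` = 0.5, `2` = 0.3,
                                                  `4` = 0.2),
                            exons_per_transcript = c(`2` = 0.25, `3` = 0.35,
                                                     `4` = 0.25, `6` = 0.15),
                            chroms = c("2L", "2R", "3L", "3R", "X"),
                            chrom_length_bp = 2e6,
                            retention_prob = 0.15,
                            seed) {
  n_genes <- check_count(n_genes, "n_genes")
  with_seed(seed, {
    chrom_of <- sample(chroms, n_genes, replace = TRUE)
    n_iso <- sample_dist_spec(isoforms_per_gene, n_genes)
    if (any(n_iso < 1L)) stop("isoform counts must be >= 1", call. = FALSE)
    rows <- vector("list", n_genes)
    ## genes placed sequentially per chromosome with random gaps
    cursor <- stats::setNames(rep(1000L, length(chroms)), chroms)
    for (g in seq_len(n_genes)) {
      gid <- sprintf("g%04d", g)
      chrom <- chrom_of[g]
      k <- n_iso[g]
      n_ex_tx <- sample_dist_spec(exons_per_transcript, k)
      pool_n <- max(n_ex_tx) + if (k > 1L) 2L else 0L
      ex_len <- sample(80:500, pool_n, replace = TRUE)
      intron_len <- sample(60:1500, pool_n, replace = TRUE)
      start <- cursor[chrom] + sample(500:5000, 1L)
      starts <- start + cumsum(c(0L, (ex_len + intron_len)[-pool_n]))
      ends <- starts + ex_len - 1L
      cursor[chrom] <- ends[pool_n]
      strand <- sample(c("+", "-"), 1L)
      for (t in seq_len(k)) {
        n_ex <- min(n_ex_tx[t], pool_n)
        ## keep first and last pool exons so isoforms share outer structure
        if (pool_n <= 2L || n_ex >= pool_n) {
          pick <- seq_len(pool_n)[seq_len(n_ex)]
        } else if (n_ex <= 2L) {
          pick <- c(1L, pool_n)[seq_len(n_ex)]
        } else {
          pick <- c(1L, sort(sample(2:(pool_n - 1L), n_ex - 2L)), pool_n)
        }
        ex <- data.frame(
          gene_id = gid,
          transcript_id = sprintf("%s.t%d", gid, t),
          exon_id = sprintf("%s.e%d", gid, pick),
          chrom = chrom, start = starts[pick], end = ends[pick],
          strand = strand, stringsAsFactors = FALSE)
        ## occasionally retain an intron: fuse an adjacent exon pair into
        ## one exon spanning the intervening intron
        if (k > 1L && nrow(ex) >= 2L &&
            stats::runif(1) < retention_prob) {
          j <- sample.int(nrow(ex) - 1L, 1L)
          ex$end[j] <- ex$end[j + 1L]
          ex$exon_id[j] <- paste0(ex$exon_id[j], "ri")
          ex <- ex[-(j + 1L), ]
        }
        rows[[length(rows) + 1L]] <- ex
      }
    }
    annotation(do.call(rbind, rows))
  })
}
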