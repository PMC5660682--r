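#' Classify the alternative-splicing event(s) between two isoforms
#'
#' Simplified transcript-pair event typing in the style of splicing
#' landscape tools: the two exon chains are compared over their overlapping
#' genomic span and the differences are labeled with the four canonical AS
#' event types, strand-aware for donor/acceptor:
#' \describe{
#'   \item{intron_retention}{an intron of one transcript lies entirely
#'     inside an exon of the other.}
#'   \item{exon_skipping}{one or more internal exons of one transcript are
#'     absent from the other, whose single intron spans them while sharing
#'     both outer splice sites with the flanking introns.}
#'   \item{alt_donor}{a pair of introns sharing the acceptor (3' splice
#'     site) but differing at the donor (5' splice site).}
#'   \item{alt_acceptor}{the converse.}
#' }
#' Remaining structural differences — e.g. alternative first/last exons —
#' are labeled `other` (transcription start/end effects, not splicing
#' events proper). Identical chains give the empty set. The classification
#' is symmetric in argument order and invariant under coordinate
#' translation; under strand reversal with mirrored coordinates, alt_donor
#' and alt_acceptor swap while skipping and retention are unchanged.
#'
#' @param tx_a,tx_b exon tables for the two transcripts (data.frames with
#'   `chrom`, `start`, `end`, `strand`; 1-based closed), e.g. from
#'   [transcript_model()]. Must share chromosome and strand.
#' @return character vector (possibly empty), subset of
#'   `c("exon_skipping", "intron_retention", "alt_donor", "alt_acceptor",
#'   "other")`.
#' @export
classify_event <- function(tx_a, tx_b) {
  a <- tx_a[order(tx_a$start), c("chrom", "start", "end", "strand")]
  b <- tx_b[order(tx_b$start), c("chrom", "start", "end", "strand")]
  if (a$chrom[1] != b$chrom[1] || a$strand[1] != b$strand[1]) {
    stop("transcripts must share chromosome and strand", call. = FALSE)
  }
  strand <- a$strand[1]
  introns <- function(ex) {
    if (nrow(ex) < 2L) {
      return(data.frame(start = numeric(0), end = numeric(0)))
    }
    data.frame(start = ex$end[-nrow(ex)] + 1, end = ex$start[-1] - 1)
  }
  ia <- introns(a); ib <- introns(b)
  span <- c(max(min(a$start), min(b$start)), min(max(a$end), max(b$end)))
  within_span <- function(iv) iv[iv$start >= span[1] & iv$end <= span[2], ,
                                 drop = FALSE]
  ia <- within_span(ia); ib <- within_span(ib)

  events <- character(0)
  ia$done <- rep(FALSE, nrow(ia))
  ib$done <- rep(FALSE, nrow(ib))

  ## exon skipping: an intron of y spans >= 1 whole exon of x and shares
  ## its boundaries with two distinct introns of x
  skip_scan <- function(x_ex, x_in, y_in) {
    hits <- list(x = logical(nrow(x_in)), y = logical(nrow(y_in)),
                 found = FALSE)
    for (j in seq_len(nrow(y_in))) {
      il <- which(x_in$start == y_in$start[j])
      ir <- which(x_in$end == y_in$end[j])
      if (length(il) == 1L && length(ir) == 1L && il < ir) {
        covered <- any(x_ex$start > y_in$start[j] &
                         x_ex$end < y_in$end[j])
        if (covered) {
          hits$found <- TRUE
          hits$y[j] <- TRUE
          hits$x[il] <- TRUE; hits$x[ir] <- TRUE
        }
      }
    }
    hits
  }
  h1 <- skip_scan(a, ia, ib)
  h2 <- skip_scan(b, ib, ia)
  if (h1$found || h2$found) events <- c(events, "exon_skipping")
  ia$done <- ia$done | h1$x | h2$y
  ib$done <- ib$done | h1$y | h2$x

  ## intron retention: an intron of x entirely inside an exon of y
  retained <- function(x_in, y_ex) {
    vapply(seq_len(nrow(x_in)), function(i) {
      any(y_ex$start <= x_in$start[i] & y_ex$end >= x_in$end[i])
    }, logical(1))
  }
  ra <- if (nrow(ia)) retained(ia, b) else logical(0)
  rb <- if (nrow(ib)) retained(ib, a) else logical(0)
  if (any(ra) || any(rb)) events <- c(events, "intron_retention")
  ia$done <- ia$done | ra
  ib$done <- ib$done | rb

  ## alt donor / acceptor among unexplained introns
  for (i in which(!ia$done)) {
    for (j in which(!ib$done)) {
      same_start <- ia$start[i] == ib$start[j]
      same_end <- ia$end[i] == ib$end[j]
      if (same_start && !same_end) {
        ## differ at the right (higher-coordinate) boundary:
        ## acceptor on +, donor on -
        events <- c(events, if (strand == "+") "alt_acceptor" else
          "alt_donor")
      } else if (same_end && !same_start) {
        events <- c(events, if (strand == "+") "alt_donor" else
          "alt_acceptor")
      }
    }
  }

  events <- sort(unique(events))
  if (length(events) == 0L) {
    same_struct <- nrow(a) == nrow(b) &&
      all(a$start == b$start) && all(a$end == b$end)
    if (!same_struct) events <- "other"
  }
  events
}

#' Tally AS event types among significant sQTL genes
#'
#' For every distinct gene in the call table, classifies all isoform pairs
#' of the gene and tallies the event types. A pair may contribute several
#' types; counts are reported both per pair (`n_pairs`: number of
#' transcript pairs exhibiting the type) and per gene (`n_genes`: number
#' of genes with at least one pair exhibiting it). Genes are deduplicated
#' before counting, so repeated calls on one gene contribute once;
#' single-isoform genes contribute nothing.
#'
#' @param calls significance-call table with a `gene_id` column.
#' @param annotation an [annotation()].
#' @return data.frame with columns `event`, `n_pairs`, `n_genes`, one row
#'   per event type (zero rows included for types not observed).
#' @export
summarize_events <- function(calls, annotation) {
  types <- c("exon_skipping", "intron_retention", "alt_donor",
             "alt_acceptor", "other")
  n_pairs <- stats::setNames(integer(length(types)), types)
  n_genes <- stats::setNames(integer(length(types)), types)
  genes <- unique(calls$gene_id)
  tx_gene <- transcript_genes(annotation)
  for (g in genes) {
    txs <- names(tx_gene)[tx_gene == g]
    if (length(txs) < 2L) next
    gene_types <- character(0)
    pairs <- utils::combn(txs, 2, simplify = FALSE)
    for (pr in pairs) {
      ev <- classify_event(transcript_model(annotation, pr[1]),
                           transcript_model(annotation, pr[2]))
      n_pairs[ev] <- n_pairs[ev] + 1L
      gene_types <- union(gene_types, ev)
    }
    n_genes[gene_types] <- n_genes[gene_types] + 1L
  }
  data.frame(event = types, n_pairs = as.integer(n_pairs),
             n_genes = as.integer(n_genes), row.names = NULL,
             stringsAsFactors = FALSE)
}
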