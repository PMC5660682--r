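#' Storey q-values
#'
#' Transforms p-values into estimated false discovery rates. The null
#' proportion pi0 is estimated by Storey's smoother: pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda)) over a grid of tuning quantiles,
#' smoothed with a cubic spline and evaluated at the largest lambda. The
#' q-value of each p is pi0 * m * p / rank(p), made monotone by a
#' cumulative minimum from the largest p down, and capped at 1. With
#' `pi0 = 1` this reduces exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs allowed; they get NA
#'   q-values and are ignored in the pi0 estimate).
#' @param lambda_grid tuning quantiles (default 0.05 to 0.95 by 0.05).
#' @param pi0 optionally force the null proportion instead of estimating.
#' @return list with `q` (same length as `p`), `pi0`, and `pi0_lambda`
#'   (the raw grid estimates).
#' @export
qvalues <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                    pi0 = NULL) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(list(q = p, pi0 = NA_real_, pi0_lambda = NULL))
  pi0_lambda <- vapply(lambda_grid,
                       function(l) mean(pv > l) / (1 - l), numeric(1))
  if (is.null(pi0)) {
    if (m < 100L || length(unique(pv)) < 4L) {
      ## too few values for the smoother to be stable
      pi0 <- 1
    } else {
      sp <- stats::smooth.spline(lambda_grid, pi0_lambda, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda_grid))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("`pi0` must be in (0, 1]", call. = FALSE)
  }
  o <- order(pv, decreasing = TRUE)
  ranks <- rank(pv, ties.method = "max")
  qv <- pi0 * m * pv / ranks
  qv[o] <- cummin(qv[o])
  qv <- pmin(qv, 1)
  q <- rep(NA_real_, length(p))
  q[ok] <- qv
  list(q = q, pi0 = pi0, pi0_lambda = pi0_lambda)
}

#' Attach q-values to an association table
#'
#' @param assoc association table from [sqtl_scan()] (column `p`).
#' @param ... passed to [qvalues()].
#' @return `assoc` with columns `q` added and attribute `"pi0"`.
#' @export
add_qvalues <- function(assoc, ...) {
  qv <- qvalues(assoc$p, ...)
  assoc$q <- qv$q
  attr(assoc, "pi0") <- qv$pi0
  assoc
}

#' Call significant sQTL associations
#'
#' An association is significant when both its p-value and its q-value
#' (estimated FDR) pass their thresholds; the conventional cutoffs are
#' p <= 1e-4 with FDR <= 0.39.
#'
#' @param assoc association table with columns `p` and `q`.
#' @param p_thresh p-value threshold (default 1e-4).
#' @param q_thresh q-value threshold (default 0.39).
#' @param best_per_gene also reduce to the best locus per gene
#'   (default FALSE).
#' @return the qualifying rows, with a `significant` flag column (all
#'   TRUE).
#' @export
call_significant <- function(assoc, p_thresh = 1e-4, q_thresh = 0.39,
                             best_per_gene = FALSE) {
  if (is.null(assoc$q)) stop("q-values missing; run add_qvalues() first",
                             call. = FALSE)
  keep <- !is.na(assoc$p) & !is.na(assoc$q) &
    assoc$p <= p_thresh & assoc$q <= q_thresh
  out <- assoc[keep, , drop = FALSE]
  if (best_per_gene && nrow(out) > 0L) {
    out <- out[order(out$gene_id, out$p), ]
    out <- out[!duplicated(out$gene_id), ]
  }
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Combine sQTL calls from the two phenotype methods
#'
#' Unions the significant calls of the exon-fraction and isoform-dosage
#' methods on a shared (gene, locus) key and labels each as found by one or
#' both methods. The union count obeys nUnion = nA + nB - nShared.
#'
#' @param calls_exon,calls_isoform significance-call tables with columns
#'   `gene_id`, `locus_chrom`, `locus_pos` (and `p` for deduplication).
#' @return union table with a `overlap` label (`exon_only`,
#'   `isoform_only`, `shared`); counts are attached as attribute
#'   `"counts"` (`nA`, `nB`, `nShared`, `nUnion`). Duplicate keys within a
#'   method are deduplicated to the best p with a warning.
#' @export
combine_methods <- function(calls_exon, calls_isoform) {
  key <- function(d) paste(d$gene_id, d$locus_chrom, d$locus_pos, sep = "\r")
  dedup <- function(d, label) {
    k <- key(d)
    if (anyDuplicated(k)) {
      warning("duplicate (gene, locus) keys in ", label,
              " calls; keeping best p", call. = FALSE)
      p <- if (!is.null(d$p)) d$p else rep(0, nrow(d))
      d <- d[order(k, p), ]
      d <- d[!duplicated(key(d)), ]
    }
    d
  }
  a <- dedup(calls_exon, "exon-fraction")
  b <- dedup(calls_isoform, "isoform-dosage")
  ka <- key(a); kb <- key(b)
  shared <- intersect(ka, kb)
  a$overlap <- ifelse(ka %in% shared, "shared", "exon_only")
  b_only <- b[!(kb %in% shared), , drop = FALSE]
  if (nrow(b_only) > 0L) b_only$overlap <- "isoform_only"
  common_cols <- intersect(names(a), names(b_only))
  out <- rbind(a[, common_cols, drop = FALSE],
               b_only[, common_cols, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "counts") <- list(nA = nrow(a), nB = nrow(b),
                              nShared = length(shared),
                              nUnion = nrow(out))
  out
}

#' Classify sQTL calls as cis or trans
#'
#' An sQTL is local (cis) when its locus lies on the same chromosome as the
#' target phenotype's anchor and within `cis_window` bp of it (closed
#' bound); otherwise distal (trans). Rows whose chromosomes cannot be
#' resolved are labeled `unclassified`.
#'
#' @param calls table with columns `pheno_chrom`, `pheno_pos`,
#'   `locus_chrom`, `locus_pos`.
#' @param cis_window distance threshold in bp (default 1 Mb).
#' @return `calls` with a `cis_trans` column.
#' @export
classify_cis_trans <- function(calls, cis_window = 1e6) {
  lab <- rep("trans", nrow(calls))
  same <- !is.na(calls$pheno_chrom) & !is.na(calls$locus_chrom) &
    calls$pheno_chrom == calls$locus_chrom
  near <- same & abs(calls$pheno_pos - calls$locus_pos) <= cis_window
  lab[near] <- "cis"
  lab[is.na(calls$pheno_chrom) | is.na(calls$locus_chrom)] <- "unclassified"
  calls$cis_trans <- lab
  calls
}
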