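#' Paired differential expression between environments
#'
#' The auxiliary expression-level contrast: per transcript, ordinary least
#' squares of normalized log2 expression on treatment with the RIL as a
#' categorical covariate (`Y ~ treatment + RIL`), which in the balanced
#' paired design is the paired treatment contrast. Expression is
#' counts-per-million on the log2 scale with a pseudocount. The MA
#' quantities follow the usual convention: M = log2(Pb mean / control
#' mean), A = (log2(control mean) + log2(Pb mean)) / 2, computed from mean
#' per-group CPM with the same pseudocount.
#'
#' @param transcript_counts integer matrix, transcripts x samples.
#' @param samples sample sheet; RILs without both treatments are excluded
#'   with a warning.
#' @param pseudocount added to (normalized) counts before logs (default 1).
#' @param norm `"cpm"` (default) normalizes by library size to counts per
#'   million; `"none"` uses raw counts (useful when library sizes are known
#'   to be equal).
#' @return data.frame with columns `transcript`, `M` (log2 fold change),
#'   `A` (mean log2 abundance), `estimate` (treatment coefficient on the
#'   log2 CPM scale), `p`, `fdr` (Benjamini-Hochberg).
#' @export
differential_expression <- function(transcript_counts, samples,
                                    pseudocount = 1,
                                    norm = c("cpm", "none")) {
  norm <- match.arg(norm)
  samples <- samples[match(colnames(transcript_counts), samples$sample), ]
  if (anyNA(samples$sample)) {
    stop("count columns missing from sample sheet", call. = FALSE)
  }
  tab <- table(samples$ril, samples$treatment)
  paired <- rownames(tab)[tab[, "control"] >= 1 & tab[, "pb"] >= 1]
  drop <- !(samples$ril %in% paired)
  if (any(drop)) {
    warning("excluding unpaired RIL(s): ",
            paste(unique(samples$ril[drop]), collapse = ", "), call. = FALSE)
    samples <- samples[!drop, ]
    transcript_counts <- transcript_counts[, samples$sample, drop = FALSE]
  }
  cpm <- if (norm == "cpm") {
    libsize <- colSums(transcript_counts)
    if (any(libsize == 0)) stop("sample(s) with zero total counts",
                                call. = FALSE)
    t(t(transcript_counts) / libsize) * 1e6
  } else {
    transcript_counts
  }
  Y <- log2(cpm + pseudocount)

  X <- stats::model.matrix(~ treatment + ril,
                           data = transform(samples,
                                            treatment = factor(treatment,
                                              c("control", "pb")),
                                            ril = factor(ril)))
  qx <- qr(X)
  df <- ncol(Y) - qx$rank
  ## all transcripts share the design: one decomposition serves every fit
  coefs <- t(qr.coef(qx, t(Y)))
  resid <- t(qr.resid(qx, t(Y)))
  rss <- rowSums(resid^2)
  xtx_inv <- chol2inv(qr.R(qx))
  j <- match("treatmentpb", colnames(X))
  se <- sqrt(rss / df * xtx_inv[j, j])
  est <- coefs[, j]
  tstat <- est / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  ## numerically zero residual variance: a zero estimate carries no
  ## evidence (identical columns), a nonzero one is an exact fit
  degenerate <- rss <= 1e-12 * (rowSums(Y^2) + 1)
  p[degenerate] <- ifelse(abs(est[degenerate]) > 1e-8, 0, 1)

  is_pb <- samples$treatment == "pb"
  mean_p <- rowMeans(cpm[, is_pb, drop = FALSE])
  mean_c <- rowMeans(cpm[, !is_pb, drop = FALSE])
  M <- log2(mean_p + pseudocount) - log2(mean_c + pseudocount)
  A <- (log2(mean_c + pseudocount) + log2(mean_p + pseudocount)) / 2

  data.frame(transcript = rownames(transcript_counts),
             M = M, A = A, estimate = est, p = p,
             fdr = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
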