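#' Quantile normalization across samples
#'
#' Forces every sample column to the same empirical distribution: the
#' cross-sample mean order-statistic vector. Each column's non-missing
#' values are ranked and replaced by the reference order statistic at that
#' rank; ties receive the mean of the tied target values. Missing cells
#' stay missing; columns with differing numbers of non-missing values are
#' matched to the reference by interpolation on rank quantiles.
#'
#' @param mat numeric matrix, phenotypes x samples (>= 2 columns).
#' @return matrix of the same shape; every pair of complete columns shares
#'   an identical multiset of values.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2L) {
    stop("`mat` must be a matrix with >= 2 sample columns", call. = FALSE)
  }
  n_ok <- colSums(!is.na(mat))
  if (any(n_ok == 0L)) {
    bad <- colnames(mat)[n_ok == 0L]
    if (is.null(bad)) bad <- which(n_ok == 0L)
    stop("all-missing sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  N <- nrow(mat)
  pgrid <- (seq_len(N) - 0.5) / N
  ## reference: mean across columns of per-column sorted values, each
  ## interpolated onto a common rank-quantile grid
  qcols <- vapply(seq_len(ncol(mat)), function(j) {
    x <- sort(mat[, j])
    nj <- length(x)
    if (nj == N) return(x)
    stats::approx((seq_len(nj) - 0.5) / nj, x, xout = pgrid, rule = 2)$y
  }, numeric(N))
  ref_full <- rowMeans(qcols)
  ref_cum <- cumsum(ref_full)

  out <- mat
  for (j in seq_len(ncol(mat))) {
    ok <- which(!is.na(mat[, j]))
    x <- mat[ok, j]
    nj <- length(x)
    ref <- if (nj == N) ref_full else {
      stats::approx(pgrid, ref_full, xout = (seq_len(nj) - 0.5) / nj,
                    rule = 2)$y
    }
    rc0 <- c(0, cumsum(ref))
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    ## mean of the target values over each tie run
    out[ok, j] <- (rc0[hi + 1L] - rc0[lo]) / (hi - lo + 1L)
  }
  out
}

#' Remove leading principal components as expression confounders
#'
#' Centers each phenotype across samples, computes the sample-space
#' principal components of the centered matrix, and regresses the top
#' `n_pc` components out of every phenotype. Unmodelled technical and
#' environmental structure (batch, library composition) concentrates in the
#' leading components; removing them sharpens the downstream association
#' scan. Defaults follow the two splicing traits' conventions: 3 components
#' for exon fractions, 4 for transcript-level values.
#'
#' When `protect` is supplied (e.g. the 0/1 environment vector), each
#' principal component is first residualized on it, so that signal aligned
#' with the protected contrast — the very contrast tested later — is not
#' absorbed into the removed confounders.
#'
#' Missing cells are imputed with the phenotype mean for the decomposition
#' and restored to missing afterwards.
#'
#' @param mat numeric matrix, phenotypes x samples.
#' @param n_pc number of components to remove (0 <= n_pc < n samples).
#' @param protect optional numeric vector (length = samples) to protect
#'   from removal; default `NULL` (plain PCA removal).
#' @return list with `matrix` (residuals, centered per phenotype) and
#'   `report` (class `normalization_report`: `n_pc`, `var_explained`,
#'   `basis` — the removed sample-space components, against which the
#'   residuals are orthogonal).
#' @export
remove_pcs <- function(mat, n_pc, protect = NULL) {
  if (!is.matrix(mat)) stop("`mat` must be a matrix", call. = FALSE)
  n_pc <- check_count(n_pc, "n_pc", min = 0L)
  if (n_pc >= ncol(mat)) {
    stop("`n_pc` must be smaller than the number of samples", call. = FALSE)
  }
  na_mask <- is.na(mat)
  work <- mat
  if (any(na_mask)) {
    rm_mean <- rowMeans(mat, na.rm = TRUE)
    work[na_mask] <- rm_mean[row(mat)[na_mask]]
  }
  work <- work - rowMeans(work)
  if (n_pc == 0L) {
    work[na_mask] <- NA_real_
    return(list(matrix = work,
                report = structure(list(n_pc = 0L,
                                        var_explained = numeric(0)),
                                   class = "normalization_report")))
  }
  sv <- svd(work, nu = 0, nv = min(n_pc, ncol(mat) - 1L))
  V <- sv$v[, seq_len(n_pc), drop = FALSE]
  var_explained <- (sv$d^2 / sum(sv$d^2))[seq_len(n_pc)]
  if (!is.null(protect)) {
    if (length(protect) != ncol(mat)) {
      stop("`protect` must have one value per sample", call. = FALSE)
    }
    pc_ <- protect - mean(protect)
    if (sum(pc_^2) > 0) {
      V <- V - pc_ %*% (crossprod(pc_, V) / sum(pc_^2))
    }
  }
  ## project out span(V): residual = Yc (I - V (V'V)^-1 V')
  keep <- colSums(V^2) > 1e-12
  V <- V[, keep, drop = FALSE]
  if (ncol(V) > 0L) {
    coef <- solve(crossprod(V), crossprod(V, t(work)))
    work <- work - t(V %*% coef)
  }
  work[na_mask] <- NA_real_
  list(matrix = work,
       report = structure(list(n_pc = n_pc, var_explained = var_explained,
                               basis = V),
                          class = "normalization_report"))
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf("removed %d PC(s); variance explained: %s\n", x$n_pc,
              paste(sprintf("%.3f", x$var_explained), collapse = ", ")))
  invisible(x)
}

#' Standard normalization for a splicing phenotype matrix
#'
#' Convenience wrapper: quantile normalization followed by PC removal, with
#' the conventional component counts per phenotype kind (3 for exon
#' fractions, 4 for isoform dosage).
#'
#' @param pheno a [phenotype_matrix()] or plain matrix.
#' @param n_pc number of PCs to remove; default by kind as above.
#' @param protect optional protected vector (see [remove_pcs()]).
#' @return same class as `pheno`, values normalized; the report is attached
#'   as attribute `"report"`.
#' @export
normalize_phenotypes <- function(pheno, n_pc = NULL, protect = NULL) {
  is_pm <- inherits(pheno, "phenotype_matrix")
  mat <- if (is_pm) pheno$values else pheno
  if (is.null(n_pc)) {
    n_pc <- if (is_pm && pheno$kind == "isoform_dosage") 4L else 3L
  }
  qn <- quantile_normalize(mat)
  res <- remove_pcs(qn, n_pc, protect = protect)
  if (is_pm) {
    pheno$values <- res$matrix
    attr(pheno, "report") <- res$report
    pheno
  } else {
    structure(res$matrix, report = res$report)
  }
}
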