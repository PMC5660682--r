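## Nested genotype-by-environment linear models and their partial F-tests.
##
## Both splicing traits are tested with a pair of nested ordinary
## least-squares models at every (phenotype, locus) pair:
##
## exon/transcript fraction trait (one response per sample):
##   H0: Y_n = mu + bE * E_n + eps_n
##   HA: Y_n = mu + bE * E_n + sum_i (bG_i * G_ij + bGxE_i * G_ij * E_n) + eps_n
##
## isoform dosage trait (long response over samples x isoforms k):
##   H0: Y_nk = mu_k + sum_i bG_i * G_ij + sum_k bE_k * T_k * E_n + eps_nk
##   HA: adds per-isoform genotype and genotype x environment x isoform
##       blocks (joint partial F over both added blocks).
##
## The eight founder-probability columns sum to one and are collinear with
## the intercept; one founder (default A8) is dropped from every genotype
## and interaction block. The F statistic is invariant to which founder is
## dropped because the column space is unchanged.

## Partial F-test between nested OLS designs, via pivoted QR.
partial_f_test <- function(X0, X1, y) {
  n <- length(y)
  q0 <- qr(X0)
  q1 <- qr(X1)
  r0 <- sum(qr.resid(q0, y)^2)
  r1 <- sum(qr.resid(q1, y)^2)
  df1 <- q1$rank - q0$rank
  df2 <- n - q1$rank
  scale <- sum(y^2) + 1
  flagged <- df1 < 1L || df2 < 1L
  if (flagged) {
    return(list(F = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                rss0 = r0, rss1 = r1, rank0 = q0$rank, rank1 = q1$rank,
                flagged = TRUE))
  }
  if (r1 < 1e-12 * scale) {
    ## residual variance numerically zero
    if (r0 - r1 < 1e-12 * scale) {
      Fstat <- 0; p <- 1   # constant (or perfectly H0-fit) response
    } else {
      Fstat <- Inf; p <- 0
    }
  } else {
    Fstat <- ((r0 - r1) / df1) / (r1 / df2)
    Fstat <- max(Fstat, 0)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  list(F = Fstat, df1 = df1, df2 = df2, p = p, rss0 = r0, rss1 = r1,
       rank0 = q0$rank, rank1 = q1$rank, flagged = FALSE)
}

model_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  rank <- fit$rank
  structure(list(coefficients = fit$coefficients,
                 rss = sum(fit$residuals^2),
                 df_residual = length(y) - rank,
                 rank = rank,
                 residuals = fit$residuals),
            class = "model_fit")
}

## Drop the reference founder column, plus any column with zero total
## probability mass: a founder absent from the sample set carries no
## information and would only make the design rank-deficient. The F
## statistic is unchanged by either removal.
drop_ref <- function(G, ref_founder) {
  if (!ref_founder %in% colnames(G)) {
    stop("reference founder '", ref_founder, "' not among founder columns",
         call. = FALSE)
  }
  out <- G[, setdiff(colnames(G), ref_founder), drop = FALSE]
  out[, colSums(abs(out)) > 0, drop = FALSE]
}

check_env <- function(E) {
  if (!all(E %in% c(0, 1)) || length(unique(E)) < 2L) {
    stop("`E` must contain both 0 (control) and 1 (treated)", call. = FALSE)
  }
  as.numeric(E)
}

#' Fit the nested G x E models for a univariate splicing phenotype
#'
#' Tests whether founder genotype probabilities at one locus, and their
#' interaction with the environment, explain a single splicing trait
#' (an exon fraction), via a partial F-test between
#' `Y ~ E` (null) and `Y ~ E + G + G:E` (alternative). Missing phenotype
#' values are removed pairwise. One founder column (`ref_founder`) is
#' dropped from the genotype and interaction blocks; the F statistic does
#' not depend on the choice.
#'
#' @param y numeric phenotype vector (one value per sample; NAs allowed).
#' @param G numeric matrix, samples x founders, rows on the probability
#'   simplex; column names are founder labels.
#' @param E environment indicator (0 = control, 1 = treated).
#' @param ref_founder founder column dropped as reference (default `"A8"`).
#' @return list with `h0`, `ha` (class `model_fit`: coefficients, rss,
#'   df_residual, residuals) and `record`, a one-row data.frame with
#'   `F`, `df1`, `df2`, `p`, `top_founder` (largest absolute interaction
#'   coefficient) and `flagged` (TRUE when the fit is rank-deficient beyond
#'   the planned reference drop or has too few observations; then `p` is
#'   NA, not 1).
#' @export
fit_exon_model <- function(y, G, E, ref_founder = "A8") {
  E <- check_env(E)
  ok <- !is.na(y)
  y <- y[ok]; Gk <- G[ok, , drop = FALSE]; Ek <- E[ok]
  flagged_pre <- length(unique(Ek)) < 2L || min(table(Ek)) < 2L
  Gd <- drop_ref(Gk, ref_founder)
  X0 <- cbind(`(Intercept)` = 1, E = Ek)
  GxE <- Gd * Ek
  colnames(GxE) <- paste0(colnames(Gd), ":E")
  X1 <- cbind(X0, Gd, GxE)
  expected_rank <- ncol(X1)
  ft <- partial_f_test(X0, X1, y)
  flagged <- flagged_pre || ft$flagged || ft$rank1 < expected_rank
  h0 <- model_fit(X0, y)
  ha <- model_fit(X1, y)
  inter <- ha$coefficients[colnames(GxE)]
  top <- if (all(is.na(inter))) NA_character_ else
    sub(":E$", "", names(inter)[which.max(abs(inter))])
  record <- data.frame(F = if (flagged) NA_real_ else ft$F,
                       df1 = ft$df1, df2 = ft$df2,
                       p = if (flagged) NA_real_ else ft$p,
                       top_founder = top, flagged = flagged,
                       stringsAsFactors = FALSE)
  list(h0 = h0, ha = ha, record = record)
}

## Build the long-format designs for the isoform-dosage model.
isoform_designs <- function(Y, G, E, ref_founder, tested_block) {
  n <- nrow(Y); k <- ncol(Y)
  y <- as.vector(Y)                       # sample-major within isoform
  Tk <- factor(rep(seq_len(k), each = n))
  El <- rep(E, k)
  Gd <- drop_ref(G, ref_founder)[rep(seq_len(n), k), , drop = FALSE]
  MT <- stats::model.matrix(~ 0 + Tk)     # mu_k block
  colnames(MT) <- paste0("iso", seq_len(k))
  ET <- MT * El                           # per-isoform environment block
  colnames(ET) <- paste0("E:iso", seq_len(k))
  ## per-isoform genotype block for isoforms 2..k (isoform 1 = reference,
  ## shared genotype main effect carries the baseline)
  GT <- do.call(cbind, lapply(seq_len(k)[-1], function(kk) {
    m <- Gd * MT[, kk]
    colnames(m) <- paste0(colnames(Gd), ":iso", kk)
    m
  }))
  ## three-way block, all isoforms (no shared G:E term elsewhere)
  GET <- do.call(cbind, lapply(seq_len(k), function(kk) {
    m <- Gd * El * MT[, kk]
    colnames(m) <- paste0(colnames(Gd), ":E:iso", kk)
    m
  }))
  base <- cbind(MT, ET, Gd)
  if (tested_block == "as_printed") {
    list(y = y, X0 = base, X1 = cbind(base, GT, GET))
  } else {
    list(y = y, X0 = cbind(base, GT), X1 = cbind(base, GT, GET))
  }
}

#' Fit the nested G x E models for an isoform-dosage group
#'
#' Joint test over all isoforms of one gene: the long-format response
#' stacks the (normalized) values of every isoform across samples, with
#' per-isoform intercepts and per-isoform environment effects in both
#' models. Under `tested_block = "as_printed"` the null carries a genotype
#' main effect shared across isoforms and the alternative adds
#' genotype-by-isoform and genotype-by-environment-by-isoform blocks
#' (joint partial F). Under `"gxe_only"` the null also carries the
#' genotype-by-isoform block, so only the three-way interaction is tested.
#'
#' @param group an `isoform_group` (see [isoform_groups()]): complete
#'   samples x isoforms block, >= 2 isoforms.
#' @param G founder-probability matrix, samples x founders.
#' @param E environment indicator (0/1).
#' @param tested_block `"as_printed"` (default) or `"gxe_only"`.
#' @param ref_founder founder dropped as reference (default `"A8"`).
#' @return as [fit_exon_model()]; `top_founder` is taken over the
#'   three-way interaction block.
#' @export
fit_isoform_model <- function(group, G, E,
                              tested_block = c("as_printed", "gxe_only"),
                              ref_founder = "A8") {
  tested_block <- match.arg(tested_block)
  E <- check_env(E)
  Y <- group$Y
  if (ncol(Y) < 2L) stop("isoform group must have >= 2 isoforms",
                         call. = FALSE)
  ## complete-block requirement: drop samples with any missing isoform value
  ok <- rowSums(is.na(Y)) == 0L
  Y <- Y[ok, , drop = FALSE]
  Gk <- G[ok, , drop = FALSE]
  Ek <- E[ok]
  flagged_pre <- length(unique(Ek)) < 2L || min(table(Ek)) < 2L
  d <- isoform_designs(Y, Gk, Ek, ref_founder, tested_block)
  ft <- partial_f_test(d$X0, d$X1, d$y)
  flagged <- flagged_pre || ft$flagged || ft$rank1 < ncol(d$X1)
  h0 <- model_fit(d$X0, d$y)
  ha <- model_fit(d$X1, d$y)
  three_way <- grep(":E:iso", names(ha$coefficients), fixed = TRUE)
  inter <- ha$coefficients[three_way]
  top <- if (length(inter) == 0L || all(is.na(inter))) NA_character_ else
    sub(":E:iso.*$", "", names(inter)[which.max(abs(inter))])
  record <- data.frame(F = if (flagged) NA_real_ else ft$F,
                       df1 = ft$df1, df2 = ft$df2,
                       p = if (flagged) NA_real_ else ft$p,
                       top_founder = top, flagged = flagged,
                       stringsAsFactors = FALSE)
  list(h0 = h0, ha = ha, record = record)
}
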