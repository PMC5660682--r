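#' Founder-probability genotypes for a multiparental RIL panel
#'
#' A `genotype_tensor` stores, for every recombinant inbred line (RIL) and
#' every genomic locus, the probability that the line's genome at that locus
#' descends from each of the panel founders (eight founders A1..A8 in a
#' DSPR-style design). Probabilities at each (RIL, locus) sum to one.
#'
#' @param probs numeric array of dimension (rils, loci, founders).
#' @param loci data.frame with columns `chrom` and `pos` (bp), sorted by
#'   chromosome then position, positions strictly increasing within chromosome.
#' @param rils character vector of RIL identifiers.
#' @param founders character vector of founder labels (default `A1..A8`).
#'
#' @return an object of class `genotype_tensor` with elements `probs`,
#'   `loci`, `rils`, `founders`.
#' @export
genotype_tensor <- function(probs, loci, rils = NULL, founders = NULL) {
  if (!is.array(probs) || length(dim(probs)) != 3L) {
    stop("`probs` must be a 3-d array (rils x loci x founders)", call. = FALSE)
  }
  d <- dim(probs)
  if (is.null(rils)) rils <- dimnames(probs)[[1]]
  if (is.null(rils)) rils <- sprintf("RIL%03d", seq_len(d[1]))
  if (is.null(founders)) founders <- dimnames(probs)[[3]]
  if (is.null(founders)) founders <- sprintf("A%d", seq_len(d[3]))
  loci <- validate_loci(loci)
  if (nrow(loci) != d[2]) stop("`loci` rows must match dim(probs)[2]",
                               call. = FALSE)
  if (length(rils) != d[1] || length(founders) != d[3]) {
    stop("ril/founder labels do not match array dimensions", call. = FALSE)
  }
  sums <- apply(probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("founder probabilities must sum to 1 at every (ril, locus)",
         call. = FALSE)
  }
  dimnames(probs) <- list(rils, NULL, founders)
  structure(list(probs = probs, loci = loci, rils = rils,
                 founders = founders),
            class = "genotype_tensor")
}

validate_loci <- function(loci) {
  if (!is.data.frame(loci) || !all(c("chrom", "pos") %in% names(loci))) {
    stop("`loci` must be a data.frame with columns chrom, pos", call. = FALSE)
  }
  loci$chrom <- as.character(loci$chrom)
  ord <- order(loci$chrom, loci$pos)
  if (!identical(ord, seq_len(nrow(loci)))) {
    stop("loci must be sorted by (chrom, pos)", call. = FALSE)
  }
  dup <- stats::ave(loci$pos, loci$chrom,
                    FUN = function(p) c(1, diff(p)))
  if (any(dup <= 0)) {
    stop("positions must be strictly increasing within each chromosome",
         call. = FALSE)
  }
  loci[, c("chrom", "pos")]
}

#' @export
print.genotype_tensor <- function(x, ...) {
  cat(sprintf("genotype_tensor: %d RILs x %d loci x %d founders (%s)\n",
              length(x$rils), nrow(x$loci), length(x$founders),
              paste(unique(x$loci$chrom), collapse = ", ")))
  invisible(x)
}

#' Regular locus grid over simulated chromosomes
#'
#' @param chroms chromosome names.
#' @param length_bp chromosome length(s) in bp (recycled).
#' @param spacing distance between adjacent loci in bp (default 10 kb, the
#'   order of spacing of a dense genome-wide RIL genotype grid).
#' @return data.frame with columns `chrom`, `pos`.
#' @export
locus_grid <- function(chroms = c("2L", "2R", "3L", "3R", "X"),
                       length_bp = 2e6, spacing = 1e4) {
  length_bp <- rep_len(length_bp, length(chroms))
  chroms <- as.character(chroms)
  ord <- order(chroms)
  do.call(rbind, lapply(ord, function(i) {
    data.frame(chrom = chroms[i],
               pos = seq(spacing, length_bp[i], by = spacing))
  }))
}

#' Simulate founder-mosaic genotypes for a RIL panel
#'
#' Emulates the outcome of many generations of intercrossing followed by
#' inbreeding: each RIL chromosome is a mosaic of founder haplotypes.
#' The mosaic is generated phenomenologically as a founder-label Markov
#' chain along each chromosome: the label at the first locus is uniform over
#' founders, and between consecutive loci the label switches (to a uniformly
#' chosen different founder) with probability `breakpoint_rate`. With
#' `blur = 0` the result is one-hot founder assignments; with `blur > 0`
#' each (RIL, locus) probability vector is jittered with a Dirichlet draw
#' centred on the mosaic label, emulating HMM genotype uncertainty.
#'
#' @param n_rils number of RILs.
#' @param loci locus grid (data.frame `chrom`, `pos`), e.g. [locus_grid()].
#' @param n_founders number of founders (>= 2; default 8).
#' @param breakpoint_rate probability of a founder switch per locus step.
#' @param blur in [0, 1): 0 keeps one-hot labels; otherwise the Dirichlet
#'   mean is `(1-blur)` on the mosaic founder and `blur` spread uniformly.
#' @param concentration Dirichlet concentration of the blur (larger = less
#'   jitter; default 200).
#' @param seed integer RNG seed (required).
#' @return a [genotype_tensor()].
#' @export
simulate_founder_mosaics <- function(n_rils, loci, n_founders = 8,
                                     breakpoint_rate = 0.05,
                                     blur = 0, concentration = 200,
                                     seed) {
  n_rils <- check_count(n_rils, "n_rils")
  n_founders <- check_count(n_founders, "n_founders", min = 2L)
  if (!is.numeric(breakpoint_rate) || length(breakpoint_rate) != 1L ||
      !is.finite(breakpoint_rate) || breakpoint_rate < 0) {
    stop("`breakpoint_rate` must be a finite non-negative number",
         call. = FALSE)
  }
  blur <- check_prob(blur, "blur")
  if (blur >= 1) stop("`blur` must be < 1", call. = FALSE)
  loci <- validate_loci(loci)
  n_loci <- nrow(loci)
  founders <- sprintf("A%d", seq_len(n_founders))
  rils <- sprintf("RIL%03d", seq_len(n_rils))

  with_seed(seed, {
    ## Markov chain of founder labels, restarted at each chromosome.
    labels <- matrix(0L, n_rils, n_loci)
    chrom_rle <- rle(loci$chrom)
    start <- 1L
    for (len in chrom_rle$lengths) {
      idx <- start:(start + len - 1L)
      labels[, idx[1]] <- sample.int(n_founders, n_rils, replace = TRUE)
      if (len > 1L) {
        for (j in idx[-1]) {
          switch_here <- stats::runif(n_rils) < breakpoint_rate
          prev <- labels[, j - 1L]
          lab <- prev
          if (any(switch_here)) {
            ## uniform over the other founders
            shift <- sample.int(n_founders - 1L, sum(switch_here),
                                replace = TRUE)
            lab[switch_here] <- 1L + (prev[switch_here] - 1L + shift) %% n_founders
          }
          labels[, j] <- lab
        }
      }
      start <- start + len
    }

    probs <- array(0, dim = c(n_rils, n_loci, n_founders))
    if (blur == 0) {
      for (f in seq_len(n_founders)) {
        probs[, , f] <- (labels == f) * 1
      }
    } else {
      onehot <- matrix(0, n_rils * n_loci, n_founders)
      onehot[cbind(seq_len(n_rils * n_loci), as.vector(labels))] <- 1
      mean_mat <- (1 - blur) * onehot + blur / n_founders
      draw <- rdirichlet_mat(mean_mat * concentration)
      probs <- array(draw, dim = c(n_rils, n_loci, n_founders))
    }
    genotype_tensor(probs, loci, rils = rils, founders = founders)
  })
}

#' Most probable founder per (RIL, locus)
#'
#' @param genotypes a [genotype_tensor()].
#' @return integer matrix (RILs x loci) of founder indices.
#' @export
dominant_founder <- function(genotypes) {
  apply(genotypes$probs, c(1, 2), which.max)
}

#' Founder-probability matrix at one locus, expanded to samples
#'
#' @param genotypes a [genotype_tensor()].
#' @param locus locus index.
#' @param rils RIL id per sample (with repeats for the paired design).
#' @return numeric matrix (samples x founders).
#' @export
locus_design <- function(genotypes, locus, rils) {
  idx <- match(rils, genotypes$rils)
  if (anyNA(idx)) {
    stop("unknown RIL id(s): ", paste(unique(rils[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  m <- genotypes$probs[idx, locus, , drop = TRUE]
  m <- matrix(m, nrow = length(idx), ncol = length(genotypes$founders),
              dimnames = list(NULL, genotypes$founders))
  m
}
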