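#' Paired two-environment sample sheet
#'
#' The study design is paired: every RIL is assayed once under control
#' conditions (NaAc) and once under lead exposure (PbAc), giving
#' 2 x n_rils samples (158 for the 79-line panel).
#'
#' @param rils character vector of RIL ids.
#' @return data.frame with columns `sample`, `ril`,
#'   `treatment` (`control` / `pb`).
#' @export
make_sample_sheet <- function(rils) {
  data.frame(sample = c(paste0(rils, "_C"), paste0(rils, "_Pb")),
             ril = c(rils, rils),
             treatment = rep(c("control", "pb"), each = length(rils)),
             stringsAsFactors = FALSE)
}

#' Environment indicator from a sample sheet
#' @param samples sample sheet (see [make_sample_sheet()]).
#' @return integer vector, 0 = control, 1 = lead-treated.
#' @export
environment_vector <- function(samples) {
  tr <- samples$treatment
  if (!all(tr %in% c("control", "pb"))) {
    stop("treatment must be 'control' or 'pb'", call. = FALSE)
  }
  e <- as.integer(tr == "pb")
  if (length(unique(e)) < 2L) stop("both environments must be present",
                                   call. = FALSE)
  e
}

#' Planted-effect registry for the synthetic generator
#'
#' Describes the ground truth planted into a simulated data set, used by
#' recovery tests. Effect kinds:
#' \describe{
#'   \item{cis_gxe}{a founder-specific, environment-conditional shift of one
#'     splicing phenotype of one gene, driven by the locus nearest the gene
#'     (or an explicit `locus_index`).}
#'   \item{trans_hotspot}{one locus applying such shifts to many genes
#'     genome-wide (isoform-usage changes), emulating a trans-sQTL hotspot.}
#' }
#' Effect sizes `delta` are on the latent additive scale the phenotype is
#' built from: the logit of expected exon inclusion for `target = "exon"`,
#' the log of expected transcript count for `target = "isoform"`.
#'
#' @param effects data.frame with columns `kind` (`cis_gxe` /
#'   `trans_hotspot`), `gene_id`, `target` (`exon` / `isoform`),
#'   `locus_index`, `founder`, `delta`. Zero rows = pure null data.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(effects = NULL) {
  if (is.null(effects)) {
    effects <- data.frame(kind = character(), gene_id = character(),
                          target = character(), locus_index = integer(),
                          founder = character(), delta = numeric(),
                          stringsAsFactors = FALSE)
  }
  need <- c("kind", "gene_id", "target", "locus_index", "founder", "delta")
  if (!all(need %in% names(effects))) {
    stop("`effects` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(effects$kind %in% c("cis_gxe", "trans_hotspot"))) {
    stop("unknown effect kind", call. = FALSE)
  }
  if (!all(effects$target %in% c("exon", "isoform"))) {
    stop("`target` must be 'exon' or 'isoform'", call. = FALSE)
  }
  structure(list(effects = effects), class = "sim_truth")
}

#' Nearest locus to a gene's anchor position
#' @param genotypes a [genotype_tensor()].
#' @param ann an [annotation()].
#' @param gene_id gene identifier(s).
#' @return integer locus index (or vector).
#' @export
nearest_locus <- function(genotypes, ann, gene_id) {
  gi <- match(gene_id, ann$genes$gene_id)
  if (anyNA(gi)) stop("unknown gene id", call. = FALSE)
  vapply(gi, function(i) {
    same <- which(genotypes$loci$chrom == ann$genes$chrom[i])
    if (length(same) == 0L) same <- seq_len(nrow(genotypes$loci))
    same[which.min(abs(genotypes$loci$pos[same] - ann$genes$anchor_pos[i]))]
  }, integer(1))
}

#' Simulate exon- and transcript-level RNA-seq counts with planted sQTLs
#'
#' Observation model: each gene g has a lognormal baseline expression level
#' and logistic-normal isoform proportions (softmax of Gaussian-perturbed
#' log weights). Expected transcript counts are
#' depth x library factor x gene level x isoform proportion; observed
#' transcript counts are negative binomial with a single global dispersion.
#' Exon counts are binomial subsamples of the gene's realized transcript
#' reads at the exon's inclusion fraction — sum over member transcripts of
#' p_k * len_e / weighted transcript length — so exon counts never exceed
#' the gene total, downstream exon fractions estimate the inclusion
#' fraction, and gene-level overdispersion cancels from the ratio as it
#' does for real subread counts.
#'
#' Planted effects (see [sim_truth()]): a `cis_gxe` effect of size delta on
#' founder f at locus j shifts the target's latent scale by
#' `delta * G[ril, j, f] * E_n` — the logit of the exon inclusion fraction
#' for exon targets, the log expected count of the target transcript for
#' isoform targets. A `trans_hotspot` applies isoform-usage shifts of this
#' form to many genes from a single locus.
#'
#' @param genotypes a [genotype_tensor()].
#' @param annotation an [annotation()].
#' @param samples sample sheet ([make_sample_sheet()]); RIL ids must exist
#'   in `genotypes`.
#' @param truth a [sim_truth()] (default: no planted effects).
#' @param nb_dispersion negative-binomial dispersion (Var = mu + disp*mu^2);
#'   default 0.1, a typical bulk RNA-seq value.
#' @param depth mean expected gene-level read count per sample (default 400).
#' @param iso_sd standard deviation of the per-sample log isoform-weight
#'   perturbation (default 0.25).
#' @param gene_sdlog lognormal sd of baseline gene expression (default 0.6).
#' @param lib_sdlog lognormal sd of per-sample library size factors
#'   (default 0.15).
#' @param n_confounders number of latent sample-level factors (batch, RNA
#'   quality, ...) loading on the transcript log-expression scale
#'   (default 4, matching the latent dimension the transcript-level
#'   pipeline removes). Exon inclusion loads only the first three factors:
#'   inclusion is a within-gene ratio, so gene-scaling technical variation
#'   cancels, which is why fraction phenotypes need fewer components
#'   removed.
#' @param confounder_sd sd of the per-feature factor loadings (default
#'   0.3).
#' @param seed integer RNG seed (required).
#' @return list with `exon_counts` and `transcript_counts` (integer
#'   matrices, features x samples), and `truth` (the registry, augmented
#'   with resolved phenotype ids and locus coordinates).
#' @export
simulate_counts <- function(genotypes, annotation, samples,
                            truth = sim_truth(), nb_dispersion = 0.1,
                            depth = 400, iso_sd = 0.25, gene_sdlog = 0.6,
                            lib_sdlog = 0.15, n_confounders = 4,
                            confounder_sd = 0.3, seed) {
  if (!inherits(truth, "sim_truth")) stop("`truth` must be a sim_truth",
                                          call. = FALSE)
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) {
    stop("`nb_dispersion` must be > 0", call. = FALSE)
  }
  ril_idx <- match(samples$ril, genotypes$rils)
  if (anyNA(ril_idx)) {
    stop("sample RIL id(s) missing from genotypes: ",
         paste(unique(samples$ril[is.na(ril_idx)]), collapse = ", "),
         call. = FALSE)
  }
  eff <- truth$effects
  if (nrow(eff) > 0L) {
    if (!all(eff$gene_id %in% annotation$genes$gene_id)) {
      stop("planted gene id not present in annotation", call. = FALSE)
    }
    if (any(eff$locus_index < 1L | eff$locus_index > nrow(genotypes$loci))) {
      stop("planted locus index out of range", call. = FALSE)
    }
    if (!all(eff$founder %in% genotypes$founders)) {
      stop("planted founder not present in genotypes", call. = FALSE)
    }
  }
  E <- environment_vector(samples)
  n <- nrow(samples)
  tx_gene <- transcript_genes(annotation)
  genes <- annotation$genes$gene_id
  size <- 1 / nb_dispersion

  with_seed(seed, {
    lib <- exp(stats::rnorm(n, 0, lib_sdlog))
    mu_gene <- stats::setNames(
      exp(stats::rnorm(length(genes), log(depth), gene_sdlog)), genes)
    ## latent sample-level confounder factors (batch-like structure)
    U <- if (n_confounders > 0) {
      matrix(stats::rnorm(n * n_confounders), n, n_confounders)
    } else {
      matrix(0, n, 0)
    }

    ## resolve planted effects to target phenotype ids and G*E dose columns
    eff$phenotype_id <- rep(NA_character_, nrow(eff))
    dose <- matrix(0, n, nrow(eff))  # delta * G * E per sample per effect
    if (nrow(eff) > 0L) {
      for (r in seq_len(nrow(eff))) {
        g <- eff$gene_id[r]
        G <- locus_design(genotypes, eff$locus_index[r], samples$ril)
        dose[, r] <- eff$delta[r] * G[, eff$founder[r]] * E
        txs <- names(tx_gene)[tx_gene == g]
        if (eff$target[r] == "isoform" && length(txs) < 2L) {
          stop("isoform-target effect on single-isoform gene ", g,
               call. = FALSE)
        }
        ## the concrete target exon/isoform is resolved per gene below,
        ## once baseline proportions are known: effects land on
        ## alternatively used features (mid-range inclusion, expressed
        ## isoforms), where a splicing QTL can act
      }
    }

    mem <- exon_membership(annotation)
    tx_ids <- sort(unique(annotation$exons$transcript_id))
    exon_key <- paste(mem$gene_id, mem$exon_id, sep = "\r")
    tx_counts <- matrix(0L, length(tx_ids), n,
                        dimnames = list(tx_ids, samples$sample))
    ex_counts <- matrix(0L, nrow(mem), n,
                        dimnames = list(mem$exon_id, samples$sample))

    ex_len_all <- stats::setNames(mem$end - mem$start + 1L, exon_key)

    for (g in genes) {
      txs <- tx_ids[tx_gene[tx_ids] == g]
      k <- length(txs)
      ## baseline isoform weights
      alpha <- as.vector(rdirichlet_mat(matrix(2, 1, k)))
      eta <- matrix(log(alpha), n, k, byrow = TRUE) +
        matrix(stats::rnorm(n * k, 0, iso_sd), n, k)
      p <- exp(eta - apply(eta, 1, max))
      p <- p / rowSums(p)
      m_tx <- lib * mu_gene[g] * p                    # n x k expected counts
      if (ncol(U) > 0) {
        lam_tx <- matrix(stats::rnorm(k * ncol(U), 0, confounder_sd),
                         ncol(U), k)
        m_tx <- m_tx * exp(U %*% lam_tx)
      }
      colnames(m_tx) <- txs

      ## isoform-target effects multiply the target transcript's mean;
      ## the target is the most-expressed isoform, where usage shifts
      ## are observable
      er <- which(eff$gene_id == g & eff$target == "isoform")
      for (r in er) {
        eff$phenotype_id[r] <- txs[which.max(alpha)]
        m_tx[, eff$phenotype_id[r]] <- m_tx[, eff$phenotype_id[r]] *
          exp(dose[, r])
      }

      tx_counts[txs, ] <- t(matrix(
        stats::rnbinom(n * k, mu = as.vector(m_tx), size = size), n, k))

      ## exon layer: baseline inclusion fractions from membership
      gm <- mem$gene_id == g
      ex_ids <- mem$exon_id[gm]
      memb <- mem$transcripts[gm]
      tx_len <- vapply(txs, function(t) {
        e <- annotation$exons[annotation$exons$transcript_id == t, ]
        sum(e$end - e$start + 1L)
      }, numeric(1))
      wlen <- as.vector(p %*% tx_len)                 # per-sample mean length
      frac0 <- matrix(0, n, length(ex_ids))
      for (ei in seq_along(ex_ids)) {
        in_tx <- txs %in% memb[[ei]]
        le <- ex_len_all[paste(g, ex_ids[ei], sep = "\r")]
        frac0[, ei] <- (p[, in_tx, drop = FALSE] %*%
                          rep(le, sum(in_tx))) / wlen
      }
      if (ncol(U) > 0) {
        ## sample factors also perturb exon inclusion on the logit scale,
        ## but with lower rank than the expression layer: inclusion is a
        ## within-gene ratio, so gene-scaling technical variation cancels
        ## (hence fraction phenotypes need fewer PCs removed than
        ## transcript levels)
        q_ex <- min(3L, ncol(U))
        Ue <- U[, seq_len(q_ex), drop = FALSE]
        lam_ex <- matrix(stats::rnorm(length(ex_ids) * q_ex, 0,
                                      confounder_sd), q_ex,
                         length(ex_ids))
        f <- pmin(pmax(frac0, 1e-6), 1 - 1e-6)
        frac0 <- stats::plogis(stats::qlogis(f) + Ue %*% lam_ex)
      }
      ## exon-target effects shift the logit of the inclusion fraction;
      ## the target is the alternatively used exon with mean inclusion
      ## closest to 1/2 (a near-saturated exon cannot respond to a
      ## splicing QTL)
      er <- which(eff$gene_id == g & eff$target == "exon")
      for (r in er) {
        n_memb <- vapply(memb, length, integer(1))
        cand <- if (any(n_memb < k)) which(n_memb < k) else
          seq_along(ex_ids)
        ei <- cand[which.min(abs(colMeans(frac0)[cand] - 0.5))]
        eff$phenotype_id[r] <- ex_ids[ei]
        f <- pmin(pmax(frac0[, ei], 1e-6), 1 - 1e-6)
        frac0[, ei] <- stats::plogis(stats::qlogis(f) + dose[, r])
      }
      ## exon reads are a binomial subsample of the gene's realized reads
      ## at the inclusion fraction, so exon counts never exceed the gene
      ## total and the exon/gene ratio is free of double-counted
      ## overdispersion
      tot <- as.integer(colSums(tx_counts[txs, , drop = FALSE]))
      frac0 <- pmin(pmax(frac0, 0), 1)
      ex_counts[which(gm), ] <- t(matrix(
        stats::rbinom(n * length(ex_ids), size = rep(tot, length(ex_ids)),
                      prob = as.vector(frac0)), n, length(ex_ids)))
    }

    if (nrow(eff) > 0L) {
      eff$locus_chrom <- genotypes$loci$chrom[eff$locus_index]
      eff$locus_pos <- genotypes$loci$pos[eff$locus_index]
    }
    out_truth <- sim_truth()
    out_truth$effects <- eff
    list(exon_counts = ex_counts, transcript_counts = tx_counts,
         truth = out_truth)
  })
}
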