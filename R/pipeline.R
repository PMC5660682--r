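#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Either a `simulate`
#' block (parameters for the synthetic generator, including its seed) or a
#' set of input `paths` (genotypes, exon/transcript counts, GTF annotation,
#' sample sheet) must be provided; referenced paths are existence-checked
#' at load.
#'
#' @param outdir output directory (created if absent).
#' @param paths named list of input paths (`genotypes`, `exon_counts`,
#'   `transcript_counts`, `annotation`, `samples`) or NULL when simulating.
#' @param simulate named list of generator parameters (`n_rils`,
#'   `n_genes`, `breakpoint_rate`, `blur`, `spacing`, `chrom_length_bp`,
#'   `effects` (a [sim_truth()] effects data.frame or NULL),
#'   `nb_dispersion`, `depth`, `seed`) or NULL when loading from paths.
#' @param p_thresh,q_thresh significance thresholds (defaults 1e-4, 0.39).
#' @param cis_window cis/trans distance in bp (default 1 Mb).
#' @param bin_size hotspot bin width in bp (default 1e5).
#' @param n_perm hotspot permutations (default 1000).
#' @param n_pc_exon,n_pc_isoform PCs removed per phenotype kind
#'   (defaults 3 and 4).
#' @param zero_policy exon-fraction zero handling (`"drop"` /
#'   `"pseudocount"`).
#' @param tested_block isoform-model tested block.
#' @param ref_founder reference founder column.
#' @param protect_env protect the environment contrast during PC removal
#'   (default TRUE).
#' @param seed top-level seed for the stochastic stages (hotspot
#'   permutations; and the generator when its block has no seed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, paths = NULL, simulate = NULL,
                            p_thresh = 1e-4, q_thresh = 0.39,
                            cis_window = 1e6, bin_size = 1e5,
                            n_perm = 1000, n_pc_exon = 3, n_pc_isoform = 4,
                            zero_policy = "drop",
                            tested_block = "as_printed",
                            ref_founder = "A8", protect_env = TRUE,
                            seed = 1) {
  if (is.null(paths) == is.null(simulate)) {
    stop("provide exactly one of `paths` or `simulate`", call. = FALSE)
  }
  stopifnot(p_thresh > 0, p_thresh <= 1, q_thresh > 0, q_thresh <= 1,
            cis_window >= 0, bin_size > 0)
  if (!is.null(paths)) {
    need <- c("genotypes", "exon_counts", "transcript_counts", "annotation",
              "samples")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("missing input path(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    absent <- !vapply(paths[need], file.exists, logical(1))
    if (any(absent)) {
      stop("input file(s) not found: ",
           paste(unlist(paths[need][absent]), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(outdir = outdir, paths = paths, simulate = simulate,
                 p_thresh = p_thresh, q_thresh = q_thresh,
                 cis_window = cis_window, bin_size = bin_size,
                 n_perm = n_perm, n_pc_exon = n_pc_exon,
                 n_pc_isoform = n_pc_isoform, zero_policy = zero_policy,
                 tested_block = tested_block, ref_founder = ref_founder,
                 protect_env = protect_env, seed = seed),
            class = "pipeline_config")
}

#' Run the full sQTL analysis end-to-end
#'
#' Orchestrates the stages: (optionally) simulate or load inputs; build
#' both splicing phenotypes; quantile-normalize and remove principal
#' components; scan both phenotype sets against all loci with the nested
#' G x E models; attach q-values and call significant associations per
#' method; combine the methods; classify cis/trans; detect trans
#' hotspots; tally AS event types among sQTL genes; and run the paired
#' differential-expression contrast. Every stage's output is written under
#' `config$outdir` together with a JSON manifest of all parameters and
#' seeds; rerunning with an identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list bundle: `assoc_exon`, `assoc_isoform`,
#'   `calls` (combined, cis/trans-labeled), `hotspots`, `events`, `de`,
#'   `truth` (when simulated), `counts` (per-stage record counts).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- inputs -----------------------------------------------------------
  inputs <- if (!is.null(config$simulate)) {
    s <- config$simulate
    sim_seed <- if (!is.null(s$seed)) s$seed else config$seed
    stage("simulate", {
      loci <- locus_grid(chroms = s$chroms %||% c("2L", "2R", "3L"),
                         length_bp = s$chrom_length_bp %||% 5e5,
                         spacing = s$spacing %||% 1e4)
      genotypes <- simulate_founder_mosaics(
        s$n_rils %||% 79, loci, n_founders = s$n_founders %||% 8,
        breakpoint_rate = s$breakpoint_rate %||% 0.05,
        blur = s$blur %||% 0.05, seed = sim_seed)
      ann <- make_annotation(s$n_genes %||% 40,
                             chroms = unique(loci$chrom),
                             chrom_length_bp = max(loci$pos),
                             seed = sim_seed + 1)
      samples <- make_sample_sheet(genotypes$rils)
      tr <- if (!is.null(s$effects)) sim_truth(s$effects) else sim_truth()
      cnt <- simulate_counts(genotypes, ann, samples, truth = tr,
                             nb_dispersion = s$nb_dispersion %||% 0.1,
                             depth = s$depth %||% 400, seed = sim_seed + 2)
      write_genotype_probs(genotypes, file.path(config$outdir,
                                                "genotypes.tsv"))
      write_annotation(ann, file.path(config$outdir, "annotation.gtf"))
      write_table_tsv(samples, file.path(config$outdir, "samples.tsv"))
      write_counts(cnt$exon_counts,
                   file.path(config$outdir, "exon_counts.tsv"), "exon")
      write_counts(cnt$transcript_counts,
                   file.path(config$outdir, "transcript_counts.tsv"),
                   "transcript")
      list(genotypes = genotypes, ann = ann, samples = samples,
           exon_counts = cnt$exon_counts,
           transcript_counts = cnt$transcript_counts, truth = cnt$truth)
    })
  } else {
    stage("load", {
      list(genotypes = read_genotype_probs(config$paths$genotypes),
           ann = read_annotation(config$paths$annotation),
           samples = read_sample_sheet(config$paths$samples),
           exon_counts = read_counts(config$paths$exon_counts),
           transcript_counts = read_counts(config$paths$transcript_counts),
           truth = NULL)
    })
  }
  genotypes <- inputs$genotypes
  ann <- inputs$ann
  samples <- inputs$samples
  exon_counts <- inputs$exon_counts
  transcript_counts <- inputs$transcript_counts
  truth <- inputs$truth
  E <- environment_vector(samples)
  log_counts$n_samples <- nrow(samples)
  log_counts$n_loci <- nrow(genotypes$loci)

  ## --- phenotypes -------------------------------------------------------
  pheno_exon <- stage("phenotypes", {
    exon_fraction(exon_counts, transcript_counts, ann,
                  zero_policy = config$zero_policy)
  })
  log_counts$n_exon_phenotypes <- nrow(pheno_exon$values)

  ## --- normalization ----------------------------------------------------
  protect <- if (config$protect_env) E else NULL
  pheno_exon <- stage("normalize", {
    normalize_phenotypes(pheno_exon, n_pc = config$n_pc_exon,
                         protect = protect)
  })
  tx_keep <- rowSums(transcript_counts) > 0
  tx_norm <- stage("normalize", {
    normalize_phenotypes(log2(transcript_counts[tx_keep, , drop = FALSE] + 1),
                         n_pc = config$n_pc_isoform, protect = protect)
  })
  groups <- stage("phenotypes", {
    isoform_groups(unclass(tx_norm), ann, min_total = -Inf)
  })
  log_counts$n_isoform_groups <- length(groups)

  ## --- scans ------------------------------------------------------------
  cfg <- scan_config(tested_block = config$tested_block,
                     ref_founder = config$ref_founder, verbose = FALSE)
  assoc_exon <- stage("scan", sqtl_scan(pheno_exon, genotypes, samples, cfg))
  assoc_iso <- stage("scan", {
    if (length(groups)) sqtl_scan(groups, genotypes, samples, cfg) else
      empty_assoc()
  })
  log_counts$n_tests_exon <- nrow(assoc_exon)
  log_counts$n_tests_isoform <- nrow(assoc_iso)

  ## --- FDR, calls, combination, classification --------------------------
  assoc_exon <- add_qvalues(assoc_exon)
  assoc_iso <- if (nrow(assoc_iso)) add_qvalues(assoc_iso) else
    transform(assoc_iso, q = numeric(0))
  calls_exon <- call_significant(assoc_exon, config$p_thresh,
                                 config$q_thresh)
  calls_iso <- call_significant(assoc_iso, config$p_thresh, config$q_thresh)
  combined <- combine_methods(calls_exon, calls_iso)
  combined <- classify_cis_trans(combined, config$cis_window)
  log_counts$n_calls <- attr(combined, "counts")

  ## --- hotspots, events, DE --------------------------------------------
  hs <- stage("hotspots", {
    find_hotspots(combined, bin_size = config$bin_size,
                  n_perm = config$n_perm, loci = genotypes$loci,
                  seed = config$seed)
  })
  events <- stage("events", summarize_events(combined, ann))
  de <- stage("differential_expression",
              differential_expression(transcript_counts, samples))

  ## --- outputs ----------------------------------------------------------
  out <- function(f) file.path(config$outdir, f)
  write_table_tsv(assoc_exon, out("assoc_exon.tsv"))
  write_table_tsv(assoc_iso, out("assoc_isoform.tsv"))
  write_table_tsv(combined, out("calls.tsv"))
  if (nrow(combined)) write_calls_bed(combined, out("calls.bed"))
  write_table_tsv(hs$profile, out("hotspot_profile.tsv"))
  write_table_tsv(hs$hotspots, out("hotspots.tsv"))
  write_table_tsv(events, out("as_events.tsv"))
  write_table_tsv(de, out("differential_expression.tsv"))
  ## sQTL-map plot data: x = locus, y = phenotype anchor
  write_table_tsv(combined[, c("locus_chrom", "locus_pos", "pheno_chrom",
                               "pheno_pos", "method")],
                  out("sqtl_map.tsv"))
  manifest <- c(unclass(config)[setdiff(names(unclass(config)), "simulate")],
                list(simulate = config$simulate, counts = log_counts))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", digits = NA),
             out("manifest.json"))

  invisible(list(assoc_exon = assoc_exon, assoc_isoform = assoc_iso,
                 calls = combined, hotspots = hs, events = events, de = de,
                 truth = truth, counts = log_counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
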