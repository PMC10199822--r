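#' Union ACR set across tissues
#'
#' Merges per-tissue ACR sets with gap 0 (overlapping or book-ended
#' intervals join); membership of a union ACR in a tissue is >= 1 bp
#' overlap with that tissue's set.
#'
#' @param acrs_by_tissue Named list of `GRanges`.
#' @return `GRanges` with `acr_id` and one logical `in_<tissue>` column per
#'   tissue.
#' @export
acr_union <- function(acrs_by_tissue) {
  pooled <- GenomicRanges::reduce(unlist(GenomicRanges::GRangesList(
    lapply(acrs_by_tissue, function(g)
      GenomicRanges::GRanges(GenomeInfoDb::seqnames(g),
                             IRanges::ranges(g))))),
    min.gapwidth = 1L)
  pooled <- GenomicRanges::sort(pooled)
  pooled$acr_id <- sprintf("uACR%05d", seq_along(pooled))
  for (ts in names(acrs_by_tissue))
    S4Vectors::mcols(pooled)[[paste0("in_", ts)]] <-
      IRanges::overlapsAny(pooled, acrs_by_tissue[[ts]], minoverlap = 1L)
  pooled
}

#' Pipeline configuration
#'
#' Every tunable threshold of the analysis, defaulting to the published
#' values where the source analysis printed them (150/50 bp bins, merge
#' gap 150, proximal cutoff 2 Kb with scan list 2/4/5/6/8/10 Kb, promoter
#' -2000/+100, DEG thresholds padj < 0.01 and |log2FC| > 1, 1000
#' shuffles) and to this package's documented defaults elsewhere.
#'
#' @param seed RNG seed for simulation and permutation nulls.
#' @param bin_size,step,merge_gap ACR refinement geometry (bp).
#' @param density_alpha Poisson tail threshold for the bin density cutoff.
#' @param density_override Fixed density cutoff (integrations/bp) or NULL.
#' @param class_cutoff Proximal/distal cutoff (bp).
#' @param class_scan Cutoff scan list (bp).
#' @param promoter_upstream,promoter_downstream Promoter window (bp).
#' @param acr_min_fc,acr_alpha Differential-ACR call thresholds.
#' @param deg_min_fc,deg_alpha DEG call thresholds.
#' @param diff_engine `"voom"` or `"t"`.
#' @param strict Strict specificity presence semantics.
#' @param n_shuffles Permutations for overlap enrichment.
#' @param triad_min_sum Minimum triad sum for bias classification.
#' @param motif_threshold PWM hit threshold fraction.
#' @param expr_min Network expression gate (TPM).
#' @param stages Network stages.
#' @param sim Optional [sim_config()] (defaults to `sim_config(seed)`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, bin_size = 150, step = 50,
                            merge_gap = 150, density_alpha = 1e-4,
                            density_override = NULL, class_cutoff = 2000,
                            class_scan = c(2, 4, 5, 6, 8, 10) * 1000,
                            promoter_upstream = 2000,
                            promoter_downstream = 100,
                            acr_min_fc = 2, acr_alpha = 0.05,
                            deg_min_fc = 2, deg_alpha = 0.01,
                            diff_engine = "voom", strict = TRUE,
                            n_shuffles = 1000, triad_min_sum = 0.5,
                            motif_threshold = 0.8, expr_min = 1.0,
                            stages = c("DAP9", "DAP15", "DAP20"),
                            sim = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim)) cfg$sim <- sim_config(seed = seed)
  structure(cfg, class = "pipeline_config")
}

# serialized, order-stable config header for output files
config_header <- function(cfg) {
  flat <- cfg[setdiff(names(cfg), "sim")]
  sim <- cfg$sim[!vapply(cfg$sim, is.null, TRUE)]
  kv <- c(vapply(names(flat), function(k)
    paste0(k, "=", paste(format(flat[[k]]), collapse = ",")), ""),
    vapply(names(sim), function(k)
      paste0("sim.", k, "=", paste(format(sim[[k]]), collapse = ",")), ""))
  c("# wheatacr run parameters", paste0("# ", sort(unname(kv))))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) data, refine and classify ACRs per tissue, build the
#' tissue-union ACR set, call differential ACR and DEG specificity
#' clusters, compute overlap enrichment, classify triad bias in expression
#' and promoter-accessibility modes with transition tables and
#' concordance, compute the variation metaprofile, motif density tables,
#' and the stage-resolved regulatory network. Every output file carries
#' the fully resolved parameter header; a manifest records md5 hashes so
#' two runs with the same seed are hash-identical. Stages are skipped when
#' their outputs already exist (unless `force`).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param sim Optional pre-built [simulate_hexaploid()] result (skips
#'   simulation).
#' @param force Recompute even when outputs exist.
#' @param quiet Suppress progress logging.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         sim = NULL, force = FALSE, quiet = FALSE) {
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
    if (!quiet) message(msg)
  }
  hdr <- config_header(config)
  outputs <- character()
  done <- function(f) {
    outputs <<- c(outputs, f)
    file.path(outdir, f)
  }
  fresh <- function(f) !force && file.exists(file.path(outdir, f))

  say("stage simulate")
  if (is.null(sim)) sim <- simulate_hexaploid(config$sim)
  genome <- sim$genome
  genes <- sim$genes
  pats <- specificity_patterns()

  ## refine + classify per tissue -----------------------------------
  say("stage refine-peaks")
  tissues <- config$sim$tissues
  acrs_by_tissue <- list()
  for (ts in tissues) {
    sig_pool <- do.call(Map, c(list(f = c),
      lapply(Filter(function(s) s$tissue == ts, sim$signals),
             function(s) s$positions)))
    pooled <- tn5_signal(sig_pool, paste0(ts, "_pooled"), tissue = ts)
    acr <- refine_peaks(sim$raw_peaks[[ts]], pooled, genome,
                        bin_size = config$bin_size, step = config$step,
                        gap = config$merge_gap,
                        alpha = config$density_alpha,
                        cutoff = config$density_override, tissue = ts)
    acr <- classify_acrs(acr, genes, cutoff = config$class_cutoff)
    acrs_by_tissue[[ts]] <- acr
    f <- done(sprintf("acrs_%s.bed", ts))
    if (!fresh(basename(f))) {
      out <- acr
      out$name <- acr$acr_id
      out$score <- 0
      write_bed(out, f, header = hdr)
    }
  }

  ## class-fraction scan --------------------------------------------
  say("stage classify-scan")
  f <- done("class_scan.tsv")
  if (!fresh(basename(f))) {
    scan <- do.call(rbind, lapply(config$class_scan, function(cut) {
      do.call(rbind, lapply(tissues, function(ts) {
        cl <- classify_acrs(acrs_by_tissue[[ts]], genes, cutoff = cut)$class
        data.frame(cutoff = cut, tissue = ts,
                   genic = mean(cl == "genic"),
                   proximal = mean(cl == "proximal"),
                   distal = mean(cl == "distal"))
      }))
    }))
    write_tsv_hdr(scan, f, hdr)
  }

  ## replicate QC -----------------------------------------------------
  say("stage replicate-qc")
  f <- done("replicate_qc.tsv")
  if (!fresh(basename(f))) {
    qc <- do.call(rbind, lapply(tissues, function(ts) {
      reps <- Filter(function(s) s$tissue == ts, sim$signals)
      data.frame(tissue = ts,
                 r = replicate_correlation(reps[[1]], reps[[2]], genome))
    }))
    write_tsv_hdr(qc, f, hdr)
  }

  ## union + differential ACR clustering -----------------------------
  say("stage diff-acrs")
  union_acrs <- acr_union(acrs_by_tissue)
  scores <- normalize_acr_scores(union_acrs, sim$signals)
  acr_clusters <- cluster_diff_features(
    scores$counts, scores$samples$tissue, min_fc = config$acr_min_fc,
    alpha = config$acr_alpha, engine = config$diff_engine,
    strict = config$strict)
  union_acrs$cluster <- acr_clusters$cluster
  f <- done("diff_acrs.tsv")
  if (!fresh(basename(f))) {
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(union_acrs)),
                     start = BiocGenerics::start(union_acrs) - 1L,
                     end = BiocGenerics::end(union_acrs),
                     acr_id = union_acrs$acr_id,
                     cluster = union_acrs$cluster)
    write_tsv_hdr(df, f, hdr)
  }

  ## DEG clustering ---------------------------------------------------
  say("stage diff-genes")
  counts <- SummarizedExperiment::assay(sim$expr, "counts")
  col <- SummarizedExperiment::colData(sim$expr)
  degs <- call_degs(counts, col$tissue, min_fc = config$deg_min_fc,
                    alpha = config$deg_alpha, engine = config$diff_engine,
                    strict = config$strict)
  f <- done("degs.tsv")
  if (!fresh(basename(f))) write_tsv_hdr(degs, f, hdr)

  ## overlap enrichment ----------------------------------------------
  say("stage enrich-overlap")
  assoc <- associate_acr_genes(union_acrs, genes,
                               window = config$class_cutoff)
  universe <- genes$gene_id
  f <- done("enrichment.tsv")
  enr <- do.call(rbind, lapply(names(pats), function(cl) {
    a <- assoc[[cl]]
    b <- degs$feature_id[degs$cluster == cl]
    if (is.null(a) || length(a) == 0 || length(b) == 0)
      return(data.frame(cluster = cl, observed = NA_integer_,
                        null_mean = NA_real_, fold = NA_real_,
                        p = NA_real_, seed = config$seed))
    e <- overlap_enrichment(a, b, universe,
                            n_shuffles = config$n_shuffles,
                            seed = config$seed)
    data.frame(cluster = cl, observed = e$observed,
               null_mean = mean(e$null), fold = e$fold, p = e$p,
               seed = config$seed)
  }))
  if (!fresh(basename(f))) write_tsv_hdr(enr, f, hdr)

  ## triad bias: expression and promoter accessibility ---------------
  say("stage triad-bias")
  tpm <- SummarizedExperiment::assay(sim$expr, "tpm")
  tpm_tissue <- tissue_means(tpm, col$tissue)
  expr_prof <- classify_triads(sim$triads, tpm_tissue,
                               min_sum = config$triad_min_sum,
                               mode = "expression")
  prom_scores <- promoter_accessibility_matrix(
    genes, sim$signals, upstream = config$promoter_upstream,
    downstream = config$promoter_downstream,
    seqlengths = genome$seqlengths)
  acc_prof <- classify_triads(sim$triads, prom_scores$tissue_cpm,
                              min_sum = config$triad_min_sum,
                              mode = "promoter_accessibility")
  trans_expr <- transition_table(expr_prof, tissues)
  trans_acc <- transition_table(acc_prof, tissues)
  conc <- bias_concordance(expr_prof, acc_prof)
  for (x in list(list("triad_expression.tsv", expr_prof),
                 list("triad_accessibility.tsv", acc_prof),
                 list("triad_transitions_expression.tsv", trans_expr$tidy),
                 list("triad_transitions_accessibility.tsv", trans_acc$tidy),
                 list("triad_concordance.tsv", conc))) {
    f <- done(x[[1]])
    if (!fresh(basename(f))) write_tsv_hdr(x[[2]], f, hdr)
  }

  ## variation metaprofile -------------------------------------------
  say("stage variation-profile")
  f <- done("variation_profile.tsv")
  prof <- variation_metaprofile(union_acrs, sim$variants, genes,
                                min_gene_distance = config$class_cutoff)
  if (!fresh(basename(f))) write_tsv_hdr(prof, f, hdr)

  ## motif density -----------------------------------------------------
  say("stage motif-density")
  dens <- motif_density_table(sim$motifs, union_acrs, genome,
                              stratify_by_subgenome = TRUE)
  f <- done("motif_density.tsv")
  if (!fresh(basename(f)))
    write_tsv_hdr(dens, f, c(hdr, "# density unit: hits per kilobase of scanned ACR sequence"))

  ## regulatory network ------------------------------------------------
  say("stage build-network")
  targets <- sim$truth$genes$gene_id[sim$truth$genes$coupled]
  net <- build_network(sim$truth$tf_table, targets, genes,
                       acrs_by_tissue, sim$motifs, tpm_tissue, genome,
                       stages = config$stages, expr_min = config$expr_min,
                       upstream = config$promoter_upstream,
                       downstream = config$promoter_downstream)
  f <- done("network_edges.tsv")
  if (!fresh(basename(f))) write_tsv_hdr(net, f, hdr)

  ## manifest ----------------------------------------------------------
  say("stage manifest")
  files <- file.path(outdir, outputs)
  manifest <- data.frame(file = outputs,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(sim = sim, acrs_by_tissue = acrs_by_tissue,
                 union_acrs = union_acrs, acr_clusters = acr_clusters,
                 degs = degs, enrichment = enr, expr_prof = expr_prof,
                 acc_prof = acc_prof, concordance = conc,
                 variation_profile = prof, motif_density = dens,
                 network = net, manifest = manifest))
}

# internal: TSV with parameter header
write_tsv_hdr <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
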