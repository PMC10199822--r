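#' The eight tissue-specificity clusters
#'
#' Accessibility/expression specificity during grain development is
#' summarised into eight exact presence patterns over
#' (leaf, DAP5, DAP9, DAP15, DAP20); everything else is `Unassigned`.
#'
#' @return Named list mapping cluster label to its tissue set.
#' @export
specificity_patterns <- function() {
  list(Leafs = "leaf",
       DAP5s = "DAP5",
       DAP9s = "DAP9",
       DAP5and9s = c("DAP5", "DAP9"),
       DAP15s = "DAP15",
       DAP20s = "DAP20",
       DAP15and20s = c("DAP15", "DAP20"),
       AllGs = c("DAP5", "DAP9", "DAP15", "DAP20"))
}

#' Cluster labels including Unassigned
#' @return Character vector of the nine labels.
#' @export
specificity_levels <- function() c(names(specificity_patterns()), "Unassigned")

#' Map presence vectors to specificity clusters
#'
#' Exact-pattern map from a logical presence vector over
#' (leaf, DAP5, DAP9, DAP15, DAP20) to the eight clusters; any
#' non-enumerated pattern (including all-FALSE) is `Unassigned`.
#'
#' @param presence Logical vector of length 5, or a matrix with 5 columns
#'   (one row per feature). Columns must follow the tissue order above.
#' @param tissues Tissue order of the columns.
#' @return Character vector of cluster labels.
#' @export
assign_specificity <- function(presence,
                               tissues = c("leaf", "DAP5", "DAP9",
                                           "DAP15", "DAP20")) {
  if (is.null(dim(presence))) presence <- matrix(presence, nrow = 1)
  if (ncol(presence) != length(tissues))
    stop("presence must have one entry per tissue (", length(tissues), ")")
  pats <- specificity_patterns()
  keys <- vapply(pats, function(ts)
    paste(as.integer(tissues %in% ts), collapse = ""), "")
  got <- apply(presence, 1, function(p)
    paste(as.integer(as.logical(p)), collapse = ""))
  lab <- names(keys)[match(got, keys)]
  lab[is.na(lab)] <- "Unassigned"
  lab
}

#' CPM-in-peaks accessibility scores
#'
#' Per-sample score of an ACR is its integration count divided by the
#' sample's total integrations falling inside any ACR, times 1e6
#' ("CPM-in-peaks"); tissue scores are replicate means.
#'
#' @param acrs `GRanges` of ACRs.
#' @param signals List of [tn5_signal()] objects.
#' @return List with `counts` (ACR x sample integer matrix), `cpm`
#'   (ACR x sample), `tissue_cpm` (ACR x tissue replicate means), and
#'   `samples` (data.frame of sample annotation).
#' @export
normalize_acr_scores <- function(acrs, signals) {
  counts <- vapply(signals, function(s) integration_count(acrs, s),
                   integer(length(acrs)))
  ids <- vapply(signals, `[[`, "", "sample_id")
  colnames(counts) <- ids
  rownames(counts) <- if (!is.null(acrs$acr_id)) acrs$acr_id else
    as.character(seq_along(acrs))
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample with zero in-peak integrations: ",
         paste(ids[tot == 0], collapse = ", "))
  cpm <- sweep(counts, 2, tot, "/") * 1e6
  tissue <- vapply(signals, `[[`, "", "tissue")
  list(counts = counts, cpm = cpm,
       tissue_cpm = tissue_means(cpm, tissue),
       samples = data.frame(sample_id = ids, tissue = tissue,
                            replicate = vapply(signals, function(s)
                              as.integer(s$replicate), 1L),
                            stringsAsFactors = FALSE))
}

#' Pairwise differential test between two tissues
#'
#' log2 fold change on pseudocounted replicate means
#' (`log2((meanA+1)/(meanB+1))`), p-values from a two-sample t-test on
#' `log2(score+1)` across replicates (pooled variance; `engine =
#' "moderated"` substitutes a limma moderated t on the same two groups),
#' Benjamini-Hochberg adjustment across features, and a call when
#' `|log2FC| >= log2(min_fc)` and adjusted p < `alpha`. With a single
#' replicate per side the test is skipped (fold-change-only mode, warned).
#'
#' @param a,b Numeric matrices, features x replicates (same row order).
#' @param min_fc Minimum fold change.
#' @param alpha Adjusted-p threshold.
#' @param engine `"t"` (plain pooled t-test) or `"moderated"` (limma).
#' @return `data.frame` with `log2fc`, `p`, `padj`, `call` (-1/0/+1; sign of
#'   A relative to B).
#' @export
pairwise_diff <- function(a, b, min_fc = 2, alpha = 0.05,
                          engine = c("t", "moderated")) {
  engine <- match.arg(engine)
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("mismatched feature sets")
  lfc <- log2((rowMeans(a) + 1) / (rowMeans(b) + 1))
  la <- log2(a + 1); lb <- log2(b + 1)
  if (ncol(a) < 2 || ncol(b) < 2) {
    warning("single replicate; fold-change-only mode (p = NA)")
    p <- padj <- rep(NA_real_, nrow(a))
    call <- ifelse(abs(lfc) >= log2(min_fc), sign(lfc), 0)
    return(data.frame(log2fc = lfc, p = p, padj = padj, call = call))
  }
  if (engine == "t") {
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(la); m2 <- rowMeans(lb)
    v1 <- apply(la, 1, stats::var); v2 <- apply(lb, 1, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- (m1 - m2) / se
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(tstat), df)
    # zero pooled variance: identical groups -> p 1, separated -> p 0
    degen <- !is.finite(tstat)
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  } else {
    m <- cbind(la, lb)
    design <- cbind(Intercept = 1,
                    A = rep(c(1, 0), c(ncol(a), ncol(b))))
    fit <- limma::eBayes(limma::lmFit(m, design))
    p <- fit$p.value[, "A"]
  }
  padj <- stats::p.adjust(p, method = "BH")
  call <- ifelse(abs(lfc) >= log2(min_fc) & !is.na(padj) & padj < alpha,
                 sign(lfc), 0)
  data.frame(log2fc = lfc, p = p, padj = padj, call = call)
}

# internal: joint limma-voom model over all tissues, all pairwise contrasts.
# Returns list(lfc, padj) matrices (features x pairs), pair labels "t1|t2".
joint_pairwise_fit <- function(counts, tissue, lib.size = NULL) {
  tissues <- unique(tissue)
  grp <- factor(tissue, levels = tissues)
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- tissues
  v <- limma::voom(counts, design, lib.size = lib.size)
  fit <- limma::lmFit(v, design)
  pairs <- utils::combn(tissues, 2)
  cons <- apply(pairs, 2, function(p) paste0("`", p[1], "`-`", p[2], "`"))
  cm <- limma::makeContrasts(contrasts = cons, levels = design)
  f2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
  lab <- apply(pairs, 2, paste, collapse = "|")
  lfc <- f2$coefficients
  padj <- apply(f2$p.value, 2, stats::p.adjust, method = "BH")
  colnames(lfc) <- colnames(padj) <- lab
  list(lfc = lfc, padj = padj, pairs = pairs, tissues = tissues)
}

# internal: per-pair t-test route used by engine = "t"
per_pair_fit <- function(score_mat, tissue, min_fc, alpha, engine) {
  tissues <- unique(tissue)
  pairs <- utils::combn(tissues, 2)
  res <- apply(pairs, 2, function(p) {
    pairwise_diff(score_mat[, tissue == p[1], drop = FALSE],
                  score_mat[, tissue == p[2], drop = FALSE],
                  min_fc = min_fc, alpha = alpha, engine = engine)
  })
  lab <- apply(pairs, 2, paste, collapse = "|")
  lfc <- vapply(res, `[[`, numeric(nrow(score_mat)), "log2fc")
  padj <- vapply(res, `[[`, numeric(nrow(score_mat)), "padj")
  colnames(lfc) <- colnames(padj) <- lab
  list(lfc = lfc, padj = padj, pairs = pairs, tissues = tissues)
}

# internal: strict/loose presence matrix from up/down call matrices.
# up[i, "t1|t2"] TRUE means feature i called up in t1 vs t2.
presence_from_fit <- function(fit, min_fc, alpha, strict = TRUE) {
  up_call <- fit$padj < alpha & fit$lfc >= log2(min_fc)
  dn_call <- fit$padj < alpha & fit$lfc <= -log2(min_fc)
  up_call[is.na(up_call)] <- FALSE
  dn_call[is.na(dn_call)] <- FALSE
  tissues <- fit$tissues
  nt <- length(tissues)
  n <- nrow(up_call)
  # per-feature directed up matrix: up[t, u] = called up in t vs u
  up_arr <- array(FALSE, c(n, nt, nt), dimnames = list(NULL, tissues, tissues))
  for (k in seq_len(ncol(fit$pairs))) {
    t1 <- fit$pairs[1, k]; t2 <- fit$pairs[2, k]
    up_arr[, t1, t2] <- up_call[, k]
    up_arr[, t2, t1] <- dn_call[, k]
  }
  pres <- matrix(FALSE, n, nt, dimnames = list(rownames(fit$lfc), tissues))
  for (i in seq_len(n)) {
    m <- up_arr[i, , ]
    s0 <- tissues[!apply(m, 2, any) & apply(m, 1, any)]
    if (length(s0) == 0L) next
    if (strict) {
      outside <- setdiff(tissues, s0)
      ok <- all(m[s0, outside]) && !any(m[s0, s0])
      if (!ok) next
    }
    pres[i, s0] <- TRUE
  }
  pres
}

#' Cluster differential features into tissue-specificity groups
#'
#' One-stop pairwise differential calling and eight-way specificity
#' clustering for ACR accessibility (counts-in-peaks) or any comparable
#' feature x sample count matrix. The default engine fits one joint
#' limma-voom linear model across all tissues and extracts all pairwise
#' contrasts (replicate-aware and stable at 2 replicates); `engine = "t"`
#' runs independent per-pair pooled t-tests on `log2(CPM+1)` instead. A
#' tissue belongs to a feature's presence set when the feature is called up
#' against every tissue outside the set and not called down against any
#' tissue inside it (`strict = TRUE`, the default "specific" semantics) or
#' merely never called down and up somewhere (`strict = FALSE`).
#'
#' @param counts Integer matrix, features x samples.
#' @param tissue Tissue label per column.
#' @param min_fc,alpha Call thresholds (fold change, adjusted p).
#' @param engine `"voom"` (joint model) or `"t"` (per-pair t-tests).
#' @param strict Strict presence semantics (see above).
#' @param lib.size Optional library sizes for normalization (defaults to
#'   column sums; pass median-of-ratios effective sizes for RNA-seq).
#' @return `data.frame` with `feature_id`, `cluster`, presence flags per
#'   tissue, and max |log2FC|; attribute `fit` holds the pairwise matrices.
#' @export
cluster_diff_features <- function(counts, tissue, min_fc = 2, alpha = 0.05,
                                  engine = c("voom", "t"), strict = TRUE,
                                  lib.size = NULL) {
  engine <- match.arg(engine)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- as.character(seq_len(nrow(counts)))
  fit <- if (engine == "voom") {
    joint_pairwise_fit(counts, tissue, lib.size = lib.size)
  } else {
    sf <- if (is.null(lib.size)) colSums(counts) else lib.size
    cpm <- sweep(counts, 2, sf, "/") * 1e6
    per_pair_fit(cpm, tissue, min_fc, alpha, engine = "t")
  }
  pres <- presence_from_fit(fit, min_fc, alpha, strict = strict)
  cluster <- assign_specificity(pres, tissues = fit$tissues)
  out <- data.frame(feature_id = rownames(counts), cluster = cluster,
                    stringsAsFactors = FALSE)
  for (t in fit$tissues) out[[paste0("present_", t)]] <- pres[, t]
  out$max_abs_log2fc <- apply(abs(fit$lfc), 1, max)
  attr(out, "fit") <- fit
  out
}

#' Median-of-ratios size factors
#'
#' DESeq-style library-size normalization: per sample, the median ratio of
#' counts to the per-gene geometric mean across samples (genes with a zero
#' anywhere are excluded from the reference).
#'
#' @param counts Integer matrix, genes x samples.
#' @return Numeric vector of size factors (geometric mean 1).
#' @export
size_factors_mor <- function(counts) {
  lg <- log(counts)
  use <- is.finite(rowSums(lg))
  if (!any(use)) stop("no gene with nonzero counts in every sample")
  ref <- rowMeans(lg[use, , drop = FALSE])
  sf <- apply(lg[use, , drop = FALSE], 2, function(x)
    exp(stats::median(x - ref)))
  sf / exp(mean(log(sf)))
}

#' Call differentially expressed genes and cluster them
#'
#' Library sizes are normalized by median-of-ratios, pairwise tests run as
#' in [cluster_diff_features()] (joint voom model by default), and calls
#' use the grain-development thresholds adjusted p < 0.01 and |log2FC| > 1.
#' An externally computed DE table (columns `gene_id`, `tissue_a`,
#' `tissue_b`, `log2fc`, `padj`) may be supplied instead, bypassing the
#' internal test so calls from dedicated DE tools are reproduced verbatim.
#'
#' @param counts Integer matrix, genes x samples (non-integer values are
#'   rounded with a warning; all-zero genes are reported `Unassigned`).
#' @param tissue Tissue label per column.
#' @param min_fc,alpha Call thresholds (defaults 2 and 0.01).
#' @param engine `"voom"` or `"t"`.
#' @param strict Presence semantics, see [cluster_diff_features()].
#' @param external Optional external DE table (see above).
#' @return As [cluster_diff_features()].
#' @export
call_degs <- function(counts, tissue, min_fc = 2, alpha = 0.01,
                      engine = c("voom", "t"), strict = TRUE,
                      external = NULL) {
  engine <- match.arg(engine)
  counts <- as.matrix(counts)
  if (any(counts != floor(counts))) {
    warning("non-integer counts rounded")
    counts <- round(counts)
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- as.character(seq_len(nrow(counts)))
  if (!is.null(external)) {
    fit <- external_fit(external, rownames(counts), unique(tissue))
    pres <- presence_from_fit(fit, min_fc, alpha, strict = strict)
    out <- data.frame(feature_id = rownames(counts),
                      cluster = assign_specificity(pres, fit$tissues),
                      stringsAsFactors = FALSE)
    for (t in fit$tissues) out[[paste0("present_", t)]] <- pres[, t]
    attr(out, "fit") <- fit
    return(out)
  }
  nz <- rowSums(counts) > 0
  sf <- size_factors_mor(counts[nz, , drop = FALSE])
  # effective library size: geometric-mean depth scaled by the size factor
  res <- cluster_diff_features(counts[nz, , drop = FALSE], tissue,
                               min_fc = min_fc, alpha = alpha,
                               engine = engine, strict = strict,
                               lib.size = exp(mean(log(colSums(counts)))) * sf)
  out <- data.frame(feature_id = rownames(counts), cluster = "Unassigned",
                    stringsAsFactors = FALSE)
  idx <- match(res$feature_id, out$feature_id)
  out$cluster[idx] <- res$cluster
  for (t in unique(tissue)) {
    col <- paste0("present_", t)
    out[[col]] <- FALSE
    out[[col]][idx] <- res[[col]]
  }
  attr(out, "fit") <- attr(res, "fit")
  out
}

# internal: build a pairwise fit structure from an external DE table
external_fit <- function(external, gene_ids, tissues) {
  need <- c("gene_id", "tissue_a", "tissue_b", "log2fc", "padj")
  if (!all(need %in% names(external)))
    stop("external DE table needs columns: ", paste(need, collapse = ", "))
  pairs <- utils::combn(tissues, 2)
  lab <- apply(pairs, 2, paste, collapse = "|")
  n <- length(gene_ids)
  lfc <- matrix(0, n, length(lab), dimnames = list(gene_ids, lab))
  padj <- matrix(1, n, length(lab), dimnames = list(gene_ids, lab))
  for (k in seq_along(lab)) {
    t1 <- pairs[1, k]; t2 <- pairs[2, k]
    fwd <- external$tissue_a == t1 & external$tissue_b == t2
    rev <- external$tissue_a == t2 & external$tissue_b == t1
    for (sel in list(list(fwd, 1), list(rev, -1))) {
      rows <- which(sel[[1]])
      if (!length(rows)) next
      i <- match(external$gene_id[rows], gene_ids)
      ok <- !is.na(i)
      lfc[i[ok], k] <- sel[[2]] * external$log2fc[rows][ok]
      padj[i[ok], k] <- external$padj[rows][ok]
    }
  }
  list(lfc = lfc, padj = padj, pairs = pairs, tissues = tissues)
}

#' Associate genes with ACR clusters
#'
#' A gene is associated with an ACR when the gene body extended by
#' `window` bp on both sides overlaps the ACR by at least 1 bp; a gene may
#' associate with several ACRs and clusters.
#'
#' @param acrs `GRanges` of ACRs carrying a `cluster` column.
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param window Flanking window in bp.
#' @return Named list: cluster -> sorted unique gene IDs.
#' @export
associate_acr_genes <- function(acrs, genes, window = 2000) {
  if (is.null(acrs$cluster)) stop("acrs must carry a cluster column")
  ext <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genes),
    IRanges::IRanges(pmax(1L, BiocGenerics::start(genes) - window),
                     BiocGenerics::end(genes) + window))
  ov <- GenomicRanges::findOverlaps(acrs, ext, minoverlap = 1L)
  cl <- acrs$cluster[S4Vectors::queryHits(ov)]
  gid <- genes$gene_id[S4Vectors::subjectHits(ov)]
  lapply(split(gid, cl), function(g) sort(unique(g)))
}

#' Permutation overlap enrichment of two gene sets
#'
#' Observed overlap |A intersect B| against a null built by redrawing |A|
#' genes uniformly without replacement from the universe `n_shuffles`
#' times. Empirical p is `(1 + #(null >= observed)) / (1 + n_shuffles)`;
#' fold is observed over the null mean (infinite, flagged, when the null
#' mean is zero).
#'
#' @param set_a,set_b Character vectors of gene IDs (subsets of `universe`).
#' @param universe Character vector of all candidate gene IDs.
#' @param n_shuffles Number of permutations.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `observed`, `null`, `p`, `fold`, `fold_infinite`,
#'   `n_shuffles`, `seed`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe, n_shuffles = 1000,
                               seed = NULL) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("set_a and set_b must be subsets of the universe")
  if (length(set_a) > length(universe))
    stop("|set_a| exceeds the universe")
  if (!is.null(seed)) set.seed(seed)
  observed <- length(intersect(set_a, set_b))
  in_b <- universe %in% set_b
  null <- vapply(seq_len(n_shuffles), function(i)
    sum(in_b[sample.int(length(universe), length(set_a))]), 1L)
  mu <- mean(null)
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_shuffles),
       fold = if (mu == 0) Inf else observed / mu,
       fold_infinite = mu == 0,
       n_shuffles = n_shuffles, seed = seed)
}

#' Promoter accessibility score matrix
#'
#' Integration counts inside each gene's promoter window (-2000/+100 around
#' the TSS by default), normalized per sample to counts per million of all
#' in-promoter integrations, exactly mirroring the CPM-in-peaks ACR scores.
#' Row order matches the input gene order.
#'
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param signals List of [tn5_signal()] objects.
#' @param upstream,downstream Promoter window extent in bp.
#' @param seqlengths Optional chromosome lengths for clipping.
#' @return As [normalize_acr_scores()] (rownames = gene IDs).
#' @export
promoter_accessibility_matrix <- function(genes, signals, upstream = 2000,
                                          downstream = 100,
                                          seqlengths = NULL) {
  prom <- promoter_region(genes, upstream, downstream, seqlengths)
  prom$acr_id <- genes$gene_id
  normalize_acr_scores(prom, signals)
}
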