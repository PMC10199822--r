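#' Construct a motif model
#'
#' A scannable TF-binding motif, either an IUPAC consensus string or a
#' position weight matrix of per-position nucleotide probabilities. PWM
#' scanning scores log2-odds against a uniform background and calls a hit
#' at `threshold` times the maximal attainable score (default 0.8, the
#' usual relative-score cutoff).
#'
#' @param motif_id Motif identifier.
#' @param family TF family label (e.g. NAC, MYB, bZIP).
#' @param consensus IUPAC consensus string (alternative to `pwm`).
#' @param pwm 4 x width numeric matrix, rows A/C/G/T, columns summing to 1.
#' @param threshold Fraction of the maximum log-odds score for PWM hits.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(motif_id, family = motif_id, consensus = NULL,
                        pwm = NULL, threshold = 0.8) {
  if (is.null(consensus) == is.null(pwm))
    stop("provide exactly one of consensus or pwm")
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
    if (!all(strsplit(consensus, "")[[1]] %in% iupac))
      stop("consensus contains non-IUPAC letters")
    width <- nchar(consensus)
  } else {
    pwm <- as.matrix(pwm)
    if (nrow(pwm) != 4) stop("pwm must have 4 rows (A, C, G, T)")
    rownames(pwm) <- c("A", "C", "G", "T")
    if (any(abs(colSums(pwm) - 1) > 1e-6))
      stop("pwm columns must sum to 1")
    width <- ncol(pwm)
  }
  structure(list(motif_id = motif_id, family = family,
                 consensus = consensus, pwm = pwm, threshold = threshold,
                 width = width),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model", x$motif_id, "(", x$family, "):",
      if (!is.null(x$consensus)) paste("consensus", x$consensus)
      else paste0("PWM width ", x$width, ", threshold ", x$threshold), "\n")
  invisible(x)
}

# internal: log2-odds matrix vs uniform background, with N row that never
# matches; probabilities clamped away from zero
pwm_logodds <- function(pwm, floor_p = 1e-4) {
  p <- pmax(pwm, floor_p)
  lo <- log2(p / 0.25)
  rbind(lo, N = -Inf)
}

# internal: reverse complement of a probability PWM
pwm_revcomp <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

# internal: sliding-window log-odds scores of a sequence (character) under
# a log-odds matrix with rows A,C,G,T,N
pwm_scores <- function(seq_chars, lo) {
  w <- ncol(lo)
  L <- length(seq_chars)
  if (L < w) return(numeric(0))
  code <- match(seq_chars, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  n <- L - w + 1L
  sc <- numeric(n)
  for (j in seq_len(w)) sc <- sc + lo[cbind(code[j:(j + n - 1L)], j)]
  sc
}

#' Scan a sequence for motif hits
#'
#' Both strands are scanned; `N` never matches. Consensus mode requires an
#' exact IUPAC match; PWM mode calls a hit when the log2-odds score (vs a
#' uniform background) reaches `threshold` x the maximum score. Hits of a
#' palindromic motif at the same position on both strands are deduplicated
#' to one (+ strand) hit.
#'
#' @param sequence A [Biostrings::DNAString], or a character string over
#'   `{A, C, G, T, N}`.
#' @param motif A [motif_model()].
#' @return `data.frame` with `start`, `end` (1-based on the sequence),
#'   `strand`, `score`. A motif wider than the sequence yields zero rows.
#' @export
scan_motif <- function(sequence, motif) {
  seq_str <- toupper(as.character(sequence))
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nchar(seq_str) < motif$width) return(empty)
  if (!is.null(motif$consensus)) {
    subj <- Biostrings::DNAString(seq_str)
    fwd <- Biostrings::matchPattern(motif$consensus, subj,
                                    fixed = c(pattern = FALSE,
                                              subject = TRUE))
    rcpat <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif$consensus)))
    rev <- Biostrings::matchPattern(rcpat, subj,
                                    fixed = c(pattern = FALSE,
                                              subject = TRUE))
    hits <- data.frame(
      start = c(BiocGenerics::start(fwd), BiocGenerics::start(rev)),
      end = c(BiocGenerics::end(fwd), BiocGenerics::end(rev)),
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      score = rep(motif$width, length(fwd) + length(rev)),
      stringsAsFactors = FALSE)
    # a subject N never matches, even against a degenerate pattern letter
    npos <- which(strsplit(seq_str, "")[[1]] == "N")
    if (length(npos) && nrow(hits))
      hits <- hits[vapply(seq_len(nrow(hits)), function(i)
        !any(npos >= hits$start[i] & npos <= hits$end[i]), TRUE), ,
        drop = FALSE]
  } else {
    chars <- strsplit(seq_str, "")[[1]]
    lo <- pwm_logodds(motif$pwm)
    lo_rc <- pwm_logodds(pwm_revcomp(motif$pwm))
    cutoff <- motif$threshold * sum(apply(lo[1:4, , drop = FALSE], 2, max))
    sf <- pwm_scores(chars, lo)
    sr <- pwm_scores(chars, lo_rc)
    pf <- which(sf >= cutoff)
    pr <- which(sr >= cutoff)
    hits <- data.frame(start = c(pf, pr),
                       end = c(pf, pr) + motif$width - 1L,
                       strand = rep(c("+", "-"), c(length(pf), length(pr))),
                       score = c(sf[pf], sr[pr]),
                       stringsAsFactors = FALSE)
  }
  if (nrow(hits) == 0L) return(empty)
  # palindromes: one hit per position
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  hits <- hits[!duplicated(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# internal: extract ACR sequences as a character vector from a genome index
acr_sequences <- function(acrs, genome) {
  if (is.null(genome$sequence))
    stop("genome index carries no sequence")
  chroms <- as.character(GenomeInfoDb::seqnames(acrs))
  out <- character(length(acrs))
  for (chr in unique(chroms)) {
    sel <- which(chroms == chr)
    ir <- IRanges::IRanges(BiocGenerics::start(acrs)[sel],
                           BiocGenerics::end(acrs)[sel])
    out[sel] <- as.character(Biostrings::extractAt(genome$sequence[[chr]], ir))
  }
  out
}

#' Motif density per specificity cluster and subgenome
#'
#' Scans the member ACR sequences of every (motif, cluster) cell — or
#' (motif, cluster, subgenome) when stratified — and reports hits per
#' kilobase of scanned sequence. Cells exceeding 1 hit/kb carry the
#' `flagged` mark; unstratified `"all"` rows accompany the stratified ones
#' and their hit counts equal the sum over subgenomes.
#'
#' @param motifs List of [motif_model()] objects.
#' @param acrs `GRanges` of ACRs with a `cluster` column.
#' @param genome [genome_index()] with sequence.
#' @param stratify_by_subgenome Add per-subgenome rows.
#' @return `data.frame`: `motif_id`, `cluster`, `subgenome`, `hits`,
#'   `total_kb`, `density`, `flagged`, `n_acrs`. Empty cells are emitted
#'   with `n_acrs = 0` and `density = NA`.
#' @export
motif_density_table <- function(motifs, acrs, genome,
                                stratify_by_subgenome = TRUE) {
  if (is.null(acrs$cluster)) stop("acrs must carry a cluster column")
  seqs <- acr_sequences(acrs, genome)
  subg <- unname(genome$subgenome[as.character(GenomeInfoDb::seqnames(acrs))])
  clusters <- specificity_levels()[specificity_levels() != "Unassigned"]
  strata <- if (stratify_by_subgenome) c("A", "B", "D", "all") else "all"
  hit_counts <- vapply(motifs, function(m)
    vapply(seqs, function(s) nrow(scan_motif(s, m)), 1L),
    integer(length(acrs)))
  if (is.null(dim(hit_counts)))
    hit_counts <- matrix(hit_counts, nrow = length(acrs))
  colnames(hit_counts) <- vapply(motifs, `[[`, "", "motif_id")
  kb <- BiocGenerics::width(acrs) / 1000
  rows <- list()
  for (cl in clusters) for (sg in strata) {
    sel <- acrs$cluster == cl & (sg == "all" | subg == sg)
    tot_kb <- sum(kb[sel])
    for (mid in colnames(hit_counts)) {
      h <- sum(hit_counts[sel, mid])
      dens <- if (tot_kb > 0) h / tot_kb else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = mid, cluster = cl, subgenome = sg, hits = h,
        total_kb = tot_kb, density = dens,
        flagged = !is.na(dens) && dens > 1, n_acrs = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Intersect in-vitro TFBS peaks with tissue ACRs
#'
#' The in-vivo binding-site set of a TF in a tissue is its TFBS peaks
#' (e.g. DAP-seq) overlapping that tissue's ACRs by >= 1 bp. Sharing
#' between tissues is summarised by Jaccard indices, and the
#' tissue-different fraction is `1 - |intersection over tissues| / |union|`.
#'
#' @param tfbs_list Named list of `GRanges`, one per TF.
#' @param acrs_by_tissue Named list of `GRanges`, one per tissue.
#' @return List per TF with `sets` (peak indices per tissue), `jaccard`
#'   (tissue x tissue), `different_fraction`; plus `summary` data.frame.
#' @export
tfbs_acr_intersection <- function(tfbs_list, acrs_by_tissue) {
  tissues <- names(acrs_by_tissue)
  per_tf <- lapply(names(tfbs_list), function(tf) {
    peaks <- tfbs_list[[tf]]
    sets <- lapply(acrs_by_tissue, function(acrs)
      which(IRanges::overlapsAny(peaks, acrs, minoverlap = 1L)))
    jac <- matrix(1, length(tissues), length(tissues),
                  dimnames = list(tissues, tissues))
    for (i in seq_along(tissues)) for (j in seq_along(tissues)) {
      u <- length(union(sets[[i]], sets[[j]]))
      jac[i, j] <- if (u == 0) 1 else
        length(intersect(sets[[i]], sets[[j]])) / u
    }
    un <- Reduce(union, sets)
    it <- Reduce(intersect, sets)
    diff_frac <- if (length(un) == 0) 0 else 1 - length(it) / length(un)
    list(sets = sets, jaccard = jac, different_fraction = diff_frac)
  })
  names(per_tf) <- names(tfbs_list)
  per_tf$summary <- data.frame(
    tf = names(tfbs_list),
    different_fraction = vapply(names(tfbs_list), function(tf)
      per_tf[[tf]]$different_fraction, 1),
    stringsAsFactors = FALSE)
  per_tf
}

#' Build a stage-resolved TF-to-target regulatory network
#'
#' An edge (TF -> target, stage) requires all four gates: (i) TF mean TPM
#' >= `expr_min` at the stage; (ii) target mean TPM >= `expr_min`; (iii)
#' the target's promoter window overlaps >= 1 ACR present at that stage;
#' (iv) >= 1 hit of the TF's motif inside the promoter-ACR intersection.
#' Each edge records its full evidence tuple; raising `expr_min` or the
#' motif threshold never adds edges.
#'
#' @param tf_table `data.frame` with `tf_gene_id` and `motif_id` (TFs
#'   without a catalogued motif are skipped with a warning).
#' @param targets Character vector of candidate target gene IDs.
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param acrs_by_tissue Named list of per-tissue ACR `GRanges` (with
#'   `acr_id` columns).
#' @param motifs List of [motif_model()] objects (names or motif_id used
#'   for lookup).
#' @param expr_tpm Genes x tissues matrix of mean TPM.
#' @param genome [genome_index()] with sequence.
#' @param stages Stages to resolve (default the three grain-filling phases).
#' @param expr_min Minimum mean TPM for gates (i) and (ii).
#' @param upstream,downstream Promoter window extent in bp.
#' @return `data.frame` of edges sorted by (stage, TF, target):
#'   `stage`, `tf_gene_id`, `target_gene_id`, `motif_id`, `hit`,
#'   `acr_id`, `tf_tpm`, `target_tpm`, `n_hits`.
#' @export
build_network <- function(tf_table, targets, genes, acrs_by_tissue, motifs,
                          expr_tpm, genome,
                          stages = c("DAP9", "DAP15", "DAP20"),
                          expr_min = 1.0, upstream = 2000,
                          downstream = 100) {
  motif_ids <- vapply(motifs, `[[`, "", "motif_id")
  names(motifs) <- motif_ids
  keep <- tf_table$motif_id %in% motif_ids
  if (any(!keep))
    warning("TF(s) without catalogued motif skipped: ",
            paste(tf_table$tf_gene_id[!keep], collapse = ", "))
  tf_table <- tf_table[keep, , drop = FALSE]
  targets <- intersect(targets, genes$gene_id)
  prom <- promoter_region(genes[match(targets, genes$gene_id)],
                          upstream, downstream,
                          seqlengths = genome$seqlengths)
  edges <- list()
  for (stage in stages) {
    acrs <- acrs_by_tissue[[stage]]
    if (is.null(acrs)) stop("no ACR set for stage ", stage)
    ov <- GenomicRanges::findOverlaps(prom, acrs, minoverlap = 1L)
    if (length(ov) == 0L) next
    # promoter-ACR intersections, one per overlapping pair
    pi <- GenomicRanges::pintersect(prom[S4Vectors::queryHits(ov)],
                                    acrs[S4Vectors::subjectHits(ov)],
                                    ignore.strand = TRUE)
    pi_gene <- prom$gene_id[S4Vectors::queryHits(ov)]
    pi_acr <- acrs$acr_id[S4Vectors::subjectHits(ov)]
    pi_seq <- acr_sequences(pi, genome)
    for (ti in seq_len(nrow(tf_table))) {
      tf <- tf_table$tf_gene_id[ti]
      motif <- motifs[[tf_table$motif_id[ti]]]
      tf_tpm <- expr_tpm[tf, stage]
      if (is.na(tf_tpm) || tf_tpm < expr_min) next
      for (gi in seq_along(pi_seq)) {
        tgt <- pi_gene[gi]
        if (tgt == tf) next
        tgt_tpm <- expr_tpm[tgt, stage]
        if (is.na(tgt_tpm) || tgt_tpm < expr_min) next
        hits <- scan_motif(pi_seq[gi], motif)
        if (nrow(hits) == 0L) next
        h1 <- hits[1, ]
        chrom <- as.character(GenomeInfoDb::seqnames(pi))[gi]
        gstart <- BiocGenerics::start(pi)[gi] + h1$start - 1L
        edges[[length(edges) + 1L]] <- data.frame(
          stage = stage, tf_gene_id = tf, target_gene_id = tgt,
          motif_id = motif$motif_id,
          hit = sprintf("%s:%d-%d", chrom, gstart,
                        gstart + motif$width - 1L),
          acr_id = pi_acr[gi], tf_tpm = tf_tpm, target_tpm = tgt_tpm,
          n_hits = nrow(hits), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges) == 0L)
    return(data.frame(stage = character(), tf_gene_id = character(),
                      target_gene_id = character(), motif_id = character(),
                      hit = character(), acr_id = character(),
                      tf_tpm = numeric(), target_tpm = numeric(),
                      n_hits = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(edges, make.row.names = FALSE))
  out <- out[!duplicated(out[, c("stage", "tf_gene_id", "target_gene_id")]), ]
  out[order(match(out$stage, stages), out$tf_gene_id, out$target_gene_id), ,
      drop = FALSE]
}

#' Motif density over a gene set's accessible promoter sequence
#'
#' Pools the promoter-ACR intersection sequence of the given genes (e.g.
#' starch or gluten biosynthesis gene sets) and ranks motifs by hits per
#' kilobase of that sequence. Invariant to gene-set ordering.
#'
#' @param gene_ids Character vector of gene IDs.
#' @param motifs List of [motif_model()] objects.
#' @param acrs `GRanges` of ACRs.
#' @param genes `GRanges` of gene models.
#' @param genome [genome_index()] with sequence.
#' @param upstream,downstream Promoter window extent in bp.
#' @return `data.frame` ranked by decreasing density: `motif_id`, `hits`,
#'   `total_kb`, `density`; zero rows (with a warning) when the gene set
#'   has no accessible promoter sequence.
#' @export
promoter_motif_density <- function(gene_ids, motifs, acrs, genes, genome,
                                   upstream = 2000, downstream = 100) {
  if (length(gene_ids) == 0L) stop("empty gene set")
  gene_ids <- sort(unique(gene_ids))
  sel <- genes[genes$gene_id %in% gene_ids]
  prom <- promoter_region(sel, upstream, downstream,
                          seqlengths = genome$seqlengths)
  acc <- GenomicRanges::intersect(
    GenomicRanges::reduce(GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(prom), IRanges::ranges(prom))),
    GenomicRanges::reduce(GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(acrs), IRanges::ranges(acrs))))
  if (length(acc) == 0L || sum(BiocGenerics::width(acc)) == 0) {
    warning("gene set has no accessible promoter sequence")
    return(data.frame(motif_id = character(), hits = integer(),
                      total_kb = numeric(), density = numeric(),
                      stringsAsFactors = FALSE))
  }
  seqs <- acr_sequences(acc, genome)
  kb <- sum(BiocGenerics::width(acc)) / 1000
  out <- do.call(rbind, lapply(motifs, function(m) {
    h <- sum(vapply(seqs, function(s) nrow(scan_motif(s, m)), 1L))
    data.frame(motif_id = m$motif_id, hits = h, total_kb = kb,
               density = h / kb, stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$density, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a motif catalog TSV
#'
#' Plain-text multi-motif table with columns `motif_id`, `family`, `type`
#' (`consensus` or `pwm`) and `definition` — a consensus string, or a PWM
#' serialized as semicolon-separated columns of comma-separated A,C,G,T
#' probabilities.
#'
#' @param path Path to the catalog TSV.
#' @param threshold PWM hit threshold fraction applied to every PWM motif.
#' @return List of [motif_model()] objects.
#' @export
read_motif_catalog <- function(path, threshold = 0.8) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  lapply(seq_len(nrow(dt)), function(i) {
    if (dt$type[i] == "consensus") {
      motif_model(dt$motif_id[i], dt$family[i], consensus = dt$definition[i],
                  threshold = threshold)
    } else {
      cols <- strsplit(strsplit(dt$definition[i], ";", fixed = TRUE)[[1]],
                       ",", fixed = TRUE)
      pwm <- vapply(cols, as.numeric, numeric(4))
      motif_model(dt$motif_id[i], dt$family[i], pwm = pwm,
                  threshold = threshold)
    }
  })
}

#' Write a motif catalog TSV
#' @param motifs List of [motif_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_catalog <- function(motifs, path) {
  rows <- lapply(motifs, function(m) {
    def <- if (!is.null(m$consensus)) m$consensus else
      paste(apply(m$pwm, 2, function(col)
        paste(format(col, trim = TRUE), collapse = ",")), collapse = ";")
    data.frame(motif_id = m$motif_id, family = m$family,
               type = if (!is.null(m$consensus)) "consensus" else "pwm",
               definition = def, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
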