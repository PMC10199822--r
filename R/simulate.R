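#' Configuration for the synthetic hexaploid simulator
#'
#' The stated world of the benchmark: a three-subgenome genome with
#' syntenic triads, tissue-specific planted ACRs backed by Tn5 integration
#' pileups, expression coupled to promoter accessibility, planted triad
#' bias categories, motif plants per (cluster, subgenome) cell, planted
#' stage-resolved TF-target edges, and variant depletion at distal ACR
#' centers. Defaults are the benchmark conditions; every knob is a
#' difficulty dial, not a tuning surface.
#'
#' @param seed Integer RNG seed (Mersenne-Twister; fully deterministic).
#' @param n_chroms_per_subgenome Chromosomes per subgenome.
#' @param chrom_length Chromosome length in bp.
#' @param n_triads Number of syntenic homeolog triads.
#' @param n_singletons Non-triad genes (distributed over subgenomes).
#' @param tissues Tissue panel in developmental order.
#' @param replicates Replicates per tissue.
#' @param acrs_per_pattern Planted ACRs per specificity pattern.
#' @param acr_width Planted ACR width in bp.
#' @param open_rate Tn5 integrations per bp inside open ACRs.
#' @param background_rate Background integrations per bp.
#' @param promoter_base_rate Baseline promoter integration rate per bp; a
#'   gene's promoter rate is `promoter_base_rate * 3 * frac` with `frac`
#'   its triad bias fraction (1/3 for balanced and non-triad genes), so
#'   promoter accessibility bias mirrors expression bias.
#' @param deg_fold Expression fold between on and off tissues of a planted
#'   differential gene.
#' @param coupling Extra mean multiplier for genes owning a
#'   promoter-overlapping planted ACR, in tissues where that ACR is open.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param base_mean Baseline per-gene mean count in off tissues.
#' @param triad_total_mean Summed mean count of a bias triad.
#' @param bias_props Named proportions of the seven planted bias
#'   categories (must sum to 1).
#' @param n_switch_triads Unbalanced triads that switch category between
#'   DAP9 and DAP15.
#' @param n_targets_per_tf Planted network targets per TF.
#' @param motif_density_planted Planted motif density (hits/kb) in
#'   enriched (cluster, subgenome) cells.
#' @param motif_density_background Background motif density (hits/kb).
#' @param variant_rate Background variant rate per bp.
#' @param variant_depletion Retention probability of variants near distal
#'   ACR centers.
#' @param depletion_halfwidth Half-width (bp) of the depleted zone.
#' @param decoy_frac Decoy raw peaks as a fraction of planted ACRs.
#' @param peak_pad Raw-peak padding around planted footprints, bp.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms_per_subgenome = 1,
                       chrom_length = 2e6,
                       n_triads = 300,
                       n_singletons = 100,
                       tissues = c("leaf", "DAP5", "DAP9", "DAP15", "DAP20"),
                       replicates = 2,
                       acrs_per_pattern = 80,
                       acr_width = 300,
                       open_rate = 0.2,
                       background_rate = 0.005,
                       promoter_base_rate = 0.02,
                       deg_fold = 8,
                       coupling = 2,
                       nb_dispersion = 0.1,
                       base_mean = 30,
                       triad_total_mean = 300,
                       bias_props = c(Balanced = 0.58, ADominant = 0.06,
                                      BDominant = 0.06, DDominant = 0.06,
                                      ASuppressed = 0.08, BSuppressed = 0.08,
                                      DSuppressed = 0.08),
                       n_switch_triads = 50,
                       n_targets_per_tf = 6,
                       motif_density_planted = 2,
                       motif_density_background = 0.2,
                       variant_rate = 0.01,
                       variant_depletion = 0.2,
                       depletion_halfwidth = 150,
                       decoy_frac = 0.1,
                       peak_pad = 200) {
  cfg <- as.list(environment())
  if (cfg$open_rate <= cfg$background_rate)
    stop("open_rate must exceed background_rate")
  if (cfg$open_rate <= 0 || cfg$background_rate <= 0 ||
      cfg$variant_rate <= 0)
    stop("rates must be positive")
  if (abs(sum(cfg$bias_props) - 1) > 1e-8)
    stop("bias_props must sum to 1")
  if (!all(names(cfg$bias_props) %in% rownames(bias_centroids())))
    stop("bias_props names must be the seven bias categories")
  structure(cfg, class = "sim_config")
}

# planted bias category means as (A, B, D) fractions; dominant/suppressed
# sit well inside their centroid basins so noise is the only difficulty
bias_mean_fracs <- function() {
  rbind(Balanced = c(1, 1, 1) / 3,
        ADominant = c(0.8, 0.1, 0.1),
        BDominant = c(0.1, 0.8, 0.1),
        DDominant = c(0.1, 0.1, 0.8),
        ASuppressed = c(0.1, 0.45, 0.45),
        BSuppressed = c(0.45, 0.1, 0.45),
        DSuppressed = c(0.45, 0.45, 0.1))
}

# default toy motif catalog: 4 exact consensus 10-mers, one degenerate
# IUPAC motif, one sharp PWM (behaves like exact match at threshold 0.8)
default_motif_catalog <- function() {
  sharp_pwm <- function(consensus, p = 0.97) {
    chars <- strsplit(consensus, "")[[1]]
    m <- matrix((1 - p) / 3, 4, length(chars),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(chars, c("A", "C", "G", "T")), seq_along(chars))] <- p
    m
  }
  list(motif_model("MOTIF_NAC", "NAC", pwm = sharp_pwm("TTGCGTGTCA")),
       motif_model("MOTIF_MYB", "MYB", consensus = "CAACTACCAG"),
       motif_model("MOTIF_BZIP", "bZIP", consensus = "ATGACGTCAT"),
       motif_model("MOTIF_ARF", "ARF", consensus = "TGTCTCGCAA"),
       motif_model("MOTIF_DOF", "Dof", consensus = "CAAAGCGGTG"),
       motif_model("MOTIF_ERF", "ERF", consensus = "GCCGCCRCCA"))
}

# consensus realization: concrete letters for degenerate positions;
# PWM motifs realize their argmax consensus
realize_motif <- function(motif) {
  if (!is.null(motif$pwm))
    return(paste(c("A", "C", "G", "T")[apply(motif$pwm, 2, which.max)],
                 collapse = ""))
  amb <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  chars <- strsplit(motif$consensus, "")[[1]]
  out <- vapply(chars, function(ch) {
    if (ch %in% c("A", "C", "G", "T")) ch
    else sample(amb[[ch]], 1)
  }, "")
  paste(out, collapse = "")
}

# planted (motif, cluster, subgenome) enrichment cells
default_planted_cells <- function() {
  data.frame(motif_id = c("MOTIF_NAC", "MOTIF_MYB", "MOTIF_BZIP",
                          "MOTIF_ARF", "MOTIF_DOF", "MOTIF_ERF"),
             cluster = c("DAP15and20s", "DAP5and9s", "AllGs",
                         "Leafs", "DAP20s", "DAP9s"),
             subgenome = c("A", "B", "D", "A", "B", "D"),
             stringsAsFactors = FALSE)
}

# TF roster: expression pattern and target-pool pattern per TF family
default_tf_spec <- function() {
  data.frame(family = c("NAC", "MYB", "bZIP", "ARF", "Dof", "ERF"),
             motif_id = c("MOTIF_NAC", "MOTIF_MYB", "MOTIF_BZIP",
                          "MOTIF_ARF", "MOTIF_DOF", "MOTIF_ERF"),
             tf_pattern = c("DAP15and20s", "DAP5and9s", "AllGs",
                            "AllGs", "AllGs", "DAP9s"),
             target_pattern = c("DAP15and20s", "DAP5and9s", "AllGs",
                                "DAP15s", "DAP20s", "DAP9s"),
             stringsAsFactors = FALSE)
}

#' Simulate a labelled synthetic hexaploid dataset
#'
#' Deterministic under `config$seed`. See [sim_config()] for the stated
#' world; the returned object carries the full generator ground truth for
#' every downstream recovery test.
#'
#' @param config A [sim_config()].
#' @return An object of class `hexsim`: list with `genome`
#'   ([genome_index()] with sequence), `genes` (`GRanges`), `triads`
#'   (data.frame), `signals` (list of [tn5_signal()]), `raw_peaks` (list of
#'   `GRanges` per tissue), `expr` (`SummarizedExperiment`), `motifs`,
#'   `variants` (`GRanges`), `truth` (list of ground-truth tables) and
#'   `config`.
#' @export
simulate_hexaploid <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  subgenomes <- c("A", "B", "D")
  n_c <- cfg$n_chroms_per_subgenome
  chrom_names <- unlist(lapply(subgenomes, function(sg)
    sprintf("chr%d%s", seq_len(n_c), sg)))
  chrom_sub <- rep(subgenomes, each = n_c)
  names(chrom_sub) <- chrom_names

  ## ---- gene layout -------------------------------------------------
  triad_chrom_idx <- ((seq_len(cfg$n_triads) - 1L) %% n_c) + 1L
  triad_slot <- ((seq_len(cfg$n_triads) - 1L) %/% n_c) + 1L
  s_t <- ceiling(cfg$n_triads / n_c)
  n_per_sub <- ceiling(cfg$n_singletons / 3)
  n_slots <- s_t + ceiling(n_per_sub / n_c)
  spacing <- floor(cfg$chrom_length / n_slots)
  if (spacing < 5850)
    stop("infeasible placement: need >= 5850 bp per gene slot for the ",
         "planted layout (got ", spacing, "); enlarge chrom_length or ",
         "reduce gene counts")
  gene_off <- 2301L   # gene start offset within a slot
  triad_len <- sample(1200:1800, cfg$n_triads, replace = TRUE)
  # alternating strands keep the '+' host pool for distal plants exact
  triad_strand <- rep(c("+", "-"), length.out = cfg$n_triads)

  gene_rows <- list()
  for (t in seq_len(cfg$n_triads)) {
    for (sg in subgenomes) {
      chrom <- sprintf("chr%d%s", triad_chrom_idx[t], sg)
      slot_abs <- (triad_slot[t] - 1L) * spacing
      start <- slot_abs + gene_off
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = sprintf("Tg%04d%s", t, sg),
        triad_id = sprintf("triad%04d", t), triad_idx = t,
        type = "triad", chrom = chrom, slot = triad_slot[t],
        start = start, end = start + triad_len[t] - 1L,
        strand = triad_strand[t], subgenome = sg,
        stringsAsFactors = FALSE)
    }
  }
  single_len <- sample(1200:1800, cfg$n_singletons, replace = TRUE)
  single_strand <- sample(c("+", "-"), cfg$n_singletons, replace = TRUE)
  single_within <- integer(3)
  for (k in seq_len(cfg$n_singletons)) {
    sg_i <- ((k - 1L) %% 3L) + 1L
    single_within[sg_i] <- single_within[sg_i] + 1L
    w <- single_within[sg_i]
    chrom <- sprintf("chr%d%s", ((w - 1L) %% n_c) + 1L, subgenomes[sg_i])
    slot <- s_t + ((w - 1L) %/% n_c) + 1L
    start <- (slot - 1L) * spacing + gene_off
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = sprintf("Sg%04d%s", k, subgenomes[sg_i]),
      triad_id = NA_character_, triad_idx = NA_integer_,
      type = "singleton", chrom = chrom, slot = slot,
      start = start, end = start + single_len[k] - 1L,
      strand = single_strand[k], subgenome = subgenomes[sg_i],
      stringsAsFactors = FALSE)
  }
  gene_df <- do.call(rbind, gene_rows)
  gene_df$length <- gene_df$end - gene_df$start + 1L
  gene_df$tss <- ifelse(gene_df$strand == "+", gene_df$start, gene_df$end)

  ## ---- pattern assignment -----------------------------------------
  pats <- specificity_patterns()
  pat_names <- names(pats)
  n_prom_triads <- floor(cfg$acrs_per_pattern / 6)
  rest <- cfg$acrs_per_pattern - 3L * n_prom_triads
  n_genic <- floor(rest / 2)
  n_distal <- rest - n_genic
  n_coupled <- 8L * n_prom_triads
  if (cfg$n_triads < n_coupled + 8L)
    stop("infeasible placement: n_triads too small for acrs_per_pattern")
  coupled_pattern <- rep(pat_names, each = n_prom_triads)   # triads 1..n_coupled
  bias_triads <- (n_coupled + 1L):cfg$n_triads

  ## singleton roles: ~64% of singletons are DEGs, evenly over patterns
  n_per_pat <- max(1L, floor(0.64 * cfg$n_singletons / 8))
  n_deg_single <- min(8L * n_per_pat, cfg$n_singletons)
  single_pattern <- rep(NA_character_, cfg$n_singletons)
  single_pattern[seq_len(n_deg_single)] <-
    rep(pat_names, each = n_per_pat)[seq_len(n_deg_single)]
  tf_spec <- default_tf_spec()
  tf_gene <- character(nrow(tf_spec))
  taken <- logical(cfg$n_singletons)
  for (j in seq_len(nrow(tf_spec))) {
    k <- which(single_pattern == tf_spec$tf_pattern[j] & !taken)[1]
    if (is.na(k)) stop("infeasible placement: no singleton left for TF ",
                       tf_spec$family[j])
    taken[k] <- TRUE
    sg_i <- ((k - 1L) %% 3L) + 1L
    tf_gene[j] <- sprintf("Sg%04d%s", k, subgenomes[sg_i])
  }
  tf_table <- data.frame(tf_gene_id = tf_gene,
                         motif_id = tf_spec$motif_id,
                         family = tf_spec$family,
                         tf_pattern = tf_spec$tf_pattern,
                         stringsAsFactors = FALSE)

  ## ---- ACR placement ----------------------------------------------
  half <- floor(cfg$acr_width / 2)
  acr_rows <- list()
  add_acr <- function(pattern, class, chrom, center, host_gene) {
    acr_rows[[length(acr_rows) + 1L]] <<- data.frame(
      acr_id = sprintf("pACR_%s_%04d", pattern, length(acr_rows) + 1L),
      pattern = pattern, class = class, chrom = chrom,
      start = center - half, end = center - half + cfg$acr_width - 1L,
      center = center, subgenome = unname(chrom_sub[chrom]),
      host_gene = host_gene, stringsAsFactors = FALSE)
  }
  ## promoter ACRs on coupled triads (one per homeolog, same pattern)
  for (t in seq_len(n_coupled)) {
    for (sg in subgenomes) {
      g <- gene_df[gene_df$gene_id == sprintf("Tg%04d%s", t, sg), ]
      center <- if (g$strand == "+") g$tss - 800L else g$tss + 800L
      add_acr(coupled_pattern[t], "proximal", g$chrom, center, g$gene_id)
    }
  }
  ## genic and distal ACRs on non-coupled triad slots, subgenome-balanced;
  ## distal/decoy hosts are '+' strand only so the distal zone never sits
  ## in the host gene's promoter window
  host_pool <- lapply(subgenomes, function(sg) {
    gene_df[gene_df$type == "triad" & gene_df$triad_idx > n_coupled &
              gene_df$subgenome == sg, ]
  })
  names(host_pool) <- subgenomes
  distal_pool <- lapply(host_pool, function(h) h[h$strand == "+", ])
  g_ptr <- stats::setNames(integer(3), subgenomes)
  d_ptr <- stats::setNames(integer(3), subgenomes)
  next_host <- function(ptr, sg, pool) {
    i <- ptr[[sg]] + 1L
    if (i > nrow(pool[[sg]]))
      stop("infeasible placement: not enough host slots on subgenome ", sg)
    i
  }
  distal_center <- function(g) {
    lo <- g$end + 2001L
    hi <- min((g$slot) * spacing + gene_off - 2001L,
              cfg$chrom_length - cfg$acr_width - cfg$peak_pad)
    if (lo > hi)
      stop("infeasible placement: no distal zone after gene ", g$gene_id)
    as.integer(floor((lo + hi) / 2))
  }
  for (p in pat_names) {
    for (k in seq_len(n_genic)) {
      sg <- subgenomes[((k - 1L) %% 3L) + 1L]
      g_ptr[[sg]] <- next_host(g_ptr, sg, host_pool)
      g <- host_pool[[sg]][g_ptr[[sg]], ]
      add_acr(p, "genic", g$chrom,
              as.integer(floor((g$start + g$end) / 2)), g$gene_id)
    }
    for (k in seq_len(n_distal)) {
      sg <- subgenomes[((k - 1L) %% 3L) + 1L]
      d_ptr[[sg]] <- next_host(d_ptr, sg, distal_pool)
      g <- distal_pool[[sg]][d_ptr[[sg]], ]
      add_acr(p, "distal", g$chrom, distal_center(g), g$gene_id)
    }
  }
  acr_df <- do.call(rbind, acr_rows)
  acr_df$acr_id <- sprintf("pACR_%s_%04d", acr_df$pattern,
                           stats::ave(seq_len(nrow(acr_df)),
                                      acr_df$pattern, FUN = seq_along))

  ## decoy peaks: background-signal raw peaks in further distal zones
  n_decoys <- round(cfg$decoy_frac * nrow(acr_df))
  decoy_rows <- list()
  decoy_w <- cfg$acr_width + 2L * cfg$peak_pad
  for (k in seq_len(n_decoys)) {
    sg <- subgenomes[((k - 1L) %% 3L) + 1L]
    d_ptr[[sg]] <- next_host(d_ptr, sg, distal_pool)
    g <- distal_pool[[sg]][d_ptr[[sg]], ]
    center <- distal_center(g)
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      decoy_id = sprintf("decoy_%03d", k), chrom = g$chrom,
      start = center - floor(decoy_w / 2),
      end = center - floor(decoy_w / 2) + decoy_w - 1L,
      stringsAsFactors = FALSE)
  }
  decoy_df <- do.call(rbind, decoy_rows)

  ## ---- raw peaks per tissue ---------------------------------------
  raw_peaks <- lapply(cfg$tissues, function(ts) {
    open <- acr_df[vapply(acr_df$pattern,
                          function(p) ts %in% pats[[p]], TRUE), ]
    gr <- GenomicRanges::GRanges(
      c(open$chrom, decoy_df$chrom),
      IRanges::IRanges(c(open$start - cfg$peak_pad, decoy_df$start),
                       c(open$end + cfg$peak_pad, decoy_df$end)))
    gr$name <- c(open$acr_id, decoy_df$decoy_id)
    GenomicRanges::sort(gr)
  })
  names(raw_peaks) <- cfg$tissues

  ## ---- expression means and counts --------------------------------
  all_tissues <- cfg$tissues
  mean_mat <- matrix(cfg$base_mean, nrow(gene_df), length(all_tissues),
                     dimnames = list(gene_df$gene_id, all_tissues))
  truth_gene_cluster <- stats::setNames(rep("flat", nrow(gene_df)),
                                        gene_df$gene_id)
  ## coupled triads: DEG fold in pattern tissues x promoter coupling
  for (t in seq_len(n_coupled)) {
    on <- all_tissues %in% pats[[coupled_pattern[t]]]
    for (sg in subgenomes) {
      gid <- sprintf("Tg%04d%s", t, sg)
      mean_mat[gid, on] <- cfg$base_mean * cfg$deg_fold * cfg$coupling
      truth_gene_cluster[gid] <- coupled_pattern[t]
    }
  }
  ## bias triads: flat totals partitioned by planted category
  fracs <- bias_mean_fracs()
  n_bias <- length(bias_triads)
  cat_draw <- sample(rep(names(cfg$bias_props),
                         times = round(cfg$bias_props * n_bias))[
                           seq_len(n_bias)])
  cat_draw[is.na(cat_draw)] <- "Balanced"
  unbal <- which(cat_draw != "Balanced")
  n_switch <- min(cfg$n_switch_triads, length(unbal))
  switch_idx <- if (n_switch > 0) sort(sample(unbal, n_switch)) else integer()
  late_cat <- cat_draw
  if (n_switch > 0) {
    others <- rownames(fracs)
    late_cat[switch_idx] <- vapply(cat_draw[switch_idx], function(ct)
      sample(setdiff(others, ct), 1), "")
  }
  truth_bias <- list()
  # per-gene bias fractions (1/3 unless a bias-triad member); also drives
  # promoter accessibility bias below
  frac_mat <- matrix(1 / 3, nrow(gene_df), length(all_tissues),
                     dimnames = list(gene_df$gene_id, all_tissues))
  for (i in seq_along(bias_triads)) {
    t <- bias_triads[i]
    for (ts in all_tissues) {
      is_late <- ts %in% c("DAP15", "DAP20")
      ct <- if (is_late) late_cat[i] else cat_draw[i]
      fr <- fracs[ct, ]
      for (s in 1:3) {
        gid <- sprintf("Tg%04d%s", t, subgenomes[s])
        mean_mat[gid, ts] <- cfg$triad_total_mean * fr[s]
        frac_mat[gid, ts] <- fr[s]
      }
      truth_bias[[length(truth_bias) + 1L]] <- data.frame(
        triad_id = sprintf("triad%04d", t), tissue = ts, category = ct,
        stringsAsFactors = FALSE)
    }
  }
  ## coupled triads are balanced by construction
  for (t in seq_len(n_coupled)) for (ts in all_tissues)
    truth_bias[[length(truth_bias) + 1L]] <- data.frame(
      triad_id = sprintf("triad%04d", t), tissue = ts,
      category = "Balanced", stringsAsFactors = FALSE)
  truth_bias <- do.call(rbind, truth_bias)
  ## singleton DEGs and TFs
  for (k in seq_len(cfg$n_singletons)) {
    p <- single_pattern[k]
    if (is.na(p)) next
    sg_i <- ((k - 1L) %% 3L) + 1L
    gid <- sprintf("Sg%04d%s", k, subgenomes[sg_i])
    on <- all_tissues %in% pats[[p]]
    mean_mat[gid, on] <- cfg$base_mean * cfg$deg_fold
    truth_gene_cluster[gid] <- p
    if (gid %in% tf_table$tf_gene_id)
      mean_mat[gid, !on] <- 0   # TFs are hard-silenced off stage
  }
  n_samp <- length(all_tissues) * cfg$replicates
  samp_tissue <- rep(all_tissues, each = cfg$replicates)
  samp_rep <- rep(seq_len(cfg$replicates), times = length(all_tissues))
  samp_id <- sprintf("%s_r%d", samp_tissue, samp_rep)
  counts <- matrix(0L, nrow(gene_df), n_samp,
                   dimnames = list(gene_df$gene_id, samp_id))
  for (j in seq_len(n_samp)) {
    mu <- mean_mat[, samp_tissue[j]]
    counts[, j] <- stats::rnbinom(nrow(gene_df), mu = mu,
                                  size = 1 / cfg$nb_dispersion)
  }
  expr <- expression_dataset(counts, gene_df$length, samp_tissue, samp_rep)

  ## ---- Tn5 integration signals ------------------------------------
  ## background everywhere, open_rate inside open ACRs, and a promoter
  ## rate of promoter_base_rate * 3 * frac (floored at background) that
  ## carries the planted bias into promoter accessibility
  prom_start <- ifelse(gene_df$strand == "+", gene_df$tss - 2000L,
                       gene_df$tss - 100L)
  prom_end <- ifelse(gene_df$strand == "+", gene_df$tss + 100L,
                     gene_df$tss + 2000L)
  prom_start <- pmax(prom_start, 1L)
  prom_end <- pmin(prom_end, cfg$chrom_length)
  prom_w <- prom_end - prom_start + 1L
  signals <- list()
  for (ts in cfg$tissues) {
    open <- acr_df[vapply(acr_df$pattern,
                          function(p) ts %in% pats[[p]], TRUE), ]
    prom_extra <- pmax(cfg$promoter_base_rate * 3 * frac_mat[, ts] -
                         cfg$background_rate, 0)
    for (r in seq_len(cfg$replicates)) {
      pos <- list()
      for (chr in chrom_names) {
        nbg <- stats::rpois(1, cfg$background_rate * cfg$chrom_length)
        p <- sample.int(cfg$chrom_length, nbg, replace = TRUE)
        oc <- open[open$chrom == chr, ]
        if (nrow(oc)) {
          inside <- rep(FALSE, length(p))
          for (i in seq_len(nrow(oc)))
            inside <- inside | (p >= oc$start[i] & p <= oc$end[i])
          p <- p[!inside]
          for (i in seq_len(nrow(oc))) {
            n <- stats::rpois(1, cfg$open_rate * cfg$acr_width)
            p <- c(p, oc$start[i] +
                     sample.int(cfg$acr_width, n, replace = TRUE) - 1L)
          }
        }
        on_chr <- which(gene_df$chrom == chr)
        n_extra <- stats::rpois(length(on_chr),
                                prom_extra[on_chr] * prom_w[on_chr])
        if (sum(n_extra) > 0) {
          gi <- rep(on_chr, n_extra)
          p <- c(p, prom_start[gi] +
                   floor(stats::runif(length(gi)) * prom_w[gi]))
        }
        pos[[chr]] <- sort(p)
      }
      sid <- sprintf("%s_r%d", ts, r)
      signals[[sid]] <- tn5_signal(pos, sid, tissue = ts, replicate = r)
    }
  }

  ## ---- motif planting ---------------------------------------------
  motifs <- default_motif_catalog()
  planted_cells <- default_planted_cells()
  cursor <- stats::setNames(rep(10L, nrow(acr_df)), acr_df$acr_id)
  plant_list <- list()
  place_instance <- function(acr_ids, motif) {
    # round-robin over candidate ACRs until one has room
    for (aid in acr_ids) {
      w <- motif$width
      off <- cursor[[aid]]
      row <- acr_df[acr_df$acr_id == aid, ]
      if (off + w <= cfg$acr_width - 10L) {
        cursor[[aid]] <<- off + w + 5L
        pos <- row$start + off
        plant_list[[length(plant_list) + 1L]] <<- data.frame(
          chrom = row$chrom, pos = pos, seq = realize_motif(motif),
          stringsAsFactors = FALSE)
        return(invisible(TRUE))
      }
    }
    stop("infeasible placement: no room for motif instance in cell")
  }
  motif_by_id <- stats::setNames(motifs, vapply(motifs, `[[`, "", "motif_id"))
  kb_cell <- function(cl, sg) sum(acr_df$pattern == cl &
                                    acr_df$subgenome == sg) *
    cfg$acr_width / 1000
  truth_cells <- list()
  for (m in names(motif_by_id)) {
    for (cl in pat_names) for (sg in subgenomes) {
      planted <- any(planted_cells$motif_id == m &
                       planted_cells$cluster == cl &
                       planted_cells$subgenome == sg)
      dens <- if (planted) cfg$motif_density_planted else
        cfg$motif_density_background
      n_inst <- if (planted) ceiling(dens * kb_cell(cl, sg)) else
        round(dens * kb_cell(cl, sg))
      # instances go into genic/distal members only; promoter ACR motif
      # content is reserved for planted network edges
      members <- acr_df$acr_id[acr_df$pattern == cl &
                                 acr_df$subgenome == sg &
                                 acr_df$class != "proximal"]
      for (i in seq_len(n_inst))
        place_instance(c(members[(i - 1L) %% length(members) + 1L],
                         members), motif_by_id[[m]])
      truth_cells[[length(truth_cells) + 1L]] <- data.frame(
        motif_id = m, cluster = cl, subgenome = sg, planted = planted,
        stringsAsFactors = FALSE)
    }
  }
  truth_cells <- do.call(rbind, truth_cells)

  ## ---- network planting -------------------------------------------
  stages <- intersect(c("DAP9", "DAP15", "DAP20"), all_tissues)
  truth_edges <- list()
  for (j in seq_len(nrow(tf_table))) {
    tp <- tf_spec$target_pattern[j]
    pool <- which(coupled_pattern == tp)
    if (length(pool) < cfg$n_targets_per_tf)
      stop("infeasible placement: too few coupled triads of pattern ", tp)
    pool <- pool[seq_len(cfg$n_targets_per_tf)]
    for (i in seq_along(pool)) {
      t <- pool[i]
      sg <- subgenomes[((i - 1L) %% 3L) + 1L]
      target <- sprintf("Tg%04d%s", t, sg)
      aid <- acr_df$acr_id[acr_df$host_gene == target &
                             acr_df$class == "proximal"]
      place_instance(aid, motif_by_id[[tf_table$motif_id[j]]])
      edge_stages <- intersect(intersect(stages, pats[[tp]]),
                               pats[[tf_spec$tf_pattern[j]]])
      for (s in edge_stages)
        truth_edges[[length(truth_edges) + 1L]] <- data.frame(
          stage = s, tf_gene_id = tf_table$tf_gene_id[j],
          target_gene_id = target, stringsAsFactors = FALSE)
    }
  }
  truth_edges <- do.call(rbind, truth_edges)
  plants <- do.call(rbind, plant_list)

  ## ---- sequence assembly ------------------------------------------
  seqs <- lapply(chrom_names, function(chr) {
    v <- sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
    pl <- plants[plants$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(pl))) {
      ins <- strsplit(pl$seq[i], "")[[1]]
      v[pl$pos[i]:(pl$pos[i] + length(ins) - 1L)] <- ins
    }
    paste(v, collapse = "")
  })
  sequence <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequence) <- chrom_names
  genome <- genome_index(stats::setNames(rep(cfg$chrom_length,
                                             length(chrom_names)),
                                         chrom_names),
                         sequence = sequence)

  ## ---- variants: background process thinned at distal ACR centers --
  distal_centers <- acr_df[acr_df$class == "distal",
                           c("chrom", "center")]
  var_rows <- list()
  for (chr in chrom_names) {
    n <- stats::rpois(1, cfg$variant_rate * cfg$chrom_length)
    p <- sort(sample.int(cfg$chrom_length, n, replace = TRUE))
    ctr <- distal_centers$center[distal_centers$chrom == chr]
    if (length(ctr)) {
      near <- rep(FALSE, length(p))
      for (c0 in ctr)
        near <- near | (abs(p - c0) <= cfg$depletion_halfwidth)
      keep <- !near | (stats::runif(length(p)) < cfg$variant_depletion)
      p <- p[keep]
    }
    if (length(p))
      var_rows[[chr]] <- data.frame(chrom = chr, pos = p,
                                    stringsAsFactors = FALSE)
  }
  var_df <- do.call(rbind, var_rows)
  variants <- GenomicRanges::GRanges(var_df$chrom,
                                     IRanges::IRanges(var_df$pos, width = 1L))

  ## ---- assemble ----------------------------------------------------
  genes <- GenomicRanges::GRanges(gene_df$chrom,
                                  IRanges::IRanges(gene_df$start,
                                                   gene_df$end),
                                  strand = gene_df$strand)
  genes$gene_id <- gene_df$gene_id
  genes$subgenome <- gene_df$subgenome
  genes$tss <- gene_df$tss
  genes$tes <- ifelse(gene_df$strand == "+", gene_df$end, gene_df$start)
  names(genes) <- gene_df$gene_id
  triads <- data.frame(
    triad_id = sprintf("triad%04d", seq_len(cfg$n_triads)),
    gene_id_A = sprintf("Tg%04dA", seq_len(cfg$n_triads)),
    gene_id_B = sprintf("Tg%04dB", seq_len(cfg$n_triads)),
    gene_id_D = sprintf("Tg%04dD", seq_len(cfg$n_triads)),
    stringsAsFactors = FALSE)
  truth <- list(
    acrs = acr_df,
    decoys = decoy_df,
    genes = data.frame(gene_id = gene_df$gene_id,
                       cluster = unname(truth_gene_cluster[gene_df$gene_id]),
                       coupled = gene_df$gene_id %in%
                         acr_df$host_gene[acr_df$class == "proximal"],
                       is_tf = gene_df$gene_id %in% tf_table$tf_gene_id,
                       stringsAsFactors = FALSE),
    gene_means = mean_mat,
    triad_bias = truth_bias,
    motif_cells = truth_cells,
    edges = truth_edges,
    tf_table = tf_table)
  structure(list(genome = genome, genes = genes, triads = triads,
                 signals = signals, raw_peaks = raw_peaks, expr = expr,
                 motifs = motifs, variants = variants, truth = truth,
                 config = cfg),
            class = "hexsim")
}

#' @export
print.hexsim <- function(x, ...) {
  cat("hexsim:", length(x$genome$seqlengths), "chromosomes x",
      format(x$config$chrom_length, big.mark = ","), "bp;",
      nrow(x$truth$acrs), "planted ACRs;", length(x$genes), "genes;",
      length(x$signals), "Tn5 samples; seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits the full standard-format file tree: genome FASTA, gene GFF3,
#' triad TSV, per-sample integration BEDs, per-tissue raw-peak BEDs,
#' counts TSV, motif catalog TSV, variant BED, ground-truth TSVs, and a
#' manifest listing every file with its record count.
#'
#' @param sim A [simulate_hexaploid()] result.
#' @param outdir Output directory (created if needed).
#' @return `data.frame` manifest (also written as `manifest.tsv`).
#' @export
write_fixture <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir)
  man <- list()
  note <- function(f, n) man[[length(man) + 1L]] <<- data.frame(
    file = f, n_records = n, stringsAsFactors = FALSE)
  p <- function(f) file.path(outdir, f)
  Biostrings::writeXStringSet(sim$genome$sequence, p("genome.fa"))
  note("genome.fa", length(sim$genome$sequence))
  write_gff3_genes(sim$genes, p("genes.gff3"))
  note("genes.gff3", length(sim$genes))
  utils::write.table(sim$triads, p("triads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("triads.tsv", nrow(sim$triads))
  dir.create(p("tn5"), showWarnings = FALSE)
  for (sid in names(sim$signals)) {
    f <- file.path("tn5", paste0(sid, ".bed"))
    write_tn5_bed(sim$signals[[sid]], p(f))
    note(f, sim$signals[[sid]]$total)
  }
  dir.create(p("raw_peaks"), showWarnings = FALSE)
  for (ts in names(sim$raw_peaks)) {
    f <- file.path("raw_peaks", paste0(ts, ".bed"))
    write_bed(sim$raw_peaks[[ts]], p(f))
    note(f, length(sim$raw_peaks[[ts]]))
  }
  cm <- SummarizedExperiment::assay(sim$expr, "counts")
  write_matrix_tsv(cm, p("counts.tsv"))
  note("counts.tsv", nrow(cm))
  gl <- data.frame(gene_id = rownames(cm),
                   length = SummarizedExperiment::rowData(sim$expr)$gene_length)
  utils::write.table(gl, p("gene_lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("gene_lengths.tsv", nrow(gl))
  write_motif_catalog(sim$motifs, p("motifs.tsv"))
  note("motifs.tsv", length(sim$motifs))
  write_bed(sim$variants, p("variants.bed"))
  note("variants.bed", length(sim$variants))
  for (nm in c("acrs", "decoys", "genes", "triad_bias", "motif_cells",
               "edges", "tf_table")) {
    f <- paste0("truth_", nm, ".tsv")
    utils::write.table(sim$truth[[nm]], p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(f, nrow(sim$truth[[nm]]))
  }
  manifest <- do.call(rbind, man)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
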