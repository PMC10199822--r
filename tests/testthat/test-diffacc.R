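test_that("assign_specificity maps the eight exact patterns and nothing else", {
  expect_equal(assign_specificity(c(TRUE, FALSE, FALSE, FALSE, FALSE)),
               "Leafs")
  expect_equal(assign_specificity(c(FALSE, TRUE, TRUE, TRUE, TRUE)),
               "AllGs")
  expect_equal(assign_specificity(c(FALSE, TRUE, FALSE, TRUE, FALSE)),
               "Unassigned")
  expect_equal(assign_specificity(rep(FALSE, 5)), "Unassigned")
  # total and deterministic over all 32 patterns; exactly 8 named clusters
  all_pat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 5)))
  lab <- assign_specificity(all_pat)
  expect_equal(sum(lab != "Unassigned"), 8L)
  expect_setequal(unique(lab), specificity_levels())
  expect_error(assign_specificity(c(TRUE, FALSE)), "per tissue")
})

test_that("normalize_acr_scores is depth-invariant CPM-in-peaks", {
  acrs <- gr("chr1A", c(101, 1001, 5001), c(400, 1300, 5300))
  acrs$acr_id <- c("a1", "a2", "a3")
  mk <- function(n1, n2, n3, id, ts, rep) {
    pos <- c(sample(101:400, n1, TRUE), sample(1001:1300, n2, TRUE),
             sample(5001:5300, n3, TRUE))
    tn5_signal(list(chr1A = pos), id, ts, rep)
  }
  set.seed(9)
  s1 <- mk(100, 50, 50, "t_r1", "t", 1)
  # doubled depth, same composition
  s2 <- tn5_signal(list(chr1A = rep(s1$positions$chr1A, 2)), "t_r2", "t", 2)
  sc <- normalize_acr_scores(acrs, list(s1, s2))
  expect_equal(sc$cpm[, 1], sc$cpm[, 2])
  expect_equal(unname(colSums(sc$cpm)), c(1e6, 1e6))
  expect_equal(unname(sc$cpm[, 1]),
               c(100, 50, 50) / 200 * 1e6)
  # an ACR holding all in-peak integrations scores 1e6
  s3 <- mk(80, 0, 0, "u_r1", "u", 1)
  expect_equal(unname(normalize_acr_scores(acrs, list(s3))$cpm[1, 1]), 1e6)
  empty <- tn5_signal(list(chr1A = 999999L), "z_r1", "z", 1)
  expect_error(normalize_acr_scores(acrs, list(empty)), "zero in-peak")
})

test_that("pairwise_diff: null input, BH step-up, planted recovery", {
  m <- matrix(c(10, 12, 11, 13), 2, 2)
  null <- pairwise_diff(m, m)
  expect_equal(null$log2fc, c(0, 0))
  expect_equal(null$call, c(0, 0))
  # Benjamini-Hochberg step-up on (0.01, 0.02, 0.03, 0.04) at m = 4
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # planted 8-fold difference with tight replicates is called, right sign
  set.seed(10)
  a <- matrix(rpois(200 * 2, 400), 200, 2)
  b <- matrix(rpois(200 * 2, 50), 200, 2)
  res <- pairwise_diff(a, b)
  expect_gt(mean(res$call == 1), 0.95)
  res_m <- pairwise_diff(a, b, engine = "moderated")
  expect_gt(mean(res_m$call == 1), 0.95)
  expect_warning(pairwise_diff(a[, 1, drop = FALSE], b), "single replicate")
  expect_error(pairwise_diff(a, b[1:10, ]), "mismatched")
})

test_that("cluster_diff_features recovers planted ACR patterns on the
           tiny fixture with both engines", {
  sim <- tiny_sim()
  acrs_by_tissue <- lapply(sim$config$tissues, function(ts) {
    pooled <- tn5_signal(
      do.call(Map, c(list(f = c),
        lapply(Filter(function(s) s$tissue == ts, sim$signals),
               function(s) s$positions))), ts, tissue = ts)
    refine_peaks(sim$raw_peaks[[ts]], pooled, sim$genome, tissue = ts)
  })
  names(acrs_by_tissue) <- sim$config$tissues
  ua <- acr_union(acrs_by_tissue)
  sc <- normalize_acr_scores(ua, sim$signals)
  cl <- cluster_diff_features(sc$counts, sc$samples$tissue)
  tr <- sim$truth$acrs
  ov <- GenomicRanges::findOverlaps(gr(tr$chrom, tr$start, tr$end), ua,
                                    select = "first")
  expect_true(all(!is.na(ov)))
  expect_gt(mean(cl$cluster[ov] == tr$pattern), 0.9)
})

test_that("call_degs: planted recovery, external passthrough, rounding", {
  sim <- tiny_sim()
  counts <- SummarizedExperiment::assay(sim$expr, "counts")
  tissue <- SummarizedExperiment::colData(sim$expr)$tissue
  degs <- call_degs(counts, tissue)
  planted <- sim$truth$genes[sim$truth$genes$cluster != "flat", ]
  got <- degs$cluster[match(planted$gene_id, degs$feature_id)]
  expect_gt(mean(got == planted$cluster), 0.9)
  # external table mode reproduces supplied calls verbatim
  ext <- data.frame(gene_id = rownames(counts)[1:2],
                    tissue_a = "leaf", tissue_b = "DAP5",
                    log2fc = c(5, -5), padj = c(1e-6, 1e-6))
  dx <- call_degs(counts[1:3, ], tissue, external = ext, strict = FALSE)
  expect_equal(dx$present_leaf, c(TRUE, FALSE, FALSE))
  expect_equal(dx$present_DAP5, c(FALSE, TRUE, FALSE))
  expect_equal(dx$cluster, c("Leafs", "DAP5s", "Unassigned"))
  # strict semantics demand up-calls against every outside tissue
  dstrict <- call_degs(counts[1:3, ], tissue, external = ext)
  expect_equal(dstrict$cluster, rep("Unassigned", 3))
  expect_warning(call_degs(counts[1:20, ] + 0.5, tissue), "rounded")
})

test_that("overlap_enrichment: saturation, direction, hypergeometric mean", {
  u <- sprintf("g%03d", 1:200)
  # A = B = universe: every shuffle reproduces the observed overlap, so
  # the empirical p is 1 by the (1 + #{null >= obs}) / (1 + n) definition
  sat <- overlap_enrichment(u, u, u, n_shuffles = 99, seed = 1)
  expect_equal(sat$observed, 200L)
  expect_equal(sat$p, 1)
  # maximal enrichment of a proper subset: no shuffle reaches it
  top <- overlap_enrichment(u[1:50], u[1:50], u, n_shuffles = 99, seed = 1)
  expect_equal(top$p, 1 / 100)
  # disjoint sets -> p near 1
  dis <- overlap_enrichment(u[1:50], u[51:100], u, n_shuffles = 199,
                            seed = 1)
  expect_equal(dis$observed, 0L)
  expect_gt(dis$p, 0.9)
  # null mean matches |A||B|/|U| within 3 standard errors
  e <- overlap_enrichment(u[1:60], u[31:110], u, n_shuffles = 1000,
                          seed = 42)
  mu <- 60 * 80 / 200
  se <- sd(e$null) / sqrt(1000)
  expect_lt(abs(mean(e$null) - mu), 3 * se)
  expect_error(overlap_enrichment(c(u, "zz"), u, u), "subsets")
  # deterministic under seed
  e2 <- overlap_enrichment(u[1:60], u[31:110], u, n_shuffles = 1000,
                           seed = 42)
  expect_identical(e$null, e2$null)
})

test_that("promoter accessibility matrix tracks planted promoter ACRs", {
  sim <- tiny_sim()
  pm <- promoter_accessibility_matrix(sim$genes, sim$signals,
                                      seqlengths = sim$genome$seqlengths)
  expect_equal(rownames(pm$cpm), sim$genes$gene_id)  # row order contract
  prox <- sim$truth$acrs[sim$truth$acrs$class == "proximal", ]
  pats <- specificity_patterns()
  ok <- vapply(seq_len(nrow(prox)), function(i) {
    sc <- pm$tissue_cpm[prox$host_gene[i], ]
    on <- names(sc) %in% pats[[prox$pattern[i]]]
    min(sc[on]) > max(sc[!on])
  }, TRUE)
  expect_gt(mean(ok), 0.95)
})

test_that("associate_acr_genes honours the 1 bp overlap boundary", {
  genes <- gr("chr1A", c(10000, 30000), c(12000, 32000), strand = "+")
  genes$gene_id <- c("g1", "g2")
  acrs <- gr("chr1A", c(14001, 14000, 25000), c(14300, 14300, 28300))
  acrs$cluster <- c("Leafs", "Leafs", "DAP5s")
  assoc <- associate_acr_genes(acrs, genes, window = 2000)
  # first ACR starts 1 bp beyond gene end + window (12000+2000=14000)
  # second touches it by exactly 1 bp; third spans into g2's window
  expect_equal(assoc$Leafs, "g1")
  expect_equal(assoc$DAP5s, "g2")
  # an ACR spanning two genes' windows associates with both
  wide <- gr("chr1A", 11000, 31000)
  wide$cluster <- "AllGs"
  expect_equal(associate_acr_genes(wide, genes)$AllGs, c("g1", "g2"))
  # equals an exhaustive pairwise overlap scan on the fixture
  sim <- tiny_sim()
  tr <- sim$truth$acrs
  pl <- gr(tr$chrom, tr$start, tr$end)
  pl$cluster <- tr$pattern
  got <- associate_acr_genes(pl, sim$genes)
  for (cl in names(got)) {
    sel <- which(tr$pattern == cl)
    brute <- sort(unique(unlist(lapply(sel, function(i) {
      same <- as.character(GenomeInfoDb::seqnames(sim$genes)) == tr$chrom[i]
      hit <- same &
        BiocGenerics::start(sim$genes) - 2000 <= tr$end[i] &
        BiocGenerics::end(sim$genes) + 2000 >= tr$start[i]
      sim$genes$gene_id[hit]
    }))))
    expect_equal(got[[cl]], brute)
  }
})

test_that("size factors: median-of-ratios is scale-calibrated", {
  set.seed(11)
  base <- rpois(300, 100) + 1
  counts <- cbind(s1 = base, s2 = base * 2, s3 = round(base * 0.5))
  sf <- size_factors_mor(counts)
  expect_equal(sf[["s2"]] / sf[["s1"]], 2, tolerance = 0.05)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})
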