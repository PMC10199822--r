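test_that("scan_motif: exact consensus, palindrome dedup, misses, N", {
  acgt <- motif_model("m1", consensus = "ACGT")
  # ACGT is its own reverse complement: one deduplicated hit (0-based
  # offset 2 = 1-based start 3)
  h <- scan_motif("AAACGTAAA", acgt)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 3L)
  expect_equal(h$strand, "+")
  expect_equal(nrow(scan_motif("AAAAAA", acgt)), 0L)
  # reverse-strand-only hit is found
  h <- scan_motif("TTTTCCCC", motif_model("m2", consensus = "GGGGAAAA"))
  expect_equal(h$strand, "-")
  # N never matches, even against IUPAC N in the pattern
  expect_equal(nrow(scan_motif("AANGT", motif_model("m3",
                                                    consensus = "ANG"))), 0L)
  # IUPAC degeneracy in the pattern
  hr <- scan_motif("TTACGTT", motif_model("m4", consensus = "ACRT"))
  expect_equal(nrow(hr), 1L)
  # motif wider than the sequence: zero hits, not an error
  expect_equal(nrow(scan_motif("ACG", acgt)), 0L)
})

test_that("PWM scanning: threshold semantics and limits", {
  pwm <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.1, 0.7, 0.1, 0.1,
                  0.1, 0.1, 0.7, 0.1,
                  0.1, 0.1, 0.1, 0.7), 4, 4)
  m_strict <- motif_model("p1", pwm = pwm, threshold = 1.0)
  # threshold 1.0 hits only the consensus string ACGT
  expect_equal(scan_motif("TTACGTTT", m_strict)$start, 3L)
  expect_equal(nrow(scan_motif("TTACCTTT", m_strict)), 0L)
  # a soft threshold admits one mismatch
  m_soft <- motif_model("p2", pwm = pwm, threshold = 0.5)
  expect_gt(nrow(scan_motif("TTACCTTT", m_soft)), 0L)
  expect_error(motif_model("bad", pwm = pwm * 2), "sum to 1")
  expect_error(motif_model("bad", consensus = "ACXT"), "non-IUPAC")
  expect_error(motif_model("bad"), "exactly one")
})

test_that("scan_motif equals a brute-force matcher on random pairs", {
  iupac_tab <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    N = c("A", "C", "G", "T"))
  rc <- function(s) chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  brute_consensus <- function(seq, pat) {
    sc <- strsplit(seq, "")[[1]]
    match_at <- function(p) {
      pc <- strsplit(p, "")[[1]]
      vapply(seq_len(nchar(seq) - length(pc) + 1), function(i)
        all(mapply(function(s1, p1) s1 %in% iupac_tab[[p1]],
                   sc[i:(i + length(pc) - 1)], pc)), TRUE)
    }
    sort(unique(c(which(match_at(pat)), which(match_at(rc(pat))))))
  }
  brute_pwm <- function(seq, pwm, thr) {
    lo <- log2(pmax(pwm, 1e-4) / 0.25)
    cut <- thr * sum(apply(lo, 2, max))
    sc <- strsplit(seq, "")[[1]]
    score1 <- function(m, i) sum(vapply(seq_len(ncol(m)), function(j) {
      k <- match(sc[i + j - 1], c("A", "C", "G", "T"))
      if (is.na(k)) -Inf else m[k, j]
    }, 1))
    rcp <- pwm[c(4, 3, 2, 1), rev(seq_len(ncol(pwm))), drop = FALSE]
    lor <- log2(pmax(rcp, 1e-4) / 0.25)
    n <- nchar(seq) - ncol(pwm) + 1
    sort(unique(c(which(vapply(1:n, function(i) score1(lo, i) >= cut, TRUE)),
                  which(vapply(1:n, function(i) score1(lor, i) >= cut, TRUE)))))
  }
  set.seed(13)
  for (i in 1:120) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), sample(20:80, 1),
                        replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                 collapse = "")
    if (i %% 2 == 0) {
      pat <- paste(sample(names(iupac_tab), sample(3:6, 1), replace = TRUE,
                          prob = c(rep(0.2, 4), rep(0.2 / 7, 7))),
                   collapse = "")
      got <- scan_motif(seq, motif_model("b", consensus = pat))
      expect_equal(got$start, brute_consensus(seq, pat))
    } else {
      w <- sample(3:6, 1)
      raw <- matrix(rexp(4 * w), 4, w)
      pwm <- sweep(raw, 2, colSums(raw), "/")
      thr <- runif(1, 0.5, 1)
      got <- scan_motif(seq, motif_model("b", pwm = pwm, threshold = thr))
      expect_equal(got$start, brute_pwm(seq, pwm, thr))
    }
  }
})

test_that("motif catalog TSV round-trips both representations", {
  motifs <- wheatacr:::default_motif_catalog()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_motif_catalog(motifs, f)
  back <- read_motif_catalog(f)
  expect_equal(length(back), length(motifs))
  for (i in seq_along(motifs)) {
    expect_equal(back[[i]]$motif_id, motifs[[i]]$motif_id)
    expect_equal(back[[i]]$consensus, motifs[[i]]$consensus)
    if (!is.null(motifs[[i]]$pwm))
      expect_equal(unname(back[[i]]$pwm), unname(motifs[[i]]$pwm),
                   tolerance = 1e-6)
  }
})

test_that("motif_density_table: arithmetic, dilution, subgenome additivity", {
  # two ACRs of 2.5 kb each holding 10 planted hits in one cluster
  seqlen <- 10000
  set.seed(14)
  base <- sample(c("A", "C", "G", "T"), seqlen, replace = TRUE)
  ins <- "TTGACGTCAA"  # not a substring elsewhere w.h.p.; palindrome
  for (p in seq(101, by = 450, length.out = 10))
    base[p:(p + 9)] <- strsplit(ins, "")[[1]]
  gi <- genome_index(c(chr1A = seqlen),
                     sequence = Biostrings::DNAStringSet(
                       setNames(paste(base, collapse = ""), "chr1A")))
  acrs <- gr("chr1A", c(1, 5001), c(5000, 7500))
  acrs$cluster <- c("Leafs", "DAP5s")
  m <- motif_model("pal", consensus = ins)
  tab <- motif_density_table(list(m), acrs, gi,
                             stratify_by_subgenome = FALSE)
  leafs <- tab[tab$cluster == "Leafs", ]
  expect_equal(leafs$hits, 10L)
  expect_equal(leafs$density, 2)
  expect_true(leafs$flagged)
  expect_false(tab$flagged[tab$cluster == "DAP5s"])
  # empty cluster cell emitted with n_acrs = 0
  expect_true(all(tab$n_acrs[tab$cluster == "AllGs"] == 0))
  # dilution: doubling scanned kb with hit-free sequence halves density
  acrs2 <- gr("chr1A", c(1, 5001), c(5000, 10000))
  acrs2$cluster <- c("Leafs", "Leafs")
  tab2 <- motif_density_table(list(m), acrs2, gi,
                              stratify_by_subgenome = FALSE)
  expect_equal(tab2$density[tab2$cluster == "Leafs"], 1)
  # stratified hits over A+B+D equal the unstratified count exactly
  run <- default_run()
  md <- run$res$motif_density
  for (mid in unique(md$motif_id)) for (cl in unique(md$cluster)) {
    sel <- md$motif_id == mid & md$cluster == cl
    expect_equal(sum(md$hits[sel & md$subgenome != "all"]),
                 md$hits[sel & md$subgenome == "all"])
  }
})

test_that("tfbs_acr_intersection: sharing extremes and fixture fraction", {
  acr_a <- gr("chr1A", c(100, 500), c(200, 600))
  peaks <- gr("chr1A", c(90, 450, 900), c(150, 520, 1000))
  # identical ACRs across tissues -> jaccard 1, different fraction 0
  same <- tfbs_acr_intersection(list(tf1 = peaks),
                                list(t1 = acr_a, t2 = acr_a))
  expect_equal(unname(same$tf1$jaccard["t1", "t2"]), 1)
  expect_equal(same$tf1$different_fraction, 0)
  # disjoint tissue ACRs -> different fraction 1
  disj <- tfbs_acr_intersection(
    list(tf1 = peaks),
    list(t1 = gr("chr1A", 100, 200), t2 = gr("chr1A", 900, 1000)))
  expect_equal(disj$tf1$different_fraction, 1)
  # fixture: fraction of planted ACRs specific to one of two tissues
  sim <- tiny_sim()
  tr <- sim$truth$acrs
  pats <- specificity_patterns()
  mk_acrs <- function(ts) {
    sel <- vapply(tr$pattern, function(p) ts %in% pats[[p]], TRUE)
    gr(tr$chrom[sel], tr$start[sel], tr$end[sel])
  }
  fake_peaks <- gr(tr$chrom, tr$start, tr$end)  # peaks = all planted ACRs
  res <- tfbs_acr_intersection(list(tfX = fake_peaks),
                               list(leaf = mk_acrs("leaf"),
                                    DAP20 = mk_acrs("DAP20")))
  # expected: union = patterns containing leaf or DAP20; intersection none
  pat_n <- table(tr$pattern)
  un <- sum(pat_n[c("Leafs", "DAP20s", "DAP15and20s", "AllGs")])
  expect_equal(res$tfX$different_fraction, 1)
  expect_equal(length(Reduce(union, res$tfX$sets)), un)
})

test_that("build_network enforces all four gates and sorts stably", {
  # hand-built micro-world: one TF, two targets, one stage
  seqlen <- 30000
  set.seed(15)
  chars <- sample(c("A", "C", "G", "T"), seqlen, replace = TRUE)
  ins <- "TTGCATGCAA"
  chars[10101:10110] <- strsplit(ins, "")[[1]]   # in target1 promoter ACR
  chars[20101:20110] <- strsplit(ins, "")[[1]]   # target2: outside ACR
  gi <- genome_index(c(chr1A = seqlen),
                     sequence = Biostrings::DNAStringSet(
                       setNames(paste(chars, collapse = ""), "chr1A")))
  genes <- gr("chr1A", c(11000, 21000, 5000), c(12000, 22000, 5500),
              strand = "+")
  genes$gene_id <- c("tgt1", "tgt2", "tf1")
  acrs <- gr("chr1A", c(10050, 20500), c(10350, 20800))
  acrs$acr_id <- c("acr1", "acr2")
  tpm <- matrix(c(10, 10, 10, 5, 5, 5), 3, 2,
                dimnames = list(c("tgt1", "tgt2", "tf1"),
                                c("DAP15", "DAP20")))
  motifs <- list(motif_model("M", consensus = ins))
  tft <- data.frame(tf_gene_id = "tf1", motif_id = "M")
  net <- build_network(tft, c("tgt1", "tgt2"), genes,
                       list(DAP15 = acrs, DAP20 = acrs), motifs, tpm, gi,
                       stages = c("DAP15", "DAP20"))
  # tgt1: motif inside promoter&ACR -> edges both stages;
  # tgt2: motif in promoter but outside any ACR -> gate (iv) fails
  expect_equal(net$target_gene_id, c("tgt1", "tgt1"))
  expect_equal(net$stage, c("DAP15", "DAP20"))
  expect_equal(net$acr_id, c("acr1", "acr1"))
  # gate (i): silenced TF stage drops its edges
  tpm2 <- tpm; tpm2["tf1", "DAP20"] <- 0
  net2 <- build_network(tft, c("tgt1", "tgt2"), genes,
                        list(DAP15 = acrs, DAP20 = acrs), motifs, tpm2, gi,
                        stages = c("DAP15", "DAP20"))
  expect_equal(net2$stage, "DAP15")
  # gate (ii): silenced target
  tpm3 <- tpm; tpm3["tgt1", ] <- 0.2
  net3 <- build_network(tft, c("tgt1", "tgt2"), genes,
                        list(DAP15 = acrs, DAP20 = acrs), motifs, tpm3, gi,
                        stages = c("DAP15", "DAP20"))
  expect_equal(nrow(net3), 0L)
  # unknown motif -> TF skipped with warning
  expect_warning(build_network(data.frame(tf_gene_id = "tf1",
                                          motif_id = "nope"),
                               "tgt1", genes, list(DAP15 = acrs), motifs,
                               tpm, gi, stages = "DAP15"),
                 "skipped")
})

test_that("promoter_motif_density ranks the planted motif first and is
           order-invariant", {
  run <- default_run()
  sim <- run$sim
  # NAC targets: coupled genes whose promoter ACR received NAC plants
  nac_targets <- unique(
    sim$truth$edges$target_gene_id[sim$truth$edges$tf_gene_id ==
      sim$truth$tf_table$tf_gene_id[sim$truth$tf_table$family == "NAC"]])
  acrs <- run$res$union_acrs
  d1 <- promoter_motif_density(nac_targets, sim$motifs, acrs, sim$genes,
                               sim$genome)
  expect_equal(d1$motif_id[1], "MOTIF_NAC")
  d2 <- promoter_motif_density(rev(nac_targets), sim$motifs, acrs,
                               sim$genes, sim$genome)
  expect_equal(d1, d2)
  # gene set with no accessible promoter bp -> empty with warning
  far <- sim$truth$genes$gene_id[!sim$truth$genes$coupled][1:5]
  expect_warning(
    d0 <- promoter_motif_density(far, sim$motifs,
                                 acrs[acrs$cluster == "Leafs"][0],
                                 sim$genes, sim$genome),
    "no accessible")
  expect_equal(nrow(d0), 0L)
})
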