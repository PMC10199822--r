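test_that("split_into_bins enumerates sliding windows", {
  # 0-based (0,150) == 1-based [1,150]: single exact bin
  b <- split_into_bins(gr("chr1A", 1, 150))
  expect_equal(length(b), 1L)
  expect_equal(BiocGenerics::width(b), 150L)
  # (0,250): three bins starting 0/50/100
  b <- split_into_bins(gr("chr1A", 1, 250))
  expect_equal(BiocGenerics::start(b), c(1L, 51L, 101L))
  expect_equal(BiocGenerics::end(b), c(150L, 200L, 250L))
  # short peak (0,120): one peak-sized bin, flagged
  b <- split_into_bins(gr("chr1A", 1, 120))
  expect_equal(BiocGenerics::width(b), 120L)
  expect_true(b$short)
  expect_error(split_into_bins(gr("chr1A", 1, 100), bin_size = 0),
               "positive")
})

test_that("split_into_bins matches a sliding-window enumeration oracle", {
  set.seed(3)
  for (i in 1:50) {
    w <- sample(10:900, 1)
    st <- sample(1:5000, 1)
    b <- split_into_bins(gr("chr1A", st, st + w - 1))
    if (w < 150) {
      expect_equal(BiocGenerics::start(b), st)
      expect_equal(BiocGenerics::end(b), st + w - 1)
    } else {
      starts <- seq(st, by = 50, length.out = floor((w - 150) / 50) + 1)
      expect_equal(BiocGenerics::start(b), as.integer(starts))
      expect_true(all(BiocGenerics::end(b) <= st + w - 1))
      expect_true(all(BiocGenerics::width(b) == 150L))
    }
  }
})

test_that("integration_density counts by binary search, equals linear scan", {
  sig <- tn5_signal(list(chr1A = c(10, 20, 20, 149, 150, 151)), "s1")
  expect_equal(integration_density(gr("chr1A", 1, 150), sig), 5 / 150)
  expect_equal(integration_density(gr("chr1A", 1, 150),
                                   tn5_signal(list(), "empty")), 0)
  set.seed(4)
  pos <- sort(sample(1:20000, 3000, replace = TRUE))
  sig <- tn5_signal(list(chr1A = pos), "s2")
  st <- sample(1:19800, 1000, replace = TRUE)
  bins <- gr("chr1A", st, st + sample(10:200, 1000, replace = TRUE))
  expect_equal(
    integration_density(bins, sig),
    vapply(seq_along(bins), function(i)
      sum(pos >= BiocGenerics::start(bins)[i] &
            pos <= BiocGenerics::end(bins)[i]), 1) /
      BiocGenerics::width(bins))
})

test_that("density_cutoff equals direct Poisson tail summation", {
  # oracle: smallest k with sum_{x>=k} dpois(x, m) < alpha
  oracle_k <- function(m, alpha) {
    k <- 1
    while (sum(dpois(k:(k + 400), m)) >= alpha) k <- k + 1
    k
  }
  # the spec example pair (m = 0.75, alpha = 1e-4) resolves to k = 7
  # under the stated rule (P(X >= 5) = 1.06e-3 is not < 1e-4)
  expect_equal(attr(density_cutoff(750, 150000, alpha = 1e-4), "k"), 7L)
  expect_equal(attr(density_cutoff(750, 150000, alpha = 5e-3), "k"), 5L)
  # alpha = 1: any nonzero bin passes
  expect_equal(as.numeric(density_cutoff(750, 150000, alpha = 1)), 1 / 150)
  # override contract
  expect_equal(density_cutoff(750, 150000, override = 0.1), 0.1)
  set.seed(5)
  for (i in 1:20) {
    total <- sample(100:50000, 1)
    glen <- sample(1e5:1e7, 1)
    alpha <- 10^runif(1, -6, -1)
    m <- 150 * total / glen
    expect_equal(attr(density_cutoff(total, glen, alpha = alpha), "k"),
                 oracle_k(m, alpha))
  }
  expect_error(density_cutoff(0, 1000), "no integrations")
})

test_that("merge_bins follows the bedtools -d convention", {
  m <- merge_bins(gr("chr1A", c(1, 101), c(150, 250)))
  expect_equal(c(BiocGenerics::start(m), BiocGenerics::end(m)), c(1L, 250L))
  # gap exactly 150 merges ...
  m <- merge_bins(gr("chr1A", c(1, 301), c(150, 450)))
  expect_equal(length(m), 1L)
  # ... gap 151 does not
  m <- merge_bins(gr("chr1A", c(1, 302), c(150, 451)))
  expect_equal(length(m), 2L)
  expect_error(merge_bins(gr(c("chr1A", "chr1B"), 1, 10)),
               "single chromosome")
})

test_that("refine pipeline equals per-bp brute force on random fixtures", {
  # oracle: mark every bp covered by a passing bin; maximal runs closing
  # holes <= gap
  brute <- function(peak_start, peak_end, pos, cutoff, gap = 150) {
    L <- peak_end + 400
    covered <- logical(L)
    w <- peak_end - peak_start + 1
    starts <- if (w < 150) peak_start else
      seq(peak_start, by = 50, length.out = floor((w - 150) / 50) + 1)
    bw <- min(w, 150)
    for (s in starts) {
      cnt <- sum(pos >= s & pos <= s + bw - 1)
      if (cnt / bw >= cutoff) covered[s:(s + bw - 1)] <- TRUE
    }
    if (!any(covered)) return(NULL)
    idx <- which(covered)
    brk <- which(diff(idx) > gap + 1)
    st <- idx[c(1, brk + 1)]
    en <- idx[c(brk, length(idx))]
    cbind(st, en)
  }
  set.seed(6)
  for (i in 1:60) {
    ps <- sample(200:2000, 1)
    pe <- ps + sample(30:1200, 1)
    pos <- sort(sample(ps:pe, sample(0:300, 1), replace = TRUE))
    cutoff <- sample(c(1, 3, 8, 20), 1) / 150
    sig <- tn5_signal(list(chr1A = pos), "x", tissue = "leaf")
    got <- refine_peaks(gr("chr1A", ps, pe), sig, 1e6, cutoff = cutoff)
    want <- brute(ps, pe, pos, cutoff)
    if (is.null(want)) {
      expect_equal(length(got), 0L)
    } else {
      expect_equal(BiocGenerics::start(got), unname(want[, 1]))
      expect_equal(BiocGenerics::end(got), unname(want[, 2]))
    }
  }
})

test_that("refine_peaks drops blacklisted intervals and decoy peaks", {
  pos <- sort(sample(1001:1300, 90, replace = TRUE))
  sig <- tn5_signal(list(chr1A = pos), "x", tissue = "leaf")
  peaks <- gr("chr1A", c(801, 5001), c(1500, 5600))
  acrs <- refine_peaks(peaks, sig, 1e6, cutoff = 5 / 150)
  expect_equal(length(acrs), 1L)  # decoy peak has no signal -> no ACR
  expect_true(BiocGenerics::start(acrs) >= 801 &&
                BiocGenerics::end(acrs) <= 1500)
  # same peak fully inside a blacklist region -> dropped
  none <- refine_peaks(peaks, sig, 1e6, cutoff = 5 / 150,
                       blacklist = gr("chr1A", 700, 1600))
  expect_equal(length(none), 0L)
})

test_that("refined ACRs are disjoint with pairwise gap > merge gap and
           every ACR contains a passing bin", {
  sim <- tiny_sim()
  ts <- "DAP9"
  sig <- sim$signals[[paste0(ts, "_r1")]]
  acrs <- refine_peaks(sim$raw_peaks[[ts]], sig, sim$genome)
  expect_gt(length(acrs), 0)
  for (chr in unique(as.character(GenomeInfoDb::seqnames(acrs)))) {
    a <- acrs[GenomeInfoDb::seqnames(acrs) == chr]
    if (length(a) > 1) {
      gaps <- BiocGenerics::start(a)[-1] - BiocGenerics::end(a)[-length(a)] - 1
      expect_true(all(gaps > 150))
    }
  }
  expect_true(all(acrs$n_bins >= 1))
  # audit: each ACR holds at least one bin at or above the cutoff
  cut <- density_cutoff(sig, sim$genome)
  bins <- split_into_bins(acrs)
  d <- integration_density(bins, sig)
  pass_per_acr <- tapply(d, bins$peak_idx, max)
  expect_true(all(pass_per_acr >= cut))
})

test_that("acr_center uses floor((start0+end0)/2)", {
  # 0-based (100, 250) -> center0 175 -> 1-based 176
  expect_equal(acr_center(gr("chr1A", 101, 250)), 176L)
  # odd length
  expect_equal(acr_center(gr("chr1A", 101, 251)), 176L)
})

test_that("classify_acrs applies the genic/proximal/distal boundary rule", {
  genes <- gr("chr1A", 10000, 12000, strand = "+")
  genes$gene_id <- "g1"
  centers <- c(11000,          # inside -> genic
               10000 - 1999,   # 1999 upstream -> proximal
               10000 - 2000,   # exactly 2000 -> proximal
               10000 - 2001,   # 2001 -> distal
               12000 + 2000,   # downstream of TES boundary -> proximal
               12000 + 2001)
  acrs <- gr("chr1A", centers, centers)      # width 1: center = the bp
  got <- classify_acrs(acrs, genes)$class
  expect_equal(got, c("genic", "proximal", "proximal", "distal",
                      "proximal", "distal"))
})

test_that("class fractions on the fixture match planted classes and are
           monotone in the cutoff", {
  sim <- tiny_sim()
  tr <- sim$truth$acrs
  planted <- gr(tr$chrom, tr$start, tr$end)
  got <- classify_acrs(planted, sim$genes)$class
  expect_equal(got, tr$class)
  cuts <- c(2, 4, 5, 6, 8, 10) * 1000
  distal_frac <- vapply(cuts, function(cut)
    mean(classify_acrs(planted, sim$genes, cutoff = cut)$class == "distal"),
    1)
  expect_true(all(diff(distal_frac) <= 0))
})

test_that("replicate_correlation: identity, ordering, degenerate input", {
  sim <- tiny_sim()
  a <- sim$signals[["DAP15_r1"]]
  expect_equal(replicate_correlation(a, a, sim$genome), 1.0)
  # same tissue replicates share planted structure; tissues with disjoint
  # planted ACR sets (leaf vs DAP15) share only background
  r_rep <- replicate_correlation(a, sim$signals[["DAP15_r2"]], sim$genome)
  r_cross <- replicate_correlation(a, sim$signals[["leaf_r1"]], sim$genome)
  expect_gt(r_rep, r_cross + 0.05)
  empty <- tn5_signal(list(), "e")
  expect_warning(r <- replicate_correlation(empty, a, sim$genome),
                 "constant")
  expect_true(is.na(r))
})

test_that("variation_metaprofile: null flatness and single-variant case", {
  genes <- gr("chr1A", 1, 100, strand = "+")
  genes$gene_id <- "g"
  acrs <- gr("chr1A", 49851, 50149)   # center 50000, far from the gene
  # single variant at the center -> only the central bin is hit
  prof <- variation_metaprofile(acrs, gr("chr1A", 50000, 50000), genes)
  expect_equal(sum(prof$count), 1L)
  expect_equal(prof$density[prof$offset_start == 0], 1 / 50)
  # uniform variants -> approximately flat
  set.seed(8)
  vpos <- sample(40000:60000, 5000)
  prof <- variation_metaprofile(acrs, gr("chr1A", vpos, vpos), genes)
  expect_equal(length(prof$density), 80L)
  # no systematic central dip: center-vs-flank ratio near 1
  ctr <- mean(prof$density[abs(prof$offset_mid) <= 250])
  flk <- mean(prof$density[abs(prof$offset_mid) > 250])
  expect_lt(abs(ctr / flk - 1), 0.25)
  # no qualifying ACRs -> warning, empty profile
  near <- gr("chr1A", 120, 419)
  expect_warning(p0 <- variation_metaprofile(near, gr("chr1A", 1, 1), genes),
                 "no ACR centers")
  expect_equal(attr(p0, "n_acrs"), 0L)
})
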