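# Shared fixtures, memoized per test run.
#
# tiny_sim(): small fast simulation for unit tests.
# default_run(): one full default-scale simulation + pipeline (seed 7),
#   shared by the acceptance criteria that measure recovery on the
#   default stated world.

.fixture_cache <- new.env(parent = emptyenv())

tiny_config <- function(seed = 11) {
  sim_config(seed = seed,
             n_triads = 48, n_singletons = 39,
             chrom_length = 61 * 6000,
             acrs_per_pattern = 12,
             n_switch_triads = 10,
             n_targets_per_tf = 2)
}

tiny_sim <- function() {
  if (is.null(.fixture_cache$tiny))
    .fixture_cache$tiny <- simulate_hexaploid(tiny_config())
  .fixture_cache$tiny
}

default_run <- function() {
  if (is.null(.fixture_cache$default_run)) {
    sim <- simulate_hexaploid(sim_config(seed = 7))
    out <- file.path(tempdir(), "wheatacr_default_run")
    res <- run_pipeline(pipeline_config(seed = 7), out, sim = sim,
                        quiet = TRUE, force = TRUE)
    .fixture_cache$default_run <- list(sim = sim, res = res, outdir = out)
  }
  .fixture_cache$default_run
}

# simple GRanges builder for tests
gr <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand)
}

edge_key <- function(df) paste(df$stage, df$tf_gene_id, df$target_gene_id)
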