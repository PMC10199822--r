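#' Read a BED file into a GRanges
#'
#' BED coordinates are 0-based half-open on disk; the returned
#' [GenomicRanges::GRanges] is 1-based closed (the package-internal
#' convention). Columns 4-6 are mapped to `name`, `score` and strand when
#' present. Malformed records are hard errors naming the offending line.
#'
#' @param path Path to a BED file (3-6 tab-separated columns).
#' @return A `GRanges`; metadata columns `name`/`score` if present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", idx[which(nf < 3L)[1]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("BED line ", idx[bad[1]], ": non-integer coordinates")
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop("BED line ", idx[bad[1]], ": end <= start (zero-length or negative)")
  bad <- which(!nzchar(chrom))
  if (length(bad))
    stop("BED line ", idx[bad[1]], ": empty chromosome name")
  strand <- rep("*", length(idx))
  if (all(nf >= 6L)) {
    s6 <- vapply(fields, `[`, "", 6L)
    strand <- ifelse(s6 %in% c("+", "-"), s6, "*")
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = strand)
  if (all(nf >= 4L))
    gr$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5L))
    gr$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  gr
}

#' Write a GRanges to BED (0-based half-open on disk)
#'
#' @param gr A `GRanges`; `name` and `score` metadata columns are written as
#'   BED columns 4-5 when present (strand then as column 6).
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, header = NULL) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  strand <- as.character(BiocGenerics::strand(gr))
  has_name <- !is.null(gr$name)
  has_score <- !is.null(gr$score)
  has_strand <- any(strand != "*")
  if (has_name || has_score || has_strand)
    df$name <- if (has_name) gr$name else "."
  if (has_score || has_strand)
    df$score <- if (has_score) gr$score else 0
  if (has_strand)
    df$strand <- ifelse(strand == "*", ".", strand)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` features, computes strand-aware TSS/TES and infers the
#' subgenome of each gene from its chromosome name. GFF3 1-based inclusive
#' coordinates map directly onto the internal GRanges convention.
#'
#' @param path Path to a GFF3 file.
#' @param subgenome_pattern Passed to [infer_subgenome()].
#' @return `GRanges` with metadata columns `gene_id`, `subgenome`, `tss`,
#'   `tes` (all coordinates 1-based bp).
#' @export
read_gff3_genes <- function(path, subgenome_pattern = "([ABD])$") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  ids <- genes$ID
  if (is.null(ids) || any(is.na(ids) | !nzchar(ids)))
    stop("gene feature lacking an ID attribute in ", path)
  strand <- as.character(BiocGenerics::strand(genes))
  if (any(!strand %in% c("+", "-")))
    stop("gene with strand outside {+,-} in ", path)
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                               IRanges::ranges(genes), strand = strand)
  gr$gene_id <- as.character(ids)
  gr$subgenome <- unname(infer_subgenome(
    as.character(GenomeInfoDb::seqnames(gr)), subgenome_pattern))
  gr$tss <- ifelse(strand == "+", BiocGenerics::start(gr),
                   BiocGenerics::end(gr))
  gr$tes <- ifelse(strand == "+", BiocGenerics::end(gr),
                   BiocGenerics::start(gr))
  names(gr) <- gr$gene_id
  gr
}

#' Write gene models to GFF3
#' @param genes `GRanges` with a `gene_id` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  df <- data.frame(seqid = as.character(GenomeInfoDb::seqnames(genes)),
                   source = "wheatacr", type = "gene",
                   start = BiocGenerics::start(genes),
                   end = BiocGenerics::end(genes),
                   score = ".", strand = as.character(BiocGenerics::strand(genes)),
                   phase = ".",
                   attributes = paste0("ID=", genes$gene_id),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a counts (or TPM) matrix from TSV
#'
#' Expects a header row of sample IDs and gene IDs in the first column.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, genes x samples.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write a matrix to TSV with gene IDs in the first column
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the first column.
#' @param header Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id", header = NULL) {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  dt <- cbind(dt, data.table::as.data.table(m))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(dt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a homeolog triad table
#'
#' @param path TSV with columns `triad_id`, `gene_id_A`, `gene_id_B`,
#'   `gene_id_D`.
#' @return A `data.frame` of triads.
#' @export
read_triads <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("triad_id", "gene_id_A", "gene_id_B", "gene_id_D")
  if (!all(need %in% names(dt)))
    stop("triad table must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(dt[, need, with = FALSE])
  bad <- apply(df[, -1], 1, function(x) anyDuplicated(x) > 0)
  if (any(bad))
    stop("triad with non-distinct gene IDs: ", df$triad_id[which(bad)[1]])
  df
}

#' Read variant positions from BED or VCF
#'
#' Only positions are used. For VCF the POS column (1-based) is taken; for
#' BED the (0-based) start of each record.
#'
#' @param path Path to a `.bed` or `.vcf` file.
#' @return `GRanges` of width-1 positions.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    dt <- data.table::fread(path, sep = "\t", header = FALSE, skip = "#CHROM",
                            select = 1:2,
                            col.names = c("chrom", "pos"))
    # fread treats the "#CHROM" header row as data start; drop it
    dt <- dt[!grepl("^#", dt$chrom)]
    GenomicRanges::GRanges(dt$chrom,
                           IRanges::IRanges(as.integer(dt$pos), width = 1L))
  } else {
    gr <- read_bed(path)
    GenomicRanges::resize(gr, width = 1L, fix = "start")
  }
}

#' Per-sample Tn5 integration signal
#'
#' Holds sorted integration-site positions per chromosome for one
#' tissue/replicate sample, the per-bp unit of chromatin accessibility.
#'
#' @param positions Named list (by chromosome) of integer positions (1-based
#'   bp), any order; sorted internally.
#' @param sample_id,tissue,replicate Sample annotation.
#' @return An object of class `tn5_signal` with fields `positions` (sorted),
#'   `total` (integration count), `sample_id`, `tissue`, `replicate`.
#' @export
tn5_signal <- function(positions, sample_id, tissue = NA_character_,
                       replicate = NA_integer_) {
  positions <- lapply(positions, function(p) sort(as.integer(p)))
  structure(list(sample_id = sample_id, tissue = tissue,
                 replicate = replicate, positions = positions,
                 total = sum(lengths(positions))),
            class = "tn5_signal")
}

#' @export
print.tn5_signal <- function(x, ...) {
  cat("tn5_signal", x$sample_id, "(", x$tissue, "rep", x$replicate, "):",
      format(x$total, big.mark = ","), "integration sites on",
      length(x$positions), "chromosomes\n")
  invisible(x)
}

#' Read Tn5 integration sites from a width-1 BED file
#' @param path BED path (each record a single integration site).
#' @param sample_id,tissue,replicate Sample annotation.
#' @return A [tn5_signal()].
#' @export
read_tn5_bed <- function(path, sample_id = basename(path),
                         tissue = NA_character_, replicate = NA_integer_) {
  gr <- read_bed(path)
  pos <- split(BiocGenerics::start(gr),
               as.character(GenomeInfoDb::seqnames(gr)))
  tn5_signal(pos, sample_id, tissue, replicate)
}

#' Integration sites of a signal as width-1 GRanges
#' @param signal A `tn5_signal`.
#' @return `GRanges` of positions.
#' @export
signal_granges <- function(signal) {
  chroms <- rep(names(signal$positions), lengths(signal$positions))
  GenomicRanges::GRanges(chroms,
                         IRanges::IRanges(unlist(signal$positions,
                                                 use.names = FALSE),
                                          width = 1L))
}

#' Write integration sites to BED
#' @param signal A `tn5_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tn5_bed <- function(signal, path) {
  write_bed(signal_granges(signal), path)
}
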