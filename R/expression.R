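#' TPM from raw counts
#'
#' Transcripts per million: per sample, `tpm_g = 1e6 * (c_g/l_g) /
#' sum_j(c_j/l_j)`. Each column of the result sums to 1e6; an all-zero
#' sample yields an all-zero column with a warning.
#'
#' @param counts Non-negative numeric matrix (genes x samples) or vector.
#' @param gene_lengths Positive gene lengths in bp, one per gene.
#' @return Matrix (or vector) of TPM values, same shape as `counts`.
#' @export
tpm_from_counts <- function(counts, gene_lengths) {
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, ncol = 1) else as.matrix(counts)
  if (length(gene_lengths) != nrow(m))
    stop("gene_lengths must have one entry per gene")
  if (any(m < 0)) stop("negative counts")
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  rate <- m / gene_lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s); TPM set to 0 for those")
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  if (vec) tpm[, 1] else tpm
}

#' Bundle an expression experiment
#'
#' Wraps counts, derived TPM, gene lengths and the tissue x replicate design
#' into a [SummarizedExperiment::SummarizedExperiment] (assays `counts` and
#' `tpm`; `rowData$gene_length`; `colData$tissue`, `colData$replicate`).
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param gene_lengths Named (or ordered) gene lengths in bp.
#' @param tissue Tissue label per sample.
#' @param replicate Replicate number per sample.
#' @return A `SummarizedExperiment`.
#' @export
expression_dataset <- function(counts, gene_lengths, tissue, replicate) {
  counts <- as.matrix(counts)
  if (length(tissue) != ncol(counts) || length(replicate) != ncol(counts))
    stop("tissue/replicate must have one entry per sample")
  tpm <- tpm_from_counts(counts, gene_lengths)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm),
    rowData = S4Vectors::DataFrame(gene_length = gene_lengths,
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(tissue = tissue, replicate = replicate,
                                   row.names = colnames(counts)))
}

#' Per-tissue means of a sample-level matrix
#'
#' @param m Matrix, features x samples.
#' @param tissue Tissue label per column.
#' @return Matrix, features x tissues (column order = first occurrence).
#' @export
tissue_means <- function(m, tissue) {
  tissues <- unique(tissue)
  out <- vapply(tissues,
                function(t) rowMeans(m[, tissue == t, drop = FALSE]),
                numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), tissues)
  out
}
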