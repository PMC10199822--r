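#' Genome index for a hexaploid assembly
#'
#' Bundles chromosome lengths, the A/B/D subgenome partition and an optional
#' sequence accessor. The subgenome of each chromosome is inferred from its
#' name via a configurable regex (default: trailing letter of names like
#' `"chr1A"`); chromosomes that do not match are labelled `"other"` and are
#' excluded from subgenome-stratified analyses only.
#'
#' @param seqlengths Named integer vector of chromosome lengths (bp).
#' @param sequence Optional [Biostrings::DNAStringSet] with one entry per
#'   chromosome (names must match `names(seqlengths)`).
#' @param subgenome Optional named character vector overriding inference.
#' @param subgenome_pattern Regex with one capture group extracting the
#'   subgenome letter from a chromosome name.
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(seqlengths, sequence = NULL, subgenome = NULL,
                         subgenome_pattern = "([ABD])$") {
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths))))
    stop("seqlengths must be a named vector of chromosome lengths")
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  if (any(is.na(seqlengths)) || any(seqlengths <= 0L))
    stop("chromosome lengths must be positive integers")
  if (is.null(subgenome)) {
    subgenome <- infer_subgenome(names(seqlengths), subgenome_pattern)
  } else {
    subgenome <- subgenome[names(seqlengths)]
  }
  if (!is.null(sequence)) {
    if (!all(names(seqlengths) %in% names(sequence)))
      stop("sequence must cover every chromosome in seqlengths")
    sequence <- sequence[names(seqlengths)]
  }
  structure(list(seqlengths = seqlengths, subgenome = subgenome,
                 sequence = sequence),
            class = "genome_index")
}

#' Infer subgenome labels from chromosome names
#'
#' @param chroms Character vector of chromosome names.
#' @param pattern Regex with one capture group yielding the subgenome letter.
#' @return Character vector over `{A, B, D, other}`, named by `chroms`.
#' @export
infer_subgenome <- function(chroms, pattern = "([ABD])$") {
  m <- regmatches(chroms, regexec(pattern, chroms))
  lab <- vapply(m, function(x) if (length(x) >= 2) x[2] else "", "")
  lab[!lab %in% c("A", "B", "D")] <- "other"
  stats::setNames(lab, chroms)
}

#' Total genome length of a genome index
#' @param genome A `genome_index`.
#' @return Total length in bp.
#' @export
genome_length <- function(genome) sum(as.numeric(genome$seqlengths))

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$seqlengths), "chromosomes,",
      format(genome_length(x), big.mark = ","), "bp\n")
  cat("  subgenomes:", paste(sprintf("%s=%d", names(table(x$subgenome)),
                                     table(x$subgenome)), collapse = " "), "\n")
  cat("  sequence:", if (is.null(x$sequence)) "absent" else "present", "\n")
  invisible(x)
}

# internal: check intervals fit within the genome
check_within_genome <- function(gr, genome) {
  sl <- genome$seqlengths[as.character(GenomeInfoDb::seqnames(gr))]
  if (any(is.na(sl)))
    stop("interval on chromosome absent from genome index")
  if (any(BiocGenerics::start(gr) < 1L) || any(BiocGenerics::end(gr) > sl))
    stop("interval outside chromosome bounds")
  invisible(TRUE)
}
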