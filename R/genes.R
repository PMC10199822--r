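#' Strand-aware promoter windows
#'
#' The promoter of a gene is the window from `upstream` bp before the TSS to
#' `downstream` bp after it (default -2000/+100, the window used throughout
#' for "promoter accessibility"). Windows are clipped at chromosome edges
#' when lengths are available; clipping is recorded in a `clipped` column.
#'
#' @param genes `GRanges` of gene models (strand `+`/`-`, `gene_id` column).
#' @param upstream,downstream Window extent in bp around the TSS.
#' @param seqlengths Optional named chromosome lengths for clipping.
#' @return `GRanges` of promoter windows with `gene_id` and `clipped`.
#' @export
promoter_region <- function(genes, upstream = 2000, downstream = 100,
                            seqlengths = NULL) {
  strand <- as.character(BiocGenerics::strand(genes))
  if (any(!strand %in% c("+", "-")))
    stop("genes must be stranded (+/-) to define promoters")
  tss <- ifelse(strand == "+", BiocGenerics::start(genes),
                BiocGenerics::end(genes))
  start <- ifelse(strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream)
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  clipped <- rep(FALSE, length(genes))
  clip_lo <- start < 1L
  start[clip_lo] <- 1L
  clipped <- clipped | clip_lo
  if (!is.null(seqlengths)) {
    sl <- seqlengths[chrom]
    if (any(is.na(sl))) stop("promoter on chromosome absent from seqlengths")
    if (any(tss < 1 | tss > sl)) stop("TSS outside chromosome bounds")
    clip_hi <- end > sl
    end[clip_hi] <- sl[clip_hi]
    clipped <- clipped | clip_hi
  }
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                strand = strand)
  out$gene_id <- genes$gene_id
  out$clipped <- clipped
  names(out) <- genes$gene_id
  out
}

#' Nearest gene and distance for genomic points
#'
#' Distance is 0 when a point falls inside a gene body, otherwise the bp gap
#' to the nearest gene edge. Ties are broken by the lexicographically
#' smaller `gene_id` so results are deterministic. Points on chromosomes
#' without genes get `NA` gene and distance (reported, not an error). The
#' signed distance is negative when the point lies left of the gene start
#' in genomic orientation, positive when right of the gene end.
#'
#' @param points `GRanges` of positions (width-1 ranges; wider ranges are
#'   reduced to their start).
#' @param genes `GRanges` with a `gene_id` column.
#' @return `data.frame` with `gene_id`, `distance`, `signed_distance`.
#' @export
nearest_gene <- function(points, genes) {
  n <- length(points)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    signed_distance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (length(genes) == 0L) return(out)
  g_unstranded <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                         IRanges::ranges(genes))
  p <- GenomicRanges::resize(GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(points), IRanges::ranges(points)), 1L, "start")
  # points on chromosomes without genes simply get NA (warning-free)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(p, g_unstranded, select = "all"))
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ppos <- BiocGenerics::start(p)[q]
  gstart <- BiocGenerics::start(genes)[s]
  gend <- BiocGenerics::end(genes)[s]
  # arithmetic bp distance: adjacent base = 1, inside gene body = 0
  d <- ifelse(ppos < gstart, gstart - ppos, ifelse(ppos > gend, ppos - gend, 0))
  dt <- data.table::data.table(q = q, d = d, gid = genes$gene_id[s],
                               sgn = ifelse(ppos < gstart, -1,
                                            ifelse(ppos > gend, 1, 0)))
  data.table::setorderv(dt, c("q", "d", "gid"))
  best <- dt[!duplicated(dt$q)]
  out$gene_id[best$q] <- best$gid
  out$distance[best$q] <- best$d
  out$signed_distance[best$q] <- best$sgn * best$d
  out
}
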