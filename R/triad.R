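#' Ternary bias category centroids
#'
#' The seven reference points on the (A, B, D) expression-fraction simplex:
#' Balanced (1/3, 1/3, 1/3); A/B/D-Dominant at the corners; A/B/D-Suppressed
#' at the opposite edge midpoints.
#'
#' @return 7 x 3 numeric matrix, rows named by category.
#' @export
bias_centroids <- function() {
  m <- rbind(Balanced = c(1, 1, 1) / 3,
             ADominant = c(1, 0, 0),
             BDominant = c(0, 1, 0),
             DDominant = c(0, 0, 1),
             ASuppressed = c(0, 1, 1) / 2,
             BSuppressed = c(1, 0, 1) / 2,
             DSuppressed = c(1, 1, 0) / 2)
  colnames(m) <- c("A", "B", "D")
  m
}

#' Bias category labels (including NotExpressed)
#' @return Character vector of the eight labels.
#' @export
bias_levels <- function() c(rownames(bias_centroids()), "NotExpressed")

#' Classify a homeolog triad by ternary bias
#'
#' Triads whose summed value falls below `min_sum` are `NotExpressed`.
#' Otherwise the (A, B, D) fractions are compared by Euclidean distance to
#' the seven centroids; the nearest wins, with ties resolved to Balanced
#' first and then centroid enumeration order, so classification is total
#' and deterministic on the whole simplex.
#'
#' @param values Numeric length-3 vector `(vA, vB, vD)` or an n x 3 matrix
#'   (TPM or promoter accessibility scores; non-negative).
#' @param min_sum Minimum summed value to count as expressed.
#' @param centroids Centroid matrix (rows = categories), configurable.
#' @return `data.frame` with `category`, `fA`, `fB`, `fD`, `distance`.
#' @export
classify_triad <- function(values, min_sum = 0.5,
                           centroids = bias_centroids()) {
  m <- if (is.null(dim(values))) matrix(values, nrow = 1) else
    as.matrix(values)
  if (ncol(m) != 3) stop("values must have three homeolog columns")
  if (any(m < 0)) stop("negative values")
  tot <- rowSums(m)
  frac <- m / ifelse(tot > 0, tot, 1)
  d2 <- vapply(seq_len(nrow(centroids)), function(k)
    rowSums(sweep(frac, 2, centroids[k, ])^2), numeric(nrow(m)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  # max.col(ties = "first") honours row order of bias_centroids(), whose
  # first row is Balanced -> ties resolve to Balanced, then enumeration
  best <- max.col(-d2, ties.method = "first")
  category <- rownames(centroids)[best]
  distance <- sqrt(d2[cbind(seq_len(nrow(m)), best)])
  ne <- tot < min_sum
  category[ne] <- "NotExpressed"
  frac[ne, ] <- NA_real_
  distance[ne] <- NA_real_
  data.frame(category = category, fA = frac[, 1], fB = frac[, 2],
             fD = frac[, 3], distance = distance,
             stringsAsFactors = FALSE)
}

#' Classify all triads across tissues
#'
#' Applies [classify_triad()] to every triad in every tissue, using either
#' replicate-mean TPM (expression mode) or promoter accessibility scores
#' (accessibility mode) — the classifier is identical in both modes.
#' Triads with a member missing from the matrix are skipped with a warning.
#'
#' @param triads `data.frame` with `triad_id`, `gene_id_A`, `gene_id_B`,
#'   `gene_id_D`.
#' @param value_matrix Genes x tissues matrix of per-tissue mean values
#'   (e.g. from [tissue_means()]), rownames = gene IDs.
#' @param min_sum Passed to [classify_triad()].
#' @param mode Label recorded on the output (`"expression"` or
#'   `"promoter_accessibility"`).
#' @return `data.frame`: one row per triad per tissue with values,
#'   fractions, `category` and `distance`; attribute `n_skipped`.
#' @export
classify_triads <- function(triads, value_matrix, min_sum = 0.5,
                            mode = c("expression",
                                     "promoter_accessibility")) {
  mode <- match.arg(mode)
  have <- triads$gene_id_A %in% rownames(value_matrix) &
    triads$gene_id_B %in% rownames(value_matrix) &
    triads$gene_id_D %in% rownames(value_matrix)
  if (any(!have))
    warning(sum(!have), " triad(s) with missing genes skipped")
  tr <- triads[have, , drop = FALSE]
  tissues <- colnames(value_matrix)
  res <- lapply(tissues, function(ts) {
    v <- cbind(value_matrix[tr$gene_id_A, ts],
               value_matrix[tr$gene_id_B, ts],
               value_matrix[tr$gene_id_D, ts])
    cl <- classify_triad(v, min_sum = min_sum)
    data.frame(triad_id = tr$triad_id, tissue = ts, mode = mode,
               vA = v[, 1], vB = v[, 2], vD = v[, 3], cl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!have)
  out
}

#' Category transition counts between adjacent tissues
#'
#' For each adjacent pair in `tissue_order`, an 8 x 8 matrix of triad
#' counts moving from one bias category to another (NotExpressed included
#' as a node); row sums equal the number of classified triads, so tidy
#' output is directly consumable by Sankey renderers.
#'
#' @param profiles Output of [classify_triads()].
#' @param tissue_order Character vector of tissues in developmental order.
#' @return List with `matrices` (named list of 8 x 8 matrices) and `tidy`
#'   (`data.frame`: `from_tissue`, `to_tissue`, `from`, `to`, `count`).
#' @export
transition_table <- function(profiles, tissue_order) {
  if (!all(tissue_order %in% profiles$tissue))
    stop("profiles missing tissue(s): ",
         paste(setdiff(tissue_order, profiles$tissue), collapse = ", "))
  lev <- bias_levels()
  mats <- list()
  tidy <- list()
  for (k in seq_len(length(tissue_order) - 1)) {
    t1 <- tissue_order[k]; t2 <- tissue_order[k + 1]
    a <- profiles[profiles$tissue == t1, ]
    b <- profiles[profiles$tissue == t2, ]
    ids <- intersect(a$triad_id, b$triad_id)
    m <- table(factor(a$category[match(ids, a$triad_id)], levels = lev),
               factor(b$category[match(ids, b$triad_id)], levels = lev))
    m <- unclass(m)
    names(dimnames(m)) <- NULL
    key <- paste(t1, t2, sep = "->")
    mats[[key]] <- m
    df <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
    names(df) <- c("from", "to", "count")
    tidy[[key]] <- data.frame(from_tissue = t1, to_tissue = t2, df,
                              stringsAsFactors = FALSE)
  }
  list(matrices = mats, tidy = do.call(rbind, c(tidy, make.row.names = FALSE)))
}

#' Concordance between expression and accessibility bias
#'
#' Per tissue: (i) the category agreement rate between the two
#' classifications (triads NotExpressed in either mode excluded), and (ii)
#' the Pearson correlation between expression fractions and accessibility
#' fractions pooled over triads (three fraction values per triad), with a
#' correlation test p-value.
#'
#' @param expr_profiles,acc_profiles Outputs of [classify_triads()] on the
#'   same triads and tissues.
#' @return `data.frame` per tissue: `agreement`, `r`, `p`, `n_triads`.
#' @export
bias_concordance <- function(expr_profiles, acc_profiles) {
  tissues <- intersect(unique(expr_profiles$tissue),
                       unique(acc_profiles$tissue))
  if (length(tissues) == 0L) stop("no common tissues")
  out <- lapply(tissues, function(ts) {
    e <- expr_profiles[expr_profiles$tissue == ts, ]
    a <- acc_profiles[acc_profiles$tissue == ts, ]
    ids <- intersect(e$triad_id, a$triad_id)
    if (length(ids) == 0L) stop("no common triads in tissue ", ts)
    e <- e[match(ids, e$triad_id), ]
    a <- a[match(ids, a$triad_id), ]
    ok <- e$category != "NotExpressed" & a$category != "NotExpressed"
    agree <- mean(e$category[ok] == a$category[ok])
    ef <- c(e$fA[ok], e$fB[ok], e$fD[ok])
    af <- c(a$fA[ok], a$fB[ok], a$fD[ok])
    ct <- stats::cor.test(ef, af)
    data.frame(tissue = ts, agreement = agree, r = unname(ct$estimate),
               p = ct$p.value, n_triads = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
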