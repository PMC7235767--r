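# OTU-table summarisation: relative abundances, rank aggregation, top-N
# taxon selection, Bray-Curtis dissimilarity and principal-coordinates
# ordination.

#' Convert counts to per-sample relative abundances
#'
#' Each sample's counts are closed to proportions.  Samples with zero
#' total are not divided: their proportions are set to `NA` and the
#' sample is flagged in the `empty_samples` field.
#'
#' @param t an [abundance_table()].
#' @return An object of class `relative_profile` with fields
#'   `proportions` (samples x taxa), `samples`, `taxonomy` and
#'   `empty_samples` (named logical).
#' @export
relative_abundance <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  totals <- rowSums(t$counts)
  empty <- totals == 0
  props <- t$counts / ifelse(empty, NA_real_, totals)
  structure(list(proportions = props, samples = t$samples,
                 taxonomy = t$taxonomy, empty_samples = empty),
            class = "relative_profile")
}

#' @export
print.relative_profile <- function(x, ...) {
  cat(sprintf("<relative_profile> %d samples x %d taxa (%d empty)\n",
              nrow(x$proportions), ncol(x$proportions),
              sum(x$empty_samples)))
  invisible(x)
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Counts are summed over taxa sharing the label at `rank`.  Taxa with
#' unresolved lineage at that rank are grouped as
#' `"unclassified-<parent>"`, where the parent is the deepest resolved
#' label above `rank` (or `"unclassified-root"` when nothing is
#' resolved).  Per-sample totals are conserved exactly.
#'
#' @param t an [abundance_table()].
#' @param rank one of the ranks present in `t$taxonomy`.
#' @return An [abundance_table()] whose taxa are labels at `rank`.
#' @export
aggregate_rank <- function(t, rank) {
  stopifnot(inherits(t, "abundance_table"))
  if (!rank %in% TAXONOMY_RANKS || !rank %in% names(t$taxonomy)) {
    abort(sprintf("unknown or absent rank '%s'", rank),
          "digestor_domain_error")
  }
  ranks_above <- TAXONOMY_RANKS[seq_len(match(rank, TAXONOMY_RANKS) - 1L)]
  ranks_above <- intersect(ranks_above, names(t$taxonomy))
  labels <- as.character(t$taxonomy[[rank]])
  for (i in which(is.na(labels) | labels == "")) {
    parent <- NA_character_
    for (ra in rev(ranks_above)) {
      v <- t$taxonomy[i, ra]
      if (!is.na(v) && nzchar(v)) { parent <- v; break }
    }
    labels[i] <- paste0("unclassified-", if (is.na(parent)) "root" else parent)
  }
  groups <- unique(labels)
  agg <- sapply(groups, function(g) {
    rowSums(t$counts[, labels == g, drop = FALSE])
  })
  if (nrow(t$counts) == 1L) agg <- matrix(agg, nrow = 1L,
                                          dimnames = list(rownames(t$counts),
                                                          groups))
  # lineage retained up to `rank` where consistent within a group
  keep_ranks <- c(ranks_above, rank)
  taxonomy <- as.data.frame(do.call(rbind, lapply(groups, function(g) {
    rows <- t$taxonomy[labels == g, keep_ranks, drop = FALSE]
    vapply(keep_ranks, function(rk) {
      u <- unique(as.character(rows[[rk]]))
      if (length(u) == 1L) u else NA_character_
    }, character(1))
  })))
  names(taxonomy) <- keep_ranks
  taxonomy[[rank]] <- groups
  abundance_table(agg, samples = t$samples, taxonomy = taxonomy)
}

#' Rank taxa by summed relative abundance
#'
#' Taxa are ordered by the sum of their proportions across all samples
#' (descending); exact ties break lexicographically by taxon id.  If `n`
#' exceeds the taxon count all taxa are returned with a warning.
#'
#' @param p a [relative_abundance()] profile.
#' @param n number of taxa to return (>= 1).
#' @return Character vector of taxon ids, most abundant first, with the
#'   summed proportions as the `scores` attribute.
#' @export
top_taxa <- function(p, n) {
  stopifnot(inherits(p, "relative_profile"))
  check_number(n, "n", lower = 1)
  sums <- colSums(p$proportions[!p$empty_samples, , drop = FALSE])
  if (n > length(sums)) {
    warning(sprintf("n = %d exceeds taxon count %d; returning all taxa",
                    n, length(sums)))
    n <- length(sums)
  }
  ord <- order(-sums, names(sums))
  ids <- names(sums)[ord][seq_len(n)]
  structure(ids, scores = unname(sums[ids]))
}

#' Taxa present in every condition's top-N
#'
#' Intersects the per-condition top-N lists, returning the shared taxa
#' ordered by overall abundance (summed proportions across all
#' profiles).  This is the taxon-selection rule used ahead of
#' Lotka-Volterra modelling.
#'
#' @param profiles named list (>= 2) of [relative_abundance()] profiles,
#'   one per condition.
#' @param n top-N depth per condition (default 10).
#' @return Character vector of taxon ids.
#' @export
intersect_top <- function(profiles, n = 10) {
  stopifnot(is.list(profiles), length(profiles) >= 2)
  tops <- lapply(profiles, top_taxa, n = n)
  shared <- Reduce(intersect, lapply(tops, as.character))
  overall <- Reduce(`+`, lapply(profiles, function(p) {
    colSums(p$proportions[!p$empty_samples, , drop = FALSE])
  }))
  shared[order(-overall[shared], shared)]
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` on per-sample
#' proportions: 0 for identical profiles, 1 for disjoint supports.
#' Rows/columns for flagged-empty samples are `NA`.
#'
#' @param p a [relative_abundance()] profile with >= 2 samples.
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(p) {
  stopifnot(inherits(p, "relative_profile"))
  x <- p$proportions
  if (nrow(x) < 2) abort(">= 2 samples required", "digestor_domain_error")
  rs <- rowSums(x)
  num <- as.matrix(stats::dist(x, method = "manhattan"))
  den <- outer(rs, rs, "+")
  bc <- num / den
  diag(bc) <- 0
  bc[p$empty_samples, ] <- NA_real_
  bc[, p$empty_samples] <- NA_real_
  bc
}

#' Principal-coordinates ordination of a dissimilarity matrix
#'
#' Classical metric scaling (PCoA) of the double-centred squared
#' dissimilarities.  Negative eigenvalues, which arise because
#' Bray-Curtis is not Euclidean, are reported rather than silently
#' dropped; explained-variance fractions are computed over the positive
#' eigenvalues.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (`NA`
#'   rows from masked samples are removed first).
#' @param k number of ordination axes (default 2, capped at n - 1).
#' @return List with `points` (samples x k coordinates), `eig` (all
#'   eigenvalues) and `explained` (fractions of the positive-eigenvalue
#'   total, one per returned axis).
#' @export
ordinate <- function(d, k = 2) {
  d <- as.matrix(d)
  keep <- !apply(d, 1L, function(r) all(is.na(r)))
  d <- d[keep, keep, drop = FALSE]
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    abort("dissimilarity matrix must be symmetric", "digestor_domain_error")
  }
  if (any(abs(diag(d)) > 1e-12)) {
    abort("dissimilarity matrix must have a zero diagonal",
          "digestor_domain_error")
  }
  n <- nrow(d)
  k <- min(k, n - 1L)
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate configurations may span fewer axes
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  pos <- sum(pmax(fit$eig, 0))
  explained <- if (pos > 0) pmax(fit$eig[seq_len(k)], 0) / pos else
    rep(0, k)
  list(points = pts, eig = fit$eig, explained = explained)
}
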