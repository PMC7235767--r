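# Multiple-testing adjustment, significance filtering, and the
# three-stressor Venn classification of taxa shifting against the
# control.

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, scales `p_(i) * m / i`, enforces
#' monotonicity from the largest rank down, caps at 1 and restores the
#' original order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1]", "digestor_domain_error")
  }
  m <- length(pvalues)
  o <- order(pvalues)
  scaled <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  # p * (m/i) can round one ulp below p at the top rank; the step-up
  # estimate is mathematically >= p, so pin it there
  adj <- pmin(pmax(adj, pvalues[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Extract significantly shifted taxa
#'
#' A taxon is significantly increased when its adjusted p-value is
#' strictly below `alpha` and its log2 fold change is positive;
#' decreased likewise with a negative fold change.  `padj == alpha`
#' exactly is excluded (the significance rule is "lower than alpha").
#' When `padj` is absent it is computed from `pvalue` via
#' [bh_adjust()].
#'
#' @param results `data.frame` with columns `taxon`, `log2fc`, and
#'   `padj` (or `pvalue`).
#' @param alpha significance level (default 0.05).
#' @return List of class `shift_sets` with character vectors
#'   `increased` and `decreased`.
#' @export
significant_shifts <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) {
    return(structure(list(increased = character(), decreased = character()),
                     class = "shift_sets"))
  }
  need <- c("taxon", "log2fc")
  if (!all(need %in% names(results))) {
    abort("results must have columns 'taxon' and 'log2fc'",
          "digestor_contract_error")
  }
  if (!"padj" %in% names(results)) {
    if (!"pvalue" %in% names(results)) {
      abort("results carry neither 'padj' nor 'pvalue'",
            "digestor_contract_error")
    }
    results$padj <- bh_adjust(results$pvalue)
  }
  sig <- results$padj < alpha
  structure(
    list(increased = as.character(results$taxon[sig & results$log2fc > 0]),
         decreased = as.character(results$taxon[sig & results$log2fc < 0])),
    class = "shift_sets")
}

#' Three-condition Venn classification of significant shifts
#'
#' Each taxon significant in at least one of the three stressor
#' conditions is assigned to the Venn region of the conditions where it
#' is significant.  The region's direction label is `"increase"` when
#' all its memberships are increases, `"decrease"` when all are
#' decreases, and `"conflict"` when one stressor increases a taxon that
#' another decreases.
#'
#' @param shifts named list of exactly 3 [significant_shifts()] results
#'   (one per stressor condition).
#' @return List of class `venn_summary`: `assignments` (`data.frame`
#'   with `taxon`, `region`, `direction`), `counts` (per region x
#'   direction), and `total` (distinct significant taxa).
#' @export
venn_classify <- function(shifts) {
  stopifnot(is.list(shifts))
  if (length(shifts) != 3L) {
    abort("exactly 3 stressor conditions are required",
          "digestor_domain_error")
  }
  conds <- names(shifts) %||% paste0("condition", 1:3)
  if (is.null(names(shifts))) names(shifts) <- conds
  all_taxa <- sort(unique(unlist(lapply(shifts, function(s) {
    c(s$increased, s$decreased)
  }))))
  assignments <- do.call(rbind, lapply(all_taxa, function(tx) {
    inc <- vapply(shifts, function(s) tx %in% s$increased, logical(1))
    dec <- vapply(shifts, function(s) tx %in% s$decreased, logical(1))
    member <- inc | dec
    direction <- if (any(inc) && any(dec)) "conflict"
    else if (any(inc)) "increase" else "decrease"
    data.frame(taxon = tx,
               region = paste(conds[member], collapse = "&"),
               direction = direction)
  }))
  if (is.null(assignments)) {
    assignments <- data.frame(taxon = character(), region = character(),
                              direction = character())
  }
  counts <- as.data.frame(table(region = assignments$region,
                                direction = assignments$direction))
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(assignments = assignments, counts = counts,
                 total = nrow(assignments), conditions = conds),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("<venn_summary> %d significant taxa across %s\n", x$total,
              paste(x$conditions, collapse = ", ")))
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}

#' Read a differential-abundance result table
#'
#' TSV contract: columns `taxon`, `log2fc`, `pvalue` and optionally
#' `padj`.  This is the primary entry point for results produced by an
#' external negative-binomial tool.
#'
#' @param path file path.
#' @return A `data.frame`.
#' @export
read_da_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "log2fc", "pvalue")
  if (!all(need %in% names(df))) {
    abort(sprintf("DA table must have columns %s",
                  paste(need, collapse = ", ")),
          "digestor_contract_error")
  }
  df
}

#' Fallback differential-abundance test (not the canonical method)
#'
#' A clearly-labelled stand-in for a proper negative-binomial GLM:
#' counts get a pseudocount of 1/2, are closed to proportions and
#' centred-log-ratio transformed per sample; each taxon is then compared
#' between treatment and control replicates with a Welch t test, and
#' p-values are BH-adjusted.  Taxa with all-zero counts in both groups
#' get p = 1 by convention.  Use an external DA table via
#' [read_da_results()] whenever one is available.
#'
#' @param t an [abundance_table()] whose `samples` carry `condition`,
#'   `day` and `replicate`.
#' @param condition treatment condition label.
#' @param control control condition label.
#' @param day experiment day at which to compare.
#' @return `data.frame` with `taxon`, `log2fc`, `pvalue`, `padj`, and
#'   attribute `method = "fallback-clr-welch"`.
#' @export
fallback_da_test <- function(t, condition, control, day) {
  stopifnot(inherits(t, "abundance_table"))
  smp <- t$samples
  if (!all(c("condition", "day") %in% names(smp))) {
    abort("sample metadata must carry 'condition' and 'day'",
          "digestor_contract_error")
  }
  g1 <- smp$condition == condition & smp$day == day
  g0 <- smp$condition == control & smp$day == day
  if (sum(g1) < 2 || sum(g0) < 2) {
    abort("at least 2 replicates per group are required",
          "digestor_replication_error")
  }
  clr <- function(counts) {
    w <- counts + 0.5
    p <- w / rowSums(w)
    lp <- log(p)
    lp - rowMeans(lp)
  }
  z <- clr(t$counts[g1 | g0, , drop = FALSE])
  in1 <- (smp$condition == condition & smp$day == day)[g1 | g0]
  zero_taxa <- colSums(t$counts[g1 | g0, , drop = FALSE]) == 0
  res <- vapply(seq_len(ncol(z)), function(j) {
    if (zero_taxa[j]) return(c(0, 1))
    a <- z[in1, j]; b <- z[!in1, j]
    va <- stats::var(a) / length(a)
    vb <- stats::var(b) / length(b)
    d <- mean(a) - mean(b)
    se <- sqrt(va + vb)
    if (se == 0) return(c(d / log(2), if (d == 0) 1 else 0))
    tt <- d / se
    df <- (va + vb)^2 /
      (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    c(d / log(2), 2 * stats::pt(-abs(tt), df))
  }, numeric(2))
  out <- data.frame(taxon = colnames(z), log2fc = res[1, ],
                    pvalue = res[2, ])
  out$padj <- bh_adjust(out$pvalue)
  attr(out, "method") <- "fallback-clr-welch"
  out
}
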