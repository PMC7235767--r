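# Sign-based ecological interpretation of interaction matrices:
# a positive coefficient is read as a beneficial effect of taxon j on
# taxon i, a negative one as prejudicial, and zero as no interaction.

#' Classify interaction coefficients into signs
#'
#' Entries are mapped to +1 / -1 / 0 with a scale-free neutrality
#' threshold: with `s = median(|alpha|)` over nonzero entries, a
#' coefficient counts as positive when `alpha > epsilon * s`, negative
#' when `alpha < -epsilon * s`, and neutral otherwise.  `epsilon = 0`
#' (the default) reduces to the exact algebraic sign -- the stated
#' interpretation rule -- while a small positive `epsilon` is useful on
#' estimated coefficients, which are never exactly zero.
#'
#' @param model a [glv_model()] or a bare interaction matrix.
#' @param epsilon neutrality threshold >= 0 (default 0).
#' @return An n x n `sign_matrix` with entries in \{+1, 0, -1\} and
#'   attributes `epsilon` and `threshold`.
#' @export
classify_signs <- function(model, epsilon = 0) {
  check_number(epsilon, "epsilon", lower = 0)
  A <- if (inherits(model, "glv_model")) model$A else as.matrix(model)
  nz <- abs(A[A != 0])
  s <- if (length(nz)) stats::median(nz) else 0
  thr <- epsilon * s
  S <- matrix(0L, nrow(A), ncol(A), dimnames = dimnames(A))
  S[A > thr] <- 1L
  S[A < -thr] <- -1L
  structure(S, class = c("sign_matrix", class(S)),
            epsilon = epsilon, threshold = thr)
}

#' @export
print.sign_matrix <- function(x, ...) {
  cat(sprintf("<sign_matrix> %d x %d (epsilon = %g)\n", nrow(x), ncol(x),
              attr(x, "epsilon")))
  print(unclass(x)[seq_len(nrow(x)), seq_len(ncol(x))])
  invisible(x)
}

#' Count positive / negative / neutral interactions
#'
#' Counts run over all n^2 ordered entries including the diagonal
#' (self-interactions), so the three counts always sum to n^2 -- 49 for
#' a 7-taxon community.
#'
#' @param s a [classify_signs()] matrix.
#' @param label optional condition label carried into the summary.
#' @return List of class `interaction_summary` with `positive`,
#'   `negative`, `neutral`, `n` and `label`.
#' @export
count_interactions <- function(s, label = NULL) {
  stopifnot(inherits(s, "sign_matrix"))
  structure(list(positive = sum(s == 1L), negative = sum(s == -1L),
                 neutral = sum(s == 0L), n = nrow(s), label = label),
            class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf("<interaction_summary>%s %d taxa: %d positive, %d negative, %d neutral (of %d)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$n, x$positive, x$negative, x$neutral, x$n^2))
  invisible(x)
}

check_sign_compat <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    abort("sign matrices must have the same shape", "digestor_contract_error")
  }
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    abort("sign matrices must share taxon ordering",
          "digestor_contract_error")
  }
}

#' Count interactions shared between two conditions
#'
#' Number of ordered entries (i, j) -- diagonal included -- whose sign
#' is identical in both matrices.
#'
#' @param a,b [classify_signs()] matrices of the same shape and taxon
#'   ordering.
#' @return Integer count.
#' @export
shared_interactions <- function(a, b) {
  check_sign_compat(a, b)
  sum(unclass(a) == unclass(b))
}

#' Count interactions unique to one condition
#'
#' Number of entries whose sign in `target` differs from the sign at
#' the same position in *every* matrix of `others`.
#'
#' @param target a [classify_signs()] matrix.
#' @param others non-empty list of sign matrices to compare against.
#' @return Integer count.
#' @export
unique_interactions <- function(target, others) {
  if (!is.list(others) || length(others) == 0) {
    abort("`others` must be a non-empty list of sign matrices",
          "digestor_domain_error")
  }
  diff_all <- Reduce(`&`, lapply(others, function(o) {
    check_sign_compat(target, o)
    unclass(target) != unclass(o)
  }))
  sum(diff_all)
}
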