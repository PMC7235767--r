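# Generalized Lotka-Volterra model and trajectory containers:
# dx_i/dt = x_i (r_i + sum_j alpha_ij x_j), where r_i is the intrinsic
# growth rate (per day) and alpha_ij the interaction coefficient
# (the per-capita effect of taxon j on the growth of taxon i).

#' Construct a generalized Lotka-Volterra model
#'
#' @param r length-n vector of intrinsic growth rates (per day).
#' @param A n x n interaction matrix; `A[i, j]` is the effect of taxon
#'   j's abundance on taxon i's per-capita growth.
#' @param taxa optional taxon labels (length n).
#' @return An object of class `glv_model`.
#' @export
glv_model <- function(r, A, taxa = NULL) {
  A <- as.matrix(A)
  n <- length(r)
  if (n < 1) abort("at least one taxon is required", "digestor_contract_error")
  if (!all(dim(A) == c(n, n))) {
    abort("A must be n x n with n = length(r)", "digestor_contract_error")
  }
  if (any(!is.finite(r)) || any(!is.finite(A))) {
    abort("model parameters must be finite", "digestor_contract_error")
  }
  taxa <- taxa %||% sprintf("taxon_%02d", seq_len(n))
  stopifnot(length(taxa) == n)
  dimnames(A) <- list(taxa, taxa)
  names(r) <- taxa
  structure(list(n = n, r = r, A = A, taxa = taxa), class = "glv_model")
}

#' @export
print.glv_model <- function(x, ...) {
  cat(sprintf("<glv_model> %d taxa; r in [%.3g, %.3g]; |alpha| max %.3g\n",
              x$n, min(x$r), max(x$r), max(abs(x$A))))
  invisible(x)
}

#' Construct a community trajectory
#'
#' Abundances of n taxa observed at strictly increasing timepoints.
#' Values at or below `floor` are raised to it (positivity is needed for
#' log-derivatives); floored entries are recorded in the `floored`
#' attribute.
#'
#' @param times strictly increasing numeric timepoints (days).
#' @param X timepoints x n matrix of abundances (proportions or
#'   densities).
#' @param taxa optional taxon labels.
#' @param floor positivity floor (default 1e-8).
#' @return An object of class `glv_trajectory`.
#' @export
glv_trajectory <- function(times, X, taxa = NULL, floor = 1e-8) {
  X <- as.matrix(X)
  if (length(times) != nrow(X)) {
    abort("length(times) must equal nrow(X)", "digestor_contract_error")
  }
  if (any(diff(times) <= 0)) {
    abort("times must be strictly increasing", "digestor_contract_error")
  }
  floored <- X <= floor
  X[floored] <- floor
  taxa <- taxa %||% colnames(X) %||% sprintf("taxon_%02d", seq_len(ncol(X)))
  colnames(X) <- taxa
  structure(list(times = as.numeric(times), X = X, taxa = taxa,
                 floor = floor, floored = floored),
            class = "glv_trajectory")
}

#' @export
print.glv_trajectory <- function(x, ...) {
  cat(sprintf("<glv_trajectory> %d taxa at %d timepoints on [%g, %g]%s\n",
              ncol(x$X), length(x$times), min(x$times), max(x$times),
              if (any(x$floored))
                sprintf(" (%d values floored)", sum(x$floored)) else ""))
  invisible(x)
}

#' Write / read a gLV model as JSON
#'
#' JSON contract: object with fields `taxa`, `r` and `A` (row-major
#' list of rows).
#'
#' @param model a [glv_model()].
#' @param path file path.
#' @return `path` (write) or a [glv_model()] (read).
#' @export
write_glv_model <- function(model, path) {
  stopifnot(inherits(model, "glv_model"))
  jsonlite::write_json(
    list(taxa = model$taxa, r = unname(model$r),
         A = apply(unname(model$A), 1L, identity, simplify = FALSE)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_glv_model
#' @export
read_glv_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- if (is.list(obj$A)) do.call(rbind, obj$A) else obj$A
  glv_model(obj$r, A, taxa = obj$taxa)
}
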