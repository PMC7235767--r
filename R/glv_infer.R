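# Gradient-matching inference of gLV parameters.  Dividing the gLV
# equation by x_i gives d(ln x_i)/dt = r_i + sum_j alpha_ij x_j: the
# log-derivative is linear in the abundances, so each taxon's growth
# rate and interaction row can be estimated by (ridge) regression of
# finite-difference log-derivatives on [1, x_1 ... x_n] -- no repeated
# integration required.

#' Finite-difference derivatives on an irregular time grid
#'
#' Three-point Lagrange central differences at interior points,
#' two-point one-sided differences at the ends.  Exact for quadratics
#' on any grid.
#'
#' @param times strictly increasing timepoints.
#' @param y values at `times` (vector or matrix with one column per
#'   series).
#' @return Derivative estimates, same shape as `y`.
#' @export
finite_diff <- function(times, y) {
  y <- as.matrix(y)
  m <- length(times)
  stopifnot(m == nrow(y), m >= 2)
  d <- matrix(NA_real_, m, ncol(y))
  d[1, ] <- (y[2, ] - y[1, ]) / (times[2] - times[1])
  d[m, ] <- (y[m, ] - y[m - 1, ]) / (times[m] - times[m - 1])
  if (m > 2) {
    for (k in 2:(m - 1)) {
      t0 <- times[k - 1]; t1 <- times[k]; t2 <- times[k + 1]
      w0 <- (t1 - t2) / ((t0 - t1) * (t0 - t2))
      w1 <- (2 * t1 - t0 - t2) / ((t1 - t0) * (t1 - t2))
      w2 <- (t1 - t0) / ((t2 - t0) * (t2 - t1))
      d[k, ] <- w0 * y[k - 1, ] + w1 * y[k, ] + w2 * y[k + 1, ]
    }
  }
  if (ncol(d) == 1L) drop(d) else d
}

#' Infer gLV parameters from a trajectory by gradient matching
#'
#' For each taxon i the response is the finite-difference derivative of
#' `ln x_i` ([finite_diff()] on the possibly irregular grid), regressed
#' across timepoints on the design `[1, x_1, ..., x_n]` with a ridge
#' penalty `lambda` on all coefficients except the intercept.  Returns
#' the growth-rate vector (intercepts), the interaction matrix (slopes)
#' and per-taxon fit diagnostics.
#'
#' With T timepoints and n taxa the fit is refused as under-determined
#' when `T - 1 < n + 1` and `lambda = 0`; supply a positive ridge (the
#' default 1e-3, or see [select_ridge()]) in that regime.  A constant
#' trajectory (all derivatives ~ 0) returns an all-zero model with the
#' `degenerate` flag set.
#'
#' @param traj a [glv_trajectory()] with >= 3 timepoints.
#' @param ridge ridge penalty lambda >= 0 (default 1e-3).
#' @return List of class `glv_fit`: `model` (a [glv_model()]) and
#'   `diagnostics` (`r2` per taxon, design condition number `kappa`,
#'   `degenerate` flag, count of `floored` observations, `ridge`).
#' @export
glv_infer <- function(traj, ridge = 1e-3) {
  stopifnot(inherits(traj, "glv_trajectory"))
  check_number(ridge, "ridge", lower = 0)
  X <- traj$X
  m <- length(traj$times)
  n <- ncol(X)
  if (m < 3) {
    abort("at least 3 timepoints are required for gradient matching",
          "digestor_contract_error")
  }
  if (m - 1 < n + 1 && ridge == 0) {
    abort(sprintf(
      paste0("under-determined fit: %d timepoints for %d taxa ",
             "(n + 1 = %d coefficients per taxon); supply ridge > 0, ",
             "e.g. ridge = 1e-3 or select_ridge()"),
      m, n, n + 1), "digestor_rank_error")
  }
  D <- as.matrix(finite_diff(traj$times, log(X)))
  Z <- cbind(1, X)
  kap <- kappa(Z, exact = TRUE)
  degenerate <- max(abs(D)) < 1e-10
  if (degenerate) {
    mdl <- glv_model(rep(0, n), matrix(0, n, n), taxa = traj$taxa)
    diag <- list(r2 = rep(NA_real_, n), kappa = kap, degenerate = TRUE,
                 floored = sum(traj$floored), ridge = ridge)
    return(structure(list(model = mdl, diagnostics = diag),
                     class = "glv_fit"))
  }
  P <- diag(c(0, rep(1, n)))
  G <- crossprod(Z) + ridge * P
  beta <- solve(G, crossprod(Z, D))   # (n+1) x n, one column per taxon
  r <- beta[1, ]
  A <- t(beta[-1, , drop = FALSE])    # A[i, j]: effect of j on i
  fitted <- Z %*% beta
  rss <- colSums((D - fitted)^2)
  tss <- colSums(sweep(D, 2, colMeans(D))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  mdl <- glv_model(r, A, taxa = traj$taxa)
  structure(list(model = mdl,
                 diagnostics = list(r2 = r2, kappa = kap,
                                    degenerate = FALSE,
                                    floored = sum(traj$floored),
                                    ridge = ridge)),
            class = "glv_fit")
}

#' @export
print.glv_fit <- function(x, ...) {
  cat(sprintf(
    "<glv_fit> %d taxa; ridge = %g; median R^2 = %.3f; kappa = %.3g%s\n",
    x$model$n, x$diagnostics$ridge,
    stats::median(x$diagnostics$r2, na.rm = TRUE), x$diagnostics$kappa,
    if (x$diagnostics$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Choose the ridge penalty by leave-one-timepoint-out validation
#'
#' For each candidate lambda, each timepoint is left out in turn, the
#' gradient-matching regression is fitted on the rest, and the held-out
#' log-derivative is predicted; the lambda with the smallest summed
#' squared prediction error wins.
#'
#' @param traj a [glv_trajectory()].
#' @param lambdas candidate penalties (default `10^seq(-6, 0, 0.5)`).
#' @return The selected lambda, with the per-lambda error profile as
#'   attribute `cv_error`.
#' @export
select_ridge <- function(traj, lambdas = 10^seq(-6, 0, by = 0.5)) {
  stopifnot(inherits(traj, "glv_trajectory"))
  X <- traj$X
  m <- nrow(X); n <- ncol(X)
  D <- as.matrix(finite_diff(traj$times, log(X)))
  Z <- cbind(1, X)
  P <- diag(c(0, rep(1, n)))
  errs <- vapply(lambdas, function(lam) {
    e <- 0
    for (k in seq_len(m)) {
      Zk <- Z[-k, , drop = FALSE]
      Dk <- D[-k, , drop = FALSE]
      G <- crossprod(Zk) + lam * P
      beta <- tryCatch(solve(G, crossprod(Zk, Dk)),
                       error = function(cond) NULL)
      if (is.null(beta)) return(Inf)
      pred <- Z[k, , drop = FALSE] %*% beta
      e <- e + sum((D[k, ] - pred)^2)
    }
    e
  }, numeric(1))
  best <- lambdas[which.min(errs)]
  structure(best, cv_error = stats::setNames(errs, signif(lambdas, 3)))
}
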