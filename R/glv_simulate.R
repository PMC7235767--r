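# Adaptive Dormand-Prince 5(4) integration of the gLV system.  A
# dedicated integrator keeps the package dependency-free here; it is
# validated against exponential/logistic closed forms and the classic
# predator-prey first integral in the test suite.

# Butcher tableau (Dormand & Prince 1980)
.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
.dp_a <- list(
  c2 = c(1/5),
  c3 = c(3/40, 9/40),
  c4 = c(44/45, -56/15, 32/9),
  c5 = c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c6 = c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c7 = c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
.dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
.dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

#' Simulate a generalized Lotka-Volterra community
#'
#' Integrates `dx_i/dt = x_i (r_i + sum_j alpha_ij x_j)` with an
#' adaptive Dormand-Prince Runge-Kutta 5(4) scheme (default relative
#' tolerance 1e-8) and returns the solution at the requested times.
#' After each accepted step abundances are clamped at the positivity
#' floor.  If any abundance exceeds `blowup` (default 1e12) integration
#' aborts with an error naming the first divergent taxon and the time.
#'
#' @param model a [glv_model()].
#' @param x0 strictly positive initial abundances (length n).
#' @param times strictly increasing output times; integration starts at
#'   `times[1]`.
#' @param rtol,atol relative / absolute step-error tolerances.
#' @param floor positivity floor applied to the state.
#' @param blowup divergence threshold.
#' @param max_steps safety cap on integrator steps.
#' @return A [glv_trajectory()] at `times`.
#' @examples
#' m <- glv_model(r = 0.5, A = matrix(-1, 1, 1))
#' traj <- glv_simulate(m, x0 = 0.1, times = seq(0, 10, by = 0.5))
#' @export
glv_simulate <- function(model, x0, times, rtol = 1e-8, atol = 1e-10,
                         floor = 1e-8, blowup = 1e12, max_steps = 1e6) {
  stopifnot(inherits(model, "glv_model"))
  if (length(x0) != model$n || any(!is.finite(x0)) || any(x0 <= 0)) {
    abort("x0 must be strictly positive and of length n",
          "digestor_domain_error")
  }
  if (length(times) < 1 || any(diff(times) <= 0)) {
    abort("times must be strictly increasing", "digestor_domain_error")
  }
  r <- unname(model$r); A <- unname(model$A)
  f <- function(x) x * (r + drop(A %*% x))
  check_state <- function(x, t) {
    bad <- !is.finite(x) | abs(x) > blowup
    if (any(bad)) {
      abort(sprintf(
        "gLV blow-up: taxon '%s' diverged near t = %.4g",
        model$taxa[which(bad)[1]], t), "digestor_blowup_error")
    }
  }

  n_out <- length(times)
  out <- matrix(NA_real_, n_out, model$n)
  x <- as.numeric(x0)
  out[1, ] <- x
  t <- times[1]
  if (n_out == 1L) return(glv_trajectory(times, out, model$taxa, floor))

  span <- times[n_out] - times[1]
  h <- span / 100
  k <- matrix(0, 7, model$n)
  steps <- 0L
  next_out <- 2L
  while (next_out <= n_out) {
    h <- min(h, times[n_out] - t)
    hit_output <- FALSE
    if (t + h >= times[next_out] - 1e-14 * span) {
      h <- times[next_out] - t
      hit_output <- TRUE
    }
    k[1, ] <- f(x)
    for (s in 2:7) {
      xs <- x + h * drop(.dp_a[[s - 1]] %*% k[seq_len(s - 1), , drop = FALSE])
      k[s, ] <- f(xs)
    }
    x5 <- x + h * drop(.dp_b5 %*% k)
    x4 <- x + h * drop(.dp_b4 %*% k)
    err <- x5 - x4
    sc <- atol + rtol * pmax(abs(x), abs(x5))
    enorm <- sqrt(mean((err / sc)^2))
    if (!is.finite(enorm) || enorm > 1) {
      # reject: shrink and retry
      fac <- if (is.finite(enorm)) max(0.2, 0.9 * enorm^(-0.2)) else 0.2
      h <- h * fac
      if (h < 1e-14 * span) {
        check_state(x5, t + h)
        abort(sprintf("step size underflow near t = %.4g", t),
              "digestor_blowup_error")
      }
    } else {
      t <- t + h
      x <- pmax(x5, floor)
      check_state(x, t)
      if (hit_output) {
        out[next_out, ] <- x
        next_out <- next_out + 1L
      }
      fac <- if (enorm == 0) 5 else min(5, max(0.2, 0.9 * enorm^(-0.2)))
      h <- h * fac
    }
    steps <- steps + 1L
    if (steps > max_steps) {
      abort("maximum number of integrator steps exceeded",
            "digestor_blowup_error")
    }
  }
  glv_trajectory(times, out, model$taxa, floor)
}

# Piecewise simulation with a parameter step-change at `start_day`
# (used to realise stressor perturbations in the synthetic generator).
simulate_with_perturbation <- function(model, x0, times, perturbation,
                                       ...) {
  if (is.null(perturbation) || perturbation$start_day <= times[1] ||
      perturbation$start_day >= times[length(times)]) {
    mdl <- if (is.null(perturbation)) model else
      apply_perturbation(model, perturbation)
    return(glv_simulate(mdl, x0, times, ...))
  }
  t_switch <- perturbation$start_day
  pre_times <- c(times[times < t_switch], t_switch)
  traj1 <- glv_simulate(model, x0, pre_times, ...)
  x_switch <- traj1$X[nrow(traj1$X), ]
  post_times <- c(t_switch, times[times > t_switch])
  traj2 <- glv_simulate(apply_perturbation(model, perturbation),
                        x_switch, post_times, ...)
  keep1 <- traj1$times %in% times
  keep2 <- traj2$times %in% times & traj2$times > t_switch
  X <- rbind(traj1$X[keep1, , drop = FALSE],
             traj2$X[keep2, , drop = FALSE])
  glv_trajectory(times, X, model$taxa)
}
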