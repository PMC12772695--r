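#' @title Closed-form steady-state moments of lineage cell size
#' @description
#' Steady-state lineage moments of cell size for the multi-step adder SHS
#' are obtained exactly from the extended-generator moment equations: for
#' any function F, \eqn{d\langle F\rangle/dt = \langle f(s) F'(s)\rangle +
#' \sum \langle h(s) (F(\mathrm{after}) - F(\mathrm{before}))\rangle}.
#' Setting the left-hand sides to zero and using the algebraic identity
#' \eqn{\langle s^n/(1+\alpha s)\rangle = (\langle s^{n-1}\rangle -
#' \langle s^{n-1}/(1+\alpha s)\rangle)/\alpha} closes the system without
#' approximation. Writing \eqn{A_i = \langle g_i s/(1+\alpha s)\rangle},
#' \eqn{B_i = \langle g_i s^2/(1+\alpha s)\rangle},
#' \eqn{C_i = \langle g_i s^3/(1+\alpha s)\rangle} for stage indicators
#' \eqn{g_i}, the stationary equations give (all transition rates equal k,
#' \eqn{L = \langle\log\beta\rangle < 0}):
#' \itemize{
#'   \item \eqn{\langle 1/(1+\alpha s)\rangle = kL/(kL - M\alpha\mu)}
#'   \item all \eqn{A_i} equal: \eqn{A = \mu/(M\alpha\mu - kL)}
#'   \item \eqn{B_i = (\mu/k) i A + \langle\beta\rangle B_M},
#'     \eqn{B_M = \mu M A / (k (1-\langle\beta\rangle))}
#'   \item \eqn{C_i = (2\mu/k)\sum_{j\le i} B_j + \langle\beta^2\rangle C_M},
#'     \eqn{C_M = 2\mu \sum_j B_j / (k (1-\langle\beta^2\rangle))}
#' }
#' and the moments follow from \eqn{\langle g_i s\rangle = A_i + \alpha B_i}
#' summed over stages (likewise \eqn{\langle g_i s^2\rangle = B_i + \alpha
#' C_i}). All expressions are polynomial in \eqn{\alpha}, so the
#' exponential-growth limit \eqn{\alpha = 0} needs no special branch.
#' @name analytic_moments
NULL

new_steady_state_moments <- function(mean_size, second_moment,
                                     sat_expectation, params) {
  if (!is.finite(mean_size) || mean_size <= 0 ||
      !is.finite(second_moment) ||
      second_moment < mean_size^2 * (1 - 1e-10)) {
    stop("parameter regime yields invalid steady-state moments ",
         "(nonpositive mean or negative variance)")
  }
  if (sat_expectation <= 0 || sat_expectation > 1 + 1e-12) {
    stop("parameter regime yields invalid saturation expectation")
  }
  structure(
    list(mean_size = mean_size,
         second_moment = second_moment,
         cv2 = cv_squared(mean_size, max(second_moment, mean_size^2)),
         sat_expectation = min(sat_expectation, 1),
         params = params),
    class = "steady_state_moments"
  )
}

#' @export
print.steady_state_moments <- function(x, ...) {
  cat(sprintf(
    "Steady-state lineage size: mean = %.6g, second moment = %.6g, CV^2 = %.6g\n",
    x$mean_size, x$second_moment, x$cv2))
  cat(sprintf("  <1/(1+alpha s)> = %.6g\n", x$sat_expectation))
  invisible(x)
}

#' Squared coefficient of variation
#'
#' @param mean Mean, strictly positive.
#' @param second_moment Second raw moment, at least `mean^2`.
#' @return \eqn{(\langle s^2\rangle - \langle s\rangle^2)/\langle s\rangle^2}.
#' @export
cv_squared <- function(mean, second_moment) {
  stopifnot(is.numeric(mean), is.numeric(second_moment))
  if (any(mean <= 0)) stop("cv_squared: mean must be positive")
  if (any(second_moment < mean^2 * (1 - 1e-12))) {
    stop("cv_squared: second moment below squared mean (negative variance)")
  }
  (second_moment - mean^2) / mean^2
}

#' Steady-state moments of the single-step model
#'
#' Direct closed forms for `M = 1` (division hazard active from birth).
#' With \eqn{L = \langle\log\beta\rangle}:
#' \deqn{\langle s\rangle = \frac{\mu}{\alpha\mu - kL}
#'   \left(1 + \frac{\alpha\mu}{k(1-\langle\beta\rangle)}\right), \quad
#' \langle s^2\rangle = \frac{\mu^2}{k(1-\langle\beta\rangle)(\alpha\mu - kL)}
#'   \left(1 + \frac{2\alpha\mu}{k(1-\langle\beta^2\rangle)}\right).}
#' At \eqn{\alpha = 0}, \eqn{\mu = k = \log 2} and deterministic halving
#' these reduce to \eqn{\langle s\rangle = 1/\log 2} and
#' \eqn{CV^2 = 2\log 2 - 1}.
#'
#' @param params A [model_params()] with `M = 1`.
#' @return A `steady_state_moments` object with fields `mean_size`,
#'   `second_moment`, `cv2` and `sat_expectation`
#'   \eqn{= \langle 1/(1+\alpha s)\rangle}.
#' @export
moments_single_step <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$M != 1L) stop("moments_single_step requires M = 1")
  mu <- params$mu; alpha <- params$alpha; k <- params$k
  b1 <- params$partition$mean_beta
  b2 <- params$partition$second_moment_beta
  L <- params$partition$mean_log_beta  # < 0
  sat <- k * L / (k * L - alpha * mu)
  E1 <- mu / (alpha * mu - k * L)              # <s/(1+alpha s)>
  mean_size <- E1 * (1 + alpha * mu / (k * (1 - b1)))
  E2 <- mu * E1 / (k * (1 - b1))               # <s^2/(1+alpha s)>
  second <- E2 * (1 + 2 * alpha * mu / (k * (1 - b2)))
  new_steady_state_moments(mean_size, second, sat, params)
}

#' Steady-state moments of the multi-step model
#'
#' Evaluates the exact stage-moment recursion described in
#' [analytic_moments] for any number of stages `M >= 1`. The mean size
#' increases with the saturation coefficient \eqn{\alpha} towards a plateau
#' and decreases with `M`; the size noise \eqn{CV^2} decreases with `M`.
#' For `M = 1` the result equals [moments_single_step()] to machine
#' precision (the two are independent transcriptions).
#'
#' @param params A [model_params()] object.
#' @return A `steady_state_moments` object (see [moments_single_step()]).
#' @export
moments_multi_step <- function(params) {
  stopifnot(inherits(params, "model_params"))
  mu <- params$mu; alpha <- params$alpha; k <- params$k
  M <- params$M
  b1 <- params$partition$mean_beta
  b2 <- params$partition$second_moment_beta
  L <- params$partition$mean_log_beta
  sat <- k * L / (k * L - M * alpha * mu)        # <1/(1+alpha s)>
  A <- mu / (M * alpha * mu - k * L)             # A_i, identical for all i
  BM <- mu * M * A / (k * (1 - b1))
  B <- (mu / k) * A * seq_len(M) + b1 * BM       # B_1..B_M
  S1 <- sum(B)
  mean_size <- M * A + alpha * S1
  CM <- 2 * mu * S1 / (k * (1 - b2))
  C <- (2 * mu / k) * cumsum(B) + b2 * CM        # C_1..C_M
  second <- S1 + alpha * sum(C)
  new_steady_state_moments(mean_size, second, sat, params)
}

#' Steady-state newborn (birth-size) statistics
#'
#' In the exponential-growth regime the birth size obeys the recursion
#' \eqn{s_b' = (s_b + \Gamma)/2} with \eqn{\Gamma} the Erlang(M, k/mu) added
#' size, whose fixed point has mean \eqn{M\mu/k} and variance
#' \eqn{\mathrm{Var}(\Gamma)/3}, i.e. \eqn{CV^2 = 1/(3M)}. With the usual
#' calibration \eqn{k = \mu M} the mean birth size is exactly 1. These
#' statistics parameterize progenitor sampling for colony simulations (for
#' all \eqn{\alpha}, as an approximation when \eqn{\alpha > 0}).
#'
#' @param M Number of cycle stages.
#' @param k Transition rate constant.
#' @param mu Growth constant.
#' @return List with `mean` (\eqn{M\mu/k}) and `cv2` (\eqn{1/(3M)}).
#' @export
newborn_moments <- function(M, k, mu) {
  stopifnot(M >= 1, M == as.integer(M), k > 0, mu > 0)
  list(mean = M * mu / k, cv2 = 1 / (3 * M))
}
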