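#' Partition rule for cell division
#'
#' Describes the distribution of the partition coefficient \eqn{\beta}, the
#' fraction of the mother's size inherited by the tracked daughter at
#' division (size reset \eqn{s \to \beta s}). The rule is specified through
#' its first two moments; the `"beta"` kind draws from the beta distribution
#' whose moments match, the `"deterministic"` kind always returns
#' `mean_beta`.
#'
#' @param kind `"deterministic"` or `"beta"`.
#' @param mean_beta Mean partition fraction \eqn{\langle\beta\rangle}, in (0, 1).
#' @param second_moment_beta Second moment \eqn{\langle\beta^2\rangle}. For the
#'   deterministic kind this is forced to `mean_beta^2`; for the beta kind it
#'   must lie strictly between `mean_beta^2` and `mean_beta` (the admissible
#'   range for a beta distribution on (0, 1)).
#' @return An object of class `partition_rule` with fields `kind`,
#'   `mean_beta`, `second_moment_beta`, the matched beta shape parameters
#'   (`shape1`, `shape2`, `NA` for deterministic) and `mean_log_beta`
#'   \eqn{= \langle\log\beta\rangle}, used by the analytic moments.
#' @examples
#' partition_rule("deterministic", 0.5)
#' partition_rule("beta", 0.5, 0.26)
#' @export
partition_rule <- function(kind = c("deterministic", "beta"),
                           mean_beta = 0.5,
                           second_moment_beta = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(mean_beta), length(mean_beta) == 1L,
            mean_beta > 0, mean_beta < 1)
  if (kind == "deterministic") {
    if (!is.null(second_moment_beta) &&
        abs(second_moment_beta - mean_beta^2) > 1e-12) {
      stop("deterministic partition requires second_moment_beta = mean_beta^2")
    }
    second_moment_beta <- mean_beta^2
    shape1 <- shape2 <- NA_real_
    mlb <- log(mean_beta)
  } else {
    if (is.null(second_moment_beta)) {
      stop("second_moment_beta must be supplied for kind = \"beta\"")
    }
    if (second_moment_beta < mean_beta^2 || second_moment_beta >= mean_beta) {
      stop("second_moment_beta must lie in [mean_beta^2, mean_beta): ",
           "no beta distribution has these moments")
    }
    v <- second_moment_beta - mean_beta^2
    if (v == 0) {
      # zero-variance limit: degenerates to deterministic sampling
      shape1 <- shape2 <- NA_real_
      mlb <- log(mean_beta)
    } else {
      # moment matching: a + b = m(1-m)/v - 1
      s <- mean_beta * (1 - mean_beta) / v - 1
      shape1 <- mean_beta * s
      shape2 <- (1 - mean_beta) * s
      mlb <- digamma(shape1) - digamma(shape1 + shape2)
    }
  }
  structure(
    list(kind = kind, mean_beta = mean_beta,
         second_moment_beta = second_moment_beta,
         shape1 = shape1, shape2 = shape2, mean_log_beta = mlb),
    class = "partition_rule"
  )
}

#' @export
print.partition_rule <- function(x, ...) {
  cat(sprintf("Partition rule: %s, <beta> = %g, <beta^2> = %g\n",
              x$kind, x$mean_beta, x$second_moment_beta))
  invisible(x)
}

#' Model parameters of the multi-step adder SHS
#'
#' Collects the parameters of the stochastic hybrid system: growth law
#' \eqn{ds/dt = \mu s / (1 + \alpha s)}, stage-transition / division hazard
#' \eqn{h(s) = k s / (1 + \alpha s)} (identical rate constant `k` for every
#' one of the `M` cycle stages; division fires from stage `M`), and the
#' partition rule applied at division.
#'
#' @param mu Growth constant \eqn{\mu > 0} (1/time).
#' @param alpha Saturation coefficient \eqn{\alpha \ge 0} (1/size);
#'   `alpha = 0` is the exponential-growth limit.
#' @param k Transition rate constant \eqn{k > 0} (1/(size time) in the
#'   unsaturated limit).
#' @param M Number of cell-cycle stages, integer \eqn{\ge 1}.
#' @param partition A [partition_rule()]; defaults to deterministic halving.
#' @return An object of class `model_params`.
#' @examples
#' model_params(mu = log(2), alpha = 1, k = 10 * log(2), M = 10)
#' @export
model_params <- function(mu, alpha = 0, k = mu * M, M = 1L,
                         partition = partition_rule("deterministic", 0.5)) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu), mu > 0,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0,
            is.numeric(k), length(k) == 1L, is.finite(k), k > 0,
            length(M) == 1L, M >= 1, M == as.integer(M),
            inherits(partition, "partition_rule"))
  structure(
    list(mu = mu, alpha = alpha, k = k, M = as.integer(M),
         partition = partition),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "Multi-step adder SHS: mu = %g, alpha = %g, k = %g, M = %d\n",
    x$mu, x$alpha, x$k, x$M))
  print(x$partition)
  invisible(x)
}

check_size <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s <= 0)) {
    stop("cell size must be strictly positive and finite")
  }
  invisible(s)
}

#' Hill-type growth law
#'
#' \eqn{f(s) = \mu s / (1 + \alpha s)}: proportional to size when
#' \eqn{\alpha s \ll 1}, saturating to the constant \eqn{\mu/\alpha} when
#' \eqn{\alpha s \gg 1}.
#'
#' @param s Cell size(s), strictly positive.
#' @param params A [model_params()] object.
#' @return Growth rate(s) ds/dt, same length as `s`.
#' @export
growth_rate <- function(s, params) {
  check_size(s)
  params$mu * s / (1 + params$alpha * s)
}

#' Division / stage-transition propensity
#'
#' \eqn{h(s) = k s / (1 + \alpha s)}, proportional to the growth law with
#' factor \eqn{k/\mu}. This proportionality is the mechanistic origin of the
#' adder property: hazard accumulated while growing equals \eqn{k/\mu} times
#' the size added, regardless of \eqn{\alpha}.
#'
#' @inheritParams growth_rate
#' @return Hazard(s), same length as `s`.
#' @export
division_propensity <- function(s, params) {
  check_size(s)
  params$k * s / (1 + params$alpha * s)
}

#' Deterministic flow: time to grow between two sizes
#'
#' Closed-form integral of the growth ODE:
#' \eqn{t = [\log(s_1/s_0) + \alpha (s_1 - s_0)] / \mu}.
#'
#' @param s0,s1 Start and end sizes, `0 < s0 <= s1` (vectorized).
#' @param params A [model_params()] object.
#' @return Elapsed time(s), zero iff `s1 == s0`.
#' @export
flow_time <- function(s0, s1, params) {
  check_size(s0); check_size(s1)
  if (any(s1 < s0 * (1 - 1e-12))) {
    stop("flow_time: s1 < s0, but growth is monotone increasing")
  }
  (log(s1 / s0) + params$alpha * (s1 - s0)) / params$mu
}

#' Deterministic flow: size after a given time
#'
#' Inverse of [flow_time()]: the unique \eqn{s_1 \ge s_0} with
#' `flow_time(s0, s1) == t`. For `alpha = 0` this is exponential growth
#' `s0 * exp(mu * t)`; for `alpha > 0` the monotone equation
#' \eqn{\log s + \alpha s = \log s_0 + \alpha s_0 + \mu t} is solved by
#' Newton iteration started from an upper bound (the minimum of the
#' exponential envelope `s0 exp(mu t)` and the linear envelope
#' `s0 + mu t / alpha`; the residual is concave in `s`, so Newton from above
#' converges monotonically), to relative tolerance 1e-12.
#'
#' @param s0 Initial size(s), strictly positive.
#' @param t Elapsed time(s), nonnegative (vectorized).
#' @param params A [model_params()] object.
#' @return Size(s) after time `t`.
#' @export
flow_size <- function(s0, t, params) {
  check_size(s0)
  if (any(t < 0)) stop("flow_size: negative time")
  mu <- params$mu; alpha <- params$alpha
  if (alpha == 0) return(s0 * exp(mu * t))
  n <- max(length(s0), length(t))
  s0 <- rep_len(s0, n); t <- rep_len(t, n)
  target <- log(s0) + alpha * s0 + mu * t
  s <- pmin(s0 * exp(mu * t), s0 + mu * t / alpha)
  for (i in seq_len(100L)) {
    g <- log(s) + alpha * s - target
    if (all(abs(g) <= 1e-13 * (1 + abs(target)))) break
    s <- s - g / (1 / s + alpha)
    s <- pmax(s, s0)  # safeguard: root is >= s0
  }
  s
}

#' Sample partition fractions
#'
#' Draws division fractions \eqn{\beta} from a [partition_rule()]. The
#' deterministic kind returns `mean_beta` exactly; the beta kind draws from
#' the moment-matched beta distribution. All draws lie strictly in (0, 1).
#'
#' @param rule A [partition_rule()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_partition <- function(rule, n = 1L) {
  stopifnot(inherits(rule, "partition_rule"))
  if (rule$kind == "deterministic" || is.na(rule$shape1)) {
    rep(rule$mean_beta, n)
  } else {
    b <- stats::rbeta(n, rule$shape1, rule$shape2)
    # rbeta can return exact 0/1 only with degenerate shapes excluded above;
    # clamp defensively to the open interval
    pmin(pmax(b, .Machine$double.xmin), 1 - .Machine$double.eps)
  }
}

#' Write model parameters to a JSON config file
#'
#' Flat schema: `mu`, `alpha`, `k`, `M`, `partition.kind`, `partition.mean`,
#' `partition.second_moment`. Round-trips losslessly through
#' [read_params_config()].
#'
#' @param params A [model_params()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  x <- list(
    mu = params$mu, alpha = params$alpha, k = params$k, M = params$M,
    partition = list(
      kind = params$partition$kind,
      mean = params$partition$mean_beta,
      second_moment = params$partition$second_moment_beta
    )
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from a JSON config file
#'
#' @param path File written by [write_params_config()] (or hand-authored
#'   with the same keys).
#' @return A [model_params()] object.
#' @export
read_params_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  part <- if (identical(x$partition$kind, "deterministic")) {
    partition_rule("deterministic", x$partition$mean)
  } else {
    partition_rule("beta", x$partition$mean, x$partition$second_moment)
  }
  model_params(mu = x$mu, alpha = x$alpha, k = x$k, M = x$M, partition = part)
}
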