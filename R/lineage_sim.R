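#' @title Exact single-lineage simulation
#' @description
#' The stage-transition hazard \eqn{h(s) = k s/(1+\alpha s)} is proportional
#' to the growth law \eqn{f(s) = \mu s/(1+\alpha s)}, so the hazard
#' accumulated while a cell grows from \eqn{s_0} to \eqn{s} is
#' \eqn{\int h\,dt = (k/\mu)(s - s_0)}: the *size* added up to the next
#' stage transition is exactly Exponential(k/mu), independent of the current
#' size and of \eqn{\alpha}. The lineage simulator therefore draws
#' exponential size increments, converts them to waiting times with the
#' closed-form flow, and applies the partition reset at every M-th event —
#' no time discretization and no rejection anywhere. The generic thinning
#' simulator [oracle_simulate()] is retained purely as an independent
#' cross-validation oracle.
#' @name lineage_sim
NULL

# Derive independent substream seeds from one root seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Sample size increments to the next stage transition
#'
#' Draws from the exact increment law Exponential(rate = k/mu); see
#' [lineage_sim] for why the increment distribution does not depend on
#' \eqn{\alpha} or on the current size.
#'
#' @param params A [model_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of added sizes, mean `mu/k`.
#' @export
sample_stage_increment <- function(params, n = 1L) {
  stopifnot(inherits(params, "model_params"))
  stats::rexp(n, rate = params$k / params$mu)
}

#' Simulate a single tracked lineage
#'
#' Event-driven exact simulation of one cell line through `n_divisions`
#' cycles of `M` stages each. Per stage the added size is drawn via
#' [sample_stage_increment()] and time advances by the deterministic flow;
#' after the M-th stage event the division reset \eqn{s \to \beta s} is
#' applied and the stage returns to 1. The tracked cell is the
#' \eqn{\beta}-fraction daughter.
#'
#' @param params A [model_params()] object.
#' @param n_divisions Number of complete cycles to simulate (>= 1).
#' @param s_init Initial size (default: the newborn mean `M*mu/k`).
#' @param seed Optional integer root seed; two substreams (increments,
#'   partitions) are derived from it, so runs are reproducible and the two
#'   noise sources independent.
#' @return An object of class `lineage_trajectory`: a list with
#'   \describe{
#'     \item{events}{data.frame (time, size_before, size_after,
#'       stage_before, stage_after, kind, generation); `kind` is
#'       `"stage_advance"` or `"division"`.}
#'     \item{cycles}{data.frame (generation, s_b, s_d, delta_d, duration)
#'       of per-cycle records: birth size, division size, added size and
#'       cycle time.}
#'     \item{params, s_init}{inputs, for downstream estimators.}
#'   }
#' @examples
#' p <- model_params(mu = log(2), alpha = 1, k = 10 * log(2), M = 10)
#' traj <- simulate_lineage(p, n_divisions = 200, seed = 1)
#' head(traj$cycles)
#' @export
simulate_lineage <- function(params, n_divisions, s_init = NULL, seed = NULL) {
  stopifnot(inherits(params, "model_params"),
            length(n_divisions) == 1L, n_divisions >= 1,
            n_divisions == as.integer(n_divisions))
  mu <- params$mu; alpha <- params$alpha; k <- params$k; M <- params$M
  if (is.null(s_init)) s_init <- M * mu / k
  check_size(s_init)
  n_divisions <- as.integer(n_divisions)

  if (!is.null(seed)) {
    ss <- derive_seeds(seed, 2L)
    set.seed(ss[1L])
  }
  inc <- matrix(stats::rexp(M * n_divisions, rate = k / mu), nrow = M)
  if (!is.null(seed)) set.seed(ss[2L])
  betas <- sample_partition(params$partition, n_divisions)

  gain <- colSums(inc)                       # per-cycle added size (Erlang)
  s_b <- numeric(n_divisions)
  s_b[1L] <- s_init
  for (j in seq_len(n_divisions - 1L)) {
    s_b[j + 1L] <- betas[j] * (s_b[j] + gain[j])
  }
  s_d <- s_b + gain

  # within-cycle cumulative added size -> event sizes
  cs <- apply(inc, 2L, cumsum)               # M x n_divisions
  if (M == 1L) cs <- matrix(cs, nrow = 1L)
  size_before <- rep(s_b, each = M) + as.vector(cs)
  seg_start <- rep(s_b, each = M) +
    as.vector(rbind(0, cs[-M, , drop = FALSE]))
  dt <- (log(size_before / seg_start) + alpha * (size_before - seg_start)) / mu

  is_div <- rep(c(rep(FALSE, M - 1L), TRUE), n_divisions)
  size_after <- size_before
  size_after[is_div] <- betas * s_d
  stage_before <- rep(seq_len(M), n_divisions)
  stage_after <- ifelse(stage_before == M, 1L, stage_before + 1L)

  events <- data.frame(
    time = cumsum(dt),
    size_before = size_before,
    size_after = size_after,
    stage_before = stage_before,
    stage_after = stage_after,
    kind = ifelse(is_div, "division", "stage_advance"),
    generation = rep(seq_len(n_divisions), each = M)
  )
  cycles <- data.frame(
    generation = seq_len(n_divisions),
    s_b = s_b, s_d = s_d, delta_d = gain,
    duration = colSums(matrix(dt, nrow = M))
  )
  structure(
    list(events = events, cycles = cycles, params = params, s_init = s_init),
    class = "lineage_trajectory"
  )
}

#' @export
print.lineage_trajectory <- function(x, ...) {
  cat(sprintf(
    "Lineage trajectory: %d cycles, %d events, total time %.4g\n",
    nrow(x$cycles), nrow(x$events), max(x$events$time)))
  invisible(x)
}

#' Thinning (rejection) simulator — cross-validation oracle
#'
#' Simulates the same SHS by Ogata-style thinning: candidate events are
#' proposed from a dominating constant rate (the saturation plateau
#' \eqn{k/\alpha} when \eqn{\alpha > 0}; for \eqn{\alpha = 0} a bound
#' refreshed over a finite look-ahead horizon, since \eqn{h(s) = k s} is
#' unbounded) and accepted with probability \eqn{h(s)/\mathrm{bound}},
#' with size evolved deterministically between proposals. Statistically
#' equivalent to [simulate_lineage()] but far slower; used only to
#' cross-check the exact time-change simulator.
#'
#' @param params A [model_params()] object.
#' @param t_end End time of the simulation (> 0).
#' @param s_init Initial size (default `M*mu/k`).
#' @param seed Optional integer seed.
#' @return A `lineage_trajectory` (complete cycles only in `$cycles`).
#' @export
oracle_simulate <- function(params, t_end, s_init = NULL, seed = NULL) {
  stopifnot(inherits(params, "model_params"), t_end > 0)
  mu <- params$mu; alpha <- params$alpha; k <- params$k; M <- params$M
  if (is.null(s_init)) s_init <- M * mu / k
  check_size(s_init)
  if (!is.null(seed)) set.seed(seed)

  t <- 0; s <- s_init; stage <- 1L
  birth_s <- s_init; birth_t <- 0
  cap <- 4096L
  ev <- list(time = numeric(cap), sb = numeric(cap), sa = numeric(cap),
             stb = integer(cap), sta = integer(cap), div = logical(cap))
  n_ev <- 0L
  cyc <- list(s_b = numeric(cap), s_d = numeric(cap), dur = numeric(cap))
  n_cyc <- 0L
  horizon <- 0.5 / mu  # look-ahead for the alpha = 0 adaptive bound

  while (t < t_end) {
    if (alpha > 0) {
      bound <- k / alpha
      w <- stats::rexp(1L, bound)
      if (t + w > t_end) break
      s_new <- flow_size(s, w, params)
    } else {
      bound <- k * flow_size(s, horizon, params)
      w <- stats::rexp(1L, bound)
      if (w > horizon) {            # no proposal within the horizon
        if (t + horizon > t_end) break
        s <- flow_size(s, horizon, params)
        t <- t + horizon
        next
      }
      if (t + w > t_end) break
      s_new <- flow_size(s, w, params)
    }
    t <- t + w
    s <- s_new
    p_acc <- division_propensity(s, params) / bound
    if (p_acc > 1 + 1e-9) stop("thinning bound violated (internal error)")
    if (stats::runif(1L) > p_acc) next

    # accepted stage event
    n_ev <- n_ev + 1L
    if (n_ev > length(ev$time)) {
      ev <- lapply(ev, function(v) c(v, vector(mode(v), length(v))))  # double
    }
    if (stage < M) {
      ev$time[n_ev] <- t; ev$sb[n_ev] <- s; ev$sa[n_ev] <- s
      ev$stb[n_ev] <- stage; ev$sta[n_ev] <- stage + 1L; ev$div[n_ev] <- FALSE
      stage <- stage + 1L
    } else {
      beta <- sample_partition(params$partition, 1L)
      n_cyc <- n_cyc + 1L
      if (n_cyc > length(cyc$s_b)) cyc <- lapply(cyc, function(v) c(v, v * 0))
      cyc$s_b[n_cyc] <- birth_s; cyc$s_d[n_cyc] <- s
      cyc$dur[n_cyc] <- t - birth_t
      ev$time[n_ev] <- t; ev$sb[n_ev] <- s; ev$sa[n_ev] <- beta * s
      ev$stb[n_ev] <- M; ev$sta[n_ev] <- 1L; ev$div[n_ev] <- TRUE
      s <- beta * s
      stage <- 1L
      birth_s <- s; birth_t <- t
    }
  }

  idx <- seq_len(n_ev)
  events <- data.frame(
    time = ev$time[idx], size_before = ev$sb[idx], size_after = ev$sa[idx],
    stage_before = ev$stb[idx], stage_after = ev$sta[idx],
    kind = ifelse(ev$div[idx], "division", "stage_advance"),
    generation = cumsum(c(1L, utils::head(ev$div[idx], -1L)))
  )
  jdx <- seq_len(n_cyc)
  cycles <- data.frame(
    generation = jdx,
    s_b = cyc$s_b[jdx], s_d = cyc$s_d[jdx],
    delta_d = cyc$s_d[jdx] - cyc$s_b[jdx],
    duration = cyc$dur[jdx]
  )
  structure(
    list(events = events, cycles = cycles, params = params, s_init = s_init),
    class = "lineage_trajectory"
  )
}

#' Time-averaged steady-state moments along a lineage
#'
#' Computes the long-run time averages \eqn{(1/T)\int s\,dt},
#' \eqn{(1/T)\int s^2\,dt} and \eqn{(1/T)\int dt/(1+\alpha s)} exactly per
#' deterministic flow segment: substituting \eqn{dt = (1+\alpha s)/(\mu s)\,
#' ds} gives the closed segment integrals
#' \eqn{\int s\,dt = [(s_1 - s_0) + \alpha (s_1^2 - s_0^2)/2]/\mu},
#' \eqn{\int s^2 dt = [(s_1^2 - s_0^2)/2 + \alpha (s_1^3 - s_0^3)/3]/\mu},
#' \eqn{\int dt/(1+\alpha s) = \log(s_1/s_0)/\mu} — no quadrature error.
#' Standard errors use batch means over contiguous blocks of cycles, which
#' respects the serial correlation of the lineage.
#'
#' @param traj A `lineage_trajectory` from [simulate_lineage()] or
#'   [oracle_simulate()].
#' @param burn_in Number of initial cycles to discard (default 50).
#' @param n_batches Number of batches for batch-means standard errors.
#' @return An object of class `lineage_moments`: list with `mean_size`,
#'   `second_moment`, `cv2`, `sat_expectation`, a list `se` of batch-means
#'   standard errors for each, `n_cycles` retained and `total_time`.
#' @export
time_averaged_moments <- function(traj, burn_in = 50L, n_batches = 100L) {
  stopifnot(inherits(traj, "lineage_trajectory"))
  p <- traj$params
  ev <- traj$events
  s0 <- c(traj$s_init, utils::head(ev$size_after, -1L))
  s1 <- ev$size_before
  gen <- ev$generation
  keep <- gen > burn_in
  if (sum(ev$kind[keep] == "division") < 100L) {
    stop("fewer than 100 cycles remain after burn-in; simulate longer")
  }
  s0 <- s0[keep]; s1 <- s1[keep]; gen <- gen[keep]

  mu <- p$mu; alpha <- p$alpha
  dt <- (log(s1 / s0) + alpha * (s1 - s0)) / mu
  int_s <- ((s1 - s0) + alpha * (s1^2 - s0^2) / 2) / mu
  int_s2 <- ((s1^2 - s0^2) / 2 + alpha * (s1^3 - s0^3) / 3) / mu
  int_sat <- log(s1 / s0) / mu

  gens <- unique(gen)
  n_batches <- min(n_batches, length(gens))
  batch <- cut(match(gen, gens), breaks = n_batches, labels = FALSE)
  agg <- function(x) as.numeric(tapply(x, batch, sum))
  bT <- agg(dt); bS <- agg(int_s); bS2 <- agg(int_s2); bSat <- agg(int_sat)
  b_mean <- bS / bT
  b_sec <- bS2 / bT
  b_cv2 <- b_sec / b_mean^2 - 1
  b_sat <- bSat / bT
  se <- function(v) stats::sd(v) / sqrt(length(v))

  total_T <- sum(dt)
  m <- sum(int_s) / total_T
  m2 <- sum(int_s2) / total_T
  structure(
    list(mean_size = m,
         second_moment = m2,
         cv2 = m2 / m^2 - 1,
         sat_expectation = sum(int_sat) / total_T,
         se = list(mean_size = se(b_mean), second_moment = se(b_sec),
                   cv2 = se(b_cv2), sat_expectation = se(b_sat)),
         n_cycles = length(gens), n_batches = n_batches,
         total_time = total_T),
    class = "lineage_moments"
  )
}

#' @export
print.lineage_moments <- function(x, ...) {
  cat(sprintf(
    paste0("Time-averaged lineage moments (%d cycles, %d batches):\n",
           "  mean = %.6g (SE %.2g)   CV^2 = %.6g (SE %.2g)\n",
           "  <1/(1+alpha s)> = %.6g (SE %.2g)\n"),
    x$n_cycles, x$n_batches, x$mean_size, x$se$mean_size,
    x$cv2, x$se$cv2, x$sat_expectation, x$se$sat_expectation))
  invisible(x)
}

#' Adder regression: added size against birth size
#'
#' Ordinary least-squares slope of the added size at division
#' \eqn{\Delta_d} on the birth size \eqn{s_b} across cycles. The slope
#' discriminates division strategies: 0 for an adder, -1 for a sizer, +1
#' for a timer. For this model the slope is 0 for every \eqn{\alpha}: the
#' added size per cycle is Erlang(M, k/mu) independent of birth size.
#'
#' @param cycles A `lineage_trajectory` or its `cycles` data.frame
#'   (columns `s_b`, `delta_d`); at least 100 records.
#' @return List with `slope`, `se` (its standard error), `intercept` and
#'   `n`.
#' @export
adder_slope <- function(cycles) {
  if (inherits(cycles, "lineage_trajectory")) cycles <- cycles$cycles
  stopifnot(is.data.frame(cycles), all(c("s_b", "delta_d") %in% names(cycles)))
  if (nrow(cycles) < 100L) stop("need at least 100 cycle records")
  if (stats::var(cycles$s_b) == 0) {
    stop("birth size has zero variance; slope undefined")
  }
  fit <- stats::lm(delta_d ~ s_b, data = cycles)
  cf <- summary(fit)$coefficients
  list(slope = cf["s_b", "Estimate"], se = cf["s_b", "Std. Error"],
       intercept = cf["(Intercept)", "Estimate"], n = nrow(cycles))
}
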