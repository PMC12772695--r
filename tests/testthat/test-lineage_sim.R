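test_that("stage size increments are Exponential(k/mu) regardless of saturation", {
  p <- ref_params(alpha = 0, M = 1, mu = 1, k = 1)
  set.seed(20)
  x <- sample_stage_increment(p, 1e5)
  expect_lt(abs(mean(x) - 1), 3 / sqrt(1e5))          # Exp(1) has sd 1
  # agreement with the exponential law itself (ties warning: duplicated
  # floats among 1e5 draws, harmless)
  expect_gt(suppressWarnings(stats::ks.test(x, "pexp", 1)$p.value), 0.01)

  # doubling k halves the mean increment
  p2 <- ref_params(alpha = 0, M = 1, mu = 1, k = 2)
  y <- sample_stage_increment(p2, 1e5)
  expect_lt(abs(mean(y) - 0.5), 3 * 0.5 / sqrt(1e5))

  # the increment law does not depend on alpha (cumulative-hazard identity)
  pa <- ref_params(alpha = 10, M = 1, mu = 1, k = 1)
  expect_gt(
    suppressWarnings(
      stats::ks.test(sample_stage_increment(p, 1e4),
                     sample_stage_increment(pa, 1e4))$p.value),
    0.01)
})

test_that("simulate_lineage produces a consistent exact trajectory", {
  p <- ref_params(alpha = 2, M = 4)
  traj <- simulate_lineage(p, n_divisions = 500, seed = 21)
  ev <- traj$events
  cyc <- traj$cycles

  # times strictly increasing; exactly M events per cycle, last a division
  expect_true(all(diff(ev$time) > 0))
  expect_identical(nrow(ev), 2000L)
  expect_identical(tabulate(ev$generation), rep(4L, 500))
  last <- ev[!duplicated(ev$generation, fromLast = TRUE), ]
  expect_true(all(last$kind == "division"))
  expect_true(all(ev$kind[ev$stage_before < 4] == "stage_advance"))

  # size only jumps at division, where it is multiplied by beta = 1/2
  adv <- ev$kind == "stage_advance"
  expect_identical(ev$size_after[adv], ev$size_before[adv])
  div <- !adv
  expect_equal(ev$size_after[div], 0.5 * ev$size_before[div])

  # deterministic halving: next birth size is exactly half the division size
  expect_identical(cyc$s_b[-1], cyc$s_d[-nrow(cyc)] / 2)
  expect_equal(cyc$s_d, cyc$s_b + cyc$delta_d)
  expect_true(all(cyc$delta_d > 0))

  # between events, size follows the deterministic flow
  i <- seq(10, 1990, by = 97)
  expect_equal(ev$size_before[i + 1],
               flow_size(ev$size_after[i], diff(ev$time)[i], p),
               tolerance = 1e-9)

  # reproducibility: identical seed, identical trajectory
  traj2 <- simulate_lineage(p, n_divisions = 500, seed = 21)
  expect_identical(traj2$events, ev)
})

test_that("per-cycle added size is Erlang(M, k/mu)", {
  M <- 5L
  p <- ref_params(alpha = 3, M = M)  # k = mu*M, so mean added size is 1
  traj <- simulate_lineage(p, n_divisions = 1e4, seed = 22)
  d <- traj$cycles$delta_d
  expect_lt(abs(mean(d) - 1), 3 * stats::sd(d) / sqrt(length(d)))
  # variance M*(mu/k)^2 = 1/M
  expect_lt(abs(stats::var(d) - 1 / M), 4 * stats::sd((d - 1)^2) / sqrt(length(d)))
  expect_gt(stats::ks.test(d, "pgamma", shape = M, rate = M)$p.value, 0.01)
})

test_that("thinning oracle is statistically equivalent to the exact simulator", {
  # saturating case uses the k/alpha plateau bound; exponential case the
  # adaptive look-ahead bound
  cases <- list(ref_params(alpha = 5, M = 3), ref_params(alpha = 0, M = 2))
  t_ends <- c(2.5e4, 4e3)
  for (i in seq_along(cases)) {
    p <- cases[[i]]
    orc <- oracle_simulate(p, t_end = t_ends[i], seed = 23 + i)
    expect_gt(nrow(orc$cycles), 1500)
    sim <- simulate_lineage(p, n_divisions = nrow(orc$cycles), seed = 40 + i)
    drop <- 1:50
    expect_gt(suppressWarnings(stats::ks.test(
      orc$cycles$s_d[-drop], sim$cycles$s_d[-drop])$p.value), 0.01)
    expect_gt(suppressWarnings(stats::ks.test(
      orc$cycles$duration[-drop], sim$cycles$duration[-drop])$p.value), 0.01)
  }
})

test_that("time-averaged moments use exact segment integrals", {
  # alpha = 0: time-average of s over a segment is (s1 - s0)/(mu * dt)
  p0 <- ref_params(alpha = 0, M = 1)
  traj0 <- simulate_lineage(p0, n_divisions = 200, seed = 25)
  m0 <- time_averaged_moments(traj0, burn_in = 50)
  ev <- traj0$events
  keep <- ev$generation > 50
  s0 <- c(traj0$s_init, head(ev$size_after, -1))[keep]
  s1 <- ev$size_before[keep]
  T_tot <- sum(log(s1 / s0)) / p0$mu
  expect_equal(m0$mean_size, sum(s1 - s0) / p0$mu / T_tot, tolerance = 1e-12)

  # saturating case against adaptive quadrature of s(t) along each segment
  p <- ref_params(alpha = 4, M = 2)
  traj <- simulate_lineage(p, n_divisions = 160, seed = 26)
  m <- time_averaged_moments(traj, burn_in = 50)
  ev <- traj$events
  keep <- which(ev$generation > 50)
  s_start <- c(traj$s_init, head(ev$size_after, -1))
  t_prev <- c(0, head(ev$time, -1))
  int_s <- int_s2 <- int_sat <- tt <- 0
  for (i in keep) {
    dt <- ev$time[i] - t_prev[i]
    f <- function(u) flow_size(s_start[i], u, p)
    int_s <- int_s + stats::integrate(f, 0, dt, rel.tol = 1e-10)$value
    int_s2 <- int_s2 + stats::integrate(function(u) f(u)^2, 0, dt,
                                        rel.tol = 1e-10)$value
    int_sat <- int_sat + stats::integrate(
      function(u) 1 / (1 + p$alpha * f(u)), 0, dt, rel.tol = 1e-10)$value
    tt <- tt + dt
  }
  expect_equal(m$mean_size, int_s / tt, tolerance = 1e-8)
  expect_equal(m$second_moment, int_s2 / tt, tolerance = 1e-8)
  expect_equal(m$sat_expectation, int_sat / tt, tolerance = 1e-8)

  expect_error(time_averaged_moments(traj, burn_in = 150), "100 cycles")
})

test_that("adder regression discriminates adder, sizer and saturated model", {
  set.seed(27)
  # independence of added size and birth size => slope 0
  sb <- rgamma(500, 30, 30)
  indep <- data.frame(s_b = sb, delta_d = rgamma(500, 10, 10))
  fit <- adder_slope(indep)
  expect_lt(abs(fit$slope), 3 * fit$se)

  # sizer construction: delta = c - s_b has slope exactly -1
  sizer <- data.frame(s_b = sb, delta_d = 2 - sb)
  # exact linear relation => "perfect fit" warning from summary.lm
  expect_equal(suppressWarnings(adder_slope(sizer))$slope, -1,
               tolerance = 1e-12)

  expect_error(adder_slope(data.frame(s_b = rep(1, 200),
                                      delta_d = rgamma(200, 10, 10))),
               "zero variance")
  expect_error(adder_slope(indep[1:50, ]), "at least 100")

  # the saturated multi-step model preserves the adder property
  p <- ref_params(alpha = 10, M = 10)
  traj <- simulate_lineage(p, n_divisions = 2050, seed = 28)
  fit <- adder_slope(traj$cycles[traj$cycles$generation > 50, ])
  expect_lt(abs(fit$slope), 3 * fit$se)
})

test_that("birth-size noise at alpha = 0 scales as 1/(3M)", {
  for (M in c(1L, 10L)) {
    p <- ref_params(alpha = 0, M = M)
    traj <- simulate_lineage(p, n_divisions = 1e4, seed = 29 + M)
    sb <- traj$cycles$s_b[-(1:50)]
    cv2_hat <- stats::var(sb) / mean(sb)^2
    cv2_b <- tapply(sb, cut(seq_along(sb), 50, labels = FALSE),
                    function(x) stats::var(x) / mean(x)^2)
    expect_lt(abs(cv2_hat - 1 / (3 * M)), 3 * stats::sd(cv2_b) / sqrt(50))
    expect_lt(abs(mean(sb) - 1), 3 * batch_se(sb))
  }
})
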