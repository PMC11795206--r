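# Empirical statistics: PDF, two-/three-point TCFs, ensemble averaging,
# multi-exponential fitting, mean relaxation time, state-count inference.

test_that("empirical PDF counts, normalizes, and reports excluded samples", {
  tr <- visibility_trajectory(c(0.1, 0.1, 0.3), 1e-3)
  pdf <- empirical_pdf(tr, bin_edges = c(0, 0.2, 0.4))
  expect_equal(pdf$density * diff(pdf$bin_edges), c(2 / 3, 1 / 3))

  tr2 <- visibility_trajectory(c(0.1, 0.5, -0.2, 0.3, 0.9), 1e-3)
  pdf2 <- empirical_pdf(tr2, bin_edges = seq(0, 0.6, by = 0.1))
  expect_equal(sum(pdf2$density * diff(pdf2$bin_edges)), 1, tolerance = 1e-12)
  expect_equal(pdf2$n_excluded, 2L)   # -0.2 and 0.9 fall outside
})

test_that("empirical PDF converges to a known Gaussian mixture", {
  em <- emission_model(c(0.1, 0.3), c(0.02, 0.03), weights = c(0.6, 0.4))
  v <- withr::with_seed(99, {
    comp <- sample(1:2, 1e5, replace = TRUE, prob = em$weights)
    stats::rnorm(1e5, em$means[comp], em$sigmas[comp])
  })
  tr <- visibility_trajectory(pmin(pmax(v, -1), 1), 1e-3)
  edges <- seq(-0.05, 0.55, length.out = 61)
  pdf <- empirical_pdf(tr, edges)
  truth <- binned_mixture_density(em, edges)
  w <- diff(edges)[1]
  se <- sqrt(pmax(truth * w, 1e-12) * (1 - truth * w) / (1e5 * w^2))
  expect_true(all(abs(pdf$density - truth) < 5 * se + 1e-8))
})

test_that("two-point TCF matches hand-evaluated sums", {
  tr <- visibility_trajectory(c(0.1, 0.3, 0.1, 0.3), 1e-3)
  tc <- two_point_tcf(tr, lags = c(0, 1e-3))
  expect_equal(tc$values[1], 0.01, tolerance = 1e-12)   # variance at lag 0
  expect_equal(tc$values[2], -0.01, tolerance = 1e-12)  # alternating series
  expect_equal(tc$n_pairs, c(4L, 3L))
  expect_error(two_point_tcf(tr, lags = 4e-3), "exceeds")
  expect_error(two_point_tcf(tr, lags = 1.5e-3), "integer multiple")

  tcn <- two_point_tcf(tr, lags = c(0, 1e-3), normalized = TRUE)
  expect_equal(tcn$values[1], 1)
})

test_that("three-point TCF matches hand evaluation and zero-lag identity", {
  tr <- visibility_trajectory(c(0.1, 0.3, 0.1, 0.3), 1e-3)
  tc <- three_point_tcf(tr, lags1 = 1e-3, lags2 = 1e-3)
  expect_equal(tc$values[1, 1], 0, tolerance = 1e-15)

  v <- c(0.1, 0.1, 0.4, 0.2, 0.05)
  tr2 <- visibility_trajectory(v, 1e-3)
  dv <- v - mean(v)
  tc2 <- three_point_tcf(tr2, lags1 = 0, lags2 = 0)
  expect_equal(tc2$values[1, 1], mean(dv^3), tolerance = 1e-14)
  expect_error(three_point_tcf(tr2, lags1 = 3e-3, lags2 = 2e-3), "exceeds")
})

test_that("ensemble averaging is the unweighted mean with summed counts", {
  tr1 <- visibility_trajectory(c(0.1, 0.3, 0.1, 0.3), 1e-3)
  tc1 <- two_point_tcf(tr1, lags = c(0, 1e-3))
  same <- ensemble_average(list(tc1, tc1))
  expect_equal(same$values, tc1$values)
  expect_equal(same$n_pairs, 2L * tc1$n_pairs)

  a <- tc1; a$values <- c(0, 0)
  b <- tc1; b$values <- c(2, 2)
  expect_equal(ensemble_average(list(a, b))$values, c(1, 1))

  bad <- two_point_tcf(tr1, lags = 0)
  expect_error(ensemble_average(list(tc1, bad)), "grids")
})

test_that("ensemble averaging commutes with pooled estimation for equal-length trajectories", {
  trs <- withr::with_seed(4, {
    lapply(1:5, function(i) {
      visibility_trajectory(stats::runif(200, 0, 0.4), 1e-3)
    })
  })
  lags <- c(0, 1e-3, 5e-3)
  avg <- two_point_tcf(trs, lags = lags)
  manual <- rowMeans(sapply(trs, function(t) two_point_tcf(t, lags)$values))
  expect_equal(avg$values, manual, tolerance = 1e-14)
})

test_that("ensemble standard error shrinks like 1/sqrt(M)", {
  tr <- ps_truth_network()
  trajs <- withr::with_seed(8, {
    lapply(1:25, function(i) {
      path <- simulate_state_path(tr$network, 3)
      emit_visibility(path, tr$emission, 1e-3)
    })
  })
  lags <- c(1e-3, 1e-2)
  per <- lapply(trajs, two_point_tcf, lags = lags)
  avg <- ensemble_average(per)
  spread <- apply(sapply(per, `[[`, "values"), 1, stats::sd)
  expect_equal(avg$se, spread / sqrt(25), tolerance = 1e-12)
})

test_that("multi-exponential fit recovers clean and noisy decay constants", {
  lags <- log_spaced <- exp(seq(log(2.5e-4), log(2), length.out = 80))
  # single exponential, noiseless: near-exact recovery
  tc1 <- structure(list(lags = lags, values = exp(-lags / 5e-3),
                        n_pairs = rep(1e4, 80), normalized = FALSE,
                        bin_width = 2.5e-4, se = NULL), class = "tcf2")
  f1 <- fit_multiexponential(tc1, 1, n_starts = 8)
  expect_equal(f1$time_constants, 5e-3, tolerance = 1e-6)
  expect_equal(f1$amplitudes, 1, tolerance = 1e-6)

  # three components at 0.3 / 3.7 / 173 ms, equal amplitudes, 1% noise
  t_true <- c(0.3e-3, 3.7e-3, 173e-3)
  y <- rowSums(sapply(t_true, function(t) exp(-lags / t))) / 3
  y <- y + withr::with_seed(12, stats::rnorm(length(y), 0, 0.01 * y[1]))
  tc3 <- structure(list(lags = lags, values = y, n_pairs = rep(1e4, 80),
                        normalized = FALSE, bin_width = 2.5e-4, se = NULL),
                   class = "tcf2")
  f3 <- fit_multiexponential(tc3, 3, n_starts = 16)
  expect_equal(f3$time_constants, t_true, tolerance = 0.1)
})

test_that("overfitting clean two-exponential data leaves a degenerate component", {
  lags <- exp(seq(log(1e-3), log(1), length.out = 60))
  t_true <- c(5e-3, 200e-3)
  y <- 0.6 * exp(-lags / t_true[1]) + 0.4 * exp(-lags / t_true[2])
  tc <- structure(list(lags = lags, values = y, n_pairs = rep(1e4, 60),
                       normalized = FALSE, bin_width = 1e-3, se = NULL),
                  class = "tcf2")
  f <- fit_multiexponential(tc, 3, n_starts = 24)
  # two of the three recovered constants match the truth within 5%
  hits <- vapply(t_true, function(t) {
    any(abs(f$time_constants / t - 1) < 0.05)
  }, logical(1))
  expect_true(all(hits))
  # and the state count inference flags only 2 resolvable components -> 3
  expect_equal(as.integer(infer_state_count(f)), 3L)
})

test_that("mean relaxation time normalizes amplitudes", {
  mk <- function(a, t) structure(list(amplitudes = a, time_constants = t,
                                      offset = 0), class = "multiexp_fit")
  expect_equal(mean_relaxation_time(mk(1, 5e-3)), 5e-3)
  expect_equal(mean_relaxation_time(mk(c(0.5, 0.5), c(1e-3, 3e-3))), 2e-3)
  expect_equal(mean_relaxation_time(mk(c(2, 2), c(1e-3, 3e-3))), 2e-3)
  expect_error(mean_relaxation_time(mk(c(-1, 0.5), c(1e-3, 3e-3))), "sum")
})

test_that("state count is components + 1", {
  mk <- function(a, t) structure(list(amplitudes = a, time_constants = t,
                                      offset = 0), class = "multiexp_fit")
  expect_equal(as.integer(infer_state_count(
    mk(rep(1 / 3, 3), c(0.3e-3, 3.7e-3, 173e-3)))), 4L)
  expect_equal(as.integer(infer_state_count(mk(1, 5e-3))), 2L)
  expect_equal(as.integer(infer_state_count(
    mk(rep(0.25, 4), c(1e-4, 1e-3, 1e-2, 1e-1)))), 5L)
  # sub-threshold amplitude is not resolvable
  expect_equal(as.integer(infer_state_count(
    mk(c(1, 0.001), c(1e-3, 1e-1)))), 2L)
})

test_that("telegraph-process TCF matches the two-state closed form", {
  k <- 50   # per second, symmetric
  net <- kinetic_network(matrix(c(0, k, k, 0), 2, 2))
  em <- emission_model(c(0, 0.3), c(0.005, 0.005), weights = c(0.5, 0.5))
  trajs <- withr::with_seed(77, {
    lapply(1:6, function(i) {
      emit_visibility(simulate_state_path(net, 60), em, 1e-3)
    })
  })
  lags <- c(1e-3, 2e-3, 5e-3, 1e-2, 2e-2)
  tc <- two_point_tcf(trajs, lags = lags)
  theory <- 0.25 * 0.3^2 * exp(-2 * k * lags)
  expect_true(all(abs(tc$values - theory) < 3 * tc$se + 2e-5))
  # fitted decay rate close to k12 + k21
  f <- fit_multiexponential(tc, 1, n_starts = 8)
  expect_equal(f$time_constants, 1 / (2 * k), tolerance = 0.15)
})
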