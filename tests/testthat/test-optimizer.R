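# Simultaneous chi-square fit: objective arithmetic, parameter recovery on
# synthetic ensembles, descent and reproducibility.

# small noiseless dataset generated directly from a parameter set
model_dataset <- function(params, pdf_grid = seq(-0.04, 0.54, by = 0.02),
                          c2_lags = exp(seq(log(1e-3), log(1),
                                            length.out = 15)),
                          c3_lags = c(1e-2, 1e-1)) {
  dens <- model_pdf(params$emission, pdf_grid + 0.01)
  edges <- c(pdf_grid, max(pdf_grid) + 0.02)
  pdf <- structure(list(bin_edges = edges, mids = pdf_grid + 0.01,
                        density = dens, counts = rep(1L, length(dens)),
                        n_samples = length(dens), n_excluded = 0L),
                   class = "empirical_pdf")
  c2 <- model_c2(params$network, params$emission, c2_lags)
  c3 <- model_c3(params$network, params$emission, c3_lags, c3_lags)
  summary_statistics(pdf, c2, c3)
}

test_that("chi-square is zero on self-generated data and scales quadratically", {
  tr <- slow_truth()
  params <- fit_parameters(c(0.1, 0.5, 0.3, 0.1),
                           chain_exchange(c(4.2, 1.9, 0.4)),
                           tr$emission$means, tr$emission$sigmas)
  data <- model_dataset(params)
  chi0 <- chi_square(params, data)
  expect_lt(chi0$total, 1e-20)
  expect_named(chi0$blocks, c("pdf", "c2", "c3"))

  # perturb data by r and by 2r with fixed scales: chi2 quadruples
  data1 <- data; data2 <- data
  r_pdf <- 1e-3 * sin(seq_along(data$pdf$density))
  r_c2 <- 1e-5 * cos(seq_along(data$c2$values))
  data1$pdf$density <- data$pdf$density + r_pdf
  data2$pdf$density <- data$pdf$density + 2 * r_pdf
  data1$c2$values <- data$c2$values + r_c2
  data2$c2$values <- data$c2$values + 2 * r_c2
  scales <- c(pdf = 1, c2 = 1, c3 = 1)
  chi1 <- chi_square(params, data1, scales = scales)
  chi2_ <- chi_square(params, data2, scales = scales)
  expect_equal(chi2_$total, 4 * chi1$total, tolerance = 1e-10)

  # hand-summed value
  expect_equal(chi1$total, sum(r_pdf^2) + sum(r_c2^2), tolerance = 1e-12)
})

test_that("chi-square honours block weights and scales", {
  tr <- slow_truth()
  params <- fit_parameters(c(0.1, 0.5, 0.3, 0.1),
                           chain_exchange(c(4.2, 1.9, 0.4)),
                           tr$emission$means, tr$emission$sigmas)
  data <- model_dataset(params)
  data$pdf$density <- data$pdf$density + 0.01
  base <- chi_square(params, data, scales = c(pdf = 1, c2 = 1, c3 = 1))
  wgt <- chi_square(params, data, weights = c(pdf = 3, c2 = 1, c3 = 1),
                    scales = c(pdf = 1, c2 = 1, c3 = 1))
  expect_equal(wgt$blocks[["pdf"]], 3 * base$blocks[["pdf"]])
  scl <- chi_square(params, data, scales = c(pdf = 4, c2 = 1, c3 = 1))
  expect_equal(scl$blocks[["pdf"]], base$blocks[["pdf"]] / 4)
})

test_that("fit recovers a slow well-separated 4-state truth from synthetic data", {
  tr <- slow_truth()
  cfg <- simulation_config(tr$network, tr$emission, duration = 80,
                           bin_width = 1e-3, n_trajectories = 10, seed = 555)
  ens <- generate_ensemble(cfg)
  stats <- pipeline_estimate(ens$trajectories, c3_bin_width = 10e-3)
  fit <- fit_network(stats, 4, edge_mask = chain_mask(4), n_starts = 6,
                     seed = 20)
  p_true <- c(0.1, 0.5, 0.3, 0.1)
  expect_true(all(abs(fit$p_eq - p_true) < 0.05))
  expect_true(all(abs(fit$emission$means - tr$emission$means) < 0.01))
  # open-edge time constants within 30 percent
  t_true <- 1 / tr$network$rates
  open <- tr$network$edge_mask
  expect_true(all(abs(fit$t_ij[open] / t_true[open] - 1) < 0.3))
  # canonical ordering: means ascending
  expect_true(!is.unsorted(fit$emission$means))
  # states labelled S1.. in order of increasing visibility
  expect_equal(fit$network$state_labels, paste0("S", 1:4))
})

test_that("starting at the ground truth cannot worsen chi-square", {
  tr <- slow_truth()
  cfg <- simulation_config(tr$network, tr$emission, duration = 40,
                           bin_width = 1e-3, n_trajectories = 4, seed = 777)
  ens <- generate_ensemble(cfg)
  stats <- pipeline_estimate(ens$trajectories, c3_bin_width = 10e-3)
  truth_init <- list(p_eq = c(0.1, 0.5, 0.3, 0.1),
                     exchange = chain_exchange(c(4.2, 1.9, 0.4)),
                     means = tr$emission$means, sigmas = tr$emission$sigmas)
  params0 <- fit_parameters(truth_init$p_eq, truth_init$exchange,
                            truth_init$means, truth_init$sigmas)
  chi_start <- chi_square(params0, stats)$total
  fit <- fit_network(stats, 4, edge_mask = chain_mask(4), n_starts = 1,
                     seed = 5, init = truth_init)
  expect_lte(fit$chi_square$total, chi_start + 1e-12)
})

test_that("fits are bit-identical under identical seed and config", {
  tr <- slow_truth()
  cfg <- simulation_config(tr$network, tr$emission, duration = 30,
                           bin_width = 1e-3, n_trajectories = 3, seed = 888)
  ens <- generate_ensemble(cfg)
  stats <- pipeline_estimate(ens$trajectories, c3_bin_width = 10e-3)
  f1 <- fit_network(stats, 4, edge_mask = chain_mask(4), n_starts = 3,
                    seed = 42)
  f2 <- fit_network(stats, 4, edge_mask = chain_mask(4), n_starts = 3,
                    seed = 42)
  expect_identical(f1$p_eq, f2$p_eq)
  expect_identical(f1$exchange, f2$exchange)
  expect_identical(f1$emission$means, f2$emission$means)
  expect_identical(f1$starts$chi2, f2$starts$chi2)
})

test_that("model selection stops at the parsimonious state count", {
  # noiseless single-exponential (2-state) data: N = 2 is chosen over 3
  net <- kinetic_network(matrix(c(0, 40, 60, 0), 2, 2, byrow = TRUE))
  p2 <- unname(stationary_distribution(net))
  em <- emission_model(c(0.1, 0.3), c(0.02, 0.02), weights = p2)
  params <- fit_parameters(p2, matrix(c(0, 24, 24, 0), 2, 2) / 1,
                           em$means, em$sigmas)
  # exchange c with k = c/p: k12 = 40 -> c = 40 * 0.6 = 24
  data <- model_dataset(params, c2_lags = exp(seq(log(1e-3), log(0.5),
                                                  length.out = 12)),
                        c3_lags = c(5e-3, 5e-2))
  sel <- select_model(data, c(2, 3), n_starts = 3, seed = 31)
  expect_equal(sel$n_states, 2L)
  expect_equal(sel$table$n, c(2L, 3L))
  expect_true(is.finite(sel$table$chi2[2]))
})

test_that("write_fit serializes the fitted model", {
  tr <- slow_truth()
  params <- fit_parameters(c(0.1, 0.5, 0.3, 0.1),
                           chain_exchange(c(4.2, 1.9, 0.4)),
                           tr$emission$means, tr$emission$sigmas)
  data <- model_dataset(params)
  fit <- fit_network(data, 4, edge_mask = chain_mask(4), n_starts = 2,
                     seed = 3,
                     init = list(p_eq = c(0.1, 0.5, 0.3, 0.1),
                                 exchange = chain_exchange(c(4.2, 1.9, 0.4)),
                                 means = tr$emission$means,
                                 sigmas = tr$emission$sigmas))
  f <- tempfile(fileext = ".json")
  write_fit(fit, f)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(doc$p_eq, unname(fit$p_eq), tolerance = 1e-12)
  expect_equal(doc$seed, 3L)
})
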