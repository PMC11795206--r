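# Kinetic network core: stationary solve, propagator, spectrum, detailed
# balance construction and diagnostics.

test_that("stationary distribution matches closed forms", {
  # 2-state: p1 = k21/(k12+k21)
  net <- kinetic_network(matrix(c(0, 1, 3, 0), 2, 2, byrow = TRUE),
                         time_unit = "ms")
  expect_equal(unname(stationary_distribution(net)), c(0.75, 0.25),
               tolerance = 1e-12)
  # 4-state, all rates equal: uniform by symmetry
  r <- matrix(1000, 4, 4); diag(r) <- 0
  expect_equal(unname(stationary_distribution(kinetic_network(r))),
               rep(0.25, 4), tolerance = 1e-12)
})

test_that("invalid networks are rejected with informative errors", {
  r <- matrix(0, 4, 4)
  r[1, 2] <- r[2, 1] <- 5     # {S1,S2} and {S3,S4} disconnected
  r[3, 4] <- r[4, 3] <- 2
  expect_error(kinetic_network(r), "disconnected.*S1,S2.*S3,S4")
  expect_error(kinetic_network(matrix(0, 3, 3)), "all rate constants are zero")
  expect_error(kinetic_network(matrix(c(0, -1, 1, 0), 2, 2)), ">= 0")
  mask <- matrix(FALSE, 2, 2)
  r2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(kinetic_network(r2, edge_mask = mask), "masked")
})

test_that("conditional probabilities: identity at 0, closed form, invariants", {
  net <- kinetic_network(matrix(c(0, 1, 1, 0), 2, 2), time_unit = "ms")
  expect_equal(unclass(conditional_probabilities(net, 0))[1:4],
               c(diag(2))[1:4], tolerance = 1e-14)
  # p11(tau) = 0.5 + 0.5 exp(-(k12+k21) tau); at tau = ln2/2 ms -> 0.75
  P <- conditional_probabilities(net, log(2) / 2 / 1000)
  expect_equal(P[1, 1], 0.75, tolerance = 1e-12)
  expect_error(conditional_probabilities(net, -1), ">= 0")

  net4 <- random_db_network(4, seed = 101)
  for (tau in c(1e-4, 1e-2, 0.5)) {
    P <- conditional_probabilities(net4, tau)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
  }
})

test_that("Chapman-Kolmogorov and ergodic limit hold for random networks", {
  for (seed in c(3, 14, 15)) {
    net <- random_db_network(4, seed)
    t1 <- 0.013; t2 <- 0.047
    P12 <- conditional_probabilities(net, t1 + t2)
    prod <- conditional_probabilities(net, t1) %*%
      conditional_probabilities(net, t2)
    expect_lt(max(abs(P12 - prod)), 1e-10)
    sp <- relaxation_spectrum(net)
    tau_inf <- 25 * max(sp$time_constants)
    Pinf <- conditional_probabilities(net, tau_inf)
    p_eq <- stationary_distribution(net)
    expect_lt(max(abs(sweep(Pinf, 2, p_eq))), 1e-6)
  }
})

test_that("spectral propagator agrees with the dense matrix exponential", {
  for (seed in c(7, 21)) {
    net <- random_db_network(5, seed)
    Q <- generator_matrix(net)
    for (tau in c(1e-3, 0.1)) {
      P_spec <- conditional_probabilities(net, tau)
      P_expm <- as.matrix(Matrix::expm(Matrix::Matrix(Q * tau)))
      expect_lt(max(abs(P_spec - P_expm)), 1e-8)
    }
  }
})

test_that("relaxation spectrum: rate sum, circulant ring, count rule", {
  net <- kinetic_network(matrix(c(0, 1, 3, 0), 2, 2, byrow = TRUE),
                         time_unit = "ms")
  sp <- relaxation_spectrum(net)
  expect_equal(sp$rates, c(0, 4000), tolerance = 1e-10)
  expect_equal(sp$time_constants, 0.25e-3, tolerance = 1e-10)

  # symmetric 4-ring, all k = 1/ms: circulant eigenvalues {0, 2, 2, 4}/ms
  r <- matrix(0, 4, 4)
  for (i in 1:4) {
    j <- i %% 4 + 1
    r[i, j] <- r[j, i] <- 1000
  }
  sp_ring <- relaxation_spectrum(kinetic_network(r))
  expect_equal(sp_ring$rates, c(0, 2000, 2000, 4000), tolerance = 1e-8)

  # connected detailed-balance 4-state with generic rates: exactly 3 nonzero
  net4 <- random_db_network(4, seed = 5)
  expect_equal(sum(relaxation_spectrum(net4)$rates > 1e-9), 3L)
})

test_that("spectral reconstruction matches within 1e-8 over a tau sweep", {
  net <- slow_truth()$network
  sp <- relaxation_spectrum(net)
  expect_true(sp$modes_available)
  p_eq <- stationary_distribution(net)
  for (tau in c(1e-3, 0.05, 1)) {
    P_direct <- conditional_probabilities(net, tau)
    lam <- -sp$rates
    # reconstruct from the returned modes
    P_rec <- sp$modes$V %*% (exp(lam * tau) * sp$modes$Vinv)
    expect_lt(max(abs(P_direct - P_rec)), 1e-8)
  }
})

test_that("survival lifetime is the reciprocal exit-rate sum", {
  r <- matrix(0, 3, 3)
  r[1, 2] <- r[1, 3] <- 0.5                     # exits sum to 1/s
  r[2, 1] <- 2; r[3, 1] <- 1
  net <- kinetic_network(r)
  expect_equal(survival_lifetime(net, 1), 1.0)
  expect_equal(survival_lifetime(net, 2), 0.5)
  # exit rates summing to 1/0.081 -> 81 ms lifetime
  r2 <- matrix(0, 2, 2); r2[1, 2] <- 1 / 0.081; r2[2, 1] <- 1
  expect_equal(survival_lifetime(kinetic_network(r2), 1), 0.081)
})

test_that("detailed-balance construction is exact and recovers p_eq", {
  # symmetric 2-state: p = (.5,.5), c = 1 -> k12 = k21 = 2
  net <- build_detailed_balance_network(c(0.5, 0.5),
                                        matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(unname(net$rates[1, 2]), 2)
  expect_equal(unname(net$rates[2, 1]), 2)
  expect_lt(detailed_balance_residual(net), 1e-14)

  # printed fixture populations on a chain: stationary recovery is exact
  p <- c(0.82, 0.14, 0.02, 0.02)
  net2 <- build_detailed_balance_network(p, chain_exchange(c(2, 0.5, 7)))
  expect_equal(unname(stationary_distribution(net2)), p, tolerance = 1e-12)

  # random masked p/c: zero net flux within 1e-12
  for (seed in c(31, 32, 33)) {
    net3 <- random_db_network(5, seed)
    expect_lt(detailed_balance_residual(net3), 1e-12)
  }
  expect_error(build_detailed_balance_network(c(0, 1), diag(2) * 0 + 1),
               "> 0")
})

test_that("driven cycles violate detailed balance; trees never do", {
  r <- matrix(0, 3, 3)
  r[1, 2] <- r[2, 3] <- r[3, 1] <- 2   # clockwise
  r[2, 1] <- r[3, 2] <- r[1, 3] <- 1   # counterclockwise
  expect_gt(detailed_balance_residual(kinetic_network(r)), 1e-3)

  # star tree with arbitrary rates satisfies detailed balance
  r2 <- matrix(0, 4, 4)
  r2[1, 2] <- 3; r2[2, 1] <- 7
  r2[1, 3] <- 0.2; r2[3, 1] <- 11
  r2[1, 4] <- 5; r2[4, 1] <- 0.9
  expect_lt(detailed_balance_residual(kinetic_network(r2)), 1e-12)
})

test_that("network JSON round trip is exact to full float precision", {
  tr <- ps_truth_network()
  path <- tempfile(fileext = ".json")
  write_network(tr$network, path, emission = tr$emission)
  back <- read_network(path)
  expect_identical(back$network$rates, tr$network$rates)
  expect_identical(back$network$edge_mask, tr$network$edge_mask)
  expect_identical(back$emission$means, tr$emission$means)
  expect_identical(back$emission$weights, tr$emission$weights)
})
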