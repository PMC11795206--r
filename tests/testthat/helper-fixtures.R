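# Fixtures built in code: network/emission pairs used across test files.

chain_mask <- function(n) {
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- TRUE
  m
}

chain_exchange <- function(coefs) {
  n <- length(coefs) + 1L
  ex <- matrix(0, n, n)
  for (i in seq_len(n - 1)) ex[i, i + 1] <- ex[i + 1, i] <- coefs[i]
  ex
}

# Slow, well-separated 4-state detailed-balance chain: relaxation times
# ~19.5 / 92 / 261 ms, state means 6+ sigma apart. Used for parameter-recovery
# tests where dynamics must be slow relative to the bin width.
slow_truth <- function() {
  p <- c(0.1, 0.5, 0.3, 0.1)
  net <- build_detailed_balance_network(p, chain_exchange(c(4.2, 1.9, 0.4)))
  list(network = net,
       emission = emission_model(c(0.05, 0.15, 0.25, 0.35), rep(0.015, 4),
                                 weights = p))
}

# Random connected detailed-balance network with a random spanning-tree-plus
# mask (always connected by construction).
random_db_network <- function(n, seed) {
  withr::with_seed(seed, {
    p <- stats::runif(n, 0.05, 1)
    p <- p / sum(p)
    ex <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {           # spanning chain keeps it connected
      ex[i, i + 1] <- ex[i + 1, i] <- stats::runif(1, 1, 50)
    }
    extra <- which(upper.tri(ex) & ex == 0)
    add <- extra[stats::runif(length(extra)) < 0.4]
    for (e in add) {
      i <- row(ex)[e]; j <- col(ex)[e]
      ex[i, j] <- ex[j, i] <- stats::runif(1, 1, 50)
    }
    build_detailed_balance_network(p, ex)
  })
}

random_emission_for <- function(net, seed) {
  withr::with_seed(seed, {
    n <- net$n_states
    emission_model(sort(stats::runif(n, 0.02, 0.4)),
                   stats::runif(n, 0.01, 0.03),
                   weights = stationary_distribution(net),
                   state_labels = net$state_labels)
  })
}

# Expected histogram density of a Gaussian mixture on given bin edges
# (exact binned mass, avoiding the midpoint-curvature bias of pointwise
# density evaluation).
binned_mixture_density <- function(em, edges) {
  mass <- rep(0, length(edges) - 1L)
  for (i in seq_along(em$means)) {
    mass <- mass +
      em$weights[i] * diff(stats::pnorm(edges, em$means[i], em$sigmas[i]))
  }
  mass / diff(edges)
}

# State occupied at each query time along a Gillespie path.
states_at <- function(path, times) {
  tgrid <- c(0, cumsum(path$dwell))
  seg <- pmin(pmax(findInterval(times, tgrid, rightmost.closed = TRUE), 1L),
              nrow(path))
  path$state[seg]
}
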