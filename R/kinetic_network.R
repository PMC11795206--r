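#' N-state continuous-time Markov kinetic network
#'
#' Constructs a kinetic network of `N >= 2` macrostates interconverting with
#' first-order rate constants `k[i, j]` (state `i` to state `j`, per second).
#' The network is the kinetic backbone of the analysis: its master equation
#' \deqn{\dot p_i = \sum_{j \ne i} (-k_{ij} p_i + k_{ji} p_j)}
#' yields the equilibrium populations and the lag-dependent conditional
#' probabilities that enter the model correlation functions.
#'
#' Transitions that are absent from the network ("not observed") are declared
#' through `edge_mask`: a symmetric boolean adjacency with `FALSE` pinning both
#' `k[i, j]` and `k[j, i]` to zero. The masked graph must be connected so a
#' unique stationary distribution exists.
#'
#' @param rates square numeric matrix of rate constants; off-diagonal entry
#'   `[i, j]` is the i -> j rate. The diagonal is ignored. Units per second
#'   (or per millisecond with `time_unit = "ms"`).
#' @param edge_mask symmetric logical adjacency matrix; default: edges wherever
#'   `rates[i, j] > 0 | rates[j, i] > 0`.
#' @param state_labels character vector of state names; default `S1..SN`.
#' @param time_unit `"s"` (default) or `"ms"`; rates given per millisecond are
#'   converted to per second on construction.
#' @return An object of class `kinetic_network` with elements `n_states`,
#'   `rates` (per second), `edge_mask`, `state_labels`.
#' @seealso [stationary_distribution()], [conditional_probabilities()],
#'   [relaxation_spectrum()], [build_detailed_balance_network()]
#' @examples
#' net <- kinetic_network(matrix(c(0, 1000, 3000, 0), 2, 2, byrow = TRUE))
#' stationary_distribution(net)  # (0.75, 0.25)
#' @export
kinetic_network <- function(rates, edge_mask = NULL, state_labels = NULL,
                            time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  rates <- as.matrix(rates)
  n <- nrow(rates)
  if (n < 2L || ncol(rates) != n) {
    stop("'rates' must be a square matrix with at least 2 states")
  }
  if (time_unit == "ms") rates <- rates * 1000
  diag(rates) <- 0
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rate constants must be finite and >= 0")
  }
  if (is.null(edge_mask)) {
    edge_mask <- rates > 0 | t(rates) > 0
  }
  edge_mask <- as.matrix(edge_mask)
  diag(edge_mask) <- FALSE
  if (!isTRUE(all(edge_mask == t(edge_mask)))) {
    stop("'edge_mask' must be symmetric")
  }
  if (any(rates[!edge_mask] > 0)) {
    stop("positive rates found on masked (unobserved) transitions")
  }
  if (all(rates == 0)) stop("all rate constants are zero")
  comp <- graph_components(edge_mask)
  if (max(comp) > 1L) {
    labs <- state_labels %||% default_state_labels(n)
    groups <- vapply(seq_len(max(comp)), function(g) {
      paste0("{", paste(labs[comp == g], collapse = ","), "}")
    }, character(1))
    stop("network is disconnected; components: ", paste(groups, collapse = " "))
  }
  state_labels <- state_labels %||% default_state_labels(n)
  stopifnot(length(state_labels) == n)
  dimnames(rates) <- dimnames(edge_mask) <- list(state_labels, state_labels)
  structure(
    list(n_states = n, rates = rates, edge_mask = edge_mask,
         state_labels = state_labels),
    class = "kinetic_network"
  )
}

#' @export
print.kinetic_network <- function(x, ...) {
  cat(sprintf("kinetic_network: %d states (%s), %d open edges\n",
              x$n_states, paste(x$state_labels, collapse = ", "),
              sum(x$edge_mask) / 2))
  cat("rate constants (per second):\n")
  print(signif(x$rates, 4))
  invisible(x)
}

#' Generator matrix of a kinetic network
#'
#' Returns the master-equation generator `Q` with `Q[i, j] = k[i, j]` for
#' `i != j` and `Q[i, i] = -sum_j k[i, j]`, so rows sum to zero and
#' `p(t)^T = p(0)^T exp(Qt)`.
#'
#' @param net a [kinetic_network()].
#' @return numeric matrix.
#' @export
generator_matrix <- function(net) {
  stopifnot(inherits(net, "kinetic_network"))
  Q <- net$rates
  diag(Q) <- -rowSums(Q)
  Q
}

#' Equilibrium (stationary) populations of a kinetic network
#'
#' Solves `Q^T p = 0` with `sum(p) = 1` for the unique stationary distribution
#' of a connected network: the probabilities of observing each macrostate at
#' equilibrium.
#'
#' @param net a [kinetic_network()].
#' @return named probability vector `p_eq`.
#' @export
stationary_distribution <- function(net) {
  Q <- generator_matrix(net)
  n <- net$n_states
  # least-squares solve of the over-determined system [Q^T; 1] p = [0; 1]
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- as.vector(qr.solve(A, b))
  p[p < 0 & p > -1e-12] <- 0
  if (any(p < 0)) stop("stationary solve produced negative probabilities")
  p <- p / sum(p)
  names(p) <- net$state_labels
  p
}

# Spectral (or dense-exponential fallback) propagator factory. Returns a list
# with `propagate(tau) -> P(tau)` and the decomposition details.
propagator_factory <- function(net) {
  Q <- generator_matrix(net)
  n <- net$n_states
  if (detailed_balance_residual(net) < 1e-10 * max(net$rates)) {
    # reversible: symmetrize with D = diag(sqrt(p_eq)) for a stable real
    # eigendecomposition (S = D Q D^{-1} is symmetric)
    p <- stationary_distribution(net)
    d <- sqrt(p)
    S <- sweep(sweep(Q, 1, d, "*"), 2, d, "/")
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    V <- es$vectors / d        # columns: right eigenvectors of Q
    Vinv <- t(es$vectors * d)  # rows: left eigenvectors
    lambda <- es$values
    list(
      eigenvalues = lambda, V = V, Vinv = Vinv, spectral = TRUE,
      propagate = function(tau) {
        P <- V %*% (exp(lambda * tau) * Vinv)
        clean_stochastic(P)
      }
    )
  } else {
    es <- eigen(Q)
    V <- es$vectors
    ok <- tryCatch(rcond(V) > 1e-9, error = function(e) FALSE)
    if (ok) {
      Vinv <- solve(V)
      lambda <- es$values
      list(
        eigenvalues = lambda, V = V, Vinv = Vinv, spectral = TRUE,
        propagate = function(tau) {
          P <- Re(V %*% (exp(lambda * tau) * Vinv))
          clean_stochastic(P)
        }
      )
    } else {
      # (near-)degenerate spectrum: dense matrix exponential
      list(
        eigenvalues = es$values, V = NULL, Vinv = NULL, spectral = FALSE,
        propagate = function(tau) {
          P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * tau)))
          clean_stochastic(P)
        }
      )
    }
  }
}

clean_stochastic <- function(P) {
  P[P < 0 & P > -1e-12] <- 0
  P
}

#' Conditional transition probabilities at a lag
#'
#' `p[i, j](tau)`: the probability of finding the system in macrostate `j` a
#' lag `tau` after it was observed in macrostate `i`. Computed as
#' `exp(Q tau)` row-wise; diagonal entries are the survival probabilities.
#' Each row sums to one; `P(0)` is the identity and `P(tau)` approaches the
#' stationary distribution in every row as `tau` grows.
#'
#' @param net a [kinetic_network()].
#' @param tau lag time(s) in seconds, `>= 0`. If several are given a list of
#'   matrices is returned.
#' @return a row-stochastic matrix with attribute `tau` (or a list of them).
#' @export
conditional_probabilities <- function(net, tau) {
  stopifnot(inherits(net, "kinetic_network"))
  if (any(tau < 0)) stop("'tau' must be >= 0")
  fac <- propagator_factory(net)
  out <- lapply(tau, function(t1) {
    P <- fac$propagate(t1)
    dimnames(P) <- list(net$state_labels, net$state_labels)
    attr(P, "tau") <- t1
    P
  })
  if (length(tau) == 1L) out[[1L]] else out
}

#' Relaxation spectrum of a kinetic network
#'
#' Eigen-decomposition of the generator: the nonzero eigenvalue magnitudes are
#' the relaxation rates of the network and their reciprocals the relaxation
#' time constants that appear as decay components of the two-point
#' time-correlation function. A connected N-state network has exactly one zero
#' rate (the stationary mode) and at most `N - 1` distinct nonzero rates — the
#' basis of the macrostate-count rule (decay components observed, plus one).
#'
#' @param net a [kinetic_network()].
#' @return object of class `relaxation_spectrum`: `rates` (per second, sorted
#'   ascending, first exactly zero), `time_constants` (seconds, ascending, for
#'   nonzero rates), `modes` (list with eigenvector matrices `V`, `Vinv`, or
#'   `NULL` when the spectrum is near-degenerate and a dense propagator is
#'   used), `modes_available`.
#' @export
relaxation_spectrum <- function(net) {
  fac <- propagator_factory(net)
  lam <- fac$eigenvalues
  if (max(abs(Im(lam))) > 1e-8 * max(abs(Re(lam)))) {
    warning("complex relaxation rates (irreversible network); real parts used")
  }
  rates <- -Re(lam)
  i0 <- which.min(abs(rates))
  if (abs(rates[i0]) > 1e-8 * max(abs(rates))) {
    stop("no zero eigenvalue found; network may be invalid")
  }
  rates[i0] <- 0
  ord <- order(rates)
  rates <- rates[ord]
  structure(
    list(
      rates = rates,
      time_constants = sort(1 / rates[rates > 0]),
      modes = if (fac$spectral) list(V = fac$V[, ord, drop = FALSE],
                                     Vinv = fac$Vinv[ord, , drop = FALSE])
              else NULL,
      modes_available = fac$spectral
    ),
    class = "relaxation_spectrum"
  )
}

#' @export
print.relaxation_spectrum <- function(x, ...) {
  cat("relaxation_spectrum:\n  rates (/s):", signif(x$rates, 5), "\n")
  cat("  time constants (ms):", signif(1000 * x$time_constants, 5), "\n")
  invisible(x)
}

#' Macrostate population lifetime
#'
#' The mean dwell (survival) lifetime of macrostate `i`: the reciprocal of its
#' total exit rate, `1 / sum_j k[i, j]`. This is the time scale on which the
#' survival probability `p[i, i](tau)` decays from one toward the equilibrium
#' population.
#'
#' @param net a [kinetic_network()].
#' @param i state index or label.
#' @return lifetime in seconds.
#' @export
survival_lifetime <- function(net, i) {
  stopifnot(inherits(net, "kinetic_network"))
  if (is.character(i)) i <- match(i, net$state_labels)
  exit <- sum(net$rates[i, ])
  if (exit <= 0) stop("state ", net$state_labels[i], " has no open edges")
  1 / exit
}

#' Build a kinetic network satisfying detailed balance exactly
#'
#' Parameterizes a reversible network by its target stationary distribution
#' `p_eq` and a symmetric matrix of nonnegative exchange coefficients `c`,
#' setting `k[i, j] = c[i, j] / p_eq[i]`. By construction
#' `k[i, j] p_eq[i] = k[j, i] p_eq[j]` holds exactly and
#' [stationary_distribution()] recovers `p_eq`.
#'
#' @param p_eq strictly positive probability vector (sums to 1).
#' @param exchange symmetric nonnegative matrix of exchange coefficients
#'   (per second); entries off the edge mask must be zero.
#' @param edge_mask optional symmetric logical adjacency; default derived from
#'   `exchange > 0`.
#' @param state_labels optional state names.
#' @return a [kinetic_network()].
#' @export
build_detailed_balance_network <- function(p_eq, exchange, edge_mask = NULL,
                                           state_labels = NULL) {
  n <- length(p_eq)
  if (any(p_eq <= 0)) stop("all equilibrium populations must be > 0")
  if (abs(sum(p_eq) - 1) > 1e-8) stop("'p_eq' must sum to 1")
  exchange <- as.matrix(exchange)
  diag(exchange) <- 0
  if (max(abs(exchange - t(exchange))) > 1e-12 * max(abs(exchange), 1)) {
    stop("'exchange' must be symmetric")
  }
  if (any(exchange < 0)) stop("'exchange' must be nonnegative")
  if (!is.null(edge_mask) && any(exchange[!edge_mask & !diag(n)] != 0)) {
    stop("'exchange' has nonzero entries on masked edges")
  }
  rates <- exchange / p_eq  # divides row i by p_eq[i]
  kinetic_network(rates, edge_mask = edge_mask, state_labels = state_labels)
}

#' Detailed-balance residual of a network
#'
#' Maximum absolute net probability flux over all state pairs,
#' `max_ij |k[i, j] p_eq[i] - k[j, i] p_eq[j]|`. Zero (to round-off) for
#' reversible networks; positive for driven cycles.
#'
#' @param net a [kinetic_network()].
#' @return nonnegative scalar.
#' @export
detailed_balance_residual <- function(net) {
  p <- stationary_distribution(net)
  flux <- net$rates * p  # row i scaled by p[i]
  max(abs(flux - t(flux)))
}

#' Write / read a kinetic network (+ optional emission model) as JSON
#'
#' Serializes state labels, the rate matrix, the edge mask and, when supplied,
#' the Gaussian emission parameters, at full floating-point precision so the
#' round trip is exact.
#'
#' @param net a [kinetic_network()].
#' @param path file path.
#' @param emission optional [emission_model()] stored alongside the network.
#' @return `write_network`: the path, invisibly. `read_network`: a list with
#'   elements `network` and (possibly `NULL`) `emission`.
#' @export
write_network <- function(net, path, emission = NULL) {
  stopifnot(inherits(net, "kinetic_network"))
  doc <- list(
    state_labels = net$state_labels,
    rates_per_s = unclass(net$rates),
    edge_mask = unclass(net$edge_mask)
  )
  if (!is.null(emission)) {
    stopifnot(inherits(emission, "emission_model"))
    doc$emission <- list(means = emission$means, sigmas = emission$sigmas,
                         weights = emission$weights)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- kinetic_network(doc$rates_per_s,
                         edge_mask = matrix(as.logical(doc$edge_mask),
                                            nrow = length(doc$state_labels)),
                         state_labels = doc$state_labels)
  emission <- NULL
  if (!is.null(doc$emission)) {
    emission <- emission_model(means = doc$emission$means,
                               sigmas = doc$emission$sigmas,
                               weights = doc$emission$weights,
                               state_labels = doc$state_labels)
  }
  list(network = net, emission = emission)
}
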