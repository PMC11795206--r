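#' Gaussian macrostate emission model
#'
#' Each macrostate `i` emits visibility values from a Gaussian with mean
#' `v_bar_i` and standard deviation `sigma_i`. The visibility distribution is
#' the mixture
#' \deqn{P(v) = \sum_i A_i \exp[-(v - \bar v_i)^2 / 2\sigma_i^2],}
#' where the amplitude `A_i` and the equilibrium population are related by the
#' integrated component area `p_i = A_i sigma_i sqrt(2 pi)`. Supply either
#' `weights` (populations, summing to one) or `amplitudes`.
#'
#' @param means per-state mean visibilities.
#' @param sigmas per-state standard deviations (> 0).
#' @param weights per-state equilibrium populations (sum to 1), or `NULL`.
#' @param amplitudes per-state Gaussian amplitudes, or `NULL`.
#' @param state_labels optional state names.
#' @return object of class `emission_model` with `means`, `sigmas`, `weights`,
#'   `amplitudes`, `state_labels`.
#' @export
emission_model <- function(means, sigmas, weights = NULL, amplitudes = NULL,
                           state_labels = NULL) {
  n <- length(means)
  stopifnot(length(sigmas) == n)
  if (any(sigmas <= 0)) stop("all 'sigmas' must be > 0")
  if (is.null(weights) == is.null(amplitudes)) {
    stop("supply exactly one of 'weights' or 'amplitudes'")
  }
  if (is.null(weights)) {
    if (any(amplitudes < 0)) stop("'amplitudes' must be nonnegative")
    weights <- amplitudes * sigmas * sqrt(2 * pi)
    if (abs(sum(weights) - 1) > 1e-6) {
      stop("amplitudes imply total probability ", signif(sum(weights), 8),
           "; must equal 1 within 1e-6")
    }
    weights <- weights / sum(weights)
  } else {
    if (any(weights < 0)) stop("'weights' must be nonnegative")
    if (abs(sum(weights) - 1) > 1e-6) stop("'weights' must sum to 1 within 1e-6")
    weights <- weights / sum(weights)
  }
  amplitudes <- weights / (sigmas * sqrt(2 * pi))
  state_labels <- state_labels %||% default_state_labels(n)
  structure(
    list(means = as.numeric(means), sigmas = as.numeric(sigmas),
         weights = as.numeric(weights), amplitudes = as.numeric(amplitudes),
         state_labels = state_labels),
    class = "emission_model"
  )
}

#' @export
print.emission_model <- function(x, ...) {
  df <- data.frame(state = x$state_labels, mean = x$means, sigma = x$sigmas,
                   weight = x$weights, amplitude = x$amplitudes)
  cat("emission_model:\n")
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Equilibrium weight of a Gaussian emission component
#'
#' The integrated area of one mixture component,
#' `p_i = A_i * sigma_i * sqrt(2 pi)`: the probability that the macrostate is
#' present at equilibrium.
#'
#' @param amplitude Gaussian amplitude `A_i` (density units).
#' @param sigma standard deviation (> 0).
#' @return probability (component area).
#' @export
state_weight <- function(amplitude, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  amplitude * sigma * sqrt(2 * pi)
}

#' Model visibility distribution (Gaussian mixture)
#'
#' Evaluates `sum_i A_i exp(-(v - v_bar_i)^2 / (2 sigma_i^2))` on a grid.
#'
#' @param emission an [emission_model()].
#' @param grid numeric grid of visibility values (conventionally monotone).
#' @return numeric vector of densities on the grid.
#' @export
model_pdf <- function(emission, grid) {
  stopifnot(inherits(emission, "emission_model"))
  out <- numeric(length(grid))
  for (i in seq_along(emission$means)) {
    out <- out + emission$amplitudes[i] *
      exp(-(grid - emission$means[i])^2 / (2 * emission$sigmas[i]^2))
  }
  out
}

#' Macrostate visibility fluctuation amplitudes
#'
#' `delta_v_bar_i = v_bar_i - sum_j p_j v_bar_j`: each macrostate's mean
#' visibility relative to the population-weighted ensemble mean. These signed
#' fluctuations are the building blocks of the model correlation functions;
#' they satisfy `sum_i p_i delta_v_bar_i = 0`.
#'
#' @param emission an [emission_model()].
#' @param p_eq equilibrium populations; default the emission weights.
#' @return named numeric vector.
#' @export
fluctuation_amplitudes <- function(emission, p_eq = NULL) {
  stopifnot(inherits(emission, "emission_model"))
  p <- p_eq %||% emission$weights
  dv <- emission$means - sum(p * emission$means)
  names(dv) <- emission$state_labels
  dv
}

check_pairing <- function(net, emission, tol = 1e-6) {
  stopifnot(inherits(net, "kinetic_network"),
            inherits(emission, "emission_model"))
  if (net$n_states != length(emission$means)) {
    stop("network and emission model disagree on the number of states")
  }
  p_net <- stationary_distribution(net)
  rel <- max(abs(p_net - emission$weights)) / max(p_net)
  if (rel > tol) {
    stop("emission-implied populations deviate from the network's stationary ",
         "distribution (relative ", signif(rel, 3), " > ", tol, ")")
  }
  p_net
}

#' Model two-point time-correlation function
#'
#' The kinetic-network counterpart of the empirical two-point TCF:
#' \deqn{C^{(2)}(\tau) = \sum_{i,j} \delta\bar v_j \, p_{ij}(\tau) \,
#' \delta\bar v_i \, p_i^{eq},}
#' a statistically weighted sum over all N^2 two-point kinetic pathways. Only
#' the macrostate mean visibilities enter; the within-state Gaussian spread
#' contributes to the PDF but not to the model TCFs.
#'
#' @param net a [kinetic_network()].
#' @param emission an [emission_model()] whose weights match the network's
#'   stationary distribution (relative tolerance `p_tol`).
#' @param lags lag times in seconds.
#' @param p_tol consistency tolerance between emission weights and the
#'   stationary distribution (default 1e-6).
#' @return a `tcf2` object (unnormalized).
#' @export
model_c2 <- function(net, emission, lags, p_tol = 1e-6) {
  p <- check_pairing(net, emission, p_tol)
  dv <- fluctuation_amplitudes(emission, p)
  fac <- propagator_factory(net)
  w <- p * dv
  vals <- vapply(lags, function(tau) {
    sum(w * (fac$propagate(tau) %*% dv))
  }, numeric(1))
  new_tcf2(lags, vals, rep(NA_integer_, length(lags)), FALSE, NA_real_)
}

#' Model three-point time-correlation function
#'
#' The kinetic-network counterpart of the empirical three-point TCF:
#' \deqn{C^{(3)}(\tau_1, \tau_2) = \sum_{i,j,k} \delta\bar v_k \,
#' p_{jk}(\tau_2) \, \delta\bar v_j \, p_{ij}(\tau_1) \, \delta\bar v_i \,
#' p_i^{eq},}
#' a weighted sum over all N^3 three-point transition pathways. For a
#' detailed-balance network it is symmetric under exchange of the two lags.
#'
#' @inheritParams model_c2
#' @param lags1,lags2 lag grids in seconds.
#' @return a `tcf3` object.
#' @export
model_c3 <- function(net, emission, lags1, lags2, p_tol = 1e-6) {
  p <- check_pairing(net, emission, p_tol)
  dv <- fluctuation_amplitudes(emission, p)
  fac <- propagator_factory(net)
  taus <- sort(unique(c(lags1, lags2)))
  P <- lapply(taus, fac$propagate)
  i1 <- match(lags1, taus)
  i2 <- match(lags2, taus)
  left <- lapply(i1, function(a) as.vector((p * dv) %*% P[[a]]) * dv)
  vals <- matrix(0, length(lags1), length(lags2))
  for (b in seq_along(lags2)) {
    Pb_dv <- P[[i2[b]]] %*% dv
    for (a in seq_along(lags1)) vals[a, b] <- sum(left[[a]] * Pb_dv)
  }
  new_tcf3(lags1, lags2, vals, matrix(NA_integer_, length(lags1),
                                      length(lags2)), NA_real_)
}

#' Model statistics bundle on declared grids
#'
#' Convenience wrapper evaluating the model PDF, two-point and three-point
#' TCFs of a paired network + emission model on the grids of an empirical
#' [summary_statistics()] object (or on explicitly supplied grids).
#'
#' @param net a [kinetic_network()].
#' @param emission an [emission_model()].
#' @param data optional [summary_statistics()] supplying the grids.
#' @param pdf_grid,c2_lags,c3_lags1,c3_lags2 explicit grids (used when `data`
#'   is `NULL`).
#' @return list with `pdf`, `c2`, `c3`.
#' @export
model_statistics <- function(net, emission, data = NULL, pdf_grid = NULL,
                             c2_lags = NULL, c3_lags1 = NULL, c3_lags2 = NULL) {
  if (!is.null(data)) {
    stopifnot(inherits(data, "summary_statistics"))
    pdf_grid <- data$pdf$mids
    c2_lags <- data$c2$lags
    c3_lags1 <- data$c3$lags1
    c3_lags2 <- data$c3$lags2
  }
  list(pdf = model_pdf(emission, pdf_grid),
       c2 = model_c2(net, emission, c2_lags),
       c3 = model_c3(net, emission, c3_lags1, c3_lags2))
}
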