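#' Bundle empirical statistics for fitting
#'
#' The acceptance surface of the kinetic-network fit: the empirical visibility
#' PDF, the two-point TCF and the three-point TCF on their declared grids.
#'
#' @param pdf an [empirical_pdf()].
#' @param c2 a `tcf2` (unnormalized, lags > 0 recommended: the model TCF
#'   carries no within-state noise term, so the zero-lag point of real data is
#'   not comparable).
#' @param c3 a `tcf3`.
#' @return object of class `summary_statistics`.
#' @export
summary_statistics <- function(pdf, c2, c3) {
  stopifnot(inherits(pdf, "empirical_pdf"), inherits(c2, "tcf2"),
            inherits(c3, "tcf3"))
  if (c2$normalized) stop("fit expects an unnormalized two-point TCF")
  structure(list(pdf = pdf, c2 = c2, c3 = c3), class = "summary_statistics")
}

#' @export
print.summary_statistics <- function(x, ...) {
  cat("summary_statistics:\n  ")
  print(x$pdf)
  cat("  "); print(x$c2)
  cat("  "); print(x$c3)
  invisible(x)
}

#' Free parameters of the kinetic-network + emission fit
#'
#' Collects the model parameters the optimizer searches over: equilibrium
#' populations (on the simplex), symmetric exchange coefficients on the open
#' edges (detailed balance holds exactly by construction, `k_ij = c_ij / p_i`),
#' and per-state Gaussian emission means and widths. Gaussian amplitudes are
#' derived, `A_i = p_i / (sigma_i sqrt(2 pi))`.
#'
#' @param p_eq equilibrium populations (sum to 1, > 0).
#' @param exchange symmetric nonnegative exchange-coefficient matrix (per s).
#' @param means,sigmas emission parameters.
#' @param edge_mask symmetric logical adjacency (default from `exchange > 0`).
#' @return object of class `fit_parameters` with the network and emission
#'   realized (`$network`, `$emission`) plus the raw fields.
#' @export
fit_parameters <- function(p_eq, exchange, means, sigmas, edge_mask = NULL) {
  net <- build_detailed_balance_network(p_eq, exchange, edge_mask = edge_mask)
  em <- emission_model(means, sigmas, weights = p_eq,
                       state_labels = net$state_labels)
  structure(list(p_eq = p_eq, exchange = as.matrix(exchange),
                 means = means, sigmas = sigmas,
                 edge_mask = net$edge_mask, network = net, emission = em),
            class = "fit_parameters")
}

block_scale <- function(x) {
  s <- sum(x^2)
  if (s <= 0) 1 else s
}

fit_residuals <- function(params, data, weights) {
  m_pdf <- model_pdf(params$emission, data$pdf$mids)
  m_c2 <- model_c2(params$network, params$emission, data$c2$lags)
  m_c3 <- model_c3(params$network, params$emission, data$c3$lags1,
                   data$c3$lags2)
  c(sqrt(weights[["pdf"]] / block_scale(data$pdf$density)) *
      (m_pdf - data$pdf$density),
    sqrt(weights[["c2"]] / block_scale(data$c2$values)) *
      (m_c2$values - data$c2$values),
    sqrt(weights[["c3"]] / block_scale(data$c3$values)) *
      as.vector(m_c3$values - data$c3$values))
}

#' Chi-square objective of a parameter set against empirical statistics
#'
#' \deqn{\chi^2 = \sum_b w_b \sum_{\rm points} ({\rm model} - {\rm data})^2 /
#' s_b,} with one block `b` per statistic (PDF, C2, C3) and `s_b` the block's
#' sum of squared data values, so each block initially contributes O(1).
#' Zero iff the model reproduces the data exactly on all grids.
#'
#' @param params a [fit_parameters()] object (or a [fit_network()] result).
#' @param data a [summary_statistics()] with grids matching the model
#'   evaluation.
#' @param weights named per-block nonnegative weights
#'   (default `c(pdf = 1, c2 = 1, c3 = 1)`).
#' @param scales optional named per-block scales `s_b`; default each block's
#'   sum of squared data values.
#' @return list with `total` and per-block `blocks`.
#' @export
chi_square <- function(params, data, weights = c(pdf = 1, c2 = 1, c3 = 1),
                       scales = NULL) {
  stopifnot(inherits(data, "summary_statistics"))
  if (inherits(params, "network_fit")) {
    params <- fit_parameters(params$p_eq, params$exchange,
                             params$emission$means, params$emission$sigmas,
                             params$network$edge_mask)
  }
  stopifnot(inherits(params, "fit_parameters"))
  m_pdf <- model_pdf(params$emission, data$pdf$mids)
  m_c2 <- model_c2(params$network, params$emission, data$c2$lags)
  m_c3 <- model_c3(params$network, params$emission, data$c3$lags1,
                   data$c3$lags2)
  scales <- scales %||% c(pdf = block_scale(data$pdf$density),
                          c2 = block_scale(data$c2$values),
                          c3 = block_scale(data$c3$values))
  blocks <- c(
    pdf = weights[["pdf"]] * sum((m_pdf - data$pdf$density)^2) /
      scales[["pdf"]],
    c2 = weights[["c2"]] * sum((m_c2$values - data$c2$values)^2) /
      scales[["c2"]],
    c3 = weights[["c3"]] * sum((m_c3$values - data$c3$values)^2) /
      scales[["c3"]]
  )
  list(total = sum(blocks), blocks = blocks)
}

# ---- parameter vector encoding ----------------------------------------------

encode_theta <- function(p_eq, exchange, means, sigmas, edges) {
  c(simplex_to_free(p_eq),
    log(exchange[edges]),
    log(pmax(means, 1e-4)),
    log(sigmas))
}

decode_theta <- function(theta, n, edges, edge_mask) {
  n_e <- nrow(edges)
  z <- theta[seq_len(n - 1)]
  lc <- theta[n - 1 + seq_len(n_e)]
  lm_ <- theta[n - 1 + n_e + seq_len(n)]
  ls <- theta[n - 1 + n_e + n + seq_len(n)]
  p <- free_to_simplex(z)
  ex <- matrix(0, n, n)
  ex[edges] <- exp(lc)
  ex[edges[, c(2, 1), drop = FALSE]] <- exp(lc)
  list(p_eq = p, exchange = ex, means = exp(lm_), sigmas = exp(ls))
}

theta_bounds <- function(n, n_e) {
  list(lower = c(rep(-14, n - 1), rep(log(1e-4), n_e), rep(log(1e-4), n),
                 rep(log(5e-4), n)),
       upper = c(rep(14, n - 1), rep(log(1e6), n_e), rep(log(1), n),
                 rep(log(0.3), n)))
}

# Data-driven initial parameter guess: cluster a sample drawn from the
# empirical PDF for populations/means/widths; set a common exchange scale from
# a multi-exponential fit of the empirical C2.
initial_guess <- function(data, n_states, edge_mask) {
  widths <- diff(data$pdf$bin_edges)
  prob <- data$pdf$density * widths
  prob[prob < 0] <- 0
  draw <- sample(data$pdf$mids, 4000L, replace = TRUE, prob = prob) +
    stats::runif(4000L, -widths[1] / 2, widths[1] / 2)
  km <- stats::kmeans(draw, centers = n_states, nstart = 5L, iter.max = 50L)
  ord <- order(km$centers)
  means <- pmin(pmax(as.vector(km$centers)[ord], 1e-3), 0.99)
  p <- pmax(km$size[ord] / sum(km$size), 1e-3)
  p <- p / sum(p)
  sigmas <- vapply(ord, function(k) {
    s <- stats::sd(draw[km$cluster == k])
    if (!is.finite(s) || s < 5e-3) 5e-3 else s
  }, numeric(1))
  t_scale <- tryCatch({
    nfit <- min(n_states - 1L, 3L)
    fit <- fit_multiexponential(data$c2, nfit, n_starts = 8L, seed = 1L)
    exp(mean(log(fit$time_constants)))
  }, error = function(e) 10e-3, warning = function(w) 10e-3)
  edges <- mask_edges(edge_mask)
  ex <- matrix(0, n_states, n_states)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    c_e <- (p[i] * p[j] / (p[i] + p[j])) / t_scale
    ex[i, j] <- ex[j, i] <- c_e
  }
  list(p_eq = p, exchange = ex, means = means, sigmas = sigmas)
}

#' Fit the kinetic network + emission model to empirical statistics
#'
#' Simultaneous least-squares fit of the N-state detailed-balance network and
#' Gaussian emission model to the empirical PDF, two-point TCF and three-point
#' TCF (see [chi_square()]). The search runs bounded Levenberg-Marquardt from
#' multiple starting points: the first start is data-driven (PDF clustering
#' for populations/means/widths, a multi-exponential C2 fit for the exchange
#' time scale, or a user-supplied `init`), the rest are random perturbations
#' of it. Detailed balance is exact by parameterization (log exchange
#' coefficients + simplex populations); all mean visibilities are fitted
#' nonnegative (the measurement does not distinguish the sign; sign
#' assignment belongs to the free-energy-surface step). The returned states
#' are canonicalized in order of increasing mean visibility.
#'
#' @param data a [summary_statistics()].
#' @param n_states number of macrostates `N` (e.g. from
#'   [infer_state_count()]).
#' @param edge_mask symmetric logical adjacency declaring which transitions
#'   are observable; default all pairs open.
#' @param n_starts number of optimization starts (default 24).
#' @param seed master seed for the start stream (recorded in the result).
#' @param weights per-block weights, see [chi_square()].
#' @param init optional list with `p_eq`, `exchange`, `means`, `sigmas` used
#'   as the first start (e.g. a known ground truth).
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @return object of class `network_fit`: `network`, `emission`, `p_eq`,
#'   `exchange`, `t_ij` (seconds, `NA` off open edges), `chi_square` (total
#'   and per-block), `starts` (per-start final chi-square table), `seed`,
#'   `weights`, `converged`.
#' @export
fit_network <- function(data, n_states, edge_mask = NULL, n_starts = 24L,
                        seed = 1L, weights = c(pdf = 1, c2 = 1, c3 = 1),
                        init = NULL, max_iter = 150L) {
  stopifnot(inherits(data, "summary_statistics"), n_states >= 2L)
  n <- as.integer(n_states)
  if (is.null(edge_mask)) {
    edge_mask <- matrix(TRUE, n, n)
  }
  edge_mask <- as.matrix(edge_mask)
  diag(edge_mask) <- FALSE
  edges <- mask_edges(edge_mask)
  n_e <- nrow(edges)
  bounds <- theta_bounds(n, n_e)

  base <- withr::with_seed(child_seed(seed, 0L), {
    init %||% initial_guess(data, n, edge_mask)
  })
  theta0 <- encode_theta(base$p_eq, base$exchange + 1e-12, base$means,
                         base$sigmas, edges)
  theta0 <- pmin(pmax(theta0, bounds$lower), bounds$upper)

  start_list <- withr::with_seed(child_seed(seed, 1L), {
    lapply(seq_len(n_starts), function(s) {
      if (s == 1L) return(theta0)
      jit <- c(stats::rnorm(n - 1, 0, 0.5),
               stats::rnorm(n_e, 0, 1.5),
               stats::rnorm(n, 0, 0.15),
               stats::rnorm(n, 0, 0.2))
      pmin(pmax(theta0 + jit, bounds$lower), bounds$upper)
    })
  })

  resid_fn <- function(theta) {
    d <- decode_theta(theta, n, edges, edge_mask)
    params <- tryCatch(
      fit_parameters(d$p_eq, d$exchange, d$means, d$sigmas, edge_mask),
      error = function(e) NULL)
    if (is.null(params)) return(rep(1e6, n_resid))
    r <- tryCatch(fit_residuals(params, data, weights),
                  error = function(e) rep(1e6, n_resid))
    r[!is.finite(r)] <- 1e6
    r
  }
  n_resid <- length(data$pdf$density) + length(data$c2$values) +
    length(data$c3$values)

  results <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    results[[s]] <- tryCatch(
      minpack.lm::nls.lm(
        par = start_list[[s]], fn = resid_fn,
        lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(maxiter = max_iter)),
      error = function(e) NULL)
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all optimization starts failed")
  chis <- vapply(results, function(r) {
    if (is.null(r)) Inf else sum(r$fvec^2)
  }, numeric(1))
  best_i <- which.min(chis)
  best <- results[[best_i]]

  d <- decode_theta(best$par, n, edges, edge_mask)
  # canonical state order: increasing mean visibility
  ord <- order(d$means)
  perm <- function(m) m[ord, ord, drop = FALSE]
  p_eq <- d$p_eq[ord]
  exchange <- perm(d$exchange)
  mask2 <- perm(edge_mask)
  means <- d$means[ord]
  sigmas <- d$sigmas[ord]
  net <- build_detailed_balance_network(p_eq, exchange, edge_mask = mask2)
  em <- emission_model(means, sigmas, weights = p_eq,
                       state_labels = net$state_labels)
  t_ij <- 1 / net$rates
  t_ij[!mask2] <- NA_real_
  params <- fit_parameters(p_eq, exchange, means, sigmas, mask2)
  chi <- chi_square(params, data, weights)
  structure(
    list(network = net, emission = em, p_eq = stats::setNames(
           p_eq, net$state_labels),
         exchange = exchange, t_ij = t_ij,
         chi_square = chi,
         starts = data.frame(start = seq_len(n_starts), chi2 = chis,
                             converged = ok,
                             best = seq_len(n_starts) == best_i),
         seed = seed, weights = weights,
         converged = best$info %in% 1:4,
         n_states = n),
    class = "network_fit"
  )
}

#' @export
print.network_fit <- function(x, ...) {
  cat(sprintf("network_fit: %d states, chi^2 = %.4g (pdf %.3g, c2 %.3g, c3 %.3g)\n",
              x$n_states, x$chi_square$total, x$chi_square$blocks["pdf"],
              x$chi_square$blocks["c2"], x$chi_square$blocks["c3"]))
  df <- data.frame(state = x$network$state_labels, p_eq = x$p_eq,
                   mean = x$emission$means, sigma = x$emission$sigmas)
  print(df, row.names = FALSE, digits = 3)
  cat("time constants t_ij (ms):\n")
  print(signif(1000 * x$t_ij, 3))
  invisible(x)
}

#' Choose the macrostate count by chi-square improvement
#'
#' Fits each candidate `N` and selects the most parsimonious model: stepping
#' up through the candidates, the first `N` whose relative chi-square
#' improvement over the previous candidate falls below `threshold` stops the
#' search and the previous candidate is chosen; otherwise the largest
#' candidate wins. The full per-N table is returned for transparency.
#'
#' @param data a [summary_statistics()].
#' @param candidates integer vector of candidate state counts (>= 2 entries).
#' @param threshold relative improvement cutoff (default 0.05).
#' @param ... passed to [fit_network()].
#' @return list with `n_states` (chosen), `table` (data.frame `n`, `chi2`,
#'   `rel_improvement`), `fits` (named list of `network_fit`s).
#' @export
select_model <- function(data, candidates, threshold = 0.05, ...) {
  candidates <- sort(unique(as.integer(candidates)))
  stopifnot(length(candidates) >= 2L)
  fits <- list()
  chi2 <- rel <- rep(NA_real_, length(candidates))
  chosen <- candidates[length(candidates)]
  decided <- FALSE
  for (k in seq_along(candidates)) {
    fits[[as.character(candidates[k])]] <-
      fit_network(data, candidates[k], ...)
    chi2[k] <- fits[[k]]$chi_square$total
    if (k > 1L) {
      rel[k] <- (chi2[k - 1] - chi2[k]) / chi2[k - 1]
      if (!decided && rel[k] < threshold) {
        chosen <- candidates[k - 1]
        decided <- TRUE
      }
    }
  }
  list(n_states = chosen,
       table = data.frame(n = candidates, chi2 = chi2,
                          rel_improvement = rel),
       fits = fits)
}

#' Serialize a network fit as JSON
#'
#' @param fit a [fit_network()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "network_fit"))
  doc <- list(
    state_labels = fit$network$state_labels,
    p_eq = unname(fit$p_eq),
    means = fit$emission$means,
    sigmas = fit$emission$sigmas,
    exchange_per_s = unclass(fit$exchange),
    rates_per_s = unclass(fit$network$rates),
    t_ij_s = unclass(fit$t_ij),
    chi_square = fit$chi_square,
    seed = fit$seed,
    weights = as.list(fit$weights),
    converged = fit$converged
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", na = "null")
  invisible(path)
}
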