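#' Empirical probability distribution of visibility
#'
#' Pooled, normalized histogram estimate of `P(v)` over one or more binned
#' trajectories: each observation contributes a point mass assigned to its
#' visibility bin, and the resulting density integrates to one over the grid.
#' Samples outside the grid are counted and excluded.
#'
#' @param trajs a [visibility_trajectory()] or a list of them (common bin
#'   width required).
#' @param bin_edges visibility bin edges; default 60 equal bins over
#'   `[-0.05, 0.55]`, covering the experimentally observed 0-0.4 range with
#'   margins.
#' @return object of class `empirical_pdf`: `bin_edges`, `mids`, `density`,
#'   `counts`, `n_samples` (inside the grid), `n_excluded`.
#' @export
empirical_pdf <- function(trajs, bin_edges = seq(-0.05, 0.55, length.out = 61)) {
  trajs <- as_traj_list(trajs)
  bw <- vapply(trajs, function(t) t$bin_width, numeric(1))
  if (diff(range(bw)) > 1e-12 * bw[1]) {
    stop("all trajectories must share a common bin width")
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("'bin_edges' must be strictly increasing")
  }
  v <- unlist(lapply(trajs, `[[`, "values"), use.names = FALSE)
  inside <- v >= bin_edges[1] & v <= bin_edges[length(bin_edges)]
  counts <- as.vector(table(cut(v[inside], bin_edges, include.lowest = TRUE)))
  widths <- diff(bin_edges)
  n_in <- sum(counts)
  if (n_in == 0L) stop("no samples fall inside the visibility grid")
  structure(
    list(bin_edges = bin_edges,
         mids = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
         density = counts / (n_in * widths),
         counts = counts,
         n_samples = n_in,
         n_excluded = sum(!inside)),
    class = "empirical_pdf"
  )
}

#' @export
print.empirical_pdf <- function(x, ...) {
  cat(sprintf("empirical_pdf: %d bins on [%g, %g], %d samples (%d excluded)\n",
              length(x$density), min(x$bin_edges), max(x$bin_edges),
              x$n_samples, x$n_excluded))
  invisible(x)
}

as_traj_list <- function(trajs) {
  if (inherits(trajs, "visibility_trajectory")) return(list(trajs))
  if (is.list(trajs) && length(trajs) > 0 &&
      all(vapply(trajs, inherits, logical(1), "visibility_trajectory"))) {
    return(trajs)
  }
  stop("expected a visibility_trajectory or a list of them")
}

new_tcf2 <- function(lags, values, n_pairs, normalized, bin_width, se = NULL) {
  structure(list(lags = lags, values = values, n_pairs = n_pairs,
                 normalized = normalized, bin_width = bin_width, se = se),
            class = "tcf2")
}

new_tcf3 <- function(lags1, lags2, values, n_triples, bin_width, se = NULL) {
  structure(list(lags1 = lags1, lags2 = lags2, values = values,
                 n_triples = n_triples, bin_width = bin_width, se = se),
            class = "tcf3")
}

#' Two-point time-correlation function of the visibility
#'
#' For a single trajectory with mean-subtracted fluctuations
#' `dv_i = v_i - <v>` (the per-trajectory mean), evaluates
#' \deqn{C^{(2)}(n \Delta t) = \frac{1}{N-n} \sum_{i=1}^{N-n} \delta v_{i+n}\,
#' \delta v_i.}
#' At zero lag this is the biased sample variance of the fluctuations. Given a
#' list of trajectories the per-trajectory functions are computed and then
#' averaged together (see [ensemble_average()]).
#'
#' @param traj a [visibility_trajectory()] or list of them.
#' @param lags lag times in seconds (integer multiples of the bin width);
#'   default a log-spaced grid from one bin to a quarter of the scan.
#' @param normalized if `TRUE`, divide by the zero-lag value `C2(0)`.
#' @return object of class `tcf2` with `lags`, `values`, `n_pairs`,
#'   `normalized`, `bin_width`.
#' @export
two_point_tcf <- function(traj, lags = NULL, normalized = FALSE) {
  trajs <- as_traj_list(traj)
  bw <- trajs[[1]]$bin_width
  if (is.null(lags)) {
    nmin <- min(vapply(trajs, function(t) length(t$values), integer(1)))
    lags <- c(0, log_lag_grid(bw, bw * floor(nmin / 4)))
  }
  out <- lapply(trajs, function(t) tcf2_single(t, lags, normalized))
  if (length(out) == 1L) out[[1L]] else ensemble_average(out)
}

tcf2_single <- function(traj, lags, normalized) {
  v <- traj$values
  N <- length(v)
  nb <- lags_to_bins(lags, traj$bin_width)
  if (any(nb >= N)) stop("lag exceeds trajectory length")
  dv <- v - mean(v)
  vals <- vapply(nb, function(n) {
    if (n == 0L) mean(dv * dv)
    else sum(dv[seq_len(N - n)] * dv[(n + 1L):N]) / (N - n)
  }, numeric(1))
  if (normalized) {
    c0 <- mean(dv * dv)
    if (c0 <= 0) stop("cannot normalize: zero variance")
    vals <- vals / c0
  }
  new_tcf2(nb * traj$bin_width, vals, N - nb, normalized, traj$bin_width)
}

#' @export
print.tcf2 <- function(x, ...) {
  cat(sprintf("tcf2: %d lags in [%g, %g] s, %s\n", length(x$lags),
              min(x$lags), max(x$lags),
              if (x$normalized) "normalized" else "unnormalized"))
  invisible(x)
}

#' Three-point time-correlation function of the visibility
#'
#' Evaluates, for lag pairs `tau1 = n dt`, `tau2 = m dt`,
#' \deqn{C^{(3)}(n\Delta t, m\Delta t) = \frac{1}{N-n-m} \sum_{i=1}^{N-n-m}
#' \delta v_{i+n+m}\, \delta v_{i+n}\, \delta v_i}
#' on the product grid `lags1 x lags2`. Sensitive to the roles of transient
#' intermediates in the transition pathways connecting the macrostates.
#'
#' @param traj a [visibility_trajectory()] or list of them.
#' @param lags1,lags2 lag grids in seconds (integer multiples of the bin
#'   width); default a square log-spaced 24-point grid.
#' @return object of class `tcf3` with `lags1`, `lags2`, `values` (matrix with
#'   rows indexed by `lags1`), `n_triples`.
#' @export
three_point_tcf <- function(traj, lags1 = NULL, lags2 = NULL) {
  trajs <- as_traj_list(traj)
  bw <- trajs[[1]]$bin_width
  if (is.null(lags1)) {
    nmin <- min(vapply(trajs, function(t) length(t$values), integer(1)))
    lags1 <- log_lag_grid(bw, bw * floor(nmin / 8), n_points = 24L)
  }
  if (is.null(lags2)) lags2 <- lags1
  out <- lapply(trajs, function(t) tcf3_single(t, lags1, lags2))
  if (length(out) == 1L) out[[1L]] else ensemble_average(out)
}

tcf3_single <- function(traj, lags1, lags2) {
  v <- traj$values
  N <- length(v)
  n1 <- lags_to_bins(lags1, traj$bin_width, "lag1")
  n2 <- lags_to_bins(lags2, traj$bin_width, "lag2")
  if (max(n1) + max(n2) >= N) stop("lag pair exceeds trajectory length")
  dv <- v - mean(v)
  vals <- matrix(0, length(n1), length(n2))
  cnt <- matrix(0L, length(n1), length(n2))
  for (a in seq_along(n1)) {
    n <- n1[a]
    for (b in seq_along(n2)) {
      m <- n2[b]
      L <- N - n - m
      idx <- seq_len(L)
      vals[a, b] <- sum(dv[idx + n + m] * dv[idx + n] * dv[idx]) / L
      cnt[a, b] <- L
    }
  }
  new_tcf3(n1 * traj$bin_width, n2 * traj$bin_width, vals, cnt, traj$bin_width)
}

#' @export
print.tcf3 <- function(x, ...) {
  cat(sprintf("tcf3: %d x %d lag grid, max |C3| = %.3g\n",
              length(x$lags1), length(x$lags2), max(abs(x$values))))
  invisible(x)
}

#' Average statistics across trajectories of an ensemble
#'
#' Unweighted mean of per-trajectory statistics sharing identical grids; pair
#' and triple counts are summed, and the between-trajectory standard error of
#' the mean is attached for error bars.
#'
#' @param stat_list list of `tcf2`, `tcf3` or `empirical_pdf` objects with
#'   identical grids.
#' @return one object of the same class.
#' @export
ensemble_average <- function(stat_list) {
  stopifnot(is.list(stat_list), length(stat_list) >= 1L)
  x <- stat_list[[1L]]
  M <- length(stat_list)
  if (inherits(x, "tcf2")) {
    for (s in stat_list) {
      if (!isTRUE(all.equal(s$lags, x$lags)) || s$normalized != x$normalized) {
        stop("tcf2 grids/normalization differ across the ensemble")
      }
    }
    vals <- sapply(stat_list, `[[`, "values")  # lags x M
    vals <- matrix(vals, ncol = M)
    se <- if (M > 1) apply(vals, 1, stats::sd) / sqrt(M) else NULL
    return(new_tcf2(x$lags, rowMeans(vals),
                    Reduce(`+`, lapply(stat_list, `[[`, "n_pairs")),
                    x$normalized, x$bin_width, se))
  }
  if (inherits(x, "tcf3")) {
    for (s in stat_list) {
      if (!isTRUE(all.equal(s$lags1, x$lags1)) ||
          !isTRUE(all.equal(s$lags2, x$lags2))) {
        stop("tcf3 grids differ across the ensemble")
      }
    }
    arr <- vapply(stat_list, `[[`, x$values, "values")
    arr <- array(arr, dim = c(dim(x$values), M))
    mean_vals <- apply(arr, c(1, 2), mean)
    se <- if (M > 1) apply(arr, c(1, 2), stats::sd) / sqrt(M) else NULL
    return(new_tcf3(x$lags1, x$lags2, mean_vals,
                    Reduce(`+`, lapply(stat_list, `[[`, "n_triples")),
                    x$bin_width, se))
  }
  if (inherits(x, "empirical_pdf")) {
    for (s in stat_list) {
      if (!isTRUE(all.equal(s$bin_edges, x$bin_edges))) {
        stop("pdf grids differ across the ensemble")
      }
    }
    dens <- rowMeans(sapply(stat_list, `[[`, "density"))
    out <- x
    out$density <- dens
    out$counts <- Reduce(`+`, lapply(stat_list, `[[`, "counts"))
    out$n_samples <- sum(vapply(stat_list, `[[`, integer(1), "n_samples"))
    out$n_excluded <- sum(vapply(stat_list, `[[`, integer(1), "n_excluded"))
    return(out)
  }
  stop("unsupported statistic class: ", paste(class(x), collapse = "/"))
}

#' Fit a sum of exponential decays to a two-point TCF
#'
#' Least-squares fit of `sum_i alpha_i exp(-tau / t_i)` (optionally plus a
#' constant offset) by separable least squares: the decay constants are
#' optimized by Levenberg-Marquardt over multiple log-spaced starting points
#' while the amplitudes are profiled out linearly at each step. The best start
#' by residual norm is returned.
#'
#' @param tcf a `tcf2` object (zero-lag point is used if present).
#' @param n_components number of exponential components, `>= 1`.
#' @param offset include a constant offset term (default `FALSE`: correlation
#'   functions of ergodic mean-subtracted signals decay to zero).
#' @param n_starts number of multi-start seeds (default 32).
#' @param seed RNG seed for the start stream.
#' @return object of class `multiexp_fit`: `amplitudes`, `time_constants`
#'   (seconds, ascending), `offset`, `residual_norm`, `fitted`, `lags`,
#'   `n_starts_converged`.
#' @export
fit_multiexponential <- function(tcf, n_components, offset = FALSE,
                                 n_starts = 32L, seed = 1L) {
  stopifnot(inherits(tcf, "tcf2"), n_components >= 1L)
  tau <- tcf$lags
  y <- tcf$values
  pos <- tau[tau > 0]
  if (length(pos) < n_components + 1L) stop("too few lags for the fit")
  span <- max(pos) / min(pos)
  if (max(pos) < 10 * min(pos)) {
    warning("lag span < 10x; time constants may be poorly determined")
  }
  design <- function(logt) {
    B <- exp(-outer(tau, exp(-logt)))  # exp(-tau/t)
    if (offset) cbind(B, 1) else B
  }
  resid_fn <- function(logt) {
    B <- design(logt)
    fit <- stats::lm.fit(B, y)
    fit$residuals
  }
  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      sort(stats::runif(n_components, log(min(pos) / 3), log(max(pos) * 3)))
    })
  })
  best <- NULL
  n_conv <- 0L
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_conv <- n_conv + 1L
    rn <- sqrt(sum(res$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(par = res$par, rn = rn)
  }
  if (is.null(best)) stop("multi-exponential fit failed to converge in any start")
  B <- design(best$par)
  cf <- stats::lm.fit(B, y)$coefficients
  t_i <- exp(best$par)
  amp <- cf[seq_len(n_components)]
  off <- if (offset) unname(cf[n_components + 1L]) else 0
  ord <- order(t_i)
  structure(
    list(amplitudes = unname(amp[ord]), time_constants = unname(t_i[ord]),
         offset = off, residual_norm = best$rn,
         fitted = as.vector(B %*% cf), lags = tau,
         n_starts_converged = n_conv),
    class = "multiexp_fit"
  )
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat("multiexp_fit:\n")
  cat("  t (ms):    ", signif(1000 * x$time_constants, 4), "\n")
  cat("  amplitudes:", signif(x$amplitudes, 4), "\n")
  if (x$offset != 0) cat("  offset:    ", signif(x$offset, 4), "\n")
  cat("  residual norm:", signif(x$residual_norm, 4), "\n")
  invisible(x)
}

#' Mean relaxation time of a multi-exponential decay
#'
#' `tau_bar = sum(alpha_hat_i * t_i)` with amplitudes normalized to unit sum,
#' so the result is invariant to overall amplitude scaling.
#'
#' @param fit a [fit_multiexponential()] result.
#' @return mean relaxation time in seconds.
#' @export
mean_relaxation_time <- function(fit) {
  stopifnot(inherits(fit, "multiexp_fit"))
  s <- sum(fit$amplitudes)
  if (s <= 0) stop("amplitudes sum to <= 0; mean relaxation time undefined")
  sum(fit$amplitudes / s * fit$time_constants)
}

#' Infer the number of macrostates from a TCF decay fit
#'
#' The minimum number of macrostates consistent with a multi-exponential
#' two-point TCF is the number of resolvable decay components plus one. A
#' component is resolvable when its time constant is separated from its
#' neighbours by at least `sep_factor` and its amplitude is at least
#' `min_amp_frac` of the total fitted zero-lag amplitude.
#'
#' @param fit a [fit_multiexponential()] result.
#' @param sep_factor minimal ratio between consecutive resolvable time
#'   constants (default 3).
#' @param min_amp_frac minimal |amplitude| as a fraction of the fitted
#'   zero-lag value (default 0.02).
#' @return integer macrostate count, with attribute `details` listing the
#'   resolvable flags per component.
#' @export
infer_state_count <- function(fit, sep_factor = 3, min_amp_frac = 0.02) {
  stopifnot(inherits(fit, "multiexp_fit"))
  c0 <- sum(fit$amplitudes) + fit$offset
  keep <- abs(fit$amplitudes) >= min_amp_frac * abs(c0)
  t_keep <- fit$time_constants[keep]
  if (length(t_keep) == 0L) {
    out <- 1L
    attr(out, "details") <- list(resolvable = keep, merged_groups = 0L)
    return(out)
  }
  t_keep <- sort(t_keep)
  groups <- 1L
  for (i in seq_along(t_keep)[-1]) {
    if (t_keep[i] / t_keep[i - 1] >= sep_factor) groups <- groups + 1L
  }
  out <- groups + 1L
  attr(out, "details") <- list(resolvable = keep,
                               n_components_kept = length(t_keep),
                               n_resolvable = groups)
  out
}
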