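# Internal helpers shared across modules.

# Derive a reproducible 32-bit child seed from a master seed and an index.
child_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 16807) %% 2147483647)
}

# Connected components of a symmetric boolean adjacency matrix (simple BFS).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  current <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    current <- current + 1L
    queue <- s
    comp[s] <- current
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- current
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Log-spaced lag grid aligned to the bin width
#'
#' Builds a lag grid in seconds covering `[bin_width, max_lag]` with
#' approximately log-uniform spacing, snapped to unique integer multiples of
#' the bin width (the only lags a binned trajectory can realize).
#'
#' @param bin_width bin width in seconds.
#' @param max_lag largest lag in seconds.
#' @param n_points target number of grid points before deduplication
#'   (default 60).
#' @return numeric vector of lag times in seconds.
#' @export
log_lag_grid <- function(bin_width, max_lag, n_points = 60L) {
  stopifnot(max_lag >= bin_width)
  raw <- exp(seq(log(bin_width), log(max_lag), length.out = n_points))
  n <- sort(unique(pmax(1L, as.integer(round(raw / bin_width)))))
  n * bin_width
}

# Convert lag times (seconds) to integer bin offsets, insisting on (near)
# integer multiples of the bin width.
lags_to_bins <- function(lags, bin_width, what = "lag") {
  n <- lags / bin_width
  ni <- round(n)
  if (any(abs(n - ni) > 1e-6)) {
    stop(sprintf("every %s must be an integer multiple of the bin width (%g s)",
                 what, bin_width), call. = FALSE)
  }
  as.integer(ni)
}

# Simplex <-> unconstrained coordinates (log-ratio vs the last state).
simplex_to_free <- function(p) log(p[-length(p)] / p[length(p)])
free_to_simplex <- function(z) {
  e <- exp(c(z, 0))
  e / sum(e)
}

# Upper-triangle edge list of a symmetric mask.
mask_edges <- function(mask) {
  which(upper.tri(mask) & mask, arr.ind = TRUE)
}

default_state_labels <- function(n) paste0("S", seq_len(n))

`%||%` <- function(a, b) if (is.null(a)) b else a
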