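#' Boltzmann free-energy difference between two macrostates
#'
#' `G_ij = -ln(p_i / p_j)` in units of `k_B T`: the free energy of state `i`
#' relative to state `j` given their equilibrium populations. Antisymmetric
#' under swapping the arguments.
#'
#' @param p_i,p_j equilibrium populations (> 0).
#' @return free-energy difference in `k_B T`.
#' @examples
#' boltzmann_free_energy(0.14, 0.82)  # ~1.77 kBT
#' @export
boltzmann_free_energy <- function(p_i, p_j) {
  if (any(p_i <= 0) || any(p_j <= 0)) {
    stop("populations must be strictly positive")
  }
  -log(p_i / p_j)
}

#' Arrhenius activation barrier from a time constant
#'
#' `G_barrier = -ln(t_min / t_ij) = ln(t_ij / t_min)` in `k_B T`, referenced
#' to the fastest process of the dataset (`t_min`), which by construction has
#' zero barrier.
#'
#' @param t_ij transition time constant in seconds (`1 / k_ij`).
#' @param t_min reference (smallest) time constant of the dataset, > 0.
#' @return barrier height in `k_B T`, >= 0.
#' @export
arrhenius_barrier <- function(t_ij, t_min) {
  if (any(t_min <= 0)) stop("'t_min' must be > 0")
  if (any(t_ij < t_min * (1 - 1e-12))) {
    stop("'t_ij' must be >= 't_min' (the reference is the fastest process)")
  }
  pmax(log(t_ij / t_min), 0)
}

#' Vertically offset activation barrier
#'
#' `G_offset_ij = G_barrier_ij + G_i`: the barrier measured from the global
#' ground state rather than from the departing state's minimum, so forward and
#' backward barriers of a reversible pair refer to the same saddle.
#'
#' @param g_barrier barrier height(s) in `k_B T`.
#' @param g_i free-energy minimum of the departing state in `k_B T`.
#' @return offset barrier in `k_B T`.
#' @export
offset_barrier <- function(g_barrier, g_i) {
  stopifnot(all(is.finite(g_barrier)), all(is.finite(g_i)))
  g_barrier + g_i
}

#' Convert an energy from k_B T to kcal/mol
#'
#' Multiplies by `k_B T` expressed in kcal/mol (`R * T / 4184`); at 298 K the
#' factor is about 0.5922, so 1.8 `k_B T` is about 1.07 kcal/mol.
#'
#' @param g_kbt energy in `k_B T`.
#' @param temperature_K absolute temperature in kelvin (default 298).
#' @return energy in kcal/mol.
#' @export
to_kcal_per_mol <- function(g_kbt, temperature_K = 298) {
  if (temperature_K <= 0) stop("'temperature_K' must be > 0")
  g_kbt * 8.31446261815324 * temperature_K / 4184
}

#' Free-energy-surface parameters from a fitted kinetic network
#'
#' Converts equilibrium populations and interconversion time constants into
#' the parameters of a one-dimensional free-energy surface over a signed
#' visibility coordinate:
#' minima `G_i = -ln(p_i / max(p))` (ground state zero, Boltzmann relation),
#' per-edge barriers `G_barrier_ij = ln(t_ij / t_min)` (Arrhenius relation
#' referenced to the dataset's fastest time constant) and vertical offsets
#' `G_offset_ij = G_barrier_ij + G_i`. The measurement does not distinguish
#' the sign of the visibility, so states assigned a left-handed conformation
#' get a negative coordinate via `negative_states`.
#'
#' The rendered surface is a visualization convention: Gaussian wells of width
#' `well_width` joined at saddle points placed midway between connected
#' minima, at the offset-barrier height. Missing edges draw no barrier.
#'
#' @param fit a [fit_network()] result, or `NULL` if `p_eq` and `t_ij` are
#'   given explicitly.
#' @param p_eq equilibrium populations (used when `fit` is `NULL`).
#' @param t_ij matrix of transition time constants in seconds (`1 / k_ij`;
#'   `NA`/`Inf` off open edges), used when `fit` is `NULL`.
#' @param means per-state mean visibilities (when `fit` is `NULL`).
#' @param state_labels optional state names (when `fit` is `NULL`).
#' @param negative_states indices or labels of states assigned negative
#'   visibility coordinates (default none).
#' @param well_width Gaussian well width in visibility units (default 0.02).
#' @param temperature_K temperature for kcal/mol conversion (default 298).
#' @param n_grid points in the rendered surface polyline.
#' @return object of class `fes_parameters`: `G` (minima, `k_B T`),
#'   `barriers` and `offsets` (matrices on open edges), `t_min` (s), `x`
#'   (signed coordinates), `surface` (data.frame `x`, `G`), `temperature_K`,
#'   `db_consistency` (max deviation of `G_j - G_i` from the offset
#'   difference over open edges; a warning, not an error, for fitted rates).
#' @export
build_surface <- function(fit = NULL, p_eq = NULL, t_ij = NULL, means = NULL,
                          state_labels = NULL, negative_states = integer(0),
                          well_width = 0.02, temperature_K = 298,
                          n_grid = 400L) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "network_fit"))
    p_eq <- fit$p_eq
    t_ij <- fit$t_ij
    means <- fit$emission$means
    state_labels <- fit$network$state_labels
  }
  n <- length(p_eq)
  state_labels <- state_labels %||% default_state_labels(n)
  if (is.character(negative_states)) {
    negative_states <- match(negative_states, state_labels)
  }
  signs <- rep(1, n)
  signs[negative_states] <- -1
  x <- signs * means

  G <- boltzmann_free_energy(p_eq, max(p_eq))
  open <- is.finite(t_ij) & t_ij > 0
  diag(open) <- FALSE
  t_min <- if (any(open)) min(t_ij[open]) else NA_real_
  barriers <- offsets <- matrix(NA_real_, n, n,
                                dimnames = list(state_labels, state_labels))
  if (any(open)) {
    barriers[open] <- arrhenius_barrier(t_ij[open], t_min)
    offsets[open] <- barriers[open] + G[row(offsets)[open]]
  }

  # detailed-balance bookkeeping: forward/backward offsets should share a
  # saddle, i.e. offsets[i,j] == offsets[j,i]; report the worst deviation
  db_dev <- 0
  both <- open & t(open)
  if (any(both)) {
    db_dev <- max(abs(offsets[both] - t(offsets)[both]))
    if (db_dev > 1e-6) {
      warning("forward/backward offset barriers disagree by up to ",
              signif(db_dev, 3), " kBT (fitted rates need not share saddles ",
              "exactly)")
    }
  }

  surface <- render_surface(x, G, offsets, open, well_width, n_grid)
  structure(
    list(G = stats::setNames(G, state_labels), barriers = barriers,
         offsets = offsets, t_min = t_min,
         x = stats::setNames(x, state_labels), surface = surface,
         temperature_K = temperature_K, db_consistency = db_dev,
         p_eq = stats::setNames(p_eq, state_labels)),
    class = "fes_parameters"
  )
}

# Cartoon surface: Gaussian wells joined at saddles midway between connected
# minima; unconnected gaps carry no barrier segment.
render_surface <- function(x, G, offsets, open, w, n_grid) {
  ord <- order(x)
  xs <- x[ord]; Gs <- G[ord]
  segs <- list()
  for (s in seq_along(ord)[-1]) {
    i <- ord[s - 1]; j <- ord[s]
    if (!open[i, j] && !open[j, i]) next
    gsad <- max(offsets[i, j], offsets[j, i], na.rm = TRUE)
    xm <- (x[i] + x[j]) / 2
    gl <- seq(x[i], xm, length.out = max(8L, n_grid %/% (2 * length(ord))))
    gr <- seq(xm, x[j], length.out = length(gl))
    segs[[length(segs) + 1L]] <- data.frame(
      x = c(gl, gr[-1]),
      G = c(gsad - (gsad - G[i]) * exp(-(gl - x[i])^2 / (2 * w^2)),
            (gsad - (gsad - G[j]) * exp(-(gr - x[j])^2 / (2 * w^2)))[-1])
    )
  }
  if (length(segs) == 0L) {
    return(data.frame(x = xs, G = Gs))
  }
  do.call(rbind, segs)
}

#' @export
print.fes_parameters <- function(x, ...) {
  cat("fes_parameters (kBT, ground state = 0):\n")
  df <- data.frame(state = names(x$G), x = x$x, G = x$G, p_eq = x$p_eq)
  print(df, row.names = FALSE, digits = 3)
  if (is.finite(x$t_min)) {
    cat(sprintf("t_min = %.4g s; offset barriers (kBT):\n", x$t_min))
    print(signif(x$offsets, 3))
  }
  invisible(x)
}

#' @export
plot.fes_parameters <- function(x, ...) {
  graphics::plot(x$surface$x, x$surface$G, type = "l",
                 xlab = "signed visibility", ylab = "G (kBT)", ...)
  graphics::points(x$x, x$G, pch = 19)
  graphics::text(x$x, x$G, names(x$G), pos = 1)
  invisible(x)
}

#' Write FES parameters as JSON (and the surface polyline as CSV)
#'
#' @param fes a [build_surface()] result.
#' @param path JSON output path.
#' @param surface_path optional CSV path for the `(x, G)` polyline.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path, surface_path = NULL) {
  stopifnot(inherits(fes, "fes_parameters"))
  doc <- list(state_labels = names(fes$G), G_kBT = unname(fes$G),
              x = unname(fes$x), p_eq = unname(fes$p_eq),
              t_min_s = fes$t_min,
              barriers_kBT = unclass(fes$barriers),
              offset_barriers_kBT = unclass(fes$offsets),
              temperature_K = fes$temperature_K)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", na = "null")
  if (!is.null(surface_path)) {
    utils::write.csv(fes$surface, surface_path, row.names = FALSE)
  }
  invisible(path)
}
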