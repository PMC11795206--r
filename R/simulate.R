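#' Exact stochastic simulation of the kinetic network (Gillespie)
#'
#' Simulates a continuous-time state path: exponential dwell in state `i` with
#' rate `sum_j k[i, j]`, then a jump to `j` with probability
#' `k[i, j] / sum_j k[i, j]`. The initial state is drawn from the stationary
#' distribution unless given, so the path is an equilibrium realization of the
#' master equation.
#'
#' @param net a [kinetic_network()].
#' @param duration total simulated time in seconds.
#' @param seed optional RNG seed (scoped; the global RNG stream is restored).
#' @param init_state optional initial state index.
#' @return data.frame with columns `state`, `dwell` (seconds; the last dwell
#'   is truncated so dwells sum to `duration`), attribute `duration`.
#' @export
simulate_state_path <- function(net, duration, seed = NULL, init_state = NULL) {
  stopifnot(inherits(net, "kinetic_network"), duration > 0)
  run <- function() {
    exit <- rowSums(net$rates)
    jump_p <- net$rates / ifelse(exit > 0, exit, 1)
    s <- init_state %||% sample.int(net$n_states, 1,
                                    prob = stationary_distribution(net))
    cap <- 1024L
    states <- integer(cap); dwells <- numeric(cap)
    k <- 0L; t_now <- 0
    while (t_now < duration) {
      if (k == cap) {
        cap <- cap * 2L
        length(states) <- cap
        length(dwells) <- cap
      }
      dt <- stats::rexp(1, exit[s])
      k <- k + 1L
      states[k] <- s
      if (t_now + dt >= duration) {
        dwells[k] <- duration - t_now
        t_now <- duration
      } else {
        dwells[k] <- dt
        t_now <- t_now + dt
        s <- sample.int(net$n_states, 1, prob = jump_p[s, ])
      }
    }
    out <- data.frame(state = states[seq_len(k)], dwell = dwells[seq_len(k)])
    attr(out, "duration") <- duration
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Render a state path as a binned visibility trajectory
#'
#' Converts a continuous-time state path into the trajectory a binned
#' measurement would record: each bin's value is the occupancy-time-weighted
#' mean of the macrostate mean visibilities over the bin (dwells shorter than
#' the bin are time-weighted exactly, reproducing the motional-narrowing bias
#' of a real binned signal), plus zero-mean Gaussian noise whose standard
#' deviation is the occupancy-weighted state sigma. In `"gaussian+shot"` mode
#' the noise is additionally scaled by `sqrt(ref_counts / counts_per_bin)`
#' with Poisson-drawn per-bin counts, emulating shot-noise variation about the
#' reference count rate. Values are clipped to `[-1, 1]`; clip events are
#' counted in the metadata.
#'
#' @param path a [simulate_state_path()] result.
#' @param emission an [emission_model()].
#' @param bin_width bin width `T_w` in seconds.
#' @param noise_mode `"gaussian"` (default) or `"gaussian+shot"`.
#' @param seed optional RNG seed (scoped).
#' @param count_rate mean photon count rate in counts/s (shot mode reference;
#'   default 8000).
#' @param meta metadata list passed to the trajectory.
#' @return a [visibility_trajectory()].
#' @export
emit_visibility <- function(path, emission, bin_width,
                            noise_mode = c("gaussian", "gaussian+shot"),
                            seed = NULL, count_rate = 8000, meta = list()) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(emission, "emission_model"))
  duration <- attr(path, "duration") %||% sum(path$dwell)
  if (nrow(path) == 0L || duration < bin_width) {
    stop("path shorter than one bin")
  }
  n_bins <- floor(duration / bin_width + 1e-9)
  edges <- (0:n_bins) * bin_width
  vbar_bin <- bin_average(path, emission$means, edges)
  sig_bin <- bin_average(path, emission$sigmas, edges)
  run <- function() {
    sd_bin <- sig_bin
    if (noise_mode == "gaussian+shot") {
      counts <- stats::rpois(n_bins, count_rate * bin_width)
      sd_bin <- sd_bin * sqrt((count_rate * bin_width) / pmax(counts, 1))
    }
    vbar_bin + stats::rnorm(n_bins, 0, sd_bin)
  }
  v <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  n_clip <- sum(v > 1 | v < -1)
  v <- pmin(pmax(v, -1), 1)
  meta$n_clipped <- n_clip
  meta$noise_mode <- noise_mode
  visibility_trajectory(v, bin_width, meta)
}

# Occupancy-time-weighted mean of per-state values f over bins with the given
# edges, via the cumulative integral of the piecewise-constant signal.
bin_average <- function(path, f, edges) {
  fs <- f[path$state]
  tgrid <- c(0, cumsum(path$dwell))
  cumI <- c(0, cumsum(path$dwell * fs))
  seg <- pmin(pmax(findInterval(edges, tgrid, rightmost.closed = TRUE), 1L),
              nrow(path))
  I_edges <- cumI[seg] + (edges - tgrid[seg]) * fs[seg]
  diff(I_edges) / diff(edges)
}

#' Simulation configuration for a synthetic PS-SMF ensemble
#'
#' Bundles a ground-truth network + emission model with the acquisition
#' parameters the simulator emulates: scan duration ~30 s, ~100 trajectories
#' per condition, bin width 250 microseconds, mean count rate ~8000 counts/s.
#'
#' @param network ground-truth [kinetic_network()].
#' @param emission ground-truth [emission_model()] (weights must match the
#'   network's stationary distribution).
#' @param duration scan duration `T` in seconds (default 30).
#' @param bin_width bin width `T_w` in seconds (default 250e-6).
#' @param n_trajectories trajectories per ensemble (default 100).
#' @param count_rate mean count rate, counts/s (default 8000).
#' @param noise_mode `"gaussian"` or `"gaussian+shot"`.
#' @param seed master seed; per-trajectory child seeds are derived from it.
#' @param construct,condition labels recorded in trajectory metadata.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(network, emission, duration = 30,
                              bin_width = 250e-6, n_trajectories = 100L,
                              count_rate = 8000,
                              noise_mode = c("gaussian", "gaussian+shot"),
                              seed = 1L, construct = "synthetic",
                              condition = "default") {
  noise_mode <- match.arg(noise_mode)
  check_pairing(network, emission)
  if (duration / bin_width < 100) {
    stop("need at least 100 bins per scan (duration / bin_width >= 100)")
  }
  structure(
    list(network = network, emission = emission, duration = duration,
         bin_width = bin_width, n_trajectories = as.integer(n_trajectories),
         count_rate = count_rate, noise_mode = noise_mode,
         seed = as.integer(seed), construct = construct,
         condition = condition),
    class = "simulation_config"
  )
}

#' Generate a synthetic trajectory ensemble
#'
#' Simulates `n_trajectories` independent state paths from the ground-truth
#' network, renders each as a binned visibility trajectory, and (optionally)
#' writes the ensemble to disk in the package's trajectory/manifest formats
#' together with the ground truth as JSON. Per-trajectory seeds are derived
#' deterministically from the master seed, so the same configuration
#' regenerates a byte-identical ensemble.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; created if missing. When `NULL` the
#'   ensemble is returned in memory only.
#' @return object of class `ensemble`: `trajectories` (list), `config`,
#'   `manifest` (path or `NULL`).
#' @export
generate_ensemble <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  trajs <- vector("list", config$n_trajectories)
  for (i in seq_len(config$n_trajectories)) {
    s_path <- child_seed(config$seed, 2L * i)
    s_emit <- child_seed(config$seed, 2L * i + 1L)
    path <- simulate_state_path(config$network, config$duration, seed = s_path)
    trajs[[i]] <- emit_visibility(
      path, config$emission, config$bin_width,
      noise_mode = config$noise_mode, seed = s_emit,
      count_rate = config$count_rate,
      meta = list(construct = config$construct, condition = config$condition,
                  source = sprintf("traj%03d", i), master_seed = config$seed,
                  child_seed = s_path)
    )
  }
  manifest <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- sprintf("traj%03d.tsv", seq_along(trajs))
    for (i in seq_along(trajs)) {
      write_trajectory(trajs[[i]], file.path(dir, files[i]))
    }
    manifest <- file.path(dir, "manifest.txt")
    write_manifest(files, manifest,
                   meta = list(construct = config$construct,
                               condition = config$condition,
                               bin_width_s = config$bin_width,
                               scan_duration_s = config$duration,
                               master_seed = config$seed))
    write_network(config$network, file.path(dir, "ground_truth.json"),
                  emission = config$emission)
  }
  structure(list(trajectories = trajs, config = config, manifest = manifest),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d trajectories x %g s at T_w = %g s (seed %d)\n",
              length(x$trajectories), x$config$duration, x$config$bin_width,
              x$config$seed))
  invisible(x)
}

#' Reference 4-state ground-truth network and emission model
#'
#' The package's canonical synthetic benchmark: a detailed-balance 4-state
#' chain (S1-S2-S3-S4) with equilibrium populations (0.02, 0.82, 0.14, 0.02)
#' and exchange coefficients calibrated so the relaxation times are 0.3, 3.7
#' and 173 ms, paired with Gaussian emissions at mean visibilities
#' (0.02, 0.11, 0.14, 0.30) and common width 0.02. These are the macrostate
#' parameters reported for a dimer probe placed one base pair inside the
#' duplex side of a DNA fork junction under physiological salt.
#'
#' @param p_eq equilibrium populations (default above).
#' @param means state mean visibilities (default above).
#' @param sigmas state widths (default 0.02 each).
#' @param exchange_coefs chain exchange coefficients `c(S1-S2, S2-S3, S3-S4)`
#'   in per-second units (default the calibrated values).
#' @return list with `network` and `emission`.
#' @export
ps_truth_network <- function(p_eq = c(0.02, 0.82, 0.14, 0.02),
                             means = c(0.02, 0.11, 0.14, 0.30),
                             sigmas = rep(0.02, 4),
                             exchange_coefs = c(5.276254, 0.777107, 58.321176)) {
  n <- length(p_eq)
  stopifnot(n >= 2, length(exchange_coefs) == n - 1)
  ex <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    ex[i, i + 1] <- ex[i + 1, i] <- exchange_coefs[i]
  }
  net <- build_detailed_balance_network(p_eq, ex)
  list(network = net,
       emission = emission_model(means, sigmas, weights = p_eq,
                                 state_labels = net$state_labels))
}
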