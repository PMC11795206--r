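#' Ensemble-averaged summary statistics from trajectories
#'
#' Runs the estimator stage of the pipeline: the pooled visibility PDF and the
#' ensemble-averaged two-point TCF at the native bin width, and the
#' three-point TCF after rebinning to a coarser integration period (default
#' 10 ms, the conventional three-point resolution).
#'
#' @param trajs list of [visibility_trajectory()] objects (or one), or a
#'   manifest file path.
#' @param pdf_edges visibility bin edges (default as [empirical_pdf()]).
#' @param c2_lags two-point lag grid in seconds; default log-spaced from one
#'   bin to a sixth of the scan.
#' @param c3_bin_width integration period for the three-point TCF (default
#'   10e-3 s; must be an integer multiple of the native bin width).
#' @param c3_lags lag grid for both three-point axes; default log-spaced
#'   24 points from `c3_bin_width` to ~1/30 of the scan.
#' @return a [summary_statistics()].
#' @export
pipeline_estimate <- function(trajs, pdf_edges = seq(-0.05, 0.55,
                                                     length.out = 61),
                              c2_lags = NULL, c3_bin_width = 10e-3,
                              c3_lags = NULL) {
  if (is.character(trajs)) trajs <- read_ensemble(trajs)
  trajs <- as_traj_list(trajs)
  bw <- trajs[[1]]$bin_width
  nmin <- min(vapply(trajs, function(t) length(t$values), integer(1)))
  scan <- nmin * bw
  if (is.null(c2_lags)) {
    c2_lags <- log_lag_grid(bw, scan / 6)
  }
  factor <- as.integer(round(c3_bin_width / bw))
  if (abs(factor * bw - c3_bin_width) > 1e-9 * c3_bin_width || factor < 1L) {
    stop("'c3_bin_width' must be an integer multiple of the native bin width")
  }
  coarse <- if (factor == 1L) trajs else lapply(trajs, rebin, factor = factor)
  if (is.null(c3_lags)) {
    c3_lags <- log_lag_grid(c3_bin_width, scan / 30, n_points = 24L)
  }
  summary_statistics(
    pdf = empirical_pdf(trajs, pdf_edges),
    c2 = two_point_tcf(trajs, c2_lags),
    c3 = three_point_tcf(coarse, c3_lags, c3_lags)
  )
}

#' Fit, pathway tables and free-energy surface in one step
#'
#' Runs the inference stage: fits the N-state network to the summary
#' statistics, decomposes the fitted model's correlation functions into ranked
#' pathway terms (two-point at `c2_term_lag`, three-point at `c3_term_lag` on
#' both axes), and builds the free-energy-surface parameters.
#'
#' @param data a [summary_statistics()].
#' @param n_states macrostate count.
#' @param edge_mask optional adjacency for [fit_network()].
#' @param negative_states states drawn at negative visibility coordinates
#'   (see [build_surface()]).
#' @param c2_term_lag,c3_term_lag lags for the pathway tables (defaults
#'   250e-6 s and 10e-3 s).
#' @param ... passed to [fit_network()] (`n_starts`, `seed`, `weights`, ...).
#' @return list with `fit` ([fit_network()]), `c2_terms`, `c3_terms` (ranked),
#'   `fes` ([build_surface()]).
#' @export
pipeline_fit_report <- function(data, n_states, edge_mask = NULL,
                                negative_states = integer(0),
                                c2_term_lag = 250e-6, c3_term_lag = 10e-3,
                                ...) {
  fit <- fit_network(data, n_states, edge_mask = edge_mask, ...)
  list(
    fit = fit,
    c2_terms = rank_terms(c2_terms(fit$network, fit$emission, c2_term_lag)),
    c3_terms = rank_terms(c3_terms(fit$network, fit$emission, c3_term_lag,
                                   c3_term_lag)),
    fes = build_surface(fit, negative_states = negative_states)
  )
}

# ---- statistics table I/O ---------------------------------------------------

#' Write / read summary statistics as delimited text
#'
#' Three tab-separated tables: the PDF (`v_lo`, `v_hi`, `density`, `count`),
#' the two-point TCF (`lag_s`, `c2`, `n_pairs`[, `se`]) and the three-point
#' TCF in long form (`lag1_s`, `lag2_s`, `c3`, `n_triples`). `#`-prefixed
#' header lines carry the bin widths.
#'
#' @param stats a [summary_statistics()].
#' @param dir output directory (created if missing).
#' @return `write_statistics`: the directory, invisibly;
#'   `read_statistics`: a [summary_statistics()].
#' @export
write_statistics <- function(stats, dir) {
  stopifnot(inherits(stats, "summary_statistics"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ne <- length(stats$pdf$bin_edges)
  pdf_df <- data.frame(v_lo = stats$pdf$bin_edges[-ne],
                       v_hi = stats$pdf$bin_edges[-1],
                       density = stats$pdf$density,
                       count = stats$pdf$counts)
  write_table_hdr(pdf_df, file.path(dir, "pdf.tsv"),
                  c(n_samples = stats$pdf$n_samples,
                    n_excluded = stats$pdf$n_excluded))
  c2_df <- data.frame(lag_s = stats$c2$lags, c2 = stats$c2$values,
                      n_pairs = stats$c2$n_pairs)
  if (!is.null(stats$c2$se)) c2_df$se <- stats$c2$se
  write_table_hdr(c2_df, file.path(dir, "c2.tsv"),
                  c(bin_width_s = stats$c2$bin_width,
                    normalized = as.integer(stats$c2$normalized)))
  grid <- expand.grid(a = seq_along(stats$c3$lags1),
                      b = seq_along(stats$c3$lags2))
  c3_df <- data.frame(lag1_s = stats$c3$lags1[grid$a],
                      lag2_s = stats$c3$lags2[grid$b],
                      c3 = stats$c3$values[cbind(grid$a, grid$b)],
                      n_triples = stats$c3$n_triples[cbind(grid$a, grid$b)])
  write_table_hdr(c3_df, file.path(dir, "c3.tsv"),
                  c(bin_width_s = stats$c3$bin_width))
  invisible(dir)
}

write_table_hdr <- function(df, path, hdr) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(hdr)) writeLines(sprintf("# %s=%.17g", k, hdr[[k]]), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_hdr <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (h in sub("^#\\s*", "", lines[hdr])) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- as.numeric(kv[2])
  }
  df <- utils::read.table(text = lines[!hdr], header = TRUE, sep = "\t")
  list(df = df, meta = meta)
}

#' @rdname write_statistics
#' @export
read_statistics <- function(dir) {
  p <- read_table_hdr(file.path(dir, "pdf.tsv"))
  pdf <- structure(
    list(bin_edges = c(p$df$v_lo, p$df$v_hi[nrow(p$df)]),
         mids = (p$df$v_lo + p$df$v_hi) / 2,
         density = p$df$density, counts = p$df$count,
         n_samples = as.integer(p$meta$n_samples),
         n_excluded = as.integer(p$meta$n_excluded %||% 0)),
    class = "empirical_pdf")
  c2r <- read_table_hdr(file.path(dir, "c2.tsv"))
  c2 <- new_tcf2(c2r$df$lag_s, c2r$df$c2, c2r$df$n_pairs,
                 isTRUE(c2r$meta$normalized == 1), c2r$meta$bin_width_s,
                 se = c2r$df$se)
  c3r <- read_table_hdr(file.path(dir, "c3.tsv"))
  l1 <- sort(unique(c3r$df$lag1_s))
  l2 <- sort(unique(c3r$df$lag2_s))
  vals <- matrix(NA_real_, length(l1), length(l2))
  cnt <- matrix(NA_integer_, length(l1), length(l2))
  ia <- match(c3r$df$lag1_s, l1)
  ib <- match(c3r$df$lag2_s, l2)
  vals[cbind(ia, ib)] <- c3r$df$c3
  cnt[cbind(ia, ib)] <- c3r$df$n_triples
  c3 <- new_tcf3(l1, l2, vals, cnt, c3r$meta$bin_width_s)
  summary_statistics(pdf, c2, c3)
}

# ---- command-line interface -------------------------------------------------

#' Command-line entry point
#'
#' Thin dispatcher over the pipeline: subcommands `simulate`, `estimate`,
#' `fit`, `pathways`, `fes` and `report`. Every run writes a resolved-config
#' JSON and a log file into the output directory. Installed alongside the
#' package as an `Rscript` shim (`system.file("cli", "psmfkin.R",
#' package = "psmfkin")`).
#'
#' Common flags: `--outdir` (required for writing commands), `--seed`,
#' `--n-states`, `--manifest`, `--statsdir`, `--trajectories`, `--duration`,
#' `--bin-width`, `--c3-bin-width`, `--n-starts`, `--negative-states`.
#'
#' @param args character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success); errors are signalled as R
#'   conditions for the shim to translate into a nonzero exit.
#' @export
psmfkin_cli <- function(args) {
  if (length(args) < 1L) {
    stop("usage: psmfkin <simulate|estimate|fit|pathways|fes|report> [options]")
  }
  cmd <- args[[1L]]
  opts <- parse_cli_opts(args[-1L])
  outdir <- opts$outdir %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_path <- file.path(outdir, paste0(cmd, ".log"))
  logf <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE)
  logf("psmfkin %s | R %s | %s", cmd, getRversion(),
       format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  jsonlite::write_json(opts, file.path(outdir, paste0(cmd, "_config.json")),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  seed <- as.integer(opts$seed %||% 1L)
  switch(cmd,
    simulate = {
      truth <- ps_truth_network()
      cfg <- simulation_config(
        truth$network, truth$emission,
        duration = as.numeric(opts$duration %||% 30),
        bin_width = as.numeric(opts[["bin-width"]] %||% 250e-6),
        n_trajectories = as.integer(opts$trajectories %||% 100L),
        seed = seed)
      ens <- generate_ensemble(cfg, dir = outdir)
      logf("wrote %d trajectories + manifest under %s",
           length(ens$trajectories), outdir)
    },
    estimate = {
      man <- opts$manifest %||% stop("estimate needs --manifest")
      stats <- pipeline_estimate(
        man, c3_bin_width = as.numeric(opts[["c3-bin-width"]] %||% 10e-3))
      write_statistics(stats, outdir)
      logf("wrote pdf.tsv, c2.tsv, c3.tsv under %s", outdir)
    },
    fit = ,
    pathways = ,
    fes = ,
    report = {
      sdir <- opts$statsdir %||% stop(cmd, " needs --statsdir")
      stats <- read_statistics(sdir)
      n <- as.integer(opts[["n-states"]] %||% 4L)
      neg <- if (!is.null(opts[["negative-states"]])) {
        strsplit(opts[["negative-states"]], ",")[[1]]
      } else integer(0)
      rep_ <- pipeline_fit_report(
        stats, n, seed = seed,
        n_starts = as.integer(opts[["n-starts"]] %||% 24L),
        negative_states = neg)
      write_fit(rep_$fit, file.path(outdir, "fit.json"))
      write_pathway_table(rep_$c2_terms, file.path(outdir, "c2_terms.csv"))
      write_pathway_table(rep_$c3_terms, file.path(outdir, "c3_terms.csv"))
      write_fes(rep_$fes, file.path(outdir, "fes.json"),
                surface_path = file.path(outdir, "fes_surface.csv"))
      logf("chi^2 = %.6g; outputs under %s", rep_$fit$chi_square$total, outdir)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (grepl("=", key, fixed = TRUE)) {
      kv <- strsplit(key, "=", fixed = TRUE)[[1]]
      opts[[kv[1]]] <- kv[2]
      i <- i + 1L
    } else if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
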