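#' Binned visibility trajectory
#'
#' A uniformly binned time series of visibility values from a single molecule:
#' the raw modulated fluorescence signal averaged over consecutive integration
#' (bin) periods of width `T_w`. Visibility is dimensionless and physically
#' confined to `[-1, 1]`.
#'
#' @param values numeric vector of visibility values, one per bin.
#' @param bin_width bin width `T_w` in seconds (or milliseconds with
#'   `time_unit = "ms"`).
#' @param meta named list of provenance metadata (construct, condition,
#'   source id, ...). `scan_duration_s` is filled in if missing.
#' @param time_unit `"s"` (default) or `"ms"`.
#' @return object of class `visibility_trajectory`.
#' @export
visibility_trajectory <- function(values, bin_width, meta = list(),
                                  time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  if (time_unit == "ms") bin_width <- bin_width / 1000
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a trajectory needs at least 2 bins")
  if (any(!is.finite(values))) stop("visibility values must be finite")
  if (any(abs(values) > 1 + 1e-9)) stop("|visibility| must be <= 1")
  if (!is.finite(bin_width) || bin_width <= 0) stop("'bin_width' must be > 0")
  meta$scan_duration_s <- meta$scan_duration_s %||% (length(values) * bin_width)
  structure(list(values = values, bin_width = bin_width, meta = meta),
            class = "visibility_trajectory")
}

#' @export
print.visibility_trajectory <- function(x, ...) {
  cat(sprintf("visibility_trajectory: %d bins x %g s = %.3g s",
              length(x$values), x$bin_width, length(x$values) * x$bin_width))
  if (!is.null(x$meta$construct)) cat(" |", x$meta$construct)
  if (!is.null(x$meta$condition)) cat(" |", x$meta$condition)
  cat("\n")
  invisible(x)
}

#' Rebin a visibility trajectory to a coarser integration period
#'
#' Averages `factor` consecutive bins into one, multiplying the bin width by
#' `factor`; a trailing remainder shorter than `factor` bins is dropped. This
#' reproduces re-analysis of the same signal at a longer integration period
#' (e.g. 250 microseconds for the two-point statistics versus 10 ms for the
#' three-point statistics).
#'
#' @param traj a [visibility_trajectory()].
#' @param factor positive integer rebinning factor.
#' @return a [visibility_trajectory()] with `factor`-fold coarser bins.
#' @export
rebin <- function(traj, factor) {
  stopifnot(inherits(traj, "visibility_trajectory"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be a positive integer")
  if (factor == 1L) return(traj)
  n_out <- length(traj$values) %/% factor
  if (n_out < 2L) stop("trajectory too short to rebin by ", factor)
  m <- matrix(traj$values[seq_len(n_out * factor)], nrow = factor)
  visibility_trajectory(colMeans(m), traj$bin_width * factor, traj$meta)
}

#' Write / read a visibility trajectory as delimited text
#'
#' One visibility value per line, preceded by `#`-prefixed metadata header
#' lines; the bin width is stored as `# bin_width_s=<value>`.
#'
#' @param traj a [visibility_trajectory()].
#' @param path file path.
#' @return `write_trajectory`: the path, invisibly; `read_trajectory`: a
#'   [visibility_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "visibility_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_s=%.17g", traj$bin_width), con)
  for (key in names(traj$meta)) {
    val <- traj$meta[[key]]
    if (is.numeric(val)) val <- sprintf("%.17g", val)
    writeLines(sprintf("# %s=%s", key, val), con)
  }
  writeLines(sprintf("%.17g", traj$values), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (h in sub("^#\\s*", "", lines[hdr])) {
    kv <- regmatches(h, regexpr("=", h), invert = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  fields <- strsplit(trimws(body[1]), "[,\t ]+")[[1]]
  if (length(fields) >= 2L) {
    # two columns: time_s, visibility
    tab <- utils::read.table(text = body)
    values <- tab[[2]]
    bw <- stats::median(diff(tab[[1]]))
  } else {
    values <- as.numeric(body)
    if (is.null(meta$bin_width_s)) {
      stop("single-column trajectory file lacks '# bin_width_s=' header: ", path)
    }
    bw <- as.numeric(meta$bin_width_s)
  }
  meta$bin_width_s <- NULL
  label_keys <- c("construct", "condition", "source")
  num <- suppressWarnings(lapply(seq_along(meta), function(i) {
    if (names(meta)[i] %in% label_keys) return(meta[[i]])
    x <- as.numeric(meta[[i]])
    if (!is.na(x)) x else meta[[i]]
  }))
  names(num) <- names(meta)
  visibility_trajectory(values, bw, num)
}

#' Write / read an ensemble manifest
#'
#' A manifest is a plain-text file listing member trajectory paths (relative
#' to the manifest's directory), plus shared `#`-prefixed metadata.
#'
#' @param paths character vector of member trajectory file paths.
#' @param path manifest file path.
#' @param meta named list of shared metadata.
#' @return `write_manifest`: the path, invisibly; `read_manifest`: list with
#'   `paths` (absolute) and `meta`.
#' @export
write_manifest <- function(paths, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    val <- meta[[key]]
    if (is.numeric(val)) val <- sprintf("%.17g", val)
    writeLines(sprintf("# %s=%s", key, val), con)
  }
  writeLines(paths, con)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (h in sub("^#\\s*", "", lines[hdr])) {
    kv <- regmatches(h, regexpr("=", h), invert = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  rel <- trimws(lines[!hdr & nzchar(trimws(lines))])
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", rel), rel, file.path(base, rel))
  list(paths = abs, meta = meta)
}

#' Read all member trajectories of a manifest
#'
#' @param path manifest file path.
#' @return list of [visibility_trajectory()] objects.
#' @export
read_ensemble <- function(path) {
  man <- read_manifest(path)
  lapply(man$paths, read_trajectory)
}
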