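#' Two-point kinetic pathway terms
#'
#' Decomposes the model two-point TCF at lag `tau` into its N^2 signed pathway
#' terms: for each ordered state pair (i -> j) the fluctuation product
#' `delta_v_bar_j * delta_v_bar_i` times the statistical weight
#' `w_ij = p_ij(tau) * p_i_eq`. The contributions sum exactly to
#' `model_c2(net, emission, tau)`.
#'
#' @param net a [kinetic_network()].
#' @param emission a paired [emission_model()].
#' @param tau lag time in seconds (default 250 microseconds, the resolution at
#'   which two-point pathway tables are typically reported).
#' @return data.frame of class `pathway_terms` with columns `path`, `product`,
#'   `weight`, `contribution`, `sign`; attributes `lags` and `total`.
#' @export
c2_terms <- function(net, emission, tau = 250e-6) {
  p <- check_pairing(net, emission)
  dv <- fluctuation_amplitudes(emission, p)
  P <- conditional_probabilities(net, tau)
  n <- net$n_states
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  product <- dv[idx$j] * dv[idx$i]
  weight <- P[cbind(idx$i, idx$j)] * p[idx$i]
  contribution <- product * weight
  out <- data.frame(
    path = paste0(net$state_labels[idx$i], "->", net$state_labels[idx$j]),
    product = unname(product),
    weight = unname(weight),
    contribution = unname(contribution),
    sign = ifelse(contribution >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  attr(out, "lags") <- tau
  attr(out, "total") <- sum(contribution)
  class(out) <- c("pathway_terms", "data.frame")
  out
}

#' Three-point transition pathway terms
#'
#' Decomposes the model three-point TCF at lags `(tau1, tau2)` into its N^3
#' signed pathway terms (i -> j -> k): fluctuation product
#' `delta_v_bar_k * delta_v_bar_j * delta_v_bar_i` times the weight
#' `w_ijk = p_jk(tau2) * p_ij(tau1) * p_i_eq`. The contributions sum exactly
#' to `model_c3(net, emission, tau1, tau2)`.
#'
#' @inheritParams c2_terms
#' @param tau1,tau2 lag times in seconds (default 10 ms each, the resolution
#'   at which three-point pathway tables are typically reported).
#' @return data.frame of class `pathway_terms` (see [c2_terms()]).
#' @export
c3_terms <- function(net, emission, tau1 = 10e-3, tau2 = 10e-3) {
  p <- check_pairing(net, emission)
  dv <- fluctuation_amplitudes(emission, p)
  P1 <- conditional_probabilities(net, tau1)
  P2 <- conditional_probabilities(net, tau2)
  n <- net$n_states
  idx <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  product <- dv[idx$k] * dv[idx$j] * dv[idx$i]
  weight <- P2[cbind(idx$j, idx$k)] * P1[cbind(idx$i, idx$j)] * p[idx$i]
  contribution <- product * weight
  out <- data.frame(
    path = paste0(net$state_labels[idx$i], "->", net$state_labels[idx$j],
                  "->", net$state_labels[idx$k]),
    product = unname(product),
    weight = unname(weight),
    contribution = unname(contribution),
    sign = ifelse(contribution >= 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  attr(out, "lags") <- c(tau1, tau2)
  attr(out, "total") <- sum(contribution)
  class(out) <- c("pathway_terms", "data.frame")
  out
}

#' Rank pathway terms by importance
#'
#' Orders pathway terms by decreasing |contribution| (ties broken by path
#' label), optionally keeping only positive or negative terms and/or the
#' `top_n` largest — e.g. the eight largest positive and negative three-point
#' terms conventionally tabulated.
#'
#' @param terms a `pathway_terms` data.frame from [c2_terms()] or [c3_terms()].
#' @param top_n keep at most this many rows (default all).
#' @param sign_filter `"both"` (default), `"positive"` or `"negative"`.
#' @return the filtered, ordered `pathway_terms` data.frame.
#' @export
rank_terms <- function(terms, top_n = NULL,
                       sign_filter = c("both", "positive", "negative")) {
  sign_filter <- match.arg(sign_filter)
  stopifnot(inherits(terms, "pathway_terms"))
  out <- terms
  if (sign_filter == "positive") out <- out[out$contribution >= 0, ]
  if (sign_filter == "negative") out <- out[out$contribution < 0, ]
  ord <- order(-abs(out$contribution), out$path)
  out <- out[ord, ]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  class(out) <- c("pathway_terms", "data.frame")
  out
}

#' Write a ranked pathway table as CSV
#'
#' @param terms a `pathway_terms` data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_pathway_table <- function(terms, path) {
  stopifnot(inherits(terms, "pathway_terms"))
  utils::write.csv(as.data.frame(terms), path, row.names = FALSE)
  invisible(path)
}
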