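#' FBCCA configuration
#'
#' Parameters of static filter-bank CCA scoring: the sub-band decomposition,
#' the number of reference harmonics k, and the sub-band weighting exponents.
#' The weight of sub-band d is \eqn{w(d) = d^{-a} + b}; the defaults
#' `a = 1.25`, `b = 0.25` are the standard FBCCA values, downweighting
#' higher sub-bands where SSVEP harmonic energy decays.
#'
#' @param filter_bank a [filter_bank_spec]; default [default_filter_bank]
#'   with `n_subbands` bands.
#' @param n_subbands used only when `filter_bank` is NULL.
#' @param n_harmonics number of reference harmonics k.
#' @param weight_a,weight_b weighting parameters a and b.
#' @return An object of class `fbcca_config`.
#' @export
fbcca_config <- function(filter_bank = NULL, n_subbands = 5L, n_harmonics = 5L,
                         weight_a = 1.25, weight_b = 0.25) {
  if (is.null(filter_bank)) filter_bank <- default_filter_bank(n_subbands)
  stopifnot(inherits(filter_bank, "filter_bank_spec"))
  if (!is.finite(weight_a) || !is.finite(weight_b)) stop("weights a, b must be finite")
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  structure(list(filter_bank = filter_bank, n_harmonics = as.integer(n_harmonics),
                 weight_a = weight_a, weight_b = weight_b),
            class = "fbcca_config")
}

#' Sub-band weight
#'
#' \eqn{w(d) = d^{-a} + b} for sub-band index d.
#'
#' @param d sub-band index, >= 1 (vectorized).
#' @param a,b weighting parameters.
#' @return Numeric weight(s).
#' @examples
#' subband_weight(1:5, 1.25, 0.25)
#' @export
subband_weight <- function(d, a = 1.25, b = 0.25) {
  if (any(d < 1)) stop("sub-band index must be >= 1")
  d^(-a) + b
}

# Precomputed decoding state shared by fbcca and the adaptive classifier:
# designed filters, per-frequency reference orthobases, sub-band weights.
# Built once per (vocabulary, fs, n_samples, config) and reused across trials.
build_decoder <- function(vocabulary, config, sampling_rate, n_samples) {
  stopifnot(inherits(vocabulary, "stimulus_vocabulary"),
            inherits(config, "fbcca_config"))
  refs <- make_reference_set(vocabulary, config$n_harmonics, sampling_rate, n_samples)
  list(vocabulary = vocabulary, config = config,
       sampling_rate = sampling_rate, n_samples = as.integer(n_samples),
       filters = design_filters(config$filter_bank, sampling_rate),
       pad_len = config$filter_bank$pad_len,
       ref_bases = lapply(refs, orth_basis),
       weights = subband_weight(seq_len(config$filter_bank$n_subbands),
                                config$weight_a, config$weight_b))
}

# D x Nf matrix of max canonical correlations between the sub-band-filtered
# epoch copies and every reference basis.
subband_correlations <- function(subbands, decoder) {
  vapply(subbands, function(Xd) {
    Ux <- orth_basis(Xd)
    vapply(decoder$ref_bases, function(Uy) cca_from_bases(Ux, Uy), numeric(1L))
  }, numeric(length(decoder$ref_bases)))  # Nf x D
}

# weighted sum over sub-bands of squared correlations -> length-Nf scores
combine_subbands <- function(rho, weights) as.vector(rho^2 %*% weights)

#' Static FBCCA score at one frequency
#'
#' \eqn{\tilde\rho_f = \sum_{d=1}^{D} w(d)\, \rho_{SB,d}^2}, where
#' \eqn{\rho_{SB,d}} is the maximal canonical correlation between sub-band d
#' of the epoch and the harmonic reference at `frequency`.
#'
#' @param epoch an [eeg_epoch].
#' @param frequency stimulus frequency in Hz.
#' @param config an [fbcca_config].
#' @return Non-negative score.
#' @export
fbcca_score <- function(epoch, frequency, config = fbcca_config()) {
  voc <- stimulus_vocabulary(frequency)
  dec <- build_decoder(voc, config, sampling_rate(epoch), n_samples(epoch))
  subbands <- apply_filter_bank(epoch, config$filter_bank)
  combine_subbands(subband_correlations(subbands, dec), dec$weights)[1L]
}

#' Static FBCCA classification over a vocabulary
#'
#' Scores the epoch at every vocabulary frequency and returns the argmax
#' label (ties broken deterministically toward the lowest index) together
#' with the full score vector.
#'
#' @param epoch an [eeg_epoch].
#' @param vocabulary a [stimulus_vocabulary].
#' @param config an [fbcca_config].
#' @return A list with `label` (index into the vocabulary) and `scores`.
#' @examples
#' voc <- ucsd_vocabulary()
#' cfg <- synth_config(voc, snr_db = 20, seed = 1)
#' e <- generate_epoch(cfg, target_index = 3)$epoch
#' fbcca_classify(e, voc, fbcca_config(n_subbands = 3, n_harmonics = 3))$label
#' @export
fbcca_classify <- function(epoch, vocabulary, config = fbcca_config()) {
  dec <- build_decoder(vocabulary, config, sampling_rate(epoch), n_samples(epoch))
  subbands <- apply_filter_bank(epoch, config$filter_bank)
  scores <- combine_subbands(subband_correlations(subbands, dec), dec$weights)
  list(label = which.max(scores), scores = scores)
}
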