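#' Per-frequency template bank
#'
#' Holds one running-average template per vocabulary frequency (the tensor Z
#' of the adaptive classifier), initialized to zero with zero update counts.
#' An all-zero template is an "empty" slot: superimposing it leaves the epoch
#' unchanged, so before any update the adaptive classifier reduces exactly to
#' static FBCCA.
#'
#' @param vocabulary a [stimulus_vocabulary].
#' @param n_channels,n_samples template shape, fixed at construction.
#' @param sampling_rate sampling rate in Hz.
#' @return An object of class `template_bank`: list with `templates` (list of
#'   channels-by-samples matrices), `update_counts`, `vocabulary`,
#'   `sampling_rate`.
#' @export
template_bank <- function(vocabulary, n_channels, n_samples, sampling_rate) {
  stopifnot(inherits(vocabulary, "stimulus_vocabulary"))
  nf <- length(vocabulary)
  structure(list(
    templates = replicate(nf, matrix(0, n_channels, n_samples), simplify = FALSE),
    update_counts = integer(nf),
    vocabulary = vocabulary,
    n_channels = as.integer(n_channels), n_samples = as.integer(n_samples),
    sampling_rate = as.numeric(sampling_rate)
  ), class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("Template bank: %d frequencies, %d x %d templates, %d/%d filled (%d updates)\n",
              length(x$vocabulary), x$n_channels, x$n_samples,
              sum(x$update_counts > 0L), length(x$vocabulary), sum(x$update_counts)))
  invisible(x)
}

#' Superimpose a template onto a test epoch
#'
#' Elementwise sum \eqn{X_i = X + Z_i}, unnormalized. Superposition is
#' coherent (SNR-raising) when the epoch's stimulus frequency and phase match
#' the template's, incoherent otherwise — the self-similarity mechanism the
#' adaptive classifier exploits.
#'
#' @param epoch an [eeg_epoch] or channels-by-samples matrix.
#' @param bank a [template_bank].
#' @param frequency_index index i into the bank's vocabulary.
#' @return The channels-by-samples matrix \eqn{X + Z_i}.
#' @export
superimpose <- function(epoch, bank, frequency_index) {
  stopifnot(inherits(bank, "template_bank"))
  X <- as_plain_matrix(epoch)
  Z <- bank$templates[[frequency_index]]
  if (!identical(dim(X), dim(Z)))
    stop(sprintf("epoch is %d x %d but templates are %d x %d",
                 nrow(X), ncol(X), nrow(Z), ncol(Z)))
  X + Z
}

#' Adaptive-classifier configuration
#'
#' The integration weight w blends the template-augmented FBCCA score p into
#' the static score p': the decision statistic is \eqn{\tilde p_i = p'_i +
#' w\,p_i}. `w = 0.45` is the tuned default for 40-class Benchmark-style
#' vocabularies and `w = 0.65` for 12-class UCSD-style ones; `w = 0` recovers
#' static FBCCA exactly.
#'
#' @param fbcca an [fbcca_config].
#' @param integration_weight w >= 0.
#' @param update_policy `"always"` updates the decided frequency's template
#'   after every trial (the online algorithm); `"frozen"` never updates;
#'   `"running_mean"` replaces the halving recursion with a count-weighted
#'   running mean (non-default variant).
#' @return An object of class `uac_config`.
#' @export
uac_config <- function(fbcca = fbcca_config(), integration_weight = 0.45,
                       update_policy = c("always", "frozen", "running_mean")) {
  stopifnot(inherits(fbcca, "fbcca_config"))
  if (!is.finite(integration_weight) || integration_weight < 0)
    stop("integration_weight must be finite and >= 0")
  structure(list(fbcca = fbcca, integration_weight = integration_weight,
                 update_policy = match.arg(update_policy)),
            class = "uac_config")
}

#' Preset configurations for the two public dataset layouts
#'
#' Benchmark-style: D = 5 sub-bands, k = 5 harmonics, w = 0.45.
#' UCSD-style: D = 3, k = 3, w = 0.65.
#'
#' @return A [uac_config].
#' @export
benchmark_preset <- function() {
  uac_config(fbcca_config(n_subbands = 5L, n_harmonics = 5L), integration_weight = 0.45)
}

#' @rdname benchmark_preset
#' @export
ucsd_preset <- function() {
  uac_config(fbcca_config(n_subbands = 3L, n_harmonics = 3L), integration_weight = 0.65)
}

# Engine: decoder + cached sub-band-filtered templates. Because zero-phase
# filtering is linear, the filtered version of X + Z_i is filtered(X) +
# filtered(Z_i), so templates are re-filtered only when they change (once per
# update) instead of once per scored frequency per trial.
uac_engine <- function(bank, config) {
  dec <- build_decoder(bank$vocabulary, config$fbcca, bank$sampling_rate, bank$n_samples)
  filt_templates <- vector("list", length(bank$vocabulary))  # NULL = empty slot
  for (i in seq_along(filt_templates)) {
    if (bank$update_counts[i] > 0L)
      filt_templates[[i]] <- lapply(dec$filters, function(f)
        filter_epoch(f, bank$templates[[i]], dec$pad_len))
  }
  list(decoder = dec, filt_templates = filt_templates)
}

# Core scoring given pre-filtered epoch sub-bands. Returns DecodeResult fields.
uac_score_engine <- function(subbands, engine, w) {
  dec <- engine$decoder
  nf <- length(dec$ref_bases)
  rho_static <- subband_correlations(subbands, dec)          # Nf x D
  static_scores <- combine_subbands(rho_static, dec$weights) # p'
  template_scores <- static_scores                           # p; equals p' on empty slots
  empty <- vapply(engine$filt_templates, is.null, logical(1L))
  for (i in which(!empty)) {
    Zi <- engine$filt_templates[[i]]
    rho_i <- vapply(seq_along(subbands), function(d) {
      cca_from_bases(orth_basis(subbands[[d]] + Zi[[d]]), dec$ref_bases[[i]])
    }, numeric(1L))
    template_scores[i] <- sum(dec$weights * rho_i^2)
  }
  integrated <- static_scores + w * template_scores
  list(label = which.max(integrated),
       static_scores = static_scores,
       template_scores = template_scores,
       integrated_scores = integrated,
       template_was_empty = empty)
}

#' Score an epoch with the adaptive classifier (no template update)
#'
#' For every vocabulary frequency i the epoch is superimposed with that
#' frequency's template and scored by FBCCA against the matching reference
#' (\eqn{p_i}); the plain epoch is scored statically (\eqn{p'_i}); the
#' decision statistic is \eqn{\tilde p_i = p'_i + w\,p_i} and the label is
#' its argmax (lowest-index tie-break).
#'
#' @param epoch an [eeg_epoch].
#' @param bank a [template_bank] whose vocabulary and shape match the epoch.
#' @param config a [uac_config].
#' @return A decode result: list with `label`, `static_scores`,
#'   `template_scores`, `integrated_scores`, `template_was_empty`.
#' @export
uac_score <- function(epoch, bank, config = uac_config()) {
  check_epoch_bank(epoch, bank)
  engine <- uac_engine(bank, config)
  subbands <- apply_filter_bank(epoch, config$fbcca$filter_bank)
  uac_score_engine(subbands, engine, config$integration_weight)
}

#' Classify one epoch and update the template bank online
#'
#' Scores the epoch exactly as [uac_score] (the template seen by the decision
#' is always the pre-update bank), then replaces the decided frequency's
#' template by the halving recursion \eqn{Z' = (X + Z)/2} — an
#' exponentially-weighted average favoring recent trials — and increments its
#' update count. All other templates are untouched. Updates use the
#' classifier's own estimated label; no confidence gating is applied, so
#' wrong decisions do contaminate templates (the method tolerates this
#' because a template polluted by a minority of wrong-label epochs still
#' raises the matched-frequency score on average).
#'
#' @inheritParams uac_score
#' @return A list with `result` (the decode result) and `bank` (the updated
#'   [template_bank]).
#' @export
classify_and_update <- function(epoch, bank, config = uac_config()) {
  check_epoch_bank(epoch, bank)
  engine <- uac_engine(bank, config)
  subbands <- apply_filter_bank(epoch, config$fbcca$filter_bank)
  result <- uac_score_engine(subbands, engine, config$integration_weight)
  bank <- update_bank(bank, as_plain_matrix(epoch), result$label, config$update_policy)
  list(result = result, bank = bank)
}

update_bank <- function(bank, X, label, policy) {
  if (policy == "frozen") return(bank)
  Z <- bank$templates[[label]]
  bank$templates[[label]] <-
    if (policy == "running_mean") {
      n <- bank$update_counts[label]
      (n * Z + X) / (n + 1)
    } else (X + Z) / 2
  bank$update_counts[label] <- bank$update_counts[label] + 1L
  bank
}

check_epoch_bank <- function(epoch, bank) {
  stopifnot(inherits(bank, "template_bank"))
  if (nrow(epoch) != bank$n_channels || ncol(epoch) != bank$n_samples)
    stop(sprintf("epoch is %d x %d but bank expects %d x %d",
                 nrow(epoch), ncol(epoch), bank$n_channels, bank$n_samples))
  invisible(TRUE)
}

#' Save / load a template bank
#'
#' Serializes the bank (templates, counts, vocabulary, shape, a format
#' version) to a single file for session persistence.
#'
#' @param bank a [template_bank].
#' @param path file path.
#' @return `read_template_bank` returns the [template_bank].
#' @export
write_template_bank <- function(bank, path) {
  stopifnot(inherits(bank, "template_bank"))
  saveRDS(c(list(format = "ssvepuac-template-bank", format_version = 1L),
            unclass(bank)), path)
  invisible(path)
}

#' @rdname write_template_bank
#' @export
read_template_bank <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "ssvepuac-template-bank"))
    stop("not a template-bank file: ", path)
  x$format <- NULL; x$format_version <- NULL
  structure(x, class = "template_bank")
}
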