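#' Filter-bank specification
#'
#' Defines the D sub-band decomposition used by FBCCA. The default bank for an
#' SSVEP vocabulary follows the standard filter-bank design from the FBCCA
#' literature: sub-band d passes `[8*d, 88]` Hz, so successive bands strip
#' away one more fundamental-range octave and isolate higher harmonics.
#' Filters are Chebyshev type-I bandpass, prototype order 4 (order 8 after the
#' bandpass transform), 0.5 dB passband ripple, applied forward-backward
#' (zero-phase) with mirrored-edge padding.
#'
#' @param band_edges numeric matrix with one row per sub-band and columns
#'   `low`, `high` (Hz), or a list of length-2 vectors.
#' @param order Chebyshev prototype order.
#' @param ripple_db passband ripple in dB.
#' @param pad_len mirrored-edge padding length in samples; default
#'   `3 * (2 * order + 1)`, three times the realized filter length.
#' @return An object of class `filter_bank_spec`.
#' @examples
#' spec <- default_filter_bank(5)
#' spec$band_edges
#' @export
filter_bank_spec <- function(band_edges, order = 4L, ripple_db = 0.5,
                             pad_len = 3L * (2L * order + 1L)) {
  if (is.list(band_edges)) band_edges <- do.call(rbind, band_edges)
  band_edges <- matrix(as.numeric(band_edges), ncol = 2L,
                       dimnames = list(NULL, c("low", "high")))
  if (nrow(band_edges) < 1L) stop("need at least one sub-band")
  if (any(band_edges[, 1L] <= 0) || any(band_edges[, 1L] >= band_edges[, 2L]))
    stop("each band needs 0 < low < high")
  if (is.unsorted(band_edges[, 1L])) stop("band low edges must be non-decreasing")
  structure(list(band_edges = band_edges, n_subbands = nrow(band_edges),
                 order = as.integer(order), ripple_db = ripple_db,
                 pad_len = as.integer(pad_len)),
            class = "filter_bank_spec")
}

#' @rdname filter_bank_spec
#' @param n_subbands number of sub-bands D.
#' @param harmonic_step low-edge spacing in Hz (band d starts at
#'   `harmonic_step * d`).
#' @param high_cut common upper edge in Hz.
#' @export
default_filter_bank <- function(n_subbands, harmonic_step = 8, high_cut = 88) {
  filter_bank_spec(cbind(harmonic_step * seq_len(n_subbands), high_cut))
}

#' @export
print.filter_bank_spec <- function(x, ...) {
  cat(sprintf("Filter bank: %d sub-bands, Chebyshev-I order %d (%.2g dB ripple), zero-phase\n",
              x$n_subbands, x$order, x$ripple_db))
  for (d in seq_len(x$n_subbands))
    cat(sprintf("  band %d: %g-%g Hz\n", d, x$band_edges[d, 1L], x$band_edges[d, 2L]))
  invisible(x)
}

# Design the D bandpass filters for a sampling rate; cached per decoder.
design_filters <- function(spec, sampling_rate) {
  nyq <- sampling_rate / 2
  lapply(seq_len(spec$n_subbands), function(d) {
    lo <- spec$band_edges[d, 1L]; hi <- spec$band_edges[d, 2L]
    if (hi >= nyq)
      stop(sprintf("band %d upper edge %g Hz is at/above Nyquist (%g Hz)", d, hi, nyq))
    signal::cheby1(spec$order, spec$ripple_db, c(lo, hi) / nyq, type = "pass")
  })
}

# Zero-phase filtering with odd (mirrored) edge extension to suppress the
# forward-backward transient at the epoch boundaries.
filtfilt_padded <- function(filt, x, pad_len) {
  n <- length(x)
  p <- min(pad_len, n - 1L)
  pre <- 2 * x[1L] - x[(p + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(p + 1L):(p + n)]
}

#' Apply a filter bank to an epoch
#'
#' Decomposes a multichannel epoch into D sub-band-filtered copies, each the
#' same shape as the input. Filtering is zero-phase (forward-backward), hence
#' linear and delay-free: filtering a superposition of two epochs equals the
#' superposition of their filtered versions, a property the adaptive
#' classifier relies on when caching filtered templates.
#'
#' @param epoch an [eeg_epoch] or channels-by-samples matrix.
#' @param spec a [filter_bank_spec].
#' @param sampling_rate required when `epoch` is a bare matrix.
#' @return A list of D channels-by-samples matrices.
#' @export
apply_filter_bank <- function(epoch, spec, sampling_rate = NULL) {
  if (inherits(epoch, "eeg_epoch")) {
    sampling_rate <- sampling_rate(epoch)
  } else if (is.null(sampling_rate)) stop("sampling_rate required for a bare matrix")
  X <- as_plain_matrix(epoch)
  if (ncol(X) < 3L * spec$order)
    stop("epoch too short for the filter transient (need >= 3x filter order samples)")
  filts <- design_filters(spec, sampling_rate)
  lapply(filts, function(f) filter_epoch(f, X, spec$pad_len))
}

filter_epoch <- function(filt, X, pad_len) {
  t(apply(X, 1L, function(ch) filtfilt_padded(filt, ch, pad_len)))
}
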