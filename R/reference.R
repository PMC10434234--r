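#' Sinusoidal harmonic reference matrix for CCA
#'
#' Builds the standard SSVEP reference matrix \eqn{Y_f} for one stimulus
#' frequency: `2k` rows alternating \eqn{\cos(2\pi j f t)} and
#' \eqn{\sin(2\pi j f t)} for harmonics \eqn{j = 1..k}, sampled at
#' \eqn{t = 1/f_s, 2/f_s, \ldots, N_s/f_s}. The time axis starts at
#' \eqn{1/f_s}, not 0, so the construction is bit-reproducible against its
#' textbook definition. No phase term is included: phase-coded references are
#' deliberately out of scope.
#'
#' @param frequency stimulus frequency in Hz, > 0.
#' @param n_harmonics number of harmonics k, >= 1.
#' @param sampling_rate sampling rate in Hz.
#' @param n_samples number of samples Ns, >= 1.
#' @return A `2*n_harmonics` by `n_samples` matrix with rows
#'   `cos1, sin1, cos2, sin2, ...`; attributes `frequency`, `sampling_rate`.
#' @examples
#' Y <- make_reference(10, n_harmonics = 5, sampling_rate = 250, n_samples = 250)
#' dim(Y)  # 10 x 250
#' @export
make_reference <- function(frequency, n_harmonics, sampling_rate, n_samples) {
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop("frequency must be a single positive number")
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (n_harmonics * frequency >= sampling_rate / 2)
    warning(sprintf("harmonic %d of %g Hz is at/above Nyquist (%g Hz)",
                    n_harmonics, frequency, sampling_rate / 2))
  t <- seq_len(n_samples) / sampling_rate
  Y <- matrix(0, nrow = 2L * n_harmonics, ncol = n_samples)
  for (j in seq_len(n_harmonics)) {
    w <- 2 * pi * j * frequency * t
    Y[2L * j - 1L, ] <- cos(w)
    Y[2L * j, ] <- sin(w)
  }
  structure(Y, frequency = frequency, sampling_rate = sampling_rate)
}

#' Reference set for a whole vocabulary
#'
#' One [make_reference] matrix per vocabulary frequency, in vocabulary order.
#'
#' @param vocabulary a [stimulus_vocabulary].
#' @inheritParams make_reference
#' @return A list of reference matrices, one per frequency.
#' @export
make_reference_set <- function(vocabulary, n_harmonics, sampling_rate, n_samples) {
  stopifnot(inherits(vocabulary, "stimulus_vocabulary"))
  lapply(vocabulary$frequencies, make_reference,
         n_harmonics = n_harmonics, sampling_rate = sampling_rate,
         n_samples = n_samples)
}
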