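#' Synthetic SSVEP generator configuration
#'
#' Describes a simulated SSVEP recording: a phase-locked harmonic response per
#' stimulus target, mixed across channels, embedded in broadband or 1/f EEG
#' background noise at a controlled SNR, with optional between-block amplitude
#' drift emulating non-stationarity.
#'
#' SNR is defined as total harmonic signal power over total noise power within
#' the 6-90 Hz analysis band (where all stimulation fundamentals and modeled
#' harmonics live), measured per epoch from the discrete spectrum. Targets are
#' phase-locked: target i always flickers with the same initial phase, so
#' same-target epochs average coherently while noise averages incoherently.
#'
#' @param vocabulary a [stimulus_vocabulary]; targets without explicit phases
#'   get fixed per-target phases drawn once from the seed.
#' @param sampling_rate Hz.
#' @param epoch_length seconds.
#' @param n_channels number of EEG channels.
#' @param n_harmonics_signal harmonics present in the simulated response.
#' @param harmonic_decay amplitude ratio between consecutive harmonics
#'   (harmonic h has amplitude `harmonic_decay^(h-1)`).
#' @param snr_db epoch signal-to-noise ratio in dB (6-90 Hz band).
#' @param noise_model `"one_over_f"` (spectrally shaped, power ~ 1/f above
#'   1 Hz, channel-correlated) or `"white"`.
#' @param mixing `"random_orthonormal"` (a seeded orthonormal
#'   channels-by-harmonics topography, fixed for the whole session) or an
#'   explicit channels-by-harmonics gain matrix.
#' @param block_drift multiplicative signal-amplitude change per block:
#'   block b is scaled by `block_drift^(b-1)`. 1 = stationary.
#' @param seed integer; mandatory — every generated epoch is a pure function
#'   of (seed, target, block, trial).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(vocabulary, sampling_rate = 250, epoch_length = 1,
                         n_channels = 8L, n_harmonics_signal = 3L,
                         harmonic_decay = 0.5, snr_db = -10,
                         noise_model = c("one_over_f", "white"),
                         mixing = "random_orthonormal", block_drift = 1,
                         seed) {
  stopifnot(inherits(vocabulary, "stimulus_vocabulary"))
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory")
  noise_model <- match.arg(noise_model)
  n_samples <- round(epoch_length * sampling_rate)
  if (n_samples < 2L) stop("epoch_length * sampling_rate must give >= 2 samples")
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  cfg <- structure(list(
    vocabulary = vocabulary, sampling_rate = sampling_rate,
    epoch_length = epoch_length, n_samples = as.integer(n_samples),
    n_channels = as.integer(n_channels),
    n_harmonics_signal = as.integer(n_harmonics_signal),
    harmonic_decay = harmonic_decay, snr_db = snr_db,
    noise_model = noise_model, mixing = mixing, block_drift = block_drift,
    seed = as.integer(seed)
  ), class = "synth_config")
  cfg$phases <- session_phases(cfg)
  cfg$mixing_matrix <- session_mixing(cfg)
  cfg$noise_mixing_matrix <- session_noise_mixing(cfg)
  cfg
}

# Lehmer-style integer hash chain, exact in double arithmetic (products stay
# below 2^53). Gives every (seed, target, block, trial) its own RNG stream.
hash_seed <- function(...) {
  h <- 0
  for (x in c(...)) h <- (48271 * (h + x + 1)) %% 2147483647
  as.integer(h)
}

session_phases <- function(cfg) {
  if (!is.null(cfg$vocabulary$phases)) return(cfg$vocabulary$phases)
  withr_seed(hash_seed(cfg$seed, 7, 0, 0), stats::runif(length(cfg$vocabulary), 0, 2 * pi))
}

session_mixing <- function(cfg) {
  H <- cfg$n_harmonics_signal
  if (is.matrix(cfg$mixing)) {
    stopifnot(nrow(cfg$mixing) == cfg$n_channels, ncol(cfg$mixing) == H)
    return(cfg$mixing)
  }
  withr_seed(hash_seed(cfg$seed, 11, 0, 0), random_orthonormal(cfg$n_channels, H))
}

session_noise_mixing <- function(cfg) {
  withr_seed(hash_seed(cfg$seed, 13, 0, 0),
             random_orthonormal(cfg$n_channels, cfg$n_channels))
}

# n x k matrix with orthonormal columns (k <= n)
random_orthonormal <- function(n, k) {
  stopifnot(k <= n)
  qr.Q(qr(matrix(stats::rnorm(n * n), n)))[, seq_len(k), drop = FALSE]
}

# run expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# noiseless channels x samples response for one target (drift excluded)
target_signal <- function(cfg, target_index) {
  f <- cfg$vocabulary$frequencies[target_index]
  phi <- cfg$phases[target_index]
  t <- seq_len(cfg$n_samples) / cfg$sampling_rate
  H <- cfg$n_harmonics_signal
  S <- matrix(0, H, cfg$n_samples)
  for (h in seq_len(H))
    S[h, ] <- cfg$harmonic_decay^(h - 1) * sin(2 * pi * h * f * t + h * phi)
  cfg$mixing_matrix %*% S
}

# spectral power in [lo, hi] Hz summed over channels
band_power <- function(X, fs, lo = 6, hi = 90) {
  n <- ncol(X)
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= lo & freqs <= min(hi, fs / 2)
  sum(vapply(seq_len(nrow(X)), function(ch) {
    p <- Mod(stats::fft(X[ch, ]))^2 / n
    sum(p[sel])
  }, numeric(1L)))
}

# unit-scale background noise, channels x samples
raw_noise <- function(cfg) {
  n <- cfg$n_samples
  N <- matrix(stats::rnorm(cfg$n_channels * n), cfg$n_channels, n)
  if (cfg$noise_model == "one_over_f") {
    freqs <- (seq_len(n) - 1) * cfg$sampling_rate / n
    freqs <- pmin(freqs, cfg$sampling_rate - freqs)       # two-sided axis
    shape <- 1 / sqrt(pmax(freqs, 1))                     # power ~ 1/f, f >= 1 Hz
    for (ch in seq_len(cfg$n_channels))
      N[ch, ] <- Re(stats::fft(stats::fft(N[ch, ]) * shape, inverse = TRUE)) / n
    N <- cfg$noise_mixing_matrix %*% N                    # induce channel correlation
  }
  N
}

#' Generate one synthetic SSVEP epoch
#'
#' The epoch is `mixing %*% (harmonic sinusoids at the target frequency with
#' the target's fixed phase) * drift(block) + noise`, with noise scaled so the
#' realized 6-90 Hz signal-to-noise power ratio equals `snr_db`. Bitwise
#' deterministic given `(seed, target, block, trial)`.
#'
#' @param config a [synth_config].
#' @param target_index which vocabulary target is gazed at.
#' @param block_index,trial_index position in the session (enter the epoch's
#'   RNG stream and the block drift).
#' @param return_components also return the noiseless `signal` and the scaled
#'   `noise` matrices (diagnostics).
#' @return A list with `epoch` (an [eeg_epoch]), `label` (= `target_index`),
#'   `block`, and optionally `signal` and `noise`.
#' @export
generate_epoch <- function(config, target_index, block_index = 1L,
                           trial_index = 1L, return_components = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (target_index < 1L || target_index > length(config$vocabulary))
    stop("target_index out of range")
  drift <- config$block_drift^(block_index - 1)
  S <- target_signal(config, target_index) * drift
  N <- withr_seed(hash_seed(config$seed, target_index, block_index, trial_index),
                  raw_noise(config))
  ps <- band_power(S, config$sampling_rate)
  pn <- band_power(N, config$sampling_rate)
  N <- N * sqrt(ps / (pn * 10^(config$snr_db / 10)))
  out <- list(epoch = eeg_epoch(S + N, config$sampling_rate),
              label = as.integer(target_index), block = as.integer(block_index))
  if (return_components) { out$signal <- S; out$noise <- N }
  out
}

#' Generate a sequential multi-block session
#'
#' Each block presents every vocabulary target exactly once, in a seeded
#' random order — the sequential-block protocol of cue-guided SSVEP
#' experiments.
#'
#' @param config a [synth_config].
#' @param n_blocks number of blocks.
#' @return An object of class `ssvep_session`: list with `trials` (each a
#'   [generate_epoch] record plus `trial`, in presentation order),
#'   `vocabulary`, `n_blocks`, `config`.
#' @export
generate_session <- function(config, n_blocks) {
  stopifnot(inherits(config, "synth_config"), n_blocks >= 1L)
  nf <- length(config$vocabulary)
  trials <- vector("list", n_blocks * nf)
  k <- 0L
  for (b in seq_len(n_blocks)) {
    order_b <- withr_seed(hash_seed(config$seed, 17, b, 0), sample.int(nf))
    for (j in seq_len(nf)) {
      k <- k + 1L
      trials[[k]] <- c(generate_epoch(config, order_b[j], b, j), list(trial = j))
    }
  }
  structure(list(trials = trials, vocabulary = config$vocabulary,
                 n_blocks = as.integer(n_blocks), config = config),
            class = "ssvep_session")
}

#' @export
print.ssvep_session <- function(x, ...) {
  cat(sprintf("SSVEP session: %d trials (%d blocks x %d targets), %g Hz, %g s epochs\n",
              length(x$trials), x$n_blocks, length(x$vocabulary),
              x$config$sampling_rate, x$config$epoch_length))
  invisible(x)
}

#' Save / load a session as an epoch archive
#'
#' Writes the epochs as a serialized array bundle next to a human-readable
#' JSON sidecar (vocabulary, sampling rate, labels, block ids) — the
#' interchange format the command-line tools use.
#'
#' @param session an `ssvep_session` (from [generate_session] or a dataset
#'   reader).
#' @param path archive path (`.rds`); the sidecar is written at `path` +
#'   `".json"`.
#' @return `read_session` returns the `ssvep_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ssvep_session"))
  saveRDS(session, path, compress = "gzip")
  sidecar <- list(
    format = "ssvepuac-session", format_version = 1L,
    frequencies = session$vocabulary$frequencies,
    phases = session$vocabulary$phases,
    sampling_rate = if (!is.null(session$config)) session$config$sampling_rate
                    else sampling_rate(session$trials[[1L]]$epoch),
    n_trials = length(session$trials),
    labels = vapply(session$trials, `[[`, integer(1L), "label"),
    blocks = vapply(session$trials, `[[`, integer(1L), "block"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "ssvep_session")) stop("not a session archive: ", path)
  x
}
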