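# Shared fixtures: small vocabularies and configs keep module tests fast;
# full-scale study conditions live only in the acceptance tests.

tiny_vocab <- function() stimulus_vocabulary(c(9, 11, 13))

small_ucsd_config <- function(seed, snr_db = -5, epoch_length = 1) {
  synth_config(ucsd_vocabulary(), sampling_rate = 256,
               epoch_length = epoch_length, snr_db = snr_db, seed = seed)
}

fast_fbcca <- function(n_subbands = 2L, n_harmonics = 2L)
  fbcca_config(n_subbands = n_subbands, n_harmonics = n_harmonics)

# independent brute-force CCA oracle: explicit covariance matrices and the
# generalized eigenproblem Sxx^-1 Sxy Syy^-1 Syx (never shares code with the
# package's QR/SVD route)
cca_oracle <- function(X, Y) {
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Sxx <- Xc %*% t(Xc)
  Syy <- Yc %*% t(Yc)
  Sxy <- Xc %*% t(Yc)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  sqrt(max(Re(eigen(M, only.values = TRUE)$values)))
}

# noiseless per-target response at the generator's session amplitude
clean_template <- function(config, target_index)
  generate_epoch(config, target_index, return_components = TRUE)$signal
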