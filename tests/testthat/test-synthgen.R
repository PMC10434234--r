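test_that("near-noiseless epochs are decoded perfectly over the whole vocabulary", {
  voc <- ucsd_vocabulary()
  cfg <- synth_config(voc, sampling_rate = 256, snr_db = 60, seed = 41)
  fb <- fbcca_config(n_subbands = 3, n_harmonics = 3)
  labels <- vapply(1:12, function(i)
    fbcca_classify(generate_epoch(cfg, i)$epoch, voc, fb)$label, integer(1))
  expect_identical(labels, 1:12)
})

test_that("generation is a pure function of (seed, target, block, trial)", {
  cfg <- synth_config(tiny_vocab(), snr_db = -5, seed = 42)
  a <- generate_epoch(cfg, 2, 3, 4)
  b <- generate_epoch(cfg, 2, 3, 4)
  expect_identical(unclass(a$epoch), unclass(b$epoch))
  expect_false(identical(unclass(a$epoch),
                         unclass(generate_epoch(cfg, 2, 3, 5)$epoch)))
  cfg2 <- synth_config(tiny_vocab(), snr_db = -5, seed = 43)
  expect_false(identical(unclass(a$epoch),
                         unclass(generate_epoch(cfg2, 2, 3, 4)$epoch)))
  expect_error(generate_epoch(cfg, 9), "out of range")
  expect_error(synth_config(tiny_vocab(), snr_db = -5), "seed")
})

test_that("realized band SNR matches the requested snr_db within 1 dB on average", {
  for (snr in c(-10, 0)) {
    cfg <- synth_config(tiny_vocab(), snr_db = snr, seed = 44)
    measured <- vapply(1:100, function(r) {
      g <- generate_epoch(cfg, (r %% 3) + 1, 1, r, return_components = TRUE)
      10 * log10(ssvepuac:::band_power(g$signal, 250) /
                 ssvepuac:::band_power(g$noise, 250))
    }, numeric(1))
    expect_lt(abs(mean(measured) - snr), 1)
  }
})

test_that("targets are phase-locked across trials", {
  cfg <- synth_config(tiny_vocab(), snr_db = 0, seed = 45, epoch_length = 2)
  # fundamental phase of the noiseless component, per trial
  phases <- vapply(1:20, function(r) {
    S <- generate_epoch(cfg, 1, 1, r, return_components = TRUE)$signal
    bins <- (0:(ncol(S) - 1)) * 250 / ncol(S)
    Arg(fft(S[1, ])[which.min(abs(bins - 9))])
  }, numeric(1))
  circ_var <- 1 - Mod(mean(exp(1i * phases)))
  expect_lt(circ_var, 1e-6)
})

test_that("coherent averaging of same-target epochs raises narrowband SNR by ~18 dB", {
  # sqrt(n) law: averaging 64 phase-locked epochs divides noise power by 64
  voc <- stimulus_vocabulary(10.25)   # aligns with 0.25 Hz bins at 4 s
  cfg <- synth_config(voc, snr_db = 0, epoch_length = 4, seed = 46)
  nb_snr <- function(X, f) {
    n <- ncol(X); bins <- (0:(n - 1)) * 250 / n
    p <- colSums(t(apply(X, 1, function(ch) Mod(fft(ch))^2)))
    sig <- abs(bins - f) < 0.01 | abs(bins - 2 * f) < 0.01 | abs(bins - 3 * f) < 0.01
    noise <- bins >= 6 & bins <= 90 & !(abs(bins - f) < 0.3 |
             abs(bins - 2 * f) < 0.3 | abs(bins - 3 * f) < 0.3)
    10 * log10(sum(p[sig]) / sum(p[noise]))
  }
  epochs <- lapply(1:64, function(r) unclass(generate_epoch(cfg, 1, 1, r)$epoch))
  snr1 <- mean(vapply(epochs[1:8], nb_snr, numeric(1), f = 10.25))
  snr64 <- nb_snr(Reduce(`+`, epochs) / 64, 10.25)
  expect_lt(abs((snr64 - snr1) - 10 * log10(64)), 1.5)
})

test_that("sessions cover every target exactly once per block in seeded order", {
  voc <- benchmark_vocabulary()
  cfg <- synth_config(voc, epoch_length = 0.2, snr_db = 0, seed = 47)
  ses <- generate_session(cfg, 6)
  expect_length(ses$trials, 240)
  labels <- vapply(ses$trials, `[[`, integer(1), "label")
  blocks <- vapply(ses$trials, `[[`, integer(1), "block")
  expect_true(all(table(labels) == 6))
  for (b in 1:6) expect_setequal(labels[blocks == b], 1:40)
  ses2 <- generate_session(cfg, 6)
  expect_identical(vapply(ses2$trials, `[[`, integer(1), "label"), labels)
  cfg3 <- synth_config(voc, epoch_length = 0.2, snr_db = 0, seed = 48)
  labels3 <- vapply(generate_session(cfg3, 6)$trials, `[[`, integer(1), "label")
  expect_false(identical(labels3, labels))
})

test_that("sessions round-trip through the archive format with a JSON sidecar", {
  cfg <- synth_config(tiny_vocab(), snr_db = 0, seed = 49, epoch_length = 0.5)
  ses <- generate_session(cfg, 2)
  p <- tempfile(fileext = ".rds")
  write_session(ses, p)
  back <- read_session(p)
  expect_identical(unclass(back$trials[[4]]$epoch), unclass(ses$trials[[4]]$epoch))
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$frequencies, tiny_vocab()$frequencies)
  expect_equal(side$n_trials, 6)
  expect_equal(side$labels, vapply(ses$trials, `[[`, integer(1), "label"))
})
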