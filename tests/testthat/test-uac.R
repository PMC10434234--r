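make_bank_epoch <- function(seed = 31, snr_db = 0) {
  cfg <- synth_config(tiny_vocab(), snr_db = snr_db, seed = seed)
  e <- generate_epoch(cfg, 2)$epoch
  bank <- template_bank(tiny_vocab(), nrow(e), ncol(e), sampling_rate(e))
  list(cfg = cfg, epoch = e, bank = bank)
}

test_that("superposition is the raw elementwise sum with the stored template", {
  f <- make_bank_epoch()
  X <- matrix(as.numeric(f$epoch), nrow(f$epoch))
  expect_equal(superimpose(f$epoch, f$bank, 1), X)           # empty slot: X + 0
  f$bank$templates[[2]] <- X
  expect_equal(superimpose(f$epoch, f$bank, 2), 2 * X)       # doubling
  f$bank$templates[[3]] <- X[, 1:10]
  expect_error(superimpose(f$epoch, f$bank, 3), "epoch is")
})

test_that("with w = 0 the adaptive decision reduces exactly to static FBCCA", {
  f <- make_bank_epoch(seed = 32)
  ucfg <- uac_config(fast_fbcca(), integration_weight = 0)
  # non-trivial bank state: pollute a template first
  f$bank$templates[[3]] <- matrix(rnorm(length(f$epoch)), nrow(f$epoch))
  f$bank$update_counts[3] <- 1L
  res <- uac_score(f$epoch, f$bank, ucfg)
  static <- fbcca_classify(f$epoch, tiny_vocab(), fast_fbcca())
  expect_identical(res$label, static$label)
  expect_identical(res$integrated_scores, res$static_scores)
  expect_equal(res$static_scores, static$scores, tolerance = 1e-12)
})

test_that("a fresh all-zero bank gives p = p' at every frequency", {
  f <- make_bank_epoch(seed = 33)
  ucfg <- uac_config(fast_fbcca(), integration_weight = 0.45)
  res <- uac_score(f$epoch, f$bank, ucfg)
  expect_identical(res$template_scores, res$static_scores)
  expect_true(all(res$template_was_empty))
  expect_equal(res$integrated_scores, (1 + 0.45) * res$static_scores)
  expect_identical(res$label, which.max(res$static_scores))
})

test_that("the halving update follows Z' = (X + Z)/2 and its closed-form recursion", {
  voc <- tiny_vocab()
  X <- matrix(as.numeric(sample.int(64, 8 * 64, replace = TRUE)), 8, 64)  # exact binary values
  epoch <- eeg_epoch(X, 250)
  bank <- template_bank(voc, 8, 64, 250)
  ucfg <- uac_config(fbcca_config(filter_bank = filter_bank_spec(rbind(c(8, 88))),
                                  n_harmonics = 1))
  out <- classify_and_update(epoch, bank, ucfg)
  i <- out$result$label
  expect_identical(out$bank$templates[[i]], X / 2)             # fresh slot -> X/2
  expect_identical(out$bank$update_counts[i], 1L)
  out2 <- classify_and_update(epoch, out$bank, ucfg)
  expect_identical(out2$result$label, i)                       # same epoch, same label
  expect_identical(out2$bank$templates[[i]], 3 * X / 4)        # (X + X/2)/2
  # n applications converge geometrically: Z_n = X * (1 - 2^-n)
  b <- bank
  for (n in 1:8) b <- classify_and_update(epoch, b, ucfg)$bank
  expect_equal(b$templates[[i]], X * (1 - 2^-8), tolerance = 1e-14)
  expect_identical(sum(b$update_counts), 8L)
})

test_that("exactly one template slot changes per update; frozen banks never change", {
  f <- make_bank_epoch(seed = 34)
  ucfg <- uac_config(fast_fbcca(), integration_weight = 0.45)
  out <- classify_and_update(f$epoch, f$bank, ucfg)
  changed <- vapply(seq_along(out$bank$templates), function(i)
    !identical(out$bank$templates[[i]], f$bank$templates[[i]]), logical(1))
  expect_identical(sum(changed), 1L)
  expect_identical(which(changed), out$result$label)
  frozen <- uac_config(fast_fbcca(), 0.45, update_policy = "frozen")
  out_f <- classify_and_update(f$epoch, f$bank, frozen)
  expect_identical(out_f$bank, f$bank)
})

test_that("the running-mean policy keeps a count-weighted average instead", {
  f <- make_bank_epoch(seed = 35)
  ucfg <- uac_config(fast_fbcca(), 0.45, update_policy = "running_mean")
  X <- matrix(as.numeric(f$epoch), nrow(f$epoch))
  b <- f$bank
  for (n in 1:3) b <- classify_and_update(f$epoch, b, ucfg)$bank
  i <- which(b$update_counts > 0)
  expect_equal(b$templates[[i]], X, tolerance = 1e-12)  # mean of identical epochs
})

test_that("matched-frequency superposition raises narrowband power at the target", {
  # phase-locked components add coherently; noise adds incoherently
  voc <- ucsd_vocabulary()
  wins <- 0L
  n_rep <- 30L
  cfg <- synth_config(voc, sampling_rate = 256, epoch_length = 4, snr_db = 0, seed = 36)
  Z <- clean_template(cfg, 4)
  f4 <- voc$frequencies[4]
  nb_power <- function(X) {
    n <- ncol(X); bins <- (0:(n - 1)) * 256 / n
    sel <- abs(bins - f4) < 0.01
    sum(apply(X, 1, function(ch) sum(Mod(fft(ch))[sel]^2)))
  }
  for (r in seq_len(n_rep)) {
    X <- unclass(generate_epoch(cfg, 4, 1, r)$epoch)
    wins <- wins + (nb_power(X + Z) > nb_power(X))
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("template banks persist losslessly through their archive format", {
  f <- make_bank_epoch(seed = 37)
  f$bank$templates[[1]] <- matrix(rnorm(length(f$epoch)), nrow(f$epoch))
  f$bank$update_counts[1] <- 3L
  p <- tempfile(fileext = ".bank")
  write_template_bank(f$bank, p)
  expect_identical(read_template_bank(p), f$bank)
  saveRDS(list(a = 1), p)
  expect_error(read_template_bank(p), "not a template-bank")
})
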