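small_session <- function(seed, snr_db = -5, n_blocks = 2) {
  generate_session(synth_config(tiny_vocab(), snr_db = snr_db, seed = seed),
                   n_blocks)
}

test_that("the ITR closed form matches hand-computed values and limits", {
  expect_equal(information_transfer_rate(1, 40, 1.5), 60 / 1.5 * log2(40),
               tolerance = 1e-12)
  expect_equal(information_transfer_rate(1 / 40, 40, 1.5), 0, tolerance = 1e-12)
  expect_equal(information_transfer_rate(1 / 12, 12, 2), 0, tolerance = 1e-12)
  expect_equal(information_transfer_rate(1, 2, 60), 1, tolerance = 1e-12)
  expect_equal(information_transfer_rate(0, 2, 60), 1, tolerance = 1e-12)
  expect_error(information_transfer_rate(1.2, 40, 1), "\\[0, 1\\]")
  expect_error(information_transfer_rate(0.5, 1, 1), "n_targets")
  expect_error(information_transfer_rate(0.5, 40, 0), "trial_time")
})

test_that("ITR is non-decreasing in accuracy above chance", {
  p <- seq(1 / 40, 1, length.out = 100)
  itr <- information_transfer_rate(p, 40, 1.5)
  expect_true(all(diff(itr) >= -1e-12))
})

test_that("trial time adds stimulation and gaze-shift intervals", {
  expect_equal(trial_time_for_itr(1.0, 0.5), 1.5)
  expect_equal(trial_time_for_itr(0.8, 0), 0.8)
  expect_equal(trial_time_for_itr(1.6), 2.1)
  expect_error(trial_time_for_itr(-1), ">= 0")
})

test_that("with w = 0 the adaptive and static label streams are identical", {
  ses <- small_session(61)
  pr <- run_sequential_protocol(ses, uac_config(fast_fbcca(), 0))
  expect_identical(pr$records$adaptive_label, pr$records$static_label)
  expect_equal(pr$adaptive_accuracy, pr$static_accuracy)
})

test_that("a frozen fresh bank reproduces static decoding exactly", {
  ses <- small_session(62)
  pr <- run_sequential_protocol(ses,
    uac_config(fast_fbcca(), 0.45, update_policy = "frozen"))
  expect_identical(pr$records$adaptive_label, pr$records$static_label)
  expect_identical(sum(pr$bank$update_counts), 0L)
})

test_that("protocol accuracies equal a manual recount and counts are conserved", {
  ses <- small_session(63)
  pr <- run_sequential_protocol(ses, uac_config(fast_fbcca(), 0.45))
  r <- pr$records
  expect_equal(pr$static_accuracy, mean(r$static_label == r$true_label))
  expect_equal(pr$adaptive_accuracy, mean(r$adaptive_label == r$true_label))
  for (b in pr$blocks)
    expect_equal(pr$adaptive_block_accuracy[b],
                 mean(r$adaptive_label[r$block == b] == r$true_label[r$block == b]))
  expect_identical(sum(pr$bank$update_counts), nrow(r))
  # sequential state evolution matches trial-by-trial classify_and_update
  bank <- template_bank(ses$vocabulary, 8, 250, 250)
  cfg <- uac_config(fast_fbcca(), 0.45)
  for (k in seq_len(nrow(r))) {
    step <- classify_and_update(ses$trials[[k]]$epoch, bank, cfg)
    expect_identical(step$result$label, r$adaptive_label[k])
    bank <- step$bank
  }
  expect_equal(bank$templates, pr$bank$templates, tolerance = 1e-10)
})

test_that("high-SNR sessions never lose accuracy to adaptation", {
  ses <- small_session(64, snr_db = 5, n_blocks = 3)
  pr <- run_sequential_protocol(ses, uac_config(fast_fbcca(), 0.45))
  expect_gte(pr$adaptive_accuracy, pr$static_accuracy)
})

test_that("the weight sweep reports the curve and the argmax without hard-coding", {
  ses <- small_session(65)
  sw0 <- weight_sweep(ses, uac_config(fast_fbcca()), grid = 0)
  pr0 <- run_sequential_protocol(ses, uac_config(fast_fbcca(), 0))
  expect_equal(sw0$curve$mean_accuracy, pr0$static_accuracy)
  sw <- weight_sweep(list(ses), uac_config(fast_fbcca()), grid = c(0, 0.45, 0.45, 1))
  expect_equal(sw$curve$mean_accuracy[2], sw$curve$mean_accuracy[3])  # determinism
  expect_true(sw$best_w %in% sw$curve$w)
  expect_equal(max(sw$curve$mean_accuracy),
               sw$curve$mean_accuracy[sw$curve$w == sw$best_w][1])
  expect_error(weight_sweep(ses, grid = numeric(0)), "non-empty")
})

test_that("block accumulation reruns truncated sessions from a fresh bank", {
  ses <- small_session(66, n_blocks = 3)
  ba <- block_accumulation(ses, uac_config(fast_fbcca(), 0.45))
  expect_equal(ba$n_blocks, 1:3)
  expect_equal(ba$gain, ba$adaptive - ba$static)
  pr1 <- run_sequential_protocol(
    structure(list(trials = ses$trials[1:3], vocabulary = ses$vocabulary,
                   n_blocks = 1L, config = ses$config), class = "ssvep_session"),
    uac_config(fast_fbcca(), 0.45))
  expect_equal(ba$static[1], pr1$static_accuracy)
})

test_that("paired per-subject accuracies feed a standard signed-rank test", {
  prs <- lapply(c(67, 68), function(s)
    run_sequential_protocol(small_session(s), uac_config(fast_fbcca(), 0.45)))
  pa <- paired_accuracies(prs)
  expect_identical(dim(pa), c(2L, 3L))
  expect_true(all(pa$static >= 0 & pa$adaptive <= 1))
  expect_s3_class(suppressWarnings(
    wilcox.test(pa$adaptive, pa$static, paired = TRUE)), "htest")
  csv <- tempfile(fileext = ".csv")
  write_protocol_csv(prs[[1]], csv)
  back <- read.csv(csv)
  expect_equal(back$adaptive_label, prs[[1]]$records$adaptive_label)
})
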