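#' Manifest describing how to epoch a public SSVEP dataset file
#'
#' The two public dataset layouts store continuous per-trial recordings; the
#' analysis epoch is cut `latency_offset` seconds after flicker onset (the
#' visual-pathway delay before the SSVEP stabilizes — a choice that changes
#' accuracy, so it is always explicit) for `window_length` seconds.
#'
#' @param layout `"benchmark40"` (40 targets, 64 channels, 250 Hz, 6 blocks,
#'   flicker onset 0.5 s after trial start) or `"ucsd12"` (12 targets, 8
#'   occipito-parietal channels, 256 Hz, 15 runs).
#' @param channel_subset integer indices into the file's channel dimension
#'   (validated against it), or NULL for all channels. Channel-name montages
#'   are not bundled with the package; subsetting is by index.
#' @param latency_offset seconds between flicker onset and epoch start.
#' @param window_length analyzed data length in seconds.
#' @param stimulus_onset_s seconds from recorded-trial start to flicker
#'   onset; defaults to the layout's published cue interval.
#' @return An object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(layout = c("benchmark40", "ucsd12"),
                             channel_subset = NULL, latency_offset = 0.14,
                             window_length = 1,
                             stimulus_onset_s = NULL) {
  layout <- match.arg(layout)
  if (is.null(stimulus_onset_s))
    stimulus_onset_s <- switch(layout, benchmark40 = 0.5, ucsd12 = 0)
  if (latency_offset < 0 || window_length <= 0 || stimulus_onset_s < 0)
    stop("offsets must be >= 0 and window_length > 0")
  structure(list(layout = layout, channel_subset = channel_subset,
                 latency_offset = latency_offset, window_length = window_length,
                 stimulus_onset_s = stimulus_onset_s),
            class = "dataset_manifest")
}

cut_window <- function(n_avail, fs, manifest) {
  start <- round((manifest$stimulus_onset_s + manifest$latency_offset) * fs) + 1L
  len <- round(manifest$window_length * fs)
  if (start + len - 1L > n_avail)
    stop(sprintf("epoch window [%d, %d] exceeds the %d samples in the file",
                 start, start + len - 1L, n_avail))
  start:(start + len - 1L)
}

pick_channels <- function(n_avail, subset) {
  if (is.null(subset)) return(seq_len(n_avail))
  subset <- as.integer(subset)
  if (any(subset < 1L | subset > n_avail))
    stop(sprintf("channel subset outside the file's %d channels", n_avail))
  subset
}

session_from_tensor <- function(get_epoch, n_targets, n_blocks, vocabulary, fs) {
  trials <- vector("list", n_targets * n_blocks)
  k <- 0L
  for (b in seq_len(n_blocks)) for (tg in seq_len(n_targets)) {
    k <- k + 1L
    trials[[k]] <- list(epoch = eeg_epoch(get_epoch(tg, b), fs),
                        label = tg, block = b, trial = tg)
  }
  structure(list(trials = trials, vocabulary = vocabulary,
                 n_blocks = as.integer(n_blocks), config = NULL),
            class = "ssvep_session")
}

#' Read one Benchmark-layout subject file
#'
#' Expects the published 4-D layout: a MATLAB v5 array named `data` of shape
#' channels x samples x 40 targets x 6 blocks sampled at 250 Hz. Epochs are
#' cut to the manifest window; labels are target indices; trials are emitted
#' block by block in target order. MATLAB v7.3 files are not supported.
#'
#' @param path subject `.mat` file.
#' @param manifest a [dataset_manifest] with layout `"benchmark40"`.
#' @return An `ssvep_session` with 240 trials (40 targets x 6 blocks).
#' @export
read_benchmark_subject <- function(path, manifest = dataset_manifest("benchmark40")) {
  stopifnot(manifest$layout == "benchmark40")
  arrays <- read_mat5(path)
  if (!"data" %in% names(arrays))
    stop("no 'data' array in ", path, " (found: ",
         paste(names(arrays), collapse = ", "), ")")
  a <- arrays$data
  if (length(dim(a)) != 4L)
    stop(sprintf("'data' must be 4-D (channels x samples x targets x blocks), got %d-D",
                 length(dim(a))))
  fs <- 250
  ch <- pick_channels(dim(a)[1L], manifest$channel_subset)
  win <- cut_window(dim(a)[2L], fs, manifest)
  session_from_tensor(function(tg, b) a[ch, win, tg, b, drop = FALSE][, , 1L, 1L],
                      dim(a)[3L], dim(a)[4L], benchmark_vocabulary(), fs)
}

#' Read one UCSD-layout subject file
#'
#' Expects the published 4-D layout: a MATLAB v5 array named `eeg` of shape
#' 12 targets x 8 channels x samples x 15 runs at 256 Hz, epochs already cut
#' around the 4 s flicker period. The manifest window is applied relative to
#' the stored epoch start.
#'
#' @param path subject `.mat` file.
#' @param manifest a [dataset_manifest] with layout `"ucsd12"`.
#' @return An `ssvep_session` with 180 trials (12 targets x 15 runs; runs
#'   play the role of blocks).
#' @export
read_ucsd_subject <- function(path, manifest = dataset_manifest("ucsd12")) {
  stopifnot(manifest$layout == "ucsd12")
  arrays <- read_mat5(path)
  if (!"eeg" %in% names(arrays))
    stop("no 'eeg' array in ", path, " (found: ",
         paste(names(arrays), collapse = ", "), ")")
  a <- arrays$eeg
  if (length(dim(a)) != 4L)
    stop(sprintf("'eeg' must be 4-D (targets x channels x samples x runs), got %d-D",
                 length(dim(a))))
  fs <- 256
  ch <- pick_channels(dim(a)[2L], manifest$channel_subset)
  win <- cut_window(dim(a)[3L], fs, manifest)
  session_from_tensor(function(tg, b) a[tg, ch, win, b, drop = FALSE][1L, , , 1L],
                      dim(a)[1L], dim(a)[4L], ucsd_vocabulary(), fs)
}

#' Write a synthetic subject file in a public dataset layout
#'
#' Generates a fully synthetic session with [generate_epoch] and stores it in
#' the Benchmark (`data`: channels x samples x targets x blocks) or UCSD
#' (`eeg`: targets x channels x samples x runs) 4-D MATLAB layout, including
#' the pre-onset interval, so the reader round-trip can be exercised without
#' the real downloads. The file is synthetic and must not be mistaken for
#' real subject data.
#'
#' @param path output `.mat` path.
#' @param layout `"benchmark40"` or `"ucsd12"`.
#' @param config a [synth_config] matching the layout's sampling rate and
#'   vocabulary.
#' @param n_blocks blocks (benchmark) or runs (ucsd).
#' @param pre_onset_s seconds of pre-flicker signal to prepend (zeros).
#' @return The path, invisibly.
#' @export
write_synthetic_subject <- function(path, layout = c("benchmark40", "ucsd12"),
                                    config, n_blocks,
                                    pre_onset_s = if (match.arg(layout) == "benchmark40") 0.5 else 0) {
  layout <- match.arg(layout)
  stopifnot(inherits(config, "synth_config"))
  nf <- length(config$vocabulary)
  pre <- round(pre_onset_s * config$sampling_rate)
  ns <- config$n_samples + pre
  nc <- config$n_channels
  if (layout == "benchmark40") {
    a <- array(0, c(nc, ns, nf, n_blocks))
    for (b in seq_len(n_blocks)) for (tg in seq_len(nf))
      a[, (pre + 1L):ns, tg, b] <- generate_epoch(config, tg, b, tg)$epoch
    write_mat5(list(data = a), path)
  } else {
    a <- array(0, c(nf, nc, ns, n_blocks))
    for (b in seq_len(n_blocks)) for (tg in seq_len(nf))
      a[tg, , (pre + 1L):ns, b] <- generate_epoch(config, tg, b, tg)$epoch
    write_mat5(list(eeg = a), path)
  }
  invisible(path)
}
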