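#' A single multichannel EEG epoch
#'
#' One trial's EEG time series plus sampling metadata. Internally all package
#' math uses the channels-by-samples orientation; constructors accept either
#' orientation through an explicit flag — never by shape-guessing, since a
#' silently transposed epoch is the classic SSVEP decoding bug.
#'
#' @param data numeric matrix of EEG samples in microvolts.
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param channel_names optional character vector of channel labels.
#' @param orientation `"channels_x_samples"` (default) or
#'   `"samples_x_channels"`; the latter is transposed on construction.
#' @return An object of class `eeg_epoch`: the channels-by-samples matrix with
#'   `sampling_rate` and `channel_names` attributes.
#' @examples
#' e <- eeg_epoch(matrix(rnorm(500), 2), sampling_rate = 250)
#' n_samples(e)
#' @export
eeg_epoch <- function(data, sampling_rate, channel_names = NULL,
                      orientation = c("channels_x_samples", "samples_x_channels")) {
  orientation <- match.arg(orientation)
  data <- as.matrix(data)
  if (orientation == "samples_x_channels") data <- t(data)
  if (nrow(data) < 1L) stop("epoch needs at least one channel")
  if (ncol(data) < 2L) stop("epoch needs at least two samples")
  if (any(!is.finite(data))) stop("epoch contains NaN or Inf values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must equal channel count")
  structure(data, sampling_rate = as.numeric(sampling_rate),
            channel_names = as.character(channel_names), class = c("eeg_epoch", "matrix"))
}

#' @rdname eeg_epoch
#' @param x an `eeg_epoch`.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' @rdname eeg_epoch
#' @export
n_channels <- function(x) nrow(x)

#' @rdname eeg_epoch
#' @export
n_samples <- function(x) ncol(x)

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("EEG epoch: %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(x), ncol(x), sampling_rate(x), ncol(x) / sampling_rate(x)))
  invisible(x)
}

# strip class/attrs, keep plain numeric matrix
as_epoch_matrix <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}
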