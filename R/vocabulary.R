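#' Stimulus vocabulary
#'
#' An ordered set of SSVEP stimulus frequencies, optionally with the initial
#' flicker phases used by phase-coded stimulation. Frequencies index the
#' template bank, the reference set and all score vectors throughout the
#' package.
#'
#' @param frequencies numeric vector of stimulus frequencies in Hz; strictly
#'   positive and distinct.
#' @param phases optional numeric vector of initial phases in radians, same
#'   length as `frequencies`. Phases are used only by the synthetic generator;
#'   sinusoidal CCA references are built without a phase term.
#' @return An object of class `stimulus_vocabulary`.
#' @examples
#' stimulus_vocabulary(seq(8, 15.8, by = 0.2))
#' @export
stimulus_vocabulary <- function(frequencies, phases = NULL) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) == 0L) stop("vocabulary must contain at least one frequency")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("all stimulus frequencies must be finite and > 0")
  if (anyDuplicated(frequencies)) stop("stimulus frequencies must be distinct")
  if (!is.null(phases)) {
    phases <- as.numeric(phases)
    if (length(phases) != length(frequencies))
      stop("phases must match frequencies in length")
    if (any(!is.finite(phases))) stop("phases must be finite")
  }
  structure(list(frequencies = frequencies, phases = phases),
            class = "stimulus_vocabulary")
}

#' @export
print.stimulus_vocabulary <- function(x, ...) {
  cat(sprintf("Stimulus vocabulary: %d targets, %.4g-%.4g Hz%s\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              if (is.null(x$phases)) "" else " (phase-coded)"))
  invisible(x)
}

#' @export
length.stimulus_vocabulary <- function(x) length(x$frequencies)

#' Preset vocabularies for the two public SSVEP datasets
#'
#' `benchmark_vocabulary()` is the 40-target layout (8 to 15.8 Hz in 0.2 Hz
#' steps, phases 0, 0.5pi, pi, 1.5pi cycling with frequency index).
#' `ucsd_vocabulary()` is the 12-target layout (f0 = 9.25 Hz, step 0.5 Hz,
#' phi0 = 0, step 0.5pi).
#'
#' @return A [stimulus_vocabulary].
#' @export
benchmark_vocabulary <- function() {
  f <- seq(8, 15.8, by = 0.2)
  stimulus_vocabulary(f, phases = (seq_along(f) - 1L) %% 4L * 0.5 * pi)
}

#' @rdname benchmark_vocabulary
#' @export
ucsd_vocabulary <- function() {
  stimulus_vocabulary(9.25 + 0.5 * (0:11), phases = 0.5 * pi * (0:11))
}

#' Read a stimulus vocabulary from a JSON or CSV config file
#'
#' JSON files must hold an object with a `frequencies` array and an optional
#' `phases` array; CSV files a `frequency` column and an optional `phase`
#' column.
#'
#' @param path file path; format chosen by extension (`.json` or `.csv`).
#' @return A [stimulus_vocabulary].
#' @export
read_vocabulary <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    stimulus_vocabulary(x$frequencies, x$phases)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    x <- utils::read.csv(path)
    if (!"frequency" %in% names(x)) stop("CSV vocabulary needs a 'frequency' column")
    stimulus_vocabulary(x$frequency, if ("phase" %in% names(x)) x$phase)
  } else stop("unrecognized vocabulary file extension: ", path)
}
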