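#' Multichannel signal container
#'
#' Wraps a real channels-by-samples matrix together with its sampling rate and
#' (optional) epoch structure. All decomposition entry points in the package
#' take a `signal_matrix`.
#'
#' @param data Real numeric matrix, one row per channel, one column per sample.
#'   A vector is treated as a single channel.
#' @param srate Sampling rate in samples per second (> 0).
#' @param epoch_length Number of samples per epoch, or `NULL` for a continuous
#'   recording. If given, `ncol(data)` must be divisible by it. Pairwise
#'   embeddings never span an epoch boundary.
#' @param channel_labels Optional character vector of channel names.
#'
#' @return An object of class `signal_matrix` with fields `data`, `srate`,
#'   `epoch_length` (`NULL` if continuous) and `channel_labels`.
#' @examples
#' x <- signal_matrix(matrix(rnorm(200), nrow = 2), srate = 100)
#' n_epochs(x)
#' @export
signal_matrix <- function(data, srate, epoch_length = NULL,
                          channel_labels = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a real numeric matrix (channels x samples)")
  }
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  if (nrow(data) < 1L) stop("need at least one channel")
  if (ncol(data) < 2L) stop("need at least two samples")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0) {
    stop("`srate` must be a positive scalar")
  }
  if (!is.null(epoch_length)) {
    epoch_length <- as.integer(epoch_length)
    if (epoch_length < 2L) stop("`epoch_length` must be at least 2 samples")
    if (ncol(data) %% epoch_length != 0L) {
      stop("number of samples (", ncol(data),
           ") is not divisible by `epoch_length` (", epoch_length, ")")
    }
  }
  if (!is.null(channel_labels)) {
    channel_labels <- as.character(channel_labels)
    if (length(channel_labels) != nrow(data)) {
      stop("`channel_labels` length must equal the number of channels")
    }
  }
  structure(
    list(data = data, srate = as.numeric(srate), epoch_length = epoch_length,
         channel_labels = channel_labels),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$srate, " Hz",
      if (is.null(x$epoch_length)) " (continuous)" else
        paste0(" (", n_epochs(x), " epochs of ", x$epoch_length, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Number of epochs in a signal
#'
#' @param signal A [signal_matrix()]. Continuous recordings count as one epoch.
#' @return Integer number of epochs.
#' @export
n_epochs <- function(signal) {
  stopifnot(inherits(signal, "signal_matrix"))
  if (is.null(signal$epoch_length)) 1L
  else ncol(signal$data) %/% signal$epoch_length
}

# Column index ranges of each epoch; continuous data is a single epoch.
epoch_bounds <- function(signal) {
  L <- if (is.null(signal$epoch_length)) ncol(signal$data) else signal$epoch_length
  k <- ncol(signal$data) %/% L
  lapply(seq_len(k), function(e) ((e - 1L) * L + 1L):(e * L))
}

#' Remove the per-channel mean of a signal
#'
#' Channel means are computed once over the whole recording (all epochs
#' pooled), matching the zero-mean assumption of the downstream variance
#' computations.
#'
#' @param signal A [signal_matrix()].
#' @return The centered `signal_matrix`.
#' @export
center_signal <- function(signal) {
  stopifnot(inherits(signal, "signal_matrix"))
  signal$data <- signal$data - rowMeans(signal$data)
  signal
}

#' Read a signal from a delimited text file
#'
#' Expects one row per channel. The sampling rate and epoch structure are
#' never inferred from the file; they must be supplied.
#'
#' @param path Path to a CSV/TSV file, one row per channel.
#' @param srate Sampling rate in Hz.
#' @param epoch_length Samples per epoch, or `NULL` for continuous data.
#' @param sep Field separator (default `","`).
#' @param header Does the first row hold column names? Default `FALSE`.
#' @return A [signal_matrix()].
#' @export
read_signal_matrix <- function(path, srate, epoch_length = NULL, sep = ",",
                               header = FALSE) {
  df <- utils::read.table(path, sep = sep, header = header)
  m <- as.matrix(df)
  dimnames(m) <- NULL
  signal_matrix(m, srate = srate, epoch_length = epoch_length)
}

#' Write a matrix as delimited text
#'
#' @param x Numeric matrix.
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @export
write_matrix_csv <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
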