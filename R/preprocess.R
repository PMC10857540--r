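#' Low-pass filter specification
#'
#' Settings for the Butterworth low-pass filter applied to every channel
#' before segmentation and feature extraction. The default is a 4th-order
#' design with a 5 Hz cut-off, applied forward and backward (zero phase) so
#' that event timing is not delayed; with two passes the design cut-off is
#' the -6 dB point of the effective response.
#'
#' @param cutoff_hz Cut-off frequency in Hz. Must satisfy
#'   `0 < cutoff_hz < fs_hz / 2`.
#' @param order Filter order per pass (>= 1).
#' @param fs_hz Sampling rate in Hz.
#' @param zero_phase Apply the filter forward and backward (no group delay)?
#'
#' @return A `filter_spec` object (a named list).
#' @export
#' @examples
#' fspec <- filter_spec()
#' x <- sin(2 * pi * 1 * seq(0, 5, by = 1 / 60))
#' y <- lowpass(x, fspec)
filter_spec <- function(cutoff_hz = 5, order = 4, fs_hz = 60, zero_phase = TRUE) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2) {
    abort("`cutoff_hz` must satisfy 0 < cutoff_hz < fs_hz/2.")
  }
  if (!is.numeric(order) || order < 1) abort("`order` must be >= 1.")
  structure(
    list(cutoff_hz = cutoff_hz, order = as.integer(order),
         fs_hz = fs_hz, zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Butterworth low-pass filtering of a time series
#'
#' Applies the Butterworth low-pass filter described by a [filter_spec()].
#' With `zero_phase = TRUE` the series is reflect-padded at both ends
#' (pad length `max(3 * order, fs)` samples, capped at `length(x) - 1`),
#' filtered forward and backward, and cropped back to its original length,
#' so a symmetric pulse stays centered and repeated runs are bit-identical.
#'
#' @param x Numeric vector.
#' @param spec A [filter_spec()].
#'
#' @return Filtered numeric vector, same length as `x`.
#' @export
lowpass <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (is.null(dim(x))) {
    as.numeric(lowpass_mat(matrix(x, ncol = 1), spec))
  } else {
    lowpass_mat(x, spec)
  }
}

# Column-wise variant for n x k channel matrices (one C-level filter pass
# for all columns).
lowpass_mat <- function(x, spec) {
  n <- nrow(x)
  if (n <= 3 * spec$order) {
    abort(sprintf("Series too short to filter: length %d <= 3 x order (%d).",
                  n, 3 * spec$order))
  }
  bf <- butter_cached(spec$order, spec$cutoff_hz / (spec$fs_hz / 2))
  if (!spec$zero_phase) {
    return(iir_apply(bf$b, bf$a, x))
  }
  npad <- min(n - 1, max(3 * spec$order, round(spec$fs_hz)))
  # reflect about the end points to suppress edge transients
  left  <- 2 * matrix(x[1, ], npad, ncol(x), byrow = TRUE) -
    x[seq(npad + 1, 2), , drop = FALSE]
  right <- 2 * matrix(x[n, ], npad, ncol(x), byrow = TRUE) -
    x[seq(n - 1, n - npad), , drop = FALSE]
  xp <- rbind(left, x, right)
  y <- iir_apply(bf$b, bf$a, xp)
  y <- iir_apply(bf$b, bf$a, y[rev(seq_len(nrow(y))), , drop = FALSE])
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y[seq(npad + 1, npad + n), , drop = FALSE]
}

# Butterworth designs reused across calls (signal::butter is not cheap
# relative to one 30 s channel).
.butter_cache <- new.env(parent = emptyenv())
butter_cached <- function(order, w) {
  key <- paste(order, format(w, digits = 15), sep = "_")
  hit <- .butter_cache[[key]]
  if (is.null(hit)) {
    bf <- signal::butter(order, w, type = "low")
    hit <- list(b = as.numeric(bf$b), a = as.numeric(bf$a))
    .butter_cache[[key]] <- hit
  }
  hit
}

# Direct-form IIR pass via C-level stats::filter: MA part as a one-sided
# convolution (zero initial conditions), AR part recursively. Works
# column-wise on matrices.
iir_apply <- function(b, a, x) {
  nb <- length(b)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  xp <- rbind(matrix(0, nb - 1, ncol(x)), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- v[nb:nrow(xp), , drop = FALSE]
  if (length(a) > 1) {
    v <- stats::filter(v, -a[-1], method = "recursive")
  }
  v <- matrix(as.numeric(v), ncol = ncol(x))
  if (vec) as.numeric(v) else v
}

#' Element-wise resultant (Euclidean norm) of three axis channels
#'
#' @param a1,a2,a3 Numeric vectors of equal length (the three axis channels).
#'
#' @return Numeric vector `sqrt(a1^2 + a2^2 + a3^2)`.
#' @export
resultant <- function(a1, a2, a3) {
  if (length(a1) != length(a2) || length(a2) != length(a3)) {
    abort("`a1`, `a2`, `a3` must have equal length.")
  }
  sqrt(a1^2 + a2^2 + a3^2)
}

#' Postural sway magnitude of a (filtered) acceleration channel
#'
#' The sway summary used for all balance features: the population standard
#' deviation of the mean-removed series. The input is expected to be
#' low-pass filtered already (see [lowpass()]); equivalently this is the RMS
#' of the mean-removed series. Zero if and only if the input is constant.
#'
#' @param x Numeric vector, length >= 2.
#'
#' @return Non-negative scalar.
#' @export
sway_summary <- function(x) {
  if (length(x) < 2) abort("`x` must have length >= 2.")
  xc <- x - mean(x)
  sqrt(mean(xc^2))
}
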