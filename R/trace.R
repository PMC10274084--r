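#' Construct a current trace
#'
#' A uniformly sampled single-channel current record. Currents are in pA,
#' time in seconds.
#'
#' @param current numeric vector of current samples (pA), length >= 2.
#' @param sampling_rate sampling rate in Hz.
#' @param filter_cutoff -3 dB cutoff of the (Gaussian) low-pass filter
#'   applied to the record, in Hz, or `NULL` if unfiltered.
#' @param t0 time of the first sample in seconds.
#' @return an object of class `current_trace`: a list with elements
#'   `current`, `sampling_rate`, `filter_cutoff`, `t0`.
#' @export
current_trace <- function(current, sampling_rate, filter_cutoff = NULL,
                          t0 = 0) {
  if (!is.numeric(current) || length(current) < 2L)
    stop("`current` must be numeric with >= 2 samples", call. = FALSE)
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  if (!is.null(filter_cutoff)) stop_if_not_scalar_pos(filter_cutoff, "filter_cutoff")
  structure(list(current = as.numeric(current),
                 sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff,
                 t0 = t0),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  dur <- length(x$current) / x$sampling_rate
  cat(sprintf("<current_trace> %d samples at %g kHz (%.3f s)",
              length(x$current), x$sampling_rate / 1000, dur))
  if (!is.null(x$filter_cutoff))
    cat(sprintf(", Gaussian low-pass %g Hz", x$filter_cutoff))
  cat(sprintf("\n  current: %.3f .. %.3f pA\n",
              min(x$current), max(x$current)))
  invisible(x)
}

#' @export
length.current_trace <- function(x) length(x$current)

#' Sample times of a current trace
#' @param trace a `current_trace`.
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$current) - 1L) / trace$sampling_rate
}

# Discrete Gaussian low-pass kernel. The -3 dB cutoff fc of an analog
# Gaussian filter corresponds to a time-domain SD of 0.1325/fc; the kernel
# is truncated at +/- 5 SD and renormalized to unit sum.
gaussian_kernel <- function(filter_cutoff, sampling_rate) {
  sigma_s <- 0.1325 / filter_cutoff * sampling_rate # SD in samples
  half <- max(1L, ceiling(5 * sigma_s))
  k <- stats::dnorm(seq(-half, half), sd = sigma_s)
  k / sum(k)
}

#' Gaussian low-pass filter a sampled signal
#'
#' Discrete convolution with a Gaussian kernel whose -3 dB cutoff is
#' `filter_cutoff` (time-domain SD 0.1325/fc, truncated at 5 SD). Edges are
#' handled by replicating the first/last sample, so the output has the same
#' length as the input.
#'
#' @param x numeric signal, or a `current_trace`.
#' @param filter_cutoff -3 dB cutoff in Hz.
#' @param sampling_rate sampling rate in Hz (taken from the trace when `x`
#'   is a `current_trace`).
#' @return filtered signal of the same type as `x`; for a `current_trace`
#'   the `filter_cutoff` field is set.
#' @export
gaussian_filter <- function(x, filter_cutoff, sampling_rate = NULL) {
  if (inherits(x, "current_trace")) {
    y <- gaussian_filter(x$current, filter_cutoff, x$sampling_rate)
    out <- x
    out$current <- y
    out$filter_cutoff <- filter_cutoff
    return(out)
  }
  stop_if_not_scalar_pos(filter_cutoff, "filter_cutoff")
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  if (sampling_rate <= 2 * filter_cutoff)
    stop("sampling_rate must exceed 2 * filter_cutoff", call. = FALSE)
  k <- gaussian_kernel(filter_cutoff, sampling_rate)
  half <- (length(k) - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, k, method = "convolution", sides = 2L)
  as.numeric(y[(half + 1L):(half + length(x))])
}
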