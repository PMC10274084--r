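#' All-points histogram of a current trace
#'
#' Histogram of every digitized sample. Bin edges are aligned so that 0 pA
#' falls on an edge, making histograms comparable across recordings.
#'
#' @param trace a `current_trace` (or numeric vector of samples, pA).
#' @param bin_width bin width, pA.
#' @return an object of class `current_histogram`: list with `bin_edges`,
#'   `mids`, `counts`, `n_total`.
#' @export
all_points_histogram <- function(trace, bin_width = 0.1,
                                 .check_range = TRUE) {
  x <- if (inherits(trace, "current_trace")) trace$current else as.numeric(trace)
  stop_if_not_scalar_pos(bin_width, "bin_width")
  rng <- range(x)
  if (.check_range && bin_width > diff(rng) && diff(rng) > 0)
    stop("bin_width exceeds the data range", call. = FALSE)
  lo <- floor(rng[1] / bin_width) * bin_width
  hi <- ceiling(rng[2] / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + bin_width)
  # half-open [lo, hi) bins; top edge closed so every sample is binned
  idx <- pmin(findInterval(x, edges), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n_total = length(x)),
            class = "current_histogram")
}

#' @export
print.current_histogram <- function(x, ...) {
  cat(sprintf("<current_histogram> %d bins over [%.2f, %.2f] pA, %d samples\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges), x$n_total))
  invisible(x)
}

two_gaussian_fun <- function(I, A_O, I_O, w_O, A_C, I_C, w_C) {
  A_O * exp(-((I - I_O) / w_O)^2) + A_C * exp(-((I - I_C) / w_C)^2)
}

# Assemble a classed fit result; component closer to 0 pA is the closed level.
# `se` (named A1,I1,w1,A2,I2,w2) is relabeled to match the assignment.
make_two_gaussian_fit <- function(A1, I1, w1, A2, I2, w2, se = NULL,
                                  method = "two_gaussian") {
  one_is_closed <- abs(I1) <= abs(I2)
  if (one_is_closed) {
    cl <- c(A1, I1, w1); op <- c(A2, I2, w2)
  } else {
    cl <- c(A2, I2, w2); op <- c(A1, I1, w1)
  }
  if (!is.null(se) && all(c("A1", "I1", "w1", "A2", "I2", "w2") %in% names(se))) {
    ord <- if (one_is_closed) c("A2", "I2", "w2", "A1", "I1", "w1")
           else c("A1", "I1", "w1", "A2", "I2", "w2")
    se <- stats::setNames(se[ord],
                          c("A_O", "I_O", "w_O", "A_C", "I_C", "w_C"))
  }
  structure(list(A_O = op[1], I_O = op[2], w_O = op[3],
                 A_C = cl[1], I_C = cl[2], w_C = cl[3],
                 unitary_current = op[2] - cl[2],
                 se = se, method = method),
            class = "two_gaussian_fit")
}

#' @export
print.two_gaussian_fit <- function(x, ...) {
  cat(sprintf("Two-Gaussian amplitude fit (%s)\n", x$method))
  cat(sprintf("  open:   I_O = %.3f pA (w = %.3f)\n", x$I_O, x$w_O))
  cat(sprintf("  closed: I_C = %.3f pA (w = %.3f)\n", x$I_C, x$w_C))
  cat(sprintf("  unitary current: %.3f pA\n", x$unitary_current))
  invisible(x)
}

#' @export
coef.two_gaussian_fit <- function(object, ...) {
  c(A_O = object$A_O, I_O = object$I_O, w_O = object$w_O,
    A_C = object$A_C, I_C = object$I_C, w_C = object$w_C)
}

#' Unitary current from open and closed level means
#'
#' The open-minus-closed difference that defines the unitary current of a
#' two-component amplitude fit.
#'
#' @param I_O,I_C open and closed mean current levels, pA.
#' @return unitary current, pA.
#' @export
unitary_current <- function(I_O, I_C) I_O - I_C

# Local maxima of a count vector (plateau-tolerant), with simple prominence.
find_peaks <- function(counts, min_sep_bins = 4L, min_prom_frac = 0.02) {
  n <- length(counts)
  cand <- which(diff(sign(diff(c(-Inf, counts, -Inf)))) < 0)
  cand <- cand[counts[cand] > 0]
  if (!length(cand)) return(integer())
  cand <- cand[order(counts[cand], decreasing = TRUE)]
  keep <- integer()
  for (i in cand) {
    if (all(abs(i - keep) >= min_sep_bins)) keep <- c(keep, i)
  }
  thr <- min_prom_frac * counts[keep[1L]]
  keep[counts[keep] >= thr]
}

#' Fit a sum of two Gaussians to an all-points histogram
#'
#' Least-squares fit of
#' \deqn{f(I) = A_O \exp\{-[(I-I_O)/\omega_O]^2\} +
#'   A_C \exp\{-[(I-I_C)/\omega_C]^2\}}
#' to the counts (Poisson-weighted: weight 1/max(count, 1)). Initialization
#' takes the two largest well-separated local maxima; a histogram with no
#' resolvable second component is rejected with advice to use
#' [fit_log_tails()]. The width parameters are the Gaussian \eqn{\omega}
#' (sqrt(2) times the SD). The unitary current is I_O - I_C.
#'
#' @param hist a `current_histogram` with >= 8 nonzero bins.
#' @param min_peak_separation minimum separation of the two initial peaks, pA.
#' @return an object of class `two_gaussian_fit`.
#' @export
fit_two_gaussian <- function(hist, min_peak_separation = 1) {
  stopifnot(inherits(hist, "current_histogram"))
  if (sum(hist$counts > 0) < 8L)
    stop("need >= 8 nonzero bins", call. = FALSE)
  bw <- diff(hist$bin_edges[1:2])
  sep_bins <- max(2L, ceiling(min_peak_separation / bw))
  pk <- find_peaks(hist$counts, min_sep_bins = sep_bins)
  if (length(pk) < 2L)
    stop("open level unresolved; use fit_log_tails", call. = FALSE)
  pk <- pk[1:2]
  occ <- hist$counts > 0 # empty bins carry no Poisson information here
  d <- data.frame(I = hist$mids[occ], y = hist$counts[occ])
  w <- 1 / d$y
  st <- list(A1 = hist$counts[pk[1L]], I1 = hist$mids[pk[1L]], w1 = 3 * bw,
             A2 = hist$counts[pk[2L]], I2 = hist$mids[pk[2L]], w2 = 3 * bw)
  fit <- minpack.lm::nlsLM(
    y ~ A1 * exp(-((I - I1) / w1)^2) + A2 * exp(-((I - I2) / w2)^2),
    data = d, weights = w, start = st,
    lower = c(A1 = 0, I1 = min(d$I), w1 = bw / 10,
              A2 = 0, I2 = min(d$I), w2 = bw / 10),
    upper = c(A1 = Inf, I1 = max(d$I), w1 = diff(range(d$I)),
              A2 = Inf, I2 = max(d$I), w2 = diff(range(d$I))),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  make_two_gaussian_fit(cf[["A1"]], cf[["I1"]], cf[["w1"]],
                        cf[["A2"]], cf[["I2"]], cf[["w2"]],
                        se = se, method = "two_gaussian")
}

# Parabola fit to log counts of a set of bins: log f = a + b I + c I^2 with
# c < 0 corresponds to a Gaussian with mean -b/(2c), omega sqrt(-1/c).
fit_log_parabola <- function(mids, counts) {
  ok <- counts > 0
  if (sum(ok) < 4L) stop("fewer than 4 nonzero bins in a tail", call. = FALSE)
  x <- mids[ok]; y <- log(counts[ok])
  # var(log count) ~ 1/count by the delta method: weight sparse tail bins down
  fit <- stats::lm(y ~ x + I(x^2), weights = counts[ok])
  cf <- stats::coef(fit)
  c2 <- cf[[3L]]
  if (!is.finite(c2) || c2 >= 0) {
    # tail too flat/short for curvature: fall back to weighted moment estimate
    wt <- counts[ok]
    mu <- sum(x * wt) / sum(wt)
    return(list(mean = mu, w = sqrt(2) * sqrt(sum(wt * (x - mu)^2) / sum(wt)),
                A = max(counts[ok])))
  }
  mu <- -cf[[2L]] / (2 * c2)
  list(mean = mu, w = sqrt(-1 / c2), A = exp(cf[[1L]] - cf[[2L]]^2 / (4 * c2)))
}

#' Estimate current levels from the semi-logarithmic histogram tails
#'
#' For low-Po records with brief openings, the open-level peak of the
#' all-points histogram is buried under open-closed transition samples. On
#' semi-logarithmic coordinates the extreme falls of the histogram are the
#' tails of the closed- and open-level Gaussians; fitting a parabola to
#' log(counts) of the outermost occupied bins on each side recovers the
#' component means without the transition shoulder.
#'
#' Each tail window runs inward from the histogram end up to at most
#' `tail_fraction` of the occupied bins, and is truncated one bin beyond the
#' outermost local count maximum (the level apex), so the fit sees only the
#' rapid fall-off of that level's Gaussian and never the shoulder.
#'
#' @param hist a `current_histogram` with occupied extreme tails.
#' @param tail_fraction maximum fraction of occupied bins (per side) in each
#'   tail fit; zero-count bins are skipped, never given pseudo-counts.
#' @return an object of class `two_gaussian_fit` (method `"log_tails"`).
#' @export
fit_log_tails <- function(hist, tail_fraction = 0.15) {
  stopifnot(inherits(hist, "current_histogram"))
  if (!(tail_fraction > 0 && tail_fraction < 0.5))
    stop("tail_fraction must be in (0, 0.5)", call. = FALSE)
  occ <- which(hist$counts > 0)
  if (length(occ) < 8L) stop("too few occupied bins", call. = FALSE)
  n_tail <- max(4L, ceiling(tail_fraction * length(occ)))
  tail_idx <- function(side) {
    o <- if (side == "upper") rev(occ) else occ
    # find the outermost count maximum that is interior to the search
    # window, growing the window when the counts are still rising at its
    # inner edge; truncate one bin beyond that apex so the parabola sees
    # only this level's falling flank, never the transition shoulder
    width <- n_tail
    repeat {
      cand <- o[seq_len(min(width, length(o)))]
      apex <- which.max(hist$counts[cand])
      if (apex < length(cand) || length(cand) == length(o)) break
      width <- 2L * width
    }
    depth <- min(max(4L, apex + 1L), length(o))
    o[seq_len(depth)]
  }
  lo_idx <- tail_idx("lower")
  hi_idx <- tail_idx("upper")
  lo <- fit_log_parabola(hist$mids[lo_idx], hist$counts[lo_idx])
  hi <- fit_log_parabola(hist$mids[hi_idx], hist$counts[hi_idx])
  make_two_gaussian_fit(lo$A, lo$mean, lo$w, hi$A, hi$mean, hi$w,
                        method = "log_tails")
}

#' Measure per-event amplitudes from the raw trace
#'
#' For each open event, the amplitude is the mean current over the event
#' trimmed by one dead time after the opening threshold crossing and one
#' dead time before the closing crossing, minus the adjacent closed
#' baseline; events shorter than twice the dead time use the current at the
#' event midpoint instead. The baseline is the mean of the flanking closed
#' segments (each trimmed by a dead time on both sides); when both flanks
#' are shorter than two dead times the global closed-level mean is used.
#'
#' @param trace the `current_trace` the events were idealized from.
#' @param events an [event_list()] with `dead_time` set.
#' @return the event list with the `amplitude` column filled for open
#'   events (pA).
#' @export
event_amplitudes <- function(trace, events) {
  stopifnot(inherits(trace, "current_trace"), inherits(events, "event_list"))
  td <- attr(events, "dead_time")
  if (!is.finite(td)) stop("events carry no dead_time", call. = FALSE)
  sr <- trace$sampling_rate
  n <- length(trace$current)
  ends <- events$start + events$duration
  if (any(events$start < trace$t0 - 1e-12) ||
      any(ends > trace$t0 + n / sr + 1e-9))
    stop("event beyond trace bounds", call. = FALSE)
  idx_of <- function(t) pmax(1L, pmin(n, as.integer(round((t - trace$t0) * sr)) + 1L))
  seg_mean <- function(t1, t2) {
    i1 <- idx_of(t1); i2 <- idx_of(t2)
    if (i2 < i1) return(NA_real_)
    mean(trace$current[i1:i2])
  }
  closed <- events$level == 0L
  global_closed <- if (any(closed)) {
    idx <- unlist(lapply(which(closed), function(k)
      idx_of(events$start[k]):idx_of(ends[k])))
    mean(trace$current[idx])
  } else NA_real_
  amp <- events$amplitude
  for (k in which(events$level >= 1L)) {
    # flanking closed baseline, trimmed by a dead time on each side
    bvals <- c()
    if (k > 1L && events$level[k - 1L] == 0L &&
        events$duration[k - 1L] >= 2 * td) {
      bvals <- c(bvals, seg_mean(events$start[k - 1L] + td, ends[k - 1L] - td))
    }
    if (k < nrow(events) && events$level[k + 1L] == 0L &&
        events$duration[k + 1L] >= 2 * td) {
      bvals <- c(bvals, seg_mean(events$start[k + 1L] + td, ends[k + 1L] - td))
    }
    base <- if (length(bvals)) mean(bvals) else global_closed
    if (!is.finite(base)) base <- 0
    if (events$duration[k] < 2 * td) {
      mid <- events$start[k] + events$duration[k] / 2
      amp[k] <- trace$current[idx_of(mid)] - base
    } else {
      amp[k] <- seg_mean(events$start[k] + td, ends[k] - td) - base
    }
  }
  events$amplitude <- amp
  events
}

#' Histogram of open-event amplitudes above a duration cutoff
#'
#' Brief filtered openings have attenuated amplitudes (50% at one dead time,
#' near-complete by four); a duration cutoff of six dead times (1.074 ms at
#' 1 kHz) restricts the histogram to events that reached full amplitude with
#' several samples to average.
#'
#' @param events an [event_list()] with measured amplitudes.
#' @param min_duration inclusion cutoff, s; defaults to 6 x dead time.
#' @param bin_width histogram bin width, pA.
#' @param normalize scale the histogram to unit area.
#' @return list with `histogram` (`current_histogram` or `NULL` when no
#'   event qualifies), `mean`, `sd`, `n`, `density` (when normalized).
#' @export
amplitude_histogram <- function(events, min_duration = NULL, bin_width = 0.5,
                                normalize = FALSE) {
  stopifnot(inherits(events, "event_list"))
  td <- attr(events, "dead_time")
  min_duration <- min_duration %||% (6 * td)
  if (!is.finite(min_duration) || min_duration < 0)
    stop("min_duration must be >= 0 (is dead_time set?)", call. = FALSE)
  sel <- events$level >= 1L & events$duration > min_duration &
    is.finite(events$amplitude)
  a <- events$amplitude[sel]
  if (!length(a))
    return(list(histogram = NULL, mean = NA_real_, sd = NA_real_, n = 0L))
  h <- all_points_histogram(a, bin_width, .check_range = FALSE)
  out <- list(histogram = h, mean = mean(a),
              sd = if (length(a) > 1L) stats::sd(a) else NA_real_,
              n = length(a))
  if (normalize) out$density <- h$counts / (sum(h$counts) * bin_width)
  out
}
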