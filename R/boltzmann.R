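#' Boltzmann gating parameters
#'
#' Parameters of the voltage dependence of open probability,
#' \deqn{Po(V) = Pomax / \{1 + \exp[z\delta (V - V_{1/2}) / k_B T]\},}
#' with `z_delta` the effective gating valence (e0), `V_half` the
#' half-maximal voltage (mV) and `Pomax` the maximal open probability.
#' With this sign convention Po falls with depolarization, as for
#' selectivity-filter (inactivation-type) gating.
#'
#' @param Pomax maximal open probability, in (0, 1].
#' @param z_delta effective gating valence, e0.
#' @param V_half half-maximal voltage, mV.
#' @param temperature temperature, K.
#' @return an object of class `boltzmann_params`.
#' @export
boltzmann_params <- function(Pomax, z_delta, V_half, temperature = 295) {
  if (!(Pomax > 0 && Pomax <= 1)) stop("Pomax must be in (0, 1]", call. = FALSE)
  stop_if_not_scalar_pos(temperature, "temperature")
  structure(list(Pomax = Pomax, z_delta = z_delta, V_half = V_half,
                 temperature = temperature),
            class = "boltzmann_params")
}

#' Boltzmann open-probability curve
#'
#' @param voltage voltage(s), mV.
#' @param params a [boltzmann_params()].
#' @return open probability at each voltage.
#' @export
boltzmann_po <- function(voltage, params) {
  stopifnot(inherits(params, "boltzmann_params"))
  kt <- kT_mV(params$temperature)
  params$Pomax / (1 + exp(params$z_delta * (voltage - params$V_half) / kt))
}

#' E-fold slope of a Boltzmann curve
#'
#' Millivolts of depolarization per e-fold change of the Boltzmann factor:
#' \eqn{k_B T / (z\delta e)}.
#'
#' @param z_delta effective gating valence, e0.
#' @param temperature temperature, K.
#' @return slope in mV per e-fold.
#' @export
efold_slope <- function(z_delta, temperature = 295) {
  kT_mV(temperature) / z_delta
}

#' Fit the Boltzmann open-probability equation to Po-voltage data
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of
#' \eqn{Po(V) = Pomax/\{1+\exp[z\delta(V-V_{1/2})/k_BT]\}}. When per-point
#' SEMs are available and `weighted = TRUE`, weights are 1/SEM^2 (points
#' with zero or missing SEM get the median weight). The fit restarts from a
#' deterministic 8-point grid of initial values and keeps the solution with
#' the lowest residual sum of squares (ties broken by lower z_delta).
#'
#' @param data a `pov_data` data.frame (columns `voltage`, `po_mean`,
#'   optionally `po_sem`), or any data.frame with those columns.
#' @param temperature temperature (K) at which the curve is interpreted.
#' @param weighted use 1/SEM^2 weights when SEMs are available.
#' @return an object of class `boltzmann_fit`: list with `params`
#'   (a [boltzmann_params()]), `se` (asymptotic standard errors),
#'   `efold_mV`, `fit` (the underlying `nls` object), `data`.
#' @examples
#' p <- boltzmann_params(0.95, kT_mV(295) / 14, 190)
#' d <- simulate_po_voltage(p, seq(100, 280, 10), 1000, 5, seed = 1)
#' fit_boltzmann(d)
#' @export
fit_boltzmann <- function(data, temperature = 295, weighted = TRUE) {
  stopifnot(all(c("voltage", "po_mean") %in% names(data)))
  d <- data.frame(V = data$voltage, po = data$po_mean)
  if (nrow(d) < 4L)
    stop("need >= 4 voltage points spanning the transition", call. = FALSE)
  kt <- kT_mV(temperature)
  w <- rep(1, nrow(d))
  if (weighted && "po_sem" %in% names(data)) {
    sem <- data$po_sem
    wi <- ifelse(is.finite(sem) & sem > 0, 1 / sem^2, NA)
    if (any(is.finite(wi)))
      w <- ifelse(is.finite(wi), wi, stats::median(wi, na.rm = TRUE))
  }
  vr <- range(d$V)
  starts <- expand.grid(
    V_half = stats::quantile(d$V, c(0.25, 0.5, 0.75, 0.9), names = FALSE),
    z_delta = c(0.5, 2))
  pomax0 <- min(1, max(d$po) + 1e-6)
  best <- NULL; best_rss <- Inf; best_z <- Inf; last_err <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        po ~ Pomax / (1 + exp(z_delta * (V - V_half) / kt)),
        data = d, weights = w,
        start = list(Pomax = pomax0, z_delta = starts$z_delta[i],
                     V_half = starts$V_half[i]),
        lower = c(Pomax = 1e-6, z_delta = 1e-6, V_half = vr[1] - diff(vr)),
        upper = c(Pomax = 1, z_delta = 50, V_half = vr[2] + diff(vr)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) { last_err <- fit; next }
    rss <- sum(w * stats::residuals(fit)^2)
    z <- stats::coef(fit)[["z_delta"]]
    if (rss < best_rss - 1e-12 ||
        (abs(rss - best_rss) <= 1e-12 && z < best_z)) {
      best <- fit; best_rss <- rss; best_z <- z
    }
  }
  if (is.null(best))
    stop("Boltzmann fit failed to converge from all starts: ",
         conditionMessage(last_err), call. = FALSE)
  cf <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  structure(list(
    params = boltzmann_params(cf[["Pomax"]], cf[["z_delta"]], cf[["V_half"]],
                              temperature),
    se = se,
    efold_mV = efold_slope(cf[["z_delta"]], temperature),
    fit = best, data = d),
    class = "boltzmann_fit")
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  p <- object$params
  c(Pomax = p$Pomax, z_delta = p$z_delta, V_half = p$V_half)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  p <- x$params
  cat("Boltzmann open-probability fit\n")
  cat(sprintf("  Pomax   = %.4f\n  z_delta = %.3f e0\n  V_half  = %.1f mV\n",
              p$Pomax, p$z_delta, p$V_half))
  cat(sprintf("  e-fold slope = %.2f mV (at %g K)\n", x$efold_mV,
              p$temperature))
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  out <- data.frame(estimate = coef(object),
                    se = object$se[names(coef(object))])
  cat("Boltzmann open-probability fit (weighted least squares)\n")
  print(out)
  cat(sprintf("e-fold slope: %.2f mV per e-fold at %g K\n",
              object$efold_mV, object$params$temperature))
  invisible(out)
}

#' @export
predict.boltzmann_fit <- function(object, voltage = NULL, ...) {
  voltage <- voltage %||% object$data$V
  boltzmann_po(voltage, object$params)
}
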