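# Diagnostic plots, base graphics.

#' Plot a rate separation as the fitted line through the lag conditions
#'
#' Draws `k_eff * tau_TL` against `tau_TL` with the weighted linear fit
#' whose slope is `k_off` and intercept `k_bleach * tau_int`, with
#' error bars from the per-condition SDs.
#'
#' @param x a [separate_rates()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rate_separation <- function(x, ...) {
  y <- x$k_eff * x$tau_TL
  sy <- x$k_eff_sd * x$tau_TL
  graphics::plot(x$tau_TL, y, pch = 19,
                 xlab = expression(tau[TL] ~ "(s)"),
                 ylab = expression(k[eff] %*% tau[TL]),
                 xlim = c(0, max(x$tau_TL) * 1.1),
                 ylim = range(0, y + sy, y - sy), ...)
  ok <- is.finite(sy)
  graphics::arrows(x$tau_TL[ok], (y - sy)[ok], x$tau_TL[ok],
                   (y + sy)[ok], angle = 90, code = 3, length = 0.03)
  graphics::abline(a = x$k_bleach * x$tau_int, b = x$k_off, col = 2)
  invisible(x)
}

#' Survival curve of effective residence times
#'
#' Plots the empirical survival of `t_eff` values on a log count axis,
#' optionally overlaying mono- or bi-exponential fits.
#'
#' @param residence_times numeric vector of residence times, s.
#' @param fit optional `exp_fit` or `biexp_fit` to overlay.
#' @param ... passed to [graphics::plot()].
#' @return invisible `NULL`.
#' @export
plot_residence_survival <- function(residence_times, fit = NULL, ...) {
  t <- sort(residence_times[residence_times > 0])
  n <- length(t)
  surv <- (n:1) / n
  graphics::plot(t, surv, log = "y", type = "s",
                 xlab = "effective residence time (s)",
                 ylab = "fraction surviving", ...)
  if (!is.null(fit)) {
    tt <- seq(min(t), max(t), length.out = 200)
    s <- if (inherits(fit, "biexp_fit")) {
      fit$fast_fraction * exp(-fit$k_eff_fast * tt) +
        (1 - fit$fast_fraction) * exp(-fit$k_eff_slow * tt)
    } else {
      exp(-fit$k_eff * tt)
    }
    graphics::lines(tt, s / s[1] * surv[1], col = 2)
  }
  invisible(NULL)
}
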