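# Dissociation kinetics: exponential residence-time fits on the discrete
# frame grid and the separation of dissociation from photobleaching.
#
# Track lifetimes are observed as frame counts, so the natural likelihood
# is geometric: a track of n localizations survived n-1 frame-to-frame
# transitions, each with probability exp(-k_eff * tau_TL). Maximising the
# geometric likelihood is binning-free and converges to the continuous
# exponential MLE as tau_TL -> 0. Fits condition on usable tracks
# (t_eff > 0, i.e. n >= 2), since single-frame tracks carry no rate
# information.

# survival probability per frame interval for a given effective rate
.surv <- function(k_eff, tau_TL) exp(-k_eff * tau_TL)

# residence times (s) -> tabulated frame-interval counts m = n-1 >= 1
.res_to_counts <- function(residence_times, tau_TL, min_n) {
  if (!length(residence_times)) {
    stop("no residence times supplied", call. = FALSE)
  }
  if (any(residence_times < -1e-9)) {
    stop("residence times must be non-negative", call. = FALSE)
  }
  m <- round(residence_times / tau_TL)
  if (any(abs(m * tau_TL - residence_times) > 1e-6 * tau_TL + 1e-12)) {
    stop("residence times must be multiples of `tau_TL`", call. = FALSE)
  }
  m <- m[m >= max(1, min_n - 1)]
  tab <- table(m)
  list(m = as.numeric(names(tab)), count = as.numeric(tab),
       n_used = length(m),
       n_censored = sum(round(residence_times / tau_TL) < max(1, min_n - 1)))
}

#' Fit a mono-exponential residence-time distribution
#'
#' Maximum-likelihood fit of `f(t) = A * exp(-k_eff * t)` to effective
#' residence times observed on the discrete grid `t = m * tau_TL`
#' (geometric likelihood on frame counts). The standard deviation of
#' `k_eff` comes from the observed Fisher information.
#'
#' @param residence_times numeric vector of effective residence times,
#'   s; must be non-negative multiples of `tau_TL`.
#' @param tau_TL time-lapse period, s.
#' @param min_n minimum track length (number of localizations) for a
#'   track to enter the fit; default 2, i.e. `t_eff > 0`.
#' @param method `"mle"` (default, geometric maximum likelihood) or
#'   `"ls_loghist"`, an unweighted least-squares line through the log
#'   of the residence-time histogram — the classic alternative,
#'   provided for comparison only.
#' @return An object of class `"exp_fit"`: list with `k_eff`, `k_eff_sd`
#'   (1/s), `amplitude` (number of fitted tracks), `n_tracks`,
#'   `n_censored` (tracks below `min_n`), `log_likelihood`, `tau_TL`.
#' @examples
#' set.seed(1)
#' t_eff <- (rgeom(5000, 1 - exp(-1 * 0.02)) + 1) * 0.02
#' fit_monoexponential(t_eff, tau_TL = 0.02)$k_eff  # ~1
#' @export
fit_monoexponential <- function(residence_times, tau_TL, min_n = 2,
                                method = c("mle", "ls_loghist")) {
  method <- match.arg(method)
  check_number(tau_TL, "tau_TL", lower = 1e-12)
  check_number(min_n, "min_n", lower = 1)
  dat <- .res_to_counts(residence_times, tau_TL, min_n)
  if (dat$n_used < 10) {
    stop(sprintf("only %d usable tracks (need >= 10)", dat$n_used),
         call. = FALSE)
  }
  if (method == "ls_loghist") {
    if (length(dat$m) < 3) {
      stop("too few distinct residence times for a histogram fit",
           call. = FALSE)
    }
    fit <- lm(log(dat$count) ~ I(dat$m * tau_TL))
    sm <- suppressWarnings(summary(fit))
    k_eff <- -unname(coef(fit)[2])
    if (k_eff <= 0) stop("histogram fit found no decay", call. = FALSE)
    return(structure(list(k_eff = k_eff,
                          k_eff_sd = sm$coefficients[2, 2],
                          amplitude = exp(unname(coef(fit)[1])),
                          n_tracks = dat$n_used,
                          n_censored = dat$n_censored,
                          log_likelihood = NA_real_, tau_TL = tau_TL),
                     class = "exp_fit"))
  }
  mbar <- sum(dat$m * dat$count) / dat$n_used
  if (mbar <= 1) {
    stop("degenerate sample: no decay information (all tracks minimal length)",
         call. = FALSE)
  }
  if (length(dat$m) == 1L) {
    stop("degenerate sample: all residence times identical", call. = FALSE)
  }
  s <- 1 - 1 / mbar                       # MLE of per-frame survival
  k_eff <- -log(s) / tau_TL
  # observed information for k: I = N * tau^2 * s / (1-s)^2
  info <- dat$n_used * tau_TL^2 * s / (1 - s)^2
  ll <- sum(dat$count * ((dat$m - 1) * log(s) + log(1 - s)))
  structure(list(k_eff = k_eff, k_eff_sd = 1 / sqrt(info),
                 amplitude = dat$n_used, n_tracks = dat$n_used,
                 n_censored = dat$n_censored, log_likelihood = ll,
                 tau_TL = tau_TL),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential residence fit: k_eff = %.4g +/- %.3g 1/s (n = %d, tau_TL = %g s)\n",
              x$k_eff, x$k_eff_sd, x$n_tracks, x$tau_TL))
  invisible(x)
}

# negative log-likelihood of the two-component geometric mixture in
# th = (log k_fast, log k_slow, logit fast_fraction)
.biexp_nll <- function(th, m, count, tau_TL) {
  kf <- exp(th[1]); ks <- exp(th[2]); f <- plogis(th[3])
  s1 <- .surv(kf, tau_TL); s2 <- .surv(ks, tau_TL)
  v <- f * s1^(m - 1) * (1 - s1) + (1 - f) * s2^(m - 1) * (1 - s2)
  -sum(count * log(pmax(v, 1e-300)))
}

#' Fit a bi-exponential residence-time distribution
#'
#' Two-component exponential mixture fitted by maximum likelihood on the
#' discrete frame grid, via expectation-maximisation from
#' `n_restarts` random starting points followed by a quasi-Newton
#' polish. Components are ordered so that the reported fast rate is the
#' larger one; per-parameter SDs come from the numerical Hessian at the
#' optimum. When the two fitted rates are within 5% of each other the
#' mixture is unidentifiable and the result collapses to the
#' mono-exponential fit with a warning.
#'
#' @inheritParams fit_monoexponential
#' @param n_restarts number of random EM restarts (default 20).
#' @param seed integer seed for the restarts (deterministic fits).
#' @param trim_quantile optional upper quantile (e.g. `0.995`) beyond
#'   which residence times are discarded before fitting; the rare
#'   ultra-slow tail carries too few tracks for a reliable rate and is
#'   out of fitting scope. Default `NULL` (off).
#' @return An object of class `"biexp_fit"`: `k_eff_fast`, `k_eff_slow`,
#'   `fast_fraction` and their SDs, `n_tracks`, `log_likelihood`,
#'   `converged`, `collapsed`, `tau_TL`.
#' @examples
#' set.seed(1)
#' m <- c(rgeom(3000, 1 - exp(-5 * 0.02)), rgeom(3000, 1 - exp(-0.5 * 0.02)))
#' fit <- fit_biexponential((m + 1) * 0.02, tau_TL = 0.02, seed = 1)
#' c(fit$k_eff_fast, fit$k_eff_slow)  # ~5, ~0.5
#' @export
fit_biexponential <- function(residence_times, tau_TL, min_n = 2,
                              n_restarts = 20, seed = NULL,
                              trim_quantile = NULL) {
  check_number(tau_TL, "tau_TL", lower = 1e-12)
  if (!is.null(trim_quantile)) {
    check_number(trim_quantile, "trim_quantile", lower = 0.5, upper = 1)
    residence_times <-
      residence_times[residence_times <=
                        quantile(residence_times, trim_quantile)]
  }
  dat <- .res_to_counts(residence_times, tau_TL, min_n)
  if (dat$n_used < 100) {
    stop(sprintf("only %d usable tracks (need >= 100 for a mixture fit)",
                 dat$n_used), call. = FALSE)
  }
  mono <- fit_monoexponential(residence_times, tau_TL, min_n)
  m <- dat$m; count <- dat$count; N <- dat$n_used

  em_once <- function(k1, k2, f) {
    s1 <- .surv(k1, tau_TL); s2 <- .surv(k2, tau_TL)
    ll_old <- -Inf; ll <- -Inf
    for (it in seq_len(500)) {
      d1 <- f * s1^(m - 1) * (1 - s1)
      d2 <- (1 - f) * s2^(m - 1) * (1 - s2)
      tot <- pmax(d1 + d2, 1e-300)
      ll <- sum(count * log(tot))
      r1 <- d1 / tot
      w1 <- sum(count * r1); w2 <- N - w1
      if (w1 < 1e-9 || w2 < 1e-9) break
      s1 <- max(min(1 - w1 / sum(count * r1 * m), 1 - 1e-12), 1e-12)
      s2 <- max(min(1 - w2 / sum(count * (1 - r1) * m), 1 - 1e-12), 1e-12)
      f <- w1 / N
      if (it > 5 && ll - ll_old < 1e-9) break
      ll_old <- ll
    }
    k1 <- -log(s1) / tau_TL; k2 <- -log(s2) / tau_TL
    list(ll = ll,
         th = c(log(max(k1, k2)), log(min(k1, k2)),
                qlogis(min(max(if (k1 >= k2) f else 1 - f, 1e-9),
                           1 - 1e-9))))
  }

  best <- with_seed(seed, {
    b <- NULL
    for (r in seq_len(n_restarts)) {
      cand <- em_once(mono$k_eff * exp(runif(1, 0.05, 1.2)),
                      mono$k_eff * exp(runif(1, -1.2, -0.05)),
                      runif(1, 0.2, 0.8))
      if (is.null(b) || cand$ll > b$ll) b <- cand
    }
    b
  })
  op <- optim(best$th, .biexp_nll, m = m, count = count, tau_TL = tau_TL,
              method = "BFGS", control = list(maxit = 300))
  converged <- op$convergence == 0
  th <- op$par
  if (-op$value < best$ll) th <- best$th    # keep EM optimum if better
  kf <- exp(th[1]); ks <- exp(th[2]); f <- plogis(th[3])
  if (kf < ks) {                            # enforce fast > slow
    tmp <- kf; kf <- ks; ks <- tmp; f <- 1 - f
    th <- c(log(kf), log(ks), qlogis(f))
  }

  sds <- c(NA_real_, NA_real_, NA_real_)
  H <- try(optimHess(th, .biexp_nll, m = m, count = count,
                     tau_TL = tau_TL), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(is.finite(diag(V))) &&
        all(diag(V) > 0)) {
      sds <- sqrt(diag(V))
    }
  }
  if (anyNA(sds[1:2])) {
    # Hessian unusable (near-singular mixture): fall back to the
    # single-geometric information with the component's effective
    # sample size N * weight; the mixture fraction SD stays NA so the
    # fraction carries no weight downstream.
    info_sd <- function(k, nn) {
      s <- .surv(k, tau_TL)
      (1 - s) / (tau_TL * sqrt(max(nn, 1) * s))
    }
    if (is.na(sds[1])) sds[1] <- info_sd(kf, N * f) / kf
    if (is.na(sds[2])) sds[2] <- info_sd(ks, N * (1 - f)) / ks
  }

  # Unidentifiability guard: components (almost) equal, or the mixture
  # explains the data no better than the nested mono-exponential
  # (likelihood-ratio gain below the chi^2_2 99% bound). Collapsed
  # fits report the mono rate for both components with *uninformative*
  # SDs, so they carry no weight in a downstream rate separation.
  ll_bi <- -.biexp_nll(th, m, count, tau_TL)
  collapsed <- (kf - ks) / ks < 0.05 ||
    2 * (ll_bi - mono$log_likelihood) < stats::qchisq(0.99, 2)
  if (collapsed) {
    warning("fitted components within 5% of each other or no better ",
            "than a single exponential; mixture is unidentifiable, ",
            "collapsing to mono-exponential")
    kf <- ks <- mono$k_eff
    sds <- c(Inf, Inf, NA_real_)
  }
  structure(list(k_eff_fast = kf, k_eff_slow = ks, fast_fraction = f,
                 k_eff_fast_sd = sds[1] * kf, k_eff_slow_sd = sds[2] * ks,
                 fast_fraction_sd = sds[3] * f * (1 - f),
                 n_tracks = N, n_censored = dat$n_censored,
                 log_likelihood = -.biexp_nll(th, m, count, tau_TL),
                 converged = converged, collapsed = collapsed,
                 tau_TL = tau_TL),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(paste0("Bi-exponential residence fit (tau_TL = %g s, n = %d)\n",
                     "  k_eff fast = %.4g +/- %.3g 1/s\n",
                     "  k_eff slow = %.4g +/- %.3g 1/s\n",
                     "  fast fraction = %.3f%s\n"),
              x$tau_TL, x$n_tracks, x$k_eff_fast, x$k_eff_fast_sd,
              x$k_eff_slow, x$k_eff_slow_sd, x$fast_fraction,
              if (x$collapsed) "  [collapsed]" else ""))
  invisible(x)
}

#' Bundle a fitted effective rate with its imaging condition
#'
#' @param tau_int integration time, s.
#' @param tau_TL time-lapse period, s (>= `tau_int`).
#' @param k_eff fitted effective rate, 1/s (> 0).
#' @param k_eff_sd its standard deviation, 1/s (> 0).
#' @return An object of class `"time_lapse_condition"`.
#' @export
time_lapse_condition <- function(tau_int, tau_TL, k_eff, k_eff_sd) {
  check_number(tau_int, "tau_int", lower = 1e-12)
  check_number(tau_TL, "tau_TL", lower = tau_int)
  check_number(k_eff, "k_eff", lower = 1e-300)
  # an SD of Inf (or NA, treated as Inf) marks an uninformative fit that
  # gets zero weight in the separation
  if (length(k_eff_sd) != 1L || !is.numeric(k_eff_sd)) {
    stop("`k_eff_sd` must be a single number", call. = FALSE)
  }
  if (is.na(k_eff_sd)) k_eff_sd <- Inf
  if (k_eff_sd <= 0) stop("`k_eff_sd` must be > 0", call. = FALSE)
  structure(list(tau_int = tau_int, tau_TL = tau_TL, k_eff = k_eff,
                 k_eff_sd = k_eff_sd), class = "time_lapse_condition")
}

#' Separate dissociation from photobleaching across time-lapse periods
#'
#' The effective disappearance rate of tracked molecules combines true
#' dissociation (continuous in time) with photobleaching (active only
#' during camera integration):
#' `k_eff * tau_TL = k_bleach * tau_int + k_off * tau_TL`.
#' A weighted linear fit of `y = k_eff * tau_TL` against `tau_TL`
#' (weights `1/sigma_y^2`, with `sigma_y` propagated from the per-fit
#' `k_eff` SDs) therefore yields `k_off` as the slope and
#' `k_bleach * tau_int` as the intercept.
#'
#' @param conditions list of [time_lapse_condition()] objects with at
#'   least 2 distinct `tau_TL` values and a shared `tau_int`.
#' @return An object of class `"rate_separation"`: `k_off`, `k_bleach`,
#'   `t_off = 1/k_off` (s), `k_off_sd`, `k_bleach_sd`, `clamped` (TRUE
#'   when a negative fitted slope was clamped to 0), plus the fit
#'   inputs.
#' @examples
#' tls <- c(0.02, 0.12, 0.22)
#' keff <- 2 * 0.02 / tls + 0.5        # k_bleach = 2, k_off = 0.5
#' conds <- lapply(seq_along(tls), function(i)
#'   time_lapse_condition(0.02, tls[i], keff[i], 0.01))
#' separate_rates(conds)$k_off  # 0.5
#' @export
separate_rates <- function(conditions) {
  stopifnot(is.list(conditions))
  for (cond in conditions) {
    if (!inherits(cond, "time_lapse_condition")) {
      stop("`conditions` must be time_lapse_condition objects",
           call. = FALSE)
    }
  }
  tls <- vapply(conditions, `[[`, numeric(1), "tau_TL")
  tis <- vapply(conditions, `[[`, numeric(1), "tau_int")
  ke <- vapply(conditions, `[[`, numeric(1), "k_eff")
  kesd <- vapply(conditions, `[[`, numeric(1), "k_eff_sd")
  if (length(unique(round(tis, 12))) != 1L) {
    stop("all conditions must share the same `tau_int`", call. = FALSE)
  }
  if (length(unique(round(tls, 12))) < 2L) {
    stop("need >= 2 distinct `tau_TL` values to separate the rates",
         call. = FALSE)
  }
  tau_int <- tis[1]
  y <- ke * tls
  sigma_y <- kesd * tls
  w <- 1 / sigma_y^2
  ok <- is.finite(w) & w > 0
  if (sum(ok) < 2L) stop("fewer than 2 usable conditions", call. = FALSE)
  fit <- lm(y ~ tls, weights = w, subset = ok)
  cf <- coef(fit)
  se <- sqrt(diag(vcov_wls(fit)))
  k_off <- unname(cf[2]); k_bleach <- unname(cf[1]) / tau_int
  clamped <- FALSE
  if (k_off < 0) {
    k_off <- 0
    clamped <- TRUE
  }
  structure(list(k_off = k_off, k_bleach = max(k_bleach, 0),
                 t_off = if (k_off > 0) 1 / k_off else Inf,
                 k_off_sd = unname(se[2]),
                 k_bleach_sd = unname(se[1]) / tau_int,
                 clamped = clamped, tau_int = tau_int, tau_TL = tls,
                 k_eff = ke, k_eff_sd = kesd, weights = w),
            class = "rate_separation")
}

# Variance of WLS coefficients with *known* weights (1/sigma^2), i.e.
# without rescaling by the residual variance; with only 2-3 conditions
# the residual-based estimate would be meaningless.
vcov_wls <- function(fit) {
  X <- stats::model.matrix(fit)
  w <- fit$weights
  solve(t(X) %*% (X * w))
}

#' @export
print.rate_separation <- function(x, ...) {
  cat(sprintf(paste0("Rate separation over %d time-lapse conditions\n",
                     "  k_off    = %.4g +/- %.3g 1/s  (t_off = %.3g s)%s\n",
                     "  k_bleach = %.4g +/- %.3g 1/s\n"),
              length(x$tau_TL), x$k_off, x$k_off_sd, x$t_off,
              if (x$clamped) "  [clamped at 0]" else "",
              x$k_bleach, x$k_bleach_sd))
  invisible(x)
}

#' Tabulate residence times of fast and slow subpopulations
#'
#' Summarises one strain's dissociation analysis: residence times of the
#' fast and slow components, their rate ratio, and (optionally) the
#' fold-change of the fast rate relative to a reference strain.
#'
#' @param label strain label.
#' @param fast,slow [separate_rates()] results for the fast and slow
#'   components (`slow` may be `NULL` for a single-population strain).
#' @param reference optional `dissociation_report` to compare against.
#' @return An object of class `"dissociation_report"` (a data.frame row
#'   set) with columns `strain`, `t_off_fast_s`, `t_off_slow_s`,
#'   `slow_fast_ratio` (ratio of the two dissociation rates) and
#'   `fast_vs_reference` (this strain's fast rate over the reference's).
#' @examples
#' # ratio of rates for residence times 1.1 s and 3.1 s: 3.1/1.1 = 2.8
#' @export
dissociation_report <- function(label, fast, slow = NULL,
                                reference = NULL) {
  stopifnot(inherits(fast, "rate_separation"))
  t_fast <- fast$t_off
  t_slow <- if (!is.null(slow)) {
    stopifnot(inherits(slow, "rate_separation"))
    slow$t_off
  } else {
    NA_real_
  }
  ratio <- if (is.finite(t_slow)) t_slow / t_fast else NA_real_
  ref_ratio <- NA_real_
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "dissociation_report"))
    ref_ratio <- t_fast / reference$t_off_fast_s[1]
  }
  out <- data.frame(strain = label, t_off_fast_s = t_fast,
                    t_off_slow_s = t_slow, slow_fast_ratio = ratio,
                    fast_vs_reference = ref_ratio)
  class(out) <- c("dissociation_report", "data.frame")
  out
}
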