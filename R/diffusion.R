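# Diffusion analysis: time-averaged MSD curves, per-track diffusion
# coefficients from the first 25% of lags, mobility classes, spatial
# profiles and travel-distance estimates.

#' Time-averaged mean squared displacement of a track
#'
#' Averages the squared planar displacement over *all* ordered pairs of
#' localizations at each lag `m * tau_TL`, `m = 1 .. n-1`. Tracks need
#' more than five consecutive localizations; shorter tracks are
#' rejected with a reason so callers can count exclusions.
#'
#' @param track data.frame with consecutive `frame`, `x_um`, `y_um`.
#' @param tau_TL time-lapse period, s.
#' @return An object of class `"msd_curve"`: data.frame with `lag_s`,
#'   `msd_um2`, `n_pairs`.
#' @examples
#' tr <- data.frame(frame = 0:9, x_um = (0:9) * 0.1, y_um = 0)
#' compute_msd(tr, 0.02)$msd_um2[1]  # 0.01 (pure drift: (m*s)^2)
#' @export
compute_msd <- function(track, tau_TL) {
  check_columns(track, c("frame", "x_um", "y_um"), "`track`")
  check_number(tau_TL, "tau_TL", lower = 1e-12)
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < 6) {
    stop(sprintf("track has %d localizations; need more than 5", n),
         call. = FALSE)
  }
  if (any(diff(track$frame) != 1)) {
    stop("track has frame gaps; MSD requires gap-free tracks",
         call. = FALSE)
  }
  lags <- seq_len(n - 1)
  msd <- numeric(n - 1)
  np <- integer(n - 1)
  for (m in lags) {
    dx <- track$x_um[(1 + m):n] - track$x_um[1:(n - m)]
    dy <- track$y_um[(1 + m):n] - track$y_um[1:(n - m)]
    msd[m] <- mean(dx^2 + dy^2)
    np[m] <- n - m
  }
  structure(data.frame(lag_s = lags * tau_TL, msd_um2 = msd,
                       n_pairs = np),
            class = c("msd_curve", "data.frame"))
}

#' Estimate a diffusion coefficient from an MSD curve
#'
#' Unweighted linear fit of `MSD` against lag over the first
#' `ceil(fit_fraction * (n - 1))` lags (minimum 2), with
#' `D = slope / (2 d)` from the Einstein-Smoluchowski relation
#' `MSD = 2 d D dt` (`d = 2` for membrane diffusion, so `D = slope/4`).
#' The intercept is retained as a localization-error proxy
#' (approximately `4 sigma^2` for static error `sigma`). Negative
#' slopes are allowed and reported.
#'
#' @param msd_curve an [compute_msd()] result (or any data.frame with
#'   `lag_s` and `msd_um2`).
#' @param d dimensionality of the trajectory data (2 here).
#' @param fit_fraction fraction of lags used, default 0.25.
#' @return An object of class `"diffusion_estimate"`: list with `D`
#'   (um^2/s), `intercept` (um^2), `fit_lags_used`, `n_lags`.
#' @examples
#' msd <- data.frame(lag_s = (1:20) * 0.02, msd_um2 = 4 * 0.31 * (1:20) * 0.02)
#' estimate_diffusion(msd)$D  # 0.31
#' @export
estimate_diffusion <- function(msd_curve, d = 2, fit_fraction = 0.25) {
  check_columns(msd_curve, c("lag_s", "msd_um2"), "`msd_curve`")
  check_number(d, "d", lower = 1)
  check_number(fit_fraction, "fit_fraction", lower = 1e-12, upper = 1)
  n_lags <- nrow(msd_curve)
  k <- max(2L, as.integer(ceiling(fit_fraction * n_lags)))
  if (n_lags < 2L) {
    stop("fewer than 2 usable lags; cannot fit a slope", call. = FALSE)
  }
  k <- min(k, n_lags)
  fit <- lm(msd_um2 ~ lag_s, data = msd_curve[seq_len(k), ])
  cf <- coef(fit)
  structure(list(D = unname(cf[2]) / (2 * d),
                 intercept = unname(cf[1]),
                 fit_lags_used = k, n_lags = n_lags, d = d),
            class = "diffusion_estimate")
}

#' Per-track diffusion coefficients for a whole track table
#'
#' Convenience wrapper: computes the time-averaged MSD and the
#' first-25% diffusion estimate for every track with more than five
#' localizations.
#'
#' @param tracks a `"track_table"` (see [link_localizations()]) or any
#'   data.frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @param tau_TL time-lapse period, s.
#' @inheritParams estimate_diffusion
#' @return data.frame with one row per usable track: `track_id`, `n`,
#'   `D_um2_s`, `intercept_um2`, `class`. Tracks that are too short are
#'   counted in the `n_excluded` attribute.
#' @export
track_diffusion <- function(tracks, tau_TL, d = 2, fit_fraction = 0.25) {
  check_columns(tracks, c("track_id", "frame", "x_um", "y_um"),
                "`tracks`")
  by_track <- split(tracks[, c("frame", "x_um", "y_um")], tracks$track_id)
  usable <- vapply(by_track, nrow, integer(1)) >= 6L
  res <- lapply(by_track[usable], function(tr) {
    est <- estimate_diffusion(compute_msd(tr, tau_TL), d = d,
                              fit_fraction = fit_fraction)
    c(est$D, est$intercept, nrow(tr))
  })
  out <- data.frame(track_id = as.integer(names(res)),
                    n = vapply(res, `[[`, numeric(1), 3),
                    D_um2_s = vapply(res, `[[`, numeric(1), 1),
                    intercept_um2 = vapply(res, `[[`, numeric(1), 2))
  out$class <- classify_mobility(out$D_um2_s)
  attr(out, "n_excluded") <- sum(!usable)
  rownames(out) <- NULL
  out
}

#' Classify diffusion coefficients into mobility classes
#'
#' Thresholds follow the printed inequalities: fast for
#' `D >= 0.1 um^2/s`, intermediate for `0.01 <= D < 0.1`, slow for
#' `D < 0.01` (negative estimates are therefore slow).
#'
#' @param D numeric vector of diffusion coefficients, um^2/s (finite;
#'   negative values allowed).
#' @param thresholds upper then lower class boundary, um^2/s.
#' @return factor with levels `fast`, `intermediate`, `slow`.
#' @examples
#' classify_mobility(c(0.5, 0.05, 0.005, 0.1, 0.01, -0.001))
#' @export
classify_mobility <- function(D, thresholds = c(0.1, 0.01)) {
  stopifnot(is.numeric(D), all(is.finite(D)), length(thresholds) == 2,
            thresholds[1] > thresholds[2])
  cls <- ifelse(D >= thresholds[1], "fast",
                ifelse(D >= thresholds[2], "intermediate", "slow"))
  factor(cls, levels = c("fast", "intermediate", "slow"))
}

#' Class proportions of a set of diffusion estimates
#'
#' @param D numeric vector of diffusion coefficients (or a factor
#'   already produced by [classify_mobility()]).
#' @param thresholds passed to [classify_mobility()].
#' @return data.frame with `class`, `count`, `fraction` (fractions sum
#'   to 1).
#' @export
population_proportions <- function(D, thresholds = c(0.1, 0.01)) {
  if (!length(D)) stop("empty input: no estimates", call. = FALSE)
  cls <- if (is.factor(D)) D else classify_mobility(D, thresholds)
  tab <- table(cls)
  data.frame(class = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab))
}

#' Mobility composition along the cell axis
#'
#' Bins tracks by their distance from the pole and reports per-bin class
#' counts, max-normalized counts, the fast/(intermediate+slow) ratio and
#' per-class mean D. The ratio of a bin whose denominator is empty is
#' `NA` (flagged undefined, never 0).
#'
#' @param estimates data.frame with `D_um2_s` (or `class`) and
#'   `distance_from_pole_um` per track.
#' @param bin_width_um bin width, um (> 0), default 0.5.
#' @param thresholds passed to [classify_mobility()].
#' @return data.frame with one row per occupied bin: `bin_lo_um`,
#'   `bin_hi_um`, `n`, `n_fast`, `n_intermediate`, `n_slow`,
#'   `norm_count` (bin total / max bin total), `fast_ratio`,
#'   `mean_D_fast`, `mean_D_intermediate`, `mean_D_slow`.
#' @export
spatial_mobility_profile <- function(estimates, bin_width_um = 0.5,
                                     thresholds = c(0.1, 0.01)) {
  check_columns(estimates, "distance_from_pole_um", "`estimates`")
  check_number(bin_width_um, "bin_width_um", lower = 1e-12)
  cls <- if ("class" %in% names(estimates)) {
    factor(estimates$class, levels = c("fast", "intermediate", "slow"))
  } else {
    classify_mobility(estimates$D_um2_s, thresholds)
  }
  bin <- floor(estimates$distance_from_pole_um / bin_width_um)
  bins <- sort(unique(bin))
  rows <- lapply(bins, function(b) {
    sel <- bin == b
    cc <- table(cls[sel])
    mean_by <- vapply(levels(cls), function(lv) {
      if (!"D_um2_s" %in% names(estimates)) return(NA_real_)
      v <- estimates$D_um2_s[sel][cls[sel] == lv]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    denom <- cc[["intermediate"]] + cc[["slow"]]
    data.frame(bin_lo_um = b * bin_width_um,
               bin_hi_um = (b + 1) * bin_width_um,
               n = sum(cc), n_fast = cc[["fast"]],
               n_intermediate = cc[["intermediate"]],
               n_slow = cc[["slow"]],
               fast_ratio = if (denom > 0) cc[["fast"]] / denom else NA_real_,
               mean_D_fast = mean_by[["fast"]],
               mean_D_intermediate = mean_by[["intermediate"]],
               mean_D_slow = mean_by[["slow"]])
  })
  out <- do.call(rbind, rows)
  out$norm_count <- out$n / max(out$n)
  rownames(out) <- NULL
  out
}

#' Maximum travel distance before dissociation
#'
#' Inverts `t = x^2 / (2 D)` to estimate how far a molecule diffusing at
#' `D` travels in its membrane residence time `t`:
#' `x = sqrt(2 D t)`.
#'
#' @param D diffusion coefficient, um^2/s (>= 0).
#' @param t time, s (>= 0).
#' @return Distance in um.
#' @examples
#' max_travel_distance(0.31, 1.1)  # ~0.83 um, i.e. 0.8 at one decimal
#' @export
max_travel_distance <- function(D, t) {
  stopifnot(is.numeric(D), is.numeric(t))
  if (any(D < 0)) stop("`D` must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  sqrt(2 * D * t)
}
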