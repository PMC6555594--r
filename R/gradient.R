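# Gradient-shape analysis: alignment, smoothing, window means, decay
# lengths, amplitude-vs-decay buffering and coefficient-of-variation
# profiles.
#
# Profiles enter as long tables (cell_id, x_um, intensity_au) sampled on
# a uniform step from the cell pole; `align_profiles` converts them to a
# matrix "profile_set" on a common grid, which all other operations use.

#' Align cortical profiles to their intensity maximum
#'
#' Shifts each profile so that its maximum-intensity sample sits at
#' `x = 0`, discards samples before the maximum, and truncates all
#' profiles to the shortest aligned length so they share one grid
#' (no interpolation: truncation avoids inventing data). A profile
#' whose maximum is its last sample has no tail and is flagged.
#'
#' @param profiles long data.frame with `cell_id`, `x_um` (uniform
#'   step), `intensity_au`, or an existing `profile_set`.
#' @return An object of class `"profile_set"`: list with `x` (common
#'   grid, starting at 0), `intensity` (cells x positions matrix),
#'   `cell_id`, `step`, and `flagged` (cell ids with no tail).
#' @examples
#' prof <- data.frame(cell_id = 1, x_um = (0:49) * 0.1,
#'                    intensity_au = exp(-(0:49) * 0.1 / 1.5))
#' ps <- align_profiles(prof)
#' ps$x[1]  # 0
#' @export
align_profiles <- function(profiles) {
  if (inherits(profiles, "profile_set")) return(profiles)
  check_columns(profiles, c("cell_id", "x_um", "intensity_au"),
                "`profiles`")
  sp <- split(profiles, profiles$cell_id)
  if (!length(sp)) stop("no profiles supplied", call. = FALSE)
  steps <- vapply(sp, function(p) {
    dx <- diff(sort(p$x_um))
    if (length(dx) == 0 || max(abs(dx - dx[1])) > 1e-6) {
      stop("profiles must be sampled on a uniform step", call. = FALSE)
    }
    dx[1]
  }, numeric(1))
  if (max(abs(steps - steps[1])) > 1e-9) {
    stop("all profiles must share the same sampling step", call. = FALSE)
  }
  step <- steps[1]
  flagged <- character(0)
  tails <- lapply(sp, function(p) {
    p <- p[order(p$x_um), ]
    i_max <- which.max(p$intensity_au)
    if (i_max == nrow(p)) {
      flagged <<- c(flagged, as.character(p$cell_id[1]))
    }
    p$intensity_au[i_max:nrow(p)]
  })
  len <- min(lengths(tails))
  mat <- do.call(rbind, lapply(tails, function(v) v[seq_len(len)]))
  structure(list(x = (seq_len(len) - 1) * step, intensity = mat,
                 cell_id = names(sp), step = step, flagged = flagged),
            class = "profile_set")
}

#' Mean profile across cells of an aligned profile set
#'
#' @param pset a `"profile_set"` from [align_profiles()].
#' @return data.frame with `x_um` and `intensity_au`.
#' @export
average_profile <- function(pset) {
  stopifnot(inherits(pset, "profile_set"))
  data.frame(x_um = pset$x, intensity_au = colMeans(pset$intensity))
}

# mean intensity over a window of a single profile (x, intensity)
.window_mean <- function(x, intensity, window, from_end) {
  span <- x[length(x)] - x[1]
  if (window > span + 1e-9) {
    stop(sprintf("window (%g um) exceeds profile length (%g um)",
                 window, span), call. = FALSE)
  }
  sel <- if (from_end) x >= x[length(x)] - window else x <= x[1] + window
  mean(intensity[sel])
}

#' Mean intensity over the medial-most window of a profile
#'
#' Averages intensity over the final `window` (default 1.5 um) of the
#' profile, the medial region whose levels regulate the mid-cell
#' substrate.
#'
#' @param profile data.frame with `x_um` and `intensity_au` (a single
#'   profile or an averaged one), or a numeric intensity vector paired
#'   with `x`.
#' @param window window length, um.
#' @param x positions when `profile` is a bare numeric vector.
#' @return Mean intensity, a.u.
#' @export
midcell_intensity <- function(profile, window = 1.5, x = NULL) {
  p <- .as_xy(profile, x)
  check_number(window, "window", lower = 1e-12)
  .window_mean(p$x, p$intensity, window, from_end = TRUE)
}

#' Mean intensity over the polar window of a profile
#'
#' Mirror of [midcell_intensity()]: averages over the *first*
#' `window` (default 0.83 um) of the aligned profile, used as the
#' gradient amplitude at the pole.
#'
#' @inheritParams midcell_intensity
#' @return Mean intensity, a.u.
#' @export
pole_intensity <- function(profile, window = 0.83, x = NULL) {
  p <- .as_xy(profile, x)
  check_number(window, "window", lower = 1e-12)
  .window_mean(p$x, p$intensity, window, from_end = FALSE)
}

.as_xy <- function(profile, x = NULL) {
  if (is.data.frame(profile)) {
    check_columns(profile, c("x_um", "intensity_au"), "`profile`")
    list(x = profile$x_um, intensity = profile$intensity_au)
  } else {
    stopifnot(is.numeric(profile), !is.null(x),
              length(x) == length(profile))
    list(x = x, intensity = profile)
  }
}

#' Gaussian-smooth a profile
#'
#' Discrete Gaussian kernel convolution with reflective boundaries;
#' `sigma_um = 0` is the identity. Constant profiles are unchanged for
#' any sigma (the kernel is normalized).
#'
#' @param intensity numeric vector, or a `profile_set` (smoothed
#'   row-wise).
#' @param sigma_um kernel SD in um (>= 0).
#' @param step sampling step in um (taken from the `profile_set` when
#'   one is given).
#' @return Object of the same shape as the input.
#' @export
smooth_profile <- function(intensity, sigma_um, step = NULL) {
  check_number(sigma_um, "sigma_um", lower = 0)
  if (inherits(intensity, "profile_set")) {
    pset <- intensity
    pset$intensity <- t(apply(pset$intensity, 1, smooth_profile,
                              sigma_um = sigma_um, step = pset$step))
    return(pset)
  }
  stopifnot(is.numeric(intensity), !is.null(step))
  if (sigma_um == 0) return(intensity)
  sigma <- sigma_um / step
  half <- max(1L, ceiling(4 * sigma))
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  n <- length(intensity)
  # reflective padding
  pad <- c(intensity[pmin(half + 1, n):2][seq_len(half)],
           intensity,
           intensity[(n - 1):pmax(n - half, 1)][seq_len(half)])
  if (anyNA(pad)) {  # short profiles: fall back to edge replication
    pad <- c(rep(intensity[1], half), intensity, rep(intensity[n], half))
  }
  as.numeric(stats::filter(pad, kern, sides = 2))[(half + 1):(half + n)]
}

#' Decay length of an exponential gradient profile
#'
#' Discards the first `drop_head` um (the plateau at the pole), then
#' fits `log(intensity)` against `x` by ordinary least squares. The
#' decay length is `lambda = -1/slope`; the amplitude is the intensity
#' at the pole (`x = 0`) of the aligned profile. Non-decaying profiles
#' yield an infinite decay length with a flag.
#'
#' @inheritParams midcell_intensity
#' @param drop_head head length to discard, um (default 0.5).
#' @param subtract_min_tail subtract the minimum of the final quarter
#'   of the profile as a constant background offset before fitting.
#'   Default `FALSE`: profiles are assumed background-corrected
#'   upstream.
#' @return An object of class `"decay_fit"`: `lambda_um`, `amplitude`,
#'   `slope`, `slope_se`, `r_squared`, `fit_range_um`, `flat` (TRUE when
#'   the slope is non-negative).
#' @examples
#' x <- (0:45) * 0.1
#' decay_length(data.frame(x_um = x, intensity_au = 100 * exp(-x / 1.5)))
#' @export
decay_length <- function(profile, drop_head = 0.5, x = NULL,
                         subtract_min_tail = FALSE) {
  p <- .as_xy(profile, x)
  check_number(drop_head, "drop_head", lower = 0)
  if (isTRUE(subtract_min_tail)) {
    tail_sel <- p$x >= p$x[1] + 0.75 * (p$x[length(p$x)] - p$x[1])
    p$intensity <- p$intensity - min(p$intensity[tail_sel])
  }
  if (p$x[length(p$x)] - p$x[1] <= drop_head) {
    stop("profile no longer than `drop_head`; nothing to fit",
         call. = FALSE)
  }
  sel <- p$x > p$x[1] + drop_head - 1e-9
  xx <- p$x[sel]; yy <- p$intensity[sel]
  if (any(yy <= 0)) {
    if (isTRUE(subtract_min_tail)) {
      # offset subtraction zeroes at least one tail sample by
      # construction; fit on the remaining positive range
      xx <- xx[yy > 0]; yy <- yy[yy > 0]
      if (length(yy) < 3) {
        stop("too few positive samples after background subtraction",
             call. = FALSE)
      }
    } else {
      stop("non-positive intensities in the fit range; ",
           "background-correct the profiles before fitting",
           call. = FALSE)
    }
  }
  fit <- lm(log(yy) ~ xx)
  # summary.lm warns about "essentially perfect" fits; exact
  # exponentials are a legitimate input here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  flat <- slope >= 0
  structure(list(lambda_um = if (flat) Inf else -1 / slope,
                 amplitude = p$intensity[1], slope = slope,
                 slope_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 fit_range_um = range(xx), flat = flat),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit: lambda = %.4g um (slope %.4g +/- %.3g, R^2 %.3f)%s\n",
              x$lambda_um, x$slope, x$slope_se, x$r_squared,
              if (x$flat) " [non-decaying]" else ""))
  invisible(x)
}

#' Amplitude-vs-decay-length buffering correlation
#'
#' Sorts aligned profiles by pole amplitude, groups them into
#' consecutive bins each holding `bin_fraction` of the profiles
#' (default 5%), averages the profiles within each bin, fits a decay
#' length per bin, and correlates `log(lambda)` with `log(amplitude)`
#' across bins. A buffered gradient shows a strong negative
#' correlation: brighter gradients decay more steeply. The confidence
#' interval comes from a bootstrap over profiles.
#'
#' @param pset a `"profile_set"` (aligned, optionally smoothed) of at
#'   least 20 profiles.
#' @param bin_fraction fraction of profiles per bin (default 0.05).
#' @param drop_head passed to [decay_length()].
#' @param pole_window passed to [pole_intensity()] for sorting
#'   amplitudes.
#' @param n_boot bootstrap replicates for the CI (default 200; 0 skips
#'   the bootstrap and reports an `NA` interval).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return An object of class `"buffering_summary"`: `bins` (data.frame
#'   of per-bin `amplitude`, `lambda_um`, `slope_se`), `correlation`,
#'   `ci` (bootstrap percentile interval), `n_profiles`,
#'   `bin_fraction`.
#' @export
buffering_correlation <- function(pset, bin_fraction = 0.05,
                                  drop_head = 0.5, pole_window = 0.83,
                                  n_boot = 200, conf = 0.95,
                                  seed = NULL) {
  stopifnot(inherits(pset, "profile_set"))
  check_number(bin_fraction, "bin_fraction", lower = 1e-6, upper = 0.5)
  n <- nrow(pset$intensity)
  if (n < 20) {
    stop(sprintf("need >= 20 profiles for a buffering analysis (got %d)",
                 n), call. = FALSE)
  }
  per_bin <- max(1L, floor(bin_fraction * n))
  if (per_bin < 3) {
    stop(sprintf("only %d profiles per bin; need >= 3", per_bin),
         call. = FALSE)
  }
  amps <- apply(pset$intensity, 1, pole_intensity, window = pole_window,
                x = pset$x)
  if (stats::sd(amps) == 0) {
    stop("zero amplitude variance across profiles; nothing to correlate",
         call. = FALSE)
  }

  bin_stats <- function(idx_sorted) {
    nb <- floor(length(idx_sorted) / per_bin)
    rows <- lapply(seq_len(nb), function(b) {
      sel <- idx_sorted[((b - 1) * per_bin + 1):(b * per_bin)]
      avg <- colMeans(pset$intensity[sel, , drop = FALSE])
      df <- decay_length(avg, drop_head = drop_head, x = pset$x)
      data.frame(amplitude = mean(amps[sel]), lambda_um = df$lambda_um,
                 slope_se = df$slope_se)
    })
    do.call(rbind, rows)
  }

  bins <- bin_stats(order(amps))
  ok <- is.finite(bins$lambda_um) & bins$lambda_um > 0
  r <- cor(log(bins$amplitude[ok]), log(bins$lambda_um[ok]))

  if (n_boot == 0) {
    return(structure(list(bins = bins, correlation = r,
                          ci = c(NA_real_, NA_real_), n_profiles = n,
                          bin_fraction = bin_fraction),
                     class = "buffering_summary"))
  }
  boot_r <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      bb <- bin_stats(idx[order(amps[idx])])
      okb <- is.finite(bb$lambda_um) & bb$lambda_um > 0
      if (sum(okb) < 3) return(NA_real_)
      cor(log(bb$amplitude[okb]), log(bb$lambda_um[okb]))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boot_r, c(alpha, 1 - alpha), na.rm = TRUE,
                 names = FALSE)
  structure(list(bins = bins, correlation = r, ci = ci,
                 n_profiles = n, bin_fraction = bin_fraction),
            class = "buffering_summary")
}

#' @export
print.buffering_summary <- function(x, ...) {
  cat(sprintf(paste0("Buffering correlation over %d bins of %d profiles\n",
                     "  cor(log lambda, log A) = %.3f  [%.3f, %.3f]\n"),
              nrow(x$bins), x$n_profiles, x$correlation, x$ci[1],
              x$ci[2]))
  invisible(x)
}

#' Coefficient-of-variation profile across cells
#'
#' At each position, the CV is the across-cell SD divided by the
#' across-cell mean. The fold decrease is the mean CV over the polar
#' window divided by the mean CV over the mid-cell window; a buffered
#' gradient (amplitude fluctuations compensated by decay-length
#' changes) has fold decrease > 1, while pure amplitude scaling gives a
#' position-independent CV and fold ~ 1.
#'
#' @param pset a `"profile_set"` with >= 3 profiles on a common grid.
#' @param pole_window,mid_window window lengths, um.
#' @return An object of class `"cv_profile"`: data.frame `profile`
#'   (`x_um`, `cv`; `cv` is `NA` where the across-cell mean is 0), plus
#'   attributes `tip_cv`, `middle_cv`, `fold_decrease`.
#' @export
cv_profile <- function(pset, pole_window = 0.83, mid_window = 1.5) {
  stopifnot(inherits(pset, "profile_set"))
  if (nrow(pset$intensity) < 3) {
    stop("need >= 3 profiles for a CV profile", call. = FALSE)
  }
  mu <- colMeans(pset$intensity)
  sdv <- apply(pset$intensity, 2, sd)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu)
  tip <- .window_mean(pset$x, cv, pole_window, from_end = FALSE)
  mid <- .window_mean(pset$x, cv, mid_window, from_end = TRUE)
  structure(list(profile = data.frame(x_um = pset$x, cv = cv),
                 tip_cv = tip, middle_cv = mid,
                 fold_decrease = tip / mid),
            class = "cv_profile")
}

#' @export
print.cv_profile <- function(x, ...) {
  cat(sprintf("CV profile: tip CV %.3f, mid-cell CV %.3f, fold decrease %.2f\n",
              x$tip_cv, x$middle_cv, x$fold_decrease))
  invisible(x)
}
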