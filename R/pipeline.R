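# End-to-end studies: simulate -> (track) -> fit -> report. Each study
# takes one configuration block, derives per-stage seeds from the master
# seed, and returns a report object carrying both estimates and the
# generator truth, so recovery can be checked mechanically.

#' Default pipeline configuration
#'
#' Returns the full set of tunables with their defaults. The
#' dissociation block encodes a wild-type-like two-population scenario:
#' 76% of molecules dissociating at `1/1.1` 1/s and 24% at `1/3.1` 1/s,
#' photobleaching at 3 1/s during 20 ms integration, imaged under
#' time-lapse periods of 20, 120 and 220 ms.
#'
#' @param seed master seed.
#' @return A nested configuration list (see [write_config()]).
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    dissociation = list(
      label = "WT",
      populations = list(
        list(label = "fast", k_off = 1 / 1.1, diffusion_coeff = 0.31,
             fraction = 0.76),
        list(label = "slow", k_off = 1 / 3.1, diffusion_coeff = 0.02,
             fraction = 0.24)
      ),
      k_bleach = 3, tau_int = 0.02,
      tau_TL = c(0.02, 0.12, 0.22),
      n_events = 60000, n_replicates = 30,
      model = "biexp", track_mode = "truth",
      radius_um = 0.32, min_track_len = 2
    ),
    diffusion = list(
      D = 0.31, n_tracks = 1000, n_frames = 100, tau_TL = 0.02,
      loc_error_sd = 0.025, fit_fraction = 0.25,
      thresholds = c(0.1, 0.01), bin_um = 0.5
    ),
    gradient = list(
      n_cells = 240, profile_length = 4.5, step = 0.05,
      amplitude_median = 100, amplitude_gsd = 1.6, lambda0 = 1.5,
      beta = 0.5, background = 0, noise_frac_sd = 0.05,
      smooth_sigma_um = 0.2, drop_head = 0.5, bin_fraction = 0.05,
      window_mid = 1.5, window_pole = 0.83
    )
  )
}

# residence times for one simulated condition, by ground truth or by the
# full localize-and-link route
.condition_residences <- function(populations, scheme, geometry,
                                  n_events, seed, track_mode,
                                  radius_um, birth_window = NULL) {
  ev <- simulate_binding_events(populations, scheme, geometry, n_events,
                                seed = seed,
                                birth_window = birth_window)
  if (track_mode == "link") {
    locs <- simulate_localizations(ev, seed = seed + 1L)
    tr <- link_localizations(locs, radius = radius_um)
    track_summary(tr, scheme$tau_TL)$t_eff_s
  } else {
    ev <- observed_frames(ev)
    (ev$n_obs[ev$n_obs >= 1L] - 1) * scheme$tau_TL
  }
}

#' Run a complete dissociation study on simulated data
#'
#' For each replicate: simulate binding events under every time-lapse
#' condition, extract effective residence times (from the ground-truth
#' frame counts, or through the full localization/linking route when
#' `track_mode = "link"`), fit the per-condition residence
#' distribution (mono- or bi-exponential), and separate dissociation
#' from photobleaching with the weighted linear fit of
#' [separate_rates()]. For bi-exponential fits the mixture fraction is
#' combined across conditions by inverse-variance weighting, since
#' short time-lapse periods barely separate the two components and are
#' correspondingly uninformative about the split.
#'
#' @param config the `dissociation` block of [default_config()].
#' @param seed master seed (overrides nothing in `config`; each
#'   replicate and condition draws from its own derived stream).
#' @return An object of class `"dissociation_study"`: `replicates`
#'   (data.frame with per-replicate `t_off_fast_s`, `t_off_slow_s`,
#'   `fast_fraction`, `k_bleach`), `summary` (medians), `truth`
#'   and the configuration used.
#' @export
run_dissociation_study <- function(config, seed = 1) {
  stopifnot(is.list(config), length(config$tau_TL) >= 2)
  pops <- lapply(config$populations, function(p) {
    kinetic_population(p$label, p$k_off, p$diffusion_coeff %||% 0,
                       p$fraction)
  })
  geometry <- cell_geometry()
  model <- match.arg(config$model, c("biexp", "mono"))
  track_mode <- match.arg(config$track_mode %||% "truth",
                          c("truth", "link"))
  min_n <- config$min_track_len %||% 2

  one_replicate <- function(r) {
    fits <- lapply(seq_along(config$tau_TL), function(i) {
      tl <- config$tau_TL[i]
      scheme <- imaging_scheme(config$tau_int, delay = tl - config$tau_int,
                               k_bleach = config$k_bleach)
      s <- derive_seed(seed, sprintf("dissoc-r%d-c%d", r, i))
      res <- .condition_residences(pops, scheme, geometry,
                                   config$n_events, s, track_mode,
                                   config$radius_um %||% 0.32,
                                   config$birth_window_s)
      if (model == "biexp") {
        fit_biexponential(res, tl, min_n = min_n, seed = s + 7L)
      } else {
        fit_monoexponential(res, tl, min_n = min_n)
      }
    })
    if (model == "biexp") {
      cond_of <- function(get_k, get_sd) {
        lapply(seq_along(fits), function(i) {
          time_lapse_condition(config$tau_int, config$tau_TL[i],
                               fits[[i]][[get_k]], fits[[i]][[get_sd]])
        })
      }
      fast <- separate_rates(cond_of("k_eff_fast", "k_eff_fast_sd"))
      slow <- separate_rates(cond_of("k_eff_slow", "k_eff_slow_sd"))
      # The fitted mixture weight is conditioned on detection: fast
      # molecules more often dissociate before their first frame or
      # leave only a single-frame track, so the observed fraction
      # understates the at-birth fraction. Invert that conditioning
      # per condition using the separated k_off and fitted k_eff, then
      # combine across conditions by inverse variance (short time-lapse
      # periods barely split the components and get ~zero weight).
      p_usable <- function(k_off, k_eff, tl) {
        first <- if (k_off > 0) (1 - exp(-k_off * tl)) / (k_off * tl) else 1
        first * exp(-k_eff * tl)
      }
      fr <- vapply(seq_along(fits), function(i) {
        tl <- config$tau_TL[i]
        f_obs <- fits[[i]]$fast_fraction
        pf <- p_usable(fast$k_off, fits[[i]]$k_eff_fast, tl)
        ps <- p_usable(slow$k_off, fits[[i]]$k_eff_slow, tl)
        (f_obs / pf) / (f_obs / pf + (1 - f_obs) / ps)
      }, numeric(1))
      frsd <- vapply(fits, `[[`, numeric(1), "fast_fraction_sd")
      w <- 1 / frsd^2
      ok <- is.finite(w) & w > 0
      frac <- if (any(ok)) sum(fr[ok] * w[ok]) / sum(w[ok]) else mean(fr)
      data.frame(replicate = r, t_off_fast_s = fast$t_off,
                 t_off_slow_s = slow$t_off, fast_fraction = frac,
                 k_bleach = fast$k_bleach)
    } else {
      conds <- lapply(seq_along(fits), function(i) {
        time_lapse_condition(config$tau_int, config$tau_TL[i],
                             fits[[i]]$k_eff, fits[[i]]$k_eff_sd)
      })
      sep <- separate_rates(conds)
      data.frame(replicate = r, t_off_fast_s = sep$t_off,
                 t_off_slow_s = NA_real_, fast_fraction = 1,
                 k_bleach = sep$k_bleach)
    }
  }
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    tryCatch(one_replicate(r), error = function(e) {
      warning(sprintf("replicate %d failed (%s); recorded as NA", r,
                      conditionMessage(e)))
      data.frame(replicate = r, t_off_fast_s = NA_real_,
                 t_off_slow_s = NA_real_, fast_fraction = NA_real_,
                 k_bleach = NA_real_)
    })
  })
  replicates <- do.call(rbind, reps)
  koffs <- vapply(pops, `[[`, numeric(1), "k_off")
  fracs <- vapply(pops, `[[`, numeric(1), "fraction")
  truth <- data.frame(
    t_off_fast_s = 1 / max(koffs),
    t_off_slow_s = if (length(koffs) > 1) 1 / min(koffs) else NA_real_,
    fast_fraction = fracs[which.max(koffs)],
    k_bleach = config$k_bleach)
  structure(list(replicates = replicates,
                 summary = data.frame(
                   t_off_fast_s = median(replicates$t_off_fast_s,
                                         na.rm = TRUE),
                   t_off_slow_s = median(replicates$t_off_slow_s,
                                         na.rm = TRUE),
                   fast_fraction = median(replicates$fast_fraction,
                                          na.rm = TRUE),
                   k_bleach = median(replicates$k_bleach,
                                     na.rm = TRUE)),
                 truth = truth, config = config, seed = seed),
            class = "dissociation_study")
}

#' @export
print.dissociation_study <- function(x, ...) {
  cat(sprintf("Dissociation study (%s): %d replicates x %d events\n",
              x$config$label %||% "?", nrow(x$replicates),
              x$config$n_events))
  cat("  median recovered vs truth:\n")
  print(rbind(recovered = round(unlist(x$summary), 3),
              truth = round(unlist(x$truth), 3)))
  invisible(x)
}

#' Run a diffusion-recovery study on simulated Brownian tracks
#'
#' Simulates `n_tracks` two-dimensional Brownian tracks of `n_frames`
#' frames with Gaussian localization error, estimates each track's
#' diffusion coefficient from the first 25% of its time-averaged MSD
#' curve, and summarises the recovered distribution, mobility classes
#' and (optionally) the spatial mobility profile.
#'
#' @param config the `diffusion` block of [default_config()].
#' @param seed master seed.
#' @return An object of class `"diffusion_study"`: `estimates`
#'   (per-track data.frame), `mean_D`, `proportions`, `truth_D`.
#' @export
run_diffusion_study <- function(config, seed = 1) {
  stopifnot(is.list(config))
  pop <- kinetic_population("sim", k_off = 0,
                            diffusion_coeff = config$D, fraction = 1)
  scheme <- imaging_scheme(tau_int = config$tau_TL, delay = 0,
                           k_bleach = 0,
                           loc_error_sd = config$loc_error_sd)
  geometry <- cell_geometry(length = 1000, width = 1000)
  s <- derive_seed(seed, "diffusion")
  ev <- simulate_binding_events(pop, scheme, geometry, config$n_tracks,
                                seed = s, birth_window = 0)
  locs <- simulate_localizations(ev, seed = s + 1L,
                                 max_frames = config$n_frames)
  locs$track_id <- locs$event_id
  est <- track_diffusion(locs, config$tau_TL,
                         fit_fraction = config$fit_fraction %||% 0.25)
  structure(list(estimates = est, mean_D = mean(est$D_um2_s),
                 proportions = population_proportions(
                   est$D_um2_s, config$thresholds %||% c(0.1, 0.01)),
                 truth_D = config$D, config = config, seed = seed),
            class = "diffusion_study")
}

#' @export
print.diffusion_study <- function(x, ...) {
  cat(sprintf("Diffusion study: %d tracks, mean D = %.4g um^2/s (truth %.4g)\n",
              nrow(x$estimates), x$mean_D, x$truth_D))
  print(x$proportions, row.names = FALSE)
  invisible(x)
}

#' Run a gradient-shape study on simulated cortical profiles
#'
#' Simulates cortical gradient profiles, aligns and smooths them, and
#' computes the average-profile decay length, window means, the
#' amplitude-vs-decay buffering correlation and the CV profile.
#'
#' @param config the `gradient` block of [default_config()].
#' @param seed master seed.
#' @return An object of class `"gradient_study"` with elements
#'   `n_profiles`, `decay` ([decay_length()] of the average profile),
#'   `buffering` ([buffering_correlation()]), `cv` ([cv_profile()]),
#'   `pole_mean`, `midcell_mean`, `truth`.
#' @export
run_gradient_study <- function(config, seed = 1) {
  stopifnot(is.list(config))
  model <- gradient_model(
    amplitude_median = config$amplitude_median %||% 100,
    amplitude_gsd = config$amplitude_gsd %||% 1.6,
    lambda0 = config$lambda0 %||% 1.5, beta = config$beta %||% 0,
    background = config$background %||% 0,
    noise_frac_sd = config$noise_frac_sd %||% 0.05)
  s <- derive_seed(seed, "gradient")
  sim <- simulate_gradient_profiles(model, config$n_cells,
                                    config$profile_length %||% 4.5,
                                    config$step %||% 0.05, seed = s)
  pset <- align_profiles(sim$profiles)
  pset <- smooth_profile(pset, config$smooth_sigma_um %||% 0.2)
  avg <- average_profile(pset)
  decay <- decay_length(avg, drop_head = config$drop_head %||% 0.5)
  buf <- buffering_correlation(pset,
                               bin_fraction = config$bin_fraction %||% 0.05,
                               drop_head = config$drop_head %||% 0.5,
                               pole_window = config$window_pole %||% 0.83,
                               seed = s + 1L)
  cv <- cv_profile(pset, pole_window = config$window_pole %||% 0.83,
                   mid_window = config$window_mid %||% 1.5)
  structure(list(n_profiles = nrow(pset$intensity), decay = decay,
                 buffering = buf, cv = cv,
                 pole_mean = pole_intensity(avg,
                                            config$window_pole %||% 0.83),
                 midcell_mean = midcell_intensity(avg,
                                                  config$window_mid %||% 1.5),
                 truth = sim$truth, config = config, seed = seed),
            class = "gradient_study")
}

#' @export
print.gradient_study <- function(x, ...) {
  cat(sprintf(paste0("Gradient study: %d profiles\n",
                     "  average-profile decay length %.3g um ",
                     "(generator lambda0 %.3g)\n",
                     "  buffering correlation %.3f [%.3f, %.3f]\n",
                     "  CV fold decrease %.2f\n"),
              x$n_profiles, x$decay$lambda_um, x$config$lambda0,
              x$buffering$correlation, x$buffering$ci[1],
              x$buffering$ci[2], x$cv$fold_decrease))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
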