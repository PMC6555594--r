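# Synthetic-data generators. Every generator returns the ground truth it
# used alongside the data, so downstream estimators can be tested exactly.

#' Simulate membrane binding events with dissociation and photobleaching
#'
#' Each event binds at a uniform random time within `birth_window`, at a
#' position drawn from the geometry's binding profile, belongs to a
#' population drawn by mixture weight, and carries an exponential
#' membrane lifetime with that population's `k_off`. Photobleaching is a
#' hazard active only while the camera integrates: a fluorophore's
#' bleach budget is an `Exponential(k_bleach)` amount of *cumulative
#' integration exposure*, so its per-frame survival probability is
#' `exp(-k_bleach * tau_int)`. Molecules that bind during a dark
#' interval first appear at the next frame.
#'
#' @param populations a `kinetic_population` or list of them; fractions
#'   must sum to 1.
#' @param scheme an [imaging_scheme()].
#' @param geometry a [cell_geometry()].
#' @param n_events number of binding events (>= 1).
#' @param seed integer seed; identical inputs and seed give identical
#'   output.
#' @param birth_window length of the binding-time window, s. Defaults to
#'   `n_events * scheme$tau_TL`, which keeps the number of concurrently
#'   visible molecules of the order of a typical track length.
#' @return A data.frame of class `"binding_events"` with columns
#'   `event_id`, `population_label`, `birth_time` (s), `true_lifetime`
#'   (s, dissociation-limited), `bleach_exposure` (s of integration
#'   until bleaching; `Inf` when `k_bleach = 0`), `x0_um`, `y0_um`.
#'   The scheme and populations are attached as attributes.
#' @seealso [observed_frames()], [simulate_localizations()]
#' @examples
#' pop <- kinetic_population("fast", k_off = 1 / 1.1, fraction = 1)
#' ev <- simulate_binding_events(pop, imaging_scheme(0.02, k_bleach = 3),
#'                               cell_geometry(), n_events = 100, seed = 1)
#' head(ev)
#' @export
simulate_binding_events <- function(populations, scheme, geometry,
                                    n_events, seed,
                                    birth_window = NULL) {
  populations <- check_populations(populations)
  stopifnot(inherits(scheme, "imaging_scheme"),
            inherits(geometry, "cell_geometry"))
  check_number(n_events, "n_events", lower = 1)
  n_events <- as.integer(n_events)
  if (is.null(birth_window)) birth_window <- n_events * scheme$tau_TL
  check_number(birth_window, "birth_window", lower = 0)

  labs <- vapply(populations, `[[`, character(1), "label")
  frac <- vapply(populations, `[[`, numeric(1), "fraction")
  koff <- vapply(populations, `[[`, numeric(1), "k_off")

  with_seed(seed, {
    idx <- sample.int(length(populations), n_events, replace = TRUE,
                      prob = frac)
    lifetime <- ifelse(koff[idx] > 0, rexp(n_events, koff[idx]), Inf)
    bleach <- if (scheme$k_bleach > 0) {
      rexp(n_events, scheme$k_bleach)
    } else {
      rep(Inf, n_events)
    }
    birth <- runif(n_events, 0, birth_window)
    x0 <- if (geometry$binding_profile == "uniform") {
      runif(n_events, 0, geometry$length)
    } else {
      # truncated exponential from the pole
      u <- runif(n_events)
      lam <- geometry$binding_decay
      -lam * log(1 - u * (1 - exp(-geometry$length / lam)))
    }
    y0 <- runif(n_events, 0, geometry$width)
    out <- data.frame(event_id = seq_len(n_events),
                      population_label = labs[idx],
                      birth_time = birth,
                      true_lifetime = lifetime,
                      bleach_exposure = bleach,
                      x0_um = x0, y0_um = y0)
    attr(out, "scheme") <- scheme
    attr(out, "populations") <- populations
    attr(out, "geometry") <- geometry
    class(out) <- c("binding_events", "data.frame")
    out
  })
}

#' Observed frame span of simulated binding events
#'
#' Computes, for each event, the index of its first imaged frame and the
#' number of frames in which it is detected. A molecule is detected in a
#' frame if it is still membrane-bound and unbleached at the start of
#' that frame's integration window; under this convention the per-frame
#' survival probability is exactly
#' `exp(-k_off * tau_TL) * exp(-k_bleach * tau_int)`, the product of the
#' two Poisson processes that the rate-separation analysis assumes.
#'
#' @param events a `"binding_events"` data.frame.
#' @param scheme an [imaging_scheme()]; defaults to the scheme stored on
#'   `events`.
#' @return `events` with added integer columns `first_frame` (0-based)
#'   and `n_obs` (number of detected frames; 0 when the molecule
#'   dissociates before its first frame).
#' @export
observed_frames <- function(events, scheme = attr(events, "scheme")) {
  stopifnot(inherits(events, "binding_events"),
            inherits(scheme, "imaging_scheme"))
  tl <- scheme$tau_TL
  first <- ceiling(events$birth_time / tl)
  death <- events$birth_time + events$true_lifetime
  # frames with start time strictly before dissociation
  n_bound <- pmax(0, floor(death / tl - 1e-12) - first + 1)
  n_bound[is.infinite(death)] <- .Machine$integer.max
  n_bleach <- floor(events$bleach_exposure / scheme$tau_int) + 1
  n_bleach[is.infinite(events$bleach_exposure)] <- .Machine$integer.max
  events$first_frame <- as.integer(first)
  events$n_obs <- as.integer(pmin(n_bound, n_bleach))
  events
}

#' Simulate a localization table from binding events
#'
#' Positions evolve by 2D Brownian steps with per-axis variance
#' `2 * D * tau_TL` between frames (so the mean squared planar step is
#' `4 * D * tau_TL`), reflected at the geometry boundary, and each
#' localization carries independent Gaussian error of SD `loc_error_sd`
#' per axis. Molecules emit no rows after bleaching or dissociation.
#'
#' @inheritParams observed_frames
#' @param seed integer seed.
#' @param max_frames optional cap on the number of frames any molecule
#'   is imaged for (a finite acquisition); default unlimited.
#' @return A data.frame of class `"localization_table"` with columns
#'   `frame` (0-based integer), `x_um`, `y_um`, `z_um`, `intensity` and
#'   the ground-truth `event_id`. Rows are ordered by frame then
#'   event_id.
#' @examples
#' pop <- kinetic_population("slow", k_off = 0.5, diffusion_coeff = 0.1,
#'                           fraction = 1)
#' ev <- simulate_binding_events(pop, imaging_scheme(0.02),
#'                               cell_geometry(), 10, seed = 1)
#' locs <- simulate_localizations(ev, seed = 2)
#' @export
simulate_localizations <- function(events,
                                   scheme = attr(events, "scheme"),
                                   seed = NULL, max_frames = NULL) {
  stopifnot(inherits(events, "binding_events"),
            inherits(scheme, "imaging_scheme"))
  if (scheme$tau_TL <= 0) stop("`tau_TL` must be > 0", call. = FALSE)
  geometry <- attr(events, "geometry")
  populations <- attr(events, "populations")
  dmap <- setNames(vapply(populations, `[[`, numeric(1), "diffusion_coeff"),
                   vapply(populations, `[[`, character(1), "label"))
  ev <- observed_frames(events, scheme)
  if (!is.null(max_frames)) {
    check_number(max_frames, "max_frames", lower = 1)
    ev$n_obs <- pmin(ev$n_obs, as.integer(max_frames))
  }
  ev <- ev[ev$n_obs >= 1L, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(structure(data.frame(frame = integer(), x_um = numeric(),
                                y_um = numeric(), z_um = numeric(),
                                intensity = numeric(),
                                event_id = integer()),
                     class = c("localization_table", "data.frame")))
  }
  step_sd <- sqrt(2 * dmap[ev$population_label] * scheme$tau_TL)

  with_seed(seed, {
    idx <- rep.int(seq_len(nrow(ev)), ev$n_obs)
    within <- sequence(ev$n_obs) - 1L     # 0 .. n_obs-1 within each event
    n_rows <- length(idx)
    # cumulative Brownian displacement per event via grouped cumsum
    dx <- rnorm(n_rows, 0, step_sd[idx])
    dy <- rnorm(n_rows, 0, step_sd[idx])
    dx[within == 0L] <- 0
    dy[within == 0L] <- 0
    cx <- ave(dx, idx, FUN = cumsum)
    cy <- ave(dy, idx, FUN = cumsum)
    x <- reflect_coord(ev$x0_um[idx] + cx, geometry$length)
    y <- reflect_coord(ev$y0_um[idx] + cy, geometry$width)
    if (scheme$loc_error_sd > 0) {
      x <- x + rnorm(n_rows, 0, scheme$loc_error_sd)
      y <- y + rnorm(n_rows, 0, scheme$loc_error_sd)
    }
    keep <- if (scheme$detection_prob < 1) {
      runif(n_rows) <= scheme$detection_prob
    } else {
      rep(TRUE, n_rows)
    }
    out <- data.frame(frame = ev$first_frame[idx] + within,
                      x_um = x, y_um = y, z_um = 0,
                      intensity = rlnorm(n_rows, log(1000), 0.3),
                      event_id = ev$event_id[idx])[keep, , drop = FALSE]
    out <- out[order(out$frame, out$event_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("localization_table", "data.frame")
    out
  })
}

# Reflect coordinates into [0, limit] (membrane is a closed surface, so
# molecules never leave the field).
reflect_coord <- function(x, limit) {
  x <- x %% (2 * limit)
  ifelse(x > limit, 2 * limit - x, x)
}

#' Simulate cortical gradient profiles with optional buffering
#'
#' Generates `n_cells` intensity-vs-arclength profiles
#' `A_i * exp(-x / lambda_i) + background + noise`, where amplitudes are
#' log-normal and `lambda_i = lambda0 * (A_i / A_median)^(-beta)` (see
#' [gradient_model()]).
#'
#' @param model a [gradient_model()].
#' @param n_cells number of profiles (>= 1).
#' @param profile_length profile extent, um.
#' @param step sampling step, um (> 0).
#' @param seed integer seed.
#' @return A list with `profiles` (long data.frame: `cell_id`, `x_um`,
#'   `intensity_au`) and `truth` (data.frame: `cell_id`, `amplitude`,
#'   `lambda_um`).
#' @examples
#' g <- simulate_gradient_profiles(gradient_model(beta = 0.5), 24, 4.5,
#'                                 0.1, seed = 1)
#' head(g$truth)
#' @export
simulate_gradient_profiles <- function(model, n_cells, profile_length = 4.5,
                                       step = 0.1, seed = NULL) {
  stopifnot(inherits(model, "gradient_model"))
  check_number(n_cells, "n_cells", lower = 1)
  check_number(step, "step", lower = 1e-12)
  check_number(profile_length, "profile_length", lower = step)
  n_cells <- as.integer(n_cells)
  x <- seq(0, profile_length, by = step)

  with_seed(seed, {
    amp <- rlnorm(n_cells, log(model$amplitude_median),
                  log(model$amplitude_gsd))
    lam <- model$lambda0 * (amp / model$amplitude_median)^(-model$beta)
    signal <- outer(amp, rep(1, length(x))) *
      exp(-outer(lam, x, function(l, xx) xx / l))
    noise_mult <- if (model$noise_frac_sd > 0) {
      matrix(rnorm(length(signal), 0, model$noise_frac_sd), n_cells)
    } else {
      0
    }
    noise_add <- if (model$noise_add_sd > 0) {
      matrix(rnorm(length(signal), 0, model$noise_add_sd), n_cells)
    } else {
      0
    }
    inten <- signal * (1 + noise_mult) + model$background + noise_add
    profiles <- data.frame(cell_id = rep(seq_len(n_cells),
                                         each = length(x)),
                           x_um = rep(x, n_cells),
                           intensity_au = as.vector(t(inten)))
    list(profiles = profiles,
         truth = data.frame(cell_id = seq_len(n_cells), amplitude = amp,
                            lambda_um = lam))
  })
}

#' Simulate node-ROI intensity time series
#'
#' Each node carries a two-state telegraph occupancy process (rates
#' `on_rate * cell_length_effect(length)` and `off_rate`) sampled at the
#' frame times, an intensity of `on_intensity` or `baseline` scaled by a
#' mono-exponential bleaching trend, and additive Gaussian noise. The
#' occupancy chain starts from its stationary distribution (so a node
#' with `on_rate = 0` starts, and stays, unoccupied).
#'
#' @param model a [node_model()].
#' @param n_nodes number of nodes (>= 1).
#' @param duration series length, s.
#' @param frame_interval sampling interval, s (> 0, <= duration).
#' @param cell_lengths optional numeric vector (recycled) of cell
#'   lengths, um; default draws uniformly from 6-14 um, the range of
#'   interphase cell lengths.
#' @param seed integer seed.
#' @return A list with `series` (long data.frame: `node_id`, `t_s`,
#'   `intensity_au`, `cell_length_um`) and `truth` (long data.frame:
#'   `node_id`, `t_s`, `occupied`).
#' @examples
#' ns <- simulate_node_series(node_model(), 5, duration = 60,
#'                            frame_interval = 1, seed = 1)
#' nrow(ns$series) / 5  # 61 samples per node
#' @export
simulate_node_series <- function(model, n_nodes, duration = 60,
                                 frame_interval = 1, cell_lengths = NULL,
                                 seed = NULL) {
  stopifnot(inherits(model, "node_model"))
  check_number(n_nodes, "n_nodes", lower = 1)
  check_number(frame_interval, "frame_interval", lower = 1e-12)
  check_number(duration, "duration", lower = frame_interval)
  n_nodes <- as.integer(n_nodes)
  tt <- seq(0, duration, by = frame_interval)
  nt <- length(tt)

  with_seed(seed, {
    if (is.null(cell_lengths)) cell_lengths <- runif(n_nodes, 6, 14)
    cell_lengths <- rep_len(cell_lengths, n_nodes)
    series <- vector("list", n_nodes)
    truth <- vector("list", n_nodes)
    for (i in seq_len(n_nodes)) {
      a <- model$on_rate * model$cell_length_effect(cell_lengths[i])
      b <- model$off_rate
      tot <- a + b
      pi_on <- if (tot > 0) a / tot else 0
      occ <- integer(nt)
      occ[1] <- rbinom(1, 1, pi_on)
      if (tot > 0) {
        # exact discrete-time transition probabilities of the two-state
        # continuous-time chain over one frame interval
        decay <- exp(-tot * frame_interval)
        p_on_given_on <- pi_on + (1 - pi_on) * decay
        p_on_given_off <- pi_on * (1 - decay)
        u <- runif(nt - 1)
        for (k in 2:nt) {
          p <- if (occ[k - 1] == 1L) p_on_given_on else p_on_given_off
          occ[k] <- as.integer(u[k - 1] < p)
        }
      }
      base <- ifelse(occ == 1L, model$on_intensity, model$baseline)
      inten <- base * exp(-model$bleach_rate * tt) +
        rnorm(nt, 0, model$noise_sd)
      series[[i]] <- data.frame(node_id = i, t_s = tt,
                                intensity_au = inten,
                                cell_length_um = cell_lengths[i])
      truth[[i]] <- data.frame(node_id = i, t_s = tt, occupied = occ)
    }
    list(series = do.call(rbind, series), truth = do.call(rbind, truth))
  })
}
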