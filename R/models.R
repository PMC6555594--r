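# Model-description constructors for the synthetic-data generator.
# Each returns a validated list with a class tag; simulators accept only
# these so that invalid parameter sets fail early with a named field.

#' Define a kinetic population of membrane-binding molecules
#'
#' A population is characterised by its true membrane dissociation rate
#' `k_off`, its lateral diffusion coefficient and its mixture weight.
#' Binding-event simulations draw each molecule's population by weight
#' and its membrane lifetime from `Exponential(k_off)`.
#'
#' @param label character label (e.g. `"fast"`).
#' @param k_off dissociation rate, 1/s (>= 0; 0 means never dissociates).
#' @param diffusion_coeff lateral diffusion coefficient, um^2/s (>= 0).
#' @param fraction mixture weight in `[0, 1]`. Weights of all populations
#'   passed to a simulator must sum to 1 (tolerance 1e-9).
#' @return An object of class `"kinetic_population"`.
#' @examples
#' kinetic_population("fast", k_off = 1 / 1.1, diffusion_coeff = 0.31,
#'                    fraction = 0.76)
#' @export
kinetic_population <- function(label, k_off, diffusion_coeff = 0,
                               fraction = 1) {
  stopifnot(is.character(label), length(label) == 1L)
  check_number(k_off, "k_off", lower = 0)
  check_number(diffusion_coeff, "diffusion_coeff", lower = 0)
  check_number(fraction, "fraction", lower = 0, upper = 1)
  structure(list(label = label, k_off = k_off,
                 diffusion_coeff = diffusion_coeff, fraction = fraction),
            class = "kinetic_population")
}

# Validate a list of populations; fractions must sum to 1.
check_populations <- function(populations) {
  if (inherits(populations, "kinetic_population")) {
    populations <- list(populations)
  }
  stopifnot(length(populations) >= 1L)
  for (p in populations) {
    if (!inherits(p, "kinetic_population")) {
      stop("`populations` must be kinetic_population objects", call. = FALSE)
    }
  }
  tot <- sum(vapply(populations, `[[`, numeric(1), "fraction"))
  if (abs(tot - 1) > 1e-9) {
    stop(sprintf("population fractions must sum to 1 (got %.12g)", tot),
         call. = FALSE)
  }
  populations
}

#' Define a time-lapse imaging scheme
#'
#' A scheme is a camera integration time `tau_int` followed by a dark
#' delay, giving the time-lapse period `tau_TL = tau_int + delay`.
#' Photobleaching (rate `k_bleach`) acts only while the laser is on,
#' i.e. during integration windows; dissociation acts in continuous
#' time. This is the structure under which the linear relation
#' `k_eff * tau_TL = k_bleach * tau_int + k_off * tau_TL` holds exactly,
#' and varying the delay at fixed `tau_int` is what makes the two rates
#' separable (see [separate_rates()]).
#'
#' @param tau_int camera integration time, s (> 0).
#' @param delay inter-frame dark time, s (>= 0).
#' @param k_bleach photobleaching rate during integration, 1/s (>= 0).
#' @param loc_error_sd lateral localization error SD, um. Default 25 nm,
#'   a typical PALM localization precision.
#' @param detection_prob per-frame detection probability in `[0, 1]`.
#' @return An object of class `"imaging_scheme"` with derived `tau_TL`.
#' @examples
#' imaging_scheme(tau_int = 0.02, delay = 0.1, k_bleach = 3)
#' @export
imaging_scheme <- function(tau_int, delay = 0, k_bleach = 0,
                           loc_error_sd = 0.025, detection_prob = 1) {
  check_number(tau_int, "tau_int", lower = 1e-12)
  check_number(delay, "delay", lower = 0)
  check_number(k_bleach, "k_bleach", lower = 0)
  check_number(loc_error_sd, "loc_error_sd", lower = 0)
  check_number(detection_prob, "detection_prob", lower = 0, upper = 1)
  structure(list(tau_int = tau_int, delay = delay,
                 tau_TL = tau_int + delay, k_bleach = k_bleach,
                 loc_error_sd = loc_error_sd,
                 detection_prob = detection_prob),
            class = "imaging_scheme")
}

#' Describe the cell geometry seen by the simulator
#'
#' The membrane plane is modelled as a flat rectangle: arclength along
#' the cell axis (0 at one pole) by a transverse width representing the
#' visible portion of the cell circumference. Binding positions along
#' the axis are either uniform or exponentially enriched at the pole.
#'
#' @param length cell length, um (> 0).
#' @param width transverse extent of the imaged membrane, um (> 0).
#' @param binding_profile `"uniform"` or `"exponential"`.
#' @param binding_decay decay parameter of the exponential binding
#'   density, um (> 0; required when `binding_profile = "exponential"`).
#' @return An object of class `"cell_geometry"`.
#' @export
cell_geometry <- function(length = 10, width = 3,
                          binding_profile = c("uniform", "exponential"),
                          binding_decay = NULL) {
  binding_profile <- match.arg(binding_profile)
  check_number(length, "length", lower = 1e-9)
  check_number(width, "width", lower = 1e-9)
  if (binding_profile == "exponential") {
    if (is.null(binding_decay)) {
      stop("`binding_decay` is required for an exponential binding profile",
           call. = FALSE)
    }
    check_number(binding_decay, "binding_decay", lower = 1e-12)
  }
  structure(list(length = length, width = width,
                 binding_profile = binding_profile,
                 binding_decay = binding_decay),
            class = "cell_geometry")
}

#' Define a cortical gradient generator
#'
#' Each simulated cell `i` has a pole amplitude `A_i` drawn from a
#' log-normal distribution and a decay length
#' `lambda_i = lambda0 * (A_i / A_median)^(-beta)`. `beta = 0` gives a
#' simple diffusive gradient whose decay length is independent of
#' amplitude; `beta > 0` encodes buffering, where brighter gradients
#' decay more steeply so that mid-cell levels vary less than pole levels.
#'
#' @param amplitude_median median pole amplitude, a.u. (> 0).
#' @param amplitude_gsd geometric SD of the amplitude distribution
#'   (>= 1). Pole concentrations in vivo vary up to ~4-fold, which a
#'   geometric SD of about 1.5-2 reproduces.
#' @param lambda0 base decay length, um (> 0).
#' @param beta buffering exponent (>= 0).
#' @param background additive background, a.u.
#' @param noise_frac_sd multiplicative noise fractional SD (>= 0).
#' @param noise_add_sd additive noise SD, a.u. (>= 0).
#' @return An object of class `"gradient_model"`.
#' @examples
#' gradient_model(amplitude_median = 100, amplitude_gsd = 1.6,
#'                lambda0 = 1.5, beta = 0.5)
#' @export
gradient_model <- function(amplitude_median = 100, amplitude_gsd = 1.6,
                           lambda0 = 1.5, beta = 0, background = 0,
                           noise_frac_sd = 0.05, noise_add_sd = 0) {
  check_number(amplitude_median, "amplitude_median", lower = 1e-12)
  check_number(amplitude_gsd, "amplitude_gsd", lower = 1)
  check_number(lambda0, "lambda0", lower = 1e-12)
  check_number(beta, "beta", lower = 0)
  check_number(background, "background")
  check_number(noise_frac_sd, "noise_frac_sd", lower = 0)
  check_number(noise_add_sd, "noise_add_sd", lower = 0)
  structure(list(amplitude_median = amplitude_median,
                 amplitude_gsd = amplitude_gsd, lambda0 = lambda0,
                 beta = beta, background = background,
                 noise_frac_sd = noise_frac_sd,
                 noise_add_sd = noise_add_sd),
            class = "gradient_model")
}

#' Define a node-occupancy generator for TIRF time series
#'
#' Node intensity follows a two-state telegraph process (cluster present
#' or absent at the node), scaled by a mono-exponential photobleaching
#' trend and degraded with Gaussian noise. The encounter rate can depend
#' on cell length through `cell_length_effect`, emulating gradients that
#' reach mid-cell in short but not long cells.
#'
#' @param on_rate rate of entering the occupied state, 1/s (>= 0).
#' @param off_rate rate of leaving the occupied state, 1/s (>= 0).
#' @param on_intensity mean intensity while occupied, a.u.
#' @param baseline mean intensity while unoccupied, a.u.
#'   (must be `< on_intensity`).
#' @param noise_sd Gaussian noise SD, a.u. (>= 0).
#' @param bleach_rate photobleaching trend rate, 1/s (>= 0).
#' @param cell_length_effect function mapping cell length (um) to a
#'   multiplier applied to `on_rate`; default is constant 1.
#' @return An object of class `"node_model"`.
#' @export
node_model <- function(on_rate = 0.05, off_rate = 0.05, on_intensity = 50,
                       baseline = 5, noise_sd = 3, bleach_rate = 0,
                       cell_length_effect = NULL) {
  check_number(on_rate, "on_rate", lower = 0)
  check_number(off_rate, "off_rate", lower = 0)
  check_number(on_intensity, "on_intensity")
  check_number(baseline, "baseline")
  if (on_intensity <= baseline) {
    stop("`on_intensity` must exceed `baseline`", call. = FALSE)
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(bleach_rate, "bleach_rate", lower = 0)
  if (is.null(cell_length_effect)) cell_length_effect <- function(len) 1
  stopifnot(is.function(cell_length_effect))
  structure(list(on_rate = on_rate, off_rate = off_rate,
                 on_intensity = on_intensity, baseline = baseline,
                 noise_sd = noise_sd, bleach_rate = bleach_rate,
                 cell_length_effect = cell_length_effect),
            class = "node_model")
}
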