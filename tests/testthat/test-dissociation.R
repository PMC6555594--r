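# Fits are checked against samples whose discrete-grid law is known
# exactly: t_eff = m * tau_TL with m geometric of survival
# exp(-k_eff * tau_TL).
rgrid <- function(n, k_eff, tau_TL) {
  (stats::rgeom(n, 1 - exp(-k_eff * tau_TL)) + 1) * tau_TL
}

test_that("mono-exponential MLE recovers a known rate", {
  set.seed(31)
  fit <- fit_monoexponential(rgrid(10000, 1.0, 0.02), tau_TL = 0.02)
  expect_lt(abs(fit$k_eff - 1.0), 3 * fit$k_eff_sd)
  expect_equal(fit$n_tracks, 10000)
})

test_that("mono fit rejects degenerate and tiny samples", {
  expect_error(fit_monoexponential(rep(5, 100), tau_TL = 5),
               "degenerate")
  expect_error(fit_monoexponential(rgrid(5, 1, 0.02), 0.02),
               "usable tracks")
  expect_error(fit_monoexponential(rep(0, 100), 0.02), "usable tracks")
  expect_error(fit_monoexponential(c(0.02, 0.03), 0.02), "multiples")
})

test_that("log-histogram mode approximates the MLE on clean data", {
  # the unweighted log-histogram fit is biased by sparse tail bins --
  # the reason MLE is the default -- but should land in the same range
  set.seed(38)
  res <- rgrid(20000, 1.2, 0.02)
  mle <- fit_monoexponential(res, 0.02)
  ls <- fit_monoexponential(res, 0.02, method = "ls_loghist")
  expect_lt(abs(ls$k_eff - mle$k_eff) / mle$k_eff, 0.3)
})

test_that("tail trimming drops only the extreme quantile", {
  set.seed(39)
  res <- c(rgrid(5000, 5, 0.02), rgrid(5000, 0.5, 0.02))
  full <- fit_biexponential(res, 0.02, seed = 1)
  trimmed <- fit_biexponential(res, 0.02, seed = 1,
                               trim_quantile = 0.995)
  expect_lt(trimmed$n_tracks, full$n_tracks)
  expect_lt(abs(trimmed$k_eff_fast - full$k_eff_fast) /
              full$k_eff_fast, 0.1)
})

test_that("censored short tracks are counted, not fitted", {
  set.seed(32)
  res <- c(rgrid(500, 1, 0.02), rep(0, 250))
  fit <- fit_monoexponential(res, 0.02)
  expect_equal(fit$n_tracks, 500)
  expect_equal(fit$n_censored, 250)
})

test_that("bi-exponential fit separates well-separated components", {
  set.seed(33)
  res <- c(rgrid(10000, 5, 0.02), rgrid(10000, 0.5, 0.02))
  fit <- fit_biexponential(res, 0.02, seed = 1)
  expect_lt(abs(fit$k_eff_fast - 5) / 5, 0.1)
  expect_lt(abs(fit$k_eff_slow - 0.5) / 0.5, 0.1)
  expect_lt(abs(fit$fast_fraction - 0.5), 0.05)
  expect_gt(fit$k_eff_fast, fit$k_eff_slow)  # ordering invariant
})

test_that("pure single-rate samples collapse with a warning", {
  set.seed(34)
  expect_warning(fit <- fit_biexponential(rgrid(5000, 1, 0.02), 0.02,
                                          seed = 1),
                 "unidentifiable")
  expect_true(fit$collapsed)
  expect_equal(fit$k_eff_fast, fit$k_eff_slow)
})

test_that("bi-exponential fit needs 100 usable tracks", {
  set.seed(35)
  expect_error(fit_biexponential(rgrid(50, 1, 0.02), 0.02, seed = 1),
               ">= 100")
})

test_that("rate separation is exact on noise-free inputs", {
  k_off <- 0.5; k_bleach <- 2; tau_int <- 0.02
  tls <- c(0.02, 0.12, 0.22)
  keff <- k_bleach * tau_int / tls + k_off
  conds <- lapply(seq_along(tls), function(i) {
    time_lapse_condition(tau_int, tls[i], keff[i], 0.01)
  })
  sep <- separate_rates(conds)
  expect_lt(abs(sep$k_off - k_off) / k_off, 1e-10)
  expect_lt(abs(sep$k_bleach - k_bleach) / k_bleach, 1e-10)
  expect_equal(sep$t_off, 2)
})

test_that("zero bleaching gives equal k_eff and zero intercept", {
  tls <- c(0.02, 0.12, 0.22)
  conds <- lapply(tls, function(tl) {
    time_lapse_condition(0.02, tl, 0.7, 0.01)
  })
  sep <- separate_rates(conds)
  expect_equal(sep$k_off, 0.7, tolerance = 1e-10)
  expect_equal(sep$k_bleach, 0, tolerance = 1e-8)
})

test_that("rate separation input validation and clamping", {
  c1 <- time_lapse_condition(0.02, 0.12, 1, 0.01)
  expect_error(separate_rates(list(c1)), "distinct")
  expect_error(separate_rates(list(
    c1, time_lapse_condition(0.05, 0.22, 1, 0.01))), "tau_int")
  # increasing k_eff * tau_TL slower than tau_TL -> negative slope
  neg <- separate_rates(list(
    time_lapse_condition(0.02, 0.02, 5, 0.01),
    time_lapse_condition(0.02, 0.22, 0.3, 0.01)))
  expect_true(neg$clamped)
  expect_equal(neg$k_off, 0)
  expect_true(is.infinite(neg$t_off))
})

test_that("fitted k_eff decreases with tau_TL when bleaching dominates", {
  pop <- kinetic_population("p", k_off = 0.5, fraction = 1)
  geo <- cell_geometry()
  keffs <- vapply(c(0.02, 0.12, 0.22), function(tl) {
    sch <- imaging_scheme(0.02, delay = tl - 0.02, k_bleach = 3)
    ev <- observed_frames(simulate_binding_events(pop, sch, geo, 8000,
                                                  seed = 36))
    res <- (ev$n_obs[ev$n_obs >= 1] - 1) * tl
    fit_monoexponential(res, tl)$k_eff
  }, numeric(1))
  expect_true(all(diff(keffs) < 0))
})

test_that("report tabulates the printed rate ratios", {
  wt_fast <- structure(list(k_off = 1 / 1.1, t_off = 1.1),
                       class = "rate_separation")
  wt_slow <- structure(list(k_off = 1 / 3.1, t_off = 3.1),
                       class = "rate_separation")
  kd_fast <- structure(list(k_off = 1 / 1.9, t_off = 1.9),
                       class = "rate_separation")
  kd_slow <- structure(list(k_off = 1 / 5.2, t_off = 5.2),
                       class = "rate_separation")
  wt <- dissociation_report("WT", wt_fast, wt_slow)
  kd <- dissociation_report("KD", kd_fast, kd_slow, reference = wt)
  expect_equal(round(wt$slow_fast_ratio, 1), 2.8)
  expect_equal(round(kd$slow_fast_ratio, 1), 2.7)
  expect_equal(round(kd$fast_vs_reference, 1), 1.7)
})

test_that("recovery and coverage over replicates at realistic parameters", {
  # mono-population analogue of the full pipeline invariant, at a scale
  # that keeps the suite fast: 50 replicates, 4000 events each
  pop <- kinetic_population("p", k_off = 1 / 1.7, fraction = 1)
  geo <- cell_geometry()
  tls <- c(0.02, 0.12, 0.22)
  res <- t(vapply(1:50, function(r) {
    conds <- lapply(seq_along(tls), function(i) {
      tl <- tls[i]
      sch <- imaging_scheme(0.02, delay = tl - 0.02, k_bleach = 3)
      ev <- observed_frames(simulate_binding_events(
        pop, sch, geo, 4000, seed = derive_seed(37, paste(r, i))))
      rr <- (ev$n_obs[ev$n_obs >= 1] - 1) * tl
      fit <- fit_monoexponential(rr, tl)
      time_lapse_condition(0.02, tl, fit$k_eff, fit$k_eff_sd)
    })
    sep <- separate_rates(conds)
    c(sep$t_off, covered = abs(sep$k_off - 1 / 1.7) <= 2 * sep$k_off_sd)
  }, numeric(2)))
  expect_lt(abs(median(res[, 1]) - 1.7) / 1.7, 0.1)
  expect_gte(mean(res[, 2]), 0.8)
})
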