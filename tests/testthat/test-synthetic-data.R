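pops2 <- list(kinetic_population("fast", 1.0, fraction = 0.7),
              kinetic_population("slow", 0.2, fraction = 0.3))

test_that("constructors validate their fields by name", {
  expect_error(kinetic_population("x", k_off = -1), "k_off")
  expect_error(kinetic_population("x", 1, diffusion_coeff = -0.1),
               "diffusion_coeff")
  expect_error(imaging_scheme(tau_int = 0), "tau_int")
  expect_error(imaging_scheme(0.02, detection_prob = 1.5),
               "detection_prob")
  expect_error(gradient_model(beta = -0.5), "beta")
  expect_error(node_model(on_intensity = 1, baseline = 5), "on_intensity")
  expect_error(
    simulate_binding_events(
      list(kinetic_population("a", 1, fraction = 0.5)),
      imaging_scheme(0.02), cell_geometry(), 10, seed = 1),
    "sum to 1")
})

test_that("no hazards means no disappearance", {
  pop <- kinetic_population("immortal", k_off = 0, fraction = 1)
  ev <- simulate_binding_events(pop, imaging_scheme(0.02, k_bleach = 0),
                                cell_geometry(), 50, seed = 1)
  expect_true(all(is.infinite(ev$true_lifetime)))
  expect_true(all(is.infinite(ev$bleach_exposure)))
  locs <- simulate_localizations(ev, seed = 2, max_frames = 30)
  expect_true(all(table(locs$event_id) == 30))
})

test_that("single-population mean lifetime matches k_off", {
  pop <- kinetic_population("fast", k_off = 1 / 1.1, fraction = 1)
  ev <- simulate_binding_events(pop, imaging_scheme(0.02),
                                cell_geometry(), 10000, seed = 42)
  se <- 1.1 / sqrt(10000)
  expect_lt(abs(mean(ev$true_lifetime) - 1.1), 3 * se)
})

test_that("mixture lifetimes match the analytic survival (KS < 0.01)", {
  ev <- simulate_binding_events(pops2, imaging_scheme(0.02),
                                cell_geometry(), 50000, seed = 7)
  d <- ks_distance(ev$true_lifetime,
                   function(t) mixture_survival(t, 1.0, 0.2, 0.7))
  expect_lt(d, 0.01)
})

test_that("population draws follow the mixture weights", {
  ev <- simulate_binding_events(pops2, imaging_scheme(0.02),
                                cell_geometry(), 50000, seed = 8)
  p_fast <- mean(ev$population_label == "fast")
  expect_lt(abs(p_fast - 0.7), 3 * sqrt(0.7 * 0.3 / 50000))
})

test_that("frozen molecules produce identical coordinates", {
  pop <- kinetic_population("frozen", k_off = 0, diffusion_coeff = 0,
                            fraction = 1)
  sch <- imaging_scheme(0.02, loc_error_sd = 0)
  ev <- simulate_binding_events(pop, sch, cell_geometry(), 5, seed = 1)
  locs <- simulate_localizations(ev, seed = 2, max_frames = 20)
  for (id in unique(locs$event_id)) {
    sub <- locs[locs$event_id == id, ]
    expect_equal(var(sub$x_um), 0)
    expect_equal(var(sub$y_um), 0)
  }
})

test_that("Brownian step variance matches 4 D tau_TL", {
  D <- 0.31; tl <- 0.02
  pop <- kinetic_population("d", k_off = 0, diffusion_coeff = D,
                            fraction = 1)
  sch <- imaging_scheme(tl, loc_error_sd = 0)
  geo <- cell_geometry(length = 1e5, width = 1e5)  # no reflections
  ev <- simulate_binding_events(pop, sch, geo, 100, seed = 3,
                                birth_window = 0)
  # centre starting positions so reflection is impossible
  ev$x0_um <- 5e4; ev$y0_um <- 5e4
  locs <- simulate_localizations(ev, seed = 4, max_frames = 101)
  steps2 <- unlist(lapply(split(locs, locs$event_id), function(s) {
    s <- s[order(s$frame), ]
    diff(s$x_um)^2 + diff(s$y_um)^2
  }))
  expect_gte(length(steps2), 10000)
  expected <- 4 * D * tl            # 0.0248 um^2
  se <- expected / sqrt(length(steps2))  # SD of chi^2_2 step = mean
  expect_lt(abs(mean(steps2) - expected), 3 * se)
})

test_that("localization error inflates observed positions, not truth", {
  pop <- kinetic_population("frozen", k_off = 0, diffusion_coeff = 0,
                            fraction = 1)
  sch <- imaging_scheme(0.02, loc_error_sd = 0.025)
  ev <- simulate_binding_events(pop, sch, cell_geometry(1e3, 1e3), 200,
                                seed = 5)
  locs <- simulate_localizations(ev, seed = 6, max_frames = 50)
  dev <- unlist(lapply(split(locs, locs$event_id), function(s) {
    s$x_um - mean(s$x_um)
  }))
  expect_lt(abs(sd(dev) - 0.025), 0.005)
})

test_that("gradient generator: deterministic limit and bookkeeping", {
  m <- gradient_model(amplitude_median = 100, amplitude_gsd = 1,
                      lambda0 = 1.5, beta = 0, background = 7,
                      noise_frac_sd = 0, noise_add_sd = 0)
  g <- simulate_gradient_profiles(m, 3, 4.5, 0.1, seed = 1)
  one <- g$profiles[g$profiles$cell_id == 2, ]
  expect_equal(one$intensity_au, 100 * exp(-one$x_um / 1.5) + 7,
               tolerance = 1e-12)
  g240 <- simulate_gradient_profiles(gradient_model(), 240, 4.5, 0.1,
                                     seed = 2)
  expect_length(unique(g240$profiles$cell_id), 240)
})

test_that("buffering exponent couples decay length to amplitude", {
  m <- gradient_model(amplitude_gsd = 2, beta = 0.5)
  g <- simulate_gradient_profiles(m, 240, 4.5, 0.1, seed = 3)
  fit <- lm(log(lambda_um) ~ log(amplitude), data = g$truth)
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 1e-9)
  expect_lt(cor(log(g$truth$lambda_um), log(g$truth$amplitude)), -0.9)
})

test_that("node series: sample count, off-only nodes, stationary occupancy", {
  ns <- simulate_node_series(node_model(), 4, duration = 60,
                             frame_interval = 1, seed = 1)
  expect_equal(nrow(ns$series), 4 * 61)

  off <- simulate_node_series(node_model(on_rate = 0, noise_sd = 1), 5,
                              60, 1, seed = 2)
  expect_true(all(off$truth$occupied == 0))
  expect_lt(max(abs(off$series$intensity_au - 5)), 6)  # baseline 5 +- noise

  tel <- simulate_node_series(node_model(on_rate = 0.1, off_rate = 0.1),
                              200, 60, 1, seed = 3)
  node_occ <- tapply(tel$truth$occupied, tel$truth$node_id, mean)
  se <- sd(node_occ) / sqrt(length(node_occ))
  expect_lt(abs(mean(node_occ) - 0.5), 3 * se)
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_binding_events(pops2, imaging_scheme(0.02, k_bleach = 3),
                               cell_geometry(), 100, seed = 9)
  b <- simulate_binding_events(pops2, imaging_scheme(0.02, k_bleach = 3),
                               cell_geometry(), 100, seed = 9)
  expect_identical(a, b)
  la <- simulate_localizations(a, seed = 10)
  lb <- simulate_localizations(b, seed = 10)
  expect_identical(la, lb)
  ga <- simulate_gradient_profiles(gradient_model(), 20, 4, 0.1, seed = 11)
  gb <- simulate_gradient_profiles(gradient_model(), 20, 4, 0.1, seed = 11)
  expect_identical(ga, gb)
  na <- simulate_node_series(node_model(), 5, 30, 1, seed = 12)
  nb <- simulate_node_series(node_model(), 5, 30, 1, seed = 12)
  expect_identical(na, nb)
  expect_false(identical(
    simulate_gradient_profiles(gradient_model(), 20, 4, 0.1, seed = 11),
    simulate_gradient_profiles(gradient_model(), 20, 4, 0.1, seed = 13)))
})

test_that("per-frame bleach survival equals exp(-k_bleach * tau_int)", {
  # geometric tail of observed frame counts for a non-dissociating,
  # bleach-limited molecule
  pop <- kinetic_population("x", k_off = 0, fraction = 1)
  sch <- imaging_scheme(0.02, delay = 0.2, k_bleach = 3)
  ev <- simulate_binding_events(pop, sch, cell_geometry(), 20000,
                                seed = 13)
  ev <- observed_frames(ev)
  s_hat <- 1 - 1 / mean(ev$n_obs)      # geometric MLE of survival
  s_true <- exp(-3 * 0.02)
  expect_lt(abs(s_hat - s_true), 0.01)
})
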