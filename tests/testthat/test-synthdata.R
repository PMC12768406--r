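test_that("identical seed and config give bit-identical tables", {
  cfgs <- list(
    two_choice = function(s) simulate_two_choice(two_choice_config(seed = s)),
    gradient = function(s) simulate_gradient(gradient_config(seed = s)),
    tracks = function(s) simulate_tracks(
      trajectory_config(n_moths = 3, duration = 1800, seed = s)),
    deafening = function(s) simulate_deafening(25, 20, 0.2, 0.05, seed = s))
  for (f in cfgs) {
    expect_identical(f(11), f(11))
    expect_false(identical(f(11), f(12)))
  }
})

test_that("two-choice counts match Poisson moments when sigmas are 0", {
  cfg <- two_choice_config(n_repetitions = 4000, nights_per_repetition = 1,
                           beta0 = log(0.40), beta1 = 1.0,
                           sigma_arena = 0, sigma_rep = 0, sigma_night = 0,
                           seed = 42)
  n <- simulate_two_choice(cfg)
  # closed-form Poisson means: 0.40 on control, 0.40 * e on treatment
  expect_equal(mean(n$clusters_control), 0.40, tolerance = 0.08)
  expect_equal(mean(n$clusters_treatment), 0.40 * exp(1), tolerance = 0.08)
  expect_equal(mean(n$clusters_treatment) / mean(n$clusters_control),
               exp(1), tolerance = 0.1)
  expect_equal(var(n$clusters_control), 0.40, tolerance = 0.1)
})

test_that("beta1 = 0 gives symmetric sides and zero nights are flagged, not dropped", {
  cfg <- two_choice_config(n_repetitions = 3000, nights_per_repetition = 1,
                           beta1 = 0, sigma_arena = 0, sigma_rep = 0,
                           sigma_night = 0, seed = 7)
  n <- simulate_two_choice(cfg)
  expect_equal(mean(n$clusters_treatment), mean(n$clusters_control),
               tolerance = 0.06)
  expect_true(any(n$zero_laying))
  expect_equal(nrow(n), 3000)  # nothing silently dropped
  expect_identical(n$zero_laying,
                   n$clusters_treatment == 0 & n$clusters_control == 0)
})

test_that("paper-scale defaults land near 1.08 vs 0.40 clusters per laying night", {
  cfg <- two_choice_config(n_repetitions = 2000, seed = 3)
  n <- simulate_two_choice(cfg)
  laid <- n[!n$zero_laying, ]
  expect_gt(mean(laid$clusters_treatment), 0.8)
  expect_lt(mean(laid$clusters_treatment), 1.6)
  expect_gt(mean(laid$clusters_control), 0.25)
  expect_lt(mean(laid$clusters_control), 0.75)
})

test_that("invalid two-choice parameters error by name", {
  expect_error(two_choice_config(beta1 = Inf), "beta1")
  expect_error(two_choice_config(sigma_rep = -1), "sigma_rep")
  expect_error(two_choice_config(n_repetitions = 0), "n_repetitions")
  expect_error(two_choice_config(females_per_arena = 0), "females_per_arena")
})

test_that("gradient positions stay in bounds with a bimodal shape at the stated centres", {
  cfg <- gradient_config(n_females = 100, n_nights = 20,
                         clusters_per_night_rate = 5, w_speaker = 0.5,
                         sigma_speaker = 5, sigma_feeder = 5, seed = 9)
  e <- simulate_gradient(cfg)
  expect_gt(nrow(e), 5000)
  expect_true(all(abs(e$position_cm) <= 75))
  # histogram-mode oracle: two modes within 2 cm of the component centres
  h <- hist(e$position_cm, breaks = seq(-75, 75, by = 2), plot = FALSE)
  dens <- h$density
  is_mode <- vapply(seq_along(dens), function(i) {
    left <- if (i > 1) dens[i - 1] else -Inf
    right <- if (i < length(dens)) dens[i + 1] else -Inf
    dens[i] > left & dens[i] >= right & dens[i] > 0.25 * max(dens)
  }, logical(1))
  modes <- h$mids[is_mode]
  expect_length(modes, 2)
  expect_lt(abs(modes[1] - (-75)), 2.5)
  expect_lt(abs(modes[2] - 0), 2.5)
})

test_that("degenerate mixture collapses onto the feeder", {
  cfg <- gradient_config(w_speaker = 0, sigma_feeder = 1e-4,
                         n_females = 5, n_nights = 5, seed = 2)
  e <- simulate_gradient(cfg)
  expect_true(all(abs(e$position_cm) < 0.01))
})

test_that("egg counts are integral, at least 1, and heavily overdispersed", {
  cfg <- gradient_config(n_females = 60, n_nights = 20,
                         clusters_per_night_rate = 4, seed = 5)
  e <- simulate_gradient(cfg)
  expect_true(all(e$n_eggs >= 1))
  expect_true(all(e$n_eggs == round(e$n_eggs)))
  expect_equal(mean(e$n_eggs), 68, tolerance = 0.1)
  # SD far above the mean, in the regime of 68 +/- 134
  expect_gt(sd(e$n_eggs), 1.5 * mean(e$n_eggs))
  expect_equal(sd(e$n_eggs), 134, tolerance = 0.25)
})

test_that("w_speaker outside [0,1] errors", {
  expect_error(gradient_config(w_speaker = 1.2), "w_speaker")
  expect_error(gradient_config(w_speaker = -0.1), "w_speaker")
  expect_error(gradient_config(sigma_feeder = 0), "sigma")
})

test_that("track time stamps are an arithmetic 12-s sequence within arena bounds", {
  tr <- simulate_tracks(trajectory_config(n_moths = 3, seed = 6))
  for (m in split(tr, tr$moth_id)) {
    expect_equal(unique(diff(m$t_s)), 12)
    expect_equal(m$t_s[1], 0)
  }
  expect_true(all(abs(tr$x_cm) <= 50))
  expect_true(all(tr$y_cm >= 0 & tr$y_cm <= 50))
})

test_that("symmetric chain occupies the playback side half the time; bias shifts late bins", {
  tr0 <- simulate_tracks(trajectory_config(n_moths = 40, duration = 4 * 3600,
                                           bias_slope = 0, switch_prob0 = 0.5,
                                           switch_sd = 0, seed = 8))
  occ <- vapply(split(tr0, tr0$moth_id), function(m) {
    s <- assign_sides(m)
    mean(s$on_playback, na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(occ), 0.5, tolerance = 0.02)

  trb <- simulate_tracks(trajectory_config(n_moths = 60, duration = 4 * 3600,
                                           bias_slope = 2e-4, switch_prob0 = 0.05,
                                           switch_sd = 0, seed = 13))
  firstlast <- vapply(split(trb, trb$moth_id), function(m) {
    b <- assign_sides(m)$bins
    c(b$prop_playback[1], b$prop_playback[nrow(b)])
  }, numeric(2))
  expect_gt(mean(firstlast[2, ]), mean(firstlast[1, ]))
})

test_that("default switching propensity reproduces the observed crossing regime", {
  tr <- simulate_tracks(trajectory_config(n_moths = 300, seed = 21))
  cr <- vapply(split(tr, tr$moth_id),
               function(m) count_crossings(assign_sides(m)), integer(1))
  expect_equal(mean(cr), 4.2, tolerance = 0.25)
  # heterogeneous moths: SD of the same order as the observed 5.7
  expect_gt(sd(cr), 3.5)
  expect_lt(sd(cr), 9)
})

test_that("deafening table is Bernoulli per moth with degenerate limits exact", {
  tab <- simulate_deafening(25, 20, p_control = 1, p_deaf = 0, seed = 1)
  expect_identical(unname(tab), matrix(c(25L, 0L, 0L, 20L), 2, byrow = TRUE))
  tabs <- vapply(1:400, function(s)
    simulate_deafening(25, 20, 0.2, 0, seed = s)[1, 1], numeric(1))
  expect_equal(mean(tabs), 5, tolerance = 0.3)  # E[responders] = 25 * 0.2
})
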