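# Superframe protocol: truncated-Poisson request model, analytic delay,
# discrete-event simulator and the periodic-only baseline.

test_that("truncated Poisson PMF normalises and matches brute force", {
  expect_equal(truncated_poisson_pmf(1, 1), c(0.5, 0.5))

  for (alpha in c(0, 0.5, 1, 5, 25)) {
    for (n_max in c(1, 10, 50)) {
      p <- truncated_poisson_pmf(alpha, n_max)
      expect_length(p, n_max + 1)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
  expect_equal(truncated_poisson_pmf(0, 10), c(1, rep(0, 10)))

  # term-by-term brute-force normalisation oracle
  alpha <- 2; n_max <- 10
  terms <- alpha^(0:n_max) * exp(-alpha) / factorial(0:n_max)
  expect_equal(truncated_poisson_pmf(alpha, n_max), terms / sum(terms),
               tolerance = 1e-12)

  expect_error(truncated_poisson_pmf(-1, 10), "range")
  expect_error(truncated_poisson_pmf(2, 0), "range")
})

test_that("periodic interval is ceil(n/p) frames", {
  expect_equal(periodic_interval(default_cfg(p_slots = 10)), 25e-3)
  expect_equal(periodic_interval(default_cfg(p_slots = 7)), 40e-3)
  # p = n: a single frame serves all devices
  expect_equal(periodic_interval(default_cfg(n_devices = 10, p_slots = 10)),
               5e-3)
})

test_that("analytic delay: no requests means no requested-communication delay", {
  cfg <- default_cfg()
  rep0 <- analytic_average_delay(cfg, delay_params(0, 0, 0, cfg))
  expect_equal(rep0$ds, 0)
  expect_equal(rep0$total, 0)
  # sigma and dc enter the total additively
  rep1 <- analytic_average_delay(cfg, delay_params(0, 2e-3, 3e-3, cfg))
  expect_equal(rep1$total, rep1$ds + 2e-3 + 3e-3)
})

test_that("analytic ds is non-decreasing in the request rate", {
  cfg <- default_cfg(p_slots = 5)
  ds <- vapply(1:25, function(a) {
    analytic_average_delay(cfg, delay_params(a, 0, 0, cfg))$ds
  }, numeric(1))
  expect_true(all(diff(ds) >= 0))
  expect_true(all(diff(ds) > 0)) # strictly, on this grid
})

test_that("invalid configurations are rejected", {
  expect_error(superframe_config(p_slots = 0), "range|positive")
  expect_error(superframe_config(delta = 1.2), "range|\\(0, 1\\)")
  expect_error(superframe_config(m_slots = 20, t_slot = 300e-6),
               "fit")
  cfg_full <- default_cfg(p_slots = 10)
  expect_error(analytic_average_delay(cfg_full, delay_params(1, 0, 0)),
               "exceed")
  expect_error(simulate_superframes(cfg_full, 1, 10, 1), "exceed")
})

test_that("simulation is reproducible and conserves requests", {
  cfg <- default_cfg()
  a <- simulate_superframes(cfg, 3, 2000, seed = 7, keep_samples = TRUE)
  b <- simulate_superframes(cfg, 3, 2000, seed = 7, keep_samples = TRUE)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ds, b$ds)

  # every generated request is served exactly once
  expect_equal(length(a$samples), a$n_requests)
  expect_true(all(a$samples > 0))

  # within a cohort, no two requests share a service slot: the per-request
  # delays of a maximal cohort are strictly increasing, hence all distinct
  d <- bedegress:::cohort_request_delays(cfg, cfg$n_devices)
  expect_length(d, cfg$n_devices)
  expect_true(all(diff(d) > 0))
  # slot wait of the first request: one communication window into the frame
  expect_equal(d[1], (1 - cfg$delta) * cfg$t_slot)
  # first deferred request waits a whole extra frame
  K <- cfg$m_slots - cfg$p_slots
  expect_equal(d[K + 1] - d[1], cfg$T_frame)
})

test_that("analytic model matches the discrete-event oracle within 3 SE", {
  cfg <- default_cfg(p_slots = 5)
  for (alpha in c(1, 5, 10)) {
    an <- analytic_average_delay(cfg, delay_params(alpha, 0, 0, cfg))
    si <- simulate_superframes(cfg, alpha, 1e5, seed = 100 + alpha)
    expect_lt(abs(an$ds - si$ds), 3 * si$se)
  }
})

test_that("simulated mean delay is non-decreasing in alpha within error", {
  cfg <- default_cfg(p_slots = 5)
  sims <- lapply(c(1, 4, 8, 16), function(a) {
    simulate_superframes(cfg, a, 4e4, seed = a)
  })
  ds <- vapply(sims, `[[`, numeric(1), "ds")
  se <- vapply(sims, `[[`, numeric(1), "se")
  expect_true(all(diff(ds) > -3 * sqrt(se[-1]^2 + se[-length(se)]^2)))
})

test_that("periodic baseline: uniform arrivals wait TR/2 on average, TR worst", {
  cfg <- default_cfg(p_slots = 10)
  base <- baseline_periodic_delay(cfg)
  expect_equal(base$worst, 25e-3)
  expect_equal(base$mean, 12.5e-3)
  # p = n: every device served each frame
  expect_lte(baseline_periodic_delay(default_cfg(n_devices = 10,
                                                 p_slots = 10))$worst,
             5e-3)
})

test_that("round-robin periodic schedule gives every device a TR cadence", {
  cfg <- default_cfg(p_slots = 5)
  tr <- periodic_interval(cfg)
  sched <- periodic_schedule(cfg, n_frames = 40)
  gaps <- sched |>
    dplyr::group_by(device) |>
    dplyr::summarise(gap = list(diff(time)), .groups = "drop") |>
    tidyr::unnest(gap)
  expect_true(all(abs(gaps$gap - tr) < 1e-12))
  # no slot serves two devices
  expect_false(any(duplicated(sched[c("frame", "slot")])))
})

test_that("delay sweep reports the proposed scheme below the periodic baseline", {
  cfg <- default_cfg(p_slots = 5)
  sw <- delay_sweep(cfg, alphas = c(1, 3, 5), n_frames = 5e3, seed = 2)
  expect_s3_class(sw, "delay_sweep")
  expect_equal(sw$baseline_worst[1], 25e-3)
  expect_true(all(sw$ds_analytic < sw$baseline_mean))
  p <- ggplot2::autoplot(sw)
  expect_s3_class(p, "ggplot")
})
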