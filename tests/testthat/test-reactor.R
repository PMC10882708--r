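test_that("schedule bookkeeping reproduces the segmented-flow throughput", {
  cfg <- reactor_config(tau = 135, dt = 6.6, horizon = 270)
  sched <- build_schedule(cfg)
  expect_equal(n_produced(sched), 20L)
  expect_equal(sched$t_out_min, sched$t_in_min + 135)
  expect_equal(diff(sched$t_in_min), rep(6.6, nrow(sched) - 1))
  expect_equal(productivity_factor(cfg), 10)

  # degenerate spacing: injections a full residence time apart
  expect_equal(n_produced(build_schedule(reactor_config(135, 135, 270))), 1L)
  # simple arithmetic case
  expect_equal(n_produced(build_schedule(reactor_config(10, 1, 20))), 10L)
  expect_equal(productivity_factor(reactor_config(30, 2, 90)), 10)
})

test_that("slug count is monotone in tau, dt and horizon", {
  count <- function(tau, dt, T) {
    n_produced(suppressWarnings(build_schedule(reactor_config(tau, dt, T))))
  }
  for (tau in c(10, 60, 135)) {
    expect_true(all(diff(vapply(c(1, 2, 5, 10), function(dt)
      count(tau, dt, 300), numeric(1))) <= 0))
  }
  expect_true(all(diff(vapply(c(10, 60, 135), function(tau)
    count(tau, 5, 300), numeric(1))) <= 0))
  expect_true(all(diff(vapply(c(150, 200, 300, 500), function(T)
    count(135, 6.6, T), numeric(1))) >= 0))
})

test_that("horizon shorter than tau + dt yields zero slugs with a warning", {
  expect_warning(s <- build_schedule(reactor_config(100, 50, 120)),
                 "no slug completes")
  expect_equal(n_produced(s), 0L)
})

test_that("slug detection recovers clean and noisy rectangular pulse trains", {
  sched <- (1:6) * 6.6
  clean <- gen_trace(sched, baseline = 1, amplitude = 10, duration = 3,
                     smooth_sd = 0, noise_sd = 0)
  det <- detect_slugs(clean)
  expect_equal(det$count, 6L)
  expect_equal(det$spacing_sd_min, 0)
  expect_equal(det$spacing_mean_min, 6.6, tolerance = 1e-9)

  noisy <- gen_trace(sched, baseline = 1, amplitude = 10, duration = 3,
                     smooth_sd = 0.1, noise_sd = 0.5, seed = 8)
  det_n <- detect_slugs(noisy)
  expect_equal(det_n$count, 6L)
  expect_lt(abs(det_n$spacing_mean_min - 6.6), 0.2)

  flat <- tibble::tibble(t_min = seq(0, 10, by = 0.05), signal = 1)
  expect_equal(detect_slugs(flat)$count, 0L)
})

test_that("detection recovers the generating schedule count at high SNR", {
  for (n_slugs in c(3, 10, 20)) {
    sched <- (1:n_slugs) * 6.6
    tr <- gen_trace(sched, baseline = 2, amplitude = 10, duration = 3,
                    smooth_sd = 0.1, noise_sd = 1, drift = 0.002,
                    seed = n_slugs)
    expect_equal(detect_slugs(tr)$count, n_slugs)
  }
})

test_that("residence statistics pair events and quantify transit jitter", {
  t_in <- (1:20) * 6.6
  exact <- residence_stats(t_in, t_in + 135)
  expect_equal(exact$residence_mean_min, 135)
  expect_equal(exact$residence_sd_min, 0)
  expect_equal(exact$spacing_dev_mean_min, 0)

  jitter <- withr::with_seed(13, rnorm(20, sd = 0.6))
  st <- residence_stats(t_in, t_in + 135 + jitter)
  expect_equal(st$residence_mean_min, 135, tolerance = 0.01)
  expect_lt(abs(st$residence_sd_min - 0.6) / 0.6, 0.5)

  single <- residence_stats(5, 140)
  expect_equal(single$residence_mean_min, 135)
  expect_true(single$single_slug)
  expect_true(is.na(single$residence_sd_min))

  expect_error(residence_stats(1:3, 1:2), class = "ivtwin_pairing_error")
})

test_that("consumption percentages follow the arithmetic and the symmetry", {
  same <- consumption_pct(equimolar(10000), equimolar(10000))
  expect_equal(same$consumed_pct, rep(0, 4))
  one <- consumption_pct(equimolar(10000),
                         c(A = 2850, C = 2850, G = 2850, U = 2850))
  expect_equal(one$consumed_pct, rep(71.5, 4))
  expect_equal(mean_consumption(one), 71.5)
  expect_error(consumption_pct(equimolar(100), equimolar(200)),
               class = "ivtwin_negative_consumption")

  # a symmetric reaction consumes all four bases equally
  p <- ref_params(); ts <- tiny_transcript()
  p_sym <- kinetic_params(vmax = p$vmax,
                          km = c(A = 100, C = 100, G = 100, U = 100))
  tr <- simulate_batch(equimolar(10000), p_sym, quiet_ppiase(), ts,
                       c(0, 200, 400))
  cons <- consumption_pct(equimolar(10000),
                          unlist(tr[nrow(tr), c("c_ATP_uM", "c_CTP_uM",
                                                "c_GTP_uM", "c_UTP_uM")]) |>
                            setNames(c("A", "C", "G", "U")))
  expect_lt(diff(range(cons$consumed_pct)), 1e-6)
})

test_that("relative change reports signed percent reductions", {
  expect_equal(relative_change(82, 82), 0)
  expect_equal(relative_change(100, 0), 100)
  expect_equal(round(relative_change(82, 55.3), 1), 32.6)
  expect_error(relative_change(0, 10), class = "ivtwin_invalid_input")
})
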