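test_that("noise-free progress curves reproduce the simulator exactly", {
  p <- ref_params(); ts <- tiny_transcript()
  times <- seq(0, 40, by = 5)
  gen <- gen_progress_curves(p, ts, equimolar(3000), times,
                             ppiase = quiet_ppiase(), noise = NULL)
  sim <- simulate_batch(equimolar(3000), p, quiet_ppiase(), ts, times)
  expect_equal(tibble::as_tibble(gen), tibble::as_tibble(sim)[names(gen)],
               ignore_attr = TRUE)
})

test_that("generators are pure functions of configuration and seed", {
  p <- ref_params(); ts <- tiny_transcript()
  g1 <- gen_progress_curves(p, ts, equimolar(3000), seq(0, 20, 5),
                            ppiase = quiet_ppiase(), seed = 17)
  g2 <- gen_progress_curves(p, ts, equimolar(3000), seq(0, 20, 5),
                            ppiase = quiet_ppiase(), seed = 17)
  expect_identical(g1, g2)

  d1 <- gen_initial_rate_dataset("ref-CTP", seed = 5)
  d2 <- gen_initial_rate_dataset("ref-CTP", seed = 5)
  expect_identical(d1, d2)
  expect_false(identical(d1$v_uM_per_min,
                         gen_initial_rate_dataset("ref-CTP", seed = 6)$v_uM_per_min))

  t1 <- gen_trace((1:4) * 5, noise_sd = 0.3, seed = 2)
  expect_identical(t1, gen_trace((1:4) * 5, noise_sd = 0.3, seed = 2))
})

test_that("generator truth travels with the data in a sidecar attribute", {
  d <- gen_initial_rate_dataset("ref-UTP", noise = NULL)
  tr <- attr(d, "truth")
  expect_equal(tr$km, 101.5)
  expect_equal(tr$vmax, 0.358)
  expect_equal(tr$base, "U")
  # noise-free rates equal the law at the recorded truth
  expect_equal(d$v_uM_per_min, rate_simple(d$c_uM, tr$km, tr$vmax))
  # replicate count honored
  d3 <- gen_initial_rate_dataset("ref-UTP", replicates = 3)
  expect_equal(nrow(d3), 12L)
})

test_that("noisy replicate means concentrate on the noise-free curve", {
  km <- 140.4; vmax <- 0.358; c0 <- 5000
  v_true <- rate_simple(c0, km, vmax)
  reps <- vapply(1:1000, function(i) {
    d <- gen_initial_rate_dataset(km = km, vmax = vmax,
                                  noise = noise_spec(cv = 0.02), seed = i)
    d$v_uM_per_min[d$c_uM == c0]
  }, numeric(1))
  # one-sided CLT guard: sample mean within 3 SEs of the truth
  expect_lt(abs(mean(reps) - v_true), 3 * 0.02 * v_true / sqrt(1000))
})

test_that("generated traces carry one pulse per scheduled slug", {
  sched <- build_schedule(reactor_config(135, 6.6, 270))
  tr <- gen_trace(sched$t_in_min, duration = 3, smooth_sd = 0.1,
                  noise_sd = 0.2, seed = 3, sample_dt = 0.05)
  expect_equal(detect_slugs(tr)$count, nrow(sched))
  # zero amplitude: flat trace, no slugs
  flat <- gen_trace(sched$t_in_min, amplitude = 0, noise_sd = 0)
  expect_equal(detect_slugs(flat)$count, 0L)
})

test_that("DoE generator responses follow the supplied surface", {
  des <- generate_design(list(factor_spec("temp_C", 37, 40),
                              factor_spec("urea_M", 0.4, 1.2),
                              factor_spec("additive_mg_ml", 0.1, 1)))
  truth <- c(`(Intercept)` = 4, x2 = 1.5, `x2:x3` = -1)
  clean <- gen_doe_dataset(des, truth)
  expect_equal(clean$response,
               4 + 1.5 * des$x2 - des$x2 * des$x3)
  expect_identical(gen_doe_dataset(des, truth, sd = 0.2, seed = 9),
                   gen_doe_dataset(des, truth, sd = 0.2, seed = 9))
  expect_error(gen_doe_dataset(des, c(bogus = 1)),
               class = "ivtwin_invalid_input")
})

test_that("the fixture catalog names reproducible configurations", {
  cat <- fixture_catalog()
  expect_setequal(cat$fixture[cat$kind == "initial_rate"],
                  c("ref-ATP", "ref-CTP", "ref-GTP", "ref-UTP"))
  expect_equal(cat$km_uM[cat$fixture == "ref-GTP"], 165.5)
  bnt <- fixture_transcript("bnt-like")
  expect_equal(bnt$n_mrna, 4284L)
  expect_equal(sum(bnt$f), 1)
  alt <- fixture_transcript("alt-transcript")
  expect_false(identical(alt$f, bnt$f))
})
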