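test_that("initial-rate extraction recovers slopes and handles flat series", {
  d <- tibble::tibble(t_min = 0:10, c_mRNA_uM = 0.3 * (0:10))
  r <- extract_initial_rate(d)
  expect_equal(r$rate_uM_per_min, 0.3, tolerance = 1e-12)
  expect_equal(r$n_points, 11L)

  flat <- tibble::tibble(t_min = 0:5, c_mRNA_uM = rep(2, 6))
  expect_equal(extract_initial_rate(flat)$rate_uM_per_min, 0)

  expect_error(extract_initial_rate(d[1:2, ]),
               class = "ivtwin_insufficient_data")
})

test_that("initial rates from simulated curves match the apparent law", {
  p <- ref_params(); ts <- tiny_transcript()
  # ATP varied at 2500 uM, others in deep excess, strong ppiase
  tr <- simulate_batch(c(A = 2500, C = 1e7, G = 1e7, U = 1e7), p,
                       strong_ppiase(), ts, seq(0, 10, by = 0.5))
  r <- extract_initial_rate(tr, substrate = "c_ATP_uM")
  expect_equal(r$rate_uM_per_min, rate_simple(2500, 140.4, 0.358),
               tolerance = 0.02)
  expect_false(r$fallback)
  # the window respects the <10% substrate consumption rule
  expect_lt((2500 - tr$c_ATP_uM[match(r$t_end_min, tr$t_min)]) / 2500, 0.1)
})

test_that("all four estimators recover noise-free parameters exactly", {
  for (km in c(50, 100, 200)) {
    for (vmax in c(0.1, 0.358, 1)) {
      d <- gen_initial_rate_dataset(km = km, vmax = vmax, noise = NULL)
      for (f in list(fit_lineweaver_burk, fit_hanes_woolf,
                     fit_eadie_hofstee, fit_nonlinear)) {
        fit <- f(d)
        expect_equal(fit$km, km, tolerance = 1e-6)
        expect_equal(fit$vmax, vmax, tolerance = 1e-6)
      }
    }
  }
})

test_that("reference fixtures are recovered exactly from noise-free data", {
  truth <- c(`ref-ATP` = 140.4, `ref-CTP` = 71.5, `ref-GTP` = 165.5,
             `ref-UTP` = 101.5)
  for (fx in names(truth)) {
    d <- gen_initial_rate_dataset(fx, noise = NULL)
    expect_equal(fit_lineweaver_burk(d)$km, unname(truth[fx]), tolerance = 1e-9)
    expect_equal(fit_nonlinear(d)$vmax, 0.358, tolerance = 1e-7)
  }
})

test_that("linearizations reject nonpositive rates and flag 2-point fits", {
  d <- tibble::tibble(c_uM = c(100, 200, 400), v_uM_per_min = c(0.1, 0, 0.2))
  expect_error(fit_lineweaver_burk(d), class = "ivtwin_invalid_input")
  d2 <- tibble::tibble(c_uM = c(100, 400),
                       v_uM_per_min = rate_simple(c(100, 400), 120, 0.5))
  fit <- fit_lineweaver_burk(d2)
  expect_equal(fit$km, 120, tolerance = 1e-9)
  expect_true(is.na(fit$km_se))
  expect_match(fit$flags, "standard errors undefined", all = FALSE)
})

test_that("Hanes-Woolf is less biased than Lineweaver-Burk for Km under noise
          that is heteroscedastic on the linearized scale", {
  # constant absolute rate noise: the reciprocal transform of Lineweaver-Burk
  # amplifies errors at low rates, inflating its Km estimate
  km <- 100; vmax <- 0.5
  levels <- c(25, 50, 100, 200, 400)
  est <- withr::with_seed(42, {
    replicate(200, {
      v <- rate_simple(levels, km, vmax) + 0.01 * rnorm(length(levels))
      d <- tibble::tibble(c_uM = levels, v_uM_per_min = pmax(v, 1e-6))
      c(lb = tryCatch(fit_lineweaver_burk(d)$km, error = function(e) NA),
        hw = tryCatch(fit_hanes_woolf(d)$km, error = function(e) NA))
    })
  })
  bias_lb <- mean(est["lb", ], na.rm = TRUE) - km
  bias_hw <- mean(est["hw", ], na.rm = TRUE) - km
  expect_lt(abs(bias_hw), abs(bias_lb))
})

test_that("the optimizer's SSE minimum matches a brute-force profiled grid", {
  for (i in 1:10) {
    d <- gen_initial_rate_dataset(km = 120, vmax = 0.5, replicates = 2,
                                  noise = noise_spec(cv = 0.05), seed = 100 + i)
    fit <- fit_nonlinear(d)
    kms <- seq(1, 500, by = 0.1)
    sse <- vapply(kms, function(k) {
      g <- d$c_uM / (k + d$c_uM)
      vm <- sum(d$v_uM_per_min * g) / sum(g^2)
      sum((d$v_uM_per_min - vm * g)^2)
    }, numeric(1))
    k_or <- kms[which.min(sse)]
    sse_fit <- sum((d$v_uM_per_min - rate_simple(d$c_uM, fit$km, fit$vmax))^2)
    # the optimizer must never do worse than the grid optimum
    expect_lte(sse_fit, min(sse) * (1 + 1e-8))
    if (k_or > 1.05 && k_or < 499.9) {
      expect_equal(fit$km, k_or, tolerance = 2e-3)
    }
  }
})

test_that("estimate_all aggregates per base and method with R2 review flags", {
  d <- dplyr::bind_rows(lapply(c("A", "C"), function(b)
    gen_initial_rate_dataset(km = if (b == "A") 140.4 else 71.5, vmax = 0.358,
                             base = b, noise = NULL)))
  tab <- estimate_all(d)
  expect_equal(nrow(tab), 8L)  # 2 bases x 4 methods
  expect_true(all(!tab$flagged))
  expect_equal(tab$km[tab$base == "A" & tab$method == "nonlinear"], 140.4,
               tolerance = 1e-6)
  # vmax does not depend on which base the label carries
  expect_equal(unique(round(tab$vmax, 9)), 0.358)
})

test_that("tidy and glance provide the broom view of a fit", {
  d <- gen_initial_rate_dataset(km = 100, vmax = 0.5,
                                noise = noise_spec(cv = 0.01), seed = 7)
  fit <- fit_nonlinear(d)
  td <- tidy(fit)
  expect_equal(td$term, c("km", "vmax"))
  expect_true(all(td$std.error >= 0))
  gl <- glance(fit)
  expect_equal(gl$method, "nonlinear")
  expect_equal(gl$nobs, 4L)
})
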