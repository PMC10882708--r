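screen_factors <- function() {
  list(factor_spec("temp_C", 37, 40, "degC"),
       factor_spec("urea_M", 0.4, 1.2, "M"),
       factor_spec("additive_mg_ml", 0.1, 1, "mg/mL"))
}

test_that("the default screening design has 15 runs with 3 centers", {
  des <- generate_design(screen_factors())
  expect_equal(nrow(des), 15L)
  expect_equal(sum(des$is_center), 3L)
  # center points sit at the physical midpoints of each range
  centers <- des[des$is_center, ]
  expect_equal(unique(centers$temp_C), 38.5)
  expect_equal(unique(centers$urea_M), 0.8)
  expect_equal(unique(centers$additive_mg_ml), 0.55)
  # design moments: each coded column sums to zero
  expect_equal(colSums(des[, c("x1", "x2", "x3")]), c(x1 = 0, x2 = 0, x3 = 0))
  expect_error(generate_design(screen_factors()[1:2]),
               class = "ivtwin_invalid_input")
})

test_that("coded/physical mapping round-trips exactly", {
  f <- factor_spec("urea_M", 0.4, 1.2)
  x <- c(-1, -0.5, 0, 0.25, 1)
  phys <- ivtwin:::.coded_to_physical(x, f)
  expect_equal(ivtwin:::.physical_to_coded(phys, f), x)
  expect_equal(ivtwin:::.coded_to_physical(0, f), 0.8)
})

test_that("quadratic fits recover exact and noisy surfaces", {
  des <- generate_design(screen_factors())
  resp <- gen_doe_dataset(des, c(`(Intercept)` = 2, x1 = 3, `I(x2^2)` = -1))
  m <- fit_quadratic(des, resp$response)
  cf <- coef(m$fit)
  expect_equal(unname(cf[["(Intercept)"]]), 2, tolerance = 1e-9)
  expect_equal(unname(cf[["x1"]]), 3, tolerance = 1e-9)
  expect_equal(unname(cf[["I(x2^2)"]]), -1, tolerance = 1e-9)
  expect_equal(unname(cf[["x2"]]), 0, tolerance = 1e-9)

  const <- fit_quadratic(des, rep(5, 15))
  cf_const <- coef(const$fit)
  expect_lt(max(abs(cf_const[names(cf_const) != "(Intercept)"])), 1e-12)
  # a constant response carries no signal: everything removable is dropped
  expect_length(stepwise_reduce(const)$terms, 0L)

  noisy <- gen_doe_dataset(des, c(`(Intercept)` = 10, x1 = 4, x3 = -2,
                                  `x1:x3` = 1.5), sd = 0.3, seed = 5)
  mn <- fit_quadratic(des, noisy$response)
  tn <- tidy(mn)
  for (tm in c("x1", "x3", "x1:x3")) {
    truth <- c(x1 = 4, x3 = -2, `x1:x3` = 1.5)[[tm]]
    row <- tn[tn$term == tm, ]
    expect_lt(abs(row$estimate - truth), 3 * row$std.error)
  }
})

test_that("the factorial template cannot estimate pure quadratics", {
  des <- generate_design(screen_factors(), template = "factorial")
  expect_equal(nrow(des), 11L)
  y <- gen_doe_dataset(des, c(`(Intercept)` = 1, x1 = 2), sd = 0.1, seed = 1)
  expect_error(fit_quadratic(des, y$response),
               class = "ivtwin_rank_deficient")
})

test_that("stepwise reduction recovers the true support as noise vanishes", {
  des <- generate_design(screen_factors())
  truth <- c(`(Intercept)` = 5, x1 = 2, x3 = -1.5, `I(x1^2)` = 1)
  resp <- gen_doe_dataset(des, truth, sd = 1e-9, seed = 2)
  red <- stepwise_reduce(fit_quadratic(des, resp$response), alpha = 0.05)
  expect_setequal(red$terms, c("x1", "x3", "I(x1^2)"))
  # refitting the reduced model reproduces its coefficients (idempotence)
  refit <- fit_quadratic(des, resp$response)
  refit <- stepwise_reduce(refit, alpha = 0.05)
  expect_equal(coef(red$fit), coef(refit$fit))
})

test_that("stepwise keeps one strong main effect among pure-noise terms", {
  des <- generate_design(screen_factors())
  sigma <- 0.1
  resp <- gen_doe_dataset(des, c(`(Intercept)` = 1, x2 = 10 * sigma),
                          sd = sigma, seed = 31)
  red <- stepwise_reduce(fit_quadratic(des, resp$response))
  expect_true("x2" %in% red$terms)
  # backward elimination admits false positives at ~alpha per noise term
  expect_lte(length(red$terms), 5L)
})

test_that("hierarchy keeps parents of significant interactions", {
  des <- generate_design(screen_factors())
  resp <- gen_doe_dataset(des, c(`(Intercept)` = 1, `x1:x2` = 5),
                          sd = 1e-9, seed = 3)
  red <- stepwise_reduce(fit_quadratic(des, resp$response))
  expect_true(all(c("x1", "x2", "x1:x2") %in% red$terms))
  # fully significant model is untouched
  full_truth <- setNames(c(1, 2, -2, 1.5, 1, -1, 0.8, 1.2, -0.9, 0.7),
                         c("(Intercept)", "x1", "x2", "x3", "x1:x2", "x1:x3",
                           "x2:x3", "I(x1^2)", "I(x2^2)", "I(x3^2)"))
  resp2 <- gen_doe_dataset(des, full_truth, sd = 1e-9, seed = 4)
  m2 <- fit_quadratic(des, resp2$response)
  expect_setequal(stepwise_reduce(m2)$terms, m2$terms)
})

test_that("desirability optimization finds boundary, center and trade-offs", {
  des <- generate_design(screen_factors())
  # monotone in x1 only: maximize at the +1 boundary
  r1 <- gen_doe_dataset(des, c(`(Intercept)` = 1, x1 = 2))
  m1 <- fit_quadratic(des, r1$response)
  opt1 <- desirability_optimize(list(y = m1), c(y = "maximize"))
  expect_equal(opt1$optimum$x1, 1)

  # concave bowl peaked at the center
  r2 <- gen_doe_dataset(des, c(`(Intercept)` = 10, `I(x1^2)` = -2,
                               `I(x2^2)` = -2, `I(x3^2)` = -2))
  m2 <- fit_quadratic(des, r2$response)
  opt2 <- desirability_optimize(list(y = m2), c(y = "maximize"))
  expect_equal(unlist(opt2$optimum[, c("x1", "x2", "x3")]),
               c(x1 = 0, x2 = 0, x3 = 0))

  # two responses with a trade-off: compare against a finer brute-force grid
  ra <- gen_doe_dataset(des, c(`(Intercept)` = 5, x1 = 2, `I(x1^2)` = -1))
  rb <- gen_doe_dataset(des, c(`(Intercept)` = 3, x1 = -1, x2 = 1))
  ma <- fit_quadratic(des, ra$response)
  mb <- fit_quadratic(des, rb$response)
  res <- 21L
  opt <- desirability_optimize(list(a = ma, b = mb),
                               c(a = "maximize", b = "maximize"),
                               resolution = res)
  # independent oracle on a 41-point grid, desirability recomputed from scratch
  s <- seq(-1, 1, length.out = 41)
  grid <- expand.grid(x1 = s, x2 = s, x3 = s)
  pa <- predict(ma, grid); pb <- predict(mb, grid)
  da <- (pa - min(pa)) / diff(range(pa))
  db <- (pb - min(pb)) / diff(range(pb))
  oracle <- grid[which.max(sqrt(da * db)), ]
  step <- 2 / (res - 1)
  expect_lte(abs(opt$optimum$x1 - oracle$x1), step + 1e-9)
  expect_lte(abs(opt$optimum$x2 - oracle$x2), step + 1e-9)
  expect_lte(abs(opt$optimum$x3 - oracle$x3), step + 1e-9)
})

test_that("contour evaluation matches direct model prediction pointwise", {
  des <- generate_design(screen_factors())
  resp <- gen_doe_dataset(des, c(`(Intercept)` = 2, x1 = 1, `I(x3^2)` = -0.5))
  m <- fit_quadratic(des, resp$response)

  grid <- contour_eval(m, vary = c("x1", "x3"), fixed = 0.5, n = 11)
  direct <- predict(m, grid[, c("x1", "x2", "x3")])
  expect_equal(grid$prediction, direct)
  expect_true(all(grid$x2 == 0.5))
  # physical columns follow the affine mapping
  expect_equal(grid$temp_C, 38.5 + grid$x1 * 1.5)

  # constant model: constant matrix
  mc <- fit_quadratic(des, rep(7, 15))
  gc <- contour_eval(stepwise_reduce(mc), n = 5)
  expect_equal(gc$prediction, rep(7, 25))
})
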