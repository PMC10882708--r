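#' Validate an initial-rate dataset
#'
#' An initial-rate experiment varies one NTP over at least three distinct
#' positive levels (the standard design uses 2500, 5000, 7500 and 10000 uM)
#' and records the observed initial rate at each level. Duplicate levels are
#' allowed and treated as replicates.
#'
#' @param data Data frame with columns `c_uM` (substrate level) and
#'   `v_uM_per_min` (initial rate); optional `base` and `replicate`.
#' @param base Varied NTP; taken from the data if present.
#' @return A tibble of class `initial_rate_data`.
#' @export
initial_rate_data <- function(data, base = NULL) {
  d <- tibble::as_tibble(data)
  if (!all(c("c_uM", "v_uM_per_min") %in% names(d))) {
    abort("need columns `c_uM` and `v_uM_per_min`",
          class = "ivtwin_invalid_input")
  }
  .assert_finite(d$c_uM, "c_uM")
  .assert_finite(d$v_uM_per_min, "v_uM_per_min")
  if (any(d$c_uM <= 0)) {
    abort("substrate levels must be > 0", class = "ivtwin_invalid_input")
  }
  if (length(unique(d$c_uM)) < 3L) {
    abort("need >= 3 distinct substrate levels",
          class = "ivtwin_insufficient_data")
  }
  if (is.null(base)) base <- if ("base" %in% names(d)) d$base[[1L]] else NA_character_
  if (!"base" %in% names(d)) d$base <- base
  if (!"replicate" %in% names(d)) d$replicate <- 1L
  class(d) <- c("initial_rate_data", class(d))
  d
}

#' Extract an initial rate from a reaction time course
#'
#' The initial rate is the slope of the product concentration over the early,
#' still-linear part of the progress curve. The window policy takes the
#' longest prefix of at least three points whose ordinary-least-squares fit
#' has R^2 >= `r2_min` and whose endpoint has consumed less than
#' `max_frac_consumed` of the varied substrate (when a substrate column is
#' given); if no prefix qualifies it falls back to the first three points
#' with a warning.
#'
#' @param timecourse Data frame with a time column and a product column
#'   (defaults match [simulate_batch()] output).
#' @param time,response Column names for time (min) and product (uM).
#' @param substrate Optional column name of the varied NTP, used for the
#'   consumption guard.
#' @param r2_min Minimum prefix R^2 (default 0.99).
#' @param max_frac_consumed Maximum fraction of the varied substrate consumed
#'   within the window (default 0.1).
#' @return One-row tibble: `rate_uM_per_min`, `se`, `n_points`, `t_end_min`,
#'   `r2`, `fallback`.
#' @export
extract_initial_rate <- function(timecourse, time = "t_min",
                                 response = "c_mRNA_uM", substrate = NULL,
                                 r2_min = 0.99, max_frac_consumed = 0.1) {
  d <- tibble::as_tibble(timecourse)
  if (!all(c(time, response) %in% names(d))) {
    abort("time/response columns not found", class = "ivtwin_invalid_input")
  }
  t <- d[[time]]; y <- d[[response]]
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 3L) {
    abort("need >= 3 usable time points", class = "ivtwin_insufficient_data")
  }
  s0 <- if (!is.null(substrate)) d[[substrate]][ok][1L] else NA_real_

  prefix_fit <- function(k) {
    fit <- lm(y[seq_len(k)] ~ t[seq_len(k)])
    ssr <- sum(residuals(fit)^2)
    sst <- sum((y[seq_len(k)] - mean(y[seq_len(k)]))^2)
    r2 <- if (sst <= .Machine$double.eps) 1 else 1 - ssr / sst
    list(fit = fit, r2 = r2)
  }
  consumed_ok <- function(k) {
    if (is.na(s0) || s0 <= 0) return(TRUE)
    s_k <- d[[substrate]][ok][k]
    (s0 - s_k) / s0 < max_frac_consumed
  }

  chosen <- NULL; fallback <- FALSE
  for (k in rev(seq(3L, length(t)))) {
    pf <- prefix_fit(k)
    if (pf$r2 >= r2_min && consumed_ok(k)) { chosen <- c(pf, k = k); break }
  }
  if (is.null(chosen)) {
    warn("extract_initial_rate: no prefix met the window policy; using first 3 points")
    chosen <- c(prefix_fit(3L), k = 3L)
    fallback <- TRUE
  }
  co <- suppressWarnings(summary(chosen$fit))$coefficients
  se <- if (nrow(co) >= 2L && ncol(co) >= 2L) co[2L, 2L] else NA_real_
  tibble::tibble(
    rate_uM_per_min = unname(coef(chosen$fit)[2L]),
    se = unname(se), n_points = chosen$k,
    t_end_min = t[chosen$k], r2 = chosen$r2, fallback = fallback
  )
}

# --- shared fit-result plumbing -------------------------------------------

new_mm_fit <- function(km, km_se, vmax, vmax_se, method, adj_r2,
                       data, fitted, flags = character()) {
  structure(
    list(km = km, km_se = km_se, vmax = vmax, vmax_se = vmax_se,
         method = method, adj_r2 = adj_r2, data = data, fitted = fitted,
         residuals = data$v_uM_per_min - fitted, flags = flags),
    class = "mm_fit"
  )
}

.check_mm_fit <- function(fit) {
  if (!is.finite(fit$km) || fit$km <= 0 || !is.finite(fit$vmax) || fit$vmax <= 0) {
    abort(sprintf("degenerate fit: km = %.4g, vmax = %.4g (method %s)",
                  fit$km, fit$vmax, fit$method),
          class = "ivtwin_degenerate_fit")
  }
  fit
}

.adj_r2_from <- function(y, fitted, p = 2L) {
  n <- length(y)
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  if (sst <= .Machine$double.eps) return(NA_real_)
  1 - (ssr / (n - p)) / (sst / (n - 1))
}

.flag_df <- function(d, flags) {
  if (nrow(d) <= 2L) c(flags, "standard errors undefined (<= 2 points)") else flags
}

.prep_rates <- function(data, positive = FALSE) {
  d <- tibble::as_tibble(data)
  if (!all(c("c_uM", "v_uM_per_min") %in% names(d))) {
    abort("need columns `c_uM` and `v_uM_per_min`",
          class = "ivtwin_invalid_input")
  }
  .assert_finite(d$c_uM, "c_uM"); .assert_finite(d$v_uM_per_min, "v_uM_per_min")
  if (any(d$c_uM <= 0)) abort("substrate levels must be > 0",
                              class = "ivtwin_invalid_input")
  if (positive && any(d$v_uM_per_min <= 0)) {
    abort("rates must be > 0 for this linearization",
          class = "ivtwin_invalid_input")
  }
  d
}

# delta-method variance of g(b) given gradient and coefficient covariance
.delta_var <- function(grad, V) as.numeric(t(grad) %*% V %*% grad)

# profiled coarse-grid start: SSE(km) with vmax profiled analytically
.grid_start <- function(d, w) {
  kms <- exp(seq(log(min(d$c_uM) * 1e-3), log(max(d$c_uM) * 1e3),
                 length.out = 80L))
  sse <- vapply(kms, function(k) {
    g <- d$c_uM / (k + d$c_uM)
    vm <- sum(w * d$v_uM_per_min * g) / sum(w * g^2)
    sum(w * (d$v_uM_per_min - vm * g)^2)
  }, numeric(1))
  k <- kms[which.min(sse)]
  g <- d$c_uM / (k + d$c_uM)
  list(km = k, vmax = max(sum(w * d$v_uM_per_min * g) / sum(w * g^2), 1e-12))
}

# profiled Brent fit over log km with manual asymptotic standard errors;
# last-resort path of fit_nonlinear for near-degenerate data
.profile_fit <- function(d, w, why) {
  sse_of <- function(logk) {
    k <- exp(logk)
    g <- d$c_uM / (k + d$c_uM)
    vm <- sum(w * d$v_uM_per_min * g) / sum(w * g^2)
    sum(w * (d$v_uM_per_min - vm * g)^2)
  }
  opt <- stats::optimize(sse_of, interval = log(c(1e-9, max(d$c_uM) * 1e6)))
  km <- exp(opt$minimum)
  g <- d$c_uM / (km + d$c_uM)
  vmax <- sum(w * d$v_uM_per_min * g) / sum(w * g^2)
  fitted <- vmax * g
  n <- nrow(d)
  J <- cbind(km = -vmax * d$c_uM / (km + d$c_uM)^2, vmax = g)
  JtJ <- crossprod(J * sqrt(w))
  ses <- tryCatch({
    s2 <- sum(w * (d$v_uM_per_min - fitted)^2) / (n - 2L)
    sqrt(diag(s2 * solve(JtJ)))
  }, error = function(e) c(km = NA_real_, vmax = NA_real_))
  .check_mm_fit(new_mm_fit(
    km, if (n > 2L) ses[["km"]] else NA_real_,
    max(vmax, .Machine$double.xmin),
    if (n > 2L) ses[["vmax"]] else NA_real_,
    "nonlinear", .adj_r2_from(d$v_uM_per_min, fitted), d, fitted,
    .flag_df(d, paste0("profile-likelihood fallback (", why, ")"))
  ))
}

#' Michaelis-Menten estimation by the Lineweaver-Burk linearization
#'
#' Ordinary least squares of `1/v` on `1/c`: `vmax = 1/intercept`,
#' `km = slope/intercept`. Standard errors follow by first-order (delta
#' method) propagation from the regression covariance. The double-reciprocal
#' transform amplifies noise at low rates, so this estimator is kept as a
#' diagnostic; [fit_nonlinear()] is the headline estimator.
#'
#' @param data An [initial_rate_data()] or data frame with `c_uM`,
#'   `v_uM_per_min`.
#' @return An object of class `mm_fit`; see [tidy.mm_fit()], [glance.mm_fit()].
#' @examples
#' d <- gen_initial_rate_dataset(km = 100, vmax = 0.5, noise = NULL)
#' fit_lineweaver_burk(d)
#' @export
fit_lineweaver_burk <- function(data) {
  d <- .prep_rates(data, positive = TRUE)
  fit <- lm(I(1 / v_uM_per_min) ~ I(1 / c_uM), data = d)
  b <- coef(fit)
  if (!is.finite(b[1L]) || b[1L] <= 0) {
    abort("Lineweaver-Burk intercept <= 0: vmax not identifiable",
          class = "ivtwin_degenerate_fit")
  }
  vmax <- 1 / b[[1L]]
  km <- b[[2L]] / b[[1L]]
  if (nrow(d) > 2L) {
    V <- suppressWarnings(vcov(fit))
    vmax_se <- sqrt(.delta_var(c(-1 / b[1L]^2, 0), V))
    km_se <- sqrt(.delta_var(c(-b[2L] / b[1L]^2, 1 / b[1L]), V))
  } else {
    vmax_se <- km_se <- NA_real_
  }
  fitted <- rate_simple(d$c_uM, km, vmax)
  .check_mm_fit(new_mm_fit(km, km_se, vmax, vmax_se, "lineweaver_burk",
                           suppressWarnings(summary(fit))$adj.r.squared, d, fitted,
                           .flag_df(d, character())))
}

#' Michaelis-Menten estimation by the Hanes-Woolf linearization
#'
#' OLS of `c/v` on `c`: `vmax = 1/slope`, `km = intercept/slope`. Less
#' noise-distorting than Lineweaver-Burk because the transform weights
#' observations more evenly.
#'
#' @inheritParams fit_lineweaver_burk
#' @return An `mm_fit`.
#' @export
fit_hanes_woolf <- function(data) {
  d <- .prep_rates(data, positive = TRUE)
  fit <- lm(I(c_uM / v_uM_per_min) ~ c_uM, data = d)
  b <- coef(fit)
  if (!is.finite(b[2L]) || b[2L] <= 0) {
    abort("Hanes-Woolf slope <= 0: vmax not identifiable",
          class = "ivtwin_degenerate_fit")
  }
  vmax <- 1 / b[[2L]]
  km <- b[[1L]] / b[[2L]]
  if (nrow(d) > 2L) {
    V <- suppressWarnings(vcov(fit))
    vmax_se <- sqrt(.delta_var(c(0, -1 / b[2L]^2), V))
    km_se <- sqrt(.delta_var(c(1 / b[2L], -b[1L] / b[2L]^2), V))
  } else {
    vmax_se <- km_se <- NA_real_
  }
  fitted <- rate_simple(d$c_uM, km, vmax)
  .check_mm_fit(new_mm_fit(km, km_se, vmax, vmax_se, "hanes_woolf",
                           suppressWarnings(summary(fit))$adj.r.squared, d, fitted,
                           .flag_df(d, character())))
}

#' Michaelis-Menten estimation by the Eadie-Hofstee linearization
#'
#' OLS of `v` on `v/c`: `vmax` is the intercept and `km` the negated slope.
#'
#' @inheritParams fit_lineweaver_burk
#' @return An `mm_fit`.
#' @export
fit_eadie_hofstee <- function(data) {
  d <- .prep_rates(data, positive = TRUE)
  fit <- lm(v_uM_per_min ~ I(v_uM_per_min / c_uM), data = d)
  b <- coef(fit)
  vmax <- b[[1L]]
  km <- -b[[2L]]
  if (nrow(d) > 2L) {
    V <- suppressWarnings(vcov(fit))
    vmax_se <- sqrt(V[1L, 1L])
    km_se <- sqrt(V[2L, 2L])
  } else {
    vmax_se <- km_se <- NA_real_
  }
  fitted <- rate_simple(d$c_uM, max(km, .Machine$double.xmin), max(vmax, 0))
  .check_mm_fit(new_mm_fit(km, km_se, vmax, vmax_se, "eadie_hofstee",
                           suppressWarnings(summary(fit))$adj.r.squared, d, fitted,
                           .flag_df(d, character())))
}

#' Michaelis-Menten estimation by nonlinear least squares
#'
#' Levenberg-Marquardt fit of `v = vmax * c / (km + c)`, started from the
#' Hanes-Woolf estimates (overridable). This is the headline estimator; the
#' linearizations serve as diagnostics. Asymptotic standard errors and an
#' adjusted R^2 on the original rate scale are reported. An optional `1/v^2`
#' weighting approximates constant relative error.
#'
#' @inheritParams fit_lineweaver_burk
#' @param start Optional named list/vector with starting `km`, `vmax`.
#' @param weight_inv_v2 Weight observations by `1/v^2`.
#' @return An `mm_fit`.
#' @export
fit_nonlinear <- function(data, start = NULL, weight_inv_v2 = FALSE) {
  d <- .prep_rates(data)
  if (is.null(start)) {
    start <- tryCatch({
      hw <- fit_hanes_woolf(d)
      list(km = hw$km, vmax = hw$vmax)
    }, error = function(e) list(km = stats::median(d$c_uM),
                                vmax = max(d$v_uM_per_min)))
  }
  w <- if (weight_inv_v2) 1 / pmax(d$v_uM_per_min, .Machine$double.eps)^2
       else rep(1, nrow(d))
  run_lm <- function(st) {
    minpack.lm::nlsLM(
      v_uM_per_min ~ vmax * c_uM / (km + c_uM), data = d,
      start = list(km = st$km, vmax = st$vmax),
      weights = w, lower = c(km = 1e-9, vmax = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }
  fit <- tryCatch(run_lm(start), error = function(e) e)
  if (inherits(fit, "error")) {
    # weakly identified data can defeat the linearization start; restart from
    # a coarse profiled grid (vmax is linear given km, so it is profiled
    # analytically at each candidate km)
    st2 <- .grid_start(d, w)
    fit <- tryCatch(run_lm(st2), error = function(e) e)
  }
  if (inherits(fit, "error")) {
    # near-degenerate data (LS optimum at km ~ 0) make the nls gradient
    # singular; fall back to profiled Brent minimization over log km, which
    # always returns the least-squares optimum
    return(.profile_fit(d, w, conditionMessage(fit)))
  }
  b <- coef(fit)
  co <- summary(fit)$coefficients
  fitted <- rate_simple(d$c_uM, b[["km"]], b[["vmax"]])
  flags <- .flag_df(d, character())
  .check_mm_fit(new_mm_fit(
    b[["km"]], if (nrow(d) > 2L) co["km", "Std. Error"] else NA_real_,
    b[["vmax"]], if (nrow(d) > 2L) co["vmax", "Std. Error"] else NA_real_,
    "nonlinear", .adj_r2_from(d$v_uM_per_min, fitted), d, fitted, flags
  ))
}

#' Fit all estimation methods across per-NTP datasets
#'
#' Applies each requested estimator to each base's initial-rate dataset and
#' returns one row per (base, method). Fits with an adjusted R^2 below
#' `r2_flag` are flagged for review.
#'
#' @param data Data frame with columns `base`, `c_uM`, `v_uM_per_min` (and
#'   optionally `replicate`) covering one dataset per base.
#' @param methods Estimators to run.
#' @param r2_flag Adjusted-R^2 review threshold (default 0.97).
#' @return Tibble: `base`, `method`, `km`, `km_se`, `vmax`, `vmax_se`,
#'   `adj_r2`, `flagged`.
#' @export
estimate_all <- function(data,
                         methods = c("lineweaver_burk", "hanes_woolf",
                                     "eadie_hofstee", "nonlinear"),
                         r2_flag = 0.97) {
  d <- .prep_rates(data)
  if (!"base" %in% names(d)) abort("need a `base` column",
                                   class = "ivtwin_invalid_input")
  fitters <- list(lineweaver_burk = fit_lineweaver_burk,
                  hanes_woolf = fit_hanes_woolf,
                  eadie_hofstee = fit_eadie_hofstee,
                  nonlinear = fit_nonlinear)
  methods <- match.arg(methods, names(fitters), several.ok = TRUE)
  grid <- tidyr::expand_grid(base = unique(d$base), method = methods)
  purrr::pmap_dfr(grid, function(base, method) {
    fit <- fitters[[method]](d[d$base == base, , drop = FALSE])
    tibble::tibble(base = base, method = method,
                   km = fit$km, km_se = fit$km_se,
                   vmax = fit$vmax, vmax_se = fit$vmax_se,
                   adj_r2 = fit$adj_r2,
                   flagged = is.na(fit$adj_r2) || fit$adj_r2 < r2_flag)
  })
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit:%s> km = %.4g +/- %.2g uM, vmax = %.4g +/- %.2g uM/min, adj R2 = %.4f\n",
              x$method, x$km, x$km_se, x$vmax, x$vmax_se, x$adj_r2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(term = c("km", "vmax"),
                 estimate = c(x$km, x$vmax),
                 std.error = c(x$km_se, x$vmax_se))
}

#' One-row summary of a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `km`, `km_se`, `vmax`, `vmax_se`,
#'   `adj.r.squared`, `nobs`, `flagged`.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(method = x$method, km = x$km, km_se = x$km_se,
                 vmax = x$vmax, vmax_se = x$vmax_se,
                 adj.r.squared = x$adj_r2, nobs = nrow(x$data),
                 flagged = length(x$flags) > 0)
}

#' Plot a Michaelis-Menten fit over its data
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot of rate vs substrate with the fitted curve.
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(c_uM = seq(0, max(object$data$c_uM), length.out = 200))
  grid$v <- rate_simple(grid$c_uM, object$km, object$vmax)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$c_uM, .data$v_uM_per_min)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$c_uM, .data$v),
                       colour = "steelblue") +
    ggplot2::labs(x = "substrate (uM)", y = "initial rate (uM/min)",
                  title = sprintf("%s: km = %.3g uM, vmax = %.3g uM/min",
                                  object$method, object$km, object$vmax)) +
    ggplot2::theme_minimal()
}
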