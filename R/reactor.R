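#' Segmented-flow reactor configuration
#'
#' Operating parameters of a plug flow reactor run in segmented (slug) flow:
#' each aqueous reaction slug transits the tube in the residence time `tau`
#' and behaves like an independent batch, so candidates can be injected every
#' `dt` minutes instead of waiting a full residence time between batches.
#' `tau` is a direct input: the tube geometry (18 m of 1/16 in. tubing at
#' 0.2 mL/min in the reference setup) does not pin it down unambiguously.
#'
#' @param tau Residence time, min (> 0).
#' @param dt Injection interval, min (> 0).
#' @param horizon Operating window T, min (>= tau).
#' @param flow_ml_min Informational flow rate, mL/min.
#' @return An object of class `reactor_config`.
#' @examples
#' reactor_config(tau = 135, dt = 6.6, horizon = 270)
#' @export
reactor_config <- function(tau, dt, horizon, flow_ml_min = NA_real_) {
  .assert_finite(tau, "tau"); .assert_finite(dt, "dt")
  .assert_finite(horizon, "horizon")
  if (tau <= 0 || dt <= 0) abort("`tau` and `dt` must be > 0",
                                 class = "ivtwin_invalid_input")
  if (horizon < tau) abort("`horizon` must be >= tau",
                           class = "ivtwin_invalid_input")
  structure(list(tau = tau, dt = dt, horizon = horizon,
                 flow_ml_min = flow_ml_min, fill = "prefill-oil"),
            class = "reactor_config")
}

#' Build a slug injection/outlet schedule
#'
#' The reactor is pre-filled with the oil phase, so the first slug enters one
#' injection interval after start-up: injections at `dt, 2*dt, 3*dt, ...` as
#' long as they fit the horizon, each slug leaving the reactor `tau` minutes
#' after injection. A slug counts as produced iff its outlet time is within
#' the horizon, giving `floor((horizon - tau) / dt)` produced slugs.
#'
#' @param cfg A [reactor_config()].
#' @param candidates Optional candidate labels, recycled over slugs.
#' @return Tibble of class `slug_schedule`: `slug`, `candidate`, `t_in_min`,
#'   `t_out_min`, `produced`.
#' @examples
#' sched <- build_schedule(reactor_config(135, 6.6, 270))
#' sum(sched$produced)
#' @export
build_schedule <- function(cfg, candidates = NULL) {
  stopifnot(inherits(cfg, "reactor_config"))
  n_inj <- floor(cfg$horizon / cfg$dt + .TIME_EPS)
  if (n_inj < 1L) {
    warn("horizon too short for a single injection; empty schedule")
    n_inj <- 0L
  }
  k <- seq_len(n_inj)
  t_in <- k * cfg$dt
  t_out <- t_in + cfg$tau
  produced <- t_out <= cfg$horizon + .TIME_EPS
  if (!any(produced) && n_inj > 0L) {
    warn("no slug completes within the horizon (horizon < tau + dt)")
  }
  lab <- if (is.null(candidates)) paste0("candidate-", k)
         else rep_len(as.character(candidates), n_inj)
  out <- tibble::tibble(slug = k, candidate = lab,
                        t_in_min = t_in, t_out_min = t_out,
                        produced = produced)
  attr(out, "config") <- cfg
  class(out) <- c("slug_schedule", class(out))
  out
}

#' Number of slugs produced within the horizon
#'
#' @param schedule A `slug_schedule` from [build_schedule()].
#' @return Integer count of slugs whose outlet time is within the horizon.
#' @export
n_produced <- function(schedule) {
  stopifnot(inherits(schedule, "slug_schedule"))
  sum(schedule$produced)
}

#' Productivity gain of segmented over sequential operation
#'
#' Ratio of the segmented-flow slug count ([build_schedule()]) to the number
#' of sequential batches that fit the same window, `floor(horizon / tau)`
#' (floored at 1). With a 6.6 min injection interval, 135 min residence time
#' and a 270 min window this is 20 / 2 = 10.
#'
#' @param cfg A [reactor_config()].
#' @return Dimensionless productivity factor.
#' @export
productivity_factor <- function(cfg) {
  stopifnot(inherits(cfg, "reactor_config"))
  seg <- n_produced(suppressWarnings(build_schedule(cfg)))
  seq_n <- max(floor(cfg$horizon / cfg$tau + .TIME_EPS), 1)
  seg / seq_n
}

#' Detect slugs in a detector trace
#'
#' Threshold-crossing detection with hysteresis on a uniformly sampled
#' conductivity (or UV) trace. The threshold sits midway between a robust
#' baseline (median) and a robust peak level (95th percentile); the rising
#' and falling thresholds are separated by `hysteresis_frac` of that span,
#' and detections shorter than `min_duration` are discarded.
#'
#' @param trace Data frame with columns `t_min` and `signal`, uniformly
#'   sampled.
#' @param min_duration Minimum slug duration, min (default 0.5).
#' @param hysteresis_frac Hysteresis as a fraction of the baseline-to-peak
#'   span (default 0.1).
#' @return List of class `slug_detection`: `events` (tibble `slug_id`,
#'   `t_start_min`, `t_end_min`, `t_mid_min`), `count`, `spacing_mean_min`,
#'   `spacing_sd_min`. A trace with no crossings yields `count = 0`.
#' @export
detect_slugs <- function(trace, min_duration = 0.5, hysteresis_frac = 0.1) {
  d <- tibble::as_tibble(trace)
  if (!all(c("t_min", "signal") %in% names(d))) {
    abort("trace needs columns `t_min` and `signal`",
          class = "ivtwin_invalid_input")
  }
  .assert_finite(d$signal, "signal")
  dt <- diff(d$t_min)
  if (length(dt) < 2L || any(abs(dt - dt[1L]) > 1e-6 * dt[1L])) {
    abort("trace must be uniformly sampled with >= 3 points",
          class = "ivtwin_invalid_input")
  }

  base <- median(d$signal)
  peak <- quantile(d$signal, 0.95, names = FALSE)
  span <- peak - base
  empty <- list(events = tibble::tibble(slug_id = integer(),
                                        t_start_min = numeric(),
                                        t_end_min = numeric(),
                                        t_mid_min = numeric()),
                count = 0L,
                spacing_mean_min = NA_real_, spacing_sd_min = NA_real_)
  class(empty) <- "slug_detection"
  if (span <= 0) return(empty)

  mid <- base + span / 2
  up_thr <- mid + hysteresis_frac * span / 2
  dn_thr <- mid - hysteresis_frac * span / 2

  inside <- FALSE
  starts <- ends <- numeric()
  for (i in seq_len(nrow(d))) {
    s <- d$signal[i]
    if (!inside && s >= up_thr) {
      inside <- TRUE
      starts <- c(starts, d$t_min[i])
    } else if (inside && s <= dn_thr) {
      inside <- FALSE
      ends <- c(ends, d$t_min[i])
    }
  }
  if (inside) ends <- c(ends, d$t_min[nrow(d)])
  keep <- (ends - starts) >= min_duration
  starts <- starts[keep]; ends <- ends[keep]

  ev <- tibble::tibble(slug_id = seq_along(starts),
                       t_start_min = starts, t_end_min = ends,
                       t_mid_min = (starts + ends) / 2)
  spacing <- diff(ev$t_mid_min)
  out <- list(events = ev, count = nrow(ev),
              spacing_mean_min = if (length(spacing)) mean(spacing) else NA_real_,
              spacing_sd_min = if (length(spacing) > 1L) sd(spacing) else NA_real_)
  class(out) <- "slug_detection"
  out
}

#' @export
print.slug_detection <- function(x, ...) {
  cat(sprintf("<slug_detection> %d slug(s); spacing %.3g +/- %.3g min\n",
              x$count, x$spacing_mean_min, x$spacing_sd_min))
  invisible(x)
}

#' Residence-time statistics from paired inlet/outlet events
#'
#' Pairs the i-th inlet with the i-th outlet event (order-preserving), giving
#' per-slug residence times, and compares adjacent inter-slug spacings at
#' inlet vs outlet (`|diff(outlet) - diff(inlet)|`) as a measure of transit
#' jitter.
#'
#' @param t_in,t_out Event times, min; equal length, each increasing.
#' @return One-row tibble: `n`, `residence_mean_min`, `residence_sd_min`,
#'   `spacing_dev_mean_min`, `spacing_dev_sd_min`, `single_slug` flag
#'   (sd undefined for one slug).
#' @export
residence_stats <- function(t_in, t_out) {
  .assert_finite(t_in, "t_in"); .assert_finite(t_out, "t_out")
  if (length(t_in) != length(t_out)) {
    abort("inlet/outlet event counts differ: cannot pair slugs",
          class = "ivtwin_pairing_error")
  }
  if (length(t_in) < 1L) abort("no events", class = "ivtwin_invalid_input")
  if (is.unsorted(t_in, strictly = TRUE) || is.unsorted(t_out, strictly = TRUE)) {
    abort("event times must be strictly increasing",
          class = "ivtwin_pairing_error")
  }
  res <- t_out - t_in
  if (any(res <= 0)) abort("outlet events must follow their inlet events",
                           class = "ivtwin_pairing_error")
  dev <- abs(diff(t_out) - diff(t_in))
  tibble::tibble(
    n = length(res),
    residence_mean_min = mean(res),
    residence_sd_min = if (length(res) > 1L) sd(res) else NA_real_,
    spacing_dev_mean_min = if (length(dev)) mean(dev) else NA_real_,
    spacing_dev_sd_min = if (length(dev) > 1L) sd(dev) else NA_real_,
    single_slug = length(res) == 1L
  )
}

#' Per-NTP substrate consumption of a reaction
#'
#' Percent of each NTP consumed between the start and the end of a reaction,
#' `100 * (initial - final) / initial`, and the arithmetic mean across bases.
#'
#' @param initial,final Named per-base concentrations, uM; `final` must not
#'   exceed `initial`.
#' @return Tibble: `base`, `initial_uM`, `final_uM`, `consumed_pct`, with the
#'   cross-base mean in attribute `mean_pct` (also via [mean_consumption()]).
#' @examples
#' consumption_pct(c(A = 10000, C = 10000, G = 10000, U = 10000),
#'                 c(A = 2850, C = 2750, G = 3570, U = 1430))
#' @export
consumption_pct <- function(initial, final) {
  initial <- .base_vec(unlist(initial), "initial")
  final <- .base_vec(unlist(final), "final")
  .assert_nonneg(initial, "initial"); .assert_nonneg(final, "final")
  if (any(final > initial * (1 + 1e-12))) {
    abort("final concentrations exceed initial: negative consumption",
          class = "ivtwin_negative_consumption")
  }
  pct <- 100 * (initial - final) / initial
  out <- tibble::tibble(base = .BASES, initial_uM = unname(initial),
                        final_uM = unname(final), consumed_pct = unname(pct))
  attr(out, "mean_pct") <- mean(pct)
  out
}

#' @rdname consumption_pct
#' @param consumption A tibble from [consumption_pct()].
#' @export
mean_consumption <- function(consumption) attr(consumption, "mean_pct")

#' Signed relative change between two percentages
#'
#' `100 * (before - after) / before`: positive values are reductions.
#' A truncated-mRNA fraction falling from 82% to 55.3% is a 32.6% reduction.
#'
#' @param before,after Values on the same scale; `before` must be nonzero.
#' @return Signed percent change.
#' @export
relative_change <- function(before, after) {
  .assert_finite(before, "before"); .assert_finite(after, "after")
  if (any(before == 0)) abort("`before` must be nonzero",
                              class = "ivtwin_invalid_input")
  100 * (before - after) / before
}

#' Plot a detector trace with detected slugs
#'
#' @param object A `slug_detection`.
#' @param trace The trace the detection was run on.
#' @param ... Unused.
#' @return A ggplot of the signal with shaded slug windows.
#' @export
autoplot.slug_detection <- function(object, trace, ...) {
  ggplot2::ggplot(tibble::as_tibble(trace),
                  ggplot2::aes(.data$t_min, .data$signal)) +
    ggplot2::geom_rect(data = object$events, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$t_start_min,
                                    xmax = .data$t_end_min,
                                    ymin = -Inf, ymax = Inf),
                       fill = "goldenrod", alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "signal") +
    ggplot2::theme_minimal()
}
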