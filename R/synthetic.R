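#' Measurement-noise specification
#'
#' Noise applied to generated observations: multiplicative Gaussian with
#' coefficient of variation `cv` and/or additive Gaussian with standard
#' deviation `sd` (concentration units). The default, cv = 2%, matches the
#' run-to-run reproducibility of segmented-flow yields the package's
#' reference system achieves; the experimental noise *structure* is not
#' identified by that workflow, so multiplicative is a documented default,
#' not an inference.
#'
#' @param cv Multiplicative coefficient of variation (>= 0).
#' @param sd Additive standard deviation (>= 0).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.02, sd = 0) {
  .assert_nonneg(cv, "cv"); .assert_nonneg(sd, "sd")
  structure(list(cv = cv, sd = sd), class = "noise_spec")
}

.apply_noise <- function(x, noise) {
  if (is.null(noise)) return(x)
  stopifnot(inherits(noise, "noise_spec"))
  y <- x * (1 + noise$cv * rnorm(length(x))) + noise$sd * rnorm(length(x))
  pmax(y, 0)  # concentrations cannot be negative after noise
}

#' Catalog of named generator fixtures
#'
#' Reproducible generator configurations used throughout the test suite:
#' per-NTP initial-rate experiments with known truth
#' (`ref-ATP/CTP/GTP/UTP`: Km 140.4 / 71.5 / 165.5 / 101.5 uM, vmax 0.358
#' uM/min), a 4284-nt GC-rich construct (`bnt-like`, synthetic base
#' composition), a shorter alternative construct (`alt-transcript`) for
#' cross-transcript checks, and a high-yield operating point
#' (`optimum-op`, 10 g/L-scale batch). Every fixture is a pure function of
#' (name, seed).
#'
#' @return Tibble: `fixture`, `kind`, `base`, `km_uM`, `vmax_uM_min`,
#'   `n_mrna`, `description`.
#' @export
fixture_catalog <- function() {
  tibble::tribble(
    ~fixture, ~kind, ~base, ~km_uM, ~vmax_uM_min, ~n_mrna, ~description,
    "ref-ATP", "initial_rate", "A", 140.4, 0.358, NA_integer_,
    "ATP initial-rate experiment, generator truth = reference calibration",
    "ref-CTP", "initial_rate", "C", 71.5, 0.358, NA_integer_,
    "CTP initial-rate experiment",
    "ref-GTP", "initial_rate", "G", 165.5, 0.358, NA_integer_,
    "GTP initial-rate experiment",
    "ref-UTP", "initial_rate", "U", 101.5, 0.358, NA_integer_,
    "UTP initial-rate experiment",
    "bnt-like", "transcript", NA_character_, NA_real_, NA_real_, 4284L,
    "4284-nt construct; synthetic GC-rich base composition",
    "alt-transcript", "transcript", NA_character_, NA_real_, NA_real_, 1500L,
    "shorter construct with a different composition",
    "optimum-op", "operating_point", NA_character_, NA_real_, NA_real_, 4284L,
    "high-yield batch reaching ~10 g/L mRNA at 10 mM NTPs"
  )
}

#' Transcript fixtures
#'
#' @param fixture `"bnt-like"` or `"alt-transcript"`.
#' @return A [transcript_spec()].
#' @export
fixture_transcript <- function(fixture = c("bnt-like", "alt-transcript")) {
  fixture <- match.arg(fixture)
  if (fixture == "bnt-like") {
    # synthetic approximation of a codon-optimized GC-rich vaccine construct
    transcript_spec("bnt-like", 4284L, c(A = 0.26, C = 0.28, G = 0.29, U = 0.17))
  } else {
    transcript_spec("alt-transcript", 1500L,
                    c(A = 0.30, C = 0.22, G = 0.24, U = 0.24))
  }
}

#' Generate noisy IVT progress curves
#'
#' Simulates a batch reaction ([simulate_batch()]) sampled at the given times
#' and overlays measurement noise on every concentration column (clipped at
#' 0). The generating truth (parameters and noise-free trajectory) travels
#' along in the `truth` attribute so tests never reverse-engineer it.
#'
#' @param params,transcript,ppiase,c_d As in [simulate_batch()].
#' @param init Named initial NTP concentrations, uM.
#' @param times Sampling times, min.
#' @param noise A [noise_spec()] or `NULL` for noise-free output.
#' @param seed Integer seed.
#' @return Trajectory tibble in the [simulate_batch()] column layout with a
#'   `truth` attribute (list: `params`, `clean`).
#' @export
gen_progress_curves <- function(params, transcript, init,
                                times = seq(0, 120, by = 10),
                                ppiase = ppiase_params(quiet = TRUE),
                                noise = noise_spec(), seed = 1L, c_d = NULL) {
  clean <- simulate_batch(init, params, ppiase, transcript, times, c_d = c_d)
  out <- tibble::as_tibble(clean)
  if (!is.null(noise)) {
    cols <- setdiff(names(out), "t_min")
    out[cols] <- withr::with_seed(seed, lapply(out[cols], .apply_noise,
                                               noise = noise))
  }
  attr(out, "truth") <- list(params = params, transcript = transcript,
                             clean = tibble::as_tibble(clean), seed = seed)
  out
}

#' Generate an initial-rate dataset with known truth
#'
#' Rates are drawn from the apparent single-substrate law
#' ([rate_simple()]) at the generator truth and perturbed by measurement
#' noise. Truth comes either from a named fixture (`ref-ATP` etc.) or from
#' explicit `km`/`vmax`.
#'
#' @param fixture Fixture name from [fixture_catalog()], or `NULL` to use
#'   `km`, `vmax` and `base` directly.
#' @param km,vmax Explicit generator truth (uM, uM/min).
#' @param base Varied NTP for explicit truth.
#' @param levels Substrate levels, uM (default 2500/5000/7500/10000).
#' @param replicates Replicates per level.
#' @param noise A [noise_spec()] or `NULL` for noise-free rates.
#' @param seed Integer seed.
#' @return An [initial_rate_data()] tibble with a `truth` attribute
#'   (list: `km`, `vmax`, `base`, `seed`).
#' @examples
#' d <- gen_initial_rate_dataset("ref-ATP", noise = NULL)
#' attr(d, "truth")$km
#' @export
gen_initial_rate_dataset <- function(fixture = NULL, km = NULL, vmax = NULL,
                                     base = "A",
                                     levels = c(2500, 5000, 7500, 10000),
                                     replicates = 1L, noise = noise_spec(),
                                     seed = 1L) {
  if (!is.null(fixture)) {
    cat_row <- fixture_catalog()
    cat_row <- cat_row[cat_row$fixture == fixture & cat_row$kind == "initial_rate", ]
    if (nrow(cat_row) != 1L) {
      abort(paste0("unknown initial-rate fixture: ", fixture),
            class = "ivtwin_invalid_input")
    }
    km <- cat_row$km_uM; vmax <- cat_row$vmax_uM_min; base <- cat_row$base
  }
  if (is.null(km) || is.null(vmax)) {
    abort("supply a fixture name or explicit km and vmax",
          class = "ivtwin_invalid_input")
  }
  if (replicates < 1L) abort("`replicates` must be >= 1",
                             class = "ivtwin_invalid_input")
  d <- tidyr::expand_grid(replicate = seq_len(replicates), c_uM = levels)
  v <- rate_simple(d$c_uM, km, vmax)
  d$v_uM_per_min <- if (is.null(noise)) v
                    else withr::with_seed(seed, .apply_noise(v, noise))
  d$base <- base
  out <- initial_rate_data(d[, c("base", "c_uM", "v_uM_per_min", "replicate")])
  attr(out, "truth") <- list(km = km, vmax = vmax, base = base, seed = seed)
  out
}

#' Generate DoE responses from a known quadratic surface
#'
#' Evaluates a user-supplied second-order polynomial on the coded design and
#' adds Gaussian noise, so [fit_quadratic()] and [stepwise_reduce()] can be
#' checked against an exact truth.
#'
#' @param design A [generate_design()] table.
#' @param coef Named coefficients on coded units; allowed names are
#'   `"(Intercept)"`, `x1..x3`, `x1:x2`, `x1:x3`, `x2:x3`, `I(x1^2)`,
#'   `I(x2^2)`, `I(x3^2)`. Missing terms are 0.
#' @param sd Response noise standard deviation.
#' @param seed Integer seed.
#' @return Tibble `run_id`, `response`, with the truth in attribute `truth`.
#' @export
gen_doe_dataset <- function(design, coef, sd = 0, seed = 1L) {
  allowed <- c("(Intercept)", .QUAD_TERMS)
  bad <- setdiff(names(coef), allowed)
  if (length(bad)) abort(paste0("unknown terms: ", paste(bad, collapse = ", ")),
                         class = "ivtwin_invalid_input")
  d <- tibble::as_tibble(design)
  X <- cbind(`(Intercept)` = 1, x1 = d$x1, x2 = d$x2, x3 = d$x3,
             `x1:x2` = d$x1 * d$x2, `x1:x3` = d$x1 * d$x3,
             `x2:x3` = d$x2 * d$x3,
             `I(x1^2)` = d$x1^2, `I(x2^2)` = d$x2^2, `I(x3^2)` = d$x3^2)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta[names(coef)] <- unlist(coef)
  y <- as.numeric(X %*% beta)
  if (sd > 0) y <- y + withr::with_seed(seed, rnorm(length(y), sd = sd))
  out <- tibble::tibble(run_id = d$run_id, response = y)
  attr(out, "truth") <- list(coef = beta[beta != 0 | names(beta) %in% names(coef)],
                             sd = sd, seed = seed)
  out
}

#' Generate a synthetic detector trace for a slug schedule
#'
#' Rectangular conductivity pulses centered on each slug event, smoothed with
#' a Gaussian kernel (mimicking detector response and slug-boundary
#' dispersion), plus optional linear drift and Gaussian noise.
#'
#' @param event_times Slug event times, min (e.g. `t_in_min` or `t_out_min`
#'   of a [build_schedule()] table).
#' @param t_end Trace end time, min (defaults to last event + one duration).
#' @param baseline,amplitude Signal levels (baseline and pulse height).
#' @param duration Slug pulse duration, min.
#' @param sample_dt Sampling interval, min.
#' @param smooth_sd Gaussian smoothing kernel sd, min (0 = none).
#' @param noise_sd Additive Gaussian noise sd (signal units).
#' @param drift Linear drift, signal units per min.
#' @param seed Integer seed.
#' @return Tibble `t_min`, `signal`, with the schedule in attribute `truth`.
#' @export
gen_trace <- function(event_times, t_end = NULL, baseline = 1, amplitude = 10,
                      duration = 3, sample_dt = 0.05, smooth_sd = 0.1,
                      noise_sd = 0, drift = 0, seed = 1L) {
  .assert_finite(event_times, "event_times")
  if (!length(event_times)) abort("no events", class = "ivtwin_invalid_input")
  if (is.null(t_end)) t_end <- max(event_times) + duration
  t <- seq(0, t_end, by = sample_dt)
  signal <- rep(baseline, length(t))
  for (tc in event_times) {
    signal[t >= tc - duration / 2 & t < tc + duration / 2] <- baseline + amplitude
  }
  if (smooth_sd > 0) {
    half <- ceiling(4 * smooth_sd / sample_dt)
    kern <- exp(-0.5 * ((-half:half) * sample_dt / smooth_sd)^2)
    kern <- kern / sum(kern)
    padded <- c(rep(signal[1L], half), signal, rep(signal[length(signal)], half))
    signal <- as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_along(t)]
  }
  signal <- signal + drift * t
  if (noise_sd > 0) {
    signal <- signal + withr::with_seed(seed, rnorm(length(t), sd = noise_sd))
  }
  out <- tibble::tibble(t_min = t, signal = signal)
  attr(out, "truth") <- list(event_times = event_times, duration = duration,
                             baseline = baseline, amplitude = amplitude,
                             seed = seed)
  out
}
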