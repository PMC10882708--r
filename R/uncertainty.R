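#' Distribution of kinetic parameters from their determination precision
#'
#' Couples a nominal [kinetic_params()] with per-parameter standard errors so
#' that parameter-determination precision can be propagated into simulation
#' envelopes. Parameters are sampled independently (no covariance is
#' estimated by the initial-rate workflow) from normal laws truncated at a
#' small positive floor.
#'
#' @param params Nominal [kinetic_params()].
#' @param km_se Named per-base standard errors of the Michaelis constants
#'   (uM); 0 disables perturbation of a parameter.
#' @param vmax_se Standard error of `vmax` (uM/min).
#' @param floor_frac Truncation floor as a fraction of the mean (default
#'   1e-6).
#' @return An object of class `param_distribution`.
#' @examples
#' ref <- ivt_reference_params()
#' dist <- param_distribution(ref$params, ref$se$km, ref$se$vmax)
#' @export
param_distribution <- function(params, km_se = c(A = 0, C = 0, G = 0, U = 0),
                               vmax_se = 0, floor_frac = 1e-6) {
  stopifnot(inherits(params, "kinetic_params"))
  km_se <- .base_vec(km_se, "km_se")
  .assert_nonneg(km_se, "km_se")
  .assert_nonneg(vmax_se, "vmax_se")
  structure(list(params = params, km_se = km_se, vmax_se = vmax_se,
                 floor_frac = floor_frac),
            class = "param_distribution")
}

# one standard-normal deviate per perturbed parameter per draw, draw-major,
# so the first n draws of a longer stream are identical (prefix stability)
.param_draws <- function(dist, n, seed, se_scale = 1) {
  p <- 5L  # vmax + four km, in fixed order
  z <- withr::with_seed(seed, matrix(rnorm(n * p), nrow = n, ncol = p,
                                     byrow = TRUE))
  means <- c(dist$params$vmax, dist$params$km)
  ses <- c(dist$vmax_se, dist$km_se) * se_scale
  lapply(seq_len(n), function(i) {
    vals <- pmax(means + ses * z[i, ], dist$floor_frac * means)
    kinetic_params(vmax = vals[1L],
                   km = setNames(vals[2:5], .BASES),
                   ki = dist$params$ki, km_d = dist$params$km_d,
                   kd_gtp = dist$params$kd_gtp, ki_ppi = dist$params$ki_ppi)
  })
}

#' Sample kinetic parameter sets from their determination precision
#'
#' Independent normal draws per parameter, truncated at
#' `floor_frac * mean`, reproducible under a fixed seed.
#'
#' @param dist A [param_distribution()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @param se_scale Multiplier on all standard errors (common-random-number
#'   comparisons of band width use the same seed with different scales).
#' @return List of `n` [kinetic_params()] objects.
#' @export
sample_params <- function(dist, n, seed = 1L, se_scale = 1) {
  stopifnot(inherits(dist, "param_distribution"))
  if (!is.numeric(n) || n < 1L) abort("`n` must be >= 1",
                                      class = "ivtwin_invalid_input")
  .param_draws(dist, as.integer(n), seed, se_scale)
}

#' Monte Carlo prediction envelope of a batch simulation
#'
#' Propagates the determination precision of the kinetic parameters into a
#' pointwise band around the simulated trajectory: `n` parameter sets are
#' drawn from `dist`, each is simulated over `t_grid`, and per time point the
#' band is the min/max (default) or a quantile range across trajectories.
#' The nominal parameter set is always included as draw 0, so the band
#' contains the nominal trajectory by construction. A draw whose simulation
#' fails is retried once with tightened tolerances before erroring.
#'
#' @param init,ppiase,transcript,t_grid,c_d As in [simulate_batch()].
#' @param dist A [param_distribution()].
#' @param n Number of Monte Carlo draws (default 30).
#' @param seed Integer seed.
#' @param mode `"minmax"` (default) or `"quantile"` (5-95%).
#' @param se_scale Multiplier on all standard errors.
#' @return Tibble of class `ivt_envelope`: `t_min`, `observable`, `lower`,
#'   `upper`, plus `nominal`; attributes record `n_draws` and `seed`.
#' @export
mc_envelope <- function(init, dist, ppiase, transcript, t_grid,
                        n = 30L, seed = 1L, mode = c("minmax", "quantile"),
                        c_d = NULL, se_scale = 1) {
  stopifnot(inherits(dist, "param_distribution"))
  mode <- match.arg(mode)
  draws <- c(list(dist$params), sample_params(dist, n, seed, se_scale))

  sim_one <- function(p) {
    tryCatch(
      simulate_batch(init, p, ppiase, transcript, t_grid, c_d = c_d),
      error = function(e) {
        simulate_batch(init, p, ppiase, transcript, t_grid, c_d = c_d,
                       rtol = 1e-10, atol = 1e-12)
      }
    )
  }
  trajs <- lapply(draws, sim_one)

  obs_cols <- c("c_mRNA_uM", "c_ATP_uM", "c_CTP_uM", "c_GTP_uM", "c_UTP_uM",
                "c_PPi_uM")
  band <- purrr::map_dfr(obs_cols, function(col) {
    m <- vapply(trajs, function(tr) tr[[col]], numeric(length(t_grid)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    bounds <- if (mode == "minmax") {
      list(lo = apply(m, 1L, min), hi = apply(m, 1L, max))
    } else {
      list(lo = apply(m, 1L, quantile, probs = 0.05, names = FALSE),
           hi = apply(m, 1L, quantile, probs = 0.95, names = FALSE))
    }
    tibble::tibble(t_min = t_grid, observable = col,
                   lower = bounds$lo, upper = bounds$hi,
                   nominal = trajs[[1L]][[col]])
  })
  attr(band, "n_draws") <- as.integer(n)
  attr(band, "seed") <- as.integer(seed)
  attr(band, "mode") <- mode
  class(band) <- c("ivt_envelope", class(band))
  band
}

#' Plot a Monte Carlo prediction envelope
#'
#' @param object An `ivt_envelope`.
#' @param ... Unused.
#' @return A ggplot: nominal trajectory with shaded band, one panel per
#'   observable.
#' @export
autoplot.ivt_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_min, .data$nominal)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$observable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (uM)") +
    ggplot2::theme_minimal()
}
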