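#' Time derivatives of the batch IVT mass balances
#'
#' Runoff transcription with recycled template: the template concentration is
#' constant, each mRNA made consumes `f_i * n_mrna` of NTP i, and each
#' incorporated NTP releases one pyrophosphate, which the pyrophosphatase
#' hydrolyzes in turn:
#'
#' \deqn{dc_{mRNA}/dt = v}
#' \deqn{dc_{NTP,i}/dt = -f_i\, n_{mRNA}\, v}
#' \deqn{dc_{PPi}/dt = n_{mRNA}\, v - v_{PPiase}}
#' \deqn{dc_D/dt = 0}
#'
#' with `v` from [rate_full()] and `v_PPiase` from [rate_ppiase()].
#'
#' @param state Named concentrations, uM: `A`, `C`, `G`, `U`, `PPi`, `mRNA`
#'   (negative entries are clipped to 0 before evaluating rates).
#' @param params A [kinetic_params()].
#' @param ppiase A [ppiase_params()] or `NULL` (no pyrophosphatase).
#' @param transcript A [transcript_spec()].
#' @param c_d Template concentration, uM, or `NULL` for saturated promoter.
#' @return Named vector of time derivatives, uM/min.
#' @export
ode_rhs <- function(state, params, ppiase, transcript, c_d = NULL) {
  stopifnot(inherits(transcript, "transcript_spec"))
  y <- pmax(unlist(state)[c(.BASES, "PPi", "mRNA")], 0)
  v <- rate_full(y[.BASES], params, c_ppi = y[["PPi"]], c_d = c_d)
  v_pp <- if (is.null(ppiase)) 0 else rate_ppiase(y[["PPi"]], ppiase)
  n <- transcript$n_mrna
  d <- c(-transcript$f * n * v, n * v - v_pp, v)
  names(d) <- c(.BASES, "PPi", "mRNA")
  d
}

#' Simulate a batch in vitro transcription reaction
#'
#' Integrates the mass balances of [ode_rhs()] over a sampling grid with a
#' stiffness-switching solver (`deSolve::lsoda`, relative tolerance 1e-8,
#' absolute tolerance 1e-10 uM). Negative concentrations produced by solver
#' overshoot are clipped to zero in the returned table; the number of clipped
#' values is recorded in the `n_clipped` attribute and warned about.
#'
#' @param init Named initial concentrations, uM: the four bases (`A`, `C`,
#'   `G`, `U`) and optionally `PPi` and `mRNA` (default 0).
#' @param params A [kinetic_params()].
#' @param ppiase A [ppiase_params()] or `NULL` to omit pyrophosphatase.
#' @param transcript A [transcript_spec()].
#' @param t_grid Strictly increasing sampling times in minutes; the first
#'   entry is the initial time.
#' @param c_d Template concentration, uM, or `NULL` (saturated promoter).
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `ivt_trajectory` with columns `t_min`,
#'   `c_ATP_uM`, `c_CTP_uM`, `c_GTP_uM`, `c_UTP_uM`, `c_PPi_uM`, `c_mRNA_uM`;
#'   attributes carry the parameter provenance.
#' @examples
#' ts <- transcript_spec("demo", 500, c(A = .25, C = .25, G = .25, U = .25))
#' p <- ivt_reference_params()$params
#' traj <- simulate_batch(c(A = 1000, C = 1000, G = 1000, U = 1000),
#'                        p, NULL, ts, t_grid = seq(0, 60, by = 10))
#' @export
simulate_batch <- function(init, params, ppiase, transcript, t_grid,
                           c_d = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(transcript, "transcript_spec"))
  if (!is.null(ppiase)) stopifnot(inherits(ppiase, "ppiase_params"))
  .assert_finite(t_grid, "t_grid")
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0)) {
    abort("`t_grid` must be strictly increasing with >= 2 points",
          class = "ivtwin_invalid_input")
  }
  init <- unlist(init)
  for (sp in c("PPi", "mRNA")) if (!sp %in% names(init)) init[[sp]] <- 0
  y0 <- init[c(.BASES, "PPi", "mRNA")]
  if (anyNA(y0)) abort("`init` must name all four bases A, C, G, U",
                       class = "ivtwin_invalid_input")
  .assert_nonneg(y0, "init")

  rhs <- function(t, y, p) {
    list(ode_rhs(y, params, ppiase, transcript, c_d = c_d))
  }
  sol <- tryCatch(
    deSolve::lsoda(y = y0, times = t_grid, func = rhs, parms = NULL,
                   rtol = rtol, atol = atol, maxsteps = 50000),
    error = function(e) {
      abort(paste0("ODE solver failed: ", conditionMessage(e),
                   " (t0 = ", t_grid[1], ", init mRNA = ", y0[["mRNA"]], ")"),
            class = "ivtwin_solver_error")
    }
  )
  if (nrow(sol) < length(t_grid)) {
    abort(sprintf(
      "ODE solver stopped early at t = %.6g min (state: %s)",
      sol[nrow(sol), "time"],
      paste(sprintf("%s=%.4g", colnames(sol)[-1], sol[nrow(sol), -1]),
            collapse = ", ")),
      class = "ivtwin_solver_error")
  }

  m <- sol[, c(.BASES, "PPi", "mRNA"), drop = FALSE]
  n_clipped <- sum(m < 0)
  if (n_clipped > 0) {
    # undershoots within solver tolerance are numerically zero; only larger
    # excursions deserve a warning
    if (min(m) < -1e3 * atol) {
      warn(sprintf(
        "simulate_batch: clipped %d negative value(s) to 0 (worst %.3g)",
        n_clipped, min(m)))
    }
    m[m < 0] <- 0
  }
  out <- tibble::tibble(
    t_min = sol[, "time"],
    c_ATP_uM = m[, "A"], c_CTP_uM = m[, "C"],
    c_GTP_uM = m[, "G"], c_UTP_uM = m[, "U"],
    c_PPi_uM = m[, "PPi"], c_mRNA_uM = m[, "mRNA"]
  )
  new_ivt_trajectory(out, params = params, ppiase = ppiase,
                     transcript = transcript, c_d = c_d,
                     n_clipped = n_clipped)
}

new_ivt_trajectory <- function(x, ...) {
  meta <- list(...)
  attr(x, "ivt_meta") <- meta
  class(x) <- c("ivt_trajectory", class(x))
  x
}

#' Stoichiometric mRNA plateau of a batch reaction
#'
#' The reaction stops when the first NTP is exhausted, so the final mRNA
#' concentration is bounded by `min_i(c_NTP_i(0) / (f_i * n_mrna))`.
#'
#' @param init Named initial NTP concentrations, uM.
#' @param transcript A [transcript_spec()].
#' @return Plateau mRNA concentration, uM.
#' @export
plateau_mrna <- function(init, transcript) {
  stopifnot(inherits(transcript, "transcript_spec"))
  init <- .base_vec(unlist(init), "init")
  min(init / (transcript$f * transcript$n_mrna))
}

#' @export
print.ivt_trajectory <- function(x, ...) {
  meta <- attr(x, "ivt_meta")
  cat(sprintf("<ivt_trajectory> %d time points, %.4g-%.4g min (%s)\n",
              nrow(x), min(x$t_min), max(x$t_min),
              if (is.null(meta$transcript)) "unknown transcript"
              else meta$transcript$name))
  NextMethod()
}

#' Plot a simulated IVT trajectory
#'
#' @param object An `ivt_trajectory`.
#' @param ... Unused.
#' @return A ggplot: concentrations over time, one panel per species group.
#' @export
autoplot.ivt_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t_min",
                              names_to = "species", values_to = "c_uM")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_min, .data$c_uM,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (uM)") +
    ggplot2::theme_minimal()
}
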