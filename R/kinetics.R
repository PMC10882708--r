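#' Kinetic parameters of the transcription rate law
#'
#' Bundles every constant of the extended Michaelis-Menten rate law used by
#' [rate_full()]: the maximum mRNA production rate `vmax`, per-NTP Michaelis
#' constants `km`, per-NTP competitive-inhibition constants `ki`, the promoter
#' Michaelis constant `km_d`, the dissociation constant for initial GTP
#' binding `kd_gtp`, and the pyrophosphate inhibition constant `ki_ppi`.
#'
#' When `km` holds *apparent* Michaelis constants -- fitted with the other
#' three NTPs in excess, as in the standard initial-rate workflow -- the NTP
#' cross-inhibition they embody is already absorbed into the constants, and
#' the explicit competitive terms must be switched off. That is the default:
#' `ki = Inf` for all four bases. Supply finite `ki` only together with
#' intrinsic `km` values.
#'
#' @param vmax Maximum mRNA production rate, uM/min.
#' @param km Named per-base Michaelis constants, uM.
#' @param ki Named per-base competitive-inhibition constants, uM
#'   (`Inf` disables the term; the default, for apparent-`km` mode).
#' @param km_d Promoter Michaelis constant, uM (used only when a molar
#'   template concentration is supplied to [rate_full()]).
#' @param kd_gtp Dissociation constant for initial GTP binding, uM.
#' @param ki_ppi Pyrophosphate competitive-inhibition constant, uM.
#' @return An object of class `kinetic_params`.
#' @seealso [ivt_reference_params()] for the calibrated reference set.
#' @export
kinetic_params <- function(vmax, km, ki = c(A = Inf, C = Inf, G = Inf, U = Inf),
                           km_d = 1, kd_gtp = 600, ki_ppi = 1000) {
  km <- .base_vec(km, "km")
  ki <- .base_vec(ki, "ki")
  if (!is.numeric(vmax) || length(vmax) != 1L || is.na(vmax) || vmax < 0) {
    abort("`vmax` must be a single non-negative number (0 = no enzyme activity)",
          class = "ivtwin_invalid_input")
  }
  for (nm in c("km_d", "kd_gtp", "ki_ppi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort(paste0("`", nm, "` must be a single positive number"),
            class = "ivtwin_invalid_input")
    }
  }
  if (any(!is.numeric(km) | is.na(km) | km <= 0)) {
    abort("`km` must be strictly positive", class = "ivtwin_invalid_input")
  }
  if (any(is.na(ki) | ki <= 0)) {
    abort("`ki` must be strictly positive (Inf allowed)",
          class = "ivtwin_invalid_input")
  }
  structure(
    list(vmax = vmax, km = km, ki = ki, km_d = km_d,
         kd_gtp = kd_gtp, ki_ppi = ki_ppi),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> vmax = %.4g uM/min\n", x$vmax))
  cat(sprintf("  Km (uM): A %.4g, C %.4g, G %.4g, U %.4g\n",
              x$km["A"], x$km["C"], x$km["G"], x$km["U"]))
  mode <- if (all(is.infinite(x$ki))) "apparent-Km mode (NTP cross-inhibition off)"
          else "intrinsic mode (finite NTP inhibition constants)"
  cat("  ", mode, "\n", sep = "")
  invisible(x)
}

#' Reference kinetic parameter set for T7 runoff IVT
#'
#' Apparent Michaelis constants and maximum rate calibrated by initial-rate
#' experiments at 2.5-10 mM of the varied NTP with the other three in excess
#' (vmax 0.358 uM/min; Km 140.4/71.5/165.5/101.5 uM for A/C/G/U), together
#' with their standard errors for Monte Carlo propagation.
#'
#' @return A list with elements `params` (a [kinetic_params()]) and
#'   `se` (named standard errors for `vmax` and the four `km`).
#' @examples
#' ref <- ivt_reference_params()
#' ref$params$vmax
#' @export
ivt_reference_params <- function() {
  params <- kinetic_params(
    vmax = 0.358,
    km = c(A = 140.4, C = 71.5, G = 165.5, U = 101.5)
  )
  list(
    params = params,
    se = list(vmax = 0.001, km = c(A = 2.9, C = 1.9, G = 6.4, U = 3.8))
  )
}

#' Pyrophosphatase parameters
#'
#' The supplemented inorganic pyrophosphatase hydrolyzes the pyrophosphate
#' released by elongation and follows simple Michaelis-Menten kinetics
#' ([rate_ppiase()]). The rate constant and Michaelis constant are not
#' measured by the package's own workflow; documented defaults are shipped
#' and announced loudly when used.
#'
#' @param k_ppiase Rate constant, uM/min per U/uL of enzyme activity.
#'   Default 2e6, on the order implied by the unit definition
#'   1 U = 1 umol/min applied at microliter scale.
#' @param c_ppase Volume-based enzyme activity, U/uL (default 0.002, the
#'   standard supplementation level of the reaction buffer).
#' @param km_ppi Michaelis constant of pyrophosphate, uM (default 50).
#' @param quiet Suppress the defaults-in-use message.
#' @return An object of class `ppiase_params`.
#' @export
ppiase_params <- function(k_ppiase = 2e6, c_ppase = 0.002, km_ppi = 50,
                          quiet = FALSE) {
  defaulted <- c(
    if (missing(k_ppiase)) "k_ppiase = 2e6 uM/min/(U/uL)",
    if (missing(km_ppi)) "km_ppi = 50 uM"
  )
  if (length(defaulted) && !quiet) {
    inform(paste0("ppiase_params: using documented literature-scale defaults: ",
                  paste(defaulted, collapse = ", ")))
  }
  .assert_nonneg(k_ppiase, "k_ppiase")
  .assert_nonneg(c_ppase, "c_ppase")
  if (!is.finite(km_ppi) || km_ppi <= 0) {
    abort("`km_ppi` must be > 0", class = "ivtwin_invalid_input")
  }
  structure(list(k_ppiase = k_ppiase, c_ppase = c_ppase, km_ppi = km_ppi),
            class = "ppiase_params")
}

#' Transcription rate: extended Michaelis-Menten rate law
#'
#' Rate of full-length mRNA production as a function of the four free NTP
#' concentrations, pyrophosphate, and (optionally) the template/promoter
#' concentration:
#'
#' \deqn{v = v_{max}\;
#'   \frac{c_D}{c_D + K_{M,D}\left[1 + K_{d,GTP}/c_{GTP}\right]}\;
#'   \prod_{i \in \{A,C,G,U\}}
#'   \frac{c_i}{c_i + K_{M,i}\big(1 + \sum_{j \ne i} c_j/K_{I,j}
#'         + c_{PPi}/K_{I,PPi}\big)}}
#'
#' The promoter fraction carries the initiation term in square brackets:
#' transcription cannot initiate without GTP, so template saturation is
#' discounted by \eqn{K_{d,GTP}/c_{GTP}}. With `c_d = NULL` (default) the
#' template is treated as saturating and the promoter fraction is 1, which
#' matches runoff transcription with template in excess. Each NTP saturation
#' term is competitively inhibited by the other NTPs and by pyrophosphate;
#' with apparent Michaelis constants the NTP cross terms are disabled
#' (see [kinetic_params()]).
#'
#' The algebraic form lives in this one function so it can be swapped
#' without touching the simulator.
#'
#' @param c_ntp Named per-base free NTP concentrations, uM.
#' @param params A [kinetic_params()].
#' @param c_ppi Pyrophosphate concentration, uM.
#' @param c_d Template concentration, uM, or `NULL` for a saturated
#'   promoter term.
#' @return mRNA production rate, uM/min (a single non-negative number).
#' @examples
#' p <- ivt_reference_params()$params
#' rate_full(c(A = 10000, C = 10000, G = 10000, U = 10000), p)
#' @export
rate_full <- function(c_ntp, params, c_ppi = 0, c_d = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  c_ntp <- .base_vec(c_ntp, "c_ntp")
  .assert_nonneg(c_ntp, "c_ntp")
  .assert_nonneg(c_ppi, "c_ppi")
  if (any(c_ntp == 0)) return(0)  # absent substrate halts elongation

  inhib_ppi <- c_ppi / params$ki_ppi
  frac <- vapply(.BASES, function(i) {
    others <- setdiff(.BASES, i)
    comp <- sum(c_ntp[others] / params$ki[others]) + inhib_ppi
    c_ntp[[i]] / (c_ntp[[i]] + params$km[[i]] * (1 + comp))
  }, numeric(1))

  d_term <- 1
  if (!is.null(c_d)) {
    .assert_nonneg(c_d, "c_d")
    # initiation bracket: template binding is unproductive without GTP
    d_term <- c_d / (c_d + params$km_d * (1 + params$kd_gtp / c_ntp[["G"]]))
  }

  params$vmax * d_term * prod(frac)
}

#' Transcription rate: apparent single-substrate form
#'
#' Simple Michaelis-Menten kinetics in the varied NTP,
#' \eqn{v = v_{max} c / (K_{M,app} + c)}, valid for initial-rate conditions
#' where the other NTPs are in excess and pyrophosphate is removed by
#' pyrophosphatase. `km_app` is an apparent Michaelis constant that absorbs
#' any competitive inhibition present during its determination.
#'
#' @param c Substrate concentration(s), uM (vectorized).
#' @param km_app Apparent Michaelis constant, uM.
#' @param vmax Maximum rate, uM/min.
#' @return Rate(s), uM/min.
#' @examples
#' rate_simple(2500, 140.4, 0.358)
#' @export
rate_simple <- function(c, km_app, vmax) {
  .assert_nonneg(c, "c")
  if (!is.finite(km_app) || km_app <= 0) {
    abort("`km_app` must be > 0", class = "ivtwin_invalid_input")
  }
  if (!is.finite(vmax) || vmax < 0) {
    abort("`vmax` must be >= 0", class = "ivtwin_invalid_input")
  }
  vmax * c / (km_app + c)
}

#' Pyrophosphate hydrolysis rate of the supplemented pyrophosphatase
#'
#' \eqn{v = k_{PPiase}\, c_{PPase}\, c_{PPi} / (K_{M,PPi} + c_{PPi})}.
#'
#' @param c_ppi Pyrophosphate concentration, uM (vectorized).
#' @param ppiase A [ppiase_params()].
#' @return Consumption rate, uM/min.
#' @export
rate_ppiase <- function(c_ppi, ppiase) {
  stopifnot(inherits(ppiase, "ppiase_params"))
  .assert_nonneg(c_ppi, "c_ppi")
  ppiase$k_ppiase * ppiase$c_ppase * c_ppi / (ppiase$km_ppi + c_ppi)
}

#' Reduce the full rate law to the apparent single-substrate form
#'
#' With three NTPs fixed at excess levels and pyrophosphate controlled, the
#' full rate law becomes Michaelis-Menten in the varied NTP. Writing the
#' full law as a product of saturation fractions and freezing the excess
#' fractions at their fixed values (the varied NTP's back-inhibition on them
#' is second order under initial-rate conditions), the varied fraction reads
#' `c / (c + km_app)` with
#'
#' `km_app = km_i * (1 + sum_j(excess_j / ki_j) + c_ppi / ki_ppi)`
#'
#' and the frozen excess fractions (and promoter term) collapse into an
#' apparent plateau rate `vmax_app <= vmax`. At excess levels of 100x Km the
#' plateau sits about 3% below the true `vmax` -- which is exactly why
#' initial-rate fits deliver *apparent* constants.
#'
#' @param params A [kinetic_params()] (intrinsic or apparent mode).
#' @param varied Base whose concentration is varied ("A", "C", "G" or "U").
#' @param excess Named concentrations (uM) of the other three NTPs.
#' @param c_ppi Pyrophosphate concentration during the assay, uM.
#' @param c_d Template concentration, uM, or `NULL` for saturated promoter.
#' @return List with `km_app` and `vmax_app` (uM, uM/min).
#' @export
km_apparent <- function(params, varied, excess, c_ppi = 0, c_d = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  varied <- match.arg(varied, .BASES)
  others <- setdiff(.BASES, varied)
  if (!all(others %in% names(excess))) {
    abort("`excess` must name the three non-varied bases",
          class = "ivtwin_invalid_input")
  }
  excess <- excess[others]
  .assert_nonneg(unlist(excess), "excess")

  inhib_ppi <- c_ppi / params$ki_ppi
  km_app <- params$km[[varied]] *
    (1 + sum(excess / params$ki[others]) + inhib_ppi)

  # frozen excess fractions: varied NTP's inhibition evaluated at c = 0
  frac <- vapply(others, function(j) {
    rest <- setdiff(others, j)
    comp <- sum(excess[rest] / params$ki[rest]) + inhib_ppi
    excess[[j]] / (excess[[j]] + params$km[[j]] * (1 + comp))
  }, numeric(1))

  d_term <- 1
  if (!is.null(c_d)) {
    c_g <- if (varied == "G") Inf else excess[["G"]]
    d_term <- c_d / (c_d + params$km_d * (1 + params$kd_gtp / c_g))
  }

  list(km_app = unname(km_app), vmax_app = unname(params$vmax * d_term * prod(frac)))
}
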