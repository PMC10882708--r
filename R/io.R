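#' Fit a chromatographic calibration line
#'
#' Ordinary least squares of peak area on injected mass (with intercept by
#' default; force through the origin with `origin = TRUE`). Duplicate
#' injections at a level are used as replicates and their agreement is
#' summarized as the mean within-level coefficient of variation.
#'
#' @param data Data frame with columns `mass` (injected mass) and `area`
#'   (peak area); at least 3 distinct levels.
#' @param analyte Label.
#' @param origin Force the line through the origin.
#' @return Object of class `cal_curve`: slope, intercept, `r2`, calibrated
#'   range, duplicate agreement.
#' @examples
#' cal <- calibrate(data.frame(mass = c(.1, .5, 1, 2.5, 5),
#'                             area = 1000 * c(.1, .5, 1, 2.5, 5)))
#' cal$r2
#' @export
calibrate <- function(data, analyte = "analyte", origin = FALSE) {
  d <- tibble::as_tibble(data)
  if (!all(c("mass", "area") %in% names(d))) {
    abort("need columns `mass` and `area`", class = "ivtwin_invalid_input")
  }
  .assert_nonneg(d$mass, "mass"); .assert_finite(d$area, "area")
  if (length(unique(d$mass)) < 3L) {
    abort("need >= 3 distinct calibration levels",
          class = "ivtwin_insufficient_data")
  }
  fit <- if (origin) lm(area ~ mass + 0, data = d) else lm(area ~ mass, data = d)
  b <- coef(fit)
  slope <- unname(b[["mass"]])
  intercept <- if (origin) 0 else unname(b[["(Intercept)"]])
  sst <- sum((d$area - mean(d$area))^2)
  r2 <- if (sst <= .Machine$double.eps) NA_real_
        else 1 - sum(residuals(fit)^2) / sst
  flags <- character()
  if (is.na(r2)) flags <- c(flags, "zero-variance response: degenerate calibration")
  if (slope <= 0) flags <- c(flags, "non-positive slope")

  dup_cv <- d |>
    dplyr::group_by(.data$mass) |>
    dplyr::summarise(cv = if (dplyr::n() > 1L && mean(.data$area) != 0)
      sd(.data$area) / mean(.data$area) else NA_real_, .groups = "drop")
  structure(
    list(analyte = analyte, slope = slope, intercept = intercept, r2 = r2,
         range = range(d$mass), duplicate_cv = mean(dup_cv$cv, na.rm = TRUE),
         n_levels = length(unique(d$mass)), flags = flags, fit = fit),
    class = "cal_curve"
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve:%s> area = %.6g * mass %+.6g, R2 = %.4f, range [%g, %g]\n",
              x$analyte, x$slope, x$intercept, x$r2, x$range[1L], x$range[2L]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Quantify an analyte from a peak area
#'
#' Inverts the calibration line and multiplies by the dilution factor.
#' Samples are diluted before injection to stay within the calibrated range,
#' so the out-of-range flag refers to the *injected* (undiluted-prediction)
#' mass, not the back-calculated sample amount.
#'
#' @param area Peak area(s).
#' @param curve A [calibrate()] result.
#' @param dilution Dilution factor applied before injection (default 1).
#' @return Tibble: `area`, `mass_injected`, `mass` (dilution-corrected),
#'   `out_of_range`.
#' @export
quantify <- function(area, curve, dilution = 1) {
  stopifnot(inherits(curve, "cal_curve"))
  .assert_finite(area, "area")
  if (any(dilution <= 0)) abort("`dilution` must be > 0",
                                class = "ivtwin_invalid_input")
  if (curve$slope <= 0) abort("calibration slope must be > 0 to quantify",
                              class = "ivtwin_invalid_input")
  area <- as.vector(area, mode = "numeric")
  m_inj <- (area - curve$intercept) / curve$slope
  tibble::tibble(
    area = area,
    mass_injected = m_inj,
    mass = m_inj * dilution,
    out_of_range = m_inj < curve$range[1L] | m_inj > curve$range[2L]
  )
}

#' Truncated-mRNA fraction from a peak table
#'
#' `100 * A_truncated / (A_truncated + A_intact)`: the early-eluting peak of
#' an IP-RP separation holds the truncated transcripts, the late peak the
#' full-length product.
#'
#' @param peaks Data frame with columns `label` (containing `"truncated"` and
#'   `"intact"`) and `area` (>= 0).
#' @return Truncated fraction in percent.
#' @examples
#' truncated_fraction(data.frame(label = c("truncated", "intact"),
#'                               area = c(55.3, 44.7)))
#' @export
truncated_fraction <- function(peaks) {
  d <- tibble::as_tibble(peaks)
  if (!all(c("label", "area") %in% names(d))) {
    abort("need columns `label` and `area`", class = "ivtwin_invalid_input")
  }
  .assert_nonneg(d$area, "area")
  a_tr <- sum(d$area[d$label == "truncated"])
  a_in <- sum(d$area[d$label == "intact"])
  if (a_tr + a_in <= 0) abort("no truncated/intact peak area",
                              class = "ivtwin_invalid_input")
  100 * a_tr / (a_tr + a_in)
}

# trapezoidal integral
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Integrate chromatogram peaks
#'
#' Baseline-subtracted trapezoidal peak areas. Explicit retention windows can
#' be given; otherwise the two-peak mode locates the two largest local maxima
#' and splits the signal at the valley minimum between them (early peak
#' labelled `truncated`, late peak `intact`). The baseline under each window
#' is the straight line between the signal values at the window endpoints.
#'
#' @param chromatogram Data frame with columns `t_min` and `signal`.
#' @param windows Optional data frame `label`, `t_start_min`, `t_end_min`.
#' @param min_prominence Minimum peak height above the signal minimum, as a
#'   fraction of the signal span, for automatic detection (default 0.05).
#' @return Tibble (`PeakTable`): `label`, `t_start_min`, `t_end_min`, `area`.
#'   Empty when no peaks are detectable.
#' @export
integrate_peaks <- function(chromatogram, windows = NULL,
                            min_prominence = 0.05) {
  d <- tibble::as_tibble(chromatogram)
  if (!all(c("t_min", "signal") %in% names(d))) {
    abort("need columns `t_min` and `signal`", class = "ivtwin_invalid_input")
  }
  .assert_finite(d$signal, "signal")
  empty <- tibble::tibble(label = character(), t_start_min = numeric(),
                          t_end_min = numeric(), area = numeric())

  area_in <- function(t0, t1, label) {
    sel <- d$t_min >= t0 & d$t_min <= t1
    tt <- d$t_min[sel]; ss <- d$signal[sel]
    if (length(tt) < 2L) return(NULL)
    base <- ss[1L] + (ss[length(ss)] - ss[1L]) * (tt - tt[1L]) /
      (tt[length(tt)] - tt[1L])
    tibble::tibble(label = label, t_start_min = t0, t_end_min = t1,
                   area = .trapz(tt, ss - base))
  }

  if (!is.null(windows)) {
    w <- tibble::as_tibble(windows)
    out <- purrr::pmap_dfr(w[, c("t_start_min", "t_end_min", "label")],
                           function(t_start_min, t_end_min, label)
                             area_in(t_start_min, t_end_min, label))
    return(out)
  }

  span <- diff(range(d$signal))
  if (span <= 0) return(empty)
  s <- d$signal
  n <- length(s)
  is_max <- c(FALSE, s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n],
              FALSE) & (s - min(s) > min_prominence * span)
  peaks <- which(is_max)
  # collapse plateau maxima
  if (length(peaks) > 1L) peaks <- peaks[c(TRUE, diff(peaks) > 1L)]
  if (!length(peaks)) return(empty)

  if (length(peaks) == 1L) {
    return(area_in(d$t_min[1L], d$t_min[n], "intact"))
  }
  top2 <- peaks[order(s[peaks], decreasing = TRUE)][1:2]
  top2 <- sort(top2)
  valley <- top2[1L] - 1L + which.min(s[top2[1L]:top2[2L]])
  dplyr::bind_rows(
    area_in(d$t_min[1L], d$t_min[valley], "truncated"),
    area_in(d$t_min[valley], d$t_min[n], "intact")
  )
}

# --- CSV and config plumbing ----------------------------------------------

.TRAJ_COLS <- c("t_min", "c_ATP_uM", "c_CTP_uM", "c_GTP_uM", "c_UTP_uM",
                "c_PPi_uM", "c_mRNA_uM")

#' Read and write trajectory tables
#'
#' CSV dialect is fixed package-wide: comma separator, "." decimal, UTF-8,
#' mandatory header. Numbers are written with 12 significant digits so
#' round-trips are lossless to float-formatting precision.
#'
#' @param x Trajectory tibble with the [simulate_batch()] columns.
#' @param path File path.
#' @return `read_trajectory()` returns a tibble; `write_trajectory()` its
#'   input, invisibly.
#' @export
write_trajectory <- function(x, path) {
  d <- tibble::as_tibble(x)[, .TRAJ_COLS]
  .write_csv12(d, path)
  invisible(x)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(.TRAJ_COLS %in% names(d))) {
    abort("not a trajectory CSV (missing canonical columns)",
          class = "ivtwin_invalid_input")
  }
  d[, .TRAJ_COLS]
}

#' Read and write initial-rate tables
#'
#' Columns `base`, `c_uM`, `v_uM_per_min`, `replicate`.
#'
#' @param x Rate table.
#' @param path File path.
#' @return `read_rate_table()` returns an [initial_rate_data()] tibble.
#' @export
write_rate_table <- function(x, path) {
  d <- tibble::as_tibble(x)[, c("base", "c_uM", "v_uM_per_min", "replicate")]
  .write_csv12(d, path)
  invisible(x)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  initial_rate_data(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a generated dataset with its truth sidecar
#'
#' Writes the table as CSV plus a JSON sidecar (`<path>.truth.json`) holding
#' the generator truth, so downstream checks never reverse-engineer it.
#'
#' @param x A generated tibble carrying a `truth` attribute.
#' @param path CSV path.
#' @return The input, invisibly.
#' @export
write_with_truth <- function(x, path) {
  .write_csv12(tibble::as_tibble(x), path)
  truth <- attr(x, "truth")
  if (!is.null(truth)) {
    truth <- rapply(truth, function(v) if (is.object(v)) unclass(v) else v,
                    how = "replace")
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(x)
}

.write_csv12 <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) formatC(v, digits = 12, format = "g"))
  readr::write_csv(d, path)
}

#' Read a run configuration file
#'
#' YAML or JSON (by extension) with optional blocks `transcript` (name,
#' n_mrna, f, residue_masses), `params` (vmax, km, ki, km_d, kd_gtp, ki_ppi,
#' plus optional `se` for Monte Carlo propagation), `ppiase`, `reactor` and
#' `factors`. Recognized blocks are promoted to package objects; the raw list
#' is kept under `$raw`.
#'
#' @param path Config file path (`.yml`, `.yaml` or `.json`).
#' @return List with any of `transcript`, `params`, `dist`, `ppiase`,
#'   `reactor`, `factors`, and `raw`.
#' @export
read_ivt_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list(raw = raw)
  if (!is.null(raw$transcript)) {
    tr <- raw$transcript
    out$transcript <- transcript_spec(
      tr$name, tr$n_mrna, unlist(tr$f),
      residue_masses = if (!is.null(tr$residue_masses)) unlist(tr$residue_masses)
                       else c(A = 329.2, C = 305.2, G = 345.2, U = 306.2))
  }
  if (!is.null(raw$params)) {
    p <- raw$params
    args <- list(vmax = p$vmax, km = unlist(p$km))
    for (nm in c("km_d", "kd_gtp", "ki_ppi")) {
      if (!is.null(p[[nm]])) args[[nm]] <- p[[nm]]
    }
    if (!is.null(p$ki)) args$ki <- unlist(p$ki)
    out$params <- do.call(kinetic_params, args)
    if (!is.null(p$se)) {
      out$dist <- param_distribution(out$params,
                                     km_se = unlist(p$se$km),
                                     vmax_se = p$se$vmax %||% 0)
    }
  }
  if (!is.null(raw$ppiase)) {
    pp <- raw$ppiase
    out$ppiase <- ppiase_params(k_ppiase = pp$k_ppiase %||% 2e6,
                                c_ppase = pp$c_ppase %||% 0.002,
                                km_ppi = pp$km_ppi %||% 50, quiet = TRUE)
  }
  if (!is.null(raw$reactor)) {
    r <- raw$reactor
    out$reactor <- reactor_config(tau = r$tau, dt = r$dt, horizon = r$horizon,
                                  flow_ml_min = r$flow_ml_min %||% NA_real_)
  }
  if (!is.null(raw$factors)) {
    out$factors <- lapply(raw$factors, function(f)
      factor_spec(f$name, f$low, f$high, f$unit %||% ""))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
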