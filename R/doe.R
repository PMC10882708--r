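#' Define a DoE factor
#'
#' @param name Factor name (used as the physical column name).
#' @param low,high Physical bounds of the screening range (`low < high`).
#' @param unit Unit label.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("temp_C", 37, 40, "degC")
#' @export
factor_spec <- function(name, low, high, unit = "") {
  .assert_finite(low, "low"); .assert_finite(high, "high")
  if (low >= high) abort("`low` must be < `high`",
                         class = "ivtwin_invalid_input")
  structure(list(name = as.character(name), low = low, high = high,
                 unit = unit),
            class = "factor_spec")
}

.coded_to_physical <- function(x, f) (f$low + f$high) / 2 + x * (f$high - f$low) / 2
.physical_to_coded <- function(p, f) (p - (f$low + f$high) / 2) / ((f$high - f$low) / 2)

#' Generate the three-factor screening design
#'
#' The default template is a Box-Behnken layout for three factors: the 12
#' edge midpoints of the coded cube plus `n_center` center replicates --
#' 15 runs for the default -- which supports the full quadratic model
#' (pure quadratic effects estimable). A two-level factorial template
#' (2^3 corners plus centers) is available behind the `template` flag; it
#' aliases the pure quadratic terms with each other and is intended for
#' main-effect screening only.
#'
#' @param factors List of exactly 3 [factor_spec()]s.
#' @param n_center Number of center-point replicates (default 3).
#' @param template `"box_behnken"` (default) or `"factorial"`.
#' @param seed Optional seed; when given, a randomized `run_order` column is
#'   added.
#' @return Tibble of class `doe_design`: `run_id`, coded `x1..x3`, one
#'   physical column per factor, `is_center` (and `run_order` if seeded).
#' @examples
#' des <- generate_design(list(factor_spec("temp_C", 37, 40),
#'                             factor_spec("urea_M", 0.4, 1.2),
#'                             factor_spec("additive_mg_ml", 0.1, 1)))
#' nrow(des)
#' @export
generate_design <- function(factors, n_center = 3L,
                            template = c("box_behnken", "factorial"),
                            seed = NULL) {
  template <- match.arg(template)
  if (length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec"))) {
    abort("the screening design template takes exactly 3 factor_spec objects",
          class = "ivtwin_invalid_input")
  }
  if (n_center < 0L) abort("`n_center` must be >= 0",
                           class = "ivtwin_invalid_input")

  pts <- if (template == "box_behnken") {
    # 12 edge midpoints of the coded cube: (+-1, +-1, 0) over each factor pair
    rbind(c(-1, -1, 0), c(1, -1, 0), c(-1, 1, 0), c(1, 1, 0),
          c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1), c(1, 0, 1),
          c(0, -1, -1), c(0, 1, -1), c(0, -1, 1), c(0, 1, 1))
  } else {
    as.matrix(expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1)))
  }
  colnames(pts) <- c("x1", "x2", "x3")
  centers <- matrix(0, nrow = n_center, ncol = 3L,
                    dimnames = list(NULL, c("x1", "x2", "x3")))
  coded <- rbind(pts, centers)

  out <- tibble::as_tibble(coded)
  out$run_id <- seq_len(nrow(out))
  out$is_center <- rowSums(abs(coded)) == 0
  for (k in 1:3) out[[factors[[k]]$name]] <- .coded_to_physical(coded[, k],
                                                                factors[[k]])
  out <- out[, c("run_id", "x1", "x2", "x3",
                 vapply(factors, `[[`, character(1), "name"), "is_center")]
  if (!is.null(seed)) {
    out$run_order <- withr::with_seed(seed, sample.int(nrow(out)))
  }
  attr(out, "factors") <- factors
  attr(out, "template") <- template
  class(out) <- c("doe_design", class(out))
  out
}

# full second-order term labels (coded units) and their main-effect parents
.QUAD_TERMS <- c("x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
                 "I(x1^2)", "I(x2^2)", "I(x3^2)")

.term_parents <- function(term) {
  if (grepl("^I\\(", term)) return(sub("^I\\((x[1-3])\\^2\\)$", "\\1", term))
  if (grepl(":", term, fixed = TRUE)) return(strsplit(term, ":", fixed = TRUE)[[1L]])
  character()
}

.fit_rs_lm <- function(design, response, terms) {
  d <- tibble::as_tibble(design)[, c("x1", "x2", "x3")]
  d$.y <- response
  f <- as.formula(paste(".y ~", if (length(terms)) paste(terms, collapse = " + ")
                        else "1"))
  lm(f, data = d)
}

#' Fit a full quadratic response-surface model
#'
#' Ordinary least squares of the response on the full second-order model in
#' coded units: intercept, three main effects, three two-way interactions and
#' three pure quadratics. Per-term p-values and the adjusted R^2 are
#' reported; rank deficiency (e.g. from a design that cannot estimate the
#' quadratics) errors with the aliased terms named.
#'
#' @param design A [generate_design()] table (coded columns `x1..x3`).
#' @param response Numeric response vector, one value per run.
#' @param response_name Label for reports.
#' @return An object of class `rs_model`.
#' @export
fit_quadratic <- function(design, response, response_name = "response") {
  if (length(response) != nrow(design)) {
    abort("response length must equal the run count",
          class = "ivtwin_invalid_input")
  }
  .assert_finite(response, "response")
  fit <- .fit_rs_lm(design, response, .QUAD_TERMS)
  if (anyNA(coef(fit))) {
    abort(paste0("design cannot estimate terms: ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "ivtwin_rank_deficient")
  }
  new_rs_model(fit, .QUAD_TERMS, design, response, response_name)
}

new_rs_model <- function(fit, terms, design, response, response_name) {
  structure(
    list(fit = fit, terms = terms, design = design, response = response,
         response_name = response_name,
         factors = attr(design, "factors")),
    class = "rs_model"
  )
}

#' Backward stepwise term reduction at a p-value threshold
#'
#' Starting from the fitted model, repeatedly removes the removable term with
#' the largest p-value above `alpha` and refits, until every removable term
#' is significant. A term is removable only if the hierarchy stays closed:
#' main effects are kept while any interaction or quadratic involving them is
#' retained.
#'
#' @param model An [fit_quadratic()] result.
#' @param alpha Significance threshold (default 0.05).
#' @return A reduced `rs_model`.
#' @export
stepwise_reduce <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "rs_model"))
  terms <- model$terms
  repeat {
    fit <- .fit_rs_lm(model$design, model$response, terms)
    if (!length(terms)) break
    tab <- suppressWarnings(summary(fit))$coefficients
    pvals <- setNames(rep(NA_real_, length(terms)), terms)
    present <- intersect(terms, rownames(tab))
    pvals[present] <- tab[present, "Pr(>|t|)"]
    pvals[is.na(pvals)] <- 1  # unestimable => never significant
    # a coefficient at float-noise level relative to the response scale is
    # not a real effect, whatever its nominal t statistic (exact-fit guard)
    tiny <- present[abs(tab[present, "Estimate"]) <
                      1e-8 * max(abs(model$response), .Machine$double.xmin)]
    pvals[tiny] <- 1

    needed <- unique(unlist(lapply(terms, .term_parents)))
    removable <- setdiff(terms, needed)
    cand <- removable[pvals[removable] > alpha]
    if (!length(cand)) break
    terms <- setdiff(terms, cand[which.max(pvals[cand])])
  }
  new_rs_model(.fit_rs_lm(model$design, model$response, terms),
               terms, model$design, model$response, model$response_name)
}

#' Predict a response-surface model on coded coordinates
#'
#' @param object An `rs_model`.
#' @param newdata Data frame with coded columns `x1`, `x2`, `x3`.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.rs_model <- function(object, newdata, ...) {
  unname(predict(object$fit, newdata = tibble::as_tibble(newdata)))
}

#' @export
print.rs_model <- function(x, ...) {
  cat(sprintf("<rs_model> %s ~ %s\n", x$response_name,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  cat(sprintf("  adj R2 = %.4f on %d runs\n",
              summary(x$fit)$adj.r.squared, length(x$response)))
  invisible(x)
}

#' Tidy a response-surface model
#'
#' @param x An `rs_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `p.value`.
#' @export
tidy.rs_model <- function(x, ...) {
  tab <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(tab), estimate = tab[, "Estimate"],
                 std.error = tab[, "Std. Error"],
                 p.value = tab[, "Pr(>|t|)"])
}

#' One-row summary of a response-surface model
#'
#' @param x An `rs_model`.
#' @param ... Unused.
#' @return One-row tibble: `response`, `n_terms`, `adj.r.squared`, `sigma`,
#'   `nobs`.
#' @export
glance.rs_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(response = x$response_name, n_terms = length(x$terms),
                 adj.r.squared = s$adj.r.squared, sigma = s$sigma,
                 nobs = length(x$response))
}

#' Joint optimization by composite desirability
#'
#' Derringer-Suich desirability: each response is mapped to [0, 1] by a
#' linear ramp anchored at the min/max of its model predictions over the
#' coded design cube (rising for `maximize`, falling for `minimize`); the
#' composite desirability is the geometric mean, maximized by grid search
#' over the cube.
#'
#' @param models Named list of `rs_model`s sharing the factor space.
#' @param goals Named character vector, `"maximize"` or `"minimize"` per
#'   response (names matching `models`).
#' @param resolution Grid points per coded dimension (default 21).
#' @return List: `optimum` (one-row tibble with coded and physical settings
#'   and `desirability`), `grid` (full evaluation grid tibble).
#' @export
desirability_optimize <- function(models, goals, resolution = 21L) {
  if (!length(models) || is.null(names(models))) {
    abort("`models` must be a named list", class = "ivtwin_invalid_input")
  }
  goals <- vapply(names(models), function(nm) match.arg(goals[[nm]],
                                                        c("maximize", "minimize")),
                  character(1))
  if (resolution < 2L) abort("grid resolution must be >= 2",
                             class = "ivtwin_invalid_input")
  s <- seq(-1, 1, length.out = resolution)
  grid <- tidyr::expand_grid(x1 = s, x2 = s, x3 = s)

  d_each <- lapply(names(models), function(nm) {
    pred <- predict(models[[nm]], grid)
    rng <- range(pred)
    if (diff(rng) <= .Machine$double.eps) {
      rep(1, length(pred))  # flat response carries no preference
    } else if (goals[[nm]] == "maximize") {
      (pred - rng[1L]) / diff(rng)
    } else {
      (rng[2L] - pred) / diff(rng)
    }
  })
  grid$desirability <- exp(Reduce(`+`, lapply(d_each, function(d)
    log(pmax(d, .Machine$double.xmin)))) / length(d_each))
  # degenerate all-zero rows stay ~0
  best <- grid[which.max(grid$desirability), , drop = FALSE]

  factors <- models[[1L]]$factors
  opt <- best
  if (!is.null(factors)) {
    for (k in 1:3) {
      opt[[factors[[k]]$name]] <- .coded_to_physical(best[[paste0("x", k)]],
                                                     factors[[k]])
    }
  }
  list(optimum = tibble::as_tibble(opt), grid = grid)
}

#' Evaluate a response surface on a two-factor grid
#'
#' Predictions on a rectangular grid over two factors with the third held
#' fixed, in physical units, ready for contour plotting.
#'
#' @param model An `rs_model` fitted on a design carrying factor specs.
#' @param vary Character vector of two coded axes, e.g. `c("x1", "x3")`.
#' @param fixed Coded value of the remaining factor (default 0, the center).
#' @param n Grid points per axis.
#' @return Tibble with the two physical factor columns, their coded values
#'   and `prediction`.
#' @export
contour_eval <- function(model, vary = c("x1", "x2"), fixed = 0, n = 50L) {
  stopifnot(inherits(model, "rs_model"))
  axes <- paste0("x", 1:3)
  vary <- match.arg(vary, axes, several.ok = TRUE)
  if (length(vary) != 2L) abort("`vary` must name two coded axes",
                                class = "ivtwin_invalid_input")
  other <- setdiff(axes, vary)
  s <- seq(-1, 1, length.out = n)
  grid <- tidyr::expand_grid(a = s, b = s)
  names(grid) <- vary
  grid[[other]] <- fixed
  grid$prediction <- predict(model, grid[, axes])
  if (!is.null(model$factors)) {
    for (k in 1:3) {
      grid[[model$factors[[k]]$name]] <-
        .coded_to_physical(grid[[axes[k]]], model$factors[[k]])
    }
  }
  tibble::as_tibble(grid)
}

#' Contour plot of a fitted response surface
#'
#' @param model An `rs_model`.
#' @param vary Two coded axes to vary (default `c("x1", "x2")`).
#' @param fixed Coded value of the remaining factor.
#' @param n Grid resolution.
#' @return A ggplot filled-contour panel in physical units.
#' @export
plot_contour <- function(model, vary = c("x1", "x2"), fixed = 0, n = 50L) {
  grid <- contour_eval(model, vary, fixed, n)
  phys <- vapply(model$factors, `[[`, character(1), "name")
  names(phys) <- paste0("x", 1:3)
  ggplot2::ggplot(grid, ggplot2::aes(.data[[phys[[vary[1L]]]]],
                                     .data[[phys[[vary[2L]]]]],
                                     z = .data$prediction)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(fill = model$response_name) +
    ggplot2::theme_minimal()
}

#' Actual-vs-predicted plot of a response-surface model
#'
#' @param object An `rs_model`.
#' @param ... Unused.
#' @return A ggplot of observed vs fitted responses with the identity line.
#' @export
autoplot.rs_model <- function(object, ...) {
  d <- tibble::tibble(actual = object$response, predicted = fitted(object$fit))
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$actual)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predicted", y = "actual", title = object$response_name) +
    ggplot2::theme_minimal()
}
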