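#' Therapeutic window
#'
#' Target exposure range for total sunitinib (parent + N-desethyl
#' metabolite): either the steady-state trough concentration (default
#' 50-100 ng/mL) or the steady-state interval AUC (default 1200-2150
#' ng/mL.h). Window bounds are inclusive.
#'
#' @param metric `"trough"` or `"auc"`.
#' @param low,high Window bounds (ng/mL for trough, ng/mL.h for AUC);
#'   defaults depend on `metric`.
#' @return An object of class `therapeutic_window`.
#' @export
therapeutic_window <- function(metric = c("trough", "auc"),
                               low = NULL, high = NULL) {
  metric <- match.arg(metric)
  if (is.null(low)) low <- if (metric == "trough") 50 else 1200
  if (is.null(high)) high <- if (metric == "trough") 100 else 2150
  if (!(low > 0 && high > low)) stop("need 0 < low < high", call. = FALSE)
  structure(list(metric = metric, low = low, high = high),
            class = "therapeutic_window")
}

#' Classify an exposure value against a window
#'
#' @param value Metric value(s), >= 0; vectorised.
#' @param window A [therapeutic_window()].
#' @return Factor with levels `below`, `within`, `above` (bounds
#'   inclusive: `value == low` or `value == high` is `within`).
#' @export
classify_exposure <- function(value, window) {
  stopifnot(inherits(window, "therapeutic_window"), all(value >= 0))
  out <- ifelse(value < window$low, "below",
                ifelse(value > window$high, "above", "within"))
  factor(out, levels = c("below", "within", "above"))
}

#' Classify a dose action
#'
#' @param current Current dose (mg, > 0); vectorised.
#' @param recommended Recommended (or adopted) dose (mg); vectorised.
#' @return Factor with levels `decrease`, `keep`, `increase` by exact
#'   sign comparison.
#' @export
classify_action <- function(current, recommended) {
  stopifnot(all(current > 0))
  out <- ifelse(recommended < current, "decrease",
                ifelse(recommended > current, "increase", "keep"))
  factor(out, levels = c("decrease", "keep", "increase"))
}

## Per-draw metric values at a reference dose. Because the PK model is
## linear, the metric at any dose d is (d / ref_dose) * these values --
## the identity every grid evaluation relies on.
.draw_metric <- function(draws, dose, tau, metric) {
  met <- .metrics_from_matrix(draws$draws, dose, tau)
  switch(metric, trough = met$cmin_total, auc = met$auc_tau_total,
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Fraction of conditional-distribution profiles inside the window
#'
#' The dose-selection metric: the share of posterior draws whose
#' steady-state exposure (total trough or total AUC) at the candidate
#' dose falls inside the therapeutic window (inclusive bounds).
#'
#' @param draws A `posterior_draws` object (>= 100 draws), or a numeric
#'   vector of per-draw metric values at `dose` itself.
#' @param dose Candidate dose (mg).
#' @param tau Dosing interval (h).
#' @param window A [therapeutic_window()].
#' @return Fraction in `[0, 1]`.
#' @export
fraction_in_window <- function(draws, dose, tau, window) {
  stopifnot(inherits(window, "therapeutic_window"))
  x <- if (inherits(draws, "posterior_draws")) {
    .draw_metric(draws, dose, tau, window$metric)
  } else {
    as.numeric(draws)
  }
  mean(x >= window$low & x <= window$high)
}

#' Recommend a dose by therapeutic-window attainment
#'
#' Evaluates every candidate dose on a grid, scores it by
#' [fraction_in_window()], and recommends the dose with the highest
#' fraction; ties (within `1/n` of the maximum, `n` the number of
#' draws) are broken toward the lowest tied dose, favouring the safer
#' option. When no candidate dose attains the window at all (maximum
#' fraction 0), the recommendation falls back to the grid dose
#' minimizing the expected squared distance of the metric to the window
#' midpoint, and the result is flagged (`window_unreachable = TRUE`);
#' the fraction-argmax tie-break dose is still reported alongside.
#'
#' @param draws A `posterior_draws` object, or a numeric vector of
#'   per-draw metric values at the current regimen's dose.
#' @param current_regimen A [dose_regimen()] with the patient's current
#'   dose.
#' @param grid Ascending candidate doses (mg); default 12.5-100 mg in
#'   12.5 mg steps.
#' @param window A [therapeutic_window()].
#' @return An object of class `dose_recommendation`: list with `table`
#'   (data.frame of dose and fraction_in_window), `recommended_dose`,
#'   `current_dose`, `action`, `percent_change`,
#'   `window_unreachable`, and `argmax_dose` (the tie-broken
#'   fraction-argmax, equal to `recommended_dose` unless the window is
#'   unreachable).
#' @export
recommend_dose <- function(draws, current_regimen,
                           grid = seq(12.5, 100, by = 12.5), window) {
  stopifnot(inherits(current_regimen, "dose_regimen"),
            inherits(window, "therapeutic_window"))
  if (!length(grid) || is.unsorted(grid) || any(grid <= 0)) {
    stop("grid must be a non-empty ascending vector of positive doses",
         call. = FALSE)
  }
  d0 <- current_regimen$dose
  base <- if (inherits(draws, "posterior_draws")) {
    .draw_metric(draws, d0, current_regimen$tau, window$metric)
  } else {
    as.numeric(draws)
  }
  n <- length(base)
  ## dose linearity: metric at dose d is (d/d0) * metric at d0
  frac <- vapply(grid, function(d) {
    x <- (d / d0) * base
    mean(x >= window$low & x <= window$high)
  }, numeric(1))
  best <- max(frac)
  ## ties within 1/n of the maximum break toward the lowest dose;
  ## zero-fraction doses never tie with a positive maximum
  argmax <- min(grid[frac >= best - 1 / n & (best == 0 | frac > 0)])
  unreachable <- best == 0
  if (unreachable) {
    mid <- (window$low + window$high) / 2
    dist <- vapply(grid, function(d) mean(((d / d0) * base - mid)^2),
                   numeric(1))
    recommended <- grid[which.min(dist)]
    warning("no candidate dose attains the therapeutic window; ",
            "recommending the dose closest to the window midpoint",
            call. = FALSE)
  } else {
    recommended <- argmax
  }
  structure(list(
    table = data.frame(dose = grid, fraction_in_window = frac),
    recommended_dose = recommended,
    current_dose = d0,
    action = as.character(classify_action(d0, recommended)),
    percent_change = 100 * (recommended - d0) / d0,
    window_unreachable = unreachable,
    argmax_dose = argmax),
    class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf(
    "<dose_recommendation> %s: %g mg -> %g mg (%+.1f%%)%s\n",
    x$action, x$current_dose, x$recommended_dose, x$percent_change,
    if (x$window_unreachable) " [window unreachable]" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}
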