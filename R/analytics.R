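## Cohort-level analytics comparing clinical-sign-based with
## model-based dose tailoring: window attainment, benefit by exposure
## group, dose-action proportions, exposure-toxicity stratification,
## concordance between recommendation metrics, and association tests.

.pct1 <- function(k, n) round(100 * k / n, 1)

#' Therapeutic-window attainment summary
#'
#' Classifies each patient's exposure metric against the window and
#' tabulates counts and percentages below / within / above.
#'
#' @param values Per-patient metric values (trough ng/mL or AUC
#'   ng/mL.h).
#' @param window A [therapeutic_window()].
#' @return An object of class `attainment_summary`: data.frame with
#'   columns `category`, `n`, `percent` (1-decimal). Counts sum to the
#'   cohort size.
#' @export
attainment_summary <- function(values, window) {
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  cl <- classify_exposure(values, window)
  k <- table(cl)
  structure(data.frame(category = names(k), n = as.integer(k),
                       percent = .pct1(as.integer(k), length(values))),
            class = c("attainment_summary", "data.frame"))
}

#' Clinical benefit by exposure status and dose adjustment
#'
#' Splits the cohort into three groups -- adequate baseline exposure;
#' abnormal exposure with a subsequent change in dosing; abnormal
#' exposure without a change -- and reports the percentage with
#' clinical benefit in each.
#'
#' @param adequate Logical: baseline exposure within the window.
#' @param dose_changed Logical: dose was subsequently changed.
#' @param benefit Logical: clinical benefit observed.
#' @return data.frame with columns `group`, `n`, `benefit_n`,
#'   `benefit_percent` (1-decimal; `NA` for an empty group).
#' @export
benefit_by_group <- function(adequate, dose_changed, benefit) {
  stopifnot(length(adequate) == length(dose_changed),
            length(adequate) == length(benefit))
  grp <- ifelse(adequate, "adequate",
                ifelse(dose_changed, "abnormal_changed",
                       "abnormal_unchanged"))
  levs <- c("adequate", "abnormal_changed", "abnormal_unchanged")
  n <- vapply(levs, function(g) sum(grp == g), integer(1))
  bn <- vapply(levs, function(g) sum(benefit[grp == g]), integer(1))
  data.frame(group = levs, n = n, benefit_n = bn,
             benefit_percent = ifelse(n > 0, .pct1(bn, n), NA_real_),
             row.names = NULL)
}

#' Proportion of dose reductions per strategy
#'
#' Fraction of patients whose dose was decreased (negative percent
#' change) under each dosing strategy.
#'
#' @param actions data.frame with an `initial_dose` column and one
#'   column of new doses per strategy (any other columns are treated as
#'   strategies).
#' @return data.frame with columns `strategy`, `n_decrease`, `n`,
#'   `fraction`, `percent` (1-decimal) and `percent_int` (integer, as
#'   commonly printed).
#' @export
reduction_proportions <- function(actions) {
  stopifnot(is.data.frame(actions), "initial_dose" %in% names(actions),
            nrow(actions) > 0)
  strategies <- setdiff(names(actions), "initial_dose")
  n <- nrow(actions)
  k <- vapply(strategies,
              function(s) sum(actions[[s]] < actions$initial_dose),
              integer(1))
  data.frame(strategy = strategies, n_decrease = k, n = n,
             fraction = k / n, percent = .pct1(k, n),
             percent_int = as.integer(round(100 * k / n)),
             row.names = NULL)
}

#' Toxicity proportion by exposure category
#'
#' Proportion of patients with grade >= 2 early-onset toxicity within
#' each exposure category (patients within vs. above the window; the
#' below-target patients are too few to stratify and are excluded).
#'
#' @param category Factor/character of exposure categories per patient
#'   (`"within"` / `"above"`; other values are dropped).
#' @param toxic Logical grade >= 2 toxicity flag per patient.
#' @return data.frame with columns `category`, `n_toxic`, `n`,
#'   `percent` (1-decimal) and `percent_int` (integer).
#' @export
toxicity_by_exposure <- function(category, toxic) {
  stopifnot(length(category) == length(toxic))
  keep <- category %in% c("within", "above")
  category <- as.character(category[keep]); toxic <- toxic[keep]
  levs <- c("within", "above")
  n <- vapply(levs, function(g) sum(category == g), integer(1))
  k <- vapply(levs, function(g) sum(toxic[category == g]), integer(1))
  data.frame(category = levs, n_toxic = k, n = n,
             percent = ifelse(n > 0, .pct1(k, n), NA_real_),
             percent_int = as.integer(round(100 * k / n)),
             row.names = NULL)
}

#' Concordance between two sets of dose actions
#'
#' Fraction of patients for whom two strategies agree. Agreement is
#' evaluated on the action class (decrease/keep/increase); when dose
#' vectors are supplied via `dose_a`/`dose_b`, exact-dose agreement is
#' reported as well.
#'
#' @param a,b Action classes (character/factor), equal length.
#' @param dose_a,dose_b Optional recommended doses (mg) per strategy.
#' @return List with `action_match` (fraction) and, when doses are
#'   given, `dose_match`.
#' @export
action_concordance <- function(a, b, dose_a = NULL, dose_b = NULL) {
  if (length(a) != length(b)) {
    stop("action vectors must have equal length", call. = FALSE)
  }
  out <- list(action_match = mean(as.character(a) == as.character(b)))
  if (!is.null(dose_a) && !is.null(dose_b)) {
    if (length(dose_a) != length(dose_b) || length(dose_a) != length(a)) {
      stop("dose vectors must match the action vectors in length",
           call. = FALSE)
    }
    out$dose_match <- mean(dose_a == dose_b)
  }
  out
}

#' Exposure-outcome association tests
#'
#' `exposure_ttest()` runs a two-sided Welch t-test of a metric between
#' two outcome groups; `exposure_chisq()` runs a Pearson chi-square
#' test (without continuity correction) on a 2x2 contingency table,
#' e.g. toxicity by exposure category.
#'
#' @param x Metric values.
#' @param group Two-level grouping factor/logical, same length as `x`.
#' @return For both: list with `statistic`, `p_value` (two-sided) and
#'   the underlying `htest` object.
#' @export
exposure_ttest <- function(x, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels",
                            call. = FALSE)
  if (any(table(g) < 2)) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  ht <- stats::t.test(x ~ g)
  list(statistic = unname(ht$statistic), p_value = ht$p.value, htest = ht)
}

#' @rdname exposure_ttest
#' @param tab A 2x2 matrix of counts.
#' @export
exposure_chisq <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, htest = ht)
}
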