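#' Pharmacokinetic parameter set for one analyte
#'
#' Apparent parameters of a two-compartment disposition model with
#' first-order oral absorption. Bioavailability is absorbed into the
#' apparent parameters (CL/F, V/F), as is the formation fraction for the
#' metabolite when it is modelled as an independently "dosed" system.
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param cl Apparent clearance CL/F (L/h).
#' @param v1 Apparent central volume of distribution (L).
#' @param q Apparent inter-compartmental clearance (L/h).
#' @param v2 Apparent peripheral volume of distribution (L).
#'
#' @return An object of class `analyte_pk`: a named list of the five
#'   parameters.
#'
#' @details The hybrid disposition rate constants satisfy
#'   \eqn{\alpha + \beta = (CL+Q)/V_1 + Q/V_2} and
#'   \eqn{\alpha\beta = CL\,Q/(V_1 V_2)}, with \eqn{\alpha > \beta > 0}.
#'   When `ka` coincides numerically with \eqn{\alpha} or \eqn{\beta}
#'   the triexponential closed form is singular; concentrations are then
#'   computed with `ka` perturbed by one part in 10^6 (see
#'   [conc_single_dose()]).
#'
#' @examples
#' sun <- analyte_pk(ka = 0.195, cl = 51.8, v1 = 2030, q = 7.22, v2 = 583)
#' conc_single_dose(sun, dose = 50, t = 24)
#' @export
analyte_pk <- function(ka, cl, v1, q, v2) {
  p <- c(ka = ka, cl = cl, v1 = v1, q = q, v2 = v2)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("all analyte PK parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(p), class = "analyte_pk")
}

#' @export
print.analyte_pk <- function(x, ...) {
  cat(sprintf(
    "<analyte_pk> ka=%.4g /h, CL/F=%.4g L/h, V1/F=%.4g L, Q/F=%.4g L/h, V2/F=%.4g L\n",
    x$ka, x$cl, x$v1, x$q, x$v2))
  invisible(x)
}

#' Individual pharmacokinetic parameter set (parent + metabolite)
#'
#' Bundles the parent-drug (sunitinib) and metabolite (N-desethyl
#' sunitinib) parameter sets for one subject. The two analytes are
#' modelled with the same two-compartment oral structure, the metabolite
#' receiving the parent's nominal dose with its formation fraction
#' absorbed into its apparent clearance and volume.
#'
#' @param parent,metabolite [analyte_pk()] objects.
#' @return An object of class `individual_pk`.
#' @export
individual_pk <- function(parent, metabolite) {
  stopifnot(inherits(parent, "analyte_pk"), inherits(metabolite, "analyte_pk"))
  structure(list(parent = parent, metabolite = metabolite),
            class = "individual_pk")
}

#' @export
print.individual_pk <- function(x, ...) {
  cat("<individual_pk>\n  parent:     ")
  print(x$parent)
  cat("  metabolite: ")
  print(x$metabolite)
  invisible(x)
}

#' Dosing regimen
#'
#' Once-daily oral dosing with an on/off cycle structure (e.g., 4 weeks
#' on / 2 weeks off). Steady-state exposure metrics are computed in the
#' continuous-QD limit; the cycle structure is carried as metadata.
#'
#' @param dose Dose per administration (mg).
#' @param tau Dosing interval (h); default 24 (QD).
#' @param days_on,days_off Days on and off treatment per cycle; defaults
#'   28/14 (the "4/2" schedule).
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose, tau = 24, days_on = 28, days_off = 14) {
  if (!is.finite(dose) || dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (days_on < 1 || days_off < 0) {
    stop("days_on must be >= 1 and days_off >= 0", call. = FALSE)
  }
  structure(list(dose = dose, tau = tau,
                 days_on = as.integer(days_on),
                 days_off = as.integer(days_off)),
            class = "dose_regimen")
}

## ng/mL from mg doses and L volumes: 1e6 ng/mg over 1e3 mL/L.
.UNIT_SCALE <- 1000

## Hybrid rate constants alpha > beta > 0 from micro parameters.
## Vectorised over all arguments (standard R recycling).
.disposition <- function(cl, v1, q, v2) {
  s <- (cl + q) / v1 + q / v2
  p <- cl * q / (v1 * v2)
  disc <- sqrt(pmax(s * s - 4 * p, 0))
  list(alpha = (s + disc) / 2, beta = (s - disc) / 2, k21 = q / v2)
}

## Workhorse: two-compartment oral concentration, vectorised over every
## argument. If `tau` is non-NULL each exponential is multiplied by its
## geometric accumulation factor 1/(1 - exp(-lambda tau)) (steady state
## under an infinite QD train; valid for any t >= 0, interpreted as time
## since the last administered dose).
.conc2 <- function(t, dose, ka, cl, v1, q, v2, tau = NULL) {
  d <- .disposition(cl, v1, q, v2)
  alpha <- d$alpha; beta <- d$beta; k21 <- d$k21
  ## collision guard: the closed form is singular when ka hits alpha/beta
  bump <- (abs(ka - alpha) < 1e-9 * ka) | (abs(ka - beta) < 1e-9 * ka)
  ka <- ka * ifelse(bump, 1 + 1e-6, 1)
  ca <- (k21 - alpha) / ((ka - alpha) * (beta - alpha))
  cb <- (k21 - beta) / ((ka - beta) * (alpha - beta))
  cc <- (k21 - ka) / ((alpha - ka) * (beta - ka))
  if (is.null(tau)) {
    ea <- exp(-alpha * t); eb <- exp(-beta * t); ec <- exp(-ka * t)
  } else {
    ea <- exp(-alpha * t) / (1 - exp(-alpha * tau))
    eb <- exp(-beta * t) / (1 - exp(-beta * tau))
    ec <- exp(-ka * t) / (1 - exp(-ka * tau))
  }
  .UNIT_SCALE * dose * ka / v1 * (ca * ea + cb * eb + cc * ec)
}

#' Concentration after a single oral dose
#'
#' Closed-form (triexponential) plasma concentration of one analyte
#' `t` hours after a single oral dose, for a two-compartment model with
#' first-order absorption.
#'
#' @param pk An [analyte_pk()] object.
#' @param dose Dose (mg).
#' @param t Time after dose (h); vectorised.
#' @return Concentration(s) in ng/mL. Linear in `dose`.
#' @export
conc_single_dose <- function(pk, dose, t) {
  stopifnot(inherits(pk, "analyte_pk"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  .conc2(t, dose, pk$ka, pk$cl, pk$v1, pk$q, pk$v2)
}

#' Concentration at steady state under repeated dosing
#'
#' Steady-state concentration `t` hours after the last dose of an
#' infinite once-every-`tau` train: each exponential term of the
#' single-dose solution is multiplied by its accumulation factor
#' \eqn{1/(1 - e^{-\lambda\tau})}.
#'
#' @param pk An [analyte_pk()] object.
#' @param dose Dose (mg).
#' @param tau Dosing interval (h).
#' @param t Time after the last dose (h); vectorised. Values beyond
#'   `tau` describe a delayed sample with the next dose withheld, which
#'   is how late TDM samples (e.g., 25-26 h post-dose) arise in
#'   practice.
#' @return Concentration(s) in ng/mL. Linear in `dose`.
#' @export
conc_steady_state <- function(pk, dose, tau, t) {
  stopifnot(inherits(pk, "analyte_pk"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  .conc2(t, dose, pk$ka, pk$cl, pk$v1, pk$q, pk$v2, tau = tau)
}

#' Steady-state exposure metrics for one individual
#'
#' Trough concentration (Cmin, taken at `t = tau`) and AUC over one
#' dosing interval at steady state, per analyte and summed to total
#' sunitinib exposure. For a linear model the steady-state interval AUC
#' has the closed form dose/CL (after unit conversion).
#'
#' @param ind An [individual_pk()] object.
#' @param regimen A [dose_regimen()] object.
#' @return An object of class `exposure_metrics`: a list with
#'   `cmin_parent`, `cmin_metabolite`, `cmin_total` (ng/mL) and
#'   `auc_parent`, `auc_metabolite`, `auc_tau_total` (ng/mL.h).
#' @export
exposure_at_steady_state <- function(ind, regimen) {
  stopifnot(inherits(ind, "individual_pk"), inherits(regimen, "dose_regimen"))
  d <- regimen$dose; tau <- regimen$tau
  cmin_p <- if (d == 0) 0 else conc_steady_state(ind$parent, d, tau, tau)
  cmin_m <- if (d == 0) 0 else conc_steady_state(ind$metabolite, d, tau, tau)
  auc_p <- .UNIT_SCALE * d / ind$parent$cl
  auc_m <- .UNIT_SCALE * d / ind$metabolite$cl
  structure(list(cmin_parent = cmin_p, cmin_metabolite = cmin_m,
                 cmin_total = cmin_p + cmin_m,
                 auc_parent = auc_p, auc_metabolite = auc_m,
                 auc_tau_total = auc_p + auc_m),
            class = "exposure_metrics")
}

## --- flat parameter-vector helpers (used by estimation & simulation) ---

.PK_PAR_NAMES <- c(t(outer(c("parent", "metabolite"),
                           c("ka", "cl", "v1", "q", "v2"), paste, sep = ".")))

.ind_to_vec <- function(ind) {
  v <- c(unlist(ind$parent), unlist(ind$metabolite))
  names(v) <- .PK_PAR_NAMES
  v
}

.vec_to_ind <- function(v) {
  individual_pk(
    parent = analyte_pk(v[["parent.ka"]], v[["parent.cl"]], v[["parent.v1"]],
                        v[["parent.q"]], v[["parent.v2"]]),
    metabolite = analyte_pk(v[["metabolite.ka"]], v[["metabolite.cl"]],
                            v[["metabolite.v1"]], v[["metabolite.q"]],
                            v[["metabolite.v2"]]))
}

## Vectorised steady-state metrics from a parameter matrix (one row per
## parameter vector, columns .PK_PAR_NAMES). Returns a data.frame.
.metrics_from_matrix <- function(m, dose, tau) {
  cmin_p <- .conc2(tau, dose, m[, "parent.ka"], m[, "parent.cl"],
                   m[, "parent.v1"], m[, "parent.q"], m[, "parent.v2"],
                   tau = tau)
  cmin_m <- .conc2(tau, dose, m[, "metabolite.ka"], m[, "metabolite.cl"],
                   m[, "metabolite.v1"], m[, "metabolite.q"],
                   m[, "metabolite.v2"], tau = tau)
  if (dose == 0) cmin_p <- cmin_m <- rep(0, nrow(m))
  auc_p <- .UNIT_SCALE * dose / m[, "parent.cl"]
  auc_m <- .UNIT_SCALE * dose / m[, "metabolite.cl"]
  data.frame(cmin_total = cmin_p + cmin_m, auc_tau_total = auc_p + auc_m,
             cmin_parent = cmin_p, cmin_metabolite = cmin_m,
             auc_parent = auc_p, auc_metabolite = auc_m)
}
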