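#' Residual (unexplained) error model
#'
#' Combined proportional + additive residual error around model-predicted
#' concentrations, with left-censoring at the assay's lower limit of
#' quantification (LOQ). The observation SD at prediction `f` is
#' \eqn{\sqrt{\sigma_{add}^2 + (\sigma_{prop} f)^2}}.
#'
#' @param sigma_prop Proportional error coefficient (dimensionless).
#' @param sigma_add Additive error SD (ng/mL).
#' @param loq Lower limit of quantification (ng/mL); default 10, the
#'   assay limit for both sunitinib and N-desethyl sunitinib.
#' @return An object of class `residual_error`.
#' @export
residual_error <- function(sigma_prop = 0.2, sigma_add = 1, loq = 10) {
  if (sigma_prop < 0 || sigma_add < 0 || (sigma_prop == 0 && sigma_add == 0)) {
    stop("sigma_prop and sigma_add must be >= 0 and not both zero",
         call. = FALSE)
  }
  if (loq <= 0) stop("loq must be > 0", call. = FALSE)
  structure(list(sigma_prop = sigma_prop, sigma_add = sigma_add, loq = loq),
            class = "residual_error")
}

#' Population pharmacokinetic model (the Bayesian prior)
#'
#' Typical parameter values, log-normal inter-individual variability
#' (IIV), and a residual error model per analyte. Individual parameters
#' are \eqn{\theta_i = \theta_{pop} e^{\eta_i}}, \eqn{\eta_i \sim
#' N(0, \omega^2)}, independent across parameters. Parameters with
#' `omega = 0` (or absent from `omega`) carry no IIV and are fixed at
#' their typical value during estimation.
#'
#' @param typical An [individual_pk()] of population typical values.
#' @param omega Named numeric vector of log-scale SDs; names among
#'   `"parent.ka"`, `"parent.cl"`, `"parent.v1"`, `"parent.q"`,
#'   `"parent.v2"` and the `"metabolite.*"` counterparts.
#' @param error A [residual_error()], or a list with elements `parent`
#'   and `metabolite` for analyte-specific error models.
#' @return An object of class `population_pk`.
#' @export
population_pk <- function(typical, omega, error = residual_error()) {
  stopifnot(inherits(typical, "individual_pk"))
  om <- stats::setNames(numeric(length(.PK_PAR_NAMES)), .PK_PAR_NAMES)
  if (length(omega)) {
    if (is.null(names(omega)) || !all(names(omega) %in% .PK_PAR_NAMES)) {
      stop("omega must be named with analyte.parameter keys, e.g. 'parent.cl'",
           call. = FALSE)
    }
    if (any(omega < 0)) stop("omega entries must be >= 0", call. = FALSE)
    om[names(omega)] <- omega
  }
  if (inherits(error, "residual_error")) {
    error <- list(parent = error, metabolite = error)
  }
  stopifnot(inherits(error$parent, "residual_error"),
            inherits(error$metabolite, "residual_error"))
  structure(list(typical = typical, omega = om, error = error),
            class = "population_pk")
}

## Names of the parameters that carry IIV (the "free" parameters for
## individual estimation).
.free_names <- function(pop) names(pop$omega)[pop$omega > 0]

#' Draw individuals from the population distribution
#'
#' Samples individual parameter sets from the log-normal prior. Uses the
#' current RNG state; call `set.seed()` for reproducibility.
#'
#' @param pop A [population_pk()] object.
#' @param n Number of individuals.
#' @return If `n == 1` an [individual_pk()]; otherwise an `n` x 10
#'   matrix of parameters (columns named `analyte.parameter`).
#' @export
sample_individual <- function(pop, n = 1) {
  stopifnot(inherits(pop, "population_pk"))
  tv <- .ind_to_vec(pop$typical)
  eta <- matrix(stats::rnorm(n * length(tv), 0, rep(pop$omega, each = n)),
                nrow = n, dimnames = list(NULL, names(tv)))
  m <- sweep(exp(eta), 2, tv, `*`)
  if (n == 1) .vec_to_ind(m[1, ]) else m
}

#' Prior log-density of an individual parameter set
#'
#' Sum of independent log-normal log-densities over the parameters that
#' carry IIV. Parameters without IIV are treated as fixed and do not
#' contribute (they must equal the typical values up to numerical
#' round-off for the individual to be in the prior's support; this is
#' not enforced here).
#'
#' @param pop A [population_pk()] object.
#' @param ind An [individual_pk()] object (or a named parameter vector).
#' @return Log-density (natural-scale density of the parameters);
#'   `-Inf` for non-positive parameter values.
#' @export
prior_logdensity <- function(pop, ind) {
  stopifnot(inherits(pop, "population_pk"))
  v <- if (inherits(ind, "individual_pk")) .ind_to_vec(ind) else ind
  free <- .free_names(pop)
  if (any(v[free] <= 0)) return(-Inf)
  tv <- .ind_to_vec(pop$typical)
  sum(stats::dlnorm(v[free], meanlog = log(tv[free]),
                    sdlog = pop$omega[free], log = TRUE))
}

## Predicted concentrations for a set of observations. `obs` is a
## data.frame with columns analyte, time_after_dose, at_steady_state.
.predict_obs <- function(ind, obs, regimen) {
  pred <- numeric(nrow(obs))
  for (an in unique(obs$analyte)) {
    if (!an %in% c("parent", "metabolite")) {
      stop("unknown analyte: ", an, call. = FALSE)
    }
    i <- obs$analyte == an
    pk <- ind[[an]]
    ss <- if ("at_steady_state" %in% names(obs)) obs$at_steady_state[i] else TRUE
    ti <- obs$time_after_dose[i]
    p <- numeric(sum(i))
    if (any(ss)) {
      p[ss] <- conc_steady_state(pk, regimen$dose, regimen$tau, ti[ss])
    }
    if (any(!ss)) p[!ss] <- conc_single_dose(pk, regimen$dose, ti[!ss])
    pred[i] <- p
  }
  pred
}

#' Observation log-likelihood
#'
#' Gaussian log-likelihood of measured plasma concentrations given an
#' individual's parameters, with per-point variance
#' \eqn{\sigma_{add}^2 + (\sigma_{prop} f)^2} around the model
#' prediction \eqn{f}. Observations flagged below the limit of
#' quantification (BLQ) contribute the log cumulative probability of
#' falling below the LOQ (left-censored likelihood, the M3 convention).
#'
#' @param ind An [individual_pk()] object.
#' @param obs A data.frame of observations with columns `analyte`
#'   ("parent"/"metabolite"), `time_after_dose` (h), `conc` (ng/mL; may
#'   be `NA` for BLQ rows), `blq` (logical) and optionally
#'   `at_steady_state` (logical, default `TRUE`).
#' @param regimen A [dose_regimen()] object.
#' @param error A [residual_error()], or a list with `parent` and
#'   `metabolite` components.
#' @return The log-likelihood (sum over observations).
#' @export
observation_loglik <- function(ind, obs, regimen, error) {
  stopifnot(inherits(ind, "individual_pk"), is.data.frame(obs), nrow(obs) > 0)
  if (inherits(error, "residual_error")) {
    error <- list(parent = error, metabolite = error)
  }
  if (!"blq" %in% names(obs)) obs$blq <- FALSE
  pred <- .predict_obs(ind, obs, regimen)
  ll <- 0
  for (an in unique(obs$analyte)) {
    i <- obs$analyte == an
    e <- error[[an]]
    sd <- sqrt(e$sigma_add^2 + (e$sigma_prop * pred[i])^2)
    blq <- obs$blq[i]
    if (any(!blq)) {
      ll <- ll + sum(stats::dnorm(obs$conc[i][!blq], pred[i][!blq],
                                  sd[!blq], log = TRUE))
    }
    if (any(blq)) {
      ll <- ll + sum(stats::pnorm(e$loq, pred[i][blq], sd[blq],
                                  log.p = TRUE))
    }
  }
  ll
}

#' Construct an observation table
#'
#' Convenience constructor for the observation data.frame consumed by
#' [observation_loglik()] and [sample_conditional()].
#'
#' @param analyte Character vector, `"parent"` or `"metabolite"`.
#' @param time_after_dose Hours after the last dose (> 0).
#' @param conc Measured concentration (ng/mL); `NA` allowed when `blq`.
#' @param blq Logical BLQ flag (below limit of quantification).
#' @param at_steady_state Logical; default `TRUE`.
#' @return A data.frame with one row per measurement.
#' @export
observations <- function(analyte, time_after_dose, conc, blq = FALSE,
                         at_steady_state = TRUE) {
  if (any(time_after_dose <= 0)) {
    stop("time_after_dose must be > 0", call. = FALSE)
  }
  if (!all(analyte %in% c("parent", "metabolite"))) {
    stop("analyte must be 'parent' or 'metabolite'", call. = FALSE)
  }
  df <- data.frame(analyte = analyte, time_after_dose = time_after_dose,
                   conc = conc, blq = blq, at_steady_state = at_steady_state)
  if (any(!df$blq & (is.na(df$conc) | df$conc < 0))) {
    stop("non-BLQ observations need a concentration >= 0", call. = FALSE)
  }
  df
}
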