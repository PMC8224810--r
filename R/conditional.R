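## Conditional-distribution (posterior) estimation of individual PK
## parameters given sparse TDM observations.

## Evaluate with a locally-seeded RNG stream, restoring the caller's
## RNG state afterwards so estimation calls do not perturb simulations.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Factory for the two target functions used below, both over the free
## log-parameters theta (parameters with omega > 0):
##  * $target(theta): log density of theta under the conditional
##    distribution (Gaussian prior on theta + data likelihood) -- the
##    MCMC target;
##  * $natural(theta): log of the natural-scale posterior density
##    (log-normal prior on exp(theta) + likelihood) -- the MAP
##    objective, differing from $target by the Jacobian sum(theta).
.posterior_factory <- function(pop, obs, regimen) {
  free <- .free_names(pop)
  if (!length(free)) stop("no parameters carry IIV (all omega zero)",
                          call. = FALSE)
  tv <- .ind_to_vec(pop$typical)
  mu <- log(tv[free])
  om <- pop$omega[free]
  have_obs <- !is.null(obs) && nrow(obs) > 0
  loglik <- function(v) {
    ind <- .vec_to_ind(v)
    observation_loglik(ind, obs, regimen, pop$error)
  }
  target <- function(theta) {
    x <- exp(theta)
    if (any(!is.finite(x)) || any(x <= 0)) return(-Inf)  # exp over/underflow
    lp <- sum(stats::dnorm(theta, mu, om, log = TRUE))
    if (!have_obs) return(lp)
    v <- tv; v[free] <- x
    ll <- loglik(v)
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }
  list(free = free, tv = tv, mu = mu, om = om, target = target,
       natural = function(theta) target(theta) - sum(theta))
}

#' Sample the conditional distribution of individual PK parameters
#'
#' Draws from the posterior distribution of an individual's PK
#' parameters given the population prior and that individual's measured
#' concentrations, by adaptive random-walk Metropolis-Hastings on the
#' log-parameters. With no observations the draws are samples from the
#' prior. Only parameters with non-zero `omega` are sampled; the rest
#' stay at their typical values.
#'
#' The proposal is a diagonal Gaussian with per-parameter scale
#' proportional to `omega`; a global scale factor is adapted in batches
#' of 50 iterations during burn-in towards a 20-40% acceptance rate and
#' frozen afterwards.
#'
#' @param pop A [population_pk()] object.
#' @param obs Observation data.frame (see [observations()]); may be
#'   `NULL` or empty.
#' @param regimen A [dose_regimen()] object.
#' @param n_draws Number of retained draws (>= 100).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param burn_in Burn-in iterations (discarded).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @return An object of class `posterior_draws`: list with `draws` (an
#'   `n_draws` x 10 matrix of natural-scale parameters), `seed`,
#'   `n_kept`, and `diagnostics` (acceptance rate, chain length,
#'   frozen proposal scale).
#' @export
sample_conditional <- function(pop, obs, regimen, n_draws = 1000,
                               seed = 1L, burn_in = 1000, thin = 1) {
  stopifnot(inherits(pop, "population_pk"), inherits(regimen, "dose_regimen"))
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)
  pf <- .posterior_factory(pop, obs, regimen)
  k <- length(pf$free)
  theta <- pf$mu
  lp <- pf$target(theta)
  if (!is.finite(lp)) {
    stop("log-posterior is not finite at the typical values; ",
         "check observations and error model", call. = FALSE)
  }
  n_iter <- burn_in + n_draws * thin
  kept <- matrix(NA_real_, n_draws, k)
  scale <- 2.38 / sqrt(k)
  n_acc <- 0L; batch_acc <- 0L
  .with_seed(seed, {
    j <- 0L
    for (i in seq_len(n_iter)) {
      prop <- theta + stats::rnorm(k, 0, scale * pf$om)
      lp_prop <- pf$target(prop)
      if (log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop
        n_acc <- n_acc + 1L; batch_acc <- batch_acc + 1L
      }
      if (i <= burn_in && i %% 50 == 0) {
        rate <- batch_acc / 50
        if (rate > 0.4) scale <- scale * exp(0.2)
        if (rate < 0.2) scale <- scale * exp(-0.2)
        batch_acc <- 0L
      }
      if (i == burn_in) n_acc <- 0L
      if (i > burn_in && (i - burn_in) %% thin == 0) {
        j <- j + 1L
        kept[j, ] <- theta
      }
    }
  })
  m <- matrix(rep(pf$tv, each = n_draws), n_draws,
              dimnames = list(NULL, names(pf$tv)))
  m[, pf$free] <- exp(kept)
  structure(list(draws = m, seed = seed, n_kept = n_draws,
                 free = pf$free,
                 diagnostics = list(
                   acceptance_rate = n_acc / (n_draws * thin),
                   chain_length = n_iter, burn_in = burn_in, thin = thin,
                   proposal_scale = scale)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws (seed %s), acceptance %.1f%%\n",
              x$n_kept, x$seed, 100 * x$diagnostics$acceptance_rate))
  invisible(x)
}

#' Extract one draw as an individual parameter set
#' @param draws A `posterior_draws` object.
#' @param i Draw index.
#' @return An [individual_pk()].
#' @export
draw_individual <- function(draws, i) {
  stopifnot(inherits(draws, "posterior_draws"))
  .vec_to_ind(draws$draws[i, ])
}

#' Maximum a posteriori (empirical Bayes) estimate
#'
#' Maximizes prior log-density plus observation log-likelihood over the
#' log of the free parameters (multi-start BFGS). This is the classical
#' EBE point estimate, provided as a comparison baseline to the full
#' conditional distribution of [sample_conditional()]. With no
#' observations it returns the prior mode, `typical * exp(-omega^2)`
#' per free parameter.
#'
#' @inheritParams sample_conditional
#' @param n_starts Number of optimizer starts (typical values plus
#'   jittered restarts).
#' @return An [individual_pk()] with attributes `logpost` (the attained
#'   natural-scale log-posterior) and `convergence`.
#' @export
map_estimate <- function(pop, obs, regimen, n_starts = 5, seed = 1L) {
  stopifnot(inherits(pop, "population_pk"))
  pf <- .posterior_factory(pop, obs, regimen)
  neg <- function(th) {
    v <- -pf$natural(th)
    if (!is.finite(v)) 1e10 else v  # keep BFGS line searches finite
  }
  starts <- list(pf$mu)
  if (n_starts > 1) {
    starts <- c(starts, .with_seed(seed, lapply(seq_len(n_starts - 1),
      function(i) pf$mu + stats::rnorm(length(pf$mu), 0, pf$om))))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, neg, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("MAP optimization failed to converge from every start",
         call. = FALSE)
  }
  v <- pf$tv; v[pf$free] <- exp(best$par)
  out <- .vec_to_ind(v)
  attr(out, "logpost") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Virtual steady-state trough concentration
#'
#' Applies [exposure_at_steady_state()] to every conditional-
#' distribution draw and summarizes the total (parent + metabolite)
#' steady-state trough. This is the in-silico T24h concentration used
#' when a patient's TDM sample was not drawn at the trough.
#'
#' @param draws A `posterior_draws` object (>= 100 draws).
#' @param regimen A [dose_regimen()] object.
#' @return A list with `median` (the reported point estimate), `mean`,
#'   `q05`, `q95` (ng/mL) and `n`.
#' @export
virtual_trough <- function(draws, regimen) {
  stopifnot(inherits(draws, "posterior_draws"),
            inherits(regimen, "dose_regimen"))
  met <- .metrics_from_matrix(draws$draws, regimen$dose, regimen$tau)
  x <- met$cmin_total
  list(median = stats::median(x), mean = mean(x),
       q05 = unname(stats::quantile(x, 0.05)),
       q95 = unname(stats::quantile(x, 0.95)),
       n = length(x))
}
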