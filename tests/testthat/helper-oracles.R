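# Independent oracles and small in-code fixtures shared across tests.

# Numerical integration of the absorption/central/peripheral ODE system
# (the independent check on the closed-form solution). Amounts in ng.
ode_conc <- function(pk, dose, t, rtol = 1e-10) {
  rhs <- function(time, y, p) {
    list(c(-p$ka * y[1],
           p$ka * y[1] - (p$cl / p$v1) * y[2] - (p$q / p$v1) * y[2] +
             (p$q / p$v2) * y[3],
           (p$q / p$v1) * y[2] - (p$q / p$v2) * y[3]))
  }
  out <- deSolve::ode(c(dose * 1e6, 0, 0), sort(unique(c(0, t))), rhs, pk,
                      rtol = rtol, atol = 1e-8)
  out[match(t, out[, 1]), 3] / (pk$v1 * 1000)
}

# One-compartment first-order absorption (Bateman) solution, with
# optional steady-state accumulation.
bateman_conc <- function(ka, cl, v1, dose, t, tau = NULL) {
  ke <- cl / v1
  acc <- function(lambda) if (is.null(tau)) 1 else 1 / (1 - exp(-lambda * tau))
  1000 * dose * ka / (v1 * (ka - ke)) *
    (exp(-ke * t) * acc(ke) - exp(-ka * t) * acc(ka))
}

# A small two-analyte population built in code (no file dependency),
# with IIV on clearances and central volumes.
toy_pop <- function(omega = c(parent.cl = 0.35, parent.v1 = 0.45,
                              metabolite.cl = 0.40, metabolite.v1 = 0.50),
                    error = residual_error()) {
  typical <- individual_pk(
    parent = analyte_pk(ka = 0.195, cl = 51.8, v1 = 2030, q = 7.22, v2 = 583),
    metabolite = analyte_pk(ka = 0.195, cl = 81.4, v1 = 3020, q = 95.7,
                            v2 = 1850))
  population_pk(typical, omega, error = error)
}

random_analyte <- function() {
  analyte_pk(ka = runif(1, 0.05, 2), cl = runif(1, 5, 120),
             v1 = runif(1, 100, 4000), q = runif(1, 1, 150),
             v2 = runif(1, 100, 3000))
}

# Noise-free steady-state observation pair (parent + metabolite) for a
# known individual at a given time after dose.
truth_obs <- function(ind, dose, t, tau = 24) {
  observations(c("parent", "metabolite"), c(t, t),
               c(conc_steady_state(ind$parent, dose, tau, t),
                 conc_steady_state(ind$metabolite, dose, tau, t)))
}
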