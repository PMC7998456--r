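## Independent integration oracles (deSolve) and small builders shared by the
## tests. The oracles re-state the model equations directly as ODE
## right-hand sides, so they share no code path with the package's
## closed-form PK or exponential-step PD integrator.

## Two-compartment infusion PK integrated with lsoda. Amounts in mg,
## concentrations returned in ng/mL.
pk_ode_oracle <- function(t, doses, pk_ind, rtol = 1e-10) {
  rate_at <- function(tt) {
    sum(ifelse(tt > doses$start_time &
                 tt <= doses$start_time + doses$duration,
               doses$amount / doses$duration, 0))
  }
  rhs <- function(tt, y, p) {
    C1 <- y[1] / pk_ind[["Vc"]]
    C2 <- y[2] / pk_ind[["Vt"]]
    list(c(rate_at(tt) - pk_ind[["CLp"]] * C1 -
             pk_ind[["CLt"]] * (C1 - C2),
           pk_ind[["CLt"]] * (C1 - C2)))
  }
  brk <- sort(unique(c(doses$start_time, doses$start_time + doses$duration)))
  tt <- sort(unique(c(0, t, brk)))
  sol <- deSolve::lsoda(c(0, 0), tt, rhs, NULL, rtol = rtol, atol = 1e-12,
                        hmax = 0.1)
  1000 * sol[match(t, tt), 2] / pk_ind[["Vc"]]
}

## Coupled pump/H+ system integrated with lsoda, with the plasma
## concentration supplied as a function of time.
pd_ode_oracle <- function(t, cp_fn, pd, eta_pd = c(0, 0, 0),
                          dose_clock = 8, rtol = 1e-10) {
  kdeg <- pd$kdeg * exp(eta_pd[1])
  kd <- pd$kd * exp(eta_pd[2])
  kout <- pd$kout * exp(eta_pd[3])
  rhs <- function(tt, y, p) {
    f <- circadian_factor(tt + dose_clock, pd)
    list(c(kdeg * (1 - y[1]) - kd * cp_fn(tt) * y[1],
           kout * pd$HBASE * f * y[1] - kout * y[2]))
  }
  tt <- sort(unique(c(0, t)))
  sol <- deSolve::lsoda(c(1, pd$HBASE), tt, rhs, NULL, rtol = rtol,
                        atol = 1e-14, hmax = 0.05)
  list(E = sol[match(t, tt), 2], H = sol[match(t, tt), 3])
}

## Brute-force marginal -2 log-likelihood of a one-eta subject by adaptive
## quadrature (proportional error on CLp's eta).
quadrature_ofv_1eta <- function(obs, doses, pk, omega_clp) {
  tot <- 0
  for (id in unique(obs$ID)) {
    o <- obs[obs$ID == id, ]
    lik <- function(eta) {
      vapply(eta, function(e) {
        pki <- individual_parameters(pk, o$WT[1], o$SEX[1], c(e, 0, 0, 0))
        f <- pk_concentration(o$TIME, doses, pki)
        prod(dnorm(o$DV, f, pk$sigma_prop * f)) * dnorm(e, 0, omega_clp)
      }, numeric(1))
    }
    tot <- tot - 2 * log(integrate(lik, -5, 5, rel.tol = 1e-12)$value)
  }
  tot
}

## Parameter sets with variability switched off (deterministic fixtures).
pk_novar <- function(sigma = 0)
  pk_parameters(omega = c(CLp = 0, CLt = 0, Vc = 0, Vt = 0),
                sigma_prop = sigma)
pd_novar <- function(sigma = 0)
  pd_parameters(omega = c(kdeg = 0, kd = 0, kout = 0), sigma_add = sigma)

conc_obs <- function(ds) {
  r <- ds$records
  r[r$DVTYPE == 1 & r$MDV == 0, ]
}
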