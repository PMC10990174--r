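# Gating kinetics in closed form.  The compiled integrator carries its own
# copy of these expressions; the R versions below are vectorized and also
# provide the analytic V-derivatives used by the manifold/fold algebra and
# the equilibrium Jacobians.  A unit test pins the two copies against each
# other.

# a*(V+th)/(1 - exp(-(V+th)/k)); the removable singularity at V = -th is
# resolved by the series limit a*k*(1 + u/2 + u^2/12), u = (V+th)/k.
rate_le <- function(V, a, th, k) {
  u <- (V + th) / k
  out <- a * (V + th) / (1 - exp(-u))
  small <- abs(u) < 1e-7
  if (any(small)) out[small] <- a * k * (1 + 0.5 * u[small])
  out
}

rate_le_d <- function(V, a, th, k) {
  x <- V + th
  u <- x / k
  E <- exp(-u)
  out <- a * ((1 - E) - x * E / k) / (1 - E)^2
  small <- abs(u) < 1e-6
  if (any(small)) out[small] <- a * (0.5 + u[small] / 6)
  out
}

rates_at <- function(V, nu) {
  list(
    alpha_m = rate_le(V, 1.86, 25.4, 10.3),
    beta_m  = rate_le(V, -0.086, 29.7, -9.16),
    alpha_n = rate_le(V, 0.186, 48.4, 10.3),
    beta_n  = rate_le(V, -0.0086, 42.7, -9.16),
    alpha_h = rate_le(V, -0.0336, 118, -11),
    beta_h  = 2.3 / (1 + exp(-(V + 35.8) / 13.4)),
    alpha_s = rate_le(V, 0.00122, 19.5, 23.6),
    beta_s  = rate_le(V, -0.000739, 87.1, -21.8),
    alpha_r = 0.007 * exp(-(V + nu) / 19),
    beta_r  = 0.007 * exp((V + nu) / 22))
}

rates_deriv_at <- function(V, nu, rt) {
  bh <- rt$beta_h
  list(
    alpha_m = rate_le_d(V, 1.86, 25.4, 10.3),
    beta_m  = rate_le_d(V, -0.086, 29.7, -9.16),
    alpha_n = rate_le_d(V, 0.186, 48.4, 10.3),
    beta_n  = rate_le_d(V, -0.0086, 42.7, -9.16),
    alpha_h = rate_le_d(V, -0.0336, 118, -11),
    beta_h  = bh * (1 - bh / 2.3) / 13.4,
    alpha_s = rate_le_d(V, 0.00122, 19.5, 23.6),
    beta_s  = rate_le_d(V, -0.000739, 87.1, -21.8),
    alpha_r = -rt$alpha_r / 19,
    beta_r  = rt$beta_r / 22)
}

#' HCN half-activation shift as a function of the cAMP flag
#'
#' Direct cAMP binding shifts the HCN activation curve toward depolarized
#' potentials: the half-activation offset is 103.5 mV at basal cAMP and
#' 95 mV at elevated cAMP.
#'
#' @param cAMP binary flag (0 or 1).
#' @return The shift (mV).
#' @export
hcn_nu <- function(cAMP) 95 * cAMP + 103.5 * (1 - cAMP)

#' Gating kinetics at a membrane potential
#'
#' Evaluates the transition rates, steady states, time constants and
#' temperature factors of all gates at potential `V`. The fast Na+
#' activation (m) and persistent Na+ activation (n) are instantaneous in the
#' model (only their steady states enter the currents); h, s and r follow
#' first-order kinetics with `p_inf = alpha/(alpha+beta)` and
#' `tau_p = 1/(phi_p (alpha+beta))`; the M gate w has an explicit sigmoidal
#' steady state and bell-shaped time constant with no temperature
#' correction.
#'
#' @param V membrane potential (mV); may be a vector.
#' @param params a [neuron_parameters()] object.
#' @return A list of named numeric vectors: rates `alpha_*`/`beta_*`, steady
#'   states `*_inf`, time constants `tau_*` (ms), temperature factors
#'   `phi_*`, and the HCN shift `nu` (mV).
#' @examples
#' gk <- gate_kinetics(-35, neuron_parameters())
#' gk$w_inf  # 0.5 by construction
#' @export
gate_kinetics <- function(V, params) {
  stopifnot(all(is.finite(V)))
  nu <- hcn_nu(params$cAMP)
  rt <- rates_at(V, nu)
  phi_m <- temperature_factor(params$Qm, params$T, params$Tref1)
  phi_n <- temperature_factor(params$Qn, params$T, params$Tref1)
  phi_h <- temperature_factor(params$Qh, params$T, params$Tref1)
  phi_s <- temperature_factor(params$Qs, params$T, params$Tref1)
  phi_r <- temperature_factor(params$Qr, params$T, params$Tref2)
  out <- rt
  out$m_inf <- rt$alpha_m / (rt$alpha_m + rt$beta_m)
  out$n_inf <- rt$alpha_n / (rt$alpha_n + rt$beta_n)
  out$h_inf <- rt$alpha_h / (rt$alpha_h + rt$beta_h)
  out$s_inf <- rt$alpha_s / (rt$alpha_s + rt$beta_s)
  out$r_inf <- rt$alpha_r / (rt$alpha_r + rt$beta_r)
  out$w_inf <- 1 / (1 + exp(-(V + 35) / 10))
  out$tau_m <- 1 / (phi_m * (rt$alpha_m + rt$beta_m))
  out$tau_n <- 1 / (phi_n * (rt$alpha_n + rt$beta_n))
  out$tau_h <- 1 / (phi_h * (rt$alpha_h + rt$beta_h))
  out$tau_s <- 1 / (phi_s * (rt$alpha_s + rt$beta_s))
  out$tau_r <- 1 / (phi_r * (rt$alpha_r + rt$beta_r))
  out$tau_w <- 400 / (3.3 * exp((V + 35) / 20) + exp(-(V + 35) / 20))
  out$phi_m <- phi_m; out$phi_n <- phi_n; out$phi_h <- phi_h
  out$phi_s <- phi_s; out$phi_r <- phi_r
  out$nu <- nu
  out
}

# V-derivatives of steady states and time constants, plus the Na+ current
# "chord" terms A(V) = gNaF m^3 (V-ENa) and B(V) = gNaP n^3 (V-ENa) with
# their derivatives.  Used by the critical-manifold/fold algebra and the
# analytic 3x3 Jacobian.
gate_kinetics_deriv <- function(V, params) {
  gk <- gate_kinetics(V, params)
  dr <- rates_deriv_at(V, gk$nu, gk)
  pinf_d <- function(a, b, da, db) (da * b - a * db) / (a + b)^2
  taud <- function(tau, a, b, da, db) -tau * (da + db) / (a + b)
  out <- list(gk = gk)
  out$dm_inf <- pinf_d(gk$alpha_m, gk$beta_m, dr$alpha_m, dr$beta_m)
  out$dn_inf <- pinf_d(gk$alpha_n, gk$beta_n, dr$alpha_n, dr$beta_n)
  out$dh_inf <- pinf_d(gk$alpha_h, gk$beta_h, dr$alpha_h, dr$beta_h)
  out$ds_inf <- pinf_d(gk$alpha_s, gk$beta_s, dr$alpha_s, dr$beta_s)
  out$dr_inf <- pinf_d(gk$alpha_r, gk$beta_r, dr$alpha_r, dr$beta_r)
  out$dtau_h <- taud(gk$tau_h, gk$alpha_h, gk$beta_h, dr$alpha_h, dr$beta_h)
  out$dtau_s <- taud(gk$tau_s, gk$alpha_s, gk$beta_s, dr$alpha_s, dr$beta_s)
  out$dtau_r <- taud(gk$tau_r, gk$alpha_r, gk$beta_r, dr$alpha_r, dr$beta_r)
  m <- gk$m_inf; n <- gk$n_inf
  out$A  <- params$gNaF * m^3 * (V - params$ENa)
  out$dA <- params$gNaF * (3 * m^2 * out$dm_inf * (V - params$ENa) + m^3)
  out$B  <- params$gNaP * n^3 * (V - params$ENa)
  out$dB <- params$gNaP * (3 * n^2 * out$dn_inf * (V - params$ENa) + n^3)
  out
}

#' Ionic current densities at a state
#'
#' Evaluates the six ionic currents of the model (uA/cm^2) with the fast and
#' persistent Na+ activations instantaneous at `V`. The M current reverses
#' at the K+ Nernst potential; HCN and M conductances include the
#' cAMP-induced increments when the cAMP flag is set.
#'
#' @param state numeric vector `c(V, h, s, r, w)`.
#' @param params a [neuron_parameters()] object.
#' @return Named vector `I_NaF, I_NaP, I_KS, I_L, I_HCN, I_M`.
#' @examples
#' p <- neuron_parameters(cAMP = 1)
#' ionic_currents(c(-60, 0.5, 0.1, 0.5, 0.1), p)[["I_HCN"]]  # -175
#' @export
ionic_currents <- function(state, params) {
  V <- state[[1]]; h <- state[[2]]; s <- state[[3]]
  r <- state[[4]]; w <- state[[5]]
  gk <- gate_kinetics(V, params)
  c(I_NaF = params$gNaF * gk$m_inf^3 * h * (V - params$ENa),
    I_NaP = params$gNaP * gk$n_inf^3 * (V - params$ENa),
    I_KS  = params$gKS * s * (V - params$EK),
    I_L   = params$gL * (V - params$EL),
    I_HCN = (params$gHCN + params$cAMP * params$dgHCN) * r * (V - params$EHCN),
    I_M   = (params$gM + params$cAMP * params$dgM) * w * (V - params$EK))
}

#' Right-hand side of the full 5D model
#'
#' Time derivatives of `(V, h, s, r, w)`: the voltage equation balances the
#' six ionic currents against the applied current over the membrane
#' capacitance, and each gate relaxes to its steady state with its voltage-
#' dependent time constant.
#'
#' @param t time (ms); unused (autonomous system), kept for integrator
#'   compatibility.
#' @param state numeric vector `c(V, h, s, r, w)`.
#' @param params a [neuron_parameters()] object.
#' @return Numeric vector of derivatives.
#' @export
rhs_5d <- function(t, state, params) {
  cpp_rhs5(as.numeric(state), as_par_vector(params))
}

#' Right-hand side of the reduced 3D slow-fast subsystem
#'
#' The `(V, h, s)` subsystem with the super-slow gates frozen at scaled
#' values: `I_HCN = gHCN * r_tilde * (V - EHCN)` and
#' `I_M = gM * w_tilde * (V - EK)`. By construction the result does not
#' depend on the cAMP flag: its effect is absorbed into the scaled gates.
#'
#' @param t time (ms); unused.
#' @param state numeric vector `c(V, h, s)`.
#' @param params a [neuron_parameters()] object.
#' @param w_tilde,r_tilde frozen scaled M and HCN gates (dimensionless).
#' @return Numeric vector of derivatives.
#' @export
rhs_3d <- function(t, state, params, w_tilde, r_tilde) {
  cpp_rhs3(as.numeric(state), as_par_vector(params), w_tilde, r_tilde)
}
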