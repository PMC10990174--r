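# Reduction of the 5D model to the (V, h, s) slow-fast subsystem: the
# super-slow gates w (M) and r (HCN) are frozen at their time averages over
# the stable attractor, after rescaling that absorbs the cAMP flag.

#' Time-averaged super-slow gates
#'
#' Trapezoidal time averages of the M gate `w(t)` and HCN gate `r(t)` over
#' the window `[t0, T]`. The defaults (350 to 450 ms) skip the initial
#' transient and average over several attractor periods.
#'
#' @param traj a 5D `neuron_trajectory` spanning at least `[0, T]`.
#' @param t0 averaging start (ms).
#' @param T averaging end (ms).
#' @return Named numeric `c(w_bar, r_bar)`.
#' @export
average_gates <- function(traj, t0 = 350, T = 450) {
  stopifnot(T > t0)
  if (max(traj$t) < T) stop("trajectory shorter than the averaging horizon T")
  sel <- traj$t >= t0 & traj$t <= T
  tt <- traj$t[sel]
  trap <- function(y) sum(diff(tt) * (y[-1] + y[-length(y)]) / 2) /
    (tt[length(tt)] - tt[1])
  c(w_bar = trap(traj$state[sel, "w"]), r_bar = trap(traj$state[sel, "r"]))
}

#' Scaled super-slow gates absorbing the cAMP flag
#'
#' `w_tilde = w (1 + cAMP dgM/gM)` and `r_tilde = r (1 + cAMP dgHCN/gHCN)`,
#' so that the 3D subsystem written in terms of the base conductances is
#' independent of cAMP. With `cAMP = 0` this is the identity. When a base
#' conductance is zero while `cAMP = 1` the unscaled value is returned for
#' that channel (its conductance product vanishes anyway) and a message is
#' emitted.
#'
#' @param w,r gate values (dimensionless, possibly vectors).
#' @param params a [neuron_parameters()] object.
#' @return List with `w_tilde`, `r_tilde`.
#' @export
scale_gates <- function(w, r, params) {
  wf <- 1; rf <- 1
  if (params$cAMP == 1) {
    if (params$gM > 0) wf <- 1 + params$dgM / params$gM
    else if (params$dgM > 0) message("gM = 0 with cAMP = 1: w left unscaled")
    if (params$gHCN > 0) rf <- 1 + params$dgHCN / params$gHCN
    else if (params$dgHCN > 0) message("gHCN = 0 with cAMP = 1: r left unscaled")
  }
  list(w_tilde = wf * w, r_tilde = rf * r)
}

#' Reduced (frozen-gate) parameters from a 5D simulation
#'
#' Runs the 5D model on the given condition, averages the super-slow gates
#' over the post-transient window and applies the cAMP scaling, yielding the
#' frozen `(w_tilde, r_tilde)` of the 3D slow-fast subsystem.
#'
#' @param params a [neuron_parameters()] object (with `IApp` set) or a
#'   condition name.
#' @param I_App optional applied current override (uA/cm^2).
#' @param t0,T averaging window (ms), as in [average_gates()].
#' @param dt integration step (ms).
#' @return List with `w_bar`, `r_bar`, `w_tilde`, `r_tilde`, `t0`, `T` and
#'   the generating `params`.
#' @examples
#' \donttest{
#' red <- reduce_model(condition_params("CGS", IApp = 250))
#' red$w_tilde
#' }
#' @export
reduce_model <- function(params, I_App = NULL, t0 = 350, T = 450,
                         dt = 0.001) {
  if (is.character(params)) params <- condition_params(params)
  if (!is.null(I_App)) params$IApp <- I_App
  tr <- integrate_model("5D", params, t_end = T, dt = dt)
  av <- average_gates(tr, t0 = t0, T = T)
  sc <- scale_gates(av[["w_bar"]], av[["r_bar"]], params)
  list(w_bar = av[["w_bar"]], r_bar = av[["r_bar"]],
       w_tilde = sc$w_tilde, r_tilde = sc$r_tilde,
       t0 = t0, T = T, params = params)
}

#' Least-squares constraint line through the scaled-gate projection
#'
#' The 5D trajectory projected onto the `(w_tilde, r_tilde)` plane evolves
#' close to a straight line `r_tilde = m w_tilde + q`; this fits the line by
#' ordinary least squares of `r_tilde` on `w_tilde` and reports the RMS
#' residual.
#'
#' @param w_tilde,r_tilde numeric vectors of the projected trajectory.
#' @return An object of class `constraint_line`: list `m`, `q`, `rms`.
#' @export
fit_line <- function(w_tilde, r_tilde) {
  stopifnot(length(w_tilde) == length(r_tilde), length(w_tilde) >= 2)
  if (diff(range(w_tilde)) == 0)
    stop("degenerate fit: w_tilde is constant")
  fit <- stats::lm.fit(cbind(1, w_tilde), r_tilde)
  structure(list(m = unname(fit$coefficients[2]),
                 q = unname(fit$coefficients[1]),
                 rms = sqrt(mean(fit$residuals^2))),
            class = "constraint_line")
}

#' @export
print.constraint_line <- function(x, ...) {
  cat(sprintf("r_tilde = %.6g * w_tilde + %.6g  (RMS residual %.3g)\n",
              x$m, x$q, x$rms))
  invisible(x)
}

#' Constraint line for a condition at a given applied current
#'
#' Simulates the 5D model, projects the post-transient trajectory through
#' [scale_gates()] and fits the line with [fit_line()].
#'
#' @inheritParams reduce_model
#' @return A `constraint_line` with the fitting window in attributes.
#' @export
constraint_line_for <- function(params, I_App = NULL, t0 = 350, T = 450,
                                dt = 0.001) {
  if (is.character(params)) params <- condition_params(params)
  if (!is.null(I_App)) params$IApp <- I_App
  tr <- integrate_model("5D", params, t_end = T, dt = dt)
  sel <- tr$t >= t0
  sc <- scale_gates(tr$state[sel, "w"], tr$state[sel, "r"], params)
  line <- fit_line(sc$w_tilde, sc$r_tilde)
  attr(line, "window") <- c(t0 = t0, T = T)
  line
}

#' Time-scale separation ratios along a trajectory
#'
#' The gate time constants come from the kinetics at `V(t)`; the membrane
#' time constant is taken as `tau_V = Cm / g_tot` with `g_tot` the sum of
#' instantaneous chord conductances
#' `gNaF m_inf^3 h + gNaP n_inf^3 + gKS s + gL + gHCN_eff r + gM_eff w`.
#' Maxima are reported over the whole trace and over SAO segments (samples
#' between the local minima bracketing each subthreshold peak).
#'
#' @param traj a 5D `neuron_trajectory`.
#' @param t_min discard samples before this time (ms).
#' @return List with `samples` (data.frame of per-sample ratios),
#'   `max_full` and `max_sao` (named maxima of `tauV_tauh`, `tauV_taus`,
#'   `taus_taur`, `taus_tauw`).
#' @export
timescale_ratios <- function(traj, t_min = 350) {
  stopifnot(traj$model == "5D")
  sel <- traj$t >= t_min
  V <- traj$state[sel, "V"]
  h <- traj$state[sel, "h"]; s <- traj$state[sel, "s"]
  r <- traj$state[sel, "r"]; w <- traj$state[sel, "w"]
  p <- traj$params
  gk <- gate_kinetics(V, p)
  g_tot <- p$gNaF * gk$m_inf^3 * h + p$gNaP * gk$n_inf^3 + p$gKS * s +
    p$gL + (p$gHCN + p$cAMP * p$dgHCN) * r + (p$gM + p$cAMP * p$dgM) * w
  tauV <- p$Cm / g_tot
  df <- data.frame(t = traj$t[sel], V = V,
                   tauV_tauh = tauV / gk$tau_h,
                   tauV_taus = tauV / gk$tau_s,
                   taus_taur = gk$tau_s / gk$tau_r,
                   taus_tauw = gk$tau_s / gk$tau_w)
  ev <- detect_events(traj, t_min = t_min)
  sao_mask <- rep(FALSE, length(V))
  saos <- ev[ev$kind == "SAO", ]
  if (nrow(saos)) {
    tt <- traj$t[sel]
    mins <- which(diff(sign(diff(V))) > 0) + 1
    tmin_pts <- tt[mins]
    for (tp in saos$t_peak) {
      lo <- suppressWarnings(max(tmin_pts[tmin_pts < tp], tt[1]))
      hi <- suppressWarnings(min(tmin_pts[tmin_pts > tp], tt[length(tt)]))
      sao_mask <- sao_mask | (tt >= lo & tt <= hi)
    }
  }
  cols <- c("tauV_tauh", "tauV_taus", "taus_taur", "taus_tauw")
  max_full <- vapply(cols, function(cn) max(df[[cn]]), numeric(1))
  max_sao <- if (any(sao_mask))
    vapply(cols, function(cn) max(df[[cn]][sao_mask]), numeric(1))
  else rep(NA_real_, 4)
  names(max_sao) <- cols
  list(samples = df, max_full = max_full, max_sao = max_sao)
}

#' Reduction report
#'
#' Bundles the reduction of a condition at one applied current: averaged and
#' scaled gates plus the fitted constraint line, optionally written as JSON.
#'
#' @inheritParams reduce_model
#' @param condition condition name (used for labelling).
#' @param file optional JSON path.
#' @return A list `condition`, `I_app`, `w_bar`, `r_bar`, `w_tilde`,
#'   `r_tilde`, `m`, `q`, `rms`.
#' @export
reduction_report <- function(condition, I_App, t0 = 350, T = 450,
                             dt = 0.001, file = NULL) {
  params <- condition_params(condition, IApp = I_App)
  red <- reduce_model(params, t0 = t0, T = T, dt = dt)
  line <- constraint_line_for(params, t0 = t0, T = T, dt = dt)
  out <- list(condition = condition, I_app = I_App,
              w_bar = red$w_bar, r_bar = red$r_bar,
              w_tilde = red$w_tilde, r_tilde = red$r_tilde,
              m = line$m, q = line$q, rms = line$rms)
  if (!is.null(file))
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  out
}
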