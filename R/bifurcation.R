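# Bifurcation structure of the 3D slow-fast subsystem.  Branch-following of
# an interactive continuation tool is replaced by (a) scalar-equation
# equilibrium continuation with eigenvalue monitoring, (b) simulation-based
# attractor classification with bisection for cycle bifurcations, and (c)
# Floquet multipliers from the monodromy matrix for period doubling.

# Scalar current balance at the quasi-equilibrium h = h_inf(V), s = s_inf(V).
current_balance <- function(V, params, w_tilde, r_tilde) {
  gk <- gate_kinetics(V, params)
  INaF <- params$gNaF * gk$m_inf^3 * gk$h_inf * (V - params$ENa)
  INaP <- params$gNaP * gk$n_inf^3 * (V - params$ENa)
  IKS  <- params$gKS * gk$s_inf * (V - params$EK)
  IL   <- params$gL * (V - params$EL)
  IHCN <- params$gHCN * r_tilde * (V - params$EHCN)
  IM   <- params$gM * w_tilde * (V - params$EK)
  (-INaF - INaP - IKS - IL - IHCN - IM + params$IApp) / params$Cm
}

# Analytic 3x3 Jacobian of the reduced subsystem at a state.
jac_3d <- function(state, params, w_tilde, r_tilde) {
  V <- state[[1]]; h <- state[[2]]; s <- state[[3]]
  d <- gate_kinetics_deriv(V, params)
  gk <- d$gk
  Cm <- params$Cm
  dfdV <- -(h * d$dA + d$dB + params$gKS * s + params$gL +
              params$gHCN * r_tilde + params$gM * w_tilde) / Cm
  dfdh <- -d$A / Cm
  dfds <- -params$gKS * (V - params$EK) / Cm
  ghV <- d$dh_inf / gk$tau_h - (gk$h_inf - h) * d$dtau_h / gk$tau_h^2
  gsV <- d$ds_inf / gk$tau_s - (gk$s_inf - s) * d$dtau_s / gk$tau_s^2
  matrix(c(dfdV, dfdh, dfds,
           ghV, -1 / gk$tau_h, 0,
           gsV, 0, -1 / gk$tau_s),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("V", "h", "s"), c("V", "h", "s")))
}

#' Equilibrium of the 3D slow-fast subsystem
#'
#' At equilibrium `h = h_inf(V)` and `s = s_inf(V)`, so the equilibrium
#' voltage solves the scalar current-balance equation. Roots are bracketed
#' on a fine grid over `V_bracket` and refined with [stats::uniroot()];
#' eigenvalues come from the analytic 3x3 Jacobian.
#'
#' @param params a [neuron_parameters()] object (with `IApp` set).
#' @param w_tilde,r_tilde frozen scaled gates.
#' @param V_bracket voltage interval (mV) searched for roots.
#' @param all return every root instead of the unique one.
#' @return A list (`equilibrium_3d`) with `V`, `h`, `s`, `state`,
#'   `eigenvalues` and `stable`; with `all = TRUE`, a list of such lists.
#'   Errors when no root lies in the bracket; warns when several do.
#' @export
find_equilibrium_3d <- function(params, w_tilde, r_tilde,
                                V_bracket = c(-90, 20), all = FALSE) {
  grid <- seq(V_bracket[1], V_bracket[2], length.out = 600)
  fv <- current_balance(grid, params, w_tilde, r_tilde)
  sgn <- which(fv[-1] * fv[-length(fv)] < 0)
  if (!length(sgn))
    stop("no equilibrium in V bracket [", V_bracket[1], ", ", V_bracket[2],
         "]; widen the bracket")
  eqs <- lapply(sgn, function(i) {
    root <- stats::uniroot(current_balance, c(grid[i], grid[i + 1]),
                           params = params, w_tilde = w_tilde,
                           r_tilde = r_tilde, tol = 1e-12)
    V <- root$root
    gk <- gate_kinetics(V, params)
    st <- c(V = V, h = gk$h_inf, s = gk$s_inf)
    ev <- eigen(jac_3d(st, params, w_tilde, r_tilde),
                only.values = TRUE)$values
    list(V = V, h = gk$h_inf, s = gk$s_inf, state = st,
         eigenvalues = ev, stable = max(Re(ev)) < 0)
  })
  if (all) return(eqs)
  if (length(eqs) > 1)
    warning(length(eqs), " equilibria found; returning the first")
  structure(eqs[[1]], class = "equilibrium_3d")
}

# Real part of the complex eigenvalue pair (falls back to the largest real
# part when the pair has collapsed onto the real axis far from the Hopf).
pair_re <- function(ev) {
  cplx <- ev[Im(ev) != 0]
  if (length(cplx)) max(Re(cplx)) else max(Re(ev))
}

#' Hopf bifurcation along a constraint line
#'
#' Tracks the equilibrium of the 3D subsystem along `r_tilde = m w_tilde +
#' q` and bisects every sign change of the real part of the complex
#' eigenvalue pair, locating Hopf points to `tol` in `w_tilde`.
#'
#' @param params a [neuron_parameters()] object.
#' @param line a `constraint_line` (or list with `m`, `q`).
#' @param w_range interval of `w_tilde` scanned.
#' @param n coarse grid size.
#' @param tol root tolerance on `w_tilde` (the root is polished to at
#'   least 1e-10, so the residual real part is far below 1e-6).
#' @return A list of Hopf points: each has `w_tilde`, `r_tilde`, `omega`
#'   (imaginary pair frequency, rad/ms), `eigenvalues`, `state`. Empty list
#'   when no stability change occurs.
#' @export
hopf_on_line <- function(params, line, w_range = c(0.02, 0.6), n = 60,
                         tol = 1e-5) {
  rfun <- function(wt) line$m * wt + line$q
  f <- function(wt) {
    eq <- find_equilibrium_3d(params, wt, rfun(wt))
    pair_re(eq$eigenvalues)
  }
  grid <- seq(w_range[1], w_range[2], length.out = n)
  fv <- vapply(grid, f, numeric(1))
  out <- list()
  for (i in which(fv[-1] * fv[-length(fv)] < 0)) {
    wt <- stats::uniroot(f, c(grid[i], grid[i + 1]),
                         f.lower = fv[i], f.upper = fv[i + 1],
                         tol = min(tol, 1e-10))$root
    eq <- find_equilibrium_3d(params, wt, rfun(wt))
    cplx <- eq$eigenvalues[Im(eq$eigenvalues) > 0]
    out[[length(out) + 1]] <-
      list(w_tilde = wt, r_tilde = rfun(wt),
           omega = if (length(cplx)) Im(cplx[1]) else NA_real_,
           eigenvalues = eq$eigenvalues, state = eq$state)
  }
  out
}

#' Hopf curve in the (w_tilde, r_tilde) plane
#'
#' For each `r_tilde` in the grid, bisects the Hopf condition over
#' `w_tilde` with the line constraint relaxed. The silent region (stable
#' equilibrium) lies on the high-`w_tilde` side of the curve.
#'
#' @param params a [neuron_parameters()] object.
#' @param r_grid values of `r_tilde`.
#' @param w_range interval of `w_tilde` searched per level.
#' @param tol bisection tolerance.
#' @return data.frame `w_tilde`, `r_tilde` of Hopf points (rows with no
#'   sign change are dropped and reported via a message).
#' @export
hopf_curve_2p <- function(params, r_grid, w_range = c(0.02, 0.8),
                          tol = 1e-5) {
  rows <- lapply(r_grid, function(rt) {
    hb <- hopf_on_line(params, list(m = 0, q = rt), w_range = w_range,
                       n = 40, tol = tol)
    if (!length(hb)) return(NULL)
    data.frame(w_tilde = hb[[1]]$w_tilde, r_tilde = rt)
  })
  miss <- sum(vapply(rows, is.null, logical(1)))
  if (miss) message(miss, " r_tilde level(s) without a Hopf point in range")
  do.call(rbind, rows)
}

#' Classify the attractor of the 3D subsystem at frozen gates
#'
#' Long transient-discarded simulation classified from its events:
#' `"equilibrium"` (no oscillation events), `"SAO-cycle"` (subthreshold
#' cycling only), `"LAO-cycle"` (relaxation spiking, no SAOs) or `"MMO"`
#' (both present; includes the chaotic MMO attractor).
#'
#' @param params a [neuron_parameters()] object.
#' @param w_tilde,r_tilde frozen scaled gates.
#' @param horizon simulation horizon (ms).
#' @param analyse analysis window at the end of the run (ms).
#' @param dt integration step (ms).
#' @param prominence minimal peak prominence (mV); small, as the SAOs near
#'   the MMO onset are tiny (see [classify_regime()]).
#' @return Character label.
#' @export
classify_attractor_3d <- function(params, w_tilde, r_tilde, horizon = 1500,
                                  analyse = 600, dt = 0.001,
                                  prominence = 0.05) {
  tr <- integrate_model("3D", params, t_end = horizon, dt = dt,
                        w_tilde = w_tilde, r_tilde = r_tilde)
  ev <- detect_events(tr, t_min = horizon - analyse,
                      prominence = prominence)
  has_lao <- any(ev$kind == "LAO")
  has_sao <- any(ev$kind == "SAO")
  if (!has_lao && !has_sao) "equilibrium"
  else if (!has_lao) "SAO-cycle"
  else if (has_sao) "MMO" else "LAO-cycle"
}

#' Attractor scan along a constraint line
#'
#' Classifies the 3D attractor on a `w_tilde` grid along `r_tilde = m
#' w_tilde + q` and bisects the onset of mixed-mode oscillations (the
#' discontinuous jump from pure relaxation cycling to the MMO attractor) to
#' `tol`.
#'
#' @inheritParams hopf_on_line
#' @param n coarse grid size.
#' @param tol bisection tolerance on the MMO-onset parameter.
#' @param ... passed to [classify_attractor_3d()].
#' @return List with `grid` (data.frame `w_tilde`, `class`) and `onset`
#'   (the refined LAO-to-MMO boundary, or `NA` when absent).
#' @export
attractor_scan_on_line <- function(params, line, w_range = c(0.05, 0.45),
                                   n = 25, tol = 1e-4, ...) {
  rfun <- function(wt) line$m * wt + line$q
  cls <- function(wt) classify_attractor_3d(params, wt, rfun(wt), ...)
  grid <- seq(w_range[1], w_range[2], length.out = n)
  labs <- vapply(grid, cls, character(1))
  onset <- NA_real_
  i <- which(labs[-n] == "LAO-cycle" & labs[-1] == "MMO")
  if (length(i)) {
    lo <- grid[i[1]]; hi <- grid[i[1] + 1]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (cls(mid) == "LAO-cycle") lo <- mid else hi <- mid
    }
    onset <- (lo + hi) / 2
  }
  list(grid = data.frame(w_tilde = grid, class = labs), onset = onset)
}

# One Poincare return of the 3D flow through the section s = s0 crossed in
# direction dir, starting from x (assumed on or near the section); t_skip
# suppresses the trivial immediate recrossing.
poincare_return <- function(params, w_tilde, r_tilde, x, s0, dir,
                            t_skip, t_max, dt = 0.001) {
  pv <- as_par_vector(params)
  pre <- cpp_sim3(pv, w_tilde, r_tilde, as.numeric(x), t_skip, dt, 1000L)
  x1 <- pre$y[nrow(pre$y), ]
  res <- cpp_sim3(pv, w_tilde, r_tilde, x1, t_max, dt, 1000L,
                  stop_var = 2L, stop_val = s0, stop_dir = as.integer(dir))
  if (!res$stopped) stop("no Poincare return within t_max")
  list(x = res$y_stop, T = t_skip + res$t_stop)
}

#' Floquet multipliers of the stable cycle of the 3D subsystem
#'
#' Locates the periodic orbit by simulation, converges it on a Poincare
#' section through iteration of the return map, then integrates the
#' variational equations over one period with a high-accuracy adaptive
#' solver to obtain the monodromy matrix. One multiplier is always close to
#' +1 (the phase direction); a period-doubling bifurcation is flagged when a
#' real multiplier crosses -1.
#'
#' @param params a [neuron_parameters()] object.
#' @param w_tilde,r_tilde frozen scaled gates at which a (near-)stable
#'   period-1 cycle exists.
#' @param horizon simulation horizon (ms) used to settle onto the cycle.
#' @param dt integration step (ms) of the settling run.
#' @return List with `multipliers` (complex, ordered by decreasing
#'   modulus), `period` (ms), `state` (a point on the cycle), and `pd`
#'   (TRUE when a real multiplier lies beyond -1).
#' @export
pd1_floquet <- function(params, w_tilde, r_tilde, horizon = 1200,
                        dt = 0.001) {
  tr <- integrate_model("3D", params, t_end = horizon, dt = dt,
                        w_tilde = w_tilde, r_tilde = r_tilde)
  ev <- detect_events(tr, t_min = horizon / 2)
  laos <- ev[ev$kind == "LAO", ]
  if (nrow(laos) < 3) stop("no sustained cycle found at these parameters")
  T0 <- stats::median(diff(laos$t_peak))
  # anchor the Poincare section at the AHP trough between the last two
  # spikes: the dynamics is slow there, so the interpolated section
  # crossings are far more accurate than in the stiff spike phase
  win <- tr$t > laos$t_peak[nrow(laos) - 1] & tr$t < laos$t_peak[nrow(laos)]
  i0 <- which(win)[which.min(tr$state[win, "V"])]
  x <- tr$state[i0, ]
  s0 <- x[["s"]]
  d0 <- rhs_3d(0, x, params, w_tilde, r_tilde)[3]
  dir <- if (d0 >= 0) 1L else -1L
  Tret <- T0
  for (k in 1:30) {
    ret <- poincare_return(params, w_tilde, r_tilde, x, s0, dir,
                           t_skip = 0.25 * T0, t_max = 4 * T0, dt = dt)
    delta <- max(abs(ret$x - x))
    x <- ret$x
    Tret <- ret$T
    if (k > 2 && delta < 1e-11) break
  }
  # variational equations: d(Phi)/dt = J(x(t)) Phi
  varf <- function(t, y, parms) {
    st <- y[1:3]
    Phi <- matrix(y[4:12], 3, 3)
    J <- jac_3d(st, params, w_tilde, r_tilde)
    list(c(rhs_3d(t, st, params, w_tilde, r_tilde), as.numeric(J %*% Phi)))
  }
  y0 <- c(as.numeric(x), as.numeric(diag(3)))
  sol <- deSolve::ode(y0, c(0, Tret), varf, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  M <- matrix(sol[nrow(sol), 5:13], 3, 3)
  mult <- eigen(M, only.values = TRUE)$values
  mult <- mult[order(-Mod(mult))]
  pd <- any(Im(mult) == 0 & Re(mult) < -1)
  list(multipliers = mult, period = Tret, state = x, pd = pd)
}

#' Locate the first period doubling along a constraint line
#'
#' Bisects, in `w_tilde` along `r_tilde = m w_tilde + q`, the onset of
#' spike-height alternation of the relaxation cycle (the period-two
#' signature). The Floquet route ([pd1_floquet()]) verifies the located
#' point: just left of it the cycle's real multiplier approaches -1 from
#' above, while a multiplier-sign bisection itself becomes unusable past
#' the doubling because the located orbit is then the period-two cycle
#' (whose multipliers are products over both loops, hence positive again).
#'
#' @inheritParams hopf_on_line
#' @param tol bisection tolerance on `w_tilde`.
#' @param alt_threshold spike-height alternation (mV) regarded as
#'   period-two.
#' @param horizon settle-and-analyse horizon (ms).
#' @return List `w_tilde`, `r_tilde`, `multipliers` (Floquet multipliers
#'   just left of the located point), or `NULL` when `w_range` does not
#'   bracket an alternation onset.
#' @export
pd1_on_line <- function(params, line, w_range, tol = 1e-3,
                        alt_threshold = 0.1, horizon = 1500) {
  alternation <- function(wt) {
    # store every 2nd step: sharp spike tops need a fine grid for the
    # interpolated peak heights to resolve sub-0.1 mV alternation
    tr <- integrate_model("3D", params, t_end = horizon, thin = 2,
                          w_tilde = wt, r_tilde = line$m * wt + line$q)
    ev <- detect_events(tr, t_min = horizon - 500)
    pk <- ev$V_peak[ev$kind == "LAO"]
    if (length(pk) < 6) return(NA_real_)
    stats::median(abs(diff(pk)))
  }
  lo <- w_range[1]; hi <- w_range[2]
  alo <- alternation(lo); ahi <- alternation(hi)
  if (is.na(alo) || is.na(ahi) || alo >= alt_threshold ||
      ahi < alt_threshold)
    return(NULL)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    am <- alternation(mid)
    if (!is.na(am) && am < alt_threshold) lo <- mid else hi <- mid
  }
  wt <- (lo + hi) / 2
  wl <- wt - 2e-4   # just left of the doubling: multiplier near -1
  mult <- tryCatch(
    pd1_floquet(params, wl, line$m * wl + line$q)$multipliers,
    error = function(e) NULL)
  list(w_tilde = wt, r_tilde = line$m * wt + line$q, multipliers = mult)
}

#' Minimal cAMP-induced M-conductance increment producing MMOs beyond the
#' control range
#'
#' For the stimulated cell (`cAMP = 1`) the upper endpoint of the MMO
#' applied-current interval grows with the M-conductance increment `dgM`;
#' the threshold is the increment at which it first exceeds the control
#' upper endpoint (which does not depend on `dgM`). Located by bisection of
#' the endpoint difference.
#'
#' @param base parameters with the M/HCN conductances at their defaults.
#' @param dgm_range interval of `dgM` (mS/cm^2) bracketing the threshold.
#' @param tol bisection tolerance (mS/cm^2).
#' @param I_range,coarse,resolution passed to the regime scans.
#' @param ... passed to [classify_regime()] via the scans.
#' @return List with `threshold` (mS/cm^2), `upper_ctrl` and the bisection
#'   trace (data.frame `dgM`, `upper_stim`).
#' @export
dgm_threshold <- function(base = neuron_parameters(), dgm_range = c(0, 20),
                          tol = 0.25, I_range = c(100, 450), coarse = 20,
                          resolution = 0.25, ...) {
  ctrl <- base; ctrl$cAMP <- 0
  upper_ctrl <- mmo_interval(ctrl, I_range, coarse, resolution, ...)[2]
  trace <- data.frame(dgM = numeric(0), upper_stim = numeric(0))
  upper_stim <- function(dgm) {
    p <- base; p$cAMP <- 1; p$dgM <- dgm
    u <- mmo_interval(p, I_range, coarse, resolution, ...)[2]
    trace <<- rbind(trace, data.frame(dgM = dgm, upper_stim = u))
    u
  }
  g <- function(dgm) upper_stim(dgm) - upper_ctrl
  lo <- dgm_range[1]; hi <- dgm_range[2]
  glo <- g(lo); ghi <- g(hi)
  if (glo >= 0 || ghi <= 0)
    stop("dgm_range does not bracket the threshold (g(lo) = ", glo,
         ", g(hi) = ", ghi, ")")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) <= 0) lo <- mid else hi <- mid
  }
  list(threshold = (lo + hi) / 2, upper_ctrl = upper_ctrl, trace = trace)
}

#' Two-parameter regime map
#'
#' Either the `(w_tilde, r_tilde)` attractor map of the 3D subsystem, or
#' the `(I_App, dgM)` map of the full 5D model comparing control and
#' stimulated MMO intervals (the mechanism behind the minimal-increment
#' threshold, see [dgm_threshold()]).
#'
#' @param params a [neuron_parameters()] object.
#' @param axes `"wr"` or `"idgm"`.
#' @param grid1 grid of `w_tilde` (for `"wr"`) or `dgM` values (for
#'   `"idgm"`).
#' @param grid2 grid of `r_tilde` (for `"wr"`); for `"idgm"` the interval
#'   of `I_App` scanned, default `c(0, 450)`.
#' @param file optional CSV path.
#' @param ... passed to the per-cell classifiers.
#' @return data.frame: for `"wr"` columns `w_tilde`, `r_tilde`, `class`;
#'   for `"idgm"` columns `dgM`, `lower_ctrl`, `upper_ctrl`, `lower_stim`,
#'   `upper_stim`.
#' @export
regime_map_2p <- function(params, axes = c("wr", "idgm"), grid1, grid2,
                          file = NULL, ...) {
  axes <- match.arg(axes)
  if (axes == "wr") {
    cells <- expand.grid(w_tilde = grid1, r_tilde = grid2)
    cells$class <- mapply(function(wt, rt)
      classify_attractor_3d(params, wt, rt, ...),
      cells$w_tilde, cells$r_tilde)
    out <- cells
  } else {
    if (missing(grid2)) grid2 <- c(0, 450)
    ctrl <- params; ctrl$cAMP <- 0
    ic <- mmo_interval(ctrl, I_range = grid2, ...)
    rows <- lapply(grid1, function(dgm) {
      p <- params; p$cAMP <- 1; p$dgM <- dgm
      is <- mmo_interval(p, I_range = grid2, ...)
      data.frame(dgM = dgm, lower_ctrl = ic[1], upper_ctrl = ic[2],
                 lower_stim = is[1], upper_stim = is[2])
    })
    out <- do.call(rbind, rows)
  }
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
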