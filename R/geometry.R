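# Geometric singular perturbation analysis of the 3D slow-fast subsystem:
# closed-form critical manifold and fold curves, desingularized reduced
# flow, folded singularities, canard orbits via slow-manifold
# reconstruction, and rotational-sector prediction of SAO counts.

#' Critical manifold of the 3D subsystem in closed form
#'
#' The fast nullcline `dV/dt = 0` solved for the slow K+ gate:
#' `s = gamma(V, h) = gamma0 + gamma_rt + gamma_wt + gamma_rtheta`, where
#' `gamma0` carries the Na+/leak/applied-current structure,
#' `gamma_rt = -(gHCN/gKS) r_tilde` and `gamma_wt = -(gM/gKS) w_tilde` are
#' the constant shifts from HCN and M activation, and `gamma_rtheta`
#' applies the HCN driving-force correction proportional to
#' `(EHCN - EK)/(V - EK)`.
#'
#' @param V membrane potential (mV); vectorized. Must differ from `EK`.
#' @param h fast Na+ inactivation gate; vectorized (recycled against `V`).
#' @param params a [neuron_parameters()] object (its `IApp` enters
#'   `gamma0`).
#' @param w_tilde,r_tilde frozen scaled gates.
#' @return List with `s` and the components `gamma0`, `gamma_rt`,
#'   `gamma_wt`, `gamma_rtheta`.
#' @export
gamma_manifold <- function(V, h, params, w_tilde, r_tilde) {
  if (any(V == params$EK)) stop("gamma is singular at V = EK")
  gk <- gate_kinetics(V, params)
  INaF <- params$gNaF * gk$m_inf^3 * h * (V - params$ENa)
  INaP <- params$gNaP * gk$n_inf^3 * (V - params$ENa)
  IL <- params$gL * (V - params$EL)
  den <- params$gKS * (V - params$EK)
  g0 <- -(INaF + INaP + IL - params$IApp) / den
  grt <- -(params$gHCN / params$gKS) * r_tilde
  gwt <- -(params$gM / params$gKS) * w_tilde
  grth <- (params$gHCN / params$gKS) *
    (params$EHCN - params$EK) / (V - params$EK) * r_tilde
  list(s = g0 + grt + gwt + grth + 0 * V,
       gamma0 = g0, gamma_rt = grt + 0 * V, gamma_wt = gwt + 0 * V,
       gamma_rtheta = grth)
}

# Analytic d(dV/dt)/dV of the 3D subsystem at fixed (h, s) (units 1/ms).
dfdV_3d <- function(V, h, s, params, w_tilde, r_tilde) {
  d <- gate_kinetics_deriv(V, params)
  -(h * d$dA + d$dB + params$gKS * s + params$gL +
      params$gHCN * r_tilde + params$gM * w_tilde) / params$Cm
}

#' Sheet classification on the critical manifold
#'
#' Signs of the fast-subsystem linearization: attracting where
#' `d(dV/dt)/dV < 0`, repelling where it is positive.
#'
#' @inheritParams gamma_manifold
#' @return Character vector `"attracting"`/`"repelling"`.
#' @export
sheet_classify <- function(V, h, params, w_tilde, r_tilde) {
  s <- gamma_manifold(V, h, params, w_tilde, r_tilde)$s
  ifelse(dfdV_3d(V, h, s, params, w_tilde, r_tilde) < 0,
         "attracting", "repelling")
}

#' Fold curve of the critical manifold in closed form
#'
#' Solving `d(dV/dt)/dV = 0` on the manifold for the Na+ inactivation gate
#' gives `h = psi(V) = psi0 + psi_r`: the HCN term translates the fold
#' (proportional to `r_tilde`), whereas the `h` component is independent of
#' `w_tilde`; the `s` component of the fold inherits the M-channel shift
#' through `gamma`.
#'
#' @param V membrane potential (mV); vectorized.
#' @param params a [neuron_parameters()] object.
#' @param r_tilde frozen scaled HCN gate.
#' @return List with `h`, components `psi0`, `psi_r`, and the common
#'   denominator `denom` (zero denominators yield `NA` with a message).
#' @export
fold_psi <- function(V, params, r_tilde) {
  d <- gate_kinetics_deriv(V, params)
  D <- (V - params$EK) * d$dA - d$A
  bad <- abs(D) < 1e-12
  if (any(bad)) message(sum(bad), " fold point(s) excluded: zero denominator")
  D[bad] <- NA_real_
  psi0 <- -((V - params$EK) * d$dB - d$B +
              params$gL * (params$EL - params$EK) + params$IApp) / D
  psir <- -params$gHCN * (params$EHCN - params$EK) * r_tilde / D
  list(h = psi0 + psir, psi0 = psi0, psi_r = psir, denom = D)
}

#' Fold branches embedded in the critical manifold
#'
#' Traces `h = psi(V)` over a voltage window, embeds each point via
#' `s = gamma(V, psi(V))`, and labels points `L-` when they separate the
#' hyperpolarized attracting sheet from the repelling sheet (attracting on
#' the low-V side) and `L+` otherwise.
#'
#' @param params a [neuron_parameters()] object.
#' @param w_tilde,r_tilde frozen scaled gates.
#' @param V_window voltage interval (mV).
#' @param n number of trace points.
#' @return data.frame `V`, `h`, `s`, `branch` (rows with `h` outside
#'   `[0, 1]` or undefined are dropped).
#' @export
fold_curves <- function(params, w_tilde, r_tilde, V_window = c(-75, 10),
                        n = 1200) {
  V <- seq(V_window[1], V_window[2], length.out = n)
  ps <- fold_psi(V, params, r_tilde)
  h <- ps$h
  keep <- is.finite(h) & h >= 0 & h <= 1
  V <- V[keep]; h <- h[keep]
  s <- gamma_manifold(V, h, params, w_tilde, r_tilde)$s
  eps <- 0.05
  left <- dfdV_3d(V - eps, h, s, params, w_tilde, r_tilde)
  right <- dfdV_3d(V + eps, h, s, params, w_tilde, r_tilde)
  branch <- ifelse(left < 0 & right > 0, "L-",
                   ifelse(left > 0 & right < 0, "L+", NA))
  out <- data.frame(V = V, h = h, s = s, branch = branch)
  out[!is.na(out$branch), , drop = FALSE]
}

#' Desingularized reduced flow on the critical manifold
#'
#' The slow flow on the manifold, with `s` eliminated via `gamma` and time
#' rescaled by the fast-subsystem linearization so the vector field is
#' regular at the fold. The rescaling reverses the flow direction on the
#' repelling sheet (a standard property of desingularization, recorded in
#' the `orientation` attribute).
#'
#' @param V,h coordinates on the manifold; vectorized.
#' @inheritParams gamma_manifold
#' @return Matrix with columns `dV`, `dh`; attribute
#'   `orientation = "reversed on repelling sheet"`.
#' @export
desingularized_rhs <- function(V, h, params, w_tilde, r_tilde) {
  d <- gate_kinetics_deriv(V, params)
  gk <- d$gk
  s <- gamma_manifold(V, h, params, w_tilde, r_tilde)$s
  dV <- d$A * (h - gk$h_inf) / gk$tau_h +
    params$gKS * (V - params$EK) * (s - gk$s_inf) / gk$tau_s
  sumdI <- h * d$dA + d$dB + params$gKS * s + params$gL +
    params$gM * w_tilde + params$gHCN * r_tilde
  dh <- -(h - gk$h_inf) / gk$tau_h * sumdI
  out <- cbind(dV = dV, dh = dh)
  attr(out, "orientation") <- "reversed on repelling sheet"
  out
}

desing_jacobian <- function(V, h, params, w_tilde, r_tilde,
                            eps = c(1e-5, 1e-7)) {
  f <- function(x) as.numeric(desingularized_rhs(x[1], x[2], params,
                                                 w_tilde, r_tilde))
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- eps[j]
    J[, j] <- (f(c(V, h) + e) - f(c(V, h) - e)) / (2 * eps[j])
  }
  J
}

#' Folded singularities of the desingularized flow
#'
#' Roots of the desingularized `dV/dt` component along the fold curve
#' `h = psi(V)`, classified by the eigenvalues of the desingularized
#' Jacobian: a folded node has two real eigenvalues of equal sign (with
#' eigenvalue ratio `mu` in (0, 1)), a folded saddle has real eigenvalues
#' of opposite signs, and a folded focus a complex pair.
#'
#' @param params a [neuron_parameters()] object.
#' @param w_tilde,r_tilde frozen scaled gates.
#' @param V_window voltage interval (mV) searched along the fold.
#' @param n grid size for root bracketing.
#' @return List of folded singularities: each has `V`, `h`, `s`, `branch`,
#'   `eigenvalues`, `class`, `mu`, `strong` and `weak` eigendirections (in
#'   the `(V, h)` chart). Empty list when no root exists.
#' @export
folded_singularities <- function(params, w_tilde, r_tilde,
                                 V_window = c(-75, 10), n = 2000) {
  fc <- fold_curves(params, w_tilde, r_tilde, V_window, n)
  if (!nrow(fc)) return(list())
  res_at <- function(V) {
    h <- fold_psi(V, params, r_tilde)$h
    desingularized_rhs(V, h, params, w_tilde, r_tilde)[, "dV"]
  }
  out <- list()
  for (br in unique(fc$branch)) {
    Vb <- fc$V[fc$branch == br]
    rv <- res_at(Vb)
    for (i in which(rv[-1] * rv[-length(rv)] < 0)) {
      V0 <- stats::uniroot(res_at, c(Vb[i], Vb[i + 1]), tol = 1e-12)$root
      h0 <- fold_psi(V0, params, r_tilde)$h
      s0 <- gamma_manifold(V0, h0, params, w_tilde, r_tilde)$s
      J <- desing_jacobian(V0, h0, params, w_tilde, r_tilde)
      eg <- eigen(J)
      ev <- eg$values
      cls <- if (all(Im(ev) == 0)) {
        if (prod(Re(ev)) > 0) "folded node" else "folded saddle"
      } else "folded focus"
      mu <- NA_real_
      strong <- weak <- NULL
      if (cls == "folded node") {
        o <- order(-abs(Re(ev)))
        mu <- Re(ev[o[2]]) / Re(ev[o[1]])
        strong <- Re(eg$vectors[, o[1]])
        weak <- Re(eg$vectors[, o[2]])
        strong <- strong / sqrt(sum(strong^2))
        weak <- weak / sqrt(sum(weak^2))
      }
      out[[length(out) + 1]] <-
        list(V = V0, h = h0, s = s0, branch = br, eigenvalues = ev,
             class = cls, mu = mu, strong = strong, weak = weak)
    }
  }
  out
}

#' Ordinary singularities (equilibria of the 3D subsystem) via the manifold
#'
#' Numerical roots of `gamma(V, h_inf(V)) = s_inf(V)`: points where the
#' slow nullclines meet the critical manifold, i.e. equilibria of the
#' non-desingularized 3D subsystem (an independent construction
#' cross-checking [find_equilibrium_3d()]).
#'
#' @inheritParams folded_singularities
#' @return data.frame `V`, `h`, `s`.
#' @export
ordinary_singularities <- function(params, w_tilde, r_tilde,
                                   V_window = c(-90, 20), n = 2000) {
  g <- function(V) {
    gk <- gate_kinetics(V, params)
    gamma_manifold(V, gk$h_inf, params, w_tilde, r_tilde)$s - gk$s_inf
  }
  V <- seq(V_window[1], V_window[2], length.out = n)
  V <- V[V != params$EK]
  gv <- g(V)
  roots <- numeric(0)
  for (i in which(gv[-1] * gv[-length(gv)] < 0)) {
    # skip the pole at V = EK
    if (V[i] < params$EK && V[i + 1] > params$EK) next
    roots <- c(roots, stats::uniroot(g, c(V[i], V[i + 1]), tol = 1e-12)$root)
  }
  gk <- gate_kinetics(roots, params)
  data.frame(V = roots, h = gk$h_inf, s = gk$s_inf)
}

# Integrate the desingularized planar flow from a point; `direction` +1/-1
# multiplies the vector field (used to move away from a node).  The orbit
# is terminated at the boundary of a window that keeps it clear of the
# gamma pole at V = EK.
desing_orbit <- function(start, params, w_tilde, r_tilde, t_max = 2000,
                         direction = 1, n_out = 2000) {
  f <- function(t, y, parms) {
    d <- desingularized_rhs(y[1], y[2], params, w_tilde, r_tilde)
    list(direction * as.numeric(d))
  }
  root <- function(t, y, parms) {
    c(y[1] - (params$EK + 6), 20 - y[1], y[2] + 0.2, 1.2 - y[2])
  }
  solve_until <- function(times) {
    try(suppressWarnings(
      deSolve::ode(as.numeric(start), times, f, parms = NULL,
                   method = "lsodar", rootfunc = root,
                   rtol = 1e-9, atol = 1e-11)), silent = TRUE)
  }
  # locate the exit time first, then resolve the orbit densely up to it
  sol <- solve_until(seq(0, t_max, length.out = 200))
  if (inherits(sol, "try-error")) return(NULL)
  te <- sol[nrow(sol), 1]
  if (te > 0) {
    sol2 <- solve_until(seq(0, te, length.out = n_out))
    if (!inherits(sol2, "try-error")) sol <- sol2
  }
  m <- unclass(sol)
  data.frame(t = m[, 1], V = m[, 2], h = m[, 3])
}

#' Strong canard of a folded node
#'
#' The orbit of the desingularized flow through the folded node tangent to
#' the eigendirection of the larger-modulus eigenvalue. Together with the
#' fold `L-` it bounds the funnel: orbits landing inside exhibit SAOs,
#' orbits landing on the far side jump regularly without SAOs.
#'
#' @param fn a folded node from [folded_singularities()].
#' @param params a [neuron_parameters()] object.
#' @param w_tilde,r_tilde frozen scaled gates.
#' @param delta offset along the strong eigendirection used to start the
#'   orbit.
#' @param t_max integration horizon of the desingularized flow (its time
#'   unit is rescaled, not ms).
#' @return A `canard_orbit`: list with `index = 0`, `role = "strong"`, and
#'   `orbit` (data.frame `V`, `h`, `s` through the node).
#' @export
strong_canard <- function(fn, params, w_tilde, r_tilde, delta = 1e-3,
                          t_max = 2000) {
  if (fn$class != "folded node") stop("strong canard requires a folded node")
  ev <- Re(fn$eigenvalues)
  lam_s <- ev[which.max(abs(ev))]
  away <- sign(lam_s)   # move away from the node in this time direction
  seg <- list()
  for (sgn in c(1, -1)) {
    start <- c(fn$V, fn$h) + sgn * delta * fn$strong
    orb <- desing_orbit(start, params, w_tilde, r_tilde, t_max = t_max,
                        direction = away)
    if (!is.null(orb)) seg[[length(seg) + 1]] <- orb
  }
  if (!length(seg)) stop("strong-canard integration failed")
  # join: reverse one half so the orbit runs through the node
  a <- seg[[1]][rev(seq_len(nrow(seg[[1]]))), ]
  b <- if (length(seg) > 1) seg[[2]] else NULL
  orb <- rbind(a, b)
  keep <- is.finite(orb$V) & is.finite(orb$h) &
    orb$h > -0.2 & orb$h < 1.2 & abs(orb$V - fn$V) < 60
  orb <- orb[keep, ]
  orb$s <- gamma_manifold(orb$V, orb$h, params, w_tilde, r_tilde)$s
  structure(list(index = 0L, role = "strong",
                 orbit = orb[, c("V", "h", "s")]),
            class = "canard_orbit")
}

# Count the subthreshold rotations of an orbit seeded on the attracting
# sheet at (V_seed, h0): integrate until the voltage crosses the spike
# threshold and count small local maxima.  Divergent or non-spiking orbits
# return NA.  The coordinate that controls the rotation count is the
# super-slow gate s, which is preserved while V and h relax onto the slow
# manifold; the seed's s0 = gamma(V_seed, h0) is therefore the sector
# coordinate.
seed_rotations <- function(h0, V_seed, pv, params, w_tilde, r_tilde,
                           t_max, dt, V_LAO = -20) {
  s0 <- gamma_manifold(V_seed, h0, params, w_tilde, r_tilde)$s
  res <- tryCatch(
    cpp_sim3(pv, w_tilde, r_tilde, c(V_seed, h0, s0), t_max, dt, 10L,
             stop_var = 0L, stop_val = V_LAO, stop_dir = 1L),
    error = function(e) NULL)
  if (is.null(res) || !isTRUE(res$stopped)) return(NA_integer_)
  v <- res$y[, 1]
  if (length(v) < 3) return(0L)
  mid <- 2:(length(v) - 1)
  idx <- mid[v[mid] > v[mid - 1] & v[mid] >= v[mid + 1]]
  if (length(idx)) {
    prom <- peak_prominence(v, idx)
    idx <- idx[prom >= 1e-3 & v[idx] < V_LAO]
  }
  length(idx)
}

#' Reconstruct the slow manifolds near the folded node and extract canard
#' orbits
#'
#' Forward orbits from a line of seeds on the hyperpolarized attracting
#' sheet converge to the attracting slow manifold; backward orbits from a
#' line of seeds on the depolarized attracting sheet converge to the
#' repelling slow manifold. Both families are terminated on a plane
#' `Sigma_FS` perpendicular to the s-axis offset from the folded node on
#' the approach side, giving the manifold traces near the node.
#'
#' Canard orbits are located on the attracting seed line itself: the
#' number of subthreshold rotations an orbit performs before its spike is
#' a staircase in the seed coordinate `h0`, and each unit step of the
#' staircase is a canard (the boundary between rotational sectors). The
#' steps are refined by bisection; this brute-force refinement is robust
#' where the projected curve-intersection method degenerates because the
#' attracting family contracts below resolvable width (the contraction
#' toward the attracting slow manifold is exponential in the travel time).
#'
#' @param params a [neuron_parameters()] object.
#' @param w_tilde,r_tilde frozen scaled gates (a folded node must exist).
#' @param n_seeds seeds per family for the manifold traces.
#' @param seed_offset voltage offset (mV) of the seed lines from the folds.
#' @param h_span half-width of the seed line in `h` around the node.
#' @param sigma_offset plane offset as a fraction of the local `s` range of
#'   the funnel region.
#' @param dt integration step (ms).
#' @param t_max horizon (ms) per seed orbit.
#' @param max_index stop after locating this many canards.
#' @return List with `fn` (the folded node), `s_plane`, `dir` (s-approach
#'   direction), `seed_V` (the voltage of the attracting seed line),
#'   `attracting`/`repelling` (data.frames `V`, `h` of the family traces
#'   on the plane), `canards` (list of `canard_orbit` objects ordered by
#'   index: `index`, `role`, `h_seed`, `orbit`), `staircase` (data.frame
#'   `h0`, `rotations`), and `lost` (fraction of trace seeds not reaching
#'   the plane).
#' @export
reconstruct_slow_manifolds <- function(params, w_tilde, r_tilde,
                                       n_seeds = 60, seed_offset = 10,
                                       h_span = 0.12, sigma_offset = 0.02,
                                       dt = 0.001, t_max = 500,
                                       max_index = 8) {
  fs <- folded_singularities(params, w_tilde, r_tilde)
  nodes <- Filter(function(x) x$class == "folded node" && x$branch == "L-", fs)
  if (!length(nodes)) stop("no folded node on L- at these parameters")
  fn <- nodes[[1]]
  gk <- gate_kinetics(fn$V, params)
  dsdt <- (gk$s_inf - fn$s) / gk$tau_s
  dir <- if (dsdt >= 0) 1L else -1L
  hwin <- pmin(pmax(fn$h + c(-h_span, h_span), 1e-3), 1 - 1e-3)
  # local s-scale of the funnel (narrow h window, clear of the gamma pole)
  Vlo <- max(fn$V - 8, params$EK + 8)
  Vg <- seq(Vlo, fn$V + 5, length.out = 40)
  sg <- range(gamma_manifold(rep(Vg, 2), rep(fn$h + c(-0.02, 0.02), each = 40),
                             params, w_tilde, r_tilde)$s)
  delta <- sigma_offset * diff(sg)
  s_plane <- fn$s - dir * delta
  pv <- as_par_vector(params)
  fc <- fold_curves(params, w_tilde, r_tilde)
  Vlminus <- mean(range(fc$V[fc$branch == "L-"]))
  Vlplus <- if (any(fc$branch == "L+")) mean(range(fc$V[fc$branch == "L+"]))
            else fn$V + 40
  V_seed <- Vlminus - seed_offset
  hseq <- seq(hwin[1], hwin[2], length.out = n_seeds)

  run_family <- function(Vs, backward) {
    if (backward) {
      # seed the depolarized sheet at s values matching the funnel: gamma
      # is linear in h, so solve for the h giving each target s
      g0 <- gamma_manifold(Vs, 0, params, w_tilde, r_tilde)$s
      slope <- gamma_manifold(Vs, 1, params, w_tilde, r_tilde)$s - g0
      starts <- cbind(h = ((seq(fn$s - 0.03, fn$s + 0.03,
                                length.out = length(hseq))) - g0) / slope,
                      s = seq(fn$s - 0.03, fn$s + 0.03,
                              length.out = length(hseq)))
    } else {
      starts <- cbind(h = hseq,
                      s = gamma_manifold(Vs, hseq, params, w_tilde,
                                         r_tilde)$s)
    }
    pts <- vector("list", nrow(starts))
    for (k in seq_len(nrow(starts))) {
      h0 <- starts[k, "h"]
      s0 <- starts[k, "s"]
      # orbits that miss the slow manifold in backward time genuinely
      # diverge; count them as lost seeds
      res <- tryCatch(
        cpp_sim3(pv, w_tilde, r_tilde, c(Vs, h0, s0),
                 if (backward) -t_max else t_max,
                 if (backward) -dt else dt, 50L,
                 stop_var = 2L, stop_val = s_plane, stop_dir = 0L),
        error = function(e) NULL)
      if (!is.null(res) && isTRUE(res$stopped)) {
        y <- res$y_stop
        pre_spike <- max(res$y[, 1]) < -20
        ok <- if (backward) {
          # genuine repelling-manifold tracers reach the plane near the
          # node after a substantial backward excursion; immediate
          # crossings during the initial fall-off are discarded
          abs(res$t_stop) > 2 && abs(y[1] - fn$V) < 15
        } else {
          pre_spike && abs(y[1] - fn$V) < 40
        }
        if (ok && y[2] > -0.2 && y[2] < 1.2)
          pts[[k]] <- data.frame(V = y[1], h = y[2])
      }
    }
    ok <- !vapply(pts, is.null, logical(1))
    list(curve = do.call(rbind, pts[ok]), lost = mean(!ok))
  }
  att <- run_family(V_seed, backward = FALSE)
  rep_ <- run_family(Vlplus + seed_offset, backward = TRUE)

  # rotation staircase along the attracting seed line
  rots <- function(h0) seed_rotations(h0, V_seed, pv, params, w_tilde,
                                      r_tilde, t_max, dt)
  grid <- hseq
  cnt <- vapply(grid, rots, integer(1))
  # refine every multi-step jump until all steps are unit steps (or the
  # resolution limit is hit)
  for (pass in 1:24) {
    jumps <- which(!is.na(cnt[-length(cnt)]) & !is.na(cnt[-1]) &
                     cnt[-1] - cnt[-length(cnt)] > 1 &
                     cnt[-length(cnt)] < max_index &
                     diff(grid) > 1e-11)
    if (!length(jumps)) break
    newh <- (grid[jumps] + grid[jumps + 1]) / 2
    newc <- vapply(newh, rots, integer(1))
    o <- order(c(grid, newh))
    grid <- c(grid, newh)[o]
    cnt <- c(cnt, newc)[o]
  }
  canards <- list()
  steps <- which(!is.na(cnt[-length(cnt)]) & !is.na(cnt[-1]) &
                   cnt[-1] - cnt[-length(cnt)] == 1 &
                   cnt[-length(cnt)] <= max_index)
  for (i in steps) {
    lo <- grid[i]; hi <- grid[i + 1]
    nlo <- cnt[i]
    for (k in 1:40) {
      mid <- (lo + hi) / 2
      cm <- rots(mid)
      if (is.na(cm) || cm <= nlo) lo <- mid else hi <- mid
    }
    hs <- (lo + hi) / 2
    s0 <- gamma_manifold(V_seed, hs, params, w_tilde, r_tilde)$s
    orb <- tryCatch(
      cpp_sim3(pv, w_tilde, r_tilde, c(V_seed, hs, s0), t_max, dt, 10L,
               stop_var = 0L, stop_val = -20, stop_dir = 1L),
      error = function(e) NULL)
    orbit <- if (!is.null(orb))
      data.frame(V = orb$y[, 1], h = orb$y[, 2], s = orb$y[, 3])
    else NULL
    canards[[length(canards) + 1]] <-
      structure(list(index = nlo, role = if (nlo == 0) "strong" else
                       "secondary", h_seed = hs, s_seed = s0,
                     orbit = orbit),
                class = "canard_orbit")
  }
  canards <- canards[order(vapply(canards, function(x) x$index, integer(1)))]
  list(fn = fn, s_plane = s_plane, dir = dir, seed_V = V_seed,
       attracting = att$curve, repelling = rep_$curve,
       canards = canards,
       staircase = data.frame(h0 = grid, rotations = cnt),
       lost = c(attracting = att$lost, repelling = rep_$lost))
}

#' Rotational-sector assignment of post-spike return points
#'
#' Each rotational sector of the folded-node funnel is bounded by two
#' canards; an orbit returning into the sector between the canards of
#' indices `i-1` and `i` performs `i` SAOs before the next spike. The
#' canard partition lives on the attracting seed line (the section
#' `V = seed_V` crossed by the slow flow); each post-spike pass of the
#' simulated trajectory through that section is assigned the sector it
#' enters, and the prediction is compared against the SAO count measured
#' from the events of the same trajectory.
#'
#' @param recon result of [reconstruct_slow_manifolds()].
#' @param traj a 3D `neuron_trajectory` at the same parameters.
#' @param t_min discard the transient before this time (ms).
#' @return data.frame with one row per post-spike funnel approach:
#'   `t_return`, `h_return` (position on the section), `predicted` (sector
#'   index; 0 means a regular jump outside the strong canard) and
#'   `observed` SAO count before the next LAO.
#' @export
rotational_sectors <- function(recon, traj, t_min = 350) {
  ev <- detect_events(traj, t_min = t_min, prominence = 1e-3)
  laos <- ev$t_peak[ev$kind == "LAO"]
  if (length(laos) < 2)
    return(data.frame(t_return = numeric(0), h_return = numeric(0),
                      predicted = integer(0), observed = integer(0)))
  sel <- traj$t >= t_min
  tt <- traj$t[sel]
  V <- traj$state[sel, "V"]
  h <- traj$state[sel, "h"]
  s <- traj$state[sel, "s"]
  dVdt <- c(diff(V) / diff(tt), 0)
  cs <- vapply(recon$canards, function(x) x$s_seed, numeric(1))
  keep <- is.finite(cs)
  cs <- cs[keep]
  cidx <- vapply(recon$canards[keep], function(x) x$index, integer(1))
  # slow upward crossings of the section V = seed_V (spike upstrokes run
  # at hundreds of mV/ms and are excluded)
  up <- which(V[-length(V)] < recon$seed_V & V[-1] >= recon$seed_V &
                abs(dVdt[-length(V)]) < 20)
  rows <- lapply(seq_along(laos), function(k) {
    t_lo <- laos[k]
    t_hi <- if (k < length(laos)) laos[k + 1] else Inf
    cand <- up[tt[up] > t_lo & tt[up] < t_hi]
    if (!length(cand)) return(NULL)
    i <- cand[1]
    fr <- (recon$seed_V - V[i]) / (V[i + 1] - V[i])
    hr <- h[i] + fr * (h[i + 1] - h[i])
    sr <- s[i] + fr * (s[i + 1] - s[i])
    below <- which(cs <= sr)
    predicted <- if (!length(below)) 0L else max(cidx[below]) + 1L
    observed <- if (is.finite(t_hi))
      sum(ev$kind == "SAO" & ev$t_peak > tt[i] & ev$t_peak < t_hi)
    else NA_integer_
    data.frame(t_return = tt[i], s_return = sr, h_return = hr,
               predicted = as.integer(predicted),
               observed = as.integer(observed))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(t_return = numeric(0),
                                      s_return = numeric(0),
                                      h_return = numeric(0),
                                      predicted = integer(0),
                                      observed = integer(0))
  out[!is.na(out$observed), , drop = FALSE]
}
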