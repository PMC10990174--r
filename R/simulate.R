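# Integration and oscillation analysis.
#
# The reference scheme is fixed-step 4th-order Runge-Kutta with
# dt = 0.001 ms, run in compiled code; stored output is thinned (default
# every 10th step, i.e. a 0.01 ms grid) which is ample for peak detection
# since subthreshold oscillations have periods of milliseconds.

#' Default initial condition near rest
#'
#' `V = -70` mV with every gate at its steady state for that potential,
#' i.e. a state close to the resting branch of the critical manifold.
#'
#' @param params a [neuron_parameters()] object.
#' @param model `"5D"` or `"3D"`.
#' @return Numeric state vector.
#' @export
default_ic <- function(params, model = "5D") {
  V0 <- -70
  gk <- gate_kinetics(V0, params)
  if (model == "5D") c(V = V0, h = gk$h_inf, s = gk$s_inf,
                       r = gk$r_inf, w = gk$w_inf)
  else c(V = V0, h = gk$h_inf, s = gk$s_inf)
}

#' Integrate the 5D model or the 3D slow-fast subsystem
#'
#' Fixed-step RK4 at `dt` (default 0.001 ms). For `model = "3D"` the frozen
#' scaled gates `w_tilde` and `r_tilde` must be supplied.
#'
#' @param model `"5D"` or `"3D"`.
#' @param params a [neuron_parameters()] object.
#' @param t_end simulation horizon (ms).
#' @param dt integration step (ms).
#' @param ic initial state; defaults to [default_ic()].
#' @param thin store every `thin`-th step (the initial state is always
#'   stored).
#' @param w_tilde,r_tilde frozen scaled gates for the 3D subsystem.
#' @return A `neuron_trajectory`: list with `t` (ms), `state` (matrix, one
#'   column per variable), `params`, `model`, `dt`, and for 3D runs
#'   `w_tilde`, `r_tilde`.
#' @examples
#' p <- condition_params("Ctrl", IApp = 300)
#' tr <- integrate_model("5D", p, t_end = 50)
#' range(tr$state[, "V"])
#' @export
integrate_model <- function(model = c("5D", "3D"), params, t_end = 450,
                            dt = 0.001, ic = NULL, thin = 10,
                            w_tilde = NULL, r_tilde = NULL) {
  model <- match.arg(model)
  stopifnot(dt > 0, t_end > 0)
  if (is.null(ic)) ic <- default_ic(params, model)
  gates <- ic[-1]
  if (any(gates < 0 | gates > 1)) stop("initial gate values must lie in [0, 1]")
  pv <- as_par_vector(params)
  if (model == "5D") {
    res <- cpp_sim5(pv, as.numeric(ic), t_end, dt, as.integer(thin))
    cols <- c("V", "h", "s", "r", "w")
  } else {
    if (is.null(w_tilde) || is.null(r_tilde))
      stop("3D integration requires w_tilde and r_tilde")
    # the frozen gates are continuation parameters: slightly negative
    # values arise legitimately when following a constraint line past the
    # r_tilde = 0 axis
    res <- cpp_sim3(pv, w_tilde, r_tilde, as.numeric(ic), t_end, dt,
                    as.integer(thin))
    cols <- c("V", "h", "s")
  }
  y <- res$y
  colnames(y) <- cols
  structure(list(t = res$t, state = y, params = params, model = model,
                 dt = dt, w_tilde = w_tilde, r_tilde = r_tilde),
            class = "neuron_trajectory")
}

#' @export
print.neuron_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d samples over [0, %.6g] ms (dt = %g ms)\n",
              x$model, length(x$t), max(x$t), x$dt))
  invisible(x)
}

# Topographic prominence of local maxima: height above the higher of the two
# minima separating the peak from the nearest higher terrain on each side.
peak_prominence <- function(v, idx) {
  n <- length(v)
  vapply(idx, function(i) {
    hgt <- v[i]
    left <- if (i > 1) {
      higher <- which(v[seq_len(i - 1)] > hgt)
      lo <- if (length(higher)) max(higher) + 1 else 1
      min(v[lo:(i - 1)])
    } else hgt
    right <- if (i < n) {
      higher <- which(v[(i + 1):n] > hgt)
      hi <- if (length(higher)) i + min(higher) - 1 else n
      min(v[(i + 1):hi])
    } else hgt
    hgt - max(left, right)
  }, numeric(1))
}

#' Detect and classify voltage oscillation events
#'
#' Local maxima of `V(t)` with topographic prominence at least `prominence`
#' are classified as large-amplitude oscillations (LAO, full action
#' potentials) when the peak reaches `V_LAO`, and as small-amplitude
#' (subthreshold) oscillations (SAO) otherwise. The default threshold of
#' -20 mV sits between action-potential overshoot (above 0 mV) and
#' subthreshold oscillations (below -40 mV).
#'
#' @param traj a `neuron_trajectory`.
#' @param V_LAO peak-voltage threshold (mV) separating LAO from SAO.
#' @param prominence minimal peak prominence (mV).
#' @param t_min discard events before this time (ms).
#' @return A data.frame with columns `t_peak` (ms), `V_peak` (mV), `kind`
#'   (`"LAO"` or `"SAO"`).
#' @export
detect_events <- function(traj, V_LAO = -20, prominence = 1, t_min = 0) {
  v <- traj$state[, "V"]
  if (length(v) < 3) stop("trajectory too short for event detection")
  mid <- 2:(length(v) - 1)
  idx <- mid[v[mid] > v[mid - 1] & v[mid] >= v[mid + 1]]
  if (length(idx)) {
    prom <- peak_prominence(v, idx)
    idx <- idx[prom >= prominence]
  }
  # quadratic refinement of peak time and height (the stored grid is
  # thinned, so the raw sample under-resolves sharp spike tops)
  a <- v[pmax(idx - 1, 1)]; b <- v[idx]; c <- v[pmin(idx + 1, length(v))]
  den <- a - 2 * b + c
  off <- ifelse(abs(den) > 0, 0.5 * (a - c) / den, 0)
  off[!is.finite(off) | abs(off) > 1] <- 0
  dt_grid <- if (length(traj$t) > 1) traj$t[2] - traj$t[1] else 0
  t_pk <- traj$t[idx] + off * dt_grid
  V_pk <- b - 0.25 * (a - c) * off
  ev <- data.frame(t_peak = t_pk, V_peak = V_pk,
                   kind = ifelse(V_pk >= V_LAO, "LAO", "SAO"),
                   stringsAsFactors = FALSE)
  ev[ev$t_peak >= t_min, , drop = FALSE]
}

# Group an ordered LAO/SAO event sequence into blocks of (L consecutive
# LAOs, following SAO count).  A leading SAO run (the tail of a previous
# block) is dropped.
event_blocks <- function(kinds) {
  if (!length(kinds)) return(data.frame(L = integer(0), s = integer(0)))
  r <- rle(kinds)
  if (r$values[1] == "SAO") {
    r$values <- r$values[-1]; r$lengths <- r$lengths[-1]
  }
  L <- integer(0); s <- integer(0)
  i <- 1
  while (i <= length(r$values)) {
    if (r$values[i] != "LAO") break
    nl <- r$lengths[i]
    ns <- if (i + 1 <= length(r$values) && r$values[i + 1] == "SAO")
      r$lengths[i + 1] else 0L
    L <- c(L, nl); s <- c(s, ns)
    i <- i + 2
  }
  data.frame(L = L, s = s)
}

# Smallest repeating unit of the block sequence, matched cyclically; the
# returned unit starts at the rotation with lexicographically greatest
# digit string so that equivalent attractors print identically.
minimal_repeat <- function(blocks) {
  n <- nrow(blocks)
  if (n == 0) return(blocks)
  key <- paste(blocks$L, blocks$s, sep = ",")
  for (p in seq_len(n)) {
    if (all(key == key[((seq_len(n) - 1) %% p) + 1])) {
      unit <- blocks[seq_len(p), , drop = FALSE]
      str <- paste0(unit$L, unit$s)
      rots <- vapply(seq_len(p), function(k) {
        paste(str[((seq_len(p) + k - 2) %% p) + 1], collapse = "")
      }, character(1))
      best <- which.max(rots)
      return(unit[((seq_len(p) + best - 2) %% p) + 1, , drop = FALSE])
    }
  }
  blocks
}

#' Mixed-mode oscillation signature
#'
#' Groups a post-transient event sequence into blocks of `L` consecutive
#' LAOs followed by `s` SAOs, reduces them to the minimal repeating unit
#' over the attractor period, and concatenates the digits: blocks (1,4),(1,3)
#' print as `"1413"`.
#'
#' @param events data.frame from [detect_events()], taken from a
#'   post-transient, periodic segment.
#' @return An object of class `mmo_signature`: list with `blocks`
#'   (data.frame `L`, `s`), `string`, and `silent` (TRUE when no LAO
#'   occurred).
#' @export
mmo_signature <- function(events) {
  if (!nrow(events) || !any(events$kind == "LAO")) {
    return(structure(list(blocks = data.frame(L = integer(0), s = integer(0)),
                          string = "", silent = TRUE),
                     class = "mmo_signature"))
  }
  blocks <- event_blocks(events$kind)
  # with enough blocks, drop the possibly truncated first and last before
  # extracting the repeating unit
  core <- if (nrow(blocks) >= 5) blocks[2:(nrow(blocks) - 1), ] else blocks
  unit <- minimal_repeat(core)
  structure(list(blocks = unit,
                 string = paste0(unit$L, unit$s, collapse = ""),
                 silent = FALSE),
            class = "mmo_signature")
}

#' @export
print.mmo_signature <- function(x, ...) {
  if (x$silent) cat("silent (no LAO)\n")
  else cat("MMO signature:", x$string, "\n")
  invisible(x)
}

#' Firing frequency of a trajectory
#'
#' Number of large-amplitude oscillations (action potentials) after `t0`
#' divided by the analysed duration, in Hz. SAOs are subthreshold and do not
#' count as spikes.
#'
#' @param traj a `neuron_trajectory`.
#' @param t0 start of the analysis window (ms); the default discards the
#'   350 ms transient.
#' @param ... passed to [detect_events()].
#' @return Firing frequency (Hz); 0 for a silent trajectory.
#' @export
firing_frequency <- function(traj, t0 = 350, ...) {
  t_end <- max(traj$t)
  if (t_end <= t0) stop("trajectory shorter than the analysis start t0")
  ev <- detect_events(traj, t_min = t0, ...)
  sum(ev$kind == "LAO") / (t_end - t0) * 1000
}

#' Classify the steady-state regime at a given applied current
#'
#' Simulates past the transient and inspects the post-transient events:
#' `silent` (no LAO), `MMO` (both LAOs and SAOs), or `spiking` (LAOs only).
#'
#' @param params a [neuron_parameters()] object (its `IApp` is overridden).
#' @param I_App applied current density (uA/cm^2).
#' @param horizon simulation horizon (ms); the last `analyse` ms are
#'   inspected.
#' @param analyse length of the analysis window (ms).
#' @param dt integration step (ms).
#' @param model `"5D"` or `"3D"`.
#' @param w_tilde,r_tilde frozen gates for 3D classification.
#' @param prominence minimal peak prominence (mV) for event detection.
#'   Regime classification must resolve the genuinely small subthreshold
#'   oscillations near the edges of the MMO band (amplitudes well below
#'   1 mV), so the default here is 0.05 mV -- still orders of magnitude
#'   above integrator error.
#' @return One of `"silent"`, `"MMO"`, `"spiking"`, with attribute
#'   `low_confidence = TRUE` when the first and second half of the analysis
#'   window disagree (unresolved attractor).
#' @export
classify_regime <- function(params, I_App = params$IApp, horizon = 1000,
                            analyse = 500, dt = 0.001, model = "5D",
                            w_tilde = NULL, r_tilde = NULL,
                            prominence = 0.05) {
  params$IApp <- I_App
  tr <- integrate_model(model, params, t_end = horizon, dt = dt,
                        w_tilde = w_tilde, r_tilde = r_tilde)
  ev <- detect_events(tr, t_min = horizon - analyse,
                      prominence = prominence)
  lab <- regime_label(ev)
  half <- horizon - analyse / 2
  lab1 <- regime_label(ev[ev$t_peak < half, , drop = FALSE])
  lab2 <- regime_label(ev[ev$t_peak >= half, , drop = FALSE])
  if (lab1 != lab2) attr(lab, "low_confidence") <- TRUE
  lab
}

regime_label <- function(ev) {
  has_lao <- any(ev$kind == "LAO")
  has_sao <- any(ev$kind == "SAO")
  if (!has_lao) "silent" else if (has_sao) "MMO" else "spiking"
}

#' Scan applied current for regime intervals
#'
#' Coarse scan over `I_range` followed by bisection of every boundary where
#' the regime label changes, refined to within `resolution`.
#'
#' @param params a [neuron_parameters()] object.
#' @param I_range interval of applied current (uA/cm^2) to scan.
#' @param coarse coarse grid step (uA/cm^2).
#' @param resolution bisection half-width (uA/cm^2) for each boundary.
#' @param ... passed to [classify_regime()].
#' @return A data.frame with one row per homogeneous interval: `from`, `to`
#'   (uA/cm^2) and `regime`. Boundaries are the refined bisection midpoints.
#' @examples
#' \donttest{
#' regime_interval_scan(condition_params("Ctrl"), I_range = c(40, 260),
#'                      coarse = 20)
#' }
#' @export
regime_interval_scan <- function(params, I_range = c(0, 400), coarse = 10,
                                 resolution = 1, ...) {
  grid <- seq(I_range[1], I_range[2], by = coarse)
  labs <- vapply(grid, function(I) as.character(classify_regime(params, I, ...)),
                 character(1))
  bounds <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (labs[i] != labs[i + 1]) {
      lo <- grid[i]; hi <- grid[i + 1]
      lab_lo <- labs[i]
      while (hi - lo > 2 * resolution) {
        mid <- (lo + hi) / 2
        lm <- as.character(classify_regime(params, mid, ...))
        if (lm == lab_lo) lo <- mid else hi <- mid
      }
      bounds <- c(bounds, (lo + hi) / 2)
    }
  }
  edges <- c(I_range[1], bounds, I_range[2])
  keep <- c(TRUE, labs[-length(labs)] != labs[-1])
  data.frame(from = edges[-length(edges)], to = edges[-1],
             regime = labs[keep])
}

#' MMO interval of applied current for a parameter set
#'
#' Convenience wrapper around [regime_interval_scan()] returning the
#' endpoints of the (first) MMO interval.
#'
#' @inheritParams regime_interval_scan
#' @return Numeric `c(lower, upper)` (uA/cm^2), or `c(NA, NA)` when no MMO
#'   interval is found in `I_range`.
#' @export
mmo_interval <- function(params, I_range = c(0, 400), coarse = 10,
                         resolution = 1, ...) {
  scan <- regime_interval_scan(params, I_range, coarse, resolution, ...)
  i <- which(scan$regime == "MMO")
  if (!length(i)) return(c(NA_real_, NA_real_))
  c(scan$from[i[1]], scan$to[i[length(i)]])
}

#' Upper applied-current limit of sustained firing
#'
#' As the applied current is raised above the regular-firing range, the
#' action-potential amplitude declines continuously until the oscillation
#' dies in a depolarization block (the equilibrium restabilizes). This
#' bisects the boundary where sustained post-transient oscillations of any
#' amplitude cease, which is the natural upper limit of firing: a fixed
#' peak-voltage threshold would cut the shrinking spikes off earlier.
#'
#' @param params a [neuron_parameters()] object.
#' @param I_range interval (uA/cm^2) bracketing the boundary: oscillating
#'   at the lower end, dead at the upper end.
#' @param resolution bisection half-width (uA/cm^2).
#' @param horizon,analyse,dt as in [classify_regime()].
#' @return Boundary current (uA/cm^2).
#' @export
firing_upper_limit <- function(params, I_range = c(600, 900),
                               resolution = 1, horizon = 1000,
                               analyse = 500, dt = 0.001) {
  oscillating <- function(I) {
    params$IApp <- I
    tr <- integrate_model("5D", params, t_end = horizon, dt = dt)
    ev <- detect_events(tr, t_min = horizon - analyse, prominence = 0.05)
    nrow(ev) > 0
  }
  lo <- I_range[1]; hi <- I_range[2]
  if (!oscillating(lo) || oscillating(hi))
    stop("I_range does not bracket the oscillation-death boundary")
  while (hi - lo > 2 * resolution) {
    mid <- (lo + hi) / 2
    if (oscillating(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Firing-frequency curve over an applied-current grid
#'
#' @param condition a condition name from [condition_names()] or a
#'   [neuron_parameters()] object.
#' @param I_grid applied-current values (uA/cm^2).
#' @param horizon simulation horizon (ms); firing frequency is measured
#'   after the 350 ms transient.
#' @param dt integration step (ms).
#' @param file optional CSV path (columns `I_app, ff_hz, regime`).
#' @return A data.frame `I_app`, `ff_hz`, `regime`.
#' @export
ff_curve <- function(condition, I_grid, horizon = 1350, dt = 0.001,
                     file = NULL) {
  params <- if (is.character(condition)) condition_params(condition)
            else condition
  rows <- lapply(I_grid, function(I) {
    params$IApp <- I
    tr <- integrate_model("5D", params, t_end = horizon, dt = dt)
    ev <- detect_events(tr, t_min = 350, prominence = 0.05)
    ff <- sum(ev$kind == "LAO") / (horizon - 350) * 1000
    data.frame(I_app = I, ff_hz = ff, regime = regime_label(ev))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Crossing point of two firing-frequency curves
#'
#' Linear interpolation of the zero of the FF difference between two
#' conditions on a shared applied-current grid, restricted to currents where
#' both cells are active.
#'
#' @param ff_a,ff_b data.frames from [ff_curve()] on the same `I_app` grid.
#' @return The applied current (uA/cm^2) of the first sign change, or `NA`.
#' @export
ff_crossing <- function(ff_a, ff_b) {
  stopifnot(identical(ff_a$I_app, ff_b$I_app))
  d <- ff_a$ff_hz - ff_b$ff_hz
  act <- ff_a$ff_hz > 0 & ff_b$ff_hz > 0
  n <- length(d)
  i <- which(act[-n] & act[-1] &
               ((d[-n] < 0 & d[-1] >= 0) | (d[-n] <= 0 & d[-1] > 0) |
                  (d[-n] > 0 & d[-1] <= 0) | (d[-n] >= 0 & d[-1] < 0)))
  if (!length(i)) return(NA_real_)
  i <- i[1]
  x0 <- ff_a$I_app[i]; x1 <- ff_a$I_app[i + 1]
  x0 + (x1 - x0) * d[i] / (d[i] - d[i + 1])
}

#' Export a trajectory as CSV
#'
#' Columns `t_ms, V_mV, h, s, r, w` (5D) or `t_ms, V_mV, h, s, w_tilde,
#' r_tilde` (3D, frozen values repeated).
#'
#' @param traj a `neuron_trajectory`.
#' @param file CSV path.
#' @export
write_trajectory <- function(traj, file) {
  df <- data.frame(t_ms = traj$t)
  df$V_mV <- traj$state[, "V"]
  for (nm in setdiff(colnames(traj$state), "V")) df[[nm]] <- traj$state[, nm]
  if (traj$model == "3D") {
    df$w_tilde <- traj$w_tilde
    df$r_tilde <- traj$r_tilde
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
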