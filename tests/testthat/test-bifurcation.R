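ctrl300_line <- function() fixture("ctrl300_line", {
  constraint_line_for(condition_params("Ctrl", IApp = 300))
})

test_that("equilibria satisfy the balance equation with correct stability", {
  p <- condition_params("Ctrl", IApp = 300)
  line <- ctrl300_line()
  # high M activation: stable rest state
  eq_hi <- find_equilibrium_3d(p, 0.5, line$m * 0.5 + line$q)
  expect_lt(max(abs(rhs_3d(0, eq_hi$state, p, 0.5, line$m * 0.5 + line$q))),
            1e-9)
  expect_true(eq_hi$stable)
  expect_true(all(Re(eq_hi$eigenvalues) < 0))
  # low M activation: unstable (oscillatory) equilibrium
  eq_lo <- find_equilibrium_3d(p, 0.1, line$m * 0.1 + line$q)
  expect_gt(max(Re(eq_lo$eigenvalues)), 0)
  expect_error(find_equilibrium_3d(p, 0.5, 0.2, V_bracket = c(10, 20)),
               "widen")
})

test_that("the equilibrium is unique over the scanned gate window", {
  p <- condition_params("CGS", IApp = 250)
  for (wt in c(0.1, 0.2, 0.35)) {
    for (rt in c(0.05, 0.09)) {
      eqs <- find_equilibrium_3d(p, wt, rt, all = TRUE)
      expect_length(eqs, 1)
    }
  }
})

test_that("the Hopf point has a marginal complex pair and moves with IApp", {
  p <- condition_params("Ctrl", IApp = 300)
  line <- ctrl300_line()
  hbs <- fixture("hb300", hopf_on_line(p, line))
  expect_length(hbs, 1)
  hb <- hbs[[1]]
  ev <- hb$eigenvalues
  cplx <- ev[Im(ev) != 0]
  expect_length(cplx, 2)
  expect_lt(max(abs(Re(cplx))), 1e-4)
  expect_gt(abs(hb$omega), 0)
  # at lower applied current the bifurcation occurs at lower w_tilde
  p250 <- condition_params("Ctrl", IApp = 250)
  line250 <- constraint_line_for(p250)
  hb250 <- hopf_on_line(p250, line250)
  expect_length(hb250, 1)
  expect_lt(hb250[[1]]$w_tilde, hb$w_tilde)
})

test_that("eigenvalue Hopf location matches a simulation-based onset", {
  p <- condition_params("Ctrl", IApp = 300)
  line <- ctrl300_line()
  hb <- fixture("hb300", hopf_on_line(p, line))[[1]]
  # bisect the onset of sustained oscillation around an equilibrium kicked
  # by 0.1 mV: growth ratio of oscillation amplitude over two late windows
  grows <- function(wt) {
    rt <- line$m * wt + line$q
    eq <- find_equilibrium_3d(p, wt, rt)
    ic <- eq$state + c(0.1, 0, 0)
    tr <- integrate_model("3D", p, t_end = 2000, ic = ic,
                          w_tilde = wt, r_tilde = rt)
    amp <- function(t0, t1) {
      v <- tr$state[tr$t >= t0 & tr$t < t1, "V"]
      diff(range(v))
    }
    amp(1500, 2000) > amp(1000, 1500)
  }
  lo <- hb$w_tilde - 0.01
  hi <- hb$w_tilde + 0.01
  expect_true(grows(lo))
  expect_false(grows(hi))
  while (hi - lo > 4e-4) {
    mid <- (lo + hi) / 2
    if (grows(mid)) lo <- mid else hi <- mid
  }
  expect_lt(abs((lo + hi) / 2 - hb$w_tilde), 1e-3)
})

test_that("the 2-parameter Hopf curve bounds the silent region", {
  p <- condition_params("Ctrl", IApp = 300)
  hc <- hopf_curve_2p(p, r_grid = c(0.06, 0.08, 0.1))
  expect_equal(nrow(hc), 3)
  for (i in seq_len(nrow(hc))) {
    eq <- find_equilibrium_3d(p, hc$w_tilde[i], hc$r_tilde[i])
    expect_lt(abs(pair_re <- max(Re(eq$eigenvalues[Im(eq$eigenvalues) != 0]))),
              1e-4)
    # stable (silent) on the high-w_tilde side
    eq_hi <- find_equilibrium_3d(p, hc$w_tilde[i] + 0.05, hc$r_tilde[i])
    expect_true(eq_hi$stable)
  }
})

test_that("the attractor scan resolves LAO cycling, MMOs and rest", {
  p <- condition_params("Ctrl", IApp = 300)
  line <- ctrl300_line()
  scan <- fixture("scan300", {
    attractor_scan_on_line(p, line, w_range = c(0.1, 0.3), n = 9,
                           horizon = 1000, analyse = 400)
  })
  cls <- scan$grid$class
  expect_equal(cls[1], "LAO-cycle")
  expect_true("MMO" %in% cls)
  expect_false(is.na(scan$onset))
  # the MMO band sits between the onset and the Hopf point
  hb <- fixture("hb300", hopf_on_line(p, line))[[1]]
  mmo_w <- scan$grid$w_tilde[cls == "MMO"]
  expect_true(all(mmo_w >= scan$onset - 0.026))
  expect_true(all(mmo_w <= hb$w_tilde + 0.026))
  # beyond the Hopf the attractor is the equilibrium
  expect_equal(classify_attractor_3d(p, hb$w_tilde + 0.05,
                                     line$m * (hb$w_tilde + 0.05) + line$q,
                                     horizon = 1000, analyse = 400),
               "equilibrium")
})

test_that("Floquet multipliers of the relaxation cycle are consistent", {
  p <- condition_params("Ctrl", IApp = 300)
  line <- ctrl300_line()
  wt <- 0.15
  fl <- pd1_floquet(p, wt, line$m * wt + line$q)
  m <- fl$multipliers
  # the trivial (phase) multiplier
  expect_lt(min(abs(m - 1)), 1e-3)
  # stable cycle: nontrivial multipliers inside the unit circle
  nontriv <- m[-which.min(abs(m - 1))]
  expect_true(all(Mod(nontriv) < 1))
  expect_false(fl$pd)
  expect_gt(fl$period, 1)
})

test_that("a period-doubling precedes the MMO onset on the control line", {
  p <- condition_params("Ctrl", IApp = 300)
  line <- ctrl300_line()
  onset <- fixture("scan300", {
    attractor_scan_on_line(p, line, w_range = c(0.1, 0.3), n = 9,
                           horizon = 1000, analyse = 400)
  })$onset
  # the MMO attractor appears only just beyond the first doubling, so the
  # alternation bracket runs up to the onset itself
  pd <- pd1_on_line(p, line, w_range = c(0.15, onset), tol = 2e-5)
  expect_false(is.null(pd))
  expect_lte(pd$w_tilde, onset + 1e-4)
  expect_lt(onset - pd$w_tilde, 5e-3)
  # left of the doubling the cycle is stable with a real multiplier
  # heading towards -1
  expect_false(is.null(pd$multipliers))
  re_m <- Re(pd$multipliers[Im(pd$multipliers) == 0])
  expect_lt(min(re_m), -0.3)
  expect_gt(min(re_m), -1.05)
  # spike peaks alternate beyond PD1 (period-two), not before
  alt <- function(wt) {
    tr <- integrate_model("3D", p, t_end = 1500, thin = 2, w_tilde = wt,
                          r_tilde = line$m * wt + line$q)
    ev <- detect_events(tr, t_min = 1000)
    stats::median(abs(diff(ev$V_peak[ev$kind == "LAO"])))
  }
  expect_gt(alt(pd$w_tilde + 5e-5), 0.1)
  expect_lt(alt(pd$w_tilde - 2e-3), 0.05)
})

test_that("the dgM regime map tracks stimulated versus control intervals", {
  map <- fixture("idgm_map", {
    regime_map_2p(neuron_parameters(), "idgm", grid1 = c(5, 15),
                  grid2 = c(100, 450), coarse = 25)
  })
  expect_identical(names(map), c("dgM", "lower_ctrl", "upper_ctrl",
                                 "lower_stim", "upper_stim"))
  # a small increment keeps the stimulated band inside the control band on
  # the right; a large one pushes it beyond
  expect_lt(map$upper_stim[map$dgM == 5], map$upper_ctrl[1])
  expect_gt(map$upper_stim[map$dgM == 15], map$upper_ctrl[1])
  expect_gt(map$upper_stim[2], map$upper_stim[1])
})
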