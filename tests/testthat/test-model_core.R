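test_that("temperature factor follows the Q10 law and rejects bad input", {
  expect_equal(temperature_factor(3, 35, 35), 1)
  expect_equal(temperature_factor(3, 37, 20), 3^1.7)
  expect_equal(temperature_factor(3, 37, 20), 6.473008, tolerance = 1e-6)
  expect_equal(temperature_factor(3, 37, 35), 3^0.2)
  expect_equal(temperature_factor(3, 37, 35), 1.245731, tolerance = 1e-6)
  expect_error(temperature_factor(0, 37, 20), "positive")
  expect_error(temperature_factor(-1, 37, 20), "positive")
})

test_that("default parameters and condition presets match the study values", {
  p <- neuron_parameters()
  expect_equal(p$gNaF, 1000)
  expect_equal(p$gKS, 40)
  expect_equal(p$gL, 11.3)
  expect_equal(p$Cm, 0.9)
  expect_equal(p$EK, -84)
  expect_equal(p$EL, -83.38)
  expect_equal(p$EHCN, -50)
  expect_equal(p$Qh, 2.9)

  zd <- condition_params("ZD")
  expect_identical(c(zd$gHCN, zd$dgHCN, zd$gM, zd$dgM, zd$cAMP),
                   c(0, 0, 50, 50, 0))
  fl <- condition_params("FSK+Lin")
  expect_identical(c(fl$gM, fl$dgM, fl$gHCN, fl$dgHCN, fl$cAMP),
                   c(50, 20, 23, 12, 1))
  ctrl <- condition_params("Ctrl")
  base <- neuron_parameters()
  expect_identical(unclass(ctrl), unclass(base))
  expect_error(condition_params("nope"), "valid names")
  expect_error(neuron_parameters(gM = -1), "conductance")
  expect_error(neuron_parameters(cAMP = 0.5), "cAMP")
})

test_that("gating kinetics satisfy the alpha/beta identities on a V grid", {
  p <- neuron_parameters()
  V <- seq(-120, 60, by = 0.5)
  gk <- gate_kinetics(V, p)
  for (g in c("m", "n", "h", "s", "r")) {
    a <- gk[[paste0("alpha_", g)]]
    b <- gk[[paste0("beta_", g)]]
    pinf <- gk[[paste0(g, "_inf")]]
    tau <- gk[[paste0("tau_", g)]]
    phi <- gk[[paste0("phi_", g)]]
    expect_true(all(pinf > 0 & pinf < 1), info = g)
    expect_true(all(tau > 0), info = g)
    expect_equal(pinf, a / (a + b), tolerance = 1e-12, info = g)
    expect_equal(tau, 1 / (phi * (a + b)), tolerance = 1e-12, info = g)
  }
  expect_true(all(gk$w_inf > 0 & gk$w_inf < 1))
  expect_true(all(gk$tau_w > 0))
})

test_that("HCN shift, M-gate values and symmetry points are as printed", {
  expect_equal(hcn_nu(0), 103.5)
  expect_equal(hcn_nu(1), 95)
  p0 <- neuron_parameters()
  gk <- gate_kinetics(-35, p0)
  expect_equal(gk$w_inf, 0.5)
  expect_equal(gk$tau_w, 400 / 4.3, tolerance = 1e-12)
  expect_equal(gk$tau_w, 93.023, tolerance = 1e-4)
  # r_inf = 1/2 where the shifted exponentials balance, for both cAMP states
  gk0 <- gate_kinetics(-hcn_nu(0), p0)
  expect_equal(gk0$r_inf, 0.5, tolerance = 1e-12)
  p1 <- neuron_parameters(cAMP = 1)
  gk1 <- gate_kinetics(-hcn_nu(1), p1)
  expect_equal(gk1$r_inf, 0.5, tolerance = 1e-12)
})

test_that("rate expressions are continuous across removable singularities", {
  p <- neuron_parameters()
  sing <- c(-25.4, -29.7, -48.4, -42.7, -118, -19.5, -87.1)
  for (V0 in sing) {
    g0 <- gate_kinetics(V0, p)
    gl <- gate_kinetics(V0 - 1e-8, p)
    gr <- gate_kinetics(V0 + 1e-8, p)
    for (nm in c("m_inf", "n_inf", "h_inf", "s_inf")) {
      expect_true(is.finite(g0[[nm]]), info = paste(nm, V0))
      expect_lt(abs(g0[[nm]] - gl[[nm]]), 1e-6)
      expect_lt(abs(g0[[nm]] - gr[[nm]]), 1e-6)
    }
  }
})

test_that("R kinetics agree with the compiled kinetics", {
  for (camp in c(0, 1)) {
    p <- neuron_parameters(cAMP = camp)
    pv <- camposc:::as_par_vector(p)
    for (V in c(-95.3, -70, -35, -25.4, 0.7, 41)) {
      gkR <- gate_kinetics(V, p)
      gkC <- camposc:::cpp_gate_kinetics(V, pv)
      for (nm in names(gkC)) {
        expect_equal(gkR[[nm]], gkC[[nm]], tolerance = 1e-13,
                     info = paste(nm, V, camp))
      }
    }
  }
})

test_that("steady-state monotonicity over the physiological range", {
  p <- neuron_parameters()
  V <- seq(-120, 60, by = 0.25)
  gk <- gate_kinetics(V, p)
  expect_true(all(diff(gk$w_inf) > 0))
  expect_true(all(diff(gk$h_inf) < 0))
  expect_true(all(diff(gk$r_inf) < 0))
  expect_true(all(diff(gk$m_inf) > 0))
})

test_that("analytic kinetics derivatives match numerical differentiation", {
  p <- neuron_parameters()
  V <- c(-80, -60, -40, -20, 0)
  d <- camposc:::gate_kinetics_deriv(V, p)
  eps <- 1e-5
  gp <- gate_kinetics(V + eps, p)
  gm <- gate_kinetics(V - eps, p)
  num <- function(nm) (gp[[nm]] - gm[[nm]]) / (2 * eps)
  expect_equal(d$dm_inf, num("m_inf"), tolerance = 1e-7)
  expect_equal(d$dh_inf, num("h_inf"), tolerance = 1e-7)
  expect_equal(d$ds_inf, num("s_inf"), tolerance = 1e-7)
  expect_equal(d$dtau_h, num("tau_h"), tolerance = 1e-6)
  dp <- camposc:::gate_kinetics_deriv(V + eps, p)
  dm <- camposc:::gate_kinetics_deriv(V - eps, p)
  expect_equal(d$dA, (dp$A - dm$A) / (2 * eps), tolerance = 1e-4)
  expect_equal(d$dB, (dp$B - dm$B) / (2 * eps), tolerance = 1e-7)
})

test_that("ionic currents reproduce the closed-form examples", {
  p1 <- neuron_parameters(cAMP = 1)
  ic <- ionic_currents(c(-60, 0.5, 0.1, 0.5, 0.1), p1)
  expect_equal(unname(ic["I_HCN"]), (23 + 12) * 0.5 * (-60 + 50))
  expect_equal(unname(ic["I_HCN"]), -175)
  ic2 <- ionic_currents(c(-50, 0.5, 0.1, 0.5, 0.1), p1)
  expect_equal(unname(ic2["I_M"]), (50 + 50) * 0.1 * (-50 + 84))
  expect_equal(unname(ic2["I_M"]), 340)
  # zero driving force for the leak
  icL <- ionic_currents(c(neuron_parameters()$EL, 0.5, 0.1, 0.5, 0.1),
                        neuron_parameters())
  expect_equal(unname(icL["I_L"]), 0)
})

test_that("the 5D right-hand side vanishes at a constructed equilibrium", {
  p <- neuron_parameters()
  V <- -70
  gk <- gate_kinetics(V, p)
  st <- c(V, gk$h_inf, gk$s_inf, gk$r_inf, gk$w_inf)
  p$IApp <- sum(ionic_currents(st, p))
  expect_equal(max(abs(rhs_5d(0, st, p))), 0, tolerance = 1e-12)
})

test_that("rhs matches finite differences of the integrated flow", {
  p <- condition_params("CGS", IApp = 250)
  ic <- default_ic(p)
  delta <- 1e-4
  res <- camposc:::cpp_sim5(camposc:::as_par_vector(p), as.numeric(ic),
                            delta, 1e-6, 1L)
  fd <- (res$y[nrow(res$y), ] - res$y[1, ]) / delta
  mid <- (res$y[nrow(res$y), ] + res$y[1, ]) / 2
  expect_equal(fd, as.numeric(rhs_5d(0, mid, p)), tolerance = 1e-6)
})

test_that("with HCN and M silenced the rhs reduces to the 3-current core", {
  p <- neuron_parameters(gHCN = 0, dgHCN = 0, gM = 0, dgM = 0, IApp = 100)
  st <- c(-55, 0.4, 0.2, 0.3, 0.2)
  ic <- ionic_currents(st, p)
  expect_equal(unname(ic["I_HCN"]), 0)
  expect_equal(unname(ic["I_M"]), 0)
  dv <- rhs_5d(0, st, p)[1]
  expect_equal(dv, (-(ic["I_NaF"] + ic["I_NaP"] + ic["I_KS"] + ic["I_L"]) +
                      p$IApp) / p$Cm, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cAMP with zero increments only shifts the HCN activation", {
  p0 <- neuron_parameters(dgHCN = 0, dgM = 0, cAMP = 0)
  p1 <- neuron_parameters(dgHCN = 0, dgM = 0, cAMP = 1)
  st <- c(-58, 0.4, 0.2, 0.3, 0.2)
  expect_identical(ionic_currents(st, p0), ionic_currents(st, p1))
  gk0 <- gate_kinetics(-58, p0)
  gk1 <- gate_kinetics(-58, p1)
  expect_false(isTRUE(all.equal(gk0$r_inf, gk1$r_inf)))
  for (nm in c("m_inf", "n_inf", "h_inf", "s_inf", "w_inf", "tau_h",
               "tau_s", "tau_w")) {
    expect_identical(gk0[[nm]], gk1[[nm]])
  }
})

test_that("parameters round-trip through the flat text format", {
  p <- condition_params("ZD+CGS", IApp = 212.5)
  f <- withr::local_tempfile(fileext = ".txt")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(unclass(q)[camposc:::PAR_NAMES], unclass(p)[camposc:::PAR_NAMES])
  expect_true(any(grepl("^gNaF = ", readLines(f))))
})
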