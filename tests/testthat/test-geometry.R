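# Geometry fixtures: elevated-cAMP condition at 250 uA/cm^2, the showcase
# folded-node regime.
geom_pars <- function() condition_params("CGS", IApp = 250)
geom_red <- function() cgs250_reduced()
geom_fn <- function() fixture("geom_fn", {
  red <- geom_red()
  fs <- folded_singularities(geom_pars(), red$w_tilde, red$r_tilde)
  Filter(function(x) x$class == "folded node" && x$branch == "L-", fs)[[1]]
})

test_that("the critical manifold solves the voltage equation identically", {
  p <- geom_pars(); red <- geom_red()
  V <- seq(-80, 10, length.out = 60)
  V <- V[abs(V - p$EK) > 2]
  h <- seq(0.05, 0.95, length.out = 40)
  gr <- expand.grid(V = V, h = h)
  g <- gamma_manifold(gr$V, gr$h, p, red$w_tilde, red$r_tilde)
  f <- vapply(seq_len(nrow(gr)), function(i)
    rhs_3d(0, c(gr$V[i], gr$h[i], g$s[i]), p, red$w_tilde, red$r_tilde)[1],
    numeric(1))
  # residual relative to the current scale (currents reach ~1e4 uA/cm^2)
  expect_lt(max(abs(f * p$Cm)), 1e-10 * 1e4)
  expect_error(gamma_manifold(p$EK, 0.5, p, 0.1, 0.1), "singular")
})

test_that("the manifold decomposition matches an independent root-solve", {
  p <- geom_pars(); red <- geom_red()
  for (V in c(-75.3, -64.2, -50.8, -31.4)) {
    for (h in c(0.08, 0.41, 0.87)) {
      g <- gamma_manifold(V, h, p, red$w_tilde, red$r_tilde)
      expect_equal(g$s,
                   g$gamma0 + g$gamma_rt + g$gamma_wt + g$gamma_rtheta,
                   tolerance = 1e-14)
      s_star <- stats::uniroot(function(s)
        rhs_3d(0, c(V, h, s), p, red$w_tilde, red$r_tilde)[1],
        c(g$s - 1, g$s + 1), tol = 1e-14)$root
      expect_equal(g$s, s_star, tolerance = 1e-12)
    }
  }
  # limiting structure: shifts vanish with the channels
  g0 <- gamma_manifold(-60, 0.3, p, 0, 0)
  expect_equal(g0$s, g0$gamma0, tolerance = 1e-14)
  expect_equal(g0$gamma_rt, 0)
  expect_equal(g0$gamma_wt, 0)
  # gamma_rt component at the default conductances
  g2 <- gamma_manifold(-60, 0.3, p, 0, 0.2)
  expect_equal(g2$gamma_rt, -(23 / 40) * 0.2)
  expect_equal(g2$gamma_rt, -0.115)
})

test_that("fold curves satisfy the tangency identity and split the sheets", {
  p <- geom_pars(); red <- geom_red()
  fc <- fold_curves(p, red$w_tilde, red$r_tilde)
  expect_true(all(c("L-", "L+") %in% fc$branch))
  dfv <- camposc:::dfdV_3d(fc$V, fc$h, fc$s, p, red$w_tilde, red$r_tilde)
  expect_lt(max(abs(dfv)), 1e-8)
  # psi_r vanishes without HCN activation
  ps0 <- fold_psi(c(-70, -60), p, r_tilde = 0)
  expect_equal(ps0$psi_r, c(0, 0))
  expect_equal(ps0$h, ps0$psi0)
  # hyperpolarized side of L- is attracting, depolarized side repelling
  i <- which(fc$branch == "L-")[50]
  expect_equal(sheet_classify(fc$V[i] - 1, fc$h[i], p, red$w_tilde,
                              red$r_tilde), "attracting")
  expect_equal(sheet_classify(fc$V[i] + 1, fc$h[i], p, red$w_tilde,
                              red$r_tilde), "repelling")
})

test_that("ordinary singularities are the 3D equilibria", {
  p <- geom_pars(); red <- geom_red()
  os <- ordinary_singularities(p, red$w_tilde, red$r_tilde)
  expect_equal(nrow(os), 1)
  eq <- find_equilibrium_3d(p, red$w_tilde, red$r_tilde)
  expect_lt(abs(os$V[1] - eq$V), 1e-8)
  expect_lt(max(abs(rhs_3d(0, c(os$V[1], os$h[1], os$s[1]), p,
                           red$w_tilde, red$r_tilde))), 1e-9)
  # in the MMO regime the equilibrium is unstable and distinct from the FN
  expect_false(eq$stable)
  fn <- geom_fn()
  expect_gt(abs(os$V[1] - fn$V), 1e-3)
})

test_that("the desingularized flow vanishes at both singularity types", {
  p <- geom_pars(); red <- geom_red()
  os <- ordinary_singularities(p, red$w_tilde, red$r_tilde)
  d_eq <- desingularized_rhs(os$V[1], os$h[1], p, red$w_tilde, red$r_tilde)
  expect_lt(max(abs(d_eq)), 1e-7)
  fn <- geom_fn()
  d_fn <- desingularized_rhs(fn$V, fn$h, p, red$w_tilde, red$r_tilde)
  expect_lt(abs(d_fn[, "dV"]), 1e-7)
  # the folded singularity lies on the fold (where the time-rescaling
  # factor, hence the dh component, vanishes identically) ...
  expect_lt(abs(fn$h - fold_psi(fn$V, p, red$r_tilde)$h), 1e-10)
  expect_lt(abs(d_fn[, "dh"]), 1e-6)
  # ... but it is not an equilibrium: the slow flow itself is nonzero
  gk_fn <- gate_kinetics(fn$V, p)
  expect_gt(abs((fn$h - gk_fn$h_inf) / gk_fn$tau_h), 1e-6)
})

test_that("a folded node exists at elevated cAMP and is robust", {
  fn <- geom_fn()
  expect_equal(fn$class, "folded node")
  ev <- Re(fn$eigenvalues)
  expect_true(all(Im(fn$eigenvalues) == 0))
  expect_gt(prod(ev), 0)
  expect_gt(fn$mu, 0)
  expect_lt(fn$mu, 1)
  # the node persists under +-5% perturbation of the frozen gates
  p <- geom_pars(); red <- geom_red()
  for (f in list(c(0.95, 1), c(1.05, 1), c(1, 0.95), c(1, 1.05))) {
    fs <- folded_singularities(p, red$w_tilde * f[1], red$r_tilde * f[2])
    nodes <- Filter(function(x) x$class == "folded node" &&
                      x$branch == "L-", fs)
    expect_gte(length(nodes), 1)
  }
})

test_that("the strong canard passes through the folded node", {
  p <- geom_pars(); red <- geom_red()
  fn <- geom_fn()
  sc <- strong_canard(fn, p, red$w_tilde, red$r_tilde)
  expect_equal(sc$index, 0L)
  d <- sqrt((sc$orbit$V - fn$V)^2 + (sc$orbit$h - fn$h)^2)
  expect_lt(min(d), 2e-3)
  expect_gt(diff(range(sc$orbit$V)), 10)   # extends well beyond the node
  expect_error(strong_canard(list(class = "folded saddle"), p,
                             red$w_tilde, red$r_tilde), "folded node")
})

test_that("slow-manifold reconstruction yields ordered canards and the
           singular strong canard agrees with the funnel boundary", {
  p <- geom_pars(); red <- geom_red()
  recon <- fixture("recon250", {
    reconstruct_slow_manifolds(p, red$w_tilde, red$r_tilde)
  })
  idx <- vapply(recon$canards, function(x) x$index, integer(1))
  expect_gte(length(idx), 5)
  expect_equal(idx[1:5], 0:4)
  hs <- vapply(recon$canards, function(x) x$h_seed, numeric(1))
  expect_true(all(diff(hs[1:5]) > 0))
  expect_gt(nrow(recon$attracting), 10)
  # the singular-limit strong canard crosses the seed section close to the
  # finite-epsilon funnel boundary found by the staircase
  fn <- geom_fn()
  sc <- strong_canard(fn, p, red$w_tilde, red$r_tilde)
  o <- sc$orbit
  i <- which((o$V[-1] >= recon$seed_V) != (o$V[-nrow(o)] >= recon$seed_V))
  expect_gte(length(i), 1)
  expect_lt(min(abs(o$h[i] - recon$canards[[1]]$h_seed)), 0.01)
})

test_that("rotational sectors predict the simulated SAO counts", {
  p <- geom_pars(); red <- geom_red()
  recon <- fixture("recon250", {
    reconstruct_slow_manifolds(p, red$w_tilde, red$r_tilde)
  })
  tr3 <- integrate_model("3D", p, t_end = 1000, w_tilde = red$w_tilde,
                         r_tilde = red$r_tilde)
  rs <- rotational_sectors(recon, tr3, t_min = 400)
  expect_gt(nrow(rs), 10)
  expect_true(all(rs$predicted == rs$observed))
})
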