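co <- conductances()   # g_l 0.03, g_rep 0.1, g_err 0.06, g_den 0.1, g_nudge 0.06

test_that("derived conductance quantities follow their definitions", {
  expect_equal(co$g_tot, 0.19)
  expect_equal(co$tau_m_r, 1 / 0.19)
  expect_equal(co$tau_m_E_hidden, 1 / 0.13)
  expect_equal(co$tau_m_E_output, 1 / 0.09)
  expect_error(conductances(g_l = -0.1), ">= 0")
  expect_error(conductances(C_m = 0), "positive")
})

test_that("compartment potentials sum weighted rates and local errors", {
  net <- chain_net(c(1, 1))
  net$W[[1]]$mat <- matrix(2)
  net$L_RE[[2]] <- matrix(1)
  rates <- list(0.5, 0)
  rates_E <- list(numeric(1), 0.25)
  cp <- compartment_potentials(net, rates, rates_E, 2)
  expect_equal(cp$u_pred, 1.0)
  expect_equal(cp$u_err, 0.25)
  # all rates zero -> both compartments zero
  cp0 <- compartment_potentials(net, list(0, 0), list(0, 0), 2)
  expect_identical(cp0$u_pred, 0)
  expect_identical(cp0$u_err, 0)
  # dimension mismatch names both areas
  net$W[[1]]$mat <- matrix(0, 1, 3)
  expect_error(compartment_potentials(net, rates, rates_E, 2),
               "block 2 <- 1.*source area 1")
})

test_that("one Euler step matches the hand-computed update", {
  stp <- representation_step(u_som = 0, u_pred = 1, u_err = 0, co, dt = 0.01)
  expect_equal(stp$u_som, 0.001)   # du = g_rep * 1 / C_m = 0.1; 0 + 0.01 * 0.1
  # rest state is a fixed point
  stp0 <- representation_step(0, 0, 0, co, dt = 0.01)
  expect_identical(stp0$u_som, 0)
  expect_identical(stp0$du_som, 0)
  expect_error(representation_step(1e308, 1e308, 1e308, co, dt = 1e10),
               "non-finite")
})

test_that("clamped drives relax the soma to the conductance-weighted fixed point", {
  net <- chain_net(c(1, 1))
  net$W[[1]]$mat <- matrix(2)      # u_pred = 2 * input
  st <- mc_settle(net, input = 0.5, n_ticks = 40000)
  expect_equal(st$u_som[[2]], 0.1 / 0.19, tolerance = 1e-6)
  # convex-combination bound: steady u_som between 0 and u_pred
  expect_gt(st$u_som[[2]], 0)
  expect_lt(st$u_som[[2]], st$u_pred[[2]])
})

test_that("prospective rates follow phi(u + tau_r * du/dt)", {
  ident <- activation_fn("linear")
  expect_equal(prospective_rate(0.5, 2, 0.25, ident), 1.0)
  expect_equal(prospective_rate(0.5, 2, 0, ident), 0.5)            # retrospective
  expect_equal(prospective_rate(c(1, -1), c(0, 0), 5,
                                activation_fn("tanh")), tanh(c(1, -1)))
})

test_that("error units settle to their conductance-weighted dendritic drive", {
  lin <- activation_fn("linear")
  # hidden: L^ER = 1, phi' = 1, incoming error 1 -> e = g_den / (g_l + g_den)
  e <- 0
  for (t in 1:20000) {
    es <- error_step(e, dend = 1, co, "hidden", dt = 0.01,
                     tau_r_E = co$tau_m_E_hidden, act = lin)
    e <- es$e_som
  }
  expect_equal(e, 0.1 / 0.13, tolerance = 1e-6)
  expect_equal(es$r_E, 0.1 / 0.13, tolerance = 1e-6)  # linear: r_E = e_prosp
  # no incoming error -> silent
  es0 <- error_step(0, dend = 0, co, "hidden", 0.01, co$tau_m_E_hidden, lin)
  expect_identical(es0$e_som, 0)
  # output mode linearity: doubling the mismatch doubles the steady state
  settle_out <- function(mismatch) {
    e <- 0
    for (t in 1:20000)
      e <- error_step(e, dend = mismatch, co, "output", 0.01,
                      co$tau_m_E_output, lin)$e_som
    e
  }
  expect_equal(settle_out(0), 0)
  expect_equal(settle_out(1.0) * 2, settle_out(2.0), tolerance = 1e-9)
})

test_that("closed-form steady-state errors match the two-area hand recursion", {
  net <- chain_net(c(1, 1))
  # linear phi, identity L, B = [[1]]
  net$B[[1]]$mat <- matrix(1)
  ess <- steady_state_errors(net, phi_p_by_area = list(1, 1), mismatch = 0.5)
  expect_equal(ess[[2]], 0.06 / 0.09 * 0.5, tolerance = 1e-12)          # 0.3333
  expect_equal(ess[[1]], 0.1 / 0.13 * ess[[2]], tolerance = 1e-12)      # 0.2564
  # zero mismatch and saturated-derivative silencing
  expect_equal(unlist(steady_state_errors(net, list(1, 1), 0)), c(0, 0))
  expect_equal(steady_state_errors(net, list(0, 1), 0.7)[[1]], 0)
})

test_that("simulated equilibrium errors match the closed form on a 3-area chain", {
  net <- chain_net(c(3, 3, 2), act = "tanh", sigma_L = 0.2, b_noise = 0.3,
                   seed = 7)
  set.seed(7)
  inp <- runif(3, -1, 1); tgt <- runif(2, -0.5, 0.5)
  st <- mc_settle(net, inp, tgt, n_ticks = 20000)
  ess <- steady_state_errors(net, st$phi_p, tgt - st$r_r[[3]])
  expect_lt(max(abs(unlist(ess) - unlist(st$e_prosp))), 1e-5)
})

test_that("rest state is conserved exactly when all couplings vanish", {
  # sigmoid rates are nonzero at rest; with W, B and L all zero the
  # voltages must still stay exactly 0
  net <- chain_net(c(2, 3, 2), act = "sigmoid")
  for (i in seq_along(net$W)) net$W[[i]]$mat[] <- 0
  for (i in seq_along(net$B)) { net$B[[i]]$mat[] <- 0; net$B[[i]]$Xi[] <- 0 }
  for (l in 1:3) { net$L_RE[[l]][] <- 0; net$L_ER[[l]][] <- 0 }
  res <- run_r_ticks(net, input = c(0, 0), target = NULL, n = 50)
  expect_identical(state_max_abs(res$state), 0)
})

test_that("prospective compensation tracks a sinusoidal drive with <= 1 tick lag", {
  net <- chain_net(c(1, 1))
  net$W[[1]]$mat <- matrix(1)
  lam <- co$g_rep / co$g_tot
  st <- mc_state(net)
  drive <- sin(2 * pi * (1:400) / 200)        # period 200 dt >> dt
  r_out <- numeric(400)
  for (t in 1:400) {
    st <- mc_tick(net, st, drive[t])$state
    r_out[t] <- st$r_r[[2]]
  }
  # with tau_r = tau_m and no errors, the rate equals the attenuated
  # instantaneous drive of the previous tick exactly
  expect_equal(r_out[2:400], lam * drive[1:399], tolerance = 1e-10)
})

test_that("compiled core reproduces the reference tick to machine precision", {
  net <- mc_network(area_graph(c(4, 3, 2)), eta = 0.5, sigma_L = 0.3,
                    b_noise = 0.5, act = "tanh", seed = 42)
  set.seed(1)
  inp <- runif(4, -1, 1); tgt <- runif(2, -0.5, 0.5)
  ref <- run_r_ticks(net, inp, tgt, n = 50, plasticity = TRUE)
  res <- errnet:::.mc_present_cpp(net, mc_state(net), matrix(inp, ncol = 1),
                                  tgt, NULL, 50, TRUE)
  expect_equal(unlist(ref$state$u_som), unlist(res$state$u_som),
               tolerance = 1e-12)
  expect_equal(unlist(ref$state$e_prosp), unlist(res$state$e_prosp),
               tolerance = 1e-12)
  expect_equal(unlist(lapply(ref$net$W, `[[`, "mat")),
               unlist(lapply(res$net$W, `[[`, "mat")), tolerance = 1e-12)
  expect_equal(unlist(lapply(ref$net$B, `[[`, "mat")),
               unlist(lapply(res$net$B, `[[`, "mat")), tolerance = 1e-12)
})

test_that("degenerate areas without error units are simulated with u_err = 0", {
  g <- area_graph(c(2, 2, 1), n_E = c(0, 2, 1))
  net <- mc_network(g, eta = 0.1, seed = 3, act = "tanh")
  res <- run_r_ticks(net, input = c(0.3, -0.2), target = 0.4, n = 30,
                     plasticity = TRUE)
  expect_identical(res$state$u_err[[1]], c(0, 0))
  expect_identical(res$state$e_som[[1]], numeric(0))
})
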