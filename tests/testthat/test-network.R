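test_that("connectivity construction enforces the density rules", {
  # sub-threshold entries are rounded down to zero
  d <- matrix(0, 3, 3); d[1, 2] <- 0.005; d[2, 3] <- 0.5
  g <- area_graph(c(2, 2, 2), mode = "classifier", hierarchy = "skip",
                  density = d)
  expect_equal(g$density[1, 2], 0)
  conn <- build_connectivity(g)
  expect_equal(length(conn$W), 1L)          # only the 2 -> 3 block survives
  # strict preset on 3 areas: exactly two forward blocks
  gs <- area_graph(c(2, 2, 2), hierarchy = "strict")
  expect_equal(length(build_connectivity(gs)$W), 2L)
  # nonzero diagonal rejected
  dd <- diag(3); expect_error(area_graph(c(2, 2, 2), density = dd), "diagonal")
})

test_that("initial weight scales follow the density ratio", {
  d <- matrix(0, 3, 3); d[1, 2] <- 0.9; d[2, 3] <- 0.3   # ratio 3
  g <- area_graph(c(40, 40, 40), mode = "classifier", hierarchy = "skip",
                  density = d)
  set.seed(21)
  conn <- build_connectivity(g)
  ratio <- sd(conn$W[[1]]$mat) / sd(conn$W[[2]]$mat)
  expect_equal(ratio, 3, tolerance = 0.1)
})

test_that("mode configuration swaps input and target ends and is an involution", {
  g <- area_graph(c(10, 5, 3), mode = "classifier")
  expect_equal(c(g$input_area, g$target_area), c(1L, 3L))
  gg <- configure_mode(g, "generative")
  expect_equal(c(gg$input_area, gg$target_area), c(3L, 1L))
  expect_identical(configure_mode(gg, "classifier"), g)
  # generative image task: one-hot latent clamped deep, pixels at the front
  gen <- generative_network(side = 4, hidden = 8, seed = 1)
  expect_equal(gen$n_R[gen$input_area], 10L)
  expect_equal(gen$n_R[gen$target_area], 16L)
})

test_that("training runs are bit-reproducible from the seed", {
  run <- function() {
    set.seed(31)
    task <- generate_teacher_student(1)
    net <- ts_network(c(2, 1), eta = 2)
    mc_fit(net, task$train, epochs = 3, eval_data = task$test, eval_every = 1)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$record, f2$record)
  expect_identical(coef(f1), coef(f2))
})

test_that("a skip network with zero skip densities equals the strict network", {
  d <- matrix(0, 3, 3)
  d[cbind(1:2, 2:3)] <- 1; d[cbind(2:3, 1:2)] <- 1
  build <- function(hier, dens = NULL) {
    g <- area_graph(c(3, 2, 1), hierarchy = hier, density = dens)
    mc_network(g, eta = 0.5, act = "tanh", sigma_L = 0.2, b_noise = 0.3,
               seed = 77)
  }
  net_skip <- build("skip", d)
  net_strict <- build("strict")
  expect_identical(lapply(net_skip$W, `[[`, "mat"),
                   lapply(net_strict$W, `[[`, "mat"))
  set.seed(5)
  ds <- mc_dataset(matrix(runif(15, 0, 1), 5, 3), matrix(runif(5), 5, 1),
                   T_pres = 0.2)
  f1 <- mc_fit(net_skip, ds, epochs = 2)
  f2 <- mc_fit(net_strict, ds, epochs = 2)
  expect_identical(coef(f1), coef(f2))
})

test_that("ablation semantics: zeroed, frozen, idempotent, unknown rejected", {
  net <- generative_network(side = 3, hidden = c(4, 4), hierarchy = "skip",
                            seed = 2)
  idx <- which(vapply(net$W, function(b) b$src == 2 && b$tgt == 1, NA))
  net2 <- ablate_projection(net, src = 2, tgt = 1)
  expect_true(all(net2$W[[idx]]$mat == 0))
  expect_equal(net2$W[[idx]]$eta, 0)
  expect_false(net2$W[[idx]]$plastic)
  expect_identical(ablate_projection(net2, 2, 1)$W, net2$W)   # no-op
  expect_error(ablate_projection(net, src = 1, tgt = 4), "no projection")
  # strict network with its only input ablated still simulates, u_pred = 0
  nets <- chain_net(c(2, 1), act = "tanh", seed = 3)
  nets <- ablate_projection(nets, 1, 2)
  res <- run_r_ticks(nets, input = c(1, -1), n = 20)
  expect_identical(res$state$u_pred[[2]], 0)
})

test_that("activation variability draws per-neuron slopes and offsets", {
  net <- generative_network(side = 3, hidden = 4, seed = 4)
  expect_identical(apply_variability(net, 0, "both"), net)
  set.seed(9)
  wide <- mc_network(area_graph(c(2, 10000), n_E = c(0, 0)), act = "tanh",
                     sigma_L = 0, b_noise = 0, eta = 0, seed = 4)
  big <- apply_variability(wide, 0.2, "representation")
  slopes <- big$act_r[[2]]$slope
  expect_equal(mean(slopes), 1, tolerance = 0.05)
  expect_equal(sd(slopes), 0.2, tolerance = 0.02)
  # linear error units with offsets: rates become a * e + b
  set.seed(10)
  nv <- apply_variability(net, 0.5, "error")
  a <- nv$act_e[[1]]$slope; b <- nv$act_e[[1]]$offset
  e <- rnorm(nv$n_E[1])
  expect_equal(phi(nv$act_e[[1]], e), a * e + b)
})

test_that("zero weights and zero input leave every recorded voltage at zero", {
  net <- chain_net(c(2, 2), act = "linear")
  for (i in seq_along(net$W)) net$W[[i]]$mat[] <- 0
  set.seed(1)
  ds <- mc_dataset(matrix(0, 3, 2), matrix(0, 3, 2), T_pres = 0.2)
  fit <- mc_fit(net, ds, epochs = 2, plasticity = FALSE)
  expect_identical(state_max_abs(fit$state), 0)
  expect_true(all(fit$record$value == 0))
})

test_that("a [2-1] student distils its teacher within the first epochs", {
  med <- sapply(1:5, function(s) {
    set.seed(s)
    task <- generate_teacher_student(1)
    net <- ts_network(c(2, 1), eta = 2)
    fit <- mc_fit(net, task$train, epochs = 10, eval_data = task$test,
                  eval_every = 1)
    subset(fit$record, split == "test")$value
  })
  med_curve <- apply(med, 1, median)
  expect_true(all(diff(med_curve) < 0))     # monotone decrease over 10 epochs
})
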