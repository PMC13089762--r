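# --- cart pole and LQR ------------------------------------------------------

test_that("the upright cart pole is an equilibrium and 70 degrees resets", {
  p <- cartpole_params()
  stp <- cartpole_step(c(0, 0, 0, 0), F = 0, p)
  expect_equal(stp$state, c(0, 0, 0, 0))
  expect_false(stp$reset)
  expect_true(cartpole_step(c(0, 0, 71 * pi / 180, 0), 0, p)$reset)
  expect_false(cartpole_step(c(0, 0, 60 * pi / 180, 0), 0, p)$reset)
})

test_that("plant integration error is first order against a fine-step oracle", {
  # the upright pole is exponentially unstable, so absolute coarse-fine
  # differences grow along the trajectory; the honest invariant is Euler's
  # O(dt) convergence: halving dt halves the error against a 40x-finer
  # reference
  p <- cartpole_params()
  run <- function(dt) {
    s <- c(0, 0, 0.05, 0)
    for (k in seq_len(round(0.5 / dt))) s <- cartpole_step(s, 0, p, dt)$state
    s
  }
  ref <- run(0.0005)
  d1 <- max(abs(run(0.02) - ref))
  d2 <- max(abs(run(0.01) - ref))
  expect_gt(d1 / d2, 1.6)
  expect_lt(d1 / d2, 2.6)
  expect_lt(d1, 0.05)
})

test_that("the Riccati gain matches an independent Newton-Kleinman oracle", {
  ctrl <- lqr_gain()
  expect_true(all(ctrl$eig_mod < 1))
  # Newton-Kleinman policy iteration on the discrete-time system:
  # iterate K_j -> P_j (Lyapunov solve) -> K_{j+1}
  Ad <- ctrl$Ad; Bd <- ctrl$Bd; Q <- diag(c(1, 1, 10, 1)); R <- 5
  K <- ctrl$K * 0.9                               # stabilising warm start
  for (j in 1:60) {
    Ak <- Ad - Bd %*% K
    M <- Q + t(K) %*% R %*% K
    # vec(P) solve of P = Ak' P Ak + M
    P <- matrix(solve(diag(16) - kronecker(t(Ak), t(Ak)), as.numeric(M)), 4, 4)
    K <- solve(R + t(Bd) %*% P %*% Bd, t(Bd) %*% P %*% Ad)
  }
  expect_lt(max(abs(K - ctrl$K)), 1e-8)
})

test_that("the LQR teacher dataset respects its input box and linear law", {
  ctrl <- lqr_gain()
  expect_equal(drop(-ctrl$K %*% numeric(4)), 0)   # zero state, zero force
  set.seed(2)
  ds <- lqr_teacher_dataset(ctrl, n = 200)
  expect_true(all(abs(ds$inputs) <= 1.5))
  expect_equal(ds$targets, -ds$inputs %*% t(ctrl$K))
  bad <- ctrl; bad$eig_mod <- c(1.2, 0.5, 0.5, 0.5)
  expect_error(lqr_teacher_dataset(bad, 10), "stabilise")
})

test_that("the LQR closed loop never resets from moderate tilts", {
  ctrl <- lqr_gain()
  set.seed(3)
  for (i in 1:20) {
    s0 <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -pi / 6, pi / 6),
            runif(1, -1, 1))
    roll <- cartpole_rollout(function(s) -drop(ctrl$K %*% s),
                             inits = matrix(s0, 1), reset_every = 100)
    expect_equal(roll$penalty, 0)
  }
})

# --- delayed match-to-sample ------------------------------------------------

test_that("match-to-sample trials implement the temporal XNOR exactly", {
  set.seed(4)
  ds <- generate_dms(50)
  cond <- attr(ds, "condition")
  sgn <- sign(ds$targets[, 1])
  expect_true(all(sgn[cond %in% c("upup", "downdown")] == 1))
  expect_true(all(sgn[cond %in% c("updown", "downup")] == -1))
  # condition balance at n = 50: 13/13/12/12
  expect_true(all(table(cond) <= 13))
  expect_equal(sum(table(cond)), 50)
})

test_that("trial durations and target windows follow the protocol", {
  set.seed(5)
  ds <- generate_dms(40)
  dur <- attr(ds, "duration")
  expect_true(all(dur >= 800 & dur <= 1000))
  # stim2 window: nudging covers exactly the final 250-tick stage
  expect_equal(ds$active_from, dur - 250L + 1L)
  # literal final-step reading: active at the nominal last tick only,
  # with held frames appended
  set.seed(5)
  dsf <- generate_dms(5, target_window = "final", post_target_ticks = 3)
  durf <- attr(dsf, "duration")
  expect_equal(dsf$active_from, durf)
  expect_equal(vapply(dsf$inputs, ncol, 0L), durf + 3L)
})

# --- Yin-Yang ----------------------------------------------------------------

test_that("yin-yang inputs use the mirrored four-dimensional encoding", {
  set.seed(6)
  ds <- generate_yinyang(200)
  expect_equal(ds$inputs[, 1] + ds$inputs[, 3], rep(1, 200))
  expect_equal(ds$inputs[, 2] + ds$inputs[, 4], rep(1, 200))
  expect_true(all(rowSums(ds$targets) == 1))
})

test_that("yin-yang geometry labels dot centres and balances classes", {
  # points at the dot centres are class 3
  r <- 0.5
  d_centered <- c(0.5 + r / 2, 0.5)
  # classify via a large sample: nearest sampled point to the dot centre
  set.seed(7)
  ds <- generate_yinyang(10000)
  cls <- attr(ds, "class_id")
  near_dot <- which((ds$inputs[, 1] - d_centered[1])^2 +
                      (ds$inputs[, 2] - d_centered[2])^2 < (r / 8)^2)
  expect_true(all(cls[near_dot] == 3L))
  props <- table(cls) / length(cls)
  expect_true(all(props >= 0.25 & props <= 0.42))
})

# --- teacher-student ---------------------------------------------------------

test_that("teacher-student datasets are self-consistent and reproducible", {
  set.seed(8)
  task <- generate_teacher_student(1)
  expect_equal(task$teacher$sizes, c(2, 1))       # complexity 1 is [2-1]
  # a student with the teacher's exact weights has zero test error
  expect_equal(evaluate_outputs(ann_forward_batch(task$teacher,
                                                  task$test$inputs),
                                task$test$targets, "mse_loss"), 0)
  expect_true(all(task$train$inputs >= 0 & task$train$inputs <= 1))
  expect_gte(var(as.numeric(task$train$targets)), 1e-3)
  set.seed(8)
  task2 <- generate_teacher_student(1)
  expect_identical(task$train$inputs, task2$train$inputs)
  expect_identical(task$train$targets, task2$train$targets)
})

# --- image generation --------------------------------------------------------

test_that("synthetic image classes are deterministic, bounded and distinct", {
  t1 <- generate_image_task("synthetic", side = 8)
  t2 <- generate_image_task("synthetic", side = 8)
  expect_identical(t1$images, t2$images)
  px <- unlist(t1$images)
  expect_true(all(px >= 0 & px <= 1))
  for (i in 1:9) for (j in (i + 1):10)
    expect_gt(mean((t1$images[[i]] - t1$images[[j]])^2), 0)
  expect_identical(t1$data$inputs, diag(10))
})

test_that("the external image loader validates the class set", {
  side <- 4
  tmp <- tempfile(fileext = ".csv")
  imgs <- matrix(runif(10 * side^2), 10, side^2)
  write.table(cbind(0:9, imgs), tmp, sep = ",", row.names = FALSE,
              col.names = FALSE)
  ext <- generate_image_task("external", side = side, path = tmp)
  expect_equal(ext$images[[1]], matrix(imgs[1, ], side, side))
  bad <- tempfile(fileext = ".csv")
  write.table(cbind(0:8, imgs[1:9, ]), bad, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_error(generate_image_task("external", side = side, path = bad),
               "one image per class")
  expect_error(generate_image_task("external", side = side), "path")
})

test_that("datasets serialise to flat and long CSV", {
  set.seed(9)
  ds <- mc_dataset(matrix(runif(6), 3, 2), matrix(runif(3), 3, 1), T_pres = 1)
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, f)
  back <- read.csv(f)
  expect_equal(as.matrix(back[, 1:2]), ds$inputs, ignore_attr = TRUE)
  set.seed(9)
  dms <- generate_dms(2)
  f2 <- tempfile(fileext = ".csv")
  write_dataset_csv(dms, f2)
  long <- read.csv(f2)
  expect_equal(nrow(long), sum(vapply(dms$inputs, ncol, 0L)))
})
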